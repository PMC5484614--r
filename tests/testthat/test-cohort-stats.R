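test_that("densities and labelling indices pool fields per animal", {
  tab <- data.frame(
    litter = 1, animal = "a1", genotype = "control", field = c(1, 1, 2, 2),
    area_mm2 = 0.25,
    marker = c("CC1", "Pdgfra", "CC1", "Pdgfra"),
    count = c(100, 120, 200, 80))
  m <- count_metrics(tab, index_marker = NULL)
  expect_equal(m$density_CC1, 300 / 0.5)           # 600 cells/mm2
  expect_equal(m$density_Pdgfra, 200 / 0.5)
  # labelling index: 40 double-positive of 200 reference -> 20%
  tab2 <- rbind(tab, data.frame(litter = 1, animal = "a1",
                                genotype = "control", field = c(1, 2),
                                area_mm2 = 0.25, marker = "EdU_Pdgfra",
                                count = c(25, 15)))
  m2 <- count_metrics(tab2)
  expect_equal(m2$index_pct, 20)
  expect_error(count_metrics(transform(tab, area_mm2 = 0)), "positive")
})

test_that("densities are additive over fields (count-weighted pooling)", {
  syn <- simulate_histology_counts("dko", n_control = 4, n_mutant = 4,
                                   seed = 3)
  m <- count_metrics(syn)
  cc1 <- syn[syn$marker == "CC1", ]
  for (a in unique(cc1$animal)) {
    sa <- cc1[cc1$animal == a, ]
    per_field <- sa$count / sa$area_mm2
    pooled <- sum(sa$count) / sum(sa$area_mm2)
    expect_equal(m$density_CC1[m$animal == a],
                 sum(per_field * sa$area_mm2) / sum(sa$area_mm2))
    expect_equal(m$density_CC1[m$animal == a], pooled)
  }
})

test_that("litter normalization reproduces the worked example", {
  tab <- data.frame(litter = 1, genotype = c("control", "control", "mutant"),
                    fraction = c(0.20, 0.24, 0.262))
  out <- caspase_litter_normalization(tab)
  expect_equal(out$fold_change, 0.262 / 0.22, tolerance = 1e-12)  # 1.19
  expect_equal(out$control_mean, 0.22)
})

test_that("litter normalization is identity on homogeneous data and drops
           litters without controls", {
  tab <- data.frame(litter = rep(1:3, each = 2),
                    genotype = rep(c("control", "mutant"), 3),
                    fraction = 0.2)
  expect_equal(caspase_litter_normalization(tab)$fold_change, 1)
  tab2 <- rbind(tab, data.frame(litter = 4, genotype = "mutant",
                                fraction = 0.9))
  expect_message(out <- caspase_litter_normalization(tab2), "without controls")
  expect_equal(out$fold_change, 1)
  expect_equal(out$excluded_litters, "4")
  only_mut <- data.frame(litter = 1, genotype = "mutant", fraction = 0.2)
  expect_error(suppressMessages(caspase_litter_normalization(only_mut)),
               "no litter")
})

test_that("planted caspase fold-change is recovered across seeds", {
  folds <- vapply(1:12, function(s)
    caspase_litter_normalization(
      simulate_caspase_cohort("dko", seed = 500 + s))$fold_change,
    numeric(1))
  expect_equal(mean(folds), 1.194, tolerance = 0.02)
  expect_lt(sd(folds), 0.05)
})

test_that("compare_groups handles identical samples and picks gated tests", {
  same <- compare_groups(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(same$effect_pct, 0)
  expect_equal(same$p, 1)
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20, 1)
  g <- compare_groups(a, b)
  expect_match(g$test, "t-test")
  skewed <- compare_groups(exp(rnorm(30, 0, 1.5)), exp(rnorm(30, 0, 1.5)))
  expect_equal(skewed$test, "Mann-Whitney U")
  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
})

test_that("compare_groups detects a 27% difference at n = 14 with power >= 0.8", {
  # planted effect and dispersion of the histology generator (CV ~7%)
  set.seed(11)
  hits <- mean(replicate(200, {
    a <- rnorm(14, 1000, 70)
    b <- rnorm(14, 730, 51)
    compare_groups(a, b)$p < 0.05
  }))
  expect_gte(hits, 0.8)
})

test_that("type-I error of the gated test is nominal under the null", {
  set.seed(21)
  rej <- mean(replicate(1000, {
    compare_groups(rnorm(12), rnorm(12))$p < 0.05
  }))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("multi-group gate routes to ANOVA or Kruskal-Wallis + Dunn", {
  set.seed(3)
  gs <- list(a = rnorm(15), b = rnorm(15), c = rnorm(15, 2))
  m <- compare_multi(gs)
  expect_match(m$test, "ANOVA")
  expect_lt(m$p, 0.01)
  expect_equal(nrow(m$posthoc), 3)
  gs2 <- list(a = exp(rnorm(15, 0, 1.5)), b = exp(rnorm(15, 0, 1.5)),
              c = exp(rnorm(15, 2, 1.5)))
  m2 <- compare_multi(gs2)
  expect_match(m2$test, "Dunn")
  expect_true(all(m2$posthoc$p_adj <= 1))
})

test_that("step-down correction reproduces the stated multiplication rule", {
  expect_equal(holm_bonferroni_variant(0.03), 0.03)
  expect_equal(holm_bonferroni_variant(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_bonferroni_variant(c(0.04, 0.01)), c(0.04, 0.02))
  expect_error(holm_bonferroni_variant(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("with monotonicity the correction equals the Holm step-down oracle", {
  set.seed(5)
  for (k in 1:1000) {
    p <- runif(sample(1:8, 1))
    expect_equal(holm_bonferroni_variant(p), p.adjust(p, method = "holm"))
  }
})

test_that("corrected p-values never fall below raw ones and cap at 1", {
  set.seed(9)
  for (k in 1:50) {
    p <- runif(6)
    for (lit in c(TRUE, FALSE)) {
      cp <- holm_bonferroni_variant(p, literal = lit)
      expect_true(all(cp >= p - 1e-12))
      expect_true(all(cp <= 1))
    }
  }
  # the literal rule can invert ordering; the repaired one cannot
  p <- c(0.010, 0.035, 0.036)
  lit <- holm_bonferroni_variant(p, literal = TRUE)
  expect_gt(lit[2], lit[3])                     # inversion under the bare rule
  mono <- holm_bonferroni_variant(p)
  expect_true(all(diff(mono[order(p)]) >= 0))
})
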