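#' Per-animal densities and labelling indices from a count table
#'
#' Densities pool all fields of an animal: `density = sum(count) /
#' sum(area)` per marker (cells/mm²). The labelling index is the percentage
#' of a reference population positive for a second marker, pooled over
#' fields: `100 * sum(double positive) / sum(reference)`.
#'
#' @param table A `count_table` data.frame (`litter`, `animal`, `genotype`,
#'   `field`, `area_mm2`, `marker`, `count`).
#' @param index_marker,reference_marker Marker names for the labelling
#'   index (default EdU+Pdgfra+ of Pdgfra+); set `index_marker = NULL` to
#'   skip.
#' @return Data.frame, one row per animal: grouping columns, one
#'   `density_<marker>` column per marker, and `index_pct` (NA with a
#'   report when the reference count is zero).
#' @export
count_metrics <- function(table, index_marker = "EdU_Pdgfra",
                          reference_marker = "Pdgfra") {
  stopifnot(all(c("animal", "marker", "count", "area_mm2") %in% names(table)))
  if (any(table$count < 0)) stop("counts must be non-negative")
  if (any(table$area_mm2 <= 0)) stop("field areas must be positive")
  animals <- unique(table$animal)
  out <- do.call(rbind, lapply(animals, function(a) {
    ta <- table[table$animal == a, ]
    row <- data.frame(animal = a)
    for (col in intersect(c("litter", "genotype", "age"), names(ta)))
      row[[col]] <- ta[[col]][1]
    for (m in unique(ta$marker)) {
      tm <- ta[ta$marker == m, ]
      row[[paste0("density_", m)]] <- sum(tm$count) / sum(tm$area_mm2)
    }
    if (!is.null(index_marker) &&
        all(c(index_marker, reference_marker) %in% ta$marker)) {
      ref <- sum(ta$count[ta$marker == reference_marker])
      dbl <- sum(ta$count[ta$marker == index_marker])
      row$index_pct <- if (ref > 0) 100 * dbl / ref else NA_real_
    }
    row
  }))
  if (!is.null(out$index_pct) && anyNA(out$index_pct))
    message("labelling index undefined (zero reference count) for: ",
            paste(out$animal[is.na(out$index_pct)], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Litter-normalized apoptotic-fraction fold-change
#'
#' Implements the two-step litter normalization used for the cleaved
#' Caspase-3 data: (1) the control apoptotic fraction is averaged across
#' litters (mean of per-litter control means); (2) within each litter,
#' every animal is normalized to the mean of the controls of that same
#' litter (controls therefore average 1); (3) the normalized mutant values
#' are averaged across litters to give the fold-change. Litters without any
#' control animal cannot be normalized and are excluded with a report.
#'
#' @param table Data.frame with `litter`, `genotype`
#'   ("control" vs anything else), `fraction` (per-animal apoptotic
#'   fraction).
#' @return List: `control_mean` (cross-litter control average),
#'   `fold_change` (cross-litter mean of per-litter normalized mutant
#'   means), `per_litter` data.frame, `excluded_litters`.
#' @export
caspase_litter_normalization <- function(table) {
  stopifnot(all(c("litter", "genotype", "fraction") %in% names(table)))
  litters <- split(table, table$litter)
  has_ctrl <- vapply(litters, function(l) any(l$genotype == "control"),
                     logical(1))
  if (any(!has_ctrl))
    message("excluding litter(s) without controls: ",
            paste(names(litters)[!has_ctrl], collapse = ", "))
  litters <- litters[has_ctrl]
  if (length(litters) == 0) stop("no litter contains control animals")
  per <- do.call(rbind, lapply(litters, function(l) {
    cm <- mean(l$fraction[l$genotype == "control"])
    mut <- l$fraction[l$genotype != "control"]
    data.frame(litter = l$litter[1], control_mean = cm,
               n_mutant = length(mut),
               mutant_norm = if (length(mut)) mean(mut / cm) else NA_real_)
  }))
  rownames(per) <- NULL
  list(control_mean = mean(per$control_mean),
       fold_change = mean(per$mutant_norm[!is.na(per$mutant_norm)]),
       per_litter = per,
       excluded_litters = names(has_ctrl)[!has_ctrl])
}

#' Normality-gated two-group comparison
#'
#' The Shapiro–Wilk test (alpha = 0.05, per group) gates the test choice: if
#' both groups are consistent with normality a two-tailed Student's t-test
#' is used (with Welch's correction when an F-test of variances rejects at
#' alpha = 0.05); otherwise the Mann–Whitney U test. Groups with zero
#' variance (Shapiro–Wilk undefined) are routed to the rank test.
#'
#' @param a,b Numeric samples.
#' @param paired Paired comparison (t-test / Wilcoxon signed-rank).
#' @param alpha Gate level for normality and variance-equality tests.
#' @return List: `test`, `statistic`, `p`, `effect_pct`
#'   (`100 * (mean(b)/mean(a) - 1)`), `normal` (per-group gate results),
#'   `n`.
#' @export
compare_groups <- function(a, b, paired = FALSE, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  norm <- vapply(list(a, b), function(x) {
    if (length(x) < 3 || sd(x) == 0) return(FALSE)
    shapiro.test(x)$p.value >= alpha
  }, logical(1))
  if (all(norm)) {
    welch <- tryCatch(var.test(a, b)$p.value < alpha, error = function(e) TRUE)
    ht <- t.test(a, b, paired = paired, var.equal = !welch && !paired)
    test <- if (paired) "paired t-test"
            else if (welch) "Welch t-test" else "Student t-test"
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, paired = paired, exact = FALSE))
    test <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney U"
  }
  p <- ht$p.value
  if (is.nan(p) && identical(a, b)) p <- 1   # fully tied degenerate case
  list(test = test, statistic = unname(ht$statistic), p = p,
       effect_pct = 100 * (mean(b) / mean(a) - 1),
       normal = norm, n = c(length(a), length(b)))
}

#' Normality-gated multi-group comparison
#'
#' For three or more groups: one-way ANOVA with Bonferroni-corrected
#' pairwise t-tests when every group passes the Shapiro–Wilk gate,
#' otherwise Kruskal–Wallis with Dunn's post-hoc rank test
#' (Bonferroni-adjusted).
#'
#' @param groups Named list of numeric samples (>= 3 groups).
#' @param alpha Gate level.
#' @return List: `test`, `p` (omnibus), `posthoc` data.frame of pairwise
#'   adjusted p-values.
#' @export
compare_multi <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 3)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  norm <- vapply(groups, function(x)
    length(x) >= 3 && sd(x) > 0 && shapiro.test(x)$p.value >= alpha,
    logical(1))
  vals <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), lengths(groups)))
  if (all(norm)) {
    fit <- aov(vals ~ grp)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    ph <- stats::pairwise.t.test(vals, grp, p.adjust.method = "bonferroni")
    mat <- ph$p.value
    posthoc <- data.frame(
      a = rep(rownames(mat), ncol(mat)), b = rep(colnames(mat), each = nrow(mat)),
      p_adj = as.vector(mat))
    posthoc <- posthoc[!is.na(posthoc$p_adj), ]
    test <- "one-way ANOVA + Bonferroni"
  } else {
    kw <- kruskal.test(vals, grp)
    p <- kw$p.value
    posthoc <- dunn_posthoc(vals, grp)
    test <- "Kruskal-Wallis + Dunn"
  }
  list(test = test, p = p, posthoc = posthoc)
}

# Dunn's rank-based post-hoc z-test with tie correction, Bonferroni-adjusted
dunn_posthoc <- function(vals, grp) {
  n <- length(vals)
  r <- rank(vals)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_r <- tapply(r, grp, mean)
  n_g <- tapply(r, grp, length)
  lv <- names(mean_r)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / n_g[pr[1]] + 1 / n_g[pr[2]]))
    (mean_r[pr[1]] - mean_r[pr[2]]) / se
  })
  p_raw <- 2 * pnorm(-abs(z))
  data.frame(a = pairs[1, ], b = pairs[2, ], z = unname(z),
             p_adj = pmin(1, p_raw * ncol(pairs)))
}

#' Step-down multiple-comparison correction
#'
#' The correction described for repeated two-group tests: for `N`
#' comparisons the most significant p-value is multiplied by `N`, the
#' second most significant by `N - 1`, the third by `N - 2`, and so on;
#' corrected values are capped at 1. By default, monotone non-decreasing
#' corrected values are enforced in sorted order (running maximum), which
#' makes the procedure identical to the Holm step-down method; set
#' `literal = TRUE` to apply the bare multiplication rule without the
#' monotonicity repair.
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @param literal Disable the monotonicity enforcement.
#' @return Corrected p-values in the original order.
#' @examples
#' holm_bonferroni_variant(c(0.01, 0.04))  # 0.02, 0.04
#' @export
holm_bonferroni_variant <- function(p, literal = FALSE) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p)
  corr <- p[o] * (n - seq_len(n) + 1)
  if (!literal) corr <- cummax(corr)
  corr <- pmin(corr, 1)
  out <- numeric(n)
  out[o] <- corr
  out
}
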