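#' Simulate a histology count cohort with planted genotype effects
#'
#' Generates per-field marker counts for a littered cohort of control and
#' mutant animals. Each animal contributes 3–4 non-overlapping fields of
#' known area; counts are Poisson with mean `density x area`. Planted
#' control densities (cells/mm², corpus callosum defaults): CC1+
#' oligodendrocytes 1250, Pdgfra+ OPs 800 (about 250 OLs per 0.2 mm² field,
#' i.e. over 800 cells per animal across 3–4 fields). Mutant CC1+ densities are
#' multiplied by `1 - ol_density_effect[age]`; OP density and the EdU
#' labelling index carry no planted genotype effect. EdU+Pdgfra+ counts are
#' binomial draws from the Pdgfra+ count at the planted labelling index.
#' Biological variability: litter (CV 4%) and animal (CV 5%) lognormal
#' multipliers shared across markers of an animal.
#'
#' @param preset A [genotype_preset()] or name, supplying the mutant effects.
#' @param n_control,n_mutant Animals per genotype, interleaved across litters.
#' @param n_litters Number of litters; every litter receives both genotypes.
#' @param age One of "P7", "P14", "P21", "P70" (selects the planted OL
#'   effect).
#' @param field_area_mm2 Area of one counting field.
#' @param labelling_index Planted EdU labelling index (fraction of Pdgfra+).
#' @param ol_density,op_density Control densities (cells/mm²).
#' @param seed Integer seed.
#' @return A `count_table` data.frame with columns `litter`, `animal`,
#'   `genotype`, `age`, `field`, `area_mm2`, `marker`, `count`, and the
#'   planted values in `attr(, "ground_truth")`.
#' @export
simulate_histology_counts <- function(preset, n_control = 14, n_mutant = 14,
                                      n_litters = 4, age = "P14",
                                      field_area_mm2 = 0.2,
                                      labelling_index = 0.25,
                                      ol_density = 1250, op_density = 800,
                                      seed = 1) {
  if (is.character(preset)) preset <- genotype_preset(preset)
  if (n_litters < 2) stop("litter normalization downstream needs >= 2 litters, each with controls")
  if (field_area_mm2 <= 0) stop("fields with zero area rejected")
  age <- match.arg(age, c("P7", "P14", "P21", "P70"))
  effect <- unname(preset$ol_density_effect[age])
  with_seed(seed, {
    geno <- c(rep("control", n_control), rep("mutant", n_mutant))
    litter <- c(rep_len(seq_len(n_litters), n_control),
                rep_len(seq_len(n_litters), n_mutant))
    litter_mult <- exp(rnorm(n_litters, 0, 0.04) - 0.04^2 / 2)
    rows <- list()
    truth_density <- numeric(length(geno))
    for (a in seq_along(geno)) {
      animal_mult <- exp(rnorm(1, 0, 0.05) - 0.05^2 / 2)
      mult <- litter_mult[litter[a]] * animal_mult
      d_ol <- ol_density * mult * (if (geno[a] == "mutant") 1 - effect else 1)
      d_op <- op_density * mult
      truth_density[a] <- d_ol
      n_fields <- sample(3:4, 1)
      for (f in seq_len(n_fields)) {
        cc1 <- rpois(1, d_ol * field_area_mm2)
        pdgfra <- rpois(1, d_op * field_area_mm2)
        edu <- rbinom(1, pdgfra, labelling_index)
        rows[[length(rows) + 1]] <- data.frame(
          litter = litter[a], animal = sprintf("a%02d", a),
          genotype = geno[a], age = age, field = f,
          area_mm2 = field_area_mm2,
          marker = c("CC1", "Pdgfra", "EdU_Pdgfra"),
          count = c(cc1, pdgfra, edu))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "ground_truth") <- list(
      ol_density_control = ol_density, op_density_control = op_density,
      ol_effect = effect, labelling_index = labelling_index,
      animal_density = truth_density)
    class(out) <- c("count_table", "data.frame")
    out
  })
}

#' Simulate per-animal apoptotic fractions in a littered cohort
#'
#' Emulates the cleaved Caspase-3 / Olig2 co-labelling experiment: each
#' litter contains control and mutant animals; the control apoptotic
#' fraction averages `control_mean` (22.7% in the double-knockout
#' experiment, 24.8% in the triple-knockout one); mutants are multiplied by
#' the preset `caspase_factor`. Litter-level variability (CV 10%) is shared
#' by all animals of a litter and is removed by litter normalization;
#' within-litter animal variability has CV 6.6%.
#'
#' @param preset A [genotype_preset()] or name.
#' @param n_litters Number of litters.
#' @param controls_per_litter,mutants_per_litter Animals per litter.
#' @param control_mean Control apoptotic fraction (of Olig2+ cells).
#' @param litter_cv,animal_cv Lognormal coefficients of variation.
#' @param seed Integer seed.
#' @return Data.frame `litter`, `animal`, `genotype`, `fraction`, with the
#'   planted factor in `attr(, "ground_truth")`.
#' @export
simulate_caspase_cohort <- function(preset, n_litters = 6,
                                    controls_per_litter = 3,
                                    mutants_per_litter = 3,
                                    control_mean = 0.227,
                                    litter_cv = 0.10, animal_cv = 0.066,
                                    seed = 1) {
  if (is.character(preset)) preset <- genotype_preset(preset)
  with_seed(seed, {
    rows <- list()
    for (l in seq_len(n_litters)) {
      base <- control_mean * exp(rnorm(1, 0, litter_cv) - litter_cv^2 / 2)
      for (k in seq_len(controls_per_litter + mutants_per_litter)) {
        is_mut <- k > controls_per_litter
        f <- base * (if (is_mut) preset$caspase_factor else 1) *
          exp(rnorm(1, 0, animal_cv) - animal_cv^2 / 2)
        rows[[length(rows) + 1]] <- data.frame(
          litter = l, animal = sprintf("l%02da%02d", l, k),
          genotype = if (is_mut) "mutant" else "control", fraction = f)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "ground_truth") <- list(caspase_factor = preset$caspase_factor,
                                      control_mean = control_mean)
    out
  })
}

#' Simulate fiber morphometry: circumference pairs, myelin-figure counts
#' and 3D internode traces
#'
#' * Fibers: axon diameters lognormal (median 0.8 µm, log-SD 0.3); g-ratios
#'   normal (mean 0.78, SD 0.03) truncated to (0, 1); circumferences
#'   `C = pi d` with optional multiplicative measurement noise. Genotype has
#'   no planted effect on g or diameter.
#' * Myelin figures: one ~210 × 160 µm field per animal; control density
#'   0.0595 figures/µm² (≈2000 per field); mutants multiplied by
#'   `1 - myelin_density_effect`; animal-level lognormal CV 5%.
#' * Internodes: planted arc lengths lognormal (median 50 µm, log-SD 0.25),
#'   rendered as persistent 3D random-walk polylines rescaled to the exact
#'   planted arc length; genotype has no planted effect on length.
#'
#' @param preset A [genotype_preset()] or name.
#' @param n_animals Animals per genotype.
#' @param fibers_per_animal Measured fibers per animal.
#' @param internodes_per_group Internode traces per genotype.
#' @param field_um c(width, height) of the EM field (µm).
#' @param figure_density Control myelin-figure density (per µm²).
#' @param g_mean,g_sd Planted g-ratio distribution.
#' @param noise_cv Multiplicative circumference measurement noise CV.
#' @param seed Integer seed.
#' @return List: `fibers` (data.frame animal/genotype/C_axon_um/C_fiber_um),
#'   `figures` (data.frame animal/genotype/count/area_um2), `internodes`
#'   (list of point matrices with genotype attribute), `ground_truth`.
#' @export
simulate_fiber_geometry <- function(preset, n_animals = 5,
                                    fibers_per_animal = 80,
                                    internodes_per_group = 30,
                                    field_um = c(210, 160),
                                    figure_density = 0.0595,
                                    g_mean = 0.78, g_sd = 0.03,
                                    noise_cv = 0.01, seed = 1) {
  if (is.character(preset)) preset <- genotype_preset(preset)
  if (g_mean >= 1) stop("g-ratio >= 1 rejected: support must be within (0, 1)")
  with_seed(seed, {
    area <- prod(field_um)
    fib <- list(); figs <- list()
    for (g in c("control", "mutant")) {
      eff <- if (g == "mutant") 1 - preset$myelin_density_effect else 1
      for (a in seq_len(n_animals)) {
        id <- sprintf("%s_a%02d", g, a)
        d_axon <- rlnorm(fibers_per_animal, log(0.8), 0.3)
        gr <- truncnorm01(fibers_per_animal, g_mean, g_sd)
        noise <- function(n) exp(rnorm(n, 0, noise_cv) - noise_cv^2 / 2)
        fib[[id]] <- data.frame(
          animal = id, genotype = g,
          C_axon_um = pi * d_axon * noise(fibers_per_animal),
          C_fiber_um = pi * d_axon / gr * noise(fibers_per_animal))
        mult <- exp(rnorm(1, 0, 0.05) - 0.05^2 / 2)
        figs[[id]] <- data.frame(
          animal = id, genotype = g,
          count = rpois(1, figure_density * eff * mult * area),
          area_um2 = area)
      }
    }
    internodes <- list()
    lens <- numeric(0)
    for (g in c("control", "mutant")) {
      for (k in seq_len(internodes_per_group)) {
        len <- rlnorm(1, log(50), 0.25)
        tr <- random_walk_polyline(len, n_seg = 20)
        attr(tr, "genotype") <- g
        attr(tr, "true_length_um") <- len
        internodes[[sprintf("%s_i%02d", g, k)]] <- tr
        lens <- c(lens, len)
      }
    }
    list(fibers = do.call(rbind, c(fib, list(make.row.names = FALSE))),
         figures = do.call(rbind, c(figs, list(make.row.names = FALSE))),
         internodes = internodes,
         ground_truth = list(
           g_mean = g_mean, g_sd = g_sd,
           figure_density_control = figure_density,
           myelin_effect = preset$myelin_density_effect,
           internode_lengths_um = lens))
  })
}

truncnorm01 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0 | x >= 1)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# persistent 3D random walk with exact planted arc length
random_walk_polyline <- function(arc_length_um, n_seg = 20, persistence = 0.9) {
  dirs <- matrix(0, n_seg, 3)
  d <- c(1, 0, 0)
  for (k in seq_len(n_seg)) {
    d <- persistence * d + (1 - persistence) * rnorm(3, 0, 1)
    d <- d / sqrt(sum(d^2))
    dirs[k, ] <- d
  }
  seg_len <- rep(arc_length_um / n_seg, n_seg)
  pts <- rbind(c(0, 0, 0), apply(dirs * seg_len, 2, cumsum))
  colnames(pts) <- c("x", "y", "z")
  pts
}
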