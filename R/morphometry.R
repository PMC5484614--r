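#' Per-fiber diameters and g-ratios from circumference pairs
#'
#' Diameters are recovered from the measured circumferences assuming a
#' circular profile (`d = C / pi`); the g-ratio is the axon diameter divided
#' by the outer fiber diameter, i.e. `g = C_axon / C_fiber` (unit-free).
#' Rows with `C_axon >= C_fiber` or non-positive circumferences are rejected
#' and reported; fibers with `g > 0.98` are flagged as near the g -> 1
#' boundary.
#'
#' @param records Data.frame with `C_axon_um`, `C_fiber_um` and optional
#'   grouping columns (`animal`, `genotype`).
#' @param bin_um Diameter histogram bin width (µm).
#' @return List: `fibers` (input plus `d_axon_um`, `d_fiber_um`, `g`,
#'   `near_unity`), `rejected` (invalid rows), `histogram` (axon-diameter
#'   frequency per genotype when present), `summary` (per-genotype mean g
#'   and diameters).
#' @export
fiber_metrics <- function(records, bin_um = 0.1) {
  stopifnot(all(c("C_axon_um", "C_fiber_um") %in% names(records)))
  bad <- !(records$C_axon_um > 0 & records$C_fiber_um > 0 &
             records$C_axon_um < records$C_fiber_um)
  rejected <- records[bad, , drop = FALSE]
  if (nrow(rejected) > 0)
    message(nrow(rejected), " row(s) rejected: axon circumference must be positive and smaller than fiber circumference")
  rec <- records[!bad, , drop = FALSE]
  rec$d_axon_um <- rec$C_axon_um / pi
  rec$d_fiber_um <- rec$C_fiber_um / pi
  rec$g <- rec$C_axon_um / rec$C_fiber_um
  rec$near_unity <- rec$g > 0.98
  grp <- if ("genotype" %in% names(rec)) rec$genotype else
    rep("all", nrow(rec))
  breaks <- seq(0, ceiling(max(rec$d_axon_um) / bin_um) * bin_um, by = bin_um)
  hh <- lapply(split(rec$d_axon_um, grp), function(d)
    as.numeric(table(cut(d, breaks, right = FALSE))))
  histogram <- data.frame(bin_lo_um = rep(head(breaks, -1), length(hh)),
                          genotype = rep(names(hh), each = length(breaks) - 1),
                          n = unlist(hh, use.names = FALSE))
  summary <- do.call(rbind, lapply(split(rec, grp), function(s)
    data.frame(genotype = s$genotype[1] %||% "all", n = nrow(s),
               mean_g = mean(s$g), sd_g = sd(s$g),
               mean_d_axon_um = mean(s$d_axon_um))))
  rownames(summary) <- NULL
  list(fibers = rec, rejected = rejected, histogram = histogram,
       summary = summary)
}

#' Myelin-figure density
#'
#' Transverse myelin figures per unit area, `count / area` (vectorized over
#' fields/animals).
#'
#' @param count Figure counts.
#' @param area_um2 Field areas (µm²).
#' @return Density in figures/µm².
#' @examples
#' myelin_figure_density(2000, 210 * 160)  # 0.0595
#' @export
myelin_figure_density <- function(count, area_um2) {
  if (any(area_um2 <= 0)) stop("area must be positive")
  count / area_um2
}

#' Mutant/control myelin-figure density ratio with bootstrap CI
#'
#' Ratio of genotype mean densities (mutant over control), with a
#' percentile bootstrap over animals.
#'
#' @param figures Data.frame with `genotype` ("control"/"mutant"), `count`,
#'   `area_um2`, one row per animal (or field).
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return List: `ratio`, `ci` (length-2), `density_by_genotype`.
#' @export
myelin_density_ratio <- function(figures, n_boot = 1000, conf = 0.95,
                                 seed = 1) {
  d <- myelin_figure_density(figures$count, figures$area_um2)
  dc <- d[figures$genotype == "control"]
  dm <- d[figures$genotype == "mutant"]
  if (!length(dc) || !length(dm)) stop("both genotypes required")
  ratio <- mean(dm) / mean(dc)
  boots <- with_seed(seed, replicate(n_boot,
    mean(sample(dm, replace = TRUE)) / mean(sample(dc, replace = TRUE))))
  list(ratio = ratio,
       ci = unname(quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2))),
       density_by_genotype = c(control = mean(dc), mutant = mean(dm)))
}

#' Internode length from a 3D polyline
#'
#' Sum of Euclidean segment lengths of the ordered 3D points tracing one
#' internode.
#'
#' @param trace Numeric matrix (n x 3) of xyz coordinates (µm), n >= 2.
#' @return Length (µm).
#' @export
internode_length <- function(trace) {
  trace <- as.matrix(trace)
  if (nrow(trace) < 2) stop("an internode trace needs at least 2 points")
  seg <- diff(trace)
  lens <- sqrt(rowSums(seg^2))
  if (any(lens == 0)) stop("consecutive points must be distinct")
  sum(lens)
}
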