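#' Write / read a sweep set as plain text
#'
#' Serializes a `sweep_set` to a directory holding `current.csv` and
#' `vcmd.csv` (samples x sweeps) plus `meta.json` (sampling rate, protocol,
#' metadata, ground truth, at full double precision). This is the package's
#' text-based on-disk layout; ground truth round-trips unchanged.
#'
#' @param x A `sweep_set`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sweep_set <- function(x, dir) {
  stopifnot(inherits(x, "sweep_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(x$current), file.path(dir, "current.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(x$vcmd), file.path(dir, "vcmd.csv"),
                   row.names = FALSE)
  meta <- list(fs_khz = x$fs_khz, protocol = unclass(x$protocol),
               meta = x$meta, ground_truth = x$ground_truth)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_sweep_set
#' @export
read_sweep_set <- function(dir) {
  cur <- as.matrix(utils::read.csv(file.path(dir, "current.csv")))
  vc <- as.matrix(utils::read.csv(file.path(dir, "vcmd.csv")))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  proto <- meta$protocol
  class(proto) <- "clamp_protocol"
  sweep_set(cur, vc, meta$fs_khz, proto, meta = meta$meta,
            ground_truth = meta$ground_truth)
}

#' Write a cohort table with a generator-parameter sidecar
#'
#' Writes any cohort data.frame (count table, caspase cohort, fiber table)
#' as CSV plus a JSON sidecar recording the planted ground truth and the
#' seed, so generated cohorts are self-describing.
#'
#' @param x Data.frame (possibly with a `ground_truth` attribute).
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.params.json`.
#' @param params Extra parameters to record (e.g. `list(seed = 1)`).
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(x, path, params = list()) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  side <- c(list(ground_truth = attr(x, "ground_truth")), params)
  jsonlite::write_json(side, paste0(path, ".params.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  x <- utils::read.csv(path)
  side_path <- paste0(path, ".params.json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    attr(x, "ground_truth") <- side$ground_truth
  }
  x
}
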