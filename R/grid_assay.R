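#' Construct and validate a diet-grid pupariation assay table
#'
#' A grid assay records, for each replicate vial of larvae seeded on one
#' diet of a yeast-by-sucrose grid, the cumulative number of larvae that
#' have pupariated at each observation time. It is the raw phenotype
#' object from which the pupariation index, survival and development-time
#' metrics are derived.
#'
#' @param x a data.frame with columns `genotype`, `yeast_pct`,
#'   `sucrose_pct`, `vial`, `time_h`, `cum_pupae`, `n_larvae`.
#' @return the validated data.frame with class `grid_assay`.
#'
#' @details Validation enforces: `0 <= cum_pupae <= n_larvae`; cumulative
#'   counts non-decreasing in time within a vial; observation times unique
#'   within a vial. A vial is identified by the combination of genotype,
#'   diet and vial id.
#' @export
grid_assay <- function(x) {
  req <- c("genotype", "yeast_pct", "sucrose_pct", "vial", "time_h",
           "cum_pupae", "n_larvae")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0)
    stopf("grid_assay is missing columns: %s",
          paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x)[, req]
  if (any(x$cum_pupae < 0) || any(x$cum_pupae > x$n_larvae))
    stopf("cum_pupae must lie in [0, n_larvae]")
  if (any(x$time_h <= 0)) stopf("observation times must be positive")
  key <- vial_key(x)
  ord <- order(key, x$time_h)
  x <- x[ord, , drop = FALSE]
  key <- key[ord]
  for (k in unique(key)) {
    idx <- which(key == k)
    tt <- x$time_h[idx]
    if (anyDuplicated(tt)) stopf("duplicated observation time in vial %s", k)
    if (is.unsorted(x$cum_pupae[idx]))
      stopf("cumulative counts decrease in vial %s", k)
    if (length(unique(x$n_larvae[idx])) != 1L)
      stopf("n_larvae varies within vial %s", k)
  }
  rownames(x) <- NULL
  class(x) <- c("grid_assay", "data.frame")
  x
}

vial_key <- function(x) {
  paste(x$genotype, x$yeast_pct, x$sucrose_pct, x$vial, sep = "\r")
}

#' Read / write a grid assay as tab-separated text
#'
#' @param path file path.
#' @param x a `grid_assay`.
#' @return `read_grid_assay` returns a validated [grid_assay()];
#'   `write_grid_assay` returns `path` invisibly.
#' @export
read_grid_assay <- function(path) {
  grid_assay(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_grid_assay
#' @export
write_grid_assay <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
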