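#' Construct an ExpressionStudy
#'
#' The universal input container of the pipeline: a probes x samples signal
#' matrix of MAS5-style expression values, the matching matrix of detection
#' calls, and the sample design (exposure duration and Cd2+ dose).
#'
#' @param signal Numeric matrix (probes x samples), non-negative, with probe
#'   ids as rownames and sample ids as colnames.
#' @param calls Character matrix of the same dimensions with entries in
#'   \code{"P"} (present), \code{"A"} (absent), \code{"M"} (marginal).
#' @param design Data frame with columns \code{sample_id}, \code{time_days}
#'   and \code{dose_uM}; one row per sample. Rows are reordered to match the
#'   column order of \code{signal}.
#' @return An object of class \code{ExpressionStudy}: a list with elements
#'   \code{signal}, \code{calls} and \code{design}.
#' @export
expression_study <- function(signal, calls, design) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("'signal' must be a numeric matrix")
  if (is.null(rownames(signal)) || is.null(colnames(signal)))
    stop("'signal' must have probe rownames and sample colnames")
  if (anyNA(signal))
    stop("'signal' contains missing values")
  if (any(signal < 0)) {
    bad <- which(signal < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative signal for probe '%s', sample '%s'",
                 rownames(signal)[bad[1]], colnames(signal)[bad[2]]))
  }
  if (!is.matrix(calls) || !identical(dim(calls), dim(signal)))
    stop(sprintf("calls matrix is %s but signal matrix is %s",
                 paste(dim(calls), collapse = "x"),
                 paste(dim(signal), collapse = "x")))
  ok <- calls %in% c("P", "A", "M")
  if (!all(ok)) {
    bad <- which(matrix(!ok, nrow(calls)), arr.ind = TRUE)[1, ]
    stop(sprintf("invalid call '%s' (not P/A/M) for probe '%s', sample '%s'",
                 calls[bad[1], bad[2]], rownames(signal)[bad[1]],
                 colnames(signal)[bad[2]]))
  }
  dimnames(calls) <- dimnames(signal)
  req <- c("sample_id", "time_days", "dose_uM")
  if (!is.data.frame(design) || !all(req %in% names(design)))
    stop("'design' must be a data.frame with columns sample_id, time_days, dose_uM")
  design$sample_id <- as.character(design$sample_id)
  if (anyDuplicated(design$sample_id))
    stop(sprintf("duplicated sample id in design: '%s'",
                 design$sample_id[duplicated(design$sample_id)][1]))
  missing_s <- setdiff(colnames(signal), design$sample_id)
  if (length(missing_s))
    stop(sprintf("sample '%s' present in matrix but absent from design",
                 missing_s[1]))
  extra_s <- setdiff(design$sample_id, colnames(signal))
  if (length(extra_s))
    stop(sprintf("unknown sample '%s' in design", extra_s[1]))
  design <- design[match(colnames(signal), design$sample_id),
                   req, drop = FALSE]
  rownames(design) <- NULL
  if (!is.numeric(design$dose_uM) || any(design$dose_uM < 0))
    stop("'dose_uM' must be non-negative numeric")
  structure(list(signal = signal, calls = calls, design = design),
            class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf("ExpressionStudy: %d probes x %d samples\n",
              nrow(x$signal), ncol(x$signal)))
  for (tb in sort(unique(x$design$time_days))) {
    d <- x$design$dose_uM[x$design$time_days == tb]
    cat(sprintf("  block %g d: doses %s uM\n", tb,
                paste(sort(d), collapse = ", ")))
  }
  cat(sprintf("  present in >=1 sample: %d probes\n",
              sum(rowSums(x$calls == "P") >= 1)))
  invisible(x)
}

#' Number of probes / samples of a study
#' @param study An \code{ExpressionStudy}.
#' @return Integer count.
#' @export
n_probes <- function(study) nrow(study$signal)

#' @rdname n_probes
#' @export
n_samples <- function(study) ncol(study$signal)

#' Restrict a study to the probes detected in at least one sample
#'
#' Applies the analysis-universe filter: a probe is retained when its
#' detection call is "P" (present) in one or more samples. Marginal ("M")
#' calls do not count as present. Probe order is preserved and the filter is
#' idempotent.
#'
#' @param study An \code{ExpressionStudy}.
#' @return A new \code{ExpressionStudy} with only the present probes (may be
#'   empty).
#' @export
filter_present <- function(study) {
  stopifnot(inherits(study, "ExpressionStudy"))
  keep <- rowSums(study$calls == "P") >= 1
  structure(list(signal = study$signal[keep, , drop = FALSE],
                 calls = study$calls[keep, , drop = FALSE],
                 design = study$design),
            class = "ExpressionStudy")
}

#' Subset a study to one exposure block
#'
#' @param study An \code{ExpressionStudy}.
#' @param block Exposure duration in days identifying the block (e.g. 1 or 13).
#' @return An \code{ExpressionStudy} containing only that block's samples.
#' @export
study_block <- function(study, block) {
  stopifnot(inherits(study, "ExpressionStudy"))
  keep <- study$design$time_days == block
  if (!any(keep))
    stop(sprintf("no samples with time_days == %g", block))
  structure(list(signal = study$signal[, keep, drop = FALSE],
                 calls = study$calls[, keep, drop = FALSE],
                 design = study$design[keep, , drop = FALSE]),
            class = "ExpressionStudy")
}
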