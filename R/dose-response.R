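# Per-gene ordinary least squares of expression on Cd2+ concentration within
# one exposure block. With single-replicate designs (n = 4 samples, 2
# residual df) degenerate fits are reachable and must not abort the pipeline:
# a zero-variance response reports P = 1, an exactly linear response reports
# P = 0 with a perfect-fit flag.

#' Per-gene linear regression of expression on dose
#'
#' Fits, for every probe of one exposure block, ordinary least squares of
#' (optionally log2-transformed) expression on dose and tests the slope with
#' a two-sided t test on n - 2 residual df.
#'
#' @param study An \code{ExpressionStudy} (normally after
#'   \code{\link{filter_present}}).
#' @param block Exposure duration in days selecting the block (e.g. 1 or 13).
#' @param scale \code{"raw"} (default) regresses the signal values as given;
#'   \code{"log2"} regresses \code{log2(signal + 1)}.
#' @return Data frame of class \code{RegressionResult} with columns
#'   \code{probe}, \code{slope}, \code{intercept}, \code{t}, \code{p_value},
#'   \code{df}, \code{direction} (positive/negative/flat) and
#'   \code{perfect_fit}; rows ordered by direction then ascending P.
#'   Attributes record the block, scale and sample count.
#' @export
fit_dose_regression <- function(study, block, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  blk <- study_block(study, block)
  x <- blk$design$dose_uM
  if (length(unique(x)) < 3)
    stop(sprintf("block %g has %d distinct doses; need >= 3", block,
                 length(unique(x))))
  if (stats::var(x) == 0) stop("zero dose variance")
  y <- blk$signal
  if (scale == "log2") y <- log2(y + 1)
  nS <- length(x); df <- nS - 2L
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- as.vector(y %*% xc) / sxx
  intercept <- rowMeans(y) - slope * mean(x)
  fitted <- outer(slope, x) + intercept
  rss <- rowSums((y - fitted)^2)
  tss <- rowSums((y - rowMeans(y))^2)
  se <- sqrt(rss / df / sxx)
  tstat <- slope / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  # degenerate cases (tolerances relative to the response magnitude)
  eps <- 1e-12 * pmax(tss, 1)
  const <- tss <= eps                       # no response variance at all
  perfect <- !const & rss <= eps            # exact linear fit
  slope[const] <- 0
  tstat[const] <- 0;   pval[const] <- 1
  tstat[perfect] <- sign(slope[perfect]) * Inf
  pval[perfect] <- 0
  direction <- ifelse(slope > 0, "positive", ifelse(slope < 0, "negative", "flat"))
  out <- data.frame(probe = rownames(y), slope = slope,
                    intercept = intercept, t = tstat, p_value = pval,
                    df = df, direction = direction, perfect_fit = perfect,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$direction, c("positive", "negative", "flat")),
                   out$p_value, out$probe), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "block") <- block
  attr(out, "scale") <- scale
  attr(out, "n_samples") <- nS
  class(out) <- c("RegressionResult", "data.frame")
  out
}

#' Select significant genes from regression results
#'
#' Applies a strict P-value cutoff (\code{p_value < cutoff}) and an optional
#' direction filter, mirroring how responder lists are reported.
#'
#' @param results A \code{RegressionResult} data frame.
#' @param cutoff P-value cutoff in (0, 1]; comparison is strict.
#' @param direction \code{"any"}, \code{"positive"} or \code{"negative"}.
#' @return A \code{GeneListSelection}: list with \code{ids} (probe ids,
#'   ordered by ascending P), \code{cutoff}, \code{direction},
#'   \code{n_selected}, \code{n_universe}.
#' @export
select_genes <- function(results, cutoff,
                         direction = c("any", "positive", "negative")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(results), cutoff > 0, cutoff <= 1)
  keep <- results$p_value < cutoff
  if (direction != "any") keep <- keep & results$direction == direction
  sel <- results[keep, , drop = FALSE]
  sel <- sel[order(sel$p_value, sel$probe), , drop = FALSE]
  structure(list(ids = sel$probe, cutoff = cutoff, direction = direction,
                 n_selected = nrow(sel), n_universe = nrow(results)),
            class = "GeneListSelection")
}

#' @export
print.GeneListSelection <- function(x, ...) {
  cat(sprintf("GeneListSelection: %d / %d at P < %g (%s)\n",
              x$n_selected, x$n_universe, x$cutoff, x$direction))
  invisible(x)
}

#' P-value histogram over equal-width bins on [0, 1]
#'
#' @param results A \code{RegressionResult} data frame (or anything with a
#'   \code{p_value} column).
#' @param n_bins Number of equal-width bins, >= 2. P = 1 falls in the last bin.
#' @return Data frame with \code{bin_left}, \code{bin_right}, \code{count};
#'   counts sum to \code{nrow(results)}.
#' @export
pvalue_histogram <- function(results, n_bins = 20) {
  stopifnot(n_bins >= 2)
  p <- results$p_value
  stopifnot(all(p >= 0 & p <= 1))
  bin <- pmin(floor(p * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  data.frame(bin_left = (seq_len(n_bins) - 1) / n_bins,
             bin_right = seq_len(n_bins) / n_bins,
             count = counts)
}

#' Benjamini-Hochberg q values for regression results
#'
#' Step-up FDR adjustment across all tested probes (delegates to
#' \code{stats::p.adjust}).
#'
#' @param results A \code{RegressionResult} data frame.
#' @return Named numeric vector of q values (names = probe ids), in the row
#'   order of \code{results}.
#' @export
bh_fdr <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  stats::setNames(stats::p.adjust(results$p_value, method = "BH"),
                  results$probe)
}

#' Write a regression result table mirroring the per-block report layout
#'
#' @param results A \code{RegressionResult} data frame.
#' @param annotation Optional probe annotation to add symbol / gene name.
#' @param path Output TSV path.
#' @return Invisibly, the written data frame.
#' @export
write_regression_table <- function(results, path, annotation = NULL) {
  out <- results
  if (!is.null(annotation)) {
    idx <- match(out$probe, annotation$probe)
    out$symbol <- annotation$symbol[idx]
    out$gene_name <- annotation$gene_name[idx]
    out <- out[, c("probe", "symbol", "gene_name", "slope", "t", "p_value",
                   "direction")]
  } else {
    out <- out[, c("probe", "slope", "t", "p_value", "direction")]
  }
  names(out)[names(out) == "p_value"] <- "Pr(>|t|)"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
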