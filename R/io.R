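# Tabular IO: expression TSV + calls TSV + design CSV, probe annotation TSV,
# GMT gene sets. All files are plain UTF-8 text with headers. Numbers are
# written with 17 significant digits so that write -> read round-trips
# doubles exactly.

#' Read an expression study from its three tabular files
#'
#' @param matrix_path TSV, header row of sample ids, first column probe ids,
#'   remaining columns numeric signal.
#' @param calls_path TSV with the same layout holding P/A/M detection calls.
#' @param design_path CSV with columns \code{sample_id,time_days,dose_uM}.
#' @return An \code{\link{expression_study}} object. Column order follows the
#'   matrix file; design rows are reordered to match.
#' @export
read_expression <- function(matrix_path, calls_path, design_path) {
  for (p in c(matrix_path, calls_path, design_path))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  sig <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  cal <- utils::read.delim(calls_path, check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  smat <- as.matrix(sig[, -1, drop = FALSE])
  if (!is.numeric(smat)) {
    bad <- colnames(smat)[!vapply(as.data.frame(smat), is.numeric, TRUE)][1]
    stop(sprintf("non-numeric signal in column '%s' of %s", bad, matrix_path))
  }
  rownames(smat) <- as.character(sig[[1]])
  cmat <- as.matrix(cal[, -1, drop = FALSE])
  rownames(cmat) <- as.character(cal[[1]])
  if (!identical(dim(cmat), dim(smat)))
    stop(sprintf(
      "dimension mismatch: calls file is %d x %d but matrix file is %d x %d",
      nrow(cmat), ncol(cmat), nrow(smat), ncol(smat)))
  if (!identical(rownames(cmat), rownames(smat)))
    stop("probe ids differ between matrix and calls files")
  if (!identical(colnames(cmat), colnames(smat)))
    stop("sample ids differ between matrix and calls files")
  design <- utils::read.csv(design_path, stringsAsFactors = FALSE)
  expression_study(smat, cmat, design)
}

#' Write an expression study to its three tabular files
#'
#' @param study An \code{ExpressionStudy}.
#' @inheritParams read_expression
#' @return Invisibly, the study.
#' @export
write_expression <- function(study, matrix_path, calls_path, design_path) {
  stopifnot(inherits(study, "ExpressionStudy"))
  write_numeric_tsv(study$signal, "probe", matrix_path)
  df <- data.frame(probe = rownames(study$calls), study$calls,
                   check.names = FALSE)
  utils::write.table(df, calls_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(study$design, design_path, row.names = FALSE,
                   quote = FALSE)
  invisible(study)
}

# 17 significant digits: the shortest length guaranteeing an exact
# decimal -> binary64 round trip.
write_numeric_tsv <- function(mat, id_col, path) {
  chr <- matrix(formatC(mat, digits = 17, format = "g"), nrow(mat),
                dimnames = dimnames(mat))
  df <- data.frame(V1 = rownames(mat), chr, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' @param path TSV with columns \code{probe}, \code{symbol}, \code{gene_name};
#'   \code{NA} allowed for unannotated probes.
#' @return Data frame with those three character columns, one row per probe.
#' @export
read_probe_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("probe", "symbol", "gene_name")
  if (!all(req %in% names(ann)))
    stop("annotation must have columns probe, symbol, gene_name")
  if (anyDuplicated(ann$probe))
    stop(sprintf("duplicated probe '%s' in annotation",
                 ann$probe[duplicated(ann$probe)][1]))
  ann$symbol[ann$symbol %in% c("", "NA")] <- NA_character_
  ann$gene_name[ann$gene_name %in% c("", "NA")] <- NA_character_
  ann[, req]
}

#' Read gene sets in GMT format
#'
#' One set per tab-separated line: name, description, then member symbols.
#' Duplicate symbols within a line are dropped (first occurrence kept).
#'
#' @param path Path to a GMT file.
#' @return A \code{GeneSetCollection}: a named list of character vectors with
#'   a \code{descriptions} attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 symbol",
                   i, length(f)))
    genes <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (!length(genes))
      stop(sprintf("GMT line %d ('%s') defines an empty set", i, f[1]))
    if (f[1] %in% names(sets))
      stop(sprintf("duplicate set name '%s' at GMT line %d", f[1], i))
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  structure(sets, descriptions = desc, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (sizes %s)\n", length(x),
              if (length(x)) paste(range(lengths(x)), collapse = "-") else "-"))
  invisible(x)
}

#' Collapse per-probe regression results to the gene level
#'
#' Several probes can interrogate one gene; gene-level analyses (enrichment,
#' overlap) need one row per symbol. The representative probe is the one with
#' the smallest P value (\code{"min_p"}) or the largest absolute t statistic
#' (\code{"max_abs_t"}). Probes without a symbol are dropped.
#'
#' @param results Per-probe regression table as returned by
#'   \code{\link{fit_dose_regression}} (needs columns \code{probe},
#'   \code{t}, \code{p_value}).
#' @param annotation Probe annotation data frame
#'   (\code{\link{read_probe_annotation}}).
#' @param rule Collapse rule, \code{"min_p"} (default) or \code{"max_abs_t"}.
#' @return Data frame with one row per symbol: \code{symbol}, \code{probe}
#'   (the representative) and the representative probe's statistics.
#' @export
collapse_probes <- function(results, annotation, rule = c("min_p", "max_abs_t")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(results), all(c("probe", "t", "p_value") %in% names(results)))
  idx <- match(results$probe, annotation$probe)
  if (anyNA(idx))
    stop(sprintf("probe '%s' missing from annotation",
                 results$probe[which(is.na(idx))[1]]))
  res <- results
  res$symbol <- annotation$symbol[idx]
  res <- res[!is.na(res$symbol), , drop = FALSE]
  if (!nrow(res))
    return(cbind(symbol = character(), res[, names(results), drop = FALSE]))
  key <- switch(rule, min_p = res$p_value, max_abs_t = -abs(res$t))
  # stable: ties resolved by input order
  ord <- order(key)
  res <- res[ord, , drop = FALSE]
  res <- res[!duplicated(res$symbol), , drop = FALSE]
  res <- res[order(res$p_value, res$symbol), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("symbol", setdiff(names(res), "symbol"))]
}
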