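# Hypergeometric machinery shared by the gene-set enrichment test and the
# cross-timepoint overlap test. Both ask the same question: out of a universe
# of M genes of which K are marked (significant), a set of n is drawn; is the
# observed count r of marked genes in the draw surprisingly large? The P
# value is the strictly-greater upper tail
#   P(X > r) = sum_{k=r+1}^{min(K,n)} C(K,k) C(M-K,n-k) / C(M,n),
# evaluated in the log domain so it is stable for universes of ~30,000 genes.

#' Strictly-greater hypergeometric tail probability
#'
#' @param M Universe size (e.g. probes present in at least one sample).
#' @param K Number of marked elements (e.g. regression-significant genes).
#' @param n Draw size (gene-set size within the universe, or the second
#'   list's size for an overlap test).
#' @param r Observed number of marked elements in the draw.
#' @return \code{P(X > r)} for \code{X ~ Hypergeometric(M, K, n)}; 0 when
#'   \code{r = min(K, n)} (the tail beyond the maximum is empty).
#' @examples
#' hypergeom_tail_gt(10, 4, 3, 1)   # = 1/3
#' @export
hypergeom_tail_gt <- function(M, K, n, r) {
  vals <- c(M = M, K = K, n = n, r = r)
  if (anyNA(vals) || any(vals != round(vals)) || any(vals < 0))
    stop("M, K, n, r must be non-negative integers")
  if (K > M || n > M) stop("K and n must not exceed M")
  upper <- min(K, n)
  if (r > upper) stop(sprintf("r = %d exceeds min(K, n) = %d", r, upper))
  if (r == upper) return(0)
  k <- seq.int(r + 1, upper)
  lp <- lchoose(K, k) + lchoose(M - K, n - k) - lchoose(M, n)
  m <- max(lp)
  exp(m + log(sum(exp(lp - m))))
}

#' Gene-set over-representation test on a significant-gene selection
#'
#' For each set, counts its members inside the analysis universe (n) and
#' inside the significant selection (r), then computes the strictly-greater
#' hypergeometric tail with M = |universe| and K = |selection|. Sets with no
#' member in the universe are skipped (with a message). BH q values across
#' the tested sets are appended.
#'
#' @param selection Significant genes: a \code{GeneListSelection} or a
#'   character vector of gene ids. Must be a subset of \code{universe}.
#' @param universe Character vector of all analyzed gene ids (gene level,
#'   i.e. after \code{\link{collapse_probes}} when probes multi-map).
#' @param sets A \code{GeneSetCollection} from \code{\link{read_gmt}}, or a
#'   named list of character vectors.
#' @return Data frame of class \code{EnrichmentResult}, sorted by P:
#'   \code{set}, \code{description}, \code{n}, \code{r}, \code{p_value},
#'   \code{q_value}.
#' @export
enrich_gene_sets <- function(selection, universe, sets) {
  ids <- if (inherits(selection, "GeneListSelection")) selection$ids
         else as.character(selection)
  universe <- unique(as.character(universe))
  if (anyDuplicated(ids)) ids <- unique(ids)
  out_of_univ <- setdiff(ids, universe)
  if (length(out_of_univ))
    stop(sprintf("selection contains '%s' which is not in the universe",
                 out_of_univ[1]))
  M <- length(universe); K <- length(ids)
  desc <- attr(sets, "descriptions")
  rows <- lapply(names(sets), function(nm) {
    inU <- intersect(sets[[nm]], universe)
    n <- length(inU)
    if (n == 0) return(NULL)
    r <- length(intersect(inU, ids))
    data.frame(set = nm,
               description = if (!is.null(desc) && nm %in% names(desc))
                 desc[[nm]] else NA_character_,
               n = n, r = r,
               p_value = hypergeom_tail_gt(M, K, n, r),
               stringsAsFactors = FALSE)
  })
  skipped <- names(sets)[vapply(rows, is.null, TRUE)]
  if (length(skipped))
    message(sprintf("skipping %d set(s) with no member in the universe: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(set = character(), description = character(),
                      n = integer(), r = integer(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  res$q_value <- if (nrow(res)) stats::p.adjust(res$p_value, "BH") else numeric()
  res <- res[order(res$p_value, res$set), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "M") <- M; attr(res, "K") <- K
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Significance of the overlap between two gene lists
#'
#' Models the overlap of two lists drawn from a common universe as
#' hypergeometric and reports the strictly-greater tail P value together
#' with the expected overlap \code{|A| |B| / M}.
#'
#' @param listA,listB Character vectors of gene ids, both subsets of
#'   \code{universe}; duplicates are dropped.
#' @param universe Character vector (or a single integer giving the universe
#'   size when only counts are known; then \code{listA}/\code{listB} must be
#'   subsets of each other's id space and the observed overlap is computed
#'   from the ids supplied).
#' @return An \code{OverlapResult} list: \code{M}, \code{K}, \code{n},
#'   \code{r}, \code{expected}, \code{p_value}, \code{overlap_ids}.
#' @export
overlap_significance <- function(listA, listB, universe) {
  a <- unique(as.character(listA)); b <- unique(as.character(listB))
  universe <- unique(as.character(universe))
  badA <- setdiff(a, universe); badB <- setdiff(b, universe)
  if (length(badA))
    stop(sprintf("listA contains '%s' which is not in the universe", badA[1]))
  if (length(badB))
    stop(sprintf("listB contains '%s' which is not in the universe", badB[1]))
  ov <- intersect(a, b)
  M <- length(universe); K <- length(a); n <- length(b); r <- length(ov)
  structure(list(M = M, K = K, n = n, r = r,
                 expected = K * n / M,
                 p_value = hypergeom_tail_gt(M, K, n, r),
                 overlap_ids = ov),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf(
    "OverlapResult: %d / (%d x %d) overlapping in universe %d (expected %.2f)\n  P(X > %d) = %.3g\n",
    x$r, x$K, x$n, x$M, x$expected, x$r, x$p_value))
  invisible(x)
}

#' Write an overlap result as a one-row TSV
#' @param x An \code{OverlapResult}.
#' @param path Output path.
#' @return Invisibly, \code{x}.
#' @export
write_overlap_result <- function(x, path) {
  stopifnot(inherits(x, "OverlapResult"))
  utils::write.table(
    data.frame(M = x$M, K = x$K, n = x$n, r = x$r, expected = x$expected,
               p_value = x$p_value),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
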