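# Pooled-timepoint variance filtering and hierarchical clustering of samples
# on Pearson dissimilarity with Ward linkage, plus heat-map / Newick export.

#' Grand-mean centering and SD filtering of a pooled expression matrix
#'
#' Subtracts the single grand mean of the whole matrix (so the overall mean
#' is 0), computes each gene's SD across all samples (denominator n - 1) and
#' retains the genes whose SD strictly exceeds the threshold — the
#' "high-variability" genes used for pooled clustering and network analysis.
#'
#' @param study An \code{ExpressionStudy}, or a plain numeric matrix
#'   (genes x samples).
#' @param sd_threshold Non-negative SD threshold; comparison is strict.
#' @param scale \code{"raw"} uses the values as given; \code{"log2"} first
#'   transforms to \code{log2(signal + 1)}.
#' @param center \code{"grand"} (default) subtracts the single grand mean;
#'   \code{"gene"} centers every gene at its own mean (alternative reading
#'   of grand-mean normalization).
#' @return A \code{CenteredMatrix} list: \code{matrix} (retained genes x
#'   samples, centered), \code{gene_sd} (all genes), \code{mask} (logical,
#'   all genes), \code{sd_threshold}, \code{scale}, \code{center}.
#' @export
center_and_filter <- function(study, sd_threshold = 1,
                              scale = c("raw", "log2"),
                              center = c("grand", "gene")) {
  scale <- match.arg(scale); center <- match.arg(center)
  if (sd_threshold < 0) stop("sd_threshold must be >= 0")
  m <- if (inherits(study, "ExpressionStudy")) study$signal else study
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < 2) stop("need >= 2 samples")
  if (scale == "log2") m <- log2(m + 1)
  cm <- switch(center,
               grand = m - mean(m),
               gene = m - rowMeans(m))
  gene_sd <- apply(cm, 1, stats::sd)
  mask <- gene_sd > sd_threshold
  structure(list(matrix = cm[mask, , drop = FALSE],
                 gene_sd = gene_sd, mask = mask,
                 sd_threshold = sd_threshold, scale = scale,
                 center = center),
            class = "CenteredMatrix")
}

#' @export
print.CenteredMatrix <- function(x, ...) {
  cat(sprintf("CenteredMatrix: %d / %d genes with SD > %g (%s scale, %s centering)\n",
              nrow(x$matrix), length(x$mask), x$sd_threshold, x$scale,
              x$center))
  invisible(x)
}

#' Pearson dissimilarity matrix
#'
#' \code{d = 1 - r} with r the Pearson correlation; 0 for identical shapes,
#' 2 for exact anti-correlation.
#'
#' @param m Numeric matrix (genes x samples) or a \code{CenteredMatrix}.
#' @param axis \code{"samples"} correlates columns (the default, matching
#'   sample clustering); \code{"genes"} correlates rows.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
pearson_dissimilarity <- function(m, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  if (inherits(m, "CenteredMatrix")) m <- m$matrix
  stopifnot(is.matrix(m), is.numeric(m))
  v <- if (axis == "samples") m else t(m)
  if (ncol(v) < 2) stop("need >= 2 vectors to compare")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(v)[sds == 0][1]
    if (is.null(bad)) bad <- which(sds == 0)[1]
    stop(sprintf("zero-variance vector: '%s'", bad))
  }
  d <- 1 - stats::cor(v)
  d[d < 0] <- 0          # guard FP noise; exact correlations give d = 0
  diag(d) <- 0
  d
}

#' Agglomerative clustering with Ward linkage
#'
#' Runs \code{stats::hclust} on the dissimilarity matrix. The default
#' dialect, \code{"ward.D2"}, applies Ward's minimum-variance criterion to
#' squared dissimilarities; the historical unsquared variant
#' (\code{"ward.D"}) and the alternative linkages used for robustness checks
#' are available behind the same flag.
#'
#' @param d Symmetric dissimilarity matrix (or \code{dist}).
#' @param method \code{"ward.D2"} (default), \code{"ward.D"},
#'   \code{"average"} or \code{"complete"}.
#' @return An \code{hclust} object (merge table, heights, leaf order).
#' @export
ward_cluster <- function(d, method = c("ward.D2", "ward.D", "average",
                                       "complete")) {
  method <- match.arg(method)
  if (!inherits(d, "dist")) {
    stopifnot(is.matrix(d))
    if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
    if (any(d < 0)) stop("distances must be non-negative")
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = method)
}

#' Cut a dendrogram into k clusters
#'
#' @param hc An \code{hclust} object.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return Integer cluster labels named by leaf.
#' @export
cut_tree <- function(hc, k) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$order)
  if (k < 1 || k > n) stop(sprintf("k = %g out of range [1, %d]", k, n))
  stats::cutree(hc, k = k)
}

#' Export a dendrogram as a Newick string / file
#'
#' Branch lengths are derived from the merge heights (via
#' \code{ape::as.phylo}).
#'
#' @param hc An \code{hclust} object.
#' @param path Optional file path; when given the tree is written there.
#' @return The Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Heat map of the variance-filtered matrix
#'
#' Samples in rows, genes in columns, both ordered by hierarchical
#' clustering on Pearson dissimilarity (Ward linkage for samples, the same
#' metric for genes, which are clustered solely to order the display). The
#' underlying ordered matrix is also written as TSV when \code{matrix_path}
#' is given.
#'
#' @param centered A \code{CenteredMatrix}.
#' @param file Optional image path (png/pdf, decided by extension) passed to
#'   \code{pheatmap}.
#' @param matrix_path Optional TSV path for the displayed (ordered) matrix.
#' @return Invisibly, a list with the sample \code{hclust}, the gene
#'   \code{hclust} and the ordered matrix.
#' @export
expression_heatmap <- function(centered, file = NULL, matrix_path = NULL) {
  stopifnot(inherits(centered, "CenteredMatrix"))
  m <- centered$matrix
  if (nrow(m) < 2) stop("need >= 2 retained genes")
  hs <- ward_cluster(pearson_dissimilarity(m, "samples"), "ward.D2")
  hg <- ward_cluster(pearson_dissimilarity(m, "genes"), "ward.D2")
  disp <- t(m)[hs$order, hg$order, drop = FALSE]
  if (!is.null(file))
    pheatmap::pheatmap(disp, cluster_rows = FALSE, cluster_cols = FALSE,
                       show_colnames = ncol(disp) <= 60, filename = file)
  if (!is.null(matrix_path))
    write_numeric_tsv(disp, "sample", matrix_path)
  invisible(list(sample_hclust = hs, gene_hclust = hg, matrix = disp))
}
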