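# Mutual-information coexpression network over the high-variability genes.
# MI is estimated by the plug-in (maximum-likelihood) estimator on a binned
# joint histogram; with single-replicate designs only ~8 samples are
# available, so bins are few (default B = 3, equal-frequency) and the
# small-sample bias is large but common to all pairs — module significance
# is therefore judged against a permutation null, never against absolute MI.

#' Discretize expression rows into B bins
#'
#' Equal-frequency binning splits each gene's values, ordered by value and
#' then by input position (a deterministic tie-break), into B groups whose
#' sizes differ by at most one. A constant gene occupies the single bin 0.
#'
#' @param m Numeric matrix (genes x samples) or \code{CenteredMatrix}.
#' @param B Number of bins, \code{2 <= B <= n samples}.
#' @param scheme \code{"equal_frequency"} (default) or \code{"equal_width"}.
#' @return A \code{DiscretizedMatrix} list: \code{labels} (integer matrix,
#'   values in \code{0:(B-1)}), \code{B}, \code{scheme}.
#' @export
discretize <- function(m, B = 3, scheme = c("equal_frequency", "equal_width")) {
  scheme <- match.arg(scheme)
  if (inherits(m, "CenteredMatrix")) m <- m$matrix
  stopifnot(is.matrix(m), is.numeric(m))
  n <- ncol(m)
  if (B < 2) stop("B must be >= 2")
  if (B > n) stop(sprintf("B = %d exceeds the number of samples (%d)", B, n))
  sizes <- rep(n %/% B, B) + c(rep(1, n %% B), rep(0, B - n %% B))
  bin_of_rank <- rep.int(0:(B - 1), sizes)
  labels <- t(apply(m, 1, function(x) {
    if (max(x) == min(x)) return(rep.int(0L, n))
    if (scheme == "equal_frequency") {
      lab <- integer(n)
      lab[order(x)] <- bin_of_rank     # order() is stable: ties by position
      lab
    } else {
      br <- seq(min(x), max(x), length.out = B + 1)
      pmin(findInterval(x, br, rightmost.closed = TRUE) - 1L, B - 1L)
    }
  }))
  storage.mode(labels) <- "integer"
  dimnames(labels) <- dimnames(m)
  structure(list(labels = labels, B = as.integer(B), scheme = scheme),
            class = "DiscretizedMatrix")
}

#' Plug-in mutual information between two label vectors
#'
#' \deqn{MI = \sum_{a,b} \hat p(a,b) \log_2 \frac{\hat p(a,b)}{\hat p(a)\hat p(b)}}
#' over the B x B joint histogram, with \eqn{0 \log 0 := 0}. In bits.
#'
#' @param x,y Integer label vectors of equal length with values in
#'   \code{0:(B-1)}.
#' @param B Number of bins.
#' @return Mutual information in bits; \code{mutual_information(x, x, B)}
#'   equals the entropy of x.
#' @export
mutual_information <- function(x, y, B) {
  if (length(x) != length(y))
    stop(sprintf("length mismatch: %d vs %d", length(x), length(y)))
  n <- length(x)
  if (n < 2) stop("need >= 2 observations")
  if (any(x < 0 | x >= B) || any(y < 0 | y >= B))
    stop("labels must lie in [0, B)")
  joint <- tabulate(x * B + y + 1L, nbins = B * B) / n
  jm <- matrix(joint, B, B, byrow = TRUE)   # rows = x, cols = y
  px <- rowSums(jm); py <- colSums(jm)
  nz <- jm > 0
  sum(jm[nz] * log2(jm[nz] / outer(px, py)[nz]))
}

#' Entropy of a label vector in bits
#' @inheritParams mutual_information
#' @return Plug-in entropy estimate in bits.
#' @export
label_entropy <- function(x, B) {
  p <- tabulate(x + 1L, nbins = B) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual-information adjacency matrix
#'
#' All pairwise plug-in MI values over the (variance-filtered) gene set;
#' the diagonal holds each gene's entropy. Computed from bin-indicator
#' matrix products, so it is exactly the pairwise plug-in estimate but runs
#' in O(B^2 G^2) vectorized operations.
#'
#' @param m \code{CenteredMatrix}, \code{DiscretizedMatrix} or numeric
#'   matrix (genes x samples).
#' @param B,scheme Passed to \code{\link{discretize}} when \code{m} is not
#'   already discretized.
#' @return An \code{MIMatrix} list: \code{mi} (symmetric genes x genes, bits,
#'   diagonal = entropies), \code{entropy}, \code{B}, \code{scheme}.
#' @export
mi_adjacency <- function(m, B = 3, scheme = "equal_frequency") {
  dm <- if (inherits(m, "DiscretizedMatrix")) m else discretize(m, B, scheme)
  lab <- dm$labels; B <- dm$B
  n <- ncol(lab); G <- nrow(lab)
  if (G < 2) stop("need >= 2 genes")
  ind <- lapply(0:(B - 1), function(b) (lab == b) * 1)   # G x n indicators
  marg <- vapply(ind, rowSums, numeric(G)) / n            # G x B
  mi <- matrix(0, G, G)
  for (a in seq_len(B)) for (b in seq_len(B)) {
    Pab <- (ind[[a]] %*% t(ind[[b]])) / n                 # joint prob, all pairs
    denom <- outer(marg[, a], marg[, b])
    nz <- Pab > 0
    term <- matrix(0, G, G)
    term[nz] <- Pab[nz] * log2(Pab[nz] / denom[nz])
    mi <- mi + term
  }
  mi[mi < 0] <- 0                                         # FP guard only
  mi <- (mi + t(mi)) / 2                                  # exact symmetry
  dimnames(mi) <- list(rownames(lab), rownames(lab))
  structure(list(mi = mi, entropy = diag(mi), B = B, scheme = dm$scheme),
            class = "MIMatrix")
}

#' Transform an MI matrix into a distance matrix
#'
#' \code{"one_minus_nmi"}: \eqn{d = 1 - MI_{ij}/\sqrt{H_i H_j}} in [0, 1],
#' zero for informationally identical genes. A zero-entropy gene cannot be
#' normalized; its distances are set to 1 and its ids are recorded in the
#' \code{"flagged"} attribute. \code{"max_shift"}: \code{max(MI) - MI}
#' rescaled to [0, 1].
#'
#' @param mi An \code{MIMatrix}.
#' @param mode \code{"one_minus_nmi"} (default) or \code{"max_shift"}.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
mi_distance <- function(mi, mode = c("one_minus_nmi", "max_shift")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mi, "MIMatrix"))
  M <- mi$mi; H <- mi$entropy
  if (mode == "one_minus_nmi") {
    flagged <- names(H)[H == 0]
    if (is.null(flagged)) flagged <- which(H == 0)
    denom <- sqrt(outer(H, H))
    d <- 1 - M / denom
    d[!is.finite(d)] <- 1
    d <- pmin(pmax(d, 0), 1)
    if (length(flagged))
      warning(sprintf("zero-entropy gene(s) set to distance 1: %s",
                      paste(flagged, collapse = ", ")))
  } else {
    off <- M; diag(off) <- NA
    hi <- max(off, na.rm = TRUE); lo <- min(off, na.rm = TRUE)
    d <- if (hi > lo) (hi - M) / (hi - lo) else matrix(0, nrow(M), ncol(M))
    d <- pmin(pmax(d, 0), 1)
    flagged <- character()
  }
  diag(d) <- 0
  dimnames(d) <- dimnames(M)
  attr(d, "flagged") <- flagged
  d
}

module_separation <- function(members, mi) {
  idx <- match(members, rownames(mi))
  inside <- mi[idx, idx, drop = FALSE]
  intra <- mean(inside[upper.tri(inside)])
  extra <- mean(mi[idx, -idx, drop = FALSE])
  c(intra = intra, extra = extra, separation = intra - extra)
}

#' Detect network modules from an MI adjacency
#'
#' A module is a set of genes with short mutual distances and long distances
#' to everything else. Candidate gene sets come from hierarchical clustering
#' of the MI distance matrix (average linkage by default): by default every
#' cluster appearing anywhere in the dendrogram (each internal node's leaf
#' set, i.e. the union of all tree cuts) is a candidate; a finite
#' \code{n_candidate_cuts} restricts candidates to the cuts
#' \code{k = 2 .. n_candidate_cuts + 1}. Every candidate of size
#' \code{min_size .. n_genes - 1} is scored by its separation,
#' \code{mean(intra-module MI) - mean(MI to non-members)}. Because nested
#' tree clusters overlap heavily, reported modules are made disjoint: scored
#' candidates are accepted greedily by descending separation, skipping any
#' that shares a gene with an already-accepted module. The result is sorted
#' by separation (the first is the most prominent module).
#'
#' @param mi An \code{MIMatrix} over the variance-filtered genes.
#' @param min_size Minimum module size (>= 3; default 4).
#' @param n_candidate_cuts Number of tree cuts generating candidates;
#'   \code{NULL} (default) considers every cluster in the tree.
#' @param linkage Linkage for the candidate tree (default \code{"average"};
#'   Ward assumes Euclidean-like distances, which MI distances are not).
#' @param distance_mode Passed to \code{\link{mi_distance}}.
#' @return A \code{NetworkModuleList}: list of modules, each with
#'   \code{members}, \code{intra}, \code{extra}, \code{separation}; may be
#'   empty.
#' @export
detect_modules <- function(mi, min_size = 4, n_candidate_cuts = NULL,
                           linkage = "average",
                           distance_mode = "one_minus_nmi") {
  stopifnot(inherits(mi, "MIMatrix"))
  if (min_size < 3) stop("min_size must be >= 3")
  d <- suppressWarnings(mi_distance(mi, distance_mode))
  G <- nrow(mi$mi)
  if (G <= min_size)
    return(structure(list(), class = "NetworkModuleList"))
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  if (is.null(n_candidate_cuts)) {
    # leaf set of every internal node = union of all tree cuts
    node_leaves <- vector("list", G - 1)
    for (i in seq_len(G - 1)) {
      kids <- hc$merge[i, ]
      node_leaves[[i]] <- c(
        if (kids[1] < 0) hc$labels[-kids[1]] else node_leaves[[kids[1]]],
        if (kids[2] < 0) hc$labels[-kids[2]] else node_leaves[[kids[2]]])
    }
    candidates <- node_leaves
  } else {
    cl <- stats::cutree(hc, k = 2:min(n_candidate_cuts + 1, G - 1))
    candidates <- unlist(lapply(seq_len(ncol(cl)), function(j)
      split(rownames(cl), cl[, j])), recursive = FALSE)
  }
  seen <- character(); mods <- list()
  for (members in candidates) {
    members <- sort(members)
    if (length(members) < min_size || length(members) >= G) next
    key <- paste(members, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    sc <- module_separation(members, mi$mi)
    if (sc[["separation"]] > 0)
      mods[[length(mods) + 1]] <- list(members = members,
                                       intra = sc[["intra"]],
                                       extra = sc[["extra"]],
                                       separation = sc[["separation"]])
  }
  if (length(mods)) {
    ord <- order(-vapply(mods, `[[`, 0, "separation"),
                 vapply(mods, function(m) m$members[1], ""))
    mods <- mods[ord]
    taken <- character(); keep <- logical(length(mods))
    for (i in seq_along(mods)) {
      if (!any(mods[[i]]$members %in% taken)) {
        keep[i] <- TRUE
        taken <- c(taken, mods[[i]]$members)
      }
    }
    mods <- mods[keep]
  }
  structure(mods, class = "NetworkModuleList")
}

#' @export
print.NetworkModuleList <- function(x, ...) {
  cat(sprintf("NetworkModuleList: %d module(s)\n", length(x)))
  for (i in seq_along(utils::head(x, 5)))
    cat(sprintf("  #%d: %d genes, separation %.3f (intra %.3f, extra %.3f)\n",
                i, length(x[[i]]$members), x[[i]]$separation, x[[i]]$intra,
                x[[i]]$extra))
  invisible(x)
}

#' Permutation null for the top-module separation
#'
#' Destroys gene-gene dependence by independently permuting every gene's
#' sample labels, then records the best module separation found by
#' \code{\link{detect_modules}} on the permuted data. The 95th percentile of
#' these values is the usual threshold a reported module must beat.
#'
#' @param m Numeric matrix (genes x samples) or \code{CenteredMatrix} —
#'   the same matrix that fed \code{\link{mi_adjacency}}.
#' @param n_perm Number of permutations.
#' @param B,scheme,min_size,n_candidate_cuts,linkage,distance_mode As in the
#'   observed analysis.
#' @return Numeric vector of length \code{n_perm}: max separation per
#'   permutation (0 when no positive-separation module was found).
#' @export
null_module_separation <- function(m, n_perm = 100, B = 3,
                                   scheme = "equal_frequency",
                                   min_size = 4, n_candidate_cuts = NULL,
                                   linkage = "average",
                                   distance_mode = "one_minus_nmi") {
  if (inherits(m, "CenteredMatrix")) m <- m$matrix
  stopifnot(is.matrix(m))
  n <- ncol(m)
  vapply(seq_len(n_perm), function(i) {
    pm <- t(apply(m, 1, function(x) x[sample.int(n)]))
    dimnames(pm) <- dimnames(m)
    mods <- detect_modules(mi_adjacency(pm, B, scheme), min_size,
                           n_candidate_cuts, linkage, distance_mode)
    if (length(mods)) mods[[1]]$separation else 0
  }, numeric(1))
}

#' Write network artifacts: edge list and module membership
#'
#' @param mi An \code{MIMatrix}.
#' @param modules A \code{NetworkModuleList}.
#' @param edge_path TSV of edges \code{gene_a, gene_b, mi, distance},
#'   restricted to the strongest edges for readability.
#' @param module_path TSV of \code{gene, module, separation}.
#' @param top_edges Number of strongest edges to keep (default 500).
#' @param distance_mode Passed to \code{\link{mi_distance}}.
#' @return Invisibly, the edge data frame.
#' @export
write_network <- function(mi, modules, edge_path, module_path,
                          top_edges = 500, distance_mode = "one_minus_nmi") {
  d <- suppressWarnings(mi_distance(mi, distance_mode))
  ut <- which(upper.tri(mi$mi), arr.ind = TRUE)
  edges <- data.frame(gene_a = rownames(mi$mi)[ut[, 1]],
                      gene_b = rownames(mi$mi)[ut[, 2]],
                      mi = mi$mi[ut], distance = d[ut])
  edges <- edges[order(-edges$mi), , drop = FALSE]
  edges <- utils::head(edges, top_edges)
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mem <- do.call(rbind, lapply(seq_along(modules), function(i)
    data.frame(gene = modules[[i]]$members, module = i,
               separation = modules[[i]]$separation)))
  if (is.null(mem))
    mem <- data.frame(gene = character(), module = integer(),
                      separation = numeric())
  utils::write.table(mem, module_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edges)
}
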