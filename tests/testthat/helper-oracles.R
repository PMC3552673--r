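# Independent oracles, deliberately written with brute force / naive loops,
# never sharing code paths with the package implementation.

# Exhaustive hypergeometric strictly-greater tail: enumerate every size-n
# subset of 1..M, mark 1..K, count subsets with overlap > r.
hyper_tail_enum <- function(M, K, n, r) {
  if (n == 0) return(0)
  subsets <- utils::combn(M, n)
  hits <- colSums(subsets <= K)
  sum(hits > r) / ncol(subsets)
}

# Plug-in mutual information via explicit nested loops over the joint table.
mi_oracle <- function(x, y, B) {
  n <- length(x)
  mi <- 0
  for (a in 0:(B - 1)) for (b in 0:(B - 1)) {
    pab <- sum(x == a & y == b) / n
    if (pab > 0) {
      pa <- sum(x == a) / n
      pb <- sum(y == b) / n
      mi <- mi + pab * log2(pab / (pa * pb))
    }
  }
  mi
}

entropy_oracle <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

# Agglomerative Ward (D2 dialect) by direct Lance-Williams recurrence on
# squared distances; returns the sorted merge heights.
ward_heights_lw <- function(d) {
  n <- nrow(d)
  d2 <- d^2
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(0)
  repeat {
    k <- length(active)
    if (k == 1) break
    best <- c(Inf, NA, NA)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (d2[active[i], active[j]] < best[1])
        best <- c(d2[active[i], active[j]], i, j)
    }
    i <- active[best[2]]; j <- active[best[3]]
    heights <- c(heights, sqrt(best[1]))
    # Lance-Williams update for Ward on squared distances
    ni <- size[i]; nj <- size[j]
    for (h in setdiff(active, c(i, j))) {
      nh <- size[h]
      d2[i, h] <- d2[h, i] <-
        ((ni + nh) * d2[i, h] + (nj + nh) * d2[j, h] - nh * d2[i, j]) /
        (ni + nj + nh)
    }
    size[i] <- ni + nj
    active <- setdiff(active, active[best[3]])
  }
  heights
}

# Tiny handcrafted study used across io / regression tests.
make_toy_study <- function() {
  signal <- matrix(c(10, 20, 25, 50,  11, 12, 13, 14,
                     5, 5, 5, 5,      3, 6, 12, 24,
                     100, 90, 60, 20, 7, 7, 8, 9,
                     1, 2, 4, 8,      2, 2, 2, 2,
                     50, 50, 51, 52,  40, 41, 39, 38),
                   nrow = 5, byrow = TRUE,
                   dimnames = list(paste0("pr", 1:5),
                                   c("a1", "a2", "a3", "a4",
                                     "b1", "b2", "b3", "b4")))
  calls <- matrix("P", 5, 8, dimnames = dimnames(signal))
  calls[2, ] <- "A"                      # absent everywhere
  calls[3, ] <- c("A", "M", "A", "A", "A", "A", "A", "A")  # only marginal
  calls[4, 2] <- "P"
  calls[4, -2] <- "A"                    # present exactly once
  design <- data.frame(sample_id = colnames(signal),
                       time_days = rep(c(1, 13), each = 4),
                       dose_uM = c(0, 9, 27, 45, 0, 4.5, 9, 27))
  expression_study(signal, calls, design)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
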