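test_that("equal-frequency discretization matches the sort-and-split oracle", {
  m <- matrix(c(1, 2, 2, 3, 5, 8, 9, 9), 1, 8,
              dimnames = list("g1", paste0("s", 1:8)))
  dm <- discretize(m, 2)
  # rank-split oracle: lowest 4 values (1,2,2,3) -> bin 0, rest -> bin 1
  expect_identical(unname(dm$labels[1, ]), c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
  # B = 2 on 8 samples: two bins of 4
  expect_equal(as.integer(table(dm$labels)), c(4L, 4L))
  # ties broken by input position: all-tied values split deterministically,
  # but a constant gene collapses to a single bin
  mc <- matrix(7, 1, 8, dimnames = list("flat", paste0("s", 1:8)))
  expect_true(all(discretize(mc, 3)$labels == 0L))
  # bins differ in size by <= 1 when n mod B != 0
  m3 <- matrix(rnorm(8), 1, 8, dimnames = list("g", paste0("s", 1:8)))
  tab <- table(discretize(m3, 3)$labels)
  expect_lte(diff(range(tab)), 1)
  expect_error(discretize(m3, 9), "exceeds")
  expect_error(discretize(m3, 1), ">= 2")
})

test_that("equal-width discretization respects value ranges", {
  m <- matrix(c(0, 1, 2, 3, 4, 6, 9, 10), 1, 8,
              dimnames = list("g", paste0("s", 1:8)))
  dm <- discretize(m, 2, "equal_width")
  # bins [0, 5) and [5, 10]
  expect_identical(unname(dm$labels[1, ]), c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L))
})

test_that("mutual information reproduces hand-computed joint tables", {
  # x = y with two equal bins: MI = H = 1 bit
  x <- rep(c(0L, 1L), each = 4)
  expect_equal(mutual_information(x, x, 2), 1)
  # exact independence: joint [[2,2],[2,2]]
  y_ind <- rep(c(0L, 1L), 4)
  expect_equal(mutual_information(x, y_ind, 2), 0)
  # joint [[3,1],[1,3]]: 0.75 log2(1.5) + 0.25 log2(0.5)
  y_dep <- c(0L, 0L, 0L, 1L, 0L, 1L, 1L, 1L)
  expect_equal(mutual_information(x, y_dep, 2),
               0.75 * log2(1.5) - 0.25, tolerance = 1e-12)
  expect_error(mutual_information(x, x[-1], 2), "length mismatch")
})

test_that("MI equals the nested-loop oracle and respects entropy bounds", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    B <- sample(2:4, 1)
    x <- sample(0:(B - 1), n, replace = TRUE)
    y <- sample(0:(B - 1), n, replace = TRUE)
    mi <- mutual_information(x, y, B)
    expect_lt(abs(mi - mi_oracle(x, y, B)), 1e-12)
    expect_gte(mi, -1e-12)
    expect_lte(mi, min(entropy_oracle(x), entropy_oracle(y)) + 1e-12)
    expect_lt(abs(mutual_information(x, x, B) - entropy_oracle(x)), 1e-12)
  }
})

test_that("mi_adjacency equals pairwise scalar MI, is symmetric, diag = H", {
  set.seed(21)
  m <- matrix(rnorm(15 * 8), 15, 8,
              dimnames = list(paste0("g", 1:15), paste0("s", 1:8)))
  dm <- discretize(m, 3)
  A <- mi_adjacency(dm)
  expect_identical(A$mi, t(A$mi))
  for (i in c(1, 4, 9)) for (j in c(2, 7, 15))
    expect_equal(A$mi[i, j],
                 mutual_information(dm$labels[i, ], dm$labels[j, ], 3),
                 tolerance = 1e-12)
  expect_equal(unname(diag(A$mi)),
               unname(apply(dm$labels, 1, label_entropy, 3)),
               tolerance = 1e-12)
  # two identical genes: off-diagonal MI equals the diagonal entropy
  m2 <- rbind(a = m[1, ], b = m[1, ])
  A2 <- mi_adjacency(m2, 3)
  expect_equal(A2$mi["a", "b"], A2$mi["a", "a"], tolerance = 1e-12)
})

test_that("independent genes show only small-sample-bias MI", {
  set.seed(31)
  m <- matrix(rnorm(40 * 8), 40, 8,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:8)))
  A <- mi_adjacency(m, 3)
  off <- A$mi[upper.tri(A$mi)]
  # permutation-null bound for the mean bias
  perms <- replicate(100, {
    x <- sample(0:2, 8, replace = TRUE)[order(runif(8))]
    dm <- discretize(m[1:2, ], 3)
    mutual_information(dm$labels[1, ], sample(dm$labels[2, ]), 3)
  })
  expect_lt(mean(off), mean(perms) + 3 * sd(perms) / sqrt(length(perms)) + 0.1)
})

test_that("mi_distance implements both transforms with correct ranges", {
  m <- matrix(rnorm(24), 3, 8,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:8)))
  m <- rbind(m, a2 = m["a", ])
  A <- mi_adjacency(m, 3)
  d <- mi_distance(A, "one_minus_nmi")
  expect_equal(d["a", "a2"], 0, tolerance = 1e-12)  # identical genes
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  expect_true(all(d >= 0 & d <= 1))
  # direct formula check on one off-diagonal entry
  expect_equal(d["a", "b"],
               1 - A$mi["a", "b"] / sqrt(A$mi["a", "a"] * A$mi["b", "b"]),
               tolerance = 1e-12)
  dm <- mi_distance(A, "max_shift")
  expect_true(all(dm >= 0 & dm <= 1))
  expect_equal(diag(dm), rep(0, 4), ignore_attr = TRUE)
  # an MI = 0 pair sits at distance 1 under one_minus_nmi
  x <- rep(c(0, 1), each = 4)
  m0 <- rbind(p = x, q = rep(c(0, 1), 4))
  A0 <- mi_adjacency(m0, 2)
  expect_equal(mi_distance(A0)["p", "q"], 1, tolerance = 1e-12)
})

test_that("zero-entropy genes are flagged and pushed to distance 1", {
  m <- rbind(flat = rep(1, 8),
             var1 = rnorm(8), var2 = rnorm(8), var3 = rnorm(8))
  colnames(m) <- paste0("s", 1:8)
  A <- mi_adjacency(m, 3)
  expect_warning(d <- mi_distance(A), "flat")
  expect_true(all(d["flat", setdiff(rownames(d), "flat")] == 1))
})

test_that("detect_modules recovers a strongly planted module", {
  sim <- simulate_study(sim_config(
    seed = 5, module_specs = list(list(size = 8, driver_strength = 6,
                                       driver_shape = "linear"))))
  cf <- center_and_filter(filter_present(sim$study), 1, "log2")
  mods <- detect_modules(mi_adjacency(cf$matrix))
  planted <- sim$truth$probe[!is.na(sim$truth$module_id)]
  expect_gte(jaccard(mods[[1]]$members, planted), 0.8)
  expect_gt(mods[[1]]$separation, 0)
  expect_gt(mods[[1]]$intra, mods[[1]]$extra)
})

test_that("module detection is invariant to gene input order", {
  sim <- simulate_study(sim_config(
    n_genes = 300, seed = 6,
    module_specs = list(list(size = 8, driver_strength = 6,
                             driver_shape = "linear"))))
  cf <- center_and_filter(filter_present(sim$study), 1, "log2")
  m <- cf$matrix
  mods1 <- detect_modules(mi_adjacency(m))
  set.seed(1)
  perm <- sample.int(nrow(m))
  mods2 <- detect_modules(mi_adjacency(m[perm, ]))
  expect_identical(mods1[[1]]$members, mods2[[1]]$members)
  expect_equal(mods1[[1]]$separation, mods2[[1]]$separation, tolerance = 1e-12)
})

test_that("module recovery improves with driver strength", {
  grid <- c(1.5, 3, 6)
  jac <- vapply(grid, function(st) {
    mean(vapply(1:5, function(s) {
      sim <- simulate_study(sim_config(
        seed = 400 + s, module_specs = list(list(size = 8,
                                                 driver_strength = st,
                                                 driver_shape = "linear"))))
      cf <- center_and_filter(filter_present(sim$study), 0, "log2")
      top <- names(sort(cf$gene_sd, decreasing = TRUE))[1:60]
      mods <- detect_modules(mi_adjacency(cf$matrix[top, ]))
      planted <- sim$truth$probe[!is.na(sim$truth$module_id)]
      if (length(mods)) jaccard(mods[[1]]$members, planted) else 0
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(jac) >= 0))
})

test_that("two planted modules are both recovered among the top two", {
  sim <- simulate_study(sim_config(
    n_genes = 1000, seed = 7,
    module_specs = list(
      list(size = 8, driver_strength = 6, driver_shape = "linear"),
      list(size = 12, driver_strength = 6, driver_shape = "saturating"))))
  cf <- center_and_filter(filter_present(sim$study), 1, "log2")
  mods <- detect_modules(mi_adjacency(cf$matrix))
  expect_gte(length(mods), 2)
  tr <- sim$truth
  planted <- lapply(1:2, function(k) tr$probe[!is.na(tr$module_id) &
                                              tr$module_id == k])
  top2 <- lapply(mods[1:2], `[[`, "members")
  best <- sapply(planted, function(p) max(sapply(top2, jaccard, p)))
  expect_true(all(best >= 0.7))
})

test_that("module artifacts are written as edge list and membership table", {
  sim <- simulate_study(sim_config(
    n_genes = 200, seed = 8,
    module_specs = list(list(size = 8, driver_strength = 6,
                             driver_shape = "linear"))))
  cf <- center_and_filter(filter_present(sim$study), 1, "log2")
  A <- mi_adjacency(cf$matrix)
  mods <- detect_modules(A)
  td <- withr::local_tempdir()
  ep <- file.path(td, "edges.tsv"); mp <- file.path(td, "modules.tsv")
  write_network(A, mods, ep, mp, top_edges = 50)
  edges <- read.delim(ep)
  expect_lte(nrow(edges), 50)
  expect_true(all(diff(edges$mi) <= 0))
  mem <- read.delim(mp)
  expect_setequal(mem$gene[mem$module == 1], mods[[1]]$members)
})
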