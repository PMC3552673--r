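# Synthetic microarray studies with the statistical structure the pipeline
# assumes: dose-linear responders on the log2 scale, responders shared across
# the two exposure blocks, planted co-regulated modules driven by a shared
# latent variable, and MAS5-style Present/Absent calls. A per-gene truth
# table makes every downstream stage testable without real data.

#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline targets: a 1-day block at
#' 0/9/27/45 uM Cd2+ and a 13-day block at 0/4.5/9/27 uM, one sample per
#' condition, a small minority of dose-correlated genes per block, half of
#' the 13-day responders shared with the 1-day block, and one tightly
#' co-regulated 8-gene module.
#'
#' @param n_genes Number of simulated probes (one probe per row).
#' @param doses_block1,doses_block2 Dose series (uM), strictly increasing,
#'   starting at 0 (control), at least 3 doses each.
#' @param frac_pos_block1,frac_neg_block1 Fractions of genes with positive /
#'   negative dose response in the 1-day block.
#' @param frac_pos_block2,frac_neg_block2 Same for the 13-day block.
#' @param frac_shared Fraction of block-2 responders (per sign) drawn from
#'   the block-1 responders of the same sign (capped by availability).
#' @param slope_scale Typical effect size, log2-signal per uM; per-gene
#'   |slope| is uniform on \code{slope_scale * [0.5, 1.5]}.
#' @param noise_sd Residual SD on the log2 scale.
#' @param baseline_log2_mean,baseline_log2_sd Normal baseline of log2 signal.
#' @param module_specs List of module descriptions, each a list with
#'   \code{size}, \code{driver_strength} (log2 range of the driver across
#'   samples), \code{driver_shape} (\code{"linear"} or \code{"saturating"})
#'   and optional \code{driver_jitter_sd} (SD of the latent noise that
#'   shuffles the driver's sample ordering away from pure dose order;
#'   default 0.5 on the unit dose scale). The driver takes equally spaced
#'   activation levels across the samples, ordered by dose trend plus this
#'   jitter, and every member sees the same realization scaled by its
#'   loading.
#' @param absent_prob_low_expr Probability that a call is "A" for genes in
#'   the lowest baseline quartile.
#' @param frac_multi_probe Fraction of probes assigned a symbol shared with
#'   another probe (exercises probe-to-gene collapsing).
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A \code{SimulationConfig} list.
#' @export
sim_config <- function(n_genes = 2000,
                       doses_block1 = c(0, 9, 27, 45),
                       doses_block2 = c(0, 4.5, 9, 27),
                       frac_pos_block1 = 0.02, frac_neg_block1 = 0.02,
                       frac_pos_block2 = 0.02, frac_neg_block2 = 0.02,
                       frac_shared = 0.5,
                       slope_scale = 0.05,
                       noise_sd = 0.3,
                       baseline_log2_mean = 7, baseline_log2_sd = 2,
                       module_specs = list(list(size = 8,
                                                driver_strength = 1.5,
                                                driver_shape = "linear")),
                       absent_prob_low_expr = 0.3,
                       frac_multi_probe = 0.05,
                       seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              doses_block1 = as.numeric(doses_block1),
              doses_block2 = as.numeric(doses_block2),
              frac_pos_block1 = frac_pos_block1,
              frac_neg_block1 = frac_neg_block1,
              frac_pos_block2 = frac_pos_block2,
              frac_neg_block2 = frac_neg_block2,
              frac_shared = frac_shared,
              slope_scale = slope_scale, noise_sd = noise_sd,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              module_specs = module_specs,
              absent_prob_low_expr = absent_prob_low_expr,
              frac_multi_probe = frac_multi_probe,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1) stop("n_genes must be >= 1")
  for (b in c("doses_block1", "doses_block2")) {
    d <- cfg[[b]]
    if (length(unique(d)) < 3)
      stop(sprintf("%s needs >= 3 distinct doses (regression needs >= 1 residual df)", b))
    if (any(d < 0) || is.unsorted(d, strictly = TRUE))
      stop(sprintf("%s must be non-negative and strictly increasing", b))
    if (d[1] != 0) stop(sprintf("%s must start at dose 0 (control)", b))
  }
  fr <- c(cfg$frac_pos_block1, cfg$frac_neg_block1, cfg$frac_pos_block2,
          cfg$frac_neg_block2, cfg$frac_shared, cfg$absent_prob_low_expr,
          cfg$frac_multi_probe)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (cfg$frac_pos_block1 + cfg$frac_neg_block1 > 1 ||
      cfg$frac_pos_block2 + cfg$frac_neg_block2 > 1)
    stop("frac_pos + frac_neg must be <= 1 within each block")
  if (cfg$noise_sd < 0 || cfg$slope_scale < 0)
    stop("noise_sd and slope_scale must be non-negative")
  for (m in cfg$module_specs) {
    if (!all(c("size", "driver_strength", "driver_shape") %in% names(m)))
      stop("each module spec needs size, driver_strength, driver_shape")
    if (m$size > cfg$n_genes) stop("module size exceeds n_genes")
    if (m$size < 2) stop("module size must be >= 2")
    if (!m$driver_shape %in% c("linear", "saturating"))
      stop("driver_shape must be 'linear' or 'saturating'")
    if (!is.null(m$driver_jitter_sd) && m$driver_jitter_sd < 0)
      stop("driver_jitter_sd must be >= 0")
  }
  invisible(cfg)
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate an expression study with ground truth
#'
#' Data model, per gene g and sample s on the log2 scale:
#' \deqn{y_{gs} = baseline_g + slope_{g,block(s)} dose_s + load_g z_{m(g),s} + \epsilon_{gs}}
#' where \eqn{z_{m,s}} is a module driver shared by all members of module m
#' (a monotone function of dose plus a per-sample wiggle, the same
#' realization for every member) and \eqn{\epsilon} is Gaussian noise.
#' Signal is \eqn{2^{y}}, so effects are multiplicative on the signal scale.
#' Detection calls are "A" with probability \code{absent_prob_low_expr} for
#' genes in the lowest baseline quartile and "P" otherwise.
#'
#' @param config A \code{\link{sim_config}} object.
#' @return A \code{SimulatedStudy}: list with \code{study}
#'   (\code{\link{expression_study}}), \code{truth} (per-gene data frame:
#'   \code{probe}, \code{class_block1}, \code{class_block2}, \code{shared},
#'   \code{module_id}, \code{true_slope_block1}, \code{true_slope_block2})
#'   and \code{annotation} (probe/symbol/gene_name).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  validate_sim_config(config)
  with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  n <- cfg$n_genes
  probes <- sprintf("P%06d_at", seq_len(n))
  d1 <- cfg$doses_block1; d2 <- cfg$doses_block2
  design <- data.frame(
    sample_id = c(sprintf("d1_%guM", d1), sprintf("d13_%guM", d2)),
    time_days = c(rep(1, length(d1)), rep(13, length(d2))),
    dose_uM = c(d1, d2), stringsAsFactors = FALSE)
  # sanitize sample ids (doses may be fractional)
  design$sample_id <- gsub("\\.", "p", design$sample_id)
  ns <- nrow(design)

  n_pos1 <- round(cfg$frac_pos_block1 * n)
  n_neg1 <- round(cfg$frac_neg_block1 * n)
  n_pos2 <- round(cfg$frac_pos_block2 * n)
  n_neg2 <- round(cfg$frac_neg_block2 * n)
  mod_sizes <- vapply(cfg$module_specs, `[[`, 0, "size")
  if (n_pos1 + n_neg1 + sum(mod_sizes) > n ||
      n_pos2 + n_neg2 + sum(mod_sizes) > n)
    stop("responder fractions plus module sizes exceed n_genes")

  class1 <- class2 <- rep("null", n)
  perm <- sample.int(n)                       # block-1 responders
  pos1 <- perm[seq_len(n_pos1)]
  neg1 <- perm[n_pos1 + seq_len(n_neg1)]
  class1[pos1] <- "positive"; class1[neg1] <- "negative"

  n_sh_pos <- min(round(cfg$frac_shared * n_pos2), n_pos1)
  n_sh_neg <- min(round(cfg$frac_shared * n_neg2), n_neg1)
  pos2 <- c(if (n_sh_pos) sample(pos1, n_sh_pos),
            sample(which(class1 == "null"), n_pos2 - n_sh_pos))
  neg2 <- c(if (n_sh_neg) sample(neg1, n_sh_neg),
            sample(setdiff(which(class1 == "null"), pos2), n_neg2 - n_sh_neg))
  class2[pos2] <- "positive"; class2[neg2] <- "negative"
  shared <- class1 != "null" & class1 == class2

  slope1 <- slope2 <- numeric(n)
  rslope <- function(k) cfg$slope_scale * stats::runif(k, 0.5, 1.5)
  slope1[pos1] <- rslope(n_pos1);  slope1[neg1] <- -rslope(n_neg1)
  slope2[pos2] <- rslope(length(pos2)); slope2[neg2] <- -rslope(length(neg2))

  # planted modules: members drawn from genes untouched by dose classes
  module_id <- rep(NA_integer_, n)
  free <- which(class1 == "null" & class2 == "null")
  drivers <- matrix(0, length(cfg$module_specs), ns)
  loadings <- numeric(n)
  dmax <- max(design$dose_uM)
  for (m in seq_along(cfg$module_specs)) {
    spec <- cfg$module_specs[[m]]
    members <- sample(free, spec$size)
    free <- setdiff(free, members)
    module_id[members] <- m
    u <- design$dose_uM / dmax
    f <- switch(spec$driver_shape,
                linear = u,
                saturating = u / (u + 0.25))
    jit <- if (is.null(spec$driver_jitter_sd)) 0.5 else spec$driver_jitter_sd
    # one realization per module: graded activation levels, equally spaced
    # over [0, driver_strength], ordered by dose trend + latent jitter
    ord <- rank(f + stats::rnorm(ns, 0, jit), ties.method = "first")
    drivers[m, ] <- spec$driver_strength * (ord - 1) / (ns - 1)
    loadings[members] <- stats::runif(spec$size, 0.8, 1.2)
  }

  baseline <- stats::rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  in1 <- design$time_days == 1
  slope_term <- outer(slope1, ifelse(in1, design$dose_uM, 0)) +
    outer(slope2, ifelse(in1, 0, design$dose_uM))
  driver_term <- matrix(0, n, ns)
  has_mod <- which(!is.na(module_id))
  if (length(has_mod))
    driver_term[has_mod, ] <- loadings[has_mod] *
      drivers[module_id[has_mod], , drop = FALSE]
  y <- baseline + slope_term + driver_term +
    matrix(stats::rnorm(n * ns, 0, cfg$noise_sd), n, ns)
  signal <- 2^y
  dimnames(signal) <- list(probes, design$sample_id)

  calls <- matrix("P", n, ns, dimnames = dimnames(signal))
  lowq <- baseline <= stats::quantile(baseline, 0.25)
  nlow <- sum(lowq)
  if (nlow && cfg$absent_prob_low_expr > 0)
    calls[lowq, ] <- ifelse(
      matrix(stats::runif(nlow * ns), nlow, ns) < cfg$absent_prob_low_expr,
      "A", "P")

  # annotation: mostly 1:1 symbols, a configured fraction share a symbol
  symbol <- sprintf("G%06d", seq_len(n))
  n_multi <- round(cfg$frac_multi_probe * n)
  if (n_multi >= 2) {
    dup <- sample.int(n, n_multi)
    donor <- sample(setdiff(seq_len(n), dup), n_multi, replace = TRUE)
    symbol[dup] <- symbol[donor]
  }
  annotation <- data.frame(probe = probes, symbol = symbol,
                           gene_name = paste("synthetic gene", symbol),
                           stringsAsFactors = FALSE)

  truth <- data.frame(probe = probes, class_block1 = class1,
                      class_block2 = class2, shared = shared,
                      module_id = module_id,
                      true_slope_block1 = slope1, true_slope_block2 = slope2,
                      stringsAsFactors = FALSE)
  structure(list(study = expression_study(signal, calls, design),
                 truth = truth, annotation = annotation,
                 config = cfg),
            class = "SimulatedStudy")
}

#' @export
print.SimulatedStudy <- function(x, ...) {
  cat("SimulatedStudy\n")
  print(x$study)
  cat(sprintf("  truth: %d/%d responders block1, %d/%d block2, %d shared, %d module genes\n",
              sum(x$truth$class_block1 != "null"), nrow(x$truth),
              sum(x$truth$class_block2 != "null"), nrow(x$truth),
              sum(x$truth$shared), sum(!is.na(x$truth$module_id))))
  invisible(x)
}

#' Write a simulated study as the pipeline's standard file set
#'
#' @param sim A \code{SimulatedStudy}.
#' @param dir Output directory (created if needed). Files:
#'   \code{expression.tsv}, \code{calls.tsv}, \code{design.csv},
#'   \code{annotation.tsv}, \code{truth.tsv}.
#' @return Invisibly, the vector of written paths.
#' @export
write_simulated_study <- function(sim, dir) {
  stopifnot(inherits(sim, "SimulatedStudy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("expression.tsv", "calls.tsv", "design.csv",
                            "annotation.tsv", "truth.tsv"))
  write_expression(sim$study, paths[1], paths[2], paths[3])
  utils::write.table(sim$annotation, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, paths[5], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
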