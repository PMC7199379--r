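# Monte-Carlo data generators used to benchmark the screeners. Designs
# 2-4 share the frame n = 200, p = 5000 with the causal features first;
# the LD-block GWAS generator stands in for a real genotype matrix with
# linkage-disequilibrium structure.

#' Parameter tables of the simulation designs
#'
#' `sim2_probs()` returns the 2 x 10 matrix of conditional binomial
#' success probabilities \eqn{\pi_{mj}} (rows `Y=0`, `Y=1`) of the
#' conditional-binomial design; `sim3_cutoffs()` the 2 x 10 matrix of
#' latent-variable discretization cutoffs (rows `lower`, `upper`); and
#' `sim4_betas()` the 3 x 5 matrix of level-specific logistic coefficients
#' (rows for feature level 0, 1, 2).
#'
#' @return numeric matrix of design constants.
#' @export
sim2_probs <- function() {
  matrix(c(0.3, 0.4, 0.6, 0.7, 0.2, 0.4, 0.3, 0.8, 0.4, 0.2,
           0.6, 0.1, 0.1, 0.4, 0.8, 0.7, 0.9, 0.2, 0.7, 0.6),
         nrow = 2L, byrow = TRUE, dimnames = list(c("Y=0", "Y=1"), NULL))
}

#' @rdname sim2_probs
#' @export
sim3_cutoffs <- function() {
  matrix(c(0, 0, 0.2, 0, -0.2, 0.2, 0, 0.1, -0.2, 0.2,
           0.7, 1, 0.8, 0.9, 1.2, 1, 1, 1, 1.2, 0.8),
         nrow = 2L, byrow = TRUE, dimnames = list(c("lower", "upper"), NULL))
}

#' @rdname sim2_probs
#' @export
sim4_betas <- function() {
  matrix(c(0, -5, 2, -6, 1,
           3, -3, 4, -4, 3,
           5, -1, 6, -2, 5),
         nrow = 3L, byrow = TRUE, dimnames = list(c("X=0", "X=1", "X=2"), NULL))
}

# Linear predictor of the level-coefficient logistic design for an n x 5
# matrix of codes in {0,1,2}.
sim4_linear_predictor <- function(Xc) {
  beta <- sim4_betas()
  contrib <- vapply(seq_len(ncol(Xc)),
                    function(j) beta[Xc[, j] + 1L, j], numeric(nrow(Xc)))
  if (is.null(dim(contrib))) sum(contrib) else unname(rowSums(contrib))
}

new_replicate <- function(X, y, true_set, design, seed) {
  list(X = genotype_matrix(X), y = as.integer(y), true_set = true_set,
       design = design, seed = seed)
}

# Noise block shared by the conditional-binomial and latent-Gaussian
# designs: independent Binomial(2, pi_j), pi_j ~ Unif(0.05, 0.95) drawn
# anew per feature and per replicate.
noise_block <- function(n, p_noise) {
  pi_j <- stats::runif(p_noise, 0.05, 0.95)
  matrix(stats::rbinom(n * p_noise, 2L, rep(pi_j, each = n)), nrow = n)
}

#' Conditional-binomial screening design
#'
#' Response first: `y_i ~ Bernoulli(p_y)` with `p_y ~ Unif(0.05, 0.95)`
#' drawn once per replicate. The 10 causal features are drawn
#' `Binomial(2, pi[y_i, j])` with the [sim2_probs()] table; the remaining
#' features are `Binomial(2, pi_j)`, `pi_j ~ Unif(0.05, 0.95)` per noise
#' feature per replicate, independent of the response. Degenerate
#' responses are possible at extreme `p_y` and are deliberately kept (no
#' redraw), matching the study conditions the reported model sizes assume.
#'
#' @param n,p sample size and feature count.
#' @param seed optional integer; when given, `set.seed(seed)` first, so the
#'   replicate is bit-reproducible.
#' @return a replicate: list with `X` ([genotype_matrix()]), `y`,
#'   `true_set`, `design`, `seed`.
#' @export
gen_sim2 <- function(n = 200L, p = 5000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pi_tab <- sim2_probs()
  n_causal <- ncol(pi_tab)
  if (p < n_causal) stop("p must be at least ", n_causal)
  p_y <- stats::runif(1L, 0.05, 0.95)
  y <- stats::rbinom(n, 1L, p_y)
  Xc <- vapply(seq_len(n_causal),
               function(j) stats::rbinom(n, 2L, pi_tab[y + 1L, j]),
               integer(n))
  X <- cbind(Xc, noise_block(n, p - n_causal))
  new_replicate(X, y, seq_len(n_causal), "sim2", seed)
}

#' Latent-Gaussian discretization design
#'
#' As [gen_sim2()] for the response and the noise features, but each
#' causal feature is the discretization of a latent `Z_ij ~ N(y_i, 1)` at
#' the per-feature cutoffs of [sim3_cutoffs()]: code 0 below the lower
#' cutoff, 1 between (inclusive), 2 above the upper. Low codes associate
#' with controls and high codes with cases — a pure trend association,
#' with no regression model generating the response.
#'
#' @inheritParams gen_sim2
#' @return a replicate list as in [gen_sim2()].
#' @export
gen_sim3 <- function(n = 200L, p = 5000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kap <- sim3_cutoffs()
  n_causal <- ncol(kap)
  if (p < n_causal) stop("p must be at least ", n_causal)
  p_y <- stats::runif(1L, 0.05, 0.95)
  y <- stats::rbinom(n, 1L, p_y)
  Xc <- vapply(seq_len(n_causal), function(j) {
    z <- stats::rnorm(n, mean = y)
    (z > kap["lower", j]) + (z > kap["upper", j])
  }, integer(n))
  X <- cbind(Xc, noise_block(n, p - n_causal))
  new_replicate(X, y, seq_len(n_causal), "sim3", seed)
}

#' Level-coefficient logistic design
#'
#' All features are uniform on `{0, 1, 2}` independently; the response is
#' Bernoulli with `P(Y=1|X) = plogis(L)`, where `L` sums the
#' level-specific coefficients of the first five features ([sim4_betas()]).
#' This is the home turf of marginal-likelihood screening, used to check
#' that trend-correlation screening matches it there.
#'
#' @inheritParams gen_sim2
#' @return a replicate list as in [gen_sim2()].
#' @export
gen_sim4 <- function(n = 200L, p = 5000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_causal <- ncol(sim4_betas())
  if (p < n_causal) stop("p must be at least ", n_causal)
  X <- matrix(sample(0:2, n * p, replace = TRUE), nrow = n)
  L <- sim4_linear_predictor(X[, seq_len(n_causal), drop = FALSE])
  y <- stats::rbinom(n, 1L, stats::plogis(L))
  new_replicate(X, y, seq_len(n_causal), "sim4", seed)
}

#' LD-block GWAS design
#'
#' Synthetic genotype matrix with linkage-disequilibrium structure.
#' Latent Gaussian variables are thresholded to genotype codes 0/1/2 at
#' the Hardy-Weinberg quantiles implied by per-SNP minor allele
#' frequencies drawn from `Unif(maf_range)`. Noise blocks of `block_size`
#' SNPs carry AR(1) latent correlation `rho` (independent across blocks).
#' The first block is a tight LD bin with exchangeable latent correlation
#' `cluster_cor`, and the `n_causal` causal SNPs sit consecutively at its
#' centre, so (i) the causal loci are mutually correlated, (ii) every
#' other SNP of the bin shadows their aggregate signal as an LD
#' confounder, and (iii) whenever the random effect signs are mixed, the
#' minority-sign loci have their marginal association cancelled by the
#' correlated majority — the regime in which one-step marginal screening
#' is trapped but iterative residual-projection screening recovers the
#' loci. Effects are `beta_i ~ N(5 Z_i, 1)` with random sign `Z_i` in
#' `{-1, +1}`; the response follows a logistic model whose linear
#' predictor is the centred genetic score plus `N(0, 1)` noise on the
#' logit.
#'
#' @param n,p sample size and SNP count (`p` a multiple of `block_size`).
#' @param block_size SNPs per LD block.
#' @param rho AR(1) latent correlation of the noise blocks, `0 <= rho < 1`.
#' @param n_causal number of causal SNPs (placed mid-block in block 1).
#' @param maf_range range of the per-SNP minor allele frequency.
#' @param cluster_cor exchangeable latent correlation of the causal bin.
#' @param seed optional integer for reproducibility.
#' @return a replicate list as in [gen_sim2()], plus `beta` (causal
#'   effects) in the result.
#' @export
gen_ld_gwas <- function(n = 272L, p = 10000L, block_size = 40L, rho = 0.6,
                        n_causal = 5L, maf_range = c(0.1, 0.5),
                        cluster_cor = 0.35, seed = NULL) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (cluster_cor < 0 || cluster_cor >= 1) stop("cluster_cor must lie in [0, 1)")
  if (p %% block_size != 0L) stop("p must be a multiple of block_size")
  if (n_causal > block_size) stop("n_causal cannot exceed block_size")
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- p %/% block_size
  Z <- matrix(0, n, p)
  f <- stats::rnorm(n)
  Z[, seq_len(block_size)] <- sqrt(cluster_cor) * f +
    sqrt(1 - cluster_cor) * matrix(stats::rnorm(n * block_size), n)
  for (b in seq_len(n_blocks)[-1L]) {
    cols <- (b - 1L) * block_size + seq_len(block_size)
    E <- matrix(stats::rnorm(n * block_size), n)
    Z[, cols[1L]] <- E[, 1L]
    for (t in 2:block_size) {
      Z[, cols[t]] <- rho * Z[, cols[t - 1L]] + sqrt(1 - rho^2) * E[, t]
    }
  }
  maf <- stats::runif(p, maf_range[1L], maf_range[2L])
  q0 <- stats::qnorm((1 - maf)^2)   # P(X=0) under Hardy-Weinberg
  q1 <- stats::qnorm(1 - maf^2)     # P(X<=1)
  X <- (Z > rep(q0, each = n)) + (Z > rep(q1, each = n))
  storage.mode(X) <- "integer"
  pos <- (block_size - n_causal) %/% 2L + seq_len(n_causal)
  beta <- stats::rnorm(n_causal, mean = 5 * sample(c(-1, 1), n_causal, TRUE), sd = 1)
  g <- X[, pos, drop = FALSE] %*% beta
  eta <- g - mean(g) + stats::rnorm(n)
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  out <- new_replicate(X, y, pos, "ldgwas", seed)
  out$beta <- as.vector(beta)
  out
}

# One master seed -> reproducible per-replicate seeds; the first `reps`
# seeds are a prefix of any longer run with the same master seed.
replicate_seeds <- function(master_seed, reps) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, reps)
}

# Registry used by run_study() and the CLI.
design_generator <- function(design) {
  switch(design,
         sim2 = gen_sim2, sim3 = gen_sim3, sim4 = gen_sim4,
         ldgwas = gen_ld_gwas,
         stop("unknown design: ", design))
}

#' Write a simulated replicate to disk
#'
#' Emits the genotype matrix as TSV (header = feature ids), the response
#' as a one-column TSV, and a JSON-like sidecar recording the design tag,
#' seed and true causal set.
#'
#' @param rep_data a replicate from one of the `gen_*` generators.
#' @param prefix output path prefix; files `<prefix>_genotypes.tsv`,
#'   `<prefix>_response.tsv`, `<prefix>_meta.txt` are written.
#' @export
write_replicate <- function(rep_data, prefix) {
  gx <- as.data.frame(rep_data$X$values)
  names(gx) <- rep_data$X$feature_ids
  data.table::fwrite(gx, paste0(prefix, "_genotypes.tsv"), sep = "\t")
  data.table::fwrite(data.frame(y = rep_data$y),
                     paste0(prefix, "_response.tsv"), sep = "\t")
  meta <- c(paste0("design: ", rep_data$design),
            paste0("seed: ", if (is.null(rep_data$seed)) "NA" else rep_data$seed),
            paste0("true_set: ", paste(rep_data$true_set, collapse = ",")))
  writeLines(meta, paste0(prefix, "_meta.txt"))
  invisible(prefix)
}
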