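# Two-stage GWAS analysis pipeline: MAF filter -> cross-validated choice
# of the first-step size d1 -> iterative screening -> joint multiple
# logistic regression on the retained SNPs.

#' Minor allele frequency filter
#'
#' For additive genotype codes (allele counts 0/1/2) the allele frequency
#' of feature `j` is `f_j = mean(X_j) / 2` and the minor allele frequency
#' is `min(f_j, 1 - f_j)`. Features with MAF below the threshold are
#' removed; surviving features keep their original order and ids.
#'
#' @param X a [genotype_matrix()] or 0/1/2 integer matrix.
#' @param threshold MAF cutoff in `[0, 0.5)`; features with
#'   `MAF < threshold` are dropped.
#' @return filtered `genotype_matrix` with attributes `kept` (original
#'   column indices) and `maf` (per-surviving-feature MAF).
#' @export
maf_filter <- function(X, threshold = 0.1) {
  gm <- as_genotype_matrix(X)
  if (threshold < 0 || threshold >= 0.5) stop("threshold must lie in [0, 0.5)")
  if (!all(gm$values %in% 0:2)) {
    stop("MAF filtering requires additive allele-count coding 0/1/2; ",
         "skip the filter for other codings")
  }
  f <- unname(colMeans(gm$values)) / 2
  maf <- pmin(f, 1 - f)
  keep <- which(maf >= threshold)
  message("maf_filter: ", length(keep), " of ", gm$p,
          " features retained at MAF >= ", threshold)
  out <- genotype_matrix(gm$values[, keep, drop = FALSE],
                         level_scores = if (is.null(gm$level_scores)) NULL
                         else gm$level_scores[keep],
                         feature_ids = gm$feature_ids[keep])
  attr(out, "kept") <- keep
  attr(out, "maf") <- maf[keep]
  out
}

# Brier-type mean squared prediction error of predicted probabilities
# against held-out 0/1 outcomes.
mspe <- function(prob, y) mean((prob - y)^2)

#' Choose the first-step size by cross-validated prediction error
#'
#' For every candidate `d1` in `grid`, repeatedly: split the sample into
#' a training fraction and a test fraction, rank features on the training
#' split only (trend-correlation screening, so there is no selection
#' leakage into the test split), fit a joint logistic regression on the
#' top `d1` training features, and record the mean squared prediction
#' error (Brier score) of the predicted case probabilities on the test
#' split. The chosen `d1` is the smallest grid value whose mean MSPE is
#' within one standard deviation (across repeats, at the minimizing grid
#' point) of the minimum mean MSPE — the one-standard-error rule.
#'
#' @inheritParams tc_screen
#' @param grid candidate `d1` values; default `1:(3 * rule_of_thumb_d(n))`.
#'   Values exceeding `p` (or the training sample size minus 2) are
#'   truncated with a warning.
#' @param train_frac training fraction of each split (default 0.75).
#' @param repeats number of random splits (default 10).
#' @param seed optional seed for the splits.
#' @return list with `d1` (the choice), `curve` (data.frame: `d1`,
#'   `mean_mspe`, `sd_mspe`), and `threshold` (the one-SE cutoff).
#' @export
choose_d1_by_mspe <- function(X, y, grid = NULL, train_frac = 0.75,
                              repeats = 10L, seed = NULL) {
  gm <- as_genotype_matrix(X)
  y <- binary_response(y, n = gm$n)
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid)) grid <- seq_len(3L * rule_of_thumb_d(gm$n))
  n_train <- floor(train_frac * gm$n)
  cap <- min(gm$p, n_train - 2L)
  if (any(grid > cap)) {
    warning("grid truncated at ", cap, " (feature count / training size limit)")
    grid <- grid[grid <= cap]
  }
  if (length(grid) == 0L) stop("empty d1 grid")
  V <- score_matrix(gm)
  err <- matrix(NA_real_, repeats, length(grid))
  for (r in seq_len(repeats)) {
    tr <- sort(sample.int(gm$n, n_train))
    te <- setdiff(seq_len(gm$n), tr)
    sc <- suppressWarnings(tc_screen(gm$values[tr, , drop = FALSE], y[tr]))
    for (gi in seq_along(grid)) {
      keep <- sc$ranking[seq_len(grid[gi])]
      fit <- suppressWarnings(stats::glm.fit(
        cbind(1, V[tr, keep, drop = FALSE]), y[tr],
        family = stats::binomial()))
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0   # collinear columns dropped by the fit
      eta <- drop(cbind(1, V[te, keep, drop = FALSE]) %*% cf)
      err[r, gi] <- mspe(stats::plogis(eta), y[te])
    }
  }
  mean_mspe <- colMeans(err)
  i_min <- which.min(mean_mspe)
  thr <- mean_mspe[i_min] + stats::sd(err[, i_min])
  d1 <- grid[which(mean_mspe <= thr)[1L]]
  list(d1 = d1,
       curve = data.frame(d1 = grid, mean_mspe = mean_mspe,
                          sd_mspe = apply(err, 2L, stats::sd)),
       threshold = thr)
}

#' Joint multiple logistic regression on the screened features
#'
#' Fits `y ~ X_selected` by multiple logistic regression on the scored
#' features and reports the model-selection summary: model size, AIC
#' (`2 * #params - 2 * loglik`), in-sample misclassification rate at the
#' 0.5 probability cutoff, and the per-feature coefficient table with
#' Wald p-values. If complete separation is detected the fit is
#' stabilized by an L2-penalized refit (when \pkg{glmnet} is available)
#' and flagged. Optionally the model is refit keeping only features with
#' Wald `p <= p_cutoff`, giving the final reduced model size.
#'
#' @param X_selected matrix (or `genotype_matrix`) of the selected,
#'   scored features; fewer columns than samples.
#' @param y binary 0/1 response.
#' @param p_cutoff optional Wald p-value cutoff for a reduced refit.
#' @return a `joint_model_report`: `model_size`, `aic`,
#'   `misclassification`, `coef_table`, `separation` flag, and (when
#'   `p_cutoff` is given) `reduced` with the refit summary.
#' @export
joint_logistic_report <- function(X_selected, y, p_cutoff = NULL) {
  V <- if (inherits(X_selected, "genotype_matrix")) score_matrix(X_selected)
       else as.matrix(X_selected)
  ids <- if (inherits(X_selected, "genotype_matrix")) X_selected$feature_ids
         else colnames(V)
  if (is.null(ids) && ncol(V) > 0) ids <- paste0("X", seq_len(ncol(V)))
  y <- binary_response(y, n = nrow(V))
  if (ncol(V) >= nrow(V)) stop("selected model size must be below the sample size")
  df <- data.frame(y = y, V)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep && ncol(V) > 0 && requireNamespace("glmnet", quietly = TRUE)) {
    pen <- glmnet::glmnet(V, y, family = "binomial", alpha = 0,
                          lambda = 1e-3)
    fit$ridge_coef <- c(pen$a0, as.vector(pen$beta))
  }
  prob <- stats::fitted(fit)
  if (!sep && length(prob) > 0) {
    sep <- any(prob > 1 - 1e-8) || any(prob < 1e-8)
  }
  sm <- summary(fit)$coefficients
  coef_table <- data.frame(
    feature_id = c("(Intercept)", ids)[seq_len(nrow(sm))],
    estimate = sm[, 1], se = sm[, 2], z = sm[, 3], p_value = sm[, 4],
    row.names = NULL)
  out <- list(model_size = ncol(V), aic = stats::AIC(fit),
              misclassification = mean((prob > 0.5) != (y == 1L)),
              coef_table = coef_table, separation = sep, fit = fit)
  if (!is.null(p_cutoff) && ncol(V) > 0) {
    keep <- which(coef_table$p_value[-1L] <= p_cutoff)
    if (length(keep) > 0 && length(keep) < ncol(V)) {
      out$reduced <- joint_logistic_report(V[, keep, drop = FALSE], y)
      out$reduced$feature_ids <- ids[keep]
    }
  }
  class(out) <- "joint_model_report"
  out
}

#' @export
print.joint_model_report <- function(x, ...) {
  cat(sprintf("joint_model_report: size %d | AIC %.2f | misclassification %.2f%%%s\n",
              x$model_size, x$aic, 100 * x$misclassification,
              if (x$separation) " | separation flagged" else ""))
  invisible(x)
}

#' End-to-end screening pipeline for a genotype matrix
#'
#' Runs the full two-stage analysis: (1) MAF filter; (2) data-driven
#' choice of the first-step size `d1` by [choose_d1_by_mspe()] (unless
#' supplied); (3) iterative trend-correlation screening with schedule
#' `(d1, d - d1)`, `k = 2`, where `d` defaults to
#' `rule_of_thumb_d(n, multiplier)`; (4) joint multiple logistic
#' regression on the selected SNPs. Each stage logs its feature counts.
#'
#' @param X genotype input: a matrix / [genotype_matrix()], or a file
#'   path readable by [read_genotype()].
#' @param y binary 0/1 response (taken from a PLINK `.raw` file when
#'   `X` is a path and `y` is `NULL`).
#' @param maf_threshold MAF cutoff (default 0.1); 0 disables filtering.
#' @param multiplier rule-of-thumb multiplier for the total budget `d`
#'   (default 3).
#' @param d total screening budget; default `rule_of_thumb_d(n, multiplier)`.
#' @param d1 first-step size; default chosen by cross-validated MSPE.
#' @param d1_repeats,train_frac CV controls for the `d1` choice.
#' @param p_cutoff optional Wald p-value cutoff for the reduced joint model.
#' @param seed seed for the CV splits.
#' @return list with `filtered` counts, `d`, `d1`, `d1_curve`,
#'   `selection` (the ITC `selected_model`), `joint` (the
#'   [joint_logistic_report()]), and `snp_table` (id, iteration, ITC
#'   score, coefficient, p-value per selected SNP).
#' @export
run_pipeline <- function(X, y = NULL, maf_threshold = 0.1, multiplier = 3L,
                         d = NULL, d1 = NULL, d1_repeats = 10L,
                         train_frac = 0.75, p_cutoff = NULL, seed = NULL) {
  if (is.character(X)) {
    inp <- read_genotype(X, impute = "mode")
    if (is.null(y)) y <- inp$y
    X <- inp$X
  }
  gm <- as_genotype_matrix(X)
  y <- binary_response(y, n = gm$n)
  gm_f <- if (maf_threshold > 0) maf_filter(gm, maf_threshold) else gm
  message("pipeline: MAF stage ", gm$p, " -> ", gm_f$p, " features")
  if (is.null(d)) d <- min(rule_of_thumb_d(gm_f$n, multiplier), gm_f$p)
  grid_cap <- min(d - 1L, gm_f$p)
  d1_curve <- NULL
  if (is.null(d1)) {
    ch <- choose_d1_by_mspe(gm_f, y, grid = seq_len(grid_cap),
                            train_frac = train_frac, repeats = d1_repeats,
                            seed = seed)
    d1 <- ch$d1
    d1_curve <- ch$curve
  }
  message("pipeline: screening with schedule (", d1, ", ", d - d1, ")")
  model <- itc_screen(gm_f, y, schedule = c(d1, d - d1))
  joint <- joint_logistic_report(
    genotype_matrix(gm_f$values[, model$indices, drop = FALSE],
                    feature_ids = gm_f$feature_ids[model$indices]),
    y, p_cutoff = p_cutoff)
  message("pipeline: joint logistic model on ", joint$model_size,
          " SNPs | AIC ", round(joint$aic, 2), " | misclassification ",
          round(100 * joint$misclassification, 2), "%")
  snp_table <- data.frame(
    feature_id = model$selection$feature_id,
    iteration = model$selection$iteration,
    itc_score = model$selection$score,
    coefficient = joint$coef_table$estimate[-1L],
    p_value = joint$coef_table$p_value[-1L])
  list(filtered = c(before = gm$p, after = gm_f$p), d = d, d1 = d1,
       d1_curve = d1_curve, selection = model, joint = joint,
       snp_table = snp_table)
}

#' Score plot of an iterative screening selection
#'
#' Manhattan-style base-graphics plot: selected SNPs are drawn at their
#' selection utility, everything else sits on the baseline at zero.
#'
#' @param model a `selected_model` from [itc_screen()].
#' @param p total number of features screened.
#' @param ... passed to [plot()].
#' @export
plot_itc_scores <- function(model, p, ...) {
  ys <- numeric(p)
  ys[model$indices] <- model$selection$score
  plot(seq_len(p), ys, type = "h", col = "grey60",
       xlab = "feature index", ylab = "ITC score", ...)
  graphics::points(model$indices, model$selection$score, pch = 17,
                   col = "firebrick")
  invisible(NULL)
}
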