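#' Contingency table of one feature against a binary response
#'
#' Tabulates the joint counts of the `K` feature levels against the two
#' response classes; all screening statistics with categorical input are
#' functions of this table, its marginals and the level scores.
#'
#' @param xj integer-coded feature column.
#' @param y binary 0/1 response, same length.
#' @param levels optional level codes; defaults to the sorted observed
#'   codes. An observation outside `levels` is an error.
#' @param scores optional numeric scores for `levels` (default: the codes).
#' @return object of class `contingency_table`: `counts` (`K x 2` integer
#'   matrix, rows = levels, columns = `Y=0`, `Y=1`), `scores`, `n`.
#' @examples
#' contingency(c(0, 1, 2, 0, 1, 2), c(0, 0, 0, 1, 1, 1))
#' @export
contingency <- function(xj, y, levels = NULL, scores = NULL) {
  if (length(xj) != length(y)) stop("feature and response lengths differ")
  if (length(xj) < 1L) stop("empty input")
  y <- binary_response(y, require_both = FALSE)
  if (is.null(levels)) levels <- sort(unique(xj))
  if (!all(xj %in% levels)) {
    stop("unknown level code(s): ", paste(unique(xj[!xj %in% levels]), collapse = ", "))
  }
  if (is.null(scores)) scores <- as.numeric(levels)
  if (length(scores) != length(levels)) stop("one score per level required")
  counts <- table(factor(xj, levels = levels), factor(y, levels = 0:1))
  counts <- matrix(as.integer(counts), nrow = length(levels),
                   dimnames = list(levels, c("0", "1")))
  structure(list(counts = counts, scores = scores, n = length(xj)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("contingency_table (n =", x$n, ")\n")
  print(cbind(score = x$scores, x$counts))
  invisible(x)
}

# Trend correlation from a K x 2 probability (or count) table and scores.
# Shared by the population and sample forms; `probs` must sum to 1.
tc_from_probs <- function(probs, scores) {
  px <- rowSums(probs)
  py <- colSums(probs)
  m <- c(0, 1)
  ex <- sum(scores * px)
  ey <- py[2L]
  varx <- sum((scores - ex)^2 * px)
  vary <- sum((m - ey)^2 * py)
  if (varx <= 0 || vary <= 0) {
    stop("degenerate variable: zero standard deviation (constant feature or response)")
  }
  num <- abs(sum(outer(scores - ex, m - ey) * probs))
  unname(num / sqrt(varx * vary))
}

#' Population trend correlation
#'
#' The trend correlation between an ordinal feature with level scores
#' \eqn{v_k} and a binary response is the absolute correlation computed
#' from the joint cell probabilities:
#' \deqn{\varrho = \frac{|\sum_k \sum_m (v_k - EX)(m - EY)\, p_{km}|}{\sigma_X \sigma_Y}.}
#' It lies in \eqn{[0, 1]} and equals 0 when the feature and response are
#' independent.
#'
#' @param cell_probs `K x 2` matrix of joint probabilities
#'   \eqn{p_{km} = P(X = v_k, Y = m)}; non-negative, summing to 1, with
#'   both response marginals positive.
#' @param scores numeric level scores \eqn{v_k} (length `K`), with positive
#'   variance under the feature marginal.
#' @return the trend correlation, a scalar in `[0, 1]`.
#' @examples
#' p <- outer(c(.2, .5, .3), c(.4, .6))   # independent cells
#' tc_population(p, 0:2)                  # 0
#' @export
tc_population <- function(cell_probs, scores) {
  cell_probs <- as.matrix(cell_probs)
  if (ncol(cell_probs) != 2L) stop("cell_probs must have two response columns")
  if (any(cell_probs < 0)) stop("cell probabilities must be non-negative")
  if (abs(sum(cell_probs) - 1) > 1e-8) stop("cell probabilities must sum to 1")
  if (any(colSums(cell_probs) <= 0)) {
    stop("degenerate variable: both response classes need positive probability")
  }
  if (length(scores) != nrow(cell_probs)) stop("one score per feature level required")
  tc_from_probs(cell_probs, scores)
}

#' Sample trend correlation of one feature
#'
#' Plug-in estimator of [tc_population()]: the population cell
#' probabilities are replaced by sample proportions from the contingency
#' table of `xj` against `y`. Algebraically this equals the absolute
#' sample Pearson correlation between the scored feature vector and the
#' 0/1 response (a property the test-suite exercises as an oracle);
#' computing it from the `K x 2` table costs `O(n + K)` per feature.
#'
#' @inheritParams contingency
#' @return the estimated trend correlation in `[0, 1]`.
#' @examples
#' y <- rep(0:1, each = 50)
#' x <- rbinom(100, 2, 0.2 + 0.5 * y)
#' tc_sample(x, y)
#' @export
tc_sample <- function(xj, y, levels = NULL, scores = NULL) {
  if (length(xj) < 2L) stop("need at least two observations")
  y <- binary_response(y, n = length(xj))
  tab <- contingency(xj, y, levels = levels, scores = scores)
  tc_from_probs(tab$counts / tab$n, tab$scores)
}

# Vectorized |Pearson correlation| of each column of a numeric matrix with
# y; zero-variance columns get NA (callers decide how to treat them).
abs_cor_columns <- function(V, y) {
  n <- nrow(V)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2) / n)
  mu <- colMeans(V)
  cv <- as.vector(crossprod(V, yc)) / n
  sx2 <- colMeans(V^2) - mu^2
  sx2[sx2 < 0] <- 0
  out <- unname(abs(cv) / (sqrt(sx2) * sy))
  out[sx2 <= .Machine$double.eps * pmax(1, mu^2)] <- NA_real_
  out
}

# Construct a screening_scores object with the deterministic tie rule:
# higher score first, lower feature index wins ties.
new_screening_scores <- function(scores, method, feature_ids) {
  structure(list(scores = scores, method = method,
                 ranking = order(-scores, seq_along(scores)),
                 feature_ids = feature_ids),
            class = "screening_scores")
}

#' @export
print.screening_scores <- function(x, n = 10L, ...) {
  cat("screening_scores [", x$method, "], p =", length(x$scores), "\n")
  top <- utils::head(x$ranking, n)
  print(data.frame(rank = seq_along(top), feature = x$feature_ids[top],
                   score = x$scores[top]), row.names = FALSE)
  invisible(x)
}

#' Marginal trend-correlation screening (TC-SIS)
#'
#' Computes the sample trend correlation of every feature with the binary
#' response and ranks features by decreasing score. Constant
#' (zero-variance) features cannot carry a trend correlation; they are
#' assigned score 0 with a warning rather than aborting a genome scan.
#'
#' @param X a [genotype_matrix()] or integer matrix (samples x features).
#' @param y binary 0/1 response.
#' @return a `screening_scores` object (`scores`, `method = "TC"`,
#'   `ranking`, `feature_ids`). Ranks break ties toward the lower feature
#'   index, so results are reproducible.
#' @seealso [select_top()], [select_by_threshold()], [itc_screen()]
#' @examples
#' y <- rep(0:1, each = 30)
#' X <- cbind(causal = rbinom(60, 2, 0.2 + 0.5 * y),
#'            noise = rbinom(60, 2, 0.5))
#' tc_screen(X, y)
#' @export
tc_screen <- function(X, y) {
  gm <- as_genotype_matrix(X)
  if (gm$p < 1L) stop("empty feature matrix")
  y <- binary_response(y, n = gm$n)
  s <- abs_cor_columns(score_matrix(gm), y)
  nc <- sum(is.na(s))
  if (nc > 0L) {
    warning(nc, " constant feature(s) assigned score 0")
    s[is.na(s)] <- 0
  }
  new_screening_scores(s, "TC", gm$feature_ids)
}

#' Keep the top-d ranked features
#'
#' @param scores a `screening_scores` object (any method).
#' @param d number of features to keep, `1 <= d <= p`.
#' @return a `selected_model`: ordered `indices` (by decreasing score,
#'   ties to the lower index), `iteration_sizes`, `total_budget`.
#' @export
select_top <- function(scores, d) {
  stopifnot(inherits(scores, "screening_scores"))
  p <- length(scores$scores)
  d <- as.integer(d)
  if (d < 1L || d > p) stop("d must be between 1 and p = ", p)
  idx <- scores$ranking[seq_len(d)]
  new_selected_model(idx, d, d, scores$feature_ids[idx])
}

#' Threshold selection rule
#'
#' Returns the selected set \eqn{\{j : \hat\varrho_j > c\}} — every
#' feature whose score strictly exceeds the threshold.
#'
#' @param scores a `screening_scores` object.
#' @param c non-negative threshold.
#' @return integer vector of selected feature indices (increasing order).
#' @export
select_by_threshold <- function(scores, c) {
  stopifnot(inherits(scores, "screening_scores"))
  if (c < 0) stop("threshold must be non-negative")
  which(scores$scores > c)
}

new_selected_model <- function(indices, iteration_sizes, total_budget, ids = NULL) {
  structure(list(indices = as.integer(indices),
                 iteration_sizes = as.integer(iteration_sizes),
                 total_budget = as.integer(total_budget),
                 feature_ids = ids),
            class = "selected_model")
}

#' @export
print.selected_model <- function(x, ...) {
  cat("selected_model:", length(x$indices), "features in",
      length(x$iteration_sizes), "iteration(s) (sizes:",
      paste(x$iteration_sizes, collapse = ", "), ")\n")
  invisible(x)
}

#' Rule-of-thumb screening cutoff
#'
#' The conventional model-size cutoff for sure independence screening,
#' \eqn{d = [n^{4/5} / \log(n^{4/5})]} (natural log, rounded half-up),
#' optionally scaled by an integer multiplier (2d, 3d, ... are common when
#' a more conservative retention is wanted before a joint-model stage).
#'
#' @param n sample size (`>= 2`).
#' @param multiplier positive integer scale factor.
#' @return integer cutoff `multiplier * round(n^{4/5} / log(n^{4/5}))`.
#' @examples
#' rule_of_thumb_d(272)       # 20
#' rule_of_thumb_d(4099, 3)   # 351
#' @export
rule_of_thumb_d <- function(n, multiplier = 1L) {
  if (n < 2) stop("n must be at least 2")
  if (multiplier < 1) stop("multiplier must be a positive integer")
  m <- n^0.8
  as.integer(multiplier) * as.integer(floor(m / log(m) + 0.5))
}
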