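# ITC-SIS: iterative trend-correlation screening with residual projection.
# Between screening steps the unselected (scored) features are replaced by
# their residuals after projecting out the selected ones, which breaks the
# correlation structure induced by linkage disequilibrium and lets loci
# with weak marginal but strong joint effects surface.

#' Project features onto the orthogonal complement of selected columns
#'
#' Computes \eqn{X_r = (I - P)\, X_{rem}} where \eqn{P} is the orthogonal
#' projector onto the column space of `X_selected`. The projector is built
#' from a singular value decomposition with a relative tolerance, so
#' exactly collinear selected columns (correlation 1 under strong LD) are
#' handled without failure.
#'
#' @param X_selected numeric matrix of selected (scored) columns; include
#'   an all-ones column to remove means (done automatically by
#'   [itc_screen()]).
#' @param X_remaining numeric matrix of columns to residualize.
#' @param tol relative singular-value tolerance for the rank decision.
#' @return matrix of residual columns, same shape as `X_remaining`;
#'   each column is orthogonal to every selected column.
#' @export
residualize <- function(X_selected, X_remaining, tol = 1e-10) {
  X_selected <- as.matrix(X_selected)
  X_remaining <- as.matrix(X_remaining)
  if (nrow(X_selected) != nrow(X_remaining)) stop("row dimensions differ")
  sv <- svd(X_selected, nv = 0)
  keep <- sv$d > tol * max(sv$d, 0)
  if (!any(keep)) return(X_remaining)
  Q <- sv$u[, keep, drop = FALSE]
  X_remaining - Q %*% crossprod(Q, X_remaining)
}

#' Screening utility of a residualized column
#'
#' Residual columns are continuous, so the trend correlation reduces to
#' its continuous-input limit: the absolute sample Pearson correlation
#' with the response. Columns with (numerically) zero variance score 0.
#'
#' @param xr_column numeric vector (a residual column).
#' @param y binary 0/1 response.
#' @return non-negative scalar utility.
#' @export
residual_utility <- function(xr_column, y) {
  y <- binary_response(y, n = length(xr_column))
  v <- abs_cor_columns(matrix(xr_column, ncol = 1L), y)
  if (is.na(v)) 0 else v
}

# Resolve an iteration schedule (d_1, ..., d_k) from user input.
resolve_schedule <- function(schedule, d, d1, k, p) {
  if (is.null(schedule)) {
    if (is.null(d)) stop("supply either 'schedule' or a total budget 'd'")
    if (k == 1L) schedule <- d
    else {
      if (d1 >= d) stop("d1 must be smaller than the total budget d")
      rest <- d - d1
      steps <- k - 1L
      schedule <- c(d1, rep(rest %/% steps, steps))
      extra <- rest %% steps
      if (extra > 0) schedule[1L + seq_len(extra)] <- schedule[1L + seq_len(extra)] + 1L
    }
  }
  schedule <- as.integer(schedule)
  if (any(schedule < 1L)) stop("all iteration sizes must be >= 1")
  if (sum(schedule) > p) stop("schedule total (", sum(schedule), ") exceeds p = ", p)
  schedule
}

#' Iterative trend-correlation screening (ITC-SIS)
#'
#' Builds the selected set in `k` steps: step 1 takes the top `d_1`
#' features by [tc_screen()]; each later step regresses all remaining
#' (scored) features on the currently selected ones plus an intercept,
#' ranks the residual columns by [residual_utility()], and takes the next
#' `d_i`. Features collinear with the selected set have residuals near
#' zero and can no longer be picked, which decouples true loci from SNPs
#' that merely tag them through LD.
#'
#' @inheritParams tc_screen
#' @param schedule explicit iteration sizes `c(d1, d2, ...)`; overrides
#'   `d`, `d1`, `k`.
#' @param d total selection budget (used when `schedule` is `NULL`).
#' @param d1 first-step size (default 6).
#' @param k number of iterations (default 2; `d_2 = d - d_1`).
#' @return a `selected_model` with ordered `indices`, `iteration_sizes`,
#'   and per-feature selection metadata (`iteration`, `score` — the
#'   utility at the moment of selection) in `$selection`.
#' @examples
#' y <- rep(0:1, each = 40)
#' X <- matrix(rbinom(80 * 30, 2, 0.4), 80)
#' itc_screen(X, y, schedule = c(3, 3))
#' @export
itc_screen <- function(X, y, schedule = NULL, d = NULL, d1 = 6L, k = 2L) {
  gm <- as_genotype_matrix(X)
  y <- binary_response(y, n = gm$n)
  schedule <- resolve_schedule(schedule, d, d1, k, gm$p)
  V <- score_matrix(gm)
  first <- tc_screen(gm, y)
  sel <- first$ranking[seq_len(schedule[1L])]
  iter <- rep(1L, schedule[1L])
  selscore <- first$scores[sel]
  remaining <- setdiff(seq_len(gm$p), sel)
  for (step in seq_along(schedule)[-1L]) {
    Xr <- residualize(cbind(1, V[, sel, drop = FALSE]),
                      V[, remaining, drop = FALSE])
    util <- abs_cor_columns(Xr, y)
    util[is.na(util)] <- 0
    ord <- order(-util, remaining)
    take <- ord[seq_len(schedule[step])]
    sel <- c(sel, remaining[take])
    iter <- c(iter, rep(step, schedule[step]))
    selscore <- c(selscore, util[take])
    remaining <- remaining[-take]
  }
  out <- new_selected_model(sel, schedule, sum(schedule), gm$feature_ids[sel])
  out$selection <- data.frame(index = sel, feature_id = gm$feature_ids[sel],
                              iteration = iter, score = selscore)
  out
}
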