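#' Genotype / categorical feature matrix
#'
#' Container for an `n x p` matrix of integer-coded categorical features
#' (SNP genotypes in additive 0/1/2 coding by default), together with the
#' numeric scores attached to the levels of each feature. Screening
#' statistics operate on the *scored* values, so the scores must be finite
#' and ordered consistently with the level order; their absolute scale is
#' irrelevant (the trend correlation is invariant to affine rescaling).
#'
#' @param values integer matrix, samples in rows, features in columns.
#'   No missing values are allowed; impute or drop beforehand (see
#'   [read_genotype()]).
#' @param level_scores optional list of length `p`; element `j` is a named
#'   numeric vector mapping the level codes of feature `j` (names) to
#'   scores (values). `NULL` means the integer codes are used as scores
#'   (the additive genotype convention).
#' @param feature_ids character vector of feature labels; defaults to
#'   column names or `X1..Xp`.
#'
#' @return An object of class `genotype_matrix` with elements `values`,
#'   `level_scores`, `feature_ids`, `n`, `p`.
#' @examples
#' X <- matrix(sample(0:2, 60, TRUE), nrow = 20)
#' gm <- genotype_matrix(X)
#' gm$p
#' @export
genotype_matrix <- function(values, level_scores = NULL, feature_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric/integer matrix")
  if (anyNA(values)) {
    stop("genotype matrix contains missing values; impute or drop first ",
         "(see read_genotype(impute = \"mode\"))")
  }
  p <- ncol(values)
  if (is.null(feature_ids)) feature_ids <- colnames(values)
  if (is.null(feature_ids)) {
    feature_ids <- if (p == 0L) character(0) else paste0("X", seq_len(p))
  }
  if (length(feature_ids) != p) stop("feature_ids length must equal ncol(values)")
  if (!is.null(level_scores)) {
    if (length(level_scores) != p) stop("level_scores must have one element per feature")
    for (j in seq_len(p)) {
      sc <- level_scores[[j]]
      if (is.null(sc)) next
      if (anyNA(sc) || any(!is.finite(sc))) stop("level scores must be finite")
      if (is.unsorted(sc, strictly = TRUE)) {
        stop("level scores of feature ", j,
             " must be strictly increasing in level order")
      }
      if (is.null(names(sc))) stop("level scores must be named by level code")
      if (!all(unique(values[, j]) %in% as.numeric(names(sc)))) {
        stop("feature ", j, " has level codes without a score")
      }
    }
  }
  structure(list(values = values, level_scores = level_scores,
                 feature_ids = as.character(feature_ids),
                 n = nrow(values), p = p),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", x$n, "samples x", x$p, "features\n")
  cat("  scoring:", if (is.null(x$level_scores)) "integer codes (additive)"
      else "custom per-feature level scores", "\n")
  invisible(x)
}

# Coerce matrix-like input used throughout the screening functions.
as_genotype_matrix <- function(X) {
  if (inherits(X, "genotype_matrix")) X else genotype_matrix(X)
}

# Numeric matrix of scored feature values (codes mapped through level scores).
score_matrix <- function(X) {
  gm <- as_genotype_matrix(X)
  V <- gm$values
  if (!is.null(gm$level_scores)) {
    for (j in seq_len(gm$p)) {
      sc <- gm$level_scores[[j]]
      if (is.null(sc)) next
      V[, j] <- sc[as.character(gm$values[, j])]
    }
  }
  storage.mode(V) <- "double"
  V
}

# Level scores for one feature: named vector, default = observed codes.
feature_scores <- function(gm, j) {
  sc <- if (is.null(gm$level_scores)) NULL else gm$level_scores[[j]]
  if (is.null(sc)) {
    lev <- sort(unique(gm$values[, j]))
    sc <- stats::setNames(as.numeric(lev), lev)
  }
  sc
}

#' Validate a binary case-control response
#'
#' @param y vector; must contain only 0 and 1.
#' @param n optional expected length.
#' @param require_both require at least one case and one control (needed by
#'   every screening statistic: otherwise the response variance is zero).
#' @return the response as an integer vector, invisibly usable downstream.
#' @export
binary_response <- function(y, n = NULL, require_both = TRUE) {
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) stop("response must be coded 0/1 with no missing values")
  if (!is.null(n) && length(y) != n) stop("response length (", length(y), ") does not match sample size (", n, ")")
  if (require_both && (all(y == 0L) || all(y == 1L))) {
    stop("response is constant; screening requires both cases and controls")
  }
  y
}
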