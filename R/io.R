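#' Read a genotype matrix from delimited text or PLINK .raw
#'
#' Two dialects are auto-detected from the header line:
#' * **PLINK `.raw`** (additive recoding, `plink --recode A`): columns
#'   `FID IID PAT MAT SEX PHENOTYPE` followed by one 0/1/2 column per SNP
#'   (`NA` for missing). The phenotype is mapped `{1 -> 0 control,
#'   2 -> 1 case}`; a phenotype already coded 0/1 is kept as is.
#' * **Plain delimited text** (TSV/CSV): a header row of feature ids and
#'   one integer-coded column per feature; no phenotype column.
#'
#' Missing genotypes are not supported by the screening statistics, so they
#' must be resolved at read time: `impute = "mode"` replaces each missing
#' entry by the most frequent code of its feature (ties to the lower code),
#' `impute = "drop"` removes samples with any missing call, and the default
#' `"none"` errors if missing values are present. The action taken is
#' reported via `message()`.
#'
#' @param path file path.
#' @param impute one of `"none"`, `"mode"`, `"drop"`.
#' @return list with elements `X` (a [genotype_matrix()]), `y` (integer 0/1
#'   response for the `.raw` dialect, otherwise `NULL`) and `dialect`.
#' @export
read_genotype <- function(path, impute = c("none", "mode", "drop")) {
  impute <- match.arg(impute)
  header <- strsplit(readLines(path, n = 1L), "[\t, ]+")[[1]]
  is_raw <- length(header) >= 7 &&
    identical(toupper(header[1:6]), c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (is_raw) {
    message("read_genotype: PLINK .raw dialect detected (", nrow(dt), " samples, ",
            ncol(dt) - 6L, " SNPs)")
    y <- dt[["PHENOTYPE"]]
    if (all(y %in% c(1, 2), na.rm = TRUE)) y <- y - 1L
    if (!all(y %in% c(0, 1), na.rm = TRUE)) {
      warning("phenotype column is not 0/1 or 1/2 coded; returning it unmapped")
    }
    M <- as.matrix(dt[, -(1:6), drop = FALSE])
  } else {
    message("read_genotype: delimited matrix dialect detected (", nrow(dt),
            " samples, ", ncol(dt), " features)")
    y <- NULL
    M <- as.matrix(dt)
  }
  storage.mode(M) <- "integer"
  if (anyNA(M)) {
    n_miss <- sum(is.na(M))
    if (impute == "mode") {
      for (j in which(colSums(is.na(M)) > 0L)) {
        tab <- table(M[, j])
        M[is.na(M[, j]), j] <- as.integer(names(tab)[which.max(tab)])
      }
      message("read_genotype: mode-imputed ", n_miss, " missing genotype calls")
    } else if (impute == "drop") {
      keep <- rowSums(is.na(M)) == 0L
      message("read_genotype: dropped ", sum(!keep), " samples with missing calls")
      M <- M[keep, , drop = FALSE]
      if (!is.null(y)) y <- y[keep]
    } else {
      stop(n_miss, " missing genotype calls present; re-read with impute = ",
           "\"mode\" or \"drop\"")
    }
  }
  list(X = genotype_matrix(M), y = if (is.null(y)) NULL else as.integer(y),
       dialect = if (is_raw) "plink_raw" else "delimited")
}

#' Write screening scores as a TSV table
#'
#' Columns: `feature_id`, `method`, `score`, `rank`.
#'
#' @param scores a [screening_scores] object.
#' @param path output file.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "screening_scores"))
  rk <- integer(length(scores$scores))
  rk[scores$ranking] <- seq_along(scores$scores)
  df <- data.frame(feature_id = scores$feature_ids, method = scores$method,
                   score = scores$scores, rank = rk)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
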