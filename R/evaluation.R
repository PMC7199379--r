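# Monte-Carlo evaluation of screening procedures: minimum model size,
# individual and simultaneous success rates, and the replicated study
# runner that aggregates them per method.

# 1-based rank of every feature under the deterministic tie rule.
feature_ranks <- function(scores) {
  stopifnot(inherits(scores, "screening_scores"))
  rk <- integer(length(scores$scores))
  rk[scores$ranking] <- seq_along(rk)
  rk
}

#' Minimum model size of a screening result
#'
#' The smallest prefix of the ranked feature list that covers every truly
#' influential feature, i.e. the maximum rank attained by a causal
#' feature (ties broken toward the lower index, consistently with
#' [select_top()]).
#'
#' @param scores a `screening_scores` object.
#' @param true_set indices of the truly influential features.
#' @return integer model size.
#' @export
min_model_size <- function(scores, true_set) {
  if (length(true_set) == 0L) stop("true_set must be non-empty")
  rk <- feature_ranks(scores)
  if (any(true_set < 1L | true_set > length(rk))) {
    stop("true_set contains indices outside 1..p")
  }
  max(rk[true_set])
}

#' Per-feature and simultaneous screening success
#'
#' @inheritParams min_model_size
#' @param d retention threshold (top-`d` rule), `1 <= d <= p`.
#' @return list with `individual` (logical per causal feature: rank
#'   `<= d`) and `simultaneous` (all causal features within the top `d`).
#' @export
success_indicators <- function(scores, true_set, d) {
  rk <- feature_ranks(scores)
  if (d < 1L || d > length(rk)) stop("d must be between 1 and p")
  ind <- rk[true_set] <= d
  list(individual = ind, simultaneous = all(ind))
}

# Success bookkeeping for an ITC selected_model: a causal feature succeeds
# at budget d if it appears among the first d selected features.
itc_indicators <- function(model, true_set, d) {
  pos <- match(true_set, model$indices)
  ind <- !is.na(pos) & pos <= d
  list(individual = ind, simultaneous = all(ind),
       min_size = if (anyNA(pos)) NA_integer_ else max(pos))
}

#' Replicated screening study
#'
#' Generates `reps` replicates of a simulation design, screens each with
#' every requested method, and aggregates the three evaluation criteria:
#' average minimum model size, per-causal-feature individual success
#' rates, and the simultaneous success rate, at each retention threshold
#' in `d`. Replicate streams are spawned from the master seed, so results
#' are deterministic, parallel-safe, and the first `reps` replicates of a
#' longer run coincide with a shorter one.
#'
#' Method `"ITC"` uses [itc_screen()] with `itc_schedule` (default
#' `c(6, max(d) - 6)`); it yields a selected set rather than a full
#' ranking, so its minimum model size is the selection position covering
#' all causal features, and is `NA` (excluded, counted) in replicates
#' where the budget misses one.
#'
#' @param design `"sim2"`, `"sim3"`, `"sim4"`, `"ldgwas"`, or a function
#'   `function(seed, ...)` returning a replicate list.
#' @param methods subset of `c("TC", "DC", "PC", "MMLE", "ITC")`.
#' @param reps number of Monte-Carlo replicates.
#' @param d retention threshold(s).
#' @param seed master seed.
#' @param itc_schedule iteration sizes for `"ITC"`.
#' @param ... passed to the design generator (e.g. `n`, `p`, `rho`).
#' @return a `study_report`: per-method average minimum model size
#'   (`avg_min_model_size`), matrix of individual success rates
#'   (`p_individual`), simultaneous rates per `d` (`p_simultaneous`),
#'   per-replicate minimum sizes (`min_sizes`), failure counts and
#'   elapsed seconds.
#' @export
run_study <- function(design, methods = "TC", reps = 100L, d = 15L,
                      seed = 1L, itc_schedule = NULL, ...) {
  gen <- if (is.function(design)) design else design_generator(design)
  design_tag <- if (is.function(design)) "custom" else design
  methods <- toupper(methods)
  seeds <- replicate_seeds(seed, reps)
  d <- sort(as.integer(d))
  if (is.null(itc_schedule) && "ITC" %in% methods) {
    itc_schedule <- c(6L, max(d) - 6L)
  }
  t0 <- proc.time()[["elapsed"]]
  min_sizes <- matrix(NA_real_, reps, length(methods),
                      dimnames = list(NULL, methods))
  indiv <- NULL
  simult <- array(NA, c(reps, length(methods), length(d)),
                  dimnames = list(NULL, methods, paste0("d=", d)))
  failures <- stats::setNames(integer(length(methods)), methods)
  for (r in seq_len(reps)) {
    rep_data <- gen(seed = seeds[r], ...)
    ts <- rep_data$true_set
    if (is.null(indiv)) {
      indiv <- array(NA, c(reps, length(methods), length(ts)),
                     dimnames = list(NULL, methods, paste0("X", seq_along(ts))))
    }
    for (mi in seq_along(methods)) {
      m <- methods[mi]
      res <- tryCatch({
        if (m == "ITC") {
          model <- itc_screen(rep_data$X, rep_data$y, schedule = itc_schedule)
          at_d <- lapply(d, function(dd) itc_indicators(model, ts, dd))
          list(min_size = at_d[[length(at_d)]]$min_size,
               indiv = at_d[[length(at_d)]]$individual,
               simult = vapply(at_d, `[[`, logical(1), "simultaneous"))
        } else {
          sc <- suppressWarnings(screener_for(m)(rep_data$X, rep_data$y))
          rk <- feature_ranks(sc)[ts]
          list(min_size = max(rk), indiv = rk <= max(d),
               simult = vapply(d, function(dd) all(rk <= dd), logical(1)))
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[m] <- failures[m] + 1L
        next
      }
      min_sizes[r, mi] <- res$min_size
      indiv[r, mi, ] <- res$indiv
      simult[r, mi, ] <- res$simult
    }
  }
  structure(list(
    design = design_tag, methods = methods, reps = reps, d = d, seed = seed,
    avg_min_model_size = colMeans(min_sizes, na.rm = TRUE),
    p_individual = apply(indiv, c(2, 3), mean, na.rm = TRUE),
    p_simultaneous = apply(simult, c(2, 3), mean, na.rm = TRUE),
    min_sizes = min_sizes, failures = failures,
    elapsed = proc.time()[["elapsed"]] - t0
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report:", x$design, "|", x$reps, "replicates | d =",
      paste(x$d, collapse = ","), "| seed", x$seed,
      sprintf("| %.1fs\n", x$elapsed))
  tab <- cbind(`|M|` = round(x$avg_min_model_size, 3),
               round(x$p_individual, 3),
               P_a = round(x$p_simultaneous[, ncol(x$p_simultaneous),
                                            drop = TRUE], 3))
  print(tab)
  if (any(x$failures > 0)) cat("failures:", paste(names(x$failures),
                                                  x$failures, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a study report
#'
#' Writes the per-method summary (method rows; average minimum model
#' size, individual success rates, simultaneous rate per threshold) as a
#' TSV table mirroring the usual presentation of screening benchmarks.
#'
#' @param report a `study_report`.
#' @param path output TSV path.
#' @export
write_study_report <- function(report, path) {
  df <- data.frame(method = report$methods,
                   avg_min_model_size = report$avg_min_model_size,
                   report$p_individual,
                   report$p_simultaneous, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
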