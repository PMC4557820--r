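# MCMC trace handling: harmonic-mean lnL and AICM model comparison.

#' Construct a trace of sampled log-likelihoods
#'
#' @param lnl Numeric vector of sampled log-likelihood values.
#' @param burnin Fraction of leading samples discarded (default 0.1).
#' @return Object of class `trace_series`: `lnl` (post burn-in), `burnin`,
#'   `n`.
#' @export
trace_series <- function(lnl, burnin = 0.1) {
  stopifnot(is.numeric(lnl), all(is.finite(lnl)),
            burnin >= 0, burnin < 1)
  drop <- floor(length(lnl) * burnin)
  kept <- lnl[seq.int(drop + 1, length(lnl))]
  if (length(kept) < 1) stop("empty trace after burn-in")
  structure(list(lnl = kept, burnin = burnin, n = length(kept)),
            class = "trace_series")
}

#' Read an MCMC parameter trace
#'
#' Accepts plain TSV with a header naming the log-likelihood column, and
#' the MrBayes `.p` dialect (an `[ID: ...]` first line before the
#' tab-separated header).
#'
#' @param path Trace file.
#' @param lnl_col Name of the log-likelihood column (default `"LnL"`).
#' @param burnin Burn-in fraction (default 0.1).
#' @return A [trace_series()].
#' @export
read_trace <- function(path, lnl_col = "LnL", burnin = 0.1) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  skip <- if (grepl("^\\[", lines[1])) 1 else 0
  df <- utils::read.delim(path, skip = skip, check.names = FALSE)
  if (!lnl_col %in% names(df)) {
    stop("no column '", lnl_col, "' in trace; columns: ",
         paste(names(df), collapse = ", "))
  }
  trace_series(df[[lnl_col]], burnin = burnin)
}

#' Log harmonic mean of sampled likelihoods
#'
#' The harmonic-mean marginal-likelihood proxy, computed stably in log
#' space: `log HM = -(logsumexp(-lnl) - log n)`.
#'
#' @param trace A [trace_series()] or numeric vector.
#' @return The log harmonic-mean estimate (scalar).
#' @export
harmonic_mean_lnl <- function(trace) {
  x <- if (inherits(trace, "trace_series")) trace$lnl else trace
  if (length(x) < 1) stop("empty trace")
  -(logsumexp(-x) - log(length(x)))
}

#' AICM of an MCMC trace
#'
#' AIC-through-MCMC: `AICM = 2 * var(lnl) - 2 * mean(lnl)`, the
#' variance-penalized analogue of AIC computed from the posterior sample of
#' log-likelihoods (smaller is better). The standard deviation is estimated
#' by a seeded bootstrap over trace samples.
#'
#' @param trace A [trace_series()] or numeric vector (>= 2 samples).
#' @param boot_reps Bootstrap replicates for the SD (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return List of class `aicm_result`: `aicm`, `sd`, `n`.
#' @export
aicm <- function(trace, boot_reps = 1000, seed = 1) {
  x <- if (inherits(trace, "trace_series")) trace$lnl else trace
  if (length(x) < 2) stop("need at least 2 trace samples")
  point <- function(v) 2 * stats::var(v) - 2 * mean(v)
  boots <- with_seed(seed, vapply(seq_len(boot_reps), function(r) {
    point(sample(x, replace = TRUE))
  }, numeric(1)))
  structure(list(aicm = point(x), sd = stats::sd(boots), n = length(x)),
            class = "aicm_result")
}

#' @export
print.aicm_result <- function(x, ...) {
  cat(sprintf("AICM = %.4f (SD = %.4f, n = %d)\n", x$aicm, x$sd, x$n))
  invisible(x)
}

#' Compare two partitioning schemes from their MCMC traces
#'
#' Reports the harmonic-mean difference and the AICM difference (with
#' bootstrap SDs) between two models. Sign convention: positive differences
#' favor the second model (its harmonic mean is higher / its AICM lower).
#'
#' @param traceA,traceB [trace_series()] objects (e.g. unpartitioned vs
#'   partitioned).
#' @param boot_reps,seed Passed to [aicm()].
#' @return List of class `model_comparison`: `hm_A`, `hm_B`, `delta_hm`
#'   (`hm_B - hm_A`), `aicm_A`, `aicm_B` (each with SD), `delta_aicm`
#'   (`aicm_A - aicm_B`), `favored` (`"A"`, `"B"` or `"tie"` by AICM).
#' @export
compare_partition_models <- function(traceA, traceB, boot_reps = 1000,
                                     seed = 1) {
  hmA <- harmonic_mean_lnl(traceA)
  hmB <- harmonic_mean_lnl(traceB)
  aA <- aicm(traceA, boot_reps = boot_reps, seed = seed)
  aB <- aicm(traceB, boot_reps = boot_reps, seed = seed + 1)
  d <- aA$aicm - aB$aicm
  structure(list(hm_A = hmA, hm_B = hmB, delta_hm = hmB - hmA,
                 aicm_A = aA, aicm_B = aB, delta_aicm = d,
                 favored = if (d > 0) "B" else if (d < 0) "A" else "tie"),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("harmonic-mean lnL: A = %.4f, B = %.4f (delta = %.4f)\n",
              x$hm_A, x$hm_B, x$delta_hm))
  cat(sprintf("AICM: A = %.4f (SD %.3f), B = %.4f (SD %.3f); delta = %.4f -> favors %s\n",
              x$aicm_A$aicm, x$aicm_A$sd, x$aicm_B$aicm, x$aicm_B$sd,
              x$delta_aicm, x$favored))
  invisible(x)
}
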