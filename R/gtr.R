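# GTR + discrete-gamma substitution machinery shared by the quartet
# likelihood-mapping module and the sequence simulators.

#' Define a GTR + Gamma substitution model
#'
#' Builds the general time-reversible rate matrix from the six
#' exchangeabilities and the stationary base frequencies, normalized so the
#' expected substitution rate is 1 per unit branch length, with discrete
#' gamma rate heterogeneity (equal-probability categories at their quantile
#' medians, mean-normalized).
#'
#' @param rates Exchangeabilities in the order AC, AG, AT, CG, CT, GT.
#' @param freqs Stationary frequencies (A, C, G, T), summing to 1.
#' @param gamma_shape Gamma shape alpha; `Inf` disables rate
#'   heterogeneity. Categories are represented by their conditional means.
#' @param ncat Number of discrete gamma categories (default 4).
#' @return Object of class `gtr_model` with the rate matrix `Q`, its eigen
#'   decomposition, `freqs`, and the per-category relative rates.
#' @export
gtr_model <- function(rates = rep(1, 6), freqs = rep(0.25, 4),
                      gamma_shape = Inf, ncat = 4) {
  stopifnot(length(rates) == 6, all(rates > 0),
            length(freqs) == 4, all(freqs > 0),
            abs(sum(freqs) - 1) < 1e-8)
  freqs <- freqs / sum(freqs)
  names(freqs) <- c("A", "C", "G", "T")
  R <- matrix(0, 4, 4, dimnames = list(names(freqs), names(freqs)))
  R["A", "C"] <- rates[1]; R["A", "G"] <- rates[2]; R["A", "T"] <- rates[3]
  R["C", "G"] <- rates[4]; R["C", "T"] <- rates[5]; R["G", "T"] <- rates[6]
  R <- R + t(R)
  Q <- R %*% diag(freqs)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(names(freqs), names(freqs))
  # symmetrize for a stable eigen decomposition: B = D^1/2 Q D^-1/2
  d <- sqrt(freqs)
  B <- diag(d) %*% Q %*% diag(1 / d)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  cat_rates <- if (is.finite(gamma_shape)) {
    # equal-probability categories represented by their conditional means
    b <- stats::qgamma(seq(0, 1, length.out = ncat + 1),
                       shape = gamma_shape, rate = gamma_shape)
    r <- ncat * diff(stats::pgamma(b, shape = gamma_shape + 1,
                                   rate = gamma_shape))
    r / mean(r)
  } else {
    1
  }
  structure(list(Q = Q, freqs = freqs,
                 evec = diag(1 / d) %*% eig$vectors,
                 ivec = t(eig$vectors) %*% diag(d),
                 evals = eig$values,
                 gamma_shape = gamma_shape, cat_rates = cat_rates),
            class = "gtr_model")
}

#' Transition probability matrix P(t) of a GTR model
#'
#' @param model A [gtr_model()].
#' @param t Branch length (expected substitutions per site).
#' @param rate Relative rate multiplier (e.g. a gamma category rate).
#' @return 4 x 4 row-stochastic matrix, rows = ancestral state.
#' @export
gtr_pmatrix <- function(model, t, rate = 1) {
  P <- model$evec %*% (exp(model$evals * t * rate) * model$ivec)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(model$Q)
  P
}

# per-character conditional likelihood columns (4 x n) for a residue vector
residue_likelihoods <- function(chars) {
  out <- matrix(0, 4, length(chars),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (is_gap_char(ch) || !ch %in% names(iupac_sets)) {
      out[, i] <- 1
    } else {
      out[iupac_sets[[ch]], i] <- 1
    }
  }
  out
}
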