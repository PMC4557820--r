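# Likelihood mapping: quartet maximum likelihood under GTR+Gamma,
# barycentric weights, seven-region classification, and cluster-constrained
# hypothesis mapping.

# the three unrooted quartet topologies over taxa (1,2,3,4), by pairing
quartet_topologies <- list(c(1, 2, 3, 4),   # 12|34
                           c(1, 3, 2, 4),   # 13|24
                           c(1, 4, 2, 3))   # 14|23

# site-pattern compression: returns per-taxon conditional likelihood
# arrays (4 x npatterns) and pattern weights
compress_patterns <- function(seqmat) {
  pat <- apply(seqmat, 2, paste, collapse = "")
  tab <- table(pat)
  keys <- names(tab)
  first <- match(keys, pat)
  clv <- lapply(seq_len(nrow(seqmat)), function(i) {
    residue_likelihoods(seqmat[i, first])
  })
  list(clv = clv, weights = as.numeric(tab))
}

# log-likelihood of one quartet topology at given branch lengths
# br = (tip1, tip2, tip3, tip4, internal), topology = permutation of tips
quartet_lnl <- function(patterns, model, topology, br) {
  tot <- 0
  nw <- sum(patterns$weights)
  sitelik <- 0
  for (k in seq_along(model$cat_rates)) {
    r <- model$cat_rates[k]
    P <- lapply(seq_len(5), function(e) gtr_pmatrix(model, br[e], r))
    a <- topology[1]; b <- topology[2]; cc <- topology[3]; d <- topology[4]
    left <- (P[[1]] %*% patterns$clv[[a]]) * (P[[2]] %*% patterns$clv[[b]])
    right <- (P[[3]] %*% patterns$clv[[cc]]) * (P[[4]] %*% patterns$clv[[d]])
    sitelik <- sitelik + colSums(model$freqs * (left * (P[[5]] %*% right)))
  }
  sitelik <- sitelik / length(model$cat_rates)
  if (any(sitelik <= 0)) return(-Inf)
  sum(patterns$weights * log(sitelik))
}

# maximize a quartet topology's lnL over the 5 branch lengths by
# coordinate descent with Brent-style bounded line searches
optimize_quartet <- function(patterns, model, topology,
                             br = rep(0.1, 5), tol = 1e-6,
                             lower = 1e-8, upper = 10, max_sweeps = 25) {
  lnl <- quartet_lnl(patterns, model, topology, br)
  for (sweep in seq_len(max_sweeps)) {
    for (e in seq_len(5)) {
      f <- function(x) {
        b2 <- br
        b2[e] <- x
        -quartet_lnl(patterns, model, topology, b2)
      }
      opt <- stats::optimize(f, c(lower, upper), tol = 1e-6)
      if (-opt$objective > lnl) {
        br[e] <- opt$minimum
        lnl <- -opt$objective
      }
    }
    new_lnl <- quartet_lnl(patterns, model, topology, br)
    if (new_lnl - lnl < tol && sweep > 1) {
      lnl <- max(lnl, new_lnl)
      break
    }
    lnl <- max(lnl, new_lnl)
  }
  list(lnl = lnl, br = br)
}

#' Maximum log-likelihoods of the three quartet topologies
#'
#' For four aligned sequences, maximizes the log-likelihood of each of the
#' three unrooted quartet topologies over the five branch lengths under a
#' fixed GTR+Gamma model (bounded coordinate descent, convergence tolerance
#' 1e-6 on the log-likelihood). Gap and ambiguity columns are handled by
#' per-site marginalization over the permitted states.
#'
#' @param seqs Character matrix of 4 aligned rows.
#' @param model A [gtr_model()] with fixed parameters.
#' @return Numeric vector of 3 log-likelihoods, in the order
#'   12|34, 13|24, 14|23.
#' @export
quartet_likelihoods <- function(seqs, model) {
  stopifnot(is.matrix(seqs), nrow(seqs) == 4)
  shared <- colSums(matrix(!is_gap_char(seqs), 4)) == 4
  if (!any(shared)) stop("no column shared by all four sequences")
  patterns <- compress_patterns(seqs)
  vapply(quartet_topologies, function(tp) {
    optimize_quartet(patterns, model, tp)$lnl
  }, numeric(1))
}

#' Posterior weights of the three quartet topologies
#'
#' @param lnls Numeric vector of 3 log-likelihoods.
#' @return Numeric vector of 3 weights on the simplex (summing to 1).
#' @export
posterior_weights <- function(lnls) {
  stopifnot(length(lnls) == 3)
  if (all(!is.finite(lnls))) stop("all log-likelihoods non-finite")
  w <- exp(lnls - max(lnls))
  w / sum(w)
}

simplex_region_ids <- c("T1", "T2", "T3", "E12", "E13", "E23", "C")

#' Classify a quartet weight vector into one of seven simplex regions
#'
#' Partitions the barycentric simplex into three fully resolved corner
#' basins (`T1`, `T2`, `T3`: the dominant weight exceeds 1/2), three
#' partly resolved edge regions (`E12`, `E13`, `E23`: the omitted
#' topology's weight is at most 1/4 while no single weight dominates) and
#' the star-like central region `C` (all weights between 1/4 and 1/2).
#' The corner cuts are the mid-lines `w_i = 1/2`; the edge/center boundary
#' is the medial triangle of the remaining central triangle. Boundary
#' points are assigned deterministically to the lowest region id in the
#' order T1, T2, T3, E12, E13, E23, C.
#'
#' @param weights Numeric vector of 3 non-negative weights summing to 1.
#' @return Region id (character).
#' @export
simplex_region <- function(weights) {
  stopifnot(length(weights) == 3, all(weights >= -1e-12),
            abs(sum(weights) - 1) < 1e-6)
  if (weights[1] > 0.5) return("T1")
  if (weights[2] > 0.5) return("T2")
  if (weights[3] > 0.5) return("T3")
  if (weights[3] <= 0.25) return("E12")
  if (weights[2] <= 0.25) return("E13")
  if (weights[1] <= 0.25) return("E23")
  "C"
}

#' Likelihood mapping of an alignment
#'
#' Evaluates quartets of taxa (all quartets when their number does not
#' exceed `exhaustive_limit`, otherwise a seeded uniform sample of
#' `n_quartets`), maps each quartet's posterior topology weights onto the
#' simplex and tallies the seven regions. In cluster mode one taxon is
#' drawn per cluster for every quartet and the three topologies are
#' labeled by cluster pairings, so corner fractions answer which grouping
#' the quartets support (T1 = clusters 12|34, T2 = 13|24, T3 = 14|23).
#'
#' @param aln Character matrix or list with `seqs`.
#' @param model A [gtr_model()].
#' @param n_quartets Number of quartets in sampled mode (or `"all"`).
#' @param clusters Optional list of 4 disjoint non-empty taxon sets.
#' @param seed Integer seed for quartet sampling.
#' @param exhaustive_limit Evaluate all quartets when the total count is
#'   at most this value.
#' @return Object of class `quartet_map`: `counts` and `fractions` over
#'   the seven regions, `total`, and `resolved`, `partly`, `star`
#'   convenience fractions.
#' @export
likelihood_mapping <- function(aln, model, n_quartets = 10000,
                               clusters = NULL, seed = 1,
                               exhaustive_limit = 50000) {
  if (is.list(aln) && !is.data.frame(aln) && !is.null(aln$seqs)) {
    aln <- aln$seqs
  }
  stopifnot(is.matrix(aln), nrow(aln) >= 4)
  taxa <- rownames(aln)
  if (!is.null(clusters)) {
    stopifnot(length(clusters) == 4)
    if (any(lengths(clusters) == 0)) stop("cluster with zero taxa")
    if (length(unlist(clusters)) != length(unique(unlist(clusters)))) {
      stop("clusters must be disjoint")
    }
    if (!all(unlist(clusters) %in% taxa)) {
      stop("cluster taxa absent from alignment")
    }
    total_possible <- prod(lengths(clusters))
    draw_all <- total_possible <= exhaustive_limit &&
      (identical(n_quartets, "all") || total_possible <= n_quartets)
    quartets <- if (draw_all) {
      as.matrix(expand.grid(lapply(clusters, function(cl)
        match(cl, taxa))))
    } else {
      with_seed(seed, t(vapply(seq_len(n_quartets), function(k) {
        vapply(clusters, function(cl) match(sample(cl, 1), taxa),
               integer(1))
      }, integer(4))))
    }
  } else {
    n <- length(taxa)
    total_possible <- choose(n, 4)
    draw_all <- total_possible <= exhaustive_limit &&
      (identical(n_quartets, "all") || total_possible <= n_quartets)
    quartets <- if (draw_all) {
      t(utils::combn(n, 4))
    } else {
      with_seed(seed, t(vapply(seq_len(n_quartets), function(k) {
        sort(sample(n, 4))
      }, integer(4))))
    }
  }
  regions <- character(nrow(quartets))
  failed <- 0
  for (q in seq_len(nrow(quartets))) {
    lnls <- tryCatch(
      quartet_likelihoods(aln[quartets[q, ], , drop = FALSE], model),
      error = function(e) NULL)
    if (is.null(lnls)) {
      failed <- failed + 1
      regions[q] <- NA_character_
      next
    }
    regions[q] <- simplex_region(posterior_weights(lnls))
  }
  if (failed > 0) {
    warning(failed, " quartet(s) failed optimization and were excluded")
  }
  regions <- regions[!is.na(regions)]
  counts <- table(factor(regions, levels = simplex_region_ids))
  fr <- as.numeric(counts) / max(1, length(regions))
  names(fr) <- names(counts)
  structure(list(counts = counts, fractions = fr,
                 total = length(regions),
                 resolved = sum(fr[c("T1", "T2", "T3")]),
                 partly = sum(fr[c("E12", "E13", "E23")]),
                 star = fr[["C"]]),
            class = "quartet_map")
}

#' @export
print.quartet_map <- function(x, ...) {
  cat("likelihood mapping over", x$total, "quartets\n")
  cat(sprintf("  resolved %.1f%%  partly %.1f%%  star-like %.1f%%\n",
              100 * x$resolved, 100 * x$partly, 100 * x$star))
  print(x$counts)
  invisible(x)
}
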