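# Rescue of regions of ambiguous alignment (RAAs): block extraction,
# guide-tree progressive alignment under an affine-gap cost regime,
# concatenation, and Monte-Carlo random-similarity masking.

#' Alignment cost regime
#'
#' The cost regime used for per-block RAA alignment: a gap run of length k
#' costs `gap_open + (k - 1) * gap_extend`; every substitution costs
#' `substitution`; matches cost 0. The default (4, 1, 1) penalizes gap
#' opening four-fold relative to equally weighted gap extension and
#' substitution.
#'
#' @param gap_open,gap_extend,substitution Non-negative costs with
#'   `gap_open >= gap_extend`.
#' @return List of class `alignment_costs`.
#' @export
alignment_costs <- function(gap_open = 4, gap_extend = 1, substitution = 1) {
  stopifnot(gap_open >= 0, gap_extend >= 0, substitution >= 0,
            gap_open >= gap_extend)
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 substitution = substitution),
            class = "alignment_costs")
}

#' Extract RAA blocks from a structured alignment
#'
#' One block per annotated RAA span; a taxon's subsequence is its non-gap
#' characters within the span (possibly empty).
#'
#' @param aln A [structured_alignment()].
#' @return List of `raa_block` objects: `block`, `span` (1-based inclusive
#'   master columns), `seqs` (named character vector, no gaps).
#' @export
extract_raa_blocks <- function(aln) {
  stopifnot(inherits(aln, "structured_alignment"))
  lapply(seq_len(nrow(aln$raa)), function(k) {
    span <- c(aln$raa$start[k], aln$raa$end[k])
    sub <- aln$seqs[, span[1]:span[2], drop = FALSE]
    seqs <- apply(sub, 1, function(row) {
      paste(row[!is_gap_char(row)], collapse = "")
    })
    structure(list(block = aln$raa$block[k], span = span, seqs = seqs),
              class = "raa_block")
  })
}

# mean pairwise substitution cost between two profile columns
# (residue-residue: 0 match / substitution mismatch; residue-gap: extend;
# gap-gap: 0)
profile_column_cost <- function(colA, colB, costs) {
  total <- 0
  for (a in colA) {
    ga <- is_gap_char(a)
    for (b in colB) {
      gb <- is_gap_char(b)
      total <- total + if (ga && gb) 0
      else if (ga || gb) costs$gap_extend
      else if (a == b) 0
      else costs$substitution
    }
  }
  total / (length(colA) * length(colB))
}

# Affine-gap (Gotoh) global alignment of two profiles (character matrices).
# Cost minimization; deterministic tie-breaking: prefer match, then gap in
# the first profile, leftmost placement via backward-consistent traceback.
align_profiles <- function(A, B, costs) {
  m <- ncol(A)
  n <- ncol(B)
  go <- costs$gap_open
  ge <- costs$gap_extend
  # substitution cost matrix between profile columns
  S <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      S[i, j] <- profile_column_cost(A[, i], B[, j], costs)
    }
  }
  INF <- Inf
  M <- matrix(INF, m + 1, n + 1)  # last columns aligned
  X <- matrix(INF, m + 1, n + 1)  # gap in B (consumes A)
  Y <- matrix(INF, m + 1, n + 1)  # gap in A (consumes B)
  M[1, 1] <- 0
  if (m > 0) X[2:(m + 1), 1] <- go + (seq_len(m) - 1) * ge
  if (n > 0) Y[1, 2:(n + 1)] <- go + (seq_len(n) - 1) * ge
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      M[i, j] <- min(M[i - 1, j - 1], Y[i - 1, j - 1], X[i - 1, j - 1]) +
        S[i - 1, j - 1]
      X[i, j] <- min(M[i - 1, j] + go, X[i - 1, j] + ge, Y[i - 1, j] + go)
      Y[i, j] <- min(M[i, j - 1] + go, X[i, j - 1] + go, Y[i, j - 1] + ge)
    }
  }
  cost <- min(M[m + 1, n + 1], Y[m + 1, n + 1], X[m + 1, n + 1])
  # traceback; preference order at ties: M (match), then Y (gap in first
  # profile), then X
  i <- m; j <- n
  state <- c("M", "Y", "X")[which.min(c(M[m + 1, n + 1], Y[m + 1, n + 1],
                                        X[m + 1, n + 1]))]
  opsA <- integer(0)  # 0 = gap column, k = column k of the profile
  opsB <- integer(0)
  eps <- 1e-9
  while (i > 0 || j > 0) {
    if (state == "M") {
      opsA <- c(i, opsA); opsB <- c(j, opsB)
      prev <- c(M[i, j], Y[i, j], X[i, j]) + S[i, j]
      state <- c("M", "Y", "X")[which(abs(prev - M[i + 1, j + 1]) < eps)[1]]
      i <- i - 1; j <- j - 1
    } else if (state == "Y") {
      opsA <- c(0L, opsA); opsB <- c(j, opsB)
      prev <- c(M[i + 1, j] + go, Y[i + 1, j] + ge, X[i + 1, j] + go)
      state <- c("M", "Y", "X")[which(abs(prev - Y[i + 1, j + 1]) < eps)[1]]
      j <- j - 1
    } else {
      opsA <- c(i, opsA); opsB <- c(0L, opsB)
      prev <- c(M[i, j + 1] + go, Y[i, j + 1] + go, X[i, j + 1] + ge)
      state <- c("M", "Y", "X")[which(abs(prev - X[i + 1, j + 1]) < eps)[1]]
      i <- i - 1
    }
  }
  expand <- function(P, ops) {
    out <- matrix("-", nrow(P), length(ops))
    rownames(out) <- rownames(P)
    out[, ops > 0] <- P[, ops[ops > 0], drop = FALSE]
    out
  }
  list(aln = rbind(expand(A, opsA), expand(B, opsB)), cost = cost)
}

#' Align one RAA block under a guide tree
#'
#' Progressive profile alignment following the guide tree: subsequences are
#' merged postorder (most similar first, WPGMA-style traversal of the given
#' tree), each merge solved exactly by affine-gap dynamic programming under
#' the cost regime with deterministic tie-breaking (prefer match, then gap
#' in the first profile, leftmost placement). Taxa with empty subsequences
#' are added as all-gap rows after alignment.
#'
#' @param block A `raa_block` from [extract_raa_blocks()].
#' @param guide An `ape::phylo` guide tree whose tips cover all taxa with
#'   non-empty subsequences.
#' @param costs An [alignment_costs()].
#' @return List of class `aligned_block`: `block`, `span`, `aln` (character
#'   matrix over all block taxa, master taxon order), `cost` (total of the
#'   per-merge optimal costs).
#' @export
align_block <- function(block, guide, costs = alignment_costs()) {
  stopifnot(inherits(block, "raa_block"), inherits(guide, "phylo"))
  taxa <- names(block$seqs)
  present <- taxa[nchar(block$seqs) > 0]
  missing_tips <- setdiff(present, guide$tip.label)
  if (length(missing_tips) > 0) {
    stop("taxa missing from guide tree: ",
         paste(missing_tips, collapse = ", "))
  }
  total_cost <- 0
  if (length(present) == 0) {
    aln <- matrix(character(0), nrow = 0, ncol = 0)
    width <- 0
  } else if (length(present) == 1) {
    aln <- strings_to_matrix(block$seqs[present])
  } else {
    g <- ape::keep.tip(guide, present)
    g <- stats::reorder(g, "postorder")
    nt <- length(g$tip.label)
    profiles <- vector("list", nt + g$Nnode)
    for (k in seq_len(nt)) {
      s <- block$seqs[[g$tip.label[k]]]
      profiles[[k]] <- matrix(strsplit(s, "")[[1]], nrow = 1,
                              dimnames = list(g$tip.label[k], NULL))
    }
    for (e in seq_len(nrow(g$edge))) {
      parent <- g$edge[e, 1]
      child <- g$edge[e, 2]
      if (is.null(profiles[[parent]])) {
        profiles[[parent]] <- profiles[[child]]
      } else {
        merged <- align_profiles(profiles[[parent]], profiles[[child]],
                                 costs)
        profiles[[parent]] <- merged$aln
        total_cost <- total_cost + merged$cost
      }
    }
    aln <- profiles[[nt + 1]]
  }
  width <- ncol(aln)
  full <- matrix("-", length(taxa), width, dimnames = list(taxa, NULL))
  if (nrow(aln) > 0) full[rownames(aln), ] <- aln
  structure(list(block = block$block, span = block$span, aln = full,
                 cost = total_cost),
            class = "aligned_block")
}

#' Align one RAA block under several guide trees
#'
#' Aligns the block under every guide tree and returns the minimum-cost
#' alignment (ties broken by the first tree in input order). All candidate
#' costs are recorded, enabling sensitivity checks across the posterior
#' guide-tree sample.
#'
#' @param block A `raa_block`.
#' @param guides A list of guide trees (or an `ape::multiPhylo`).
#' @param costs An [alignment_costs()].
#' @return The winning `aligned_block` with an extra element
#'   `candidate_costs` (numeric, one per guide) and `chosen_guide` (index).
#' @export
align_block_multi <- function(block, guides, costs = alignment_costs()) {
  stopifnot(length(guides) >= 1)
  fits <- lapply(guides, function(g) align_block(block, g, costs))
  cc <- vapply(fits, `[[`, numeric(1), "cost")
  best <- which.min(cc)  # first minimum wins
  out <- fits[[best]]
  out$candidate_costs <- cc
  out$chosen_guide <- best
  out
}

#' Concatenate aligned RAA blocks
#'
#' @param blocks List of `aligned_block` objects sharing the master taxon
#'   list (taxa absent from a block are already all-gap rows).
#' @return List of class `raa_concatenation`: `aln` (character matrix),
#'   `provenance` (data.frame `column`, `block`, `offset`).
#' @export
concatenate_blocks <- function(blocks) {
  stopifnot(length(blocks) >= 1)
  ids <- vapply(blocks, `[[`, character(1), "block")
  if (anyDuplicated(ids)) stop("duplicate block id: ",
                               ids[duplicated(ids)][1])
  taxa <- rownames(blocks[[1]]$aln)
  for (b in blocks) {
    if (!identical(rownames(b$aln), taxa)) {
      stop("blocks do not share the master taxon list")
    }
  }
  aln <- do.call(cbind, lapply(blocks, `[[`, "aln"))
  widths <- vapply(blocks, function(b) ncol(b$aln), integer(1))
  prov <- data.frame(column = seq_len(sum(widths)),
                     block = rep(ids, widths),
                     offset = unlist(lapply(widths, seq_len),
                                     use.names = FALSE))
  structure(list(aln = aln, provenance = prov),
            class = "raa_concatenation")
}

#' Monte-Carlo random-similarity mask
#'
#' Identifies alignment columns whose similarity is indistinguishable from
#' random, by sliding-window Monte-Carlo resampling of pairwise sequence
#' comparisons. For every taxon pair, each window of `window` columns is
#' scored +1 per matching base pair and -1 per mismatch or per position
#' where either sequence has a gap. The null distribution pools the window
#' scores of `reps` composition-preserving shuffles of both rows; a window
#' is non-random when its observed score exceeds the null's `quantile`. A
#' site's pair profile is +1 when the majority of windows covering it are
#' non-random, else -1; the consensus profile is the mean over pairs, and
#' columns with positive consensus are kept.
#'
#' @param aln Character matrix (taxa x columns) or list with `seqs`.
#' @param window Sliding window width in columns (default 7).
#' @param reps Number of null shuffles per pair (>= 100).
#' @param quantile Null quantile above which a window is non-random.
#' @param seed Integer seed for the shuffles.
#' @return Object of class `mask_profile`: `consensus` (per-column score),
#'   `keep` (logical), and the parameters.
#' @export
random_similarity_mask <- function(aln, window = 7, reps = 200,
                                   quantile = 0.95, seed = 1) {
  if (is.list(aln) && !is.data.frame(aln) && !is.null(aln$seqs)) {
    aln <- aln$seqs
  }
  stopifnot(is.matrix(aln), window >= 2, reps >= 100)
  n <- nrow(aln)
  L <- ncol(aln)
  if (n < 2) stop("need at least 2 taxa")
  w <- min(window, L)  # alignment narrower than window: one clipped window
  pairs <- utils::combn(n, 2)
  site_votes <- matrix(0, ncol(pairs), L)
  with_seed(seed, {
    for (k in seq_len(ncol(pairs))) {
      a <- aln[pairs[1, k], ]
      b <- aln[pairs[2, k], ]
      obs <- window_scores(a, b, w)
      null_scores <- unlist(lapply(seq_len(reps), function(r) {
        window_scores(sample(a), sample(b), w)
      }), use.names = FALSE)
      thr <- stats::quantile(null_scores, quantile, names = FALSE,
                             type = 7)
      nonrandom <- obs > thr
      # per-site majority vote over covering windows
      starts <- seq_len(L - w + 1)
      cover <- numeric(L)
      good <- numeric(L)
      for (s in starts) {
        idx <- s:(s + w - 1)
        cover[idx] <- cover[idx] + 1
        good[idx] <- good[idx] + nonrandom[s]
      }
      site_votes[k, ] <- ifelse(good > cover / 2, 1, -1)
    }
  })
  consensus <- colMeans(site_votes)
  structure(list(consensus = consensus, keep = consensus > 0,
                 window = w, reps = reps, quantile = quantile, seed = seed),
            class = "mask_profile")
}

# score of every window start: +1 match, -1 mismatch, -1 any gap position
window_scores <- function(a, b, w) {
  gap <- is_gap_char(a) | is_gap_char(b)
  s <- ifelse(gap, -1, ifelse(a == b, 1, -1))
  if (length(s) == w) return(sum(s))
  cs <- cumsum(s)
  cs[w:length(s)] - c(0, cs[seq_len(length(s) - w)])
}

#' Apply a mask profile to an alignment
#'
#' @param aln Character matrix or list with `seqs`.
#' @param profile A `mask_profile` from [random_similarity_mask()].
#' @return The filtered character matrix (kept columns, order preserved).
#' @export
apply_mask <- function(aln, profile) {
  if (is.list(aln) && !is.data.frame(aln) && !is.null(aln$seqs)) {
    aln <- aln$seqs
  }
  stopifnot(inherits(profile, "mask_profile"))
  if (ncol(aln) != length(profile$keep)) {
    stop("mask length ", length(profile$keep),
         " does not match alignment width ", ncol(aln))
  }
  if (!any(profile$keep)) warning("mask removes every column")
  aln[, profile$keep, drop = FALSE]
}
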