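# Bayesian relative-rates test: per-terminal root-to-tip path lengths over
# a posterior tree sample, credible intervals, and rate-outlier flags.

#' Per-terminal path-length distributions over a posterior tree sample
#'
#' For every sampled tree, takes the most recent common ancestor (MRCA) of
#' the reference clade (recomputed per tree, so the clade need not be
#' monophyletic) and sums branch lengths from that node to each terminal of
#' interest.
#'
#' @param trees Posterior tree sample (`multiPhylo`).
#' @param clade Character vector (length >= 2) of taxa whose MRCA is the
#'   reference node.
#' @param tips Terminals to profile; defaults to `clade`.
#' @return Numeric matrix (samples x terminals) of path lengths
#'   (substitutions/site), class `pathlength_profiles`.
#' @export
pathlength_profiles <- function(trees, clade, tips = clade) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  stopifnot(length(trees) >= 1, length(clade) >= 2)
  out <- matrix(NA_real_, length(trees), length(tips),
                dimnames = list(NULL, tips))
  for (s in seq_along(trees)) {
    tr <- trees[[s]]
    missing_tips <- setdiff(c(clade, tips), tr$tip.label)
    if (length(missing_tips) > 0) {
      stop("tip(s) absent from tree ", s, ": ",
           paste(missing_tips, collapse = ", "))
    }
    mrca <- ape::getMRCA(tr, clade)
    depths <- node_depths_from(tr, mrca)
    out[s, ] <- depths[match(tips, tr$tip.label)]
  }
  class(out) <- c("pathlength_profiles", class(out))
  out
}

# path length from `from` to every tip (NA for tips not below `from`;
# tips outside the subtree are reached through the MRCA's ancestors, so we
# compute undirected path lengths via node depths on the rooted tree)
node_depths_from <- function(tree, from) {
  n <- length(tree$tip.label)
  # depth of every node from the root
  depth <- numeric(n + tree$Nnode)
  tr <- stats::reorder(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    depth[tr$edge[e, 2]] <- depth[tr$edge[e, 1]] + tr$edge.length[e]
  }
  # ancestors of each node for undirected path computation
  parent <- integer(n + tr$Nnode)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  anc <- function(v) {
    out <- v
    while (parent[v] != 0) {
      v <- parent[v]
      out <- c(out, v)
    }
    out
  }
  from_anc <- anc(from)
  vapply(seq_len(n), function(tip) {
    ta <- anc(tip)
    common <- intersect(ta, from_anc)[1]
    depth[tip] + depth[from] - 2 * depth[common]
  }, numeric(1))
}

#' Bayesian relative-rates test
#'
#' Summarizes each terminal's path-length distribution by its mean,
#' equal-tailed credible interval at `mass`, and range, and flags a
#' terminal as fast-evolving when its credible interval does not overlap
#' the credible interval of any of the remaining terminals (leave-one-out:
#' the union of the others' intervals). `mode = "hull"` compares against
#' the others' convex hull `[min of others' lower bounds, max of others'
#' upper bounds]` instead, which cannot flag a terminal sitting between
#' two other outliers.
#'
#' @param profiles A `pathlength_profiles` matrix.
#' @param mass Credible mass in (0, 1) (default 0.95, equal-tailed).
#' @param mode `"envelope"` (default; union of the others' intervals) or
#'   `"hull"`.
#' @return Data.frame of class `rate_profile`: `terminal`, `mean`, `lo`,
#'   `hi`, `min`, `max`, `fast`.
#' @export
relative_rates_test <- function(profiles, mass = 0.95,
                                mode = c("envelope", "hull")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(profiles), ncol(profiles) >= 2)
  if (mass <= 0 || mass >= 1) stop("mass must be inside (0, 1)")
  a <- (1 - mass) / 2
  sm <- do.call(rbind, lapply(colnames(profiles), function(tx) {
    x <- profiles[, tx]
    q <- stats::quantile(x, c(a, 1 - a), names = FALSE, type = 7)
    data.frame(terminal = tx, mean = mean(x), lo = q[1], hi = q[2],
               min = min(x), max = max(x))
  }))
  sm$fast <- vapply(seq_len(nrow(sm)), function(i) {
    others <- sm[-i, , drop = FALSE]
    if (mode == "envelope") {
      all(sm$hi[i] < others$lo | sm$lo[i] > others$hi)
    } else {
      sm$hi[i] < min(others$lo) || sm$lo[i] > max(others$hi)
    }
  }, logical(1))
  rownames(sm) <- NULL
  class(sm) <- c("rate_profile", "data.frame")
  sm
}

#' @export
print.rate_profile <- function(x, ...) {
  cat("relative-rates test over", nrow(x), "terminals;",
      sum(x$fast), "flagged fast-evolving\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
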