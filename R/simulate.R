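# Synthetic-data generators: structured rDNA-like alignments with known
# ground truth, bootstrap/posterior tree sets with controlled conflict, and
# MCMC traces. Every generator is deterministic under a fixed seed.

#' Simulation configuration for structured alignments
#'
#' Defaults emulate the salient features of structure-annotated rDNA
#' matrices: paired stem columns maintained by compensatory substitutions,
#' adenine-rich loop composition, and length-variable indel-rich RAA
#' blocks.
#'
#' @param stem_pairs Number of stem column pairs.
#' @param loop_length Number of loop columns.
#' @param loop_freqs Loop stationary frequencies (A, C, G, T); default
#'   A-rich with `pi_A = 0.4`.
#' @param gamma_shape Gamma shape for loop rate heterogeneity.
#' @param q Compensation probability: probability that a stem substitution
#'   is immediately matched by the pairing partner.
#' @param n_raa Number of RAA blocks.
#' @param raa_base_length Ungapped root length of each RAA block.
#' @param indel_rate Indel events per substitution-unit of branch length
#'   per site inside RAA blocks.
#' @param indel_geom Geometric parameter of indel lengths (mean
#'   `1/indel_geom`).
#' @param rate_multipliers Named numeric vector of per-lineage rate
#'   multipliers applied to the subtending terminal branch.
#' @param gc_rich_lineages Named numeric vector (values in `[0, 1]`) of
#'   per-lineage GC enrichment: on the subtending terminal branch the RAA
#'   substitution process is pushed toward G/C by this weight and the
#'   deletion probability is scaled by one minus it, planting a positive
#'   GC-length correlation across taxa.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(stem_pairs = 40, loop_length = 80,
                       loop_freqs = c(A = 0.4, C = 0.2, G = 0.2, T = 0.2),
                       gamma_shape = 0.5, q = 0.9,
                       n_raa = 3, raa_base_length = 30,
                       indel_rate = 0.2, indel_geom = 0.4,
                       rate_multipliers = numeric(0),
                       gc_rich_lineages = numeric(0)) {
  stopifnot(q >= 0, q <= 1, all(loop_freqs >= 0),
            abs(sum(loop_freqs) - 1) < 1e-8,
            indel_rate >= 0, indel_geom > 0, indel_geom <= 1,
            all(rate_multipliers > 0),
            all(gc_rich_lineages >= 0), all(gc_rich_lineages <= 1))
  structure(list(stem_pairs = stem_pairs, loop_length = loop_length,
                 loop_freqs = loop_freqs, gamma_shape = gamma_shape,
                 q = q, n_raa = n_raa, raa_base_length = raa_base_length,
                 indel_rate = indel_rate, indel_geom = indel_geom,
                 rate_multipliers = rate_multipliers,
                 gc_rich_lineages = gc_rich_lineages),
            class = "sim_config")
}

#' Simulate a birth-death tree
#'
#' @param n Number of tips (>= 4).
#' @param birth,death Birth-death rates.
#' @param seed Integer seed.
#' @param rate_multipliers Optional named per-lineage multipliers applied
#'   to the subtending terminal branch lengths.
#' @return An `ape::phylo` with tip labels `t1..tn`.
#' @export
simulate_tree <- function(n, birth = 1, death = 0, seed = 1,
                          rate_multipliers = numeric(0)) {
  stopifnot(n >= 4)
  tree <- with_seed(seed, ape::rphylo(n, birth = birth, death = death))
  tree$tip.label <- paste0("t", seq_len(n))
  apply_rate_multipliers(tree, rate_multipliers)
}

apply_rate_multipliers <- function(tree, multipliers) {
  if (length(multipliers) == 0) return(tree)
  stopifnot(!is.null(names(multipliers)),
            all(names(multipliers) %in% tree$tip.label))
  for (tx in names(multipliers)) {
    tip <- match(tx, tree$tip.label)
    e <- which(tree$edge[, 2] == tip)
    tree$edge.length[e] <- tree$edge.length[e] * multipliers[[tx]]
  }
  tree
}

# evolve i.i.d. GTR(+Gamma) sequences of length L along a tree; returns a
# character matrix (tips x L). Site categories are fixed across the tree.
evolve_sequences <- function(tree, model, L, root_states = NULL) {
  tr <- stats::reorder(tree, "cladewise")
  n <- length(tr$tip.label)
  bases <- c("A", "C", "G", "T")
  ncat <- length(model$cat_rates)
  site_cat <- sample.int(ncat, L, replace = TRUE)
  states <- matrix(NA_integer_, n + tr$Nnode, L)
  states[n + 1, ] <- if (is.null(root_states)) {
    sample.int(4, L, replace = TRUE, prob = model$freqs)
  } else {
    root_states
  }
  Pcat <- vector("list", ncat)
  for (e in seq_len(nrow(tr$edge))) {
    b <- tr$edge.length[e]
    for (k in seq_len(ncat)) {
      Pcat[[k]] <- gtr_pmatrix(model, b, model$cat_rates[k])
    }
    parent_states <- states[tr$edge[e, 1], ]
    child <- integer(L)
    for (k in seq_len(ncat)) {
      idx <- which(site_cat == k)
      if (length(idx) == 0) next
      P <- Pcat[[k]]
      u <- stats::runif(length(idx))
      cp <- t(apply(P[parent_states[idx], , drop = FALSE], 1, cumsum))
      child[idx] <- max.col(u < cp, ties.method = "first")
    }
    states[tr$edge[e, 2], ] <- child
  }
  out <- matrix(bases[states[seq_len(n), , drop = FALSE]], n, L,
                dimnames = list(tr$tip.label, NULL))
  out
}

# complementary (pair-preserving) partner of a base: Watson-Crick plus G:U
wc_partner <- c(A = "T", C = "G", G = "C", T = "A")

# evolve paired stem columns: Poisson substitution events on each pair;
# with probability q the partner immediately co-substitutes to the
# complement. Returns list(left, right, events, compensated).
evolve_stem_pairs <- function(tree, npairs, q) {
  tr <- stats::reorder(tree, "cladewise")
  n <- length(tr$tip.label)
  bases <- c("A", "C", "G", "T")
  nodes_left <- matrix(NA_character_, n + tr$Nnode, npairs)
  nodes_right <- matrix(NA_character_, n + tr$Nnode, npairs)
  root_left <- sample(bases, npairs, replace = TRUE)
  nodes_left[n + 1, ] <- root_left
  nodes_right[n + 1, ] <- wc_partner[root_left]
  events <- 0
  compensated <- 0
  for (e in seq_len(nrow(tr$edge))) {
    b <- tr$edge.length[e]
    left <- nodes_left[tr$edge[e, 1], ]
    right <- nodes_right[tr$edge[e, 1], ]
    nev <- stats::rpois(npairs, 2 * b)
    for (p in which(nev > 0)) {
      for (ev in seq_len(nev[p])) {
        events <- events + 1
        member <- sample(c("L", "R"), 1)
        if (member == "L") {
          left[p] <- sample(setdiff(bases, left[p]), 1)
          if (stats::runif(1) < q) {
            right[p] <- wc_partner[[left[p]]]
            compensated <- compensated + 1
          }
        } else {
          right[p] <- sample(setdiff(bases, right[p]), 1)
          if (stats::runif(1) < q) {
            left[p] <- wc_partner[[right[p]]]
            compensated <- compensated + 1
          }
        }
      }
    }
    nodes_left[tr$edge[e, 2], ] <- left
    nodes_right[tr$edge[e, 2], ] <- right
  }
  list(left = nodes_left[seq_len(n), , drop = FALSE],
       right = nodes_right[seq_len(n), , drop = FALSE],
       tips = tr$tip.label, events = events, compensated = compensated)
}

# evolve one RAA block: substitutions plus an indel process; on terminal
# branches of GC-enriched lineages the substitution process is pushed
# toward G/C and the deletion probability scaled down, planting a positive
# GC-length coupling. Returns named character vector of ungapped tip
# sequences.
evolve_raa_block <- function(tree, base_length, indel_rate, indel_geom,
                             freqs, gc_rich = numeric(0)) {
  tr <- stats::reorder(tree, "cladewise")
  n <- length(tr$tip.label)
  bases <- c("A", "C", "G", "T")
  model <- gtr_model(freqs = freqs)
  gc_freqs <- c(A = 0.05, C = 0.45, G = 0.45, T = 0.05)
  seqs <- vector("list", n + tr$Nnode)
  seqs[[n + 1]] <- sample(bases, base_length, replace = TRUE, prob = freqs)
  for (e in seq_len(nrow(tr$edge))) {
    b <- tr$edge.length[e]
    s <- seqs[[tr$edge[e, 1]]]
    child <- tr$edge[e, 2]
    gc_w <- if (child <= n) {
      lab <- tr$tip.label[child]
      if (lab %in% names(gc_rich)) gc_rich[[lab]] else 0
    } else {
      0
    }
    emodel <- if (gc_w > 0) {
      gtr_model(freqs = (1 - gc_w) * freqs + gc_w * gc_freqs)
    } else {
      model
    }
    p_del <- 0.5 * (1 - gc_w)
    if (length(s) > 0) {
      # substitutions
      P <- gtr_pmatrix(emodel, b)
      u <- stats::runif(length(s))
      cp <- t(apply(P[match(s, bases), , drop = FALSE], 1, cumsum))
      s <- bases[max.col(u < cp, ties.method = "first")]
      # indels
      nindel <- stats::rpois(1, indel_rate * b * length(s))
      for (k in seq_len(nindel)) {
        len <- stats::rgeom(1, indel_geom) + 1
        if (stats::runif(1) < p_del && length(s) > len) {
          pos <- sample.int(length(s) - len + 1, 1)
          s <- s[-(pos:(pos + len - 1))]
        } else {
          pos <- sample.int(length(s) + 1, 1)
          ins <- sample(bases, len, replace = TRUE,
                        prob = emodel$freqs)
          s <- append(s, ins, after = pos - 1)
        }
      }
    }
    seqs[[child]] <- s
  }
  stats::setNames(vapply(seqs[seq_len(n)], paste, character(1),
                         collapse = ""), tr$tip.label)
}

#' Simulate a structure-annotated alignment with known ground truth
#'
#' Stems evolve as paired doublets whose partner co-substitutes with
#' probability `q` (compensatory substitutions); loops evolve i.i.d. under
#' an A-rich GTR+Gamma; RAA blocks evolve with substitutions plus an indel
#' process that produces among-taxon length variation and are laid out
#' left-justified (gap-padded) inside their spans. The layout is
#' stem-left / interleaved loops and RAAs / stem-right, so stem partners
#' nest like a helix in the dot-bracket mask.
#'
#' @param tree An `ape::phylo` (e.g. from [simulate_tree()]).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A [structured_alignment()] with attribute `truth`: a list with
#'   the config, tree, compensation tally (`stem_events`,
#'   `stem_compensated`), per-block true ungapped lengths, and the class
#'   layout.
#' @export
simulate_structured_alignment <- function(tree, config = sim_config(),
                                          seed = 1) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  tree <- apply_rate_multipliers(tree, config$rate_multipliers)
  with_seed(seed, {
    taxa <- tree$tip.label
    stems <- evolve_stem_pairs(tree, config$stem_pairs, config$q)
    loop_model <- gtr_model(freqs = config$loop_freqs,
                            gamma_shape = config$gamma_shape)
    loops <- evolve_sequences(tree, loop_model, config$loop_length)
    raa_seqs <- lapply(seq_len(config$n_raa), function(k) {
      evolve_raa_block(tree, config$raa_base_length, config$indel_rate,
                       config$indel_geom, config$loop_freqs,
                       gc_rich = config$gc_rich_lineages)
    })
    # order rows by the master taxon list
    left <- stems$left[match(taxa, stems$tips), , drop = FALSE]
    right <- stems$right[match(taxa, stems$tips), , drop = FALSE]
    loops <- loops[match(taxa, rownames(loops)), , drop = FALSE]

    # layout: [stem-left] [loop+RAA interleave] [stem-right reversed]
    nseg <- config$n_raa + 1
    seg_len <- diff(round(seq(0, config$loop_length, length.out = nseg + 1)))
    pieces <- list()
    mask_pieces <- character(0)
    raa_rows <- list()
    col_cursor <- config$stem_pairs
    pieces[[1]] <- left
    mask_pieces <- strrep("(", config$stem_pairs)
    loop_cursor <- 0
    for (k in seq_len(nseg)) {
      if (seg_len[k] > 0) {
        idx <- (loop_cursor + 1):(loop_cursor + seg_len[k])
        pieces[[length(pieces) + 1]] <- loops[, idx, drop = FALSE]
        mask_pieces <- c(mask_pieces, strrep(".", seg_len[k]))
        col_cursor <- col_cursor + seg_len[k]
        loop_cursor <- loop_cursor + seg_len[k]
      }
      if (k <= config$n_raa) {
        ungapped <- raa_seqs[[k]][taxa]
        width <- max(nchar(ungapped))
        block <- matrix("-", length(taxa), width,
                        dimnames = list(taxa, NULL))
        for (i in seq_along(taxa)) {
          s <- strsplit(ungapped[[i]], "")[[1]]
          if (length(s) > 0) block[i, seq_along(s)] <- s
        }
        pieces[[length(pieces) + 1]] <- block
        mask_pieces <- c(mask_pieces, strrep(".", width))
        raa_rows[[k]] <- data.frame(block = paste0("RAA", k),
                                    start = col_cursor,  # 0-based
                                    end = col_cursor + width)
        col_cursor <- col_cursor + width
      }
    }
    pieces[[length(pieces) + 1]] <- right[, rev(seq_len(config$stem_pairs)),
                                          drop = FALSE]
    mask_pieces <- c(mask_pieces, strrep(")", config$stem_pairs))
    m <- do.call(cbind, pieces)
    rownames(m) <- taxa
    mask <- paste(mask_pieces, collapse = "")
    raa <- if (length(raa_rows)) do.call(rbind, raa_rows) else NULL
    aln <- structured_alignment(m, mask, raa = raa)
    attr(aln, "truth") <- list(
      config = config, tree = tree, seed = seed,
      stem_events = stems$events, stem_compensated = stems$compensated,
      raa_lengths = lapply(raa_seqs, function(s) nchar(s[taxa])))
    aln
  })
}

# build a rooted-at-first-taxon tree from a set of pairwise-compatible
# canonical splits (sides not containing the alphabetically first taxon)
tree_from_splits <- function(taxa, keys) {
  taxa <- sort(taxa)
  clades <- lapply(keys, function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  sizes <- lengths(clades)
  clades <- clades[order(-sizes)]
  build <- function(set, avail) {
    # maximal clades strictly inside `set`
    inside <- avail[vapply(avail, function(cl) {
      length(cl) < length(set) && all(cl %in% set)
    }, logical(1))]
    children <- list()
    covered <- character(0)
    for (cl in inside) {
      if (length(intersect(cl, covered)) > 0) next  # nested below a child
      children[[length(children) + 1]] <- cl
      covered <- c(covered, cl)
    }
    singles <- setdiff(set, covered)
    parts <- c(lapply(children, function(cl) build(cl, inside)),
               as.list(singles))
    if (length(parts) == 1) parts[[1]]
    else paste0("(", paste(unlist(parts), collapse = ","), ")")
  }
  rest <- setdiff(taxa, taxa[1])
  nwk <- paste0("(", taxa[1], ",", build(rest, clades), ");")
  tree <- ape::read.tree(text = nwk)
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

#' Simulate a bootstrap tree set with controlled bipartition conflict
#'
#' Emits `n_trees` topologies in which each chosen internode of the true
#' tree appears with frequency about `f1` and a specified conflicting
#' resolution with about `f2` (independent multinomial draws per edge;
#' remaining mass goes to the second nearest-neighbor alternative).
#' Supports testing internode-certainty estimators against planted
#' frequencies.
#'
#' @param true_tree `phylo` with >= 4 tips.
#' @param conflicts List of specs: each a list with `clade` (tips on one
#'   side of the internode), `f1` (frequency of the true resolution), `f2`
#'   (frequency of the swap of the clade's last tip with its sibling
#'   group). `f1 + f2 <= 1`.
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @return `multiPhylo` of `n_trees` topologies.
#' @export
simulate_bootstrap_tree_set <- function(true_tree, conflicts, n_trees,
                                        seed = 1) {
  stopifnot(inherits(true_tree, "phylo"), n_trees >= 1)
  taxa <- sort(true_tree$tip.label)
  base_keys <- tree_split_keys(true_tree, taxa)
  specs <- lapply(conflicts, function(cf) {
    stopifnot(!is.null(cf$clade), cf$f1 >= 0, cf$f2 >= 0,
              cf$f1 + cf$f2 <= 1)
    key <- split_key(cf$clade, taxa)
    if (!key %in% base_keys) stop("conflict clade is not an internode of ",
                                  "the true tree: ", key)
    side <- strsplit(key, "|", fixed = TRUE)[[1]]
    # two NNI alternatives: exchange one member of the clade with one
    # outside taxon (deterministically the alphabetically first of each)
    outside <- setdiff(taxa, c(side, taxa[1]))
    alt1 <- sort(c(setdiff(side, side[1]), outside[1]))
    alt2 <- sort(c(setdiff(side, side[length(side)]), outside[1]))
    # ensure alternatives are valid nontrivial splits incompatible with key
    list(key = key, alt1 = split_key(alt1, taxa),
         alt2 = split_key(alt2, taxa), f1 = cf$f1, f2 = cf$f2)
  })
  other_keys <- setdiff(base_keys, vapply(specs, `[[`, character(1),
                                          "key"))
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      chosen <- vapply(specs, function(sp) {
        u <- stats::runif(1)
        if (u < sp$f1) sp$key
        else if (u < sp$f1 + sp$f2) sp$alt1
        else sp$alt2
      }, character(1))
      # keep the unconflicted backbone splits that remain compatible with
      # every chosen resolution (an alternative resolution may collapse
      # incompatible neighboring internodes)
      keep <- vapply(other_keys, function(k) {
        all(vapply(chosen, function(r) splits_compatible(k, r, taxa),
                   logical(1)))
      }, logical(1))
      tree_from_splits(taxa, c(other_keys[keep], chosen))
    })
  })
  class(trees) <- "multiPhylo"
  trees
}

#' Simulate a posterior tree sample with per-lineage rate multipliers
#'
#' Fixed topology; branch lengths are the true lengths times the lineage
#' multiplier (terminal branches of named tips) times i.i.d. lognormal
#' jitter with log-sd `jitter_sd` (mean-one parameterization).
#'
#' @param tree True `phylo` with branch lengths.
#' @param multipliers Named positive multipliers for terminal branches.
#' @param jitter_sd Log-scale jitter standard deviation (0 = none).
#' @param n Number of sampled trees.
#' @param seed Integer seed.
#' @return `multiPhylo` of `n` trees.
#' @export
simulate_posterior_sample <- function(tree, multipliers = numeric(0),
                                      jitter_sd = 0.1, n = 100, seed = 1) {
  stopifnot(inherits(tree, "phylo"), all(multipliers > 0), n >= 1,
            jitter_sd >= 0)
  base <- apply_rate_multipliers(tree, multipliers)
  trees <- with_seed(seed, lapply(seq_len(n), function(i) {
    t2 <- base
    jit <- stats::rlnorm(nrow(t2$edge), meanlog = -jitter_sd^2 / 2,
                         sdlog = jitter_sd)
    t2$edge.length <- t2$edge.length * jit
    t2
  }))
  class(trees) <- "multiPhylo"
  trees
}

#' Simulate an MCMC log-likelihood trace
#'
#' @param mean,sd Normal moments of the sampled lnL values.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return A [trace_series()] with no burn-in.
#' @export
simulate_trace <- function(mean, sd, n, seed = 1) {
  stopifnot(sd >= 0, n >= 1)
  trace_series(with_seed(seed, stats::rnorm(n, mean, sd)), burnin = 0)
}
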