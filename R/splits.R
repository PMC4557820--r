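# Split systems from tree sets, consensus-network export, and
# internode-certainty indices (IC, ICA, TC, TCA).

# canonical key of a bipartition: the sorted side not containing the first
# taxon (taxa sorted alphabetically)
split_key <- function(side, taxa) {
  first <- sort(taxa)[1]
  if (first %in% side) side <- setdiff(taxa, side)
  paste(sort(side), collapse = "|")
}

# all nontrivial bipartitions of one tree, as canonical keys
tree_split_keys <- function(tree, taxa) {
  n <- length(tree$tip.label)
  if (n < 4) return(character(0))
  pp <- ape::prop.part(ape::unroot(tree))
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) {
    if (length(idx) < 2 || length(idx) > n - 2) return(NA_character_)
    split_key(labs[idx], taxa)
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Bipartition frequencies of a tree set
#'
#' Collects every nontrivial bipartition observed across the trees with its
#' frequency (occurrences / number of trees). Bipartitions are canonicalized
#' as the side not containing the alphabetically first taxon. Trees are
#' deduplicated by topology string first, so large bootstrap or posterior
#' sets with few distinct topologies are processed quickly.
#'
#' @param trees An `ape::multiPhylo` (or list of `phylo`) sharing one leaf
#'   set.
#' @return Object of class `split_system`: `taxa` (sorted), `keys`
#'   (canonical split keys), `freq` (named frequencies in (0, 1]),
#'   `n_trees`.
#' @export
split_frequencies <- function(trees) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  stopifnot(length(trees) >= 1)
  taxa <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!setequal(t$tip.label, taxa)) {
      stop("leaf-set mismatch; symmetric difference: ",
           paste(c(setdiff(t$tip.label, taxa), setdiff(taxa, t$tip.label)),
                 collapse = ", "))
    }
  }
  topo <- vapply(trees, function(t) {
    t$edge.length <- NULL
    t$node.label <- NULL
    ape::write.tree(ape::rotateConstr(t, taxa))
  }, character(1))
  tab <- table(topo)
  counts <- new.env()
  for (k in seq_along(tab)) {
    tr <- trees[[match(names(tab)[k], topo)]]
    for (key in tree_split_keys(tr, taxa)) {
      counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) +
        as.numeric(tab[k])
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]], numeric(1)) / length(trees)
  o <- order(-freq, keys)
  structure(list(taxa = taxa, keys = keys[o],
                 freq = stats::setNames(freq[o], keys[o]),
                 n_trees = length(trees)),
            class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  cat("split_system:", length(x$keys), "nontrivial splits over",
      length(x$taxa), "taxa from", x$n_trees, "trees\n")
  invisible(x)
}

#' Filter a split system by frequency
#'
#' Retains splits with frequency at or above the threshold — the filter
#' applied before drawing a consensus network (conventionally 0.1 for
#' bootstrap tree sets).
#'
#' @param system A `split_system`.
#' @param threshold Frequency threshold in `[0, 1]`.
#' @return The filtered `split_system`.
#' @export
filter_splits <- function(system, threshold = 0.1) {
  stopifnot(inherits(system, "split_system"),
            threshold >= 0, threshold <= 1)
  keep <- system$freq >= threshold
  system$keys <- system$keys[keep]
  system$freq <- system$freq[keep]
  system
}

#' Export a split system as a NEXUS SPLITS block
#'
#' Writes a TAXA block and a weighted SPLITS block (weights = frequencies)
#' readable by splits-graph viewers; [read_splits_nexus()] is the exact
#' inverse.
#'
#' @param system A `split_system`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_splits_nexus <- function(system, path) {
  stopifnot(inherits(system, "split_system"))
  taxa <- system$taxa
  idx_of <- stats::setNames(seq_along(taxa), taxa)
  lines <- c("#NEXUS", "",
             "BEGIN TAXA;",
             sprintf("  DIMENSIONS NTAX=%d;", length(taxa)),
             "  TAXLABELS",
             sprintf("    %s", taxa),
             "  ;", "END;", "",
             "BEGIN SPLITS;",
             sprintf("  DIMENSIONS NTAX=%d NSPLITS=%d;", length(taxa),
                     length(system$keys)),
             "  FORMAT LABELS=NO WEIGHTS=YES;",
             "  MATRIX")
  for (k in seq_along(system$keys)) {
    side <- strsplit(system$keys[k], "|", fixed = TRUE)[[1]]
    lines <- c(lines, sprintf("    [%d] %.10g %s,", k, system$freq[k],
                              paste(idx_of[side], collapse = " ")))
  }
  lines <- c(lines, "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Read a NEXUS SPLITS block written by [export_splits_nexus()]
#'
#' @param path NEXUS file.
#' @return A `split_system` (with `n_trees = NA`).
#' @export
read_splits_nexus <- function(path) {
  lines <- readLines(path)
  tx_start <- grep("TAXLABELS", lines)
  tx_end <- which(trimws(lines) == ";")
  tx_end <- min(tx_end[tx_end > tx_start])
  taxa <- trimws(lines[(tx_start + 1):(tx_end - 1)])
  mat_start <- grep("MATRIX", lines)
  mat_end <- which(trimws(lines) == ";")
  mat_end <- min(mat_end[mat_end > mat_start])
  keys <- character(0)
  freq <- numeric(0)
  body <- if (mat_end - mat_start >= 2) {
    lines[(mat_start + 1):(mat_end - 1)]
  } else {
    character(0)
  }
  for (ln in body) {
    ln <- sub("\\[\\d+\\]", "", trimws(ln))
    ln <- sub(",$", "", trimws(ln))
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    keys <- c(keys, split_key(taxa[as.integer(parts[-1])], taxa))
    freq <- c(freq, as.numeric(parts[1]))
  }
  structure(list(taxa = sort(taxa), keys = keys,
                 freq = stats::setNames(freq, keys), n_trees = NA_integer_),
            class = "split_system")
}

# two splits are compatible iff one of the four side-intersections is empty
splits_compatible <- function(keyA, keyB, taxa) {
  a <- strsplit(keyA, "|", fixed = TRUE)[[1]]
  b <- strsplit(keyB, "|", fixed = TRUE)[[1]]
  ac <- setdiff(taxa, a)
  bc <- setdiff(taxa, b)
  length(intersect(a, b)) == 0 || length(intersect(a, bc)) == 0 ||
    length(intersect(ac, b)) == 0 || length(intersect(ac, bc)) == 0
}

# IC of one internode from its frequency f1 and the most frequent
# incompatible split's frequency f2; negative when f2 outnumbers f1
ic_score <- function(f1, f2) {
  if (f2 == 0) return(1)
  p <- c(f1, f2) / (f1 + f2)
  p <- p[p > 0]
  val <- 1 + sum(p * log2(p))
  if (f2 > f1) -val else val
}

# ICA over the internode's split plus all incompatible splits above the
# threshold; log base = number of splits considered
ica_score <- function(f1, conflicts, threshold) {
  confl <- conflicts[conflicts >= threshold]
  fs <- c(f1, confl)
  k <- length(fs)
  if (k <= 1 || sum(fs) == 0) return(1)
  p <- fs / sum(fs)
  p <- p[p > 0]
  val <- 1 + sum(p * log(p, base = k))
  if (length(confl) > 0 && max(confl) > f1) -val else val
}

#' Internode certainty of a reference topology against a tree set
#'
#' For every internal edge of the reference tree, computes the internode
#' certainty IC (reference bipartition against its most frequent
#' incompatible bipartition) and ICA (against all incompatible bipartitions
#' above `ica_threshold`), plus the whole-tree sums TC and TCA and their
#' relative versions (divided by n - 3). IC is 1 + sum p_i log2 p_i over
#' the normalized pair (f1, f2) and is negative when the conflicting split
#' outnumbers the reference edge's split; ICA uses log base k over the k
#' splits considered.
#'
#' @param ref Reference `phylo` topology.
#' @param trees Tree set (`multiPhylo`) with the same leaf set.
#' @param ica_threshold Conflicting splits below this frequency are ignored
#'   in ICA (default 0.05).
#' @return Object of class `certainty_tree`: `ref`, `edges` (data.frame
#'   with `key`, `freq`, `max_conflict`, `ic`, `ica`), `tc`, `tca`,
#'   `relative_tc`, `relative_tca`.
#' @export
internode_certainty <- function(ref, trees, ica_threshold = 0.05) {
  stopifnot(inherits(ref, "phylo"))
  sys <- split_frequencies(trees)
  if (!setequal(ref$tip.label, sys$taxa)) {
    stop("reference leaf set differs from the tree set's")
  }
  ref_keys <- tree_split_keys(ref, sys$taxa)
  edges <- do.call(rbind, lapply(ref_keys, function(k) {
    f1 <- if (k %in% sys$keys) sys$freq[[k]] else 0
    incompat <- vapply(sys$keys, function(ok) {
      ok != k && !splits_compatible(k, ok, sys$taxa)
    }, logical(1))
    conflicts <- sys$freq[incompat]
    if (f1 == 0 && length(conflicts) == 0) {
      warning("reference edge ", k,
              " never observed and unopposed; certainty set to 1")
      return(data.frame(key = k, freq = 0, max_conflict = 0, ic = 1,
                        ica = 1))
    }
    f2 <- if (length(conflicts) > 0) max(conflicts) else 0
    data.frame(key = k, freq = f1, max_conflict = f2,
               ic = ic_score(f1, f2),
               ica = ica_score(f1, conflicts, ica_threshold))
  }))
  n <- length(sys$taxa)
  tc <- if (is.null(edges)) 0 else sum(edges$ic)
  tca <- if (is.null(edges)) 0 else sum(edges$ica)
  structure(list(ref = ref, edges = edges, tc = tc, tca = tca,
                 relative_tc = tc / (n - 3), relative_tca = tca / (n - 3),
                 ica_threshold = ica_threshold),
            class = "certainty_tree")
}

#' @export
print.certainty_tree <- function(x, ...) {
  ne <- if (is.null(x$edges)) 0 else nrow(x$edges)
  cat(sprintf("certainty_tree: %d internal edges; TC = %.3f (rel %.3f), TCA = %.3f (rel %.3f)\n",
              ne, x$tc, x$relative_tc, x$tca, x$relative_tca))
  invisible(x)
}

#' Write a reference tree annotated with IC/ICA edge labels
#'
#' Internal nodes are labeled `IC/ICA` (6 decimals) on the subtending edge
#' via node labels; re-parsing with [read_annotated_tree()] recovers the
#' values.
#'
#' @param scores A `certainty_tree` from [internode_certainty()].
#' @param path Output Newick path.
#' @return `path`, invisibly.
#' @export
annotate_tree <- function(scores, path) {
  stopifnot(inherits(scores, "certainty_tree"))
  tree <- ape::unroot(scores$ref)
  taxa <- sort(tree$tip.label)
  labs <- rep("", tree$Nnode)
  if (!is.null(scores$edges)) {
    pp <- ape::prop.part(tree)
    pl <- attr(pp, "labels")
    for (nd in seq_len(tree$Nnode)) {
      idx <- pp[[nd]]
      if (length(idx) < 2 || length(idx) > length(taxa) - 2) next
      k <- split_key(pl[idx], taxa)
      row <- match(k, scores$edges$key)
      if (!is.na(row)) {
        labs[nd] <- sprintf("%.6f/%.6f", scores$edges$ic[row],
                            scores$edges$ica[row])
      }
    }
  }
  tree$node.label <- labs
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a tree annotated by [annotate_tree()]
#'
#' @param path Newick path.
#' @return List with `tree` (`phylo`) and `edges` (data.frame `key`, `ic`,
#'   `ica`).
#' @export
read_annotated_tree <- function(path) {
  tree <- ape::read.tree(path)
  taxa <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  pl <- attr(pp, "labels")
  rows <- list()
  for (nd in seq_len(tree$Nnode)) {
    lab <- tree$node.label[nd]
    if (is.null(lab) || is.na(lab) || lab == "") next
    idx <- pp[[nd]]
    if (length(idx) < 2 || length(idx) > length(taxa) - 2) next
    vals <- as.numeric(strsplit(lab, "/", fixed = TRUE)[[1]])
    rows[[length(rows) + 1]] <- data.frame(key = split_key(pl[idx], taxa),
                                           ic = vals[1], ica = vals[2])
  }
  list(tree = tree,
       edges = if (length(rows)) do.call(rbind, rows)
               else data.frame(key = character(0), ic = numeric(0),
                               ica = numeric(0)))
}
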