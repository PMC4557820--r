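# Per-taxon nucleotide composition, tetrahedral simplex coordinates,
# GC-length correlation and the chi-squared stationarity test.

#' Per-taxon base composition of an alignment
#'
#' Counts A, C, G, T per taxon over ungapped positions; IUPAC ambiguity codes
#' are excluded from the counts but included in the ungapped length.
#'
#' @param aln Character matrix (taxa x columns) or the `seqs` element of a
#'   [structured_alignment()], or the list returned by [extract_partition()].
#' @param partition Optional partition label stored in the result.
#' @return A data.frame of class `composition_profile` with columns `taxon`,
#'   `partition`, `A`, `C`, `G`, `T`, `length` (ungapped nt), `gc`.
#'   All-gap rows get length 0, `gc` `NA`, and a warning.
#' @export
base_composition <- function(aln, partition = NA_character_) {
  if (is.list(aln) && !is.data.frame(aln) && !is.null(aln$seqs)) {
    aln <- aln$seqs
  }
  stopifnot(is.matrix(aln), nrow(aln) > 0, ncol(aln) > 0)
  res <- do.call(rbind, lapply(rownames(aln), function(tx) {
    col <- aln[tx, ]
    ungapped <- col[!is_gap_char(col)]
    cnt <- vapply(c("A", "C", "G", "T"), function(b) sum(ungapped == b),
                  numeric(1))
    tot <- sum(cnt)
    data.frame(taxon = tx, partition = partition,
               A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]],
               T = cnt[["T"]], length = length(ungapped),
               gc = if (tot > 0) (cnt[["C"]] + cnt[["G"]]) / tot else NA_real_)
  }))
  if (any(res$length == 0)) {
    warning("all-gap row(s): ", paste(res$taxon[res$length == 0],
                                      collapse = ", "))
  }
  rownames(res) <- NULL
  class(res) <- c("composition_profile", "data.frame")
  res
}

# vertices of a regular tetrahedron centered at the origin, one per base
tetra_vertices <- local({
  v <- rbind(A = c(1, 1, 1), C = c(1, -1, -1),
             G = c(-1, 1, -1), T = c(-1, -1, 1)) / sqrt(3)
  v
})

#' Tetrahedral simplex coordinates of base frequencies
#'
#' Affine embedding of the 4-base frequency simplex into 3-space, sending
#' the pure compositions A, C, G, T to the vertices of a regular tetrahedron
#' centered at the origin (so the uniform composition maps to the origin).
#' Used to draw the tetrahedric composition plot.
#'
#' @param freqs Numeric vector of 4 non-negative frequencies summing to 1
#'   (order A, C, G, T), or a matrix with one such row per observation.
#' @return A length-3 coordinate vector, or a matrix of such rows.
#' @export
tetrahedral_coords <- function(freqs) {
  f <- if (is.matrix(freqs)) freqs else matrix(freqs, nrow = 1)
  if (ncol(f) != 4) stop("expected 4 base frequencies (A, C, G, T)")
  if (any(f < 0)) stop("negative frequency")
  if (any(abs(rowSums(f) - 1) > 1e-9)) {
    stop("frequencies must sum to 1 (tolerance 1e-9)")
  }
  out <- f %*% tetra_vertices
  colnames(out) <- c("x", "y", "z")
  if (is.matrix(freqs)) out else drop(out)
}

#' Spearman correlation between GC content and sequence length
#'
#' Rank correlation of per-taxon GC fraction against ungapped sequence
#' length (ties mid-ranked; two-sided p from the t approximation).
#'
#' @param profiles A `composition_profile` from [base_composition()].
#' @return List with `rho`, `p`, `n`. Constant input yields `rho = NA` with
#'   a warning.
#' @export
gc_length_correlation <- function(profiles) {
  df <- profiles[profiles$length > 0 & !is.na(profiles$gc), , drop = FALSE]
  if (nrow(df) < 3) stop("need at least 3 taxa with positive length")
  if (length(unique(df$gc)) == 1 || length(unique(df$length)) == 1) {
    warning("constant GC or length vector: rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = nrow(df)))
  }
  ct <- suppressWarnings(stats::cor.test(df$gc, df$length,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(df))
}

#' Chi-squared stationarity test of base composition
#'
#' Tests, for every taxon, whether its base composition matches the average
#' (pooled) composition of the whole alignment: chi2 = sum over bases of
#' (o - e)^2 / e with e = taxon ungapped length times the pooled base
#' frequency, df = 3. Taxa with p below `alpha` are flagged as deviating.
#'
#' @param profiles A `composition_profile` from [base_composition()].
#' @param alpha Flagging level (default 0.05).
#' @param leave_one_out If `TRUE`, the expected frequencies for each taxon
#'   are pooled over the other taxa only.
#' @param pseudocount Added to every pooled base count before forming
#'   expected frequencies; required (e.g. 0.5) when a base is absent from
#'   the pool but present in some taxon.
#' @return A data.frame of class `stationarity_result` with per-taxon
#'   `chi2`, `p`, `deviates`; attribute `n_deviating`.
#' @export
stationarity_chisq <- function(profiles, alpha = 0.05,
                               leave_one_out = FALSE, pseudocount = 0) {
  df <- profiles[profiles$length > 0, , drop = FALSE]
  if (nrow(df) < 2) stop("need at least 2 taxa")
  bases <- c("A", "C", "G", "T")
  counts <- as.matrix(df[, bases])
  rownames(counts) <- df$taxon
  totals <- rowSums(counts)
  pool_all <- colSums(counts)
  res <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    pool <- if (leave_one_out) pool_all - counts[i, ] else pool_all
    pool <- pool + pseudocount
    pf <- pool / sum(pool)
    if (any(pf == 0 & counts[i, ] > 0)) {
      stop("pooled frequency zero for a base present in taxon ",
           rownames(counts)[i], "; consider pseudocount = 0.5")
    }
    e <- totals[i] * pf
    use <- e > 0
    chi2 <- sum((counts[i, use] - e[use])^2 / e[use])
    data.frame(taxon = rownames(counts)[i], chi2 = chi2,
               p = stats::pchisq(chi2, df = 3, lower.tail = FALSE))
  }))
  res$deviates <- res$p < alpha
  rownames(res) <- NULL
  attr(res, "n_deviating") <- sum(res$deviates)
  class(res) <- c("stationarity_result", "data.frame")
  res
}
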