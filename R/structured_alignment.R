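# Secondary-structure-annotated alignments: construction, classification,
# partition extraction, site-pattern counting and partition file output.

#' Construct a structure-annotated alignment
#'
#' Couples an aligned set of rDNA sequences with a dot-bracket secondary
#' structure mask and (optionally) a set of regions of ambiguous alignment
#' (RAAs). Each column is assigned exactly one class: `STEM` (a bracket in the
#' mask), `LOOP` (a dot), or `RAA` (covered by an annotated RAA span, which
#' overrides the mask class). Brackets are paired by nesting order; unmatched
#' brackets are recorded as orphans (a real situation: a helix partner may
#' simply not have been sequenced) and classified as stem columns without a
#' pairing partner.
#'
#' @param seqs Named character vector of aligned sequences (one string per
#'   taxon) or a character matrix with taxa as rownames. IUPAC nucleotide
#'   codes and `-` gaps are allowed; `U` is folded to `T`.
#' @param mask Single string over `(`, `)`, `.` of the same length as the
#'   rows. Lowercase letters are accepted as an alternative in-mask RAA
#'   convention: any lowercase run is converted to a RAA span and the mask
#'   character is replaced by `.`.
#' @param raa Optional RAA annotation: a data.frame with columns `block`,
#'   `start`, `end` (0-based half-open, BED-like) as read by
#'   [read_raa_annotation()], or `NULL`.
#' @return An object of class `structured_alignment`: a list with elements
#'   `seqs` (character matrix), `mask`, `classes` (per-column class),
#'   `pairing` (integer partner column or `NA`), `orphans` (columns marked
#'   paired but lacking a partner), and `raa` (data.frame of 1-based
#'   inclusive spans with block ids).
#' @examples
#' aln <- structured_alignment(c(t1 = "ACGUACGU", t2 = "ACGUACGU"),
#'                             "((....))")
#' aln$pairing[1:2]  # partners of the first two stem columns
#' @export
structured_alignment <- function(seqs, mask, raa = NULL) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    m <- strings_to_matrix(seqs)
  }
  if (is.null(rownames(m)) || anyNA(rownames(m)) || any(rownames(m) == "")) {
    stop("all sequences must be named by taxon")
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate taxon label: ",
         rownames(m)[duplicated(rownames(m))][1])
  }
  m[] <- normalize_residues(m)
  bad <- setdiff(unique(as.vector(m)), c(names(iupac_sets), "-"))
  if (length(bad) > 0) {
    stop("non-IUPAC characters in alignment: ", paste(bad, collapse = " "))
  }
  L <- ncol(m)
  if (nchar(mask) != L) {
    stop("mask length ", nchar(mask), " does not match alignment length ", L)
  }
  mk <- strsplit(mask, "")[[1]]

  # lowercase-in-mask RAA convention, auto-detected
  lower_cols <- which(mk %in% letters)
  if (length(lower_cols) > 0) {
    if (!is.null(raa)) {
      stop("RAA given both as sidecar annotation and as lowercase mask runs")
    }
    rng <- index_ranges(lower_cols)
    parts <- do.call(rbind, strsplit(rng, "-"))
    raa <- data.frame(block = paste0("RAA", seq_len(nrow(parts))),
                      start = as.integer(parts[, 1]) - 1L,
                      end = as.integer(parts[, 2]))
    mk[lower_cols] <- "."
  }
  bad_mask <- setdiff(unique(mk), c("(", ")", "."))
  if (length(bad_mask) > 0) {
    stop("mask characters outside '()<dot>': ", paste(bad_mask, collapse = " "))
  }

  pm <- match_brackets(mk)

  classes <- ifelse(mk == ".", "LOOP", "STEM")
  raa1 <- data.frame(block = character(0), start = integer(0),
                     end = integer(0))
  if (!is.null(raa) && nrow(raa) > 0) {
    stopifnot(all(c("block", "start", "end") %in% names(raa)))
    if (anyDuplicated(raa$block)) stop("duplicate RAA block id")
    raa <- raa[order(raa$start), , drop = FALSE]
    if (any(raa$start < 0) || any(raa$end > L) || any(raa$end <= raa$start)) {
      stop("RAA spans out of bounds or empty")
    }
    if (any(raa$start[-1] < raa$end[-nrow(raa)])) {
      stop("RAA spans overlap")
    }
    # convert 0-based half-open to 1-based inclusive for internal use
    raa1 <- data.frame(block = as.character(raa$block),
                       start = as.integer(raa$start) + 1L,
                       end = as.integer(raa$end))
    for (k in seq_len(nrow(raa1))) {
      classes[raa1$start[k]:raa1$end[k]] <- "RAA"
    }
  }

  structure(list(seqs = m, mask = paste(mk, collapse = ""),
                 classes = classes, pairing = pm$pairing,
                 orphans = pm$orphans, raa = raa1),
            class = "structured_alignment")
}

# Stack-based bracket matcher. Returns 1-based partner indices (NA when
# unpaired) and the orphan columns: brackets left unmatched because the
# partner region is absent (e.g. not sequenced).
match_brackets <- function(mk) {
  L <- length(mk)
  pairing <- rep(NA_integer_, L)
  stack <- integer(0)
  orphans <- integer(0)
  for (i in seq_len(L)) {
    if (mk[i] == "(") {
      stack <- c(stack, i)
    } else if (mk[i] == ")") {
      if (length(stack) == 0) {
        orphans <- c(orphans, i)
      } else {
        j <- stack[length(stack)]
        stack <- stack[-length(stack)]
        pairing[i] <- j
        pairing[j] <- i
      }
    }
  }
  if (length(stack) > 0) orphans <- sort(c(orphans, stack))
  if (length(orphans) > 0) {
    warning(length(orphans), " orphan paired column(s) without a partner ",
            "(columns ", paste(utils::head(orphans, 5), collapse = ", "),
            if (length(orphans) > 5) ", ..." else "", ")")
  }
  list(pairing = pairing, orphans = orphans)
}

#' @export
print.structured_alignment <- function(x, ...) {
  cat("structured_alignment:", nrow(x$seqs), "taxa x", ncol(x$seqs),
      "columns\n")
  tab <- table(factor(x$classes, levels = c("STEM", "LOOP", "RAA")))
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  cat("  paired columns:", sum(!is.na(x$pairing)) + length(x$orphans),
      if (length(x$orphans)) paste0("(", length(x$orphans), " orphan)") else "",
      "\n")
  if (nrow(x$raa) > 0) cat("  RAA blocks:", nrow(x$raa), "\n")
  invisible(x)
}

#' Read a structure-annotated FASTA alignment
#'
#' Reads an aligned FASTA file in which one record carries the dot-bracket
#' secondary structure mask: either a record whose id is `#structure` (any
#' position) or, failing that, a trailing record whose "sequence" consists of
#' mask characters only. RAA column spans come from a sidecar annotation file
#' (BED-like TSV, see [read_raa_annotation()]) or from lowercase runs inside
#' the mask itself.
#'
#' @param path FASTA file.
#' @param raa_annotation Optional path to the RAA sidecar TSV.
#' @return A [structured_alignment()].
#' @export
read_structured_fasta <- function(path, raa_annotation = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- Biostrings::readBStringSet(path)
  nm <- names(recs)
  seqs <- as.character(recs)
  is_mask <- nm == "#structure"
  if (!any(is_mask)) {
    chars <- strsplit(seqs[length(seqs)], "")[[1]]
    if (all(chars %in% c("(", ")", ".", letters))) {
      is_mask[length(seqs)] <- TRUE
    } else {
      stop("no structure mask record found (id '#structure' or trailing ",
           "dot-bracket record)")
    }
  }
  if (sum(is_mask) > 1) stop("multiple structure mask records")
  mask <- unname(seqs[is_mask])
  rows <- seqs[!is_mask]
  names(rows) <- nm[!is_mask]
  lens <- nchar(rows)
  if (any(lens != nchar(mask))) {
    stop("row/mask length mismatch for record(s): ",
         paste(names(rows)[lens != nchar(mask)], collapse = ", "))
  }
  raa <- if (!is.null(raa_annotation)) read_raa_annotation(raa_annotation)
  structured_alignment(rows, mask, raa = raa)
}

#' Read a RAA sidecar annotation
#'
#' Three-column TSV (`block`, `start`, `end`; header optional) giving the
#' regions of ambiguous alignment in 0-based half-open column coordinates.
#'
#' @param path TSV file.
#' @return data.frame with columns `block`, `start`, `end`.
#' @export
read_raa_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 3) stop("RAA annotation needs 3 columns (block, start, end)")
  if (!is.numeric(df[[2]]) || !is.numeric(df[[3]])) {
    # header line present
    hdr <- tolower(as.character(unlist(df[1, ])))
    if (!all(c("block", "start", "end") %in% hdr[1:3])) {
      stop("RAA annotation columns must be block, start, end")
    }
    df <- df[-1, , drop = FALSE]
  }
  data.frame(block = as.character(df[[1]]),
             start = as.integer(df[[2]]),
             end = as.integer(df[[3]]))
}

#' Write a RAA sidecar annotation
#'
#' @param aln A [structured_alignment()].
#' @param path Output TSV path (0-based half-open coordinates).
#' @return `path`, invisibly.
#' @export
write_raa_annotation <- function(aln, path) {
  stopifnot(inherits(aln, "structured_alignment"))
  df <- data.frame(block = aln$raa$block,
                   start = aln$raa$start - 1L,
                   end = aln$raa$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract one structural partition of the alignment
#'
#' @param aln A [structured_alignment()].
#' @param cls One of `"STEM"`, `"LOOP"`, `"RAA"`, `"STEM+LOOP"`.
#' @return List with `seqs` (character matrix of the partition's columns, in
#'   original order) and `provenance` (integer vector of master 1-based
#'   column coordinates). An empty partition yields a 0-column matrix.
#' @export
extract_partition <- function(aln, cls = c("STEM", "LOOP", "RAA",
                                           "STEM+LOOP")) {
  stopifnot(inherits(aln, "structured_alignment"))
  cls <- match.arg(cls)
  want <- if (cls == "STEM+LOOP") c("STEM", "LOOP") else cls
  idx <- which(aln$classes %in% want)
  list(seqs = aln$seqs[, idx, drop = FALSE], provenance = idx)
}

#' Count site patterns of an alignment
#'
#' Classifies every column as constant, variable-but-uninformative, or
#' parsimony informative (at least two states each present in at least two
#' taxa; gaps and ambiguity codes never count as states). Under the default
#' lenient convention gaps and ambiguity codes are ignored, so a column with
#' one real state plus gaps is constant; `strict_constant = TRUE` requires a
#' gap-free column.
#'
#' @param aln A [structured_alignment()] or a character matrix.
#' @param strict_constant Logical; see above.
#' @return Object of class `partition_counts`: `n_columns`, `n_constant`,
#'   `n_variable_uninformative`, `n_parsimony_informative`, `n_paired`,
#'   `n_unpaired` (pairing counts are 0/total for plain matrices).
#' @export
count_site_patterns <- function(aln, strict_constant = FALSE) {
  if (inherits(aln, "structured_alignment")) {
    m <- aln$seqs
    n_paired <- sum(!is.na(aln$pairing)) + length(aln$orphans)
  } else {
    m <- aln
    n_paired <- 0L
  }
  if (nrow(m) == 0) stop("alignment has zero taxa")
  L <- ncol(m)
  cls <- vapply(seq_len(L), function(j) {
    col <- m[, j]
    states <- col[is_base_char(col)]
    tab <- table(states)
    if (length(tab) >= 2 && sum(tab >= 2) >= 2) return("informative")
    has_gap_or_amb <- length(states) < length(col)
    if (length(tab) <= 1) {
      if (strict_constant && has_gap_or_amb) return("uninformative")
      return("constant")
    }
    "uninformative"
  }, character(1))
  structure(list(n_columns = L,
                 n_constant = sum(cls == "constant"),
                 n_variable_uninformative = sum(cls == "uninformative"),
                 n_parsimony_informative = sum(cls == "informative"),
                 n_paired = n_paired,
                 n_unpaired = L - n_paired),
            class = "partition_counts")
}

#' @export
print.partition_counts <- function(x, ...) {
  cat("site patterns:", x$n_columns, "columns;",
      x$n_constant, "constant,",
      x$n_variable_uninformative, "variable-uninformative,",
      x$n_parsimony_informative, "parsimony-informative;",
      x$n_paired, "paired /", x$n_unpaired, "unpaired\n")
  invisible(x)
}

#' Write partition files for downstream phylogenetic programs
#'
#' Writes, into `dir`: one relaxed PHYLIP file per non-empty partition
#' (`stem.phy`, `loop.phy`, `raa.phy`), a partition definition file
#' `partitions.txt` (`NAME = start-end, ...` in 1-based inclusive master
#' coordinates), and `structure.txt` whose first line is the mask verbatim;
#' when orphan paired columns exist a second line repeats the mask with
#' orphans downgraded to `.` (and a warning is raised).
#'
#' @param aln A [structured_alignment()].
#' @param dir Output directory (created if needed).
#' @return Character vector of paths written, invisibly.
#' @seealso [read_partition_files()] for the exact inverse.
#' @export
write_partition_files <- function(aln, dir) {
  stopifnot(inherits(aln, "structured_alignment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  defs <- character(0)
  for (cls in c("STEM", "LOOP", "RAA")) {
    part <- extract_partition(aln, cls)
    if (length(part$provenance) == 0) next
    p <- file.path(dir, paste0(tolower(cls), ".phy"))
    write_relaxed_phylip(part$seqs, p)
    paths <- c(paths, p)
    defs <- c(defs, paste0(cls, " = ",
                           paste(index_ranges(part$provenance),
                                 collapse = ", ")))
  }
  pdef <- file.path(dir, "partitions.txt")
  writeLines(defs, pdef)
  pstr <- file.path(dir, "structure.txt")
  lines <- aln$mask
  if (length(aln$orphans) > 0) {
    mk <- strsplit(aln$mask, "")[[1]]
    mk[aln$orphans] <- "."
    lines <- c(lines, paste(mk, collapse = ""))
    warning("orphan paired column(s) annotated as unpaired on line 2 of ",
            pstr)
  }
  writeLines(lines, pstr)
  invisible(c(paths, pdef, pstr))
}

#' Read back a partition file set
#'
#' Inverse of [write_partition_files()]: reassembles the master alignment
#' from the per-partition PHYLIP files, the partition definition and the
#' structure line. Sequences and mask round-trip bit-exactly.
#'
#' @param dir Directory written by [write_partition_files()].
#' @return A [structured_alignment()].
#' @export
read_partition_files <- function(dir) {
  defs <- readLines(file.path(dir, "partitions.txt"))
  mask <- readLines(file.path(dir, "structure.txt"))[1]
  L <- nchar(mask)
  m <- NULL
  raa <- NULL
  for (line in defs) {
    kv <- strsplit(line, "=")[[1]]
    cls <- trimws(kv[1])
    ranges <- strsplit(trimws(kv[2]), ",")[[1]]
    idx <- unlist(lapply(trimws(ranges), function(r) {
      ab <- as.integer(strsplit(r, "-")[[1]])
      ab[1]:ab[2]
    }))
    sub <- read_relaxed_phylip(file.path(dir, paste0(tolower(cls), ".phy")))
    if (is.null(m)) {
      m <- matrix("-", nrow(sub), L,
                  dimnames = list(rownames(sub), NULL))
    }
    m[rownames(sub), idx] <- sub
    if (cls == "RAA") {
      rng <- index_ranges(idx)
      parts <- do.call(rbind, strsplit(rng, "-"))
      raa <- data.frame(block = paste0("RAA", seq_len(nrow(parts))),
                        start = as.integer(parts[, 1]) - 1L,
                        end = as.integer(parts[, 2]))
    }
  }
  structured_alignment(m, mask, raa = raa)
}

# relaxed PHYLIP writer/reader (single block, name + whitespace + sequence)
write_relaxed_phylip <- function(m, path) {
  nm <- rownames(m)
  pad <- formatC(nm, width = max(nchar(nm)) + 2, flag = "-")
  lines <- c(paste(nrow(m), ncol(m)),
             paste0(pad, apply(m, 1, paste, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}

read_relaxed_phylip <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  rows <- lines[-1][nzchar(trimws(lines[-1]))]
  parts <- strsplit(trimws(rows), "\\s+")
  m <- strings_to_matrix(stats::setNames(
    vapply(parts, function(p) paste(p[-1], collapse = ""), character(1)),
    vapply(parts, `[`, character(1), 1)))
  stopifnot(nrow(m) == dims[1], ncol(m) == dims[2])
  m
}

#' Write a structure-annotated FASTA file
#'
#' @param aln A [structured_alignment()].
#' @param path Output path; the mask is written as a final `#structure`
#'   record.
#' @return `path`, invisibly.
#' @export
write_structured_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "structured_alignment"))
  rows <- matrix_to_strings(aln$seqs)
  out <- Biostrings::BStringSet(c(rows, "#structure" = aln$mask))
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}
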