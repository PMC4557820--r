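# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator, runs `expr`, and restores the caller's RNG state so
#' seeded simulators never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# IUPAC nucleotide ambiguity sets over A,C,G,T (U folded to T on input)
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_gap_char <- function(x) x == "-"

is_base_char <- function(x) x %in% c("A", "C", "G", "T")

is_ambiguity_char <- function(x) {
  x %in% setdiff(names(iupac_sets), c("A", "C", "G", "T"))
}

# normalize sequence characters: uppercase, U -> T
normalize_residues <- function(x) {
  x <- toupper(x)
  x[x == "U"] <- "T"
  x
}

# character matrix (taxa x columns) from named character vector of strings
strings_to_matrix <- function(strings) {
  stopifnot(length(strings) > 0)
  lens <- nchar(strings)
  if (length(unique(lens)) != 1L) {
    stop("aligned rows have unequal lengths: ",
         paste(names(strings)[lens != lens[1]], collapse = ", "))
  }
  m <- do.call(rbind, strsplit(unname(strings), ""))
  rownames(m) <- names(strings)
  m
}

matrix_to_strings <- function(m) {
  stats::setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}

# 1-based inclusive ranges ("3-7, 10-10") from a sorted column index vector
index_ranges <- function(idx) {
  if (length(idx) == 0) return(character(0))
  brk <- c(0, which(diff(idx) != 1), length(idx))
  vapply(seq_len(length(brk) - 1), function(k) {
    lo <- idx[brk[k] + 1]
    hi <- idx[brk[k + 1]]
    paste0(lo, "-", hi)
  }, character(1))
}
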