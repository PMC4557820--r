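# Independent oracles and fixture builders used across the suite.

# Brute-force affine alignment: enumerate every global alignment of two
# short sequences and score it by scanning gap runs. Independent of the
# package's Gotoh recurrences.
oracle_affine <- function(a, b, gap_open = 4, gap_extend = 1,
                          substitution = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  score_alignment <- function(ra, rb) {
    cost <- 0
    in_gap_a <- FALSE
    in_gap_b <- FALSE
    for (k in seq_along(ra)) {
      if (ra[k] == "-") {
        cost <- cost + if (in_gap_a) gap_extend else gap_open
        in_gap_a <- TRUE
        in_gap_b <- FALSE
      } else if (rb[k] == "-") {
        cost <- cost + if (in_gap_b) gap_extend else gap_open
        in_gap_b <- TRUE
        in_gap_a <- FALSE
      } else {
        cost <- cost + if (ra[k] == rb[k]) 0 else substitution
        in_gap_a <- FALSE
        in_gap_b <- FALSE
      }
    }
    cost
  }
  best <- Inf
  rec <- function(i, j, ra, rb) {
    if (i > length(a) && j > length(b)) {
      best <<- min(best, score_alignment(ra, rb))
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      rec(i + 1, j + 1, c(ra, a[i]), c(rb, b[j]))
    }
    if (i <= length(a)) rec(i + 1, j, c(ra, a[i]), c(rb, "-"))
    if (j <= length(b)) rec(i, j + 1, c(ra, "-"), c(rb, b[j]))
    invisible()
  }
  rec(1, 1, character(0), character(0))
  list(cost = best, score = score_alignment)
}

# direct per-column site-pattern classifier written from the definition
oracle_classify_column <- function(col) {
  states <- col[col %in% c("A", "C", "G", "T")]
  tab <- table(states)
  if (sum(tab >= 2) >= 2) return("informative")
  if (length(tab) <= 1) return("constant")
  "uninformative"
}

# balanced 8-taxon tree with substantial terminal branches, for planted
# rate-outlier and strong-signal fixtures
balanced8 <- function(tip = 0.2, inner = 0.25, deep = 0.3) {
  ape::read.tree(text = sprintf(
    "(((t1:%1$f,t2:%1$f):%2$f,(t3:%1$f,t4:%1$f):%2$f):%3$f,((t5:%1$f,t6:%1$f):%2$f,(t7:%1$f,t8:%1$f):%2$f):%3$f);",
    tip, inner, deep))
}

random_alignment <- function(n_taxa, n_cols, seed) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n_taxa * n_cols, TRUE),
              n_taxa, n_cols, dimnames = list(paste0("t", seq_len(n_taxa)),
                                              NULL))
  m
}
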