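test_that("bracket matching pairs nested stems and classifies columns", {
  aln <- structured_alignment(c(t1 = "ACGUACGU", t2 = "ACGUACGU"),
                              "((....))")
  expect_equal(aln$pairing, c(8L, 7L, NA, NA, NA, NA, 2L, 1L))
  expect_equal(aln$classes,
               c("STEM", "STEM", rep("LOOP", 4), "STEM", "STEM"))
  expect_equal(unname(aln$seqs[1, 4]), "T")  # U folded to T

  all_loop <- structured_alignment(c(t1 = "ACGTACGT", t2 = "ACGTACGT"),
                                   "........")
  expect_true(all(is.na(all_loop$pairing)))
  expect_true(all(all_loop$classes == "LOOP"))
})

test_that("mirroring the mask mirrors the pairing map", {
  mask <- "((..(..).))."
  n <- nchar(mask)
  rows <- c(a = strrep("A", n), b = strrep("A", n))
  fwd <- structured_alignment(rows, mask)
  rev_mask <- paste(rev(chartr("()", ")(",
                               strsplit(mask, "")[[1]])), collapse = "")
  bwd <- structured_alignment(rows, rev_mask)
  mirrored <- rev((n + 1) - fwd$pairing)
  expect_equal(bwd$pairing, mirrored)
})

test_that("orphan brackets are recorded, warned about, and counted paired", {
  rows <- c(a = "ACGTACG", b = "ACGTACG")
  expect_warning(aln <- structured_alignment(rows, "((..).."),
                 "orphan")
  expect_equal(aln$orphans, 1L)
  expect_equal(aln$pairing[2], 5L)
  cnt <- count_site_patterns(aln)
  expect_equal(cnt$n_paired, 3L)  # 2 matched + 1 orphan
})

test_that("format errors name the offending record", {
  expect_error(structured_alignment(c(a = "ACGT", a = "ACGT"), "...."),
               "duplicate taxon")
  expect_error(structured_alignment(c(a = "ACGT", b = "ACG"), "...."),
               "unequal")
  expect_error(structured_alignment(c(a = "ACGT"), "....."), "mask length")
})

test_that("partition extraction preserves order, provenance, and tiles", {
  aln <- structured_alignment(c(t1 = "ACGUACGU", t2 = "ACGUACGU"),
                              "((....))")
  stem <- extract_partition(aln, "STEM")
  expect_equal(stem$provenance, c(1L, 2L, 7L, 8L))
  expect_equal(ncol(stem$seqs), 4L)
  both <- extract_partition(aln, "STEM+LOOP")
  expect_identical(both$seqs, aln$seqs)  # no RAA -> identity

  set.seed(42)
  m <- random_alignment(6, 40, seed = 42)
  mask <- paste(c(rep("(", 8), rep(".", 24), rep(")", 8)), collapse = "")
  raa <- data.frame(block = "R1", start = 12, end = 20)
  saln <- structured_alignment(m, mask, raa = raa)
  idx <- sort(c(extract_partition(saln, "STEM")$provenance,
                extract_partition(saln, "LOOP")$provenance,
                extract_partition(saln, "RAA")$provenance))
  expect_equal(idx, 1:40)
})

test_that("lowercase mask runs become RAA spans", {
  aln <- structured_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC"),
                              "((..rrrr))")
  expect_equal(aln$raa$start, 5L)
  expect_equal(aln$raa$end, 8L)
  expect_equal(sum(aln$classes == "RAA"), 4L)
  expect_equal(substr(aln$mask, 5, 8), "....")
})

test_that("site-pattern counting matches its invariant and conventions", {
  id <- matrix("A", 5, 10, dimnames = list(paste0("t", 1:5), NULL))
  cnt <- count_site_patterns(id)
  expect_equal(cnt$n_constant, 10L)
  expect_equal(cnt$n_parsimony_informative, 0L)

  col_mat <- function(...) {
    m <- rbind(...)
    rownames(m) <- paste0("t", seq_len(nrow(m)))
    m
  }
  inf <- col_mat("A", "A", "C", "C", "G")
  expect_equal(count_site_patterns(inf)$n_parsimony_informative, 1L)
  uninf <- col_mat("A", "A", "A", "A", "C")
  expect_equal(count_site_patterns(uninf)$n_variable_uninformative, 1L)
  gappy <- col_mat("A", "A", "-", "-", "-")
  expect_equal(count_site_patterns(gappy)$n_constant, 1L)
  expect_equal(count_site_patterns(gappy,
                                   strict_constant = TRUE)$n_constant, 0L)
})

test_that("structured FASTA and partition files round-trip bit-exactly", {
  set.seed(7)
  m <- random_alignment(6, 30, seed = 7)
  m[2, 5:9] <- "-"
  mask <- paste(c(rep("(", 6), rep(".", 18), rep(")", 6)), collapse = "")
  raa <- data.frame(block = "R1", start = 10, end = 16)
  aln <- structured_alignment(m, mask, raa = raa)

  fa <- tempfile(fileext = ".fasta")
  raa_tsv <- tempfile(fileext = ".tsv")
  write_structured_fasta(aln, fa)
  write_raa_annotation(aln, raa_tsv)
  back <- read_structured_fasta(fa, raa_annotation = raa_tsv)
  expect_identical(back$seqs, aln$seqs)
  expect_identical(back$mask, aln$mask)
  expect_identical(back$raa, aln$raa)

  dir <- tempfile()
  write_partition_files(aln, dir)
  defs <- readLines(file.path(dir, "partitions.txt"))
  idx <- unlist(lapply(defs, function(line) {
    rng <- strsplit(trimws(strsplit(line, "=")[[1]][2]), ",")[[1]]
    unlist(lapply(trimws(rng), function(r) {
      ab <- as.integer(strsplit(r, "-")[[1]]); ab[1]:ab[2]
    }))
  }))
  expect_equal(sort(idx), 1:30)  # ranges tile 1..L exactly
  back2 <- read_partition_files(dir)
  expect_identical(back2$seqs[rownames(aln$seqs), ], aln$seqs)
  expect_identical(back2$mask, aln$mask)
})

test_that("orphaned structure file annotates the orphan and still round-trips", {
  rows <- c(a = "ACGTACG", b = "ACGTACG")
  suppressWarnings(aln <- structured_alignment(rows, "((..).."))
  dir <- tempfile()
  expect_warning(write_partition_files(aln, dir), "unpaired")
  lines <- readLines(file.path(dir, "structure.txt"))
  expect_length(lines, 2L)
  expect_identical(lines[1], aln$mask)
  expect_identical(substr(lines[2], 1, 1), ".")
  back <- suppressWarnings(read_partition_files(dir))
  expect_identical(back$mask, aln$mask)
})
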