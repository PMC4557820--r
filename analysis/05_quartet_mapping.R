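#!/usr/bin/env Rscript

# Step 5 — likelihood mapping: how much of the quartet space is resolved
# per partition, and which grouping wins under a cluster constraint.

suppressMessages(library(structsignal))

aln <- read_structured_fasta("results/data/synthetic_alignment.fasta",
                             raa_annotation = "results/data/synthetic_raa.tsv")
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

model <- gtr_model(freqs = c(.3, .2, .2, .3), gamma_shape = 1)
rows <- list()
for (cls in c("STEM", "LOOP", "STEM+LOOP")) {
  part <- extract_partition(aln, cls)
  lm <- likelihood_mapping(part, model, n_quartets = "all",
                           seed = 20260925)
  cat(sprintf("%-10s resolved %.1f%%  partly %.1f%%  star %.1f%% (%d quartets)\n",
              cls, 100 * lm$resolved, 100 * lm$partly, 100 * lm$star,
              lm$total))
  rows[[cls]] <- data.frame(partition = cls, t(lm$fractions),
                            resolved = lm$resolved, partly = lm$partly,
                            star = lm$star, quartets = lm$total)
}

# cluster-constrained mapping: do quartets support the true deep split?
clusters <- list(c("t1", "t2"), c("t3", "t4"), c("t5", "t6"),
                 c("t7", "t8"))
lmc <- likelihood_mapping(extract_partition(aln, "STEM+LOOP"), model,
                          clusters = clusters, n_quartets = "all",
                          seed = 20260925)
cat(sprintf("cluster mode: T1 (12|34 grouping) %.1f%%, T2 %.1f%%, T3 %.1f%%\n",
            100 * lmc$fractions[["T1"]], 100 * lmc$fractions[["T2"]],
            100 * lmc$fractions[["T3"]]))
rows[["clusters"]] <- data.frame(partition = "clusters:12|34",
                                 t(lmc$fractions),
                                 resolved = lmc$resolved,
                                 partly = lmc$partly, star = lmc$star,
                                 quartets = lmc$total)
write.table(do.call(rbind, rows), "results/tables/likelihood_mapping.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
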