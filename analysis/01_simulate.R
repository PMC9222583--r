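#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Emulates the study design: 2 ecomorphs (wood, rock) x 3 tissues
# (radula, mantle, foot) x 3 pools per morph for expression and pool-seq
# allele counts, plus 37 landmarked shell specimens (19 wood / 18 rock
# substrate). All downstream stages read the files written here, so the whole
# analysis is reproducible from this one seed.

suppressMessages(library(ecomorphdiv))

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- simulate_all(cfg)

write_fasta(sim$transcripts$sequences, file.path(out, "transcripts.fasta"))
write_sync(sim$sites, file.path(out, "allele_counts.sync"))
write_counts(sim$expression$counts, file.path(out, "counts.tsv"))
write_sample_sheet(sim$expression$samples, file.path(out, "samples.csv"))
write_tps(sim$landmarks$coords, file.path(out, "landmarks.tps"))
utils::write.csv(sim$landmarks$labels, file.path(out, "specimens.csv"),
                 row.names = FALSE, quote = FALSE)

# ground truth, kept aside for validation only -- no analysis stage reads it
truth_dir <- file.path(out, "truth")
dir.create(truth_dir, showWarnings = FALSE)
jsonlite::write_json(
  list(orfs = sim$truth$orfs, af_snps = sim$truth$af_snps,
       de = sim$truth$de, universal_de = sim$truth$universal_de,
       shape_classes = as.list(sim$truth$shape_classes)),
  file.path(truth_dir, "truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d transcripts, %d allele-count sites (%d planted af-SNPs),\n",
            cfg$n_genes, nrow(sim$sites$info), nrow(sim$truth$af_snps)))
cat(sprintf("%d x %d count matrix, %d landmark specimens -> %s\n",
            nrow(sim$expression$counts), ncol(sim$expression$counts),
            dim(sim$landmarks$coords)[1], out))
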