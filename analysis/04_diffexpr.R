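#!/usr/bin/env Rscript
# Stage 4: differential expression between ecomorphs, per tissue.
#
# Median-ratio library normalization, method-of-moments common dispersion,
# conditional NB exact test per gene (rock vs wood within each tissue),
# BH adjustment per tissue, and the two significance tiers:
# DE (FDR <= 1e-2, FC >= 4) and highly DE (FDR <= 1e-10, FC >= 4).
# Also runs the two artifact diagnostics: the mapping-bias Fisher test and
# the allele-collapse similarity check among highly DE genes.

suppressMessages(library(ecomorphdiv))

data_dir <- "results/data"
out <- "results/de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sheet <- read_sample_sheet(file.path(data_dir, "samples.csv"))
counts <- parse_counts(file.path(data_dir, "counts.tsv"), sheet)
seqs <- parse_fasta(file.path(data_dir, "transcripts.fasta"))
snps <- utils::read.delim("results/popdiv/snps.tsv", stringsAsFactors = FALSE)

de <- classify_tiers(run_de_tests(counts, sheet))
for (t in unique(de$tissue))
  cat(sprintf("%s: %d DE, %d highly DE\n", t,
              sum(de$tier != "none" & de$tissue == t),
              sum(de$tier == "highlyDE" & de$tissue == t)))

libsizes <- normalize_libsizes(counts)
lens <- setNames(nchar(seqs), names(seqs))
fp <- fpkm_summary(counts, lens, sheet, libsizes, threshold = 1)

af_genes <- unique(snps$contig[snps$af_snp])
bias <- mapping_bias_test(rownames(counts) %in% de$gene[de$tier != "none"],
                          rownames(counts) %in% af_genes)
cat(sprintf("mapping-bias Fisher test: OR %.2f, p = %.3g (af-SNP genes %s overrepresented among DE genes)\n",
            bias$odds_ratio, bias$p, if (bias$p < 0.05) "ARE" else "are not"))

hde <- de[de$tier == "highlyDE", c("gene", "tissue", "log2fc")]
collapse <- allele_collapse_check(seqs, hde)
cat("allele-collapse fraction per tissue:",
    paste(sprintf("%s %.1f%%", names(collapse$fraction),
                  100 * collapse$fraction), collapse = ", "), "\n")

utils::write.table(de, file.path(out, "de.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(fp$summary, file.path(out, "expression_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(mapping_bias = bias[c("p", "odds_ratio")],
                          collapse_fraction = as.list(collapse$fraction)),
                     file.path(out, "diagnostics.json"),
                     auto_unbox = TRUE, digits = NA)
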