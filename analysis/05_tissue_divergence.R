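#!/usr/bin/env Rscript
# Stage 5: tissue-wise transcriptomic divergence.
#
# Proportions of (highly) DE genes among expressed genes per tissue with
# universally DE genes excluded, af-SNP frequencies among non-universally
# expressed genes (overall / in ORFs / non-synonymous), pairwise Fisher
# tests between tissues, the tissue composition of the most significant
# tests, and the highly-DE x af-SNP overlap.

suppressMessages(library(ecomorphdiv))

out <- "results/tissuediv"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

de <- utils::read.delim("results/de/de.tsv", stringsAsFactors = FALSE)
es <- utils::read.delim("results/de/expression_summary.tsv", stringsAsFactors = FALSE)
snps <- utils::read.delim("results/popdiv/snps.tsv", stringsAsFactors = FALSE)
eff <- utils::read.delim("results/orf/snp_effects.tsv", stringsAsFactors = FALSE)
af <- snps[snps$af_snp, c("contig", "pos")]

univ <- universal_sets(de)
cat(sprintf("universally DE: %d genes; universally highly DE: %d\n",
            length(univ$universal_de), length(univ$universal_highly_de)))

props <- tissue_de_proportions(de, es, univ)
print(props$per_tissue, row.names = FALSE)
print(props$pairwise, row.names = FALSE)

afreq <- tissue_afsnp_frequency(af, eff, es)
print(afreq$per_tissue, row.names = FALSE)

topq <- top_quantile_composition(de)
print(topq, row.names = FALSE)

ov <- de_afsnp_overlap(de, af, eff, es, univ)
print(ov$per_tissue, row.names = FALSE)

for (nm in c("per_tissue", "pairwise"))
  utils::write.table(props[[nm]], file.path(out, paste0("de_proportions_", nm, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(afreq$per_tissue, file.path(out, "afsnp_frequency.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(afreq$pairwise, file.path(out, "afsnp_frequency_tests.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(topq, file.path(out, "top_quantile.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ov$per_tissue, file.path(out, "overlap.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
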