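#!/usr/bin/env Rscript
# Stage 3: longest ORFs and codon effects of the called SNPs.
#
# Finds the longest complete forward-strand ORF of every transcript,
# classifies each SNP inside it as synonymous / non-synonymous by substituting
# major and minor allele into the affected codon, and ranks genes by the
# density of non-synonymous alternatively fixed SNPs per kb of ORF.

suppressMessages(library(ecomorphdiv))

data_dir <- "results/data"
out <- "results/orf"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

seqs <- parse_fasta(file.path(data_dir, "transcripts.fasta"))
snps <- utils::read.delim("results/popdiv/snps.tsv", stringsAsFactors = FALSE)

orfs <- annotate_orfs(seqs)
cat(sprintf("annotated ORFs on %d / %d transcripts\n", nrow(orfs), length(seqs)))

eff <- classify_snp_effects(snps, orfs, seqs)
tab <- table(eff$location, useNA = "no")
cat(sprintf("%d coding / %d noncoding SNPs; coding split: %d synonymous, %d non-synonymous\n",
            tab[["coding"]], tab[["noncoding"]],
            sum(eff$effect == "synonymous", na.rm = TRUE),
            sum(eff$effect == "non-synonymous", na.rm = TRUE)))

dens <- af_snp_density(orfs, eff, snps$af_snp)
top <- dens[1, ]
cat(sprintf("densest gene: %s with %d non-synonymous af-SNPs (%.1f-fold over all transcripts, %.2f-fold over af-bearing ones)\n",
            top$gene, top$n_nonsyn_af, top$fold_vs_all, top$fold_vs_af_bearing))

utils::write.table(orfs, file.path(out, "orfs.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(eff, file.path(out, "snp_effects.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(dens, file.path(out, "af_snp_density.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
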