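#!/usr/bin/env Rscript
# Stage 6: candidate genes for radula divergence.
#
# Expression-based set: highly DE between radulae (FDR <= 1e-10, FC >= 4) but
# quiet in mantle and foot (FDR >= 1e-5 and FC <= 4). SNP-based set: genes
# with >= 1 non-synonymous af-SNP, expressed in the radula of both morphs.

suppressMessages(library(ecomorphdiv))

out <- "results/candidates"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

de <- utils::read.delim("results/de/de.tsv", stringsAsFactors = FALSE)
es <- utils::read.delim("results/de/expression_summary.tsv", stringsAsFactors = FALSE)
snps <- utils::read.delim("results/popdiv/snps.tsv", stringsAsFactors = FALSE)
eff <- utils::read.delim("results/orf/snp_effects.tsv", stringsAsFactors = FALSE)
dens <- utils::read.delim("results/orf/af_snp_density.tsv", stringsAsFactors = FALSE)
af <- snps[snps$af_snp, c("contig", "pos")]

expr_set <- expression_candidates(de)
snp_set <- snp_candidates(af, eff, es)
rep <- candidate_report(expr_set, snp_set, af, eff, dens)

cat(sprintf("expression-based candidates: %d; SNP-based: %d; intersection: %d\n",
            rep$n_expression, rep$n_snp, length(rep$intersection)))
if (rep$n_snp > 0)
  cat(sprintf("%.0f%% of SNP-based candidates carry exactly one non-synonymous af-SNP (maximum %d)\n",
              100 * rep$fraction_single, rep$max_count))

writeLines(expr_set, file.path(out, "expression_candidates.txt"))
writeLines(snp_set, file.path(out, "snp_candidates.txt"))
jsonlite::write_json(rep[c("n_expression", "n_snp", "intersection",
                           "fraction_single", "max_count")],
                     file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
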