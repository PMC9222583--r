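## Candidate-gene filters: the expression-based set (highly DE in the radula,
## quiet in mantle and foot) and the SNP-based set (non-synonymous af-SNPs in
## genes expressed in the radula of both morphs), plus the combined report.

#' Expression-based candidate genes
#'
#' A gene qualifies iff in the radula FDR <= `fdr_high` and |FC| >= `fc`,
#' while in each of mantle and foot FDR >= `fdr_quiet` and |FC| <= `fc`
#' (both conditions, i.e. no sign of differential expression there). A gene
#' untested in a tissue fails the radula criterion and passes the quiet
#' criterion; the number of such genes is reported via a message.
#'
#' @param de Tiered DE table (gene, tissue, log2fc, fdr).
#' @param radula_tissue Name of the focal tissue (default "radula").
#' @param fdr_high Radula FDR gate (default 1e-10).
#' @param fdr_quiet Minimum FDR required in the other tissues (default 1e-5).
#' @param fc Linear fold-change threshold (default 4), used as >= for the
#'   radula and <= for the other tissues.
#' @return Character vector of candidate gene ids.
#' @export
expression_candidates <- function(de, radula_tissue = "radula",
                                  fdr_high = 1e-10, fdr_quiet = 1e-5, fc = 4) {
  lfc <- log2(fc)
  tissues <- unique(de$tissue)
  others <- setdiff(tissues, radula_tissue)
  rad <- de[de$tissue == radula_tissue, ]
  pass_rad <- rad$gene[rad$fdr <= fdr_high & abs(rad$log2fc) >= lfc]
  n_untested <- 0L
  quiet <- lapply(others, function(t) {
    d <- de[de$tissue == t, ]
    ok <- d$gene[d$fdr >= fdr_quiet & abs(d$log2fc) <= lfc]
    miss <- setdiff(pass_rad, d$gene)   # untested: passes the quiet criterion
    n_untested <<- n_untested + length(miss)
    c(ok, miss)
  })
  if (n_untested > 0)
    message(n_untested, " gene-tissue pair(s) untested; treated as quiet")
  sort(Reduce(intersect, c(list(pass_rad), quiet)))
}

#' SNP-based candidate genes
#'
#' A gene qualifies iff it carries at least one non-synonymous alternatively
#' fixed SNP and is expressed (mean FPKM >= 1) in the radula of both morphs.
#'
#' @param af_snps af-SNP data.frame (contig, pos).
#' @param effects Effect table from [classify_snp_effects()].
#' @param expr_summary Expression summary from [fpkm_summary()].
#' @param radula_tissue Focal tissue (default "radula").
#' @return Character vector of candidate gene ids.
#' @export
snp_candidates <- function(af_snps, effects, expr_summary,
                           radula_tissue = "radula") {
  key <- paste(af_snps$contig, af_snps$pos)
  eff <- effects[match(key, paste(effects$contig, effects$pos)), , drop = FALSE]
  ns_genes <- unique(af_snps$contig[!is.na(eff$effect) &
                                      eff$effect == "non-synonymous"])
  both <- expressed_genes(expr_summary, radula_tissue, both_morphs = TRUE)
  sort(intersect(ns_genes, both))
}

#' Combined candidate report
#'
#' Summarizes both sets: sizes, their intersection (the filters can in
#' principle overlap; any overlap is reported, never removed), the
#' distribution of non-synonymous af-SNP counts per SNP-based candidate
#' (fraction with exactly one; the maximum), and the density ranking.
#'
#' @param expr_set,snp_set Candidate gene vectors.
#' @param af_snps,effects As in [snp_candidates()].
#' @param densities Optional density table from [af_snp_density()].
#' @return List: `n_expression`, `n_snp`, `intersection`, `counts_per_gene`,
#'   `fraction_single`, `max_count`, `top_density`.
#' @export
candidate_report <- function(expr_set, snp_set, af_snps, effects,
                             densities = NULL) {
  key <- paste(af_snps$contig, af_snps$pos)
  eff <- effects[match(key, paste(effects$contig, effects$pos)), , drop = FALSE]
  ns <- af_snps$contig[!is.na(eff$effect) & eff$effect == "non-synonymous"]
  cnt <- table(factor(ns, levels = snp_set))
  counts <- stats::setNames(as.integer(cnt), names(cnt))
  list(n_expression = length(expr_set),
       n_snp = length(snp_set),
       intersection = intersect(expr_set, snp_set),
       counts_per_gene = counts,
       fraction_single = if (length(counts)) mean(counts == 1) else NA_real_,
       max_count = if (length(counts)) max(counts) else NA_integer_,
       top_density = if (!is.null(densities))
         utils::head(densities[densities$gene %in% snp_set, ], 10) else NULL)
}
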