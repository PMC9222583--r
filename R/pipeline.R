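## End-to-end orchestration on synthetic data: simulate -> coverage/SNP/F_st ->
## ORF/codon effects -> differential expression -> tissue divergence ->
## candidates -> morphometrics, with a deterministic JSON manifest.

#' Pipeline thresholds
#'
#' Default analysis gates: target coverage 20x, MAF 10%, FDR tiers
#' 1e-2 (DE) and 1e-10 (highly DE), linear fold change 4, quiet-tissue gate
#' FDR >= 1e-5 with FC <= 4, FPKM >= 1, and a 5% PC variance gate.
#'
#' @param target_coverage,maf,fdr,fdr_high,fc,fdr_quiet,fpkm,min_var Gates.
#' @return Named list of thresholds.
#' @export
pipeline_thresholds <- function(target_coverage = 20, maf = 0.10,
                                fdr = 1e-2, fdr_high = 1e-10, fc = 4,
                                fdr_quiet = 1e-5, fpkm = 1, min_var = 0.05) {
  as.list(environment())
}

#' Run the full pipeline on synthetic data
#'
#' Executes every stage on one synthetic dataset and, when `out_dir` is
#' given, writes the generated inputs, the per-stage result tables, and a
#' deterministic JSON manifest (seed, thresholds, stage summaries; no
#' timestamps), so identical seeds yield byte-identical manifests.
#'
#' @param config A [sim_config()]; its seed drives every stage substream.
#' @param thresholds A [pipeline_thresholds()] list.
#' @param out_dir Optional output directory.
#' @return (Invisibly) a list with every stage's results and the manifest.
#' @export
run_all <- function(config = sim_config(), thresholds = pipeline_thresholds(),
                    out_dir = NULL) {
  th <- thresholds
  sim <- simulate_all(config)

  ## population divergence
  std <- standardize_coverage(sim$sites, target = th$target_coverage,
                              seed = derive_seed(config$seed, "subsample"))
  st <- detect_af_snps(call_snps(std, maf_threshold = th$maf))
  medmat <- median_fst_matrix(st)
  comb <- combined_fst_distribution(st, maf_threshold = th$maf)
  af <- st$snps[st$snps$af_snp, c("contig", "pos", "major", "minor")]

  ## ORFs and codon effects
  orfs <- suppressMessages(annotate_orfs(sim$transcripts$sequences))
  effects <- classify_snp_effects(st$snps, orfs, sim$transcripts$sequences)
  dens <- af_snp_density(orfs, effects, st$snps$af_snp)

  ## differential expression
  de <- classify_tiers(run_de_tests(sim$expression$counts, sim$expression$samples),
                       fdr = th$fdr, fdr_high = th$fdr_high, fc = th$fc)
  libsizes <- normalize_libsizes(sim$expression$counts)
  fp <- fpkm_summary(sim$expression$counts, sim$expression$gene_lengths,
                     sim$expression$samples, libsizes, threshold = th$fpkm)
  gene_univ <- rownames(sim$expression$counts)
  de_any <- gene_univ %in% de$gene[de$tier != "none"]
  af_any <- gene_univ %in% unique(af$contig)
  bias <- tryCatch(mapping_bias_test(de_any, af_any),
                   warning = function(w) list(p = 1, odds_ratio = NA_real_))
  hde <- de[de$tier == "highlyDE", c("gene", "tissue", "log2fc")]
  collapse <- allele_collapse_check(sim$transcripts$sequences, hde)

  ## tissue divergence
  univ <- universal_sets(de)
  props <- tissue_de_proportions(de, fp$summary, univ)
  afreq <- tissue_afsnp_frequency(af, effects, fp$summary)
  topq <- top_quantile_composition(de)
  overlap <- de_afsnp_overlap(de, af, effects, fp$summary, univ)

  ## candidates
  cand_expr <- suppressMessages(expression_candidates(
    de, fdr_high = th$fdr_high, fdr_quiet = th$fdr_quiet, fc = th$fc))
  cand_snp <- snp_candidates(af, effects, fp$summary)
  cand <- candidate_report(cand_expr, cand_snp, af, effects, dens)

  ## morphometrics
  gpa <- procrustes_gpa(sim$landmarks$coords)
  pca <- shape_pca(gpa)
  shape_tests <- pc_group_tests(pca, sim$landmarks$labels$morph,
                                min_var = th$min_var)
  chi <- habitat_chi2(table(sim$landmarks$labels$substrate,
                            sim$landmarks$labels$morph))

  manifest <- list(
    package = "ecomorphdiv",
    version = as.character(utils::packageVersion("ecomorphdiv")),
    seed = config$seed,
    thresholds = th,
    stages = list(
      simulate = list(n_genes = config$n_genes,
                      n_sites = nrow(sim$sites$info),
                      n_planted_af = nrow(attr(sim$sites, "truth_af")),
                      n_samples = nrow(sim$expression$samples),
                      n_specimens = dim(sim$landmarks$coords)[1]),
      popdiv = list(n_sites_retained = nrow(std$info),
                    n_snps = nrow(st$snps),
                    n_af_snps = sum(st$snps$af_snp),
                    median_fst_combined = comb$median,
                    mean_fst_combined = comb$mean,
                    af_percentile = comb$af_percentile,
                    median_fst_matrix = round(medmat, 10)),
      orf = list(n_orfs = nrow(orfs),
                 n_coding_snps = sum(effects$location == "coding"),
                 n_synonymous = sum(effects$effect == "synonymous", na.rm = TRUE),
                 n_nonsynonymous = sum(effects$effect == "non-synonymous",
                                       na.rm = TRUE)),
      de = list(n_de = sum(de$tier != "none"),
                n_highly_de = sum(de$tier == "highlyDE"),
                mapping_bias_p = bias$p,
                collapse_fraction = collapse$fraction),
      tissuediv = list(proportions = props$per_tissue,
                       top_quantile = topq,
                       overlap = overlap$per_tissue),
      candidates = list(n_expression = cand$n_expression,
                        n_snp = cand$n_snp,
                        fraction_single = cand$fraction_single,
                        max_count = cand$max_count),
      morpho = list(gpa_iterations = gpa$iterations,
                    pc1_var = if (pca$rank > 0) pca$var_fraction[1] else NA_real_,
                    n_pcs_tested = sum(shape_tests$tested),
                    min_tested_p = suppressWarnings(min(shape_tests$p, na.rm = TRUE)),
                    chisq = chi$chisq, chisq_p = chi$p)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(sim$transcripts$sequences, file.path(out_dir, "transcripts.fasta"))
    write_sync(sim$sites, file.path(out_dir, "allele_counts.sync"))
    write_counts(sim$expression$counts, file.path(out_dir, "counts.tsv"))
    write_sample_sheet(sim$expression$samples, file.path(out_dir, "samples.csv"))
    write_tps(sim$landmarks$coords, file.path(out_dir, "landmarks.tps"))
    utils::write.table(st$snps, file.path(out_dir, "snps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(de, file.path(out_dir, "de.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(effects, file.path(out_dir, "snp_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "columns")
  }

  invisible(list(sim = sim, standardized = std, snps = st,
                 median_fst = medmat, combined_fst = comb, orfs = orfs,
                 effects = effects, densities = dens, de = de, fpkm = fp,
                 mapping_bias = bias, collapse = collapse, universal = univ,
                 proportions = props, af_frequency = afreq, top_quantile = topq,
                 overlap = overlap,
                 candidates = list(expression = cand_expr, snp = cand_snp,
                                   report = cand),
                 morpho = list(gpa = gpa, pca = pca, tests = shape_tests,
                               chi2 = chi),
                 manifest = manifest))
}
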