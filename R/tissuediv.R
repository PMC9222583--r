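## Tissue-wise transcriptomic divergence: DE / highly-DE proportions with
## universal-set exclusion, af-SNP frequencies per tissue, cross-tissue
## Fisher tests, top-quantile composition, and the highly-DE x af-SNP overlap.

#' Universal-DE and universal-highly-DE gene sets
#'
#' Genes DE (respectively highly DE) in all three tissues; these are
#' uninformative for tissue-specific divergence and excluded from all
#' tissue-wise proportions.
#'
#' @param de Tiered DE table from [classify_tiers()].
#' @return List: `universal_de`, `universal_highly_de` (character vectors).
#' @export
universal_sets <- function(de) {
  tissues <- unique(de$tissue)
  in_all <- function(tiers) {
    g <- de$gene[de$tier %in% tiers]
    tab <- table(g)
    names(tab)[tab == length(tissues)]
  }
  list(universal_de = in_all(c("DE", "highlyDE")),
       universal_highly_de = in_all("highlyDE"))
}

fisher_2x2 <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, b, c, d), 2))$p.value
}

# (p_a - p_b) / p_b * 100; equal proportions (including both zero) give 0
percent_diff <- function(pa, pb) {
  if (pa == pb) 0 else if (pb == 0) Inf else (pa - pb) / pb * 100
}

rbind_all <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst)) do.call(rbind, c(lst, list(make.row.names = FALSE))) else NULL
}

#' Per-tissue DE proportions with pairwise Fisher tests
#'
#' For each tissue, the proportion of expressed genes (either morph,
#' universal set excluded) that are DE, at both tiers. Each tissue pair is
#' compared with a two-sided Fisher's exact test on (DE, not-DE) counts, and
#' the percent difference `(p_a - p_b)/p_b * 100` is reported.
#'
#' @param de Tiered DE table.
#' @param expr_summary Expression summary from [fpkm_summary()].
#' @param universal List from [universal_sets()].
#' @return List: `per_tissue` data.frame (tissue, tier, n_expressed, n_de,
#'   proportion) and `pairwise` data.frame (tier, tissue_a, tissue_b,
#'   percent_difference, p).
#' @export
tissue_de_proportions <- function(de, expr_summary, universal) {
  tissues <- unique(de$tissue)
  tiers <- list(DE = c("DE", "highlyDE"), highlyDE = "highlyDE")
  excl <- list(DE = universal$universal_de,
               highlyDE = universal$universal_highly_de)
  pt <- list(); pw <- list()
  for (tier in names(tiers)) {
    stats_t <- list()
    for (t in tissues) {
      denom <- setdiff(expressed_genes(expr_summary, t), excl[[tier]])
      if (length(denom) == 0) {
        warning(sprintf("no expressed genes for tissue %s after exclusion; skipped", t))
        next
      }
      de_genes <- de$gene[de$tissue == t & de$tier %in% tiers[[tier]]]
      num <- intersect(setdiff(de_genes, excl[[tier]]), denom)
      stats_t[[t]] <- c(n_expressed = length(denom), n_de = length(num))
      pt[[paste(tier, t)]] <- data.frame(
        tissue = t, tier = tier, n_expressed = length(denom),
        n_de = length(num), proportion = length(num) / length(denom),
        stringsAsFactors = FALSE)
    }
    ts <- names(stats_t)
    if (length(ts) >= 2) {
      for (i in seq_len(length(ts) - 1)) for (j in (i + 1):length(ts)) {
        a <- stats_t[[ts[i]]]; b <- stats_t[[ts[j]]]
        pa <- a["n_de"] / a["n_expressed"]; pb <- b["n_de"] / b["n_expressed"]
        pw[[paste(tier, i, j)]] <- data.frame(
          tier = tier, tissue_a = ts[i], tissue_b = ts[j],
          percent_difference = percent_diff(unname(pa), unname(pb)),
          p = fisher_2x2(a["n_de"], a["n_expressed"] - a["n_de"],
                         b["n_de"], b["n_expressed"] - b["n_de"]),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(per_tissue = rbind_all(pt), pairwise = rbind_all(pw))
}

#' Per-tissue af-SNP frequency among non-universally expressed genes
#'
#' The denominator for each tissue is the set of genes expressed (FPKM gate,
#' either morph) in that tissue but not in all three tissues. Frequencies are
#' reported overall, restricted to af-SNPs inside ORFs, and restricted to
#' non-synonymous af-SNPs; pairwise tissue differences are Fisher-tested on
#' (af-SNP-bearing gene, not) counts.
#'
#' @param af_snps data.frame of af-SNPs with columns contig (gene), pos.
#' @param effects Effect table from [classify_snp_effects()] aligned with
#'   `af_snps` (same rows) or covering them by (contig, pos).
#' @param expr_summary Expression summary from [fpkm_summary()].
#' @return List: `per_tissue` data.frame (tissue, scope, n_genes, n_af_snps,
#'   n_bearing, frequency) and `pairwise` Fisher results per scope.
#' @export
tissue_afsnp_frequency <- function(af_snps, effects, expr_summary) {
  tissues <- unique(expr_summary$tissue)
  expr_in <- lapply(tissues, function(t) expressed_genes(expr_summary, t))
  names(expr_in) <- tissues
  universal <- Reduce(intersect, expr_in)
  key <- paste(af_snps$contig, af_snps$pos)
  ekey <- paste(effects$contig, effects$pos)
  eff <- effects[match(key, ekey), , drop = FALSE]
  scopes <- list(
    all = rep(TRUE, nrow(af_snps)),
    in_orf = !is.na(eff$location) & eff$location == "coding",
    nonsynonymous = !is.na(eff$effect) & eff$effect == "non-synonymous")
  pt <- list(); pw <- list()
  for (sc in names(scopes)) {
    snps_sc <- af_snps[scopes[[sc]], , drop = FALSE]
    per <- list()
    for (t in tissues) {
      denom <- setdiff(expr_in[[t]], universal)
      if (length(denom) == 0) {
        warning(sprintf("all genes universally expressed; tissue %s skipped", t))
        next
      }
      hit <- snps_sc$contig %in% denom
      per[[t]] <- c(n_genes = length(denom), n_af = sum(hit),
                    n_bearing = length(unique(snps_sc$contig[hit])))
      pt[[paste(sc, t)]] <- data.frame(
        tissue = t, scope = sc, n_genes = length(denom),
        n_af_snps = sum(hit),
        n_bearing = length(unique(snps_sc$contig[hit])),
        frequency = sum(hit) / length(denom), stringsAsFactors = FALSE)
    }
    ts <- names(per)
    if (length(ts) >= 2) {
      for (i in seq_len(length(ts) - 1)) for (j in (i + 1):length(ts)) {
        a <- per[[ts[i]]]; b <- per[[ts[j]]]
        fa <- a["n_bearing"] / a["n_genes"]; fb <- b["n_bearing"] / b["n_genes"]
        pw[[paste(sc, i, j)]] <- data.frame(
          scope = sc, tissue_a = ts[i], tissue_b = ts[j],
          percent_difference = percent_diff(unname(fa), unname(fb)),
          p = fisher_2x2(a["n_bearing"], a["n_genes"] - a["n_bearing"],
                         b["n_bearing"], b["n_genes"] - b["n_bearing"]),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(per_tissue = rbind_all(pt), pairwise = rbind_all(pw))
}

#' Tissue composition of the most significant DE tests
#'
#' All (gene, tissue) tests are pooled and ranked by p-value ascending (ties
#' by |log2FC| descending, then gene id); within the top fraction, the share
#' of entries belonging to each tissue is reported. Shares sum to 1.
#'
#' @param de DE table with columns gene, tissue, p, log2fc.
#' @param fractions Numeric fractions (default 1% and 5%).
#' @return data.frame: fraction, tissue, n, share.
#' @export
top_quantile_composition <- function(de, fractions = c(0.01, 0.05)) {
  ord <- order(de$p, -abs(de$log2fc), de$gene)
  n <- nrow(de)
  out <- list()
  for (f in fractions) {
    n_top <- floor(n * f)
    if (n_top < 1) {
      warning(sprintf("fewer than 1/%g entries; using the single smallest p", f))
      n_top <- 1L
    }
    top <- de$tissue[ord[seq_len(n_top)]]
    tab <- table(factor(top, unique(de$tissue)))
    out[[as.character(f)]] <- data.frame(
      fraction = f, tissue = names(tab), n = as.integer(tab),
      share = as.integer(tab) / n_top, stringsAsFactors = FALSE)
  }
  rbind_all(out)
}

#' Overlap of highly DE genes and af-SNP-carrying genes per tissue
#'
#' For each tissue: highly DE genes (universal highly-DE set excluded)
#' carrying at least one af-SNP, the split of those af-SNPs into
#' synonymous / non-synonymous / noncoding, and the count of overlap genes
#' exclusive to that tissue's highly DE set. Tissue pairs are Fisher-tested
#' on (overlap gene, other expressed gene) counts.
#'
#' @param de Tiered DE table.
#' @param af_snps af-SNP data.frame (contig, pos).
#' @param effects Effect table covering the af-SNPs.
#' @param expr_summary Expression summary (denominators for the tests).
#' @param universal List from [universal_sets()].
#' @return List: `per_tissue` data.frame and `pairwise` Fisher results.
#' @export
de_afsnp_overlap <- function(de, af_snps, effects, expr_summary, universal) {
  tissues <- unique(de$tissue)
  key <- paste(af_snps$contig, af_snps$pos)
  eff <- effects[match(key, paste(effects$contig, effects$pos)), , drop = FALSE]
  hde <- lapply(tissues, function(t)
    setdiff(de$gene[de$tissue == t & de$tier == "highlyDE"],
            universal$universal_highly_de))
  names(hde) <- tissues
  ov_genes <- lapply(hde, function(g) intersect(g, unique(af_snps$contig)))
  pt <- list(); pw <- list()
  for (t in tissues) {
    others <- unlist(hde[setdiff(tissues, t)])
    excl <- setdiff(ov_genes[[t]], others)
    in_ov <- af_snps$contig %in% ov_genes[[t]]
    cls <- ifelse(is.na(eff$location) | eff$location == "noncoding", "noncoding",
                  ifelse(is.na(eff$effect), "not-applicable", eff$effect))
    tab <- table(factor(cls[in_ov], c("synonymous", "non-synonymous",
                                      "noncoding", "not-applicable")))
    denom <- setdiff(expressed_genes(expr_summary, t),
                     universal$universal_highly_de)
    pt[[t]] <- data.frame(
      tissue = t, n_highly_de = length(hde[[t]]),
      n_overlap = length(ov_genes[[t]]), n_overlap_exclusive = length(excl),
      n_af_snps = sum(in_ov),
      n_synonymous = as.integer(tab["synonymous"]),
      n_nonsynonymous = as.integer(tab["non-synonymous"]),
      n_noncoding = as.integer(tab["noncoding"]),
      n_expressed = length(denom), stringsAsFactors = FALSE)
  }
  for (i in seq_len(length(tissues) - 1)) for (j in (i + 1):length(tissues)) {
    a <- pt[[tissues[i]]]; b <- pt[[tissues[j]]]
    pw[[paste(i, j)]] <- data.frame(
      tissue_a = tissues[i], tissue_b = tissues[j],
      p = fisher_2x2(a$n_overlap, a$n_expressed - a$n_overlap,
                     b$n_overlap, b$n_expressed - b$n_overlap),
      stringsAsFactors = FALSE)
  }
  list(per_tissue = rbind_all(pt), pairwise = rbind_all(pw))
}
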