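## Differential expression: median-ratio library-size normalization,
## method-of-moments common dispersion, a conditional negative-binomial exact
## test, tiered significance calls (DE / highly DE), FPKM expression flags,
## and two artifact-level diagnostics (mapping-bias Fisher test and the
## allele-collapse similarity check).

## normalization -------------------------------------------------------------

#' Median-ratio effective library sizes
#'
#' Size factors are the median, per sample, of the ratio of its counts to the
#' per-gene geometric mean, over genes with positive counts in all samples;
#' they are rescaled to library-size units (geometric mean of the column
#' totals). When fewer than 50 such genes exist the totals themselves are
#' used.
#'
#' @param counts Gene x sample count matrix (>= 2 samples).
#' @return Numeric vector of effective library sizes, one per sample.
#' @export
normalize_libsizes <- function(counts) {
  if (ncol(counts) < 2) stopf("need >= 2 samples")
  totals <- colSums(counts)
  if (any(totals == 0)) stopf("sample with all-zero counts")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (sum(pos) < 50) return(stats::setNames(as.numeric(totals), colnames(counts)))
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)  # log geometric mean per gene
  s <- apply(lg, 2, function(v) exp(stats::median(v - ref)))
  stats::setNames(s / geomean(s) * geomean(totals), colnames(counts))
}

#' Common dispersion by trimmed method of moments
#'
#' Counts are normalized to a common library size; per gene,
#' `phi_g = max(0, (s^2 - m) / m^2)` from the sample mean and variance, and
#' the common dispersion is the 20%-trimmed mean of `phi_g` over genes whose
#' normalized mean is at least 5.
#'
#' @param counts Gene x sample count matrix.
#' @param libsizes Effective library sizes from [normalize_libsizes()].
#' @return Scalar dispersion estimate `phi_hat >= 0`.
#' @export
estimate_dispersion <- function(counts, libsizes) {
  if (ncol(counts) < 2) stopf("need >= 2 replicates")
  y <- sweep(counts, 2, libsizes / geomean(libsizes), "/")
  m <- rowMeans(y)
  v <- apply(y, 1, stats::var)
  keep <- m >= 5
  if (!any(keep)) stopf("no gene with normalized mean >= 5")
  phi_g <- pmax(0, (v[keep] - m[keep]) / m[keep]^2)
  mean(phi_g, trim = 0.2)
}

## exact test ----------------------------------------------------------------

#' Conditional negative-binomial exact test for two groups
#'
#' Counts are assumed rescaled to a common library size. Conditional on the
#' grand total T, the probability of each split of T between the group sums
#' is evaluated under per-sample NB(m_hat, phi) (group sums are NB with the
#' sample sizes' aggregated size parameter); the two-sided p-value doubles
#' the smaller tail, capped at 1. The log2 fold change (group2 vs group1)
#' uses the group means with a 0.5 pseudo-count.
#'
#' @param y1,y2 Integer count vectors for the two groups (common library size).
#' @param phi Common dispersion (>= 0; 0 gives the Poisson limit).
#' @return List: `p`, `log2fc`.
#' @export
nb_exact_test <- function(y1, y2, phi) {
  n1 <- length(y1); n2 <- length(y2)
  s1 <- sum(y1); s2 <- sum(y2)
  T <- s1 + s2
  if (T == 0) return(list(p = 1, log2fc = 0))
  m <- T / (n1 + n2)
  s <- 0:T
  if (phi > 0) {
    f1 <- stats::dnbinom(s, size = n1 / phi, mu = n1 * m)
    f2 <- stats::dnbinom(T - s, size = n2 / phi, mu = n2 * m)
  } else {
    f1 <- stats::dpois(s, n1 * m)
    f2 <- stats::dpois(T - s, n2 * m)
  }
  g <- f1 * f2
  tot <- sum(g)
  plow <- sum(g[s <= s1]) / tot
  phigh <- sum(g[s >= s1]) / tot
  p <- min(1, 2 * min(plow, phigh))
  list(p = p, log2fc = log2((s2 / n2 + 0.5) / (s1 / n1 + 0.5)))
}

#' Per-tissue rock-vs-wood exact tests
#'
#' For each tissue, counts of that tissue's samples are normalized, rescaled
#' to a common library size (rounded), a common dispersion is estimated, and
#' every gene is tested wood vs rock with [nb_exact_test()]. log2FC is rock
#' relative to wood.
#'
#' @param counts Gene x sample count matrix.
#' @param samples Sample sheet (sample, morph, tissue, pool).
#' @param dispersion Optional fixed dispersion; estimated per tissue if NULL.
#' @return data.frame: gene, tissue, log2fc, p.
#' @export
run_de_tests <- function(counts, samples, dispersion = NULL) {
  out <- list()
  for (t in unique(samples$tissue)) {
    sel <- samples$tissue == t
    y <- counts[, samples$sample[sel], drop = FALSE]
    morph <- samples$morph[sel]
    ls <- normalize_libsizes(y)
    yr <- round(sweep(y, 2, ls / geomean(ls), "/"))
    phi <- dispersion %||% estimate_dispersion(y, ls)
    iw <- which(morph == "wood"); ir <- which(morph == "rock")
    res <- apply(yr, 1, function(v) nb_exact_test(v[iw], v[ir], phi))
    out[[t]] <- data.frame(
      gene = rownames(counts), tissue = t,
      log2fc = vapply(res, `[[`, numeric(1), "log2fc"),
      p = vapply(res, `[[`, numeric(1), "p"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Assign tiered differential-expression calls
#'
#' P-values are Benjamini-Hochberg adjusted within each tissue contrast.
#' Tier `DE` requires FDR <= `fdr` and linear fold change >= `fc`
#' (|log2FC| >= log2(fc)); tier `highlyDE` additionally requires
#' FDR <= `fdr_high`. `highlyDE` calls are a subset of `DE` calls.
#'
#' @param de data.frame from [run_de_tests()].
#' @param fdr,fdr_high FDR gates for the two tiers (defaults 1e-2, 1e-10).
#' @param fc Linear fold-change gate (default 4).
#' @return `de` with added columns `fdr` and `tier` in
#'   `{none, DE, highlyDE}`.
#' @export
classify_tiers <- function(de, fdr = 1e-2, fdr_high = 1e-10, fc = 4) {
  de$fdr <- stats::ave(de$p, de$tissue, FUN = function(p) stats::p.adjust(p, "BH"))
  big <- abs(de$log2fc) >= log2(fc)
  de$tier <- ifelse(de$fdr <= fdr_high & big, "highlyDE",
                    ifelse(de$fdr <= fdr & big, "DE", "none"))
  de
}

## FPKM ----------------------------------------------------------------------

#' FPKM matrix and per-(gene, tissue, morph) expression flags
#'
#' FPKM = count / (gene length in kb x effective library size in millions).
#' A gene is "expressed" in a (tissue, morph) stratum when its mean FPKM over
#' that stratum's pools is at least `threshold`.
#'
#' @param counts Gene x sample count matrix.
#' @param gene_lengths Named lengths in nt.
#' @param samples Sample sheet.
#' @param libsizes Optional effective library sizes (default:
#'   [normalize_libsizes()] over all samples).
#' @param threshold Expression gate (default 1 FPKM).
#' @return List: `fpkm` matrix, and `summary` data.frame (gene, tissue,
#'   morph, mean_fpkm, expressed).
#' @export
fpkm_summary <- function(counts, gene_lengths, samples, libsizes = NULL,
                         threshold = 1) {
  len <- gene_lengths[rownames(counts)]
  if (any(is.na(len)) || any(len <= 0)) stopf("gene lengths must be positive for all genes")
  ls <- libsizes %||% normalize_libsizes(counts)
  fpkm <- sweep(sweep(counts, 2, ls / 1e6, "/"), 1, len / 1000, "/")
  strata <- unique(samples[, c("tissue", "morph")])
  sm <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sel <- samples$tissue == strata$tissue[i] & samples$morph == strata$morph[i]
    mf <- rowMeans(fpkm[, samples$sample[sel], drop = FALSE])
    data.frame(gene = rownames(counts), tissue = strata$tissue[i],
               morph = strata$morph[i], mean_fpkm = mf,
               expressed = mf >= threshold,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(fpkm = fpkm, summary = sm)
}

#' Genes expressed in a tissue (either morph, or both morphs)
#' @param expr_summary `summary` from [fpkm_summary()].
#' @param tissue Tissue label.
#' @param both_morphs If TRUE, require the expressed flag in each morph.
#' @return Character vector of gene ids.
#' @export
expressed_genes <- function(expr_summary, tissue, both_morphs = FALSE) {
  s <- expr_summary[expr_summary$tissue == tissue & expr_summary$expressed, ]
  tab <- table(s$gene)
  names(tab)[if (both_morphs) tab == 2 else tab >= 1]
}

## diagnostics ---------------------------------------------------------------

#' Mapping-bias test: are af-SNP genes more likely to be DE?
#'
#' Two-sided Fisher's exact test on the 2x2 table of af-SNP-carrying x DE
#' over a common gene universe. Degenerate margins (e.g. all genes DE)
#' return p = 1 with a warning.
#'
#' @param de_flag,af_flag Logical vectors over the same gene universe.
#' @return List: `p`, `odds_ratio`, `table`.
#' @export
mapping_bias_test <- function(de_flag, af_flag) {
  stopifnot(length(de_flag) == length(af_flag))
  tab <- table(factor(af_flag, c(TRUE, FALSE)), factor(de_flag, c(TRUE, FALSE)),
               dnn = c("af_snp", "de"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin in mapping-bias table; p = 1")
    return(list(p = 1, odds_ratio = NA_real_, table = tab))
  }
  ft <- stats::fisher.test(tab)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}

#' Allele-collapse check among highly DE genes
#'
#' Flags pairs of highly DE genes with opposite regulation whose sequences
#' share > `min_identity` identity over at least `min_coverage` of the
#' shorter sequence, under local alignment (match +1, mismatch -1, gap -2)
#' with an exact k-mer prefilter (k = 11). Such pairs are the signature of
#' alleles erroneously assembled as distinct genes.
#'
#' @param seqs Named character vector covering all highly DE genes.
#' @param de_high data.frame with columns gene, tissue, log2fc restricted to
#'   highly DE calls.
#' @param min_identity Identity threshold (default 0.95, exclusive).
#' @param min_coverage Minimum aligned fraction of the shorter sequence
#'   (default 0.5).
#' @param k Prefilter k-mer size.
#' @return List: `pairs` (tissue, gene_up, gene_down, identity, coverage) and
#'   `fraction` (named per-tissue fraction of highly DE genes flagged).
#' @export
allele_collapse_check <- function(seqs, de_high, min_identity = 0.95,
                                  min_coverage = 0.5, k = 11) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pairs <- list()
  frac <- stats::setNames(numeric(0), character(0))
  for (t in unique(de_high$tissue)) {
    d <- de_high[de_high$tissue == t, ]
    up <- d$gene[d$log2fc > 0]; down <- d$gene[d$log2fc < 0]
    flagged <- character(0)
    if (length(up) && length(down)) {
      kms <- lapply(seqs[c(up, down)], function(s) {
        if (nchar(s) < k) return(character(0))
        unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
      })
      for (a in up) for (b in down) {
        if (!length(intersect(kms[[a]], kms[[b]]))) next
        aln <- Biostrings::pairwiseAlignment(
          seqs[[a]], seqs[[b]], type = "local", substitutionMatrix = mat,
          gapOpening = 0, gapExtension = 2)
        nm <- Biostrings::nmatch(aln); nmm <- Biostrings::nmismatch(aln)
        if (nm + nmm == 0) next
        ident <- nm / (nm + nmm)
        covg <- (nm + nmm) / min(nchar(seqs[[a]]), nchar(seqs[[b]]))
        if (ident > min_identity && covg >= min_coverage) {
          flagged <- union(flagged, c(a, b))
          pairs[[length(pairs) + 1]] <-
            data.frame(tissue = t, gene_up = a, gene_down = b,
                       identity = ident, coverage = covg,
                       stringsAsFactors = FALSE)
        }
      }
    }
    frac[t] <- if (nrow(d)) length(flagged) / length(unique(d$gene)) else NA_real_
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(tissue = character(), gene_up = character(),
                    gene_down = character(), identity = numeric(),
                    coverage = numeric()),
       fraction = frac)
}
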