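## Pool-seq population divergence: uniform-coverage subsampling, SNP calling
## with a MAF gate, SNP-wise heterozygosity-based F_st, median pairwise F_st
## between pools, the combined-ecomorph F_st distribution, and detection of
## alternatively fixed SNPs.

## coverage standardization --------------------------------------------------

# multivariate hypergeometric draw: subsample `n` reads without replacement
# from class counts `x`
rmvhyper1 <- function(x, n) {
  k <- length(x)
  out <- integer(k)
  taken <- 0L
  for (j in seq_len(k - 1)) {
    remaining <- sum(x[(j + 1):k])
    out[j] <- stats::rhyper(1, x[j], remaining, n - taken)
    taken <- taken + out[j]
    if (taken == n) break
  }
  out[k] <- as.integer(n) - sum(out[-k])
  out
}

#' Standardize every pool to a uniform target coverage
#'
#' Emulates subsampling mapped reads without replacement: any site where any
#' pool's coverage (A+T+C+G) is below `target` is removed entirely; at every
#' retained site each pool's nucleotide counts are subsampled to exactly
#' `target` by a multivariate hypergeometric draw. N and deletion counts are
#' dropped during standardization. Subsampling streams are derived per
#' (contig, position, pool), so the result does not depend on site order.
#'
#' @param ps A `pool_sites` object.
#' @param target Target coverage per pool (default 20).
#' @param seed Integer seed for the subsampling streams.
#' @return A `pool_sites` object with uniform coverage (possibly 0 sites).
#' @export
standardize_coverage <- function(ps, target = 20, seed = 1) {
  stopifnot(target >= 1)
  target <- as.integer(target)
  cov <- site_coverage(ps)
  keep <- rowSums(cov < target) == 0
  info <- ps$info[keep, , drop = FALSE]
  cov <- cov[keep, , drop = FALSE]
  counts <- ps$counts[keep, , , drop = FALSE]
  n <- nrow(info); P <- nrow(ps$pools)
  out <- array(0L, dim = c(n, P, 6), dimnames = dimnames(counts))
  if (n == 0) return(pool_sites(info, out, ps$pools))
  nuc <- counts[, , NUCS, drop = FALSE]
  nz <- rowSums(nuc > 0, dims = 2)  # per site x pool: number of observed alleles
  chash <- vapply(unique(info$contig), function(cg) derive_seed(0, cg),
                  integer(1))
  csd <- chash[info$contig]
  with_seed(seed, {
    for (i in seq_len(n)) {
      for (j in seq_len(P)) {
        x <- nuc[i, j, ]
        if (cov[i, j] == target) {
          out[i, j, 1:4] <- x
        } else if (nz[i, j] == 1L) {
          out[i, j, which(x > 0)] <- target  # monomorphic: no randomness needed
        } else {
          set.seed((as.numeric(seed) + as.numeric(csd[i]) * 7919 +
                      info$pos[i] * 131 + j) %% .SEED_MOD)
          out[i, j, 1:4] <- rmvhyper1(x, target)
        }
      }
    }
  })
  pool_sites(info, out, ps$pools)
}

## SNP calling ---------------------------------------------------------------

#' Call biallelic SNPs with a minor-allele-frequency gate
#'
#' Alleles at each site are ranked by their count summed over all pools;
#' reads of the third-ranked and lower alleles are discarded (ties between
#' ranks broken in A < C < G < T order). A site is retained as a biallelic
#' SNP iff its minor-allele frequency over the combined pools is at least
#' `maf_threshold`; monomorphic sites are dropped.
#'
#' @param ps A coverage-standardized `pool_sites` object.
#' @param maf_threshold Minimum combined minor-allele frequency (default 0.10).
#' @return A `snp_table`: list with `snps` (contig, pos, major, minor, maf,
#'   af_snp), matrices `p` (per-pool major-allele frequency), `n_major`,
#'   `n_minor`, and the pool sheet.
#' @export
call_snps <- function(ps, maf_threshold = 0.10) {
  n <- nrow(ps$info)
  if (n == 0) return(empty_snp_table(ps$pools))
  nuc <- ps$counts[, , NUCS, drop = FALSE]
  tot <- apply(nuc, c(1, 3), sum)  # site x 4 combined counts
  # rank alleles: by count desc, ties in A < C < G < T order
  ord <- apply(tot, 1, function(v) order(-v, match(NUCS, c("A", "C", "G", "T"))))
  maj_i <- ord[1, ]; min_i <- ord[2, ]
  maj_cnt <- tot[cbind(seq_len(n), maj_i)]
  min_cnt <- tot[cbind(seq_len(n), min_i)]
  maf <- ifelse(maj_cnt + min_cnt > 0, min_cnt / (maj_cnt + min_cnt), 0)
  keep <- min_cnt > 0 & maf >= maf_threshold
  idx <- which(keep)
  P <- nrow(ps$pools)
  n_major <- n_minor <- matrix(0L, length(idx), P,
                               dimnames = list(NULL, ps$pools$pool))
  for (j in seq_len(P)) {
    n_major[, j] <- nuc[cbind(idx, j, maj_i[idx])]
    n_minor[, j] <- nuc[cbind(idx, j, min_i[idx])]
  }
  denom <- n_major + n_minor
  p <- ifelse(denom > 0, n_major / denom, NA_real_)
  structure(list(
    snps = data.frame(contig = ps$info$contig[idx], pos = ps$info$pos[idx],
                      major = NUCS[maj_i[idx]], minor = NUCS[min_i[idx]],
                      maf = maf[idx], af_snp = NA, stringsAsFactors = FALSE),
    p = p, n_major = n_major, n_minor = n_minor, pools = ps$pools),
    class = "snp_table")
}

empty_snp_table <- function(pools) {
  structure(list(snps = data.frame(contig = character(), pos = integer(),
                                   major = character(), minor = character(),
                                   maf = numeric(), af_snp = logical()),
                 p = matrix(numeric(), 0, nrow(pools),
                            dimnames = list(NULL, pools$pool)),
                 n_major = matrix(integer(), 0, nrow(pools)),
                 n_minor = matrix(integer(), 0, nrow(pools)),
                 pools = pools),
            class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d SNPs x %d pools; %s af-SNPs\n", nrow(x$snps),
              nrow(x$pools),
              if (all(is.na(x$snps$af_snp))) "unflagged" else sum(x$snps$af_snp)))
  invisible(x)
}

## F_st ----------------------------------------------------------------------

#' SNP-wise F_st between two units from major-allele frequencies
#'
#' Classical heterozygosity form: per unit `pi_u = 1 - p^2 - q^2`;
#' `pi_within = (pi_1 + pi_2)/2`; `pi_total` is the heterozygosity at the
#' averaged frequency `(p_1 + p_2)/2`; `fst = (pi_total - pi_within)/pi_total`,
#' defined 0 when `pi_total = 0` (both units monomorphic for the same allele).
#' Vectorized over sites.
#'
#' @param p1,p2 Major-allele frequencies of the two units (vectors in `[0,1]`).
#' @return data.frame with `pi_within`, `pi_total`, `fst`.
#' @export
pairwise_fst <- function(p1, p2) {
  stopifnot(length(p1) == length(p2))
  pi1 <- 2 * p1 * (1 - p1)
  pi2 <- 2 * p2 * (1 - p2)
  pw <- (pi1 + pi2) / 2
  pbar <- (p1 + p2) / 2
  pt <- 2 * pbar * (1 - pbar)
  fst <- ifelse(pt == 0, 0, (pt - pw) / pt)
  data.frame(pi_within = pw, pi_total = pt, fst = fst)
}

#' Median pairwise F_st matrix over pools
#'
#' @param st A `snp_table`.
#' @return Symmetric pool x pool matrix of median SNP-wise F_st (diagonal 0);
#'   a pair with no jointly covered SNP is `NA`.
#' @export
median_fst_matrix <- function(st) {
  P <- nrow(st$pools)
  m <- matrix(0, P, P, dimnames = list(st$pools$pool, st$pools$pool))
  for (a in seq_len(P - 1)) {
    for (b in (a + 1):P) {
      ok <- !is.na(st$p[, a]) & !is.na(st$p[, b])
      m[a, b] <- m[b, a] <-
        if (!any(ok)) NA_real_
        else stats::median(pairwise_fst(st$p[ok, a], st$p[ok, b])$fst)
    }
  }
  m
}

#' F_st distribution between ecomorphs from combined pool counts
#'
#' Pools of each morph are summed per site (e.g. 3 pools x 20x = 60x per
#' morph), the MAF gate is re-applied at the combined level, and SNP-wise
#' F_st is computed between the two combined units.
#'
#' @param st A `snp_table` whose pool sheet carries a `morph` column with two
#'   morphs.
#' @param maf_threshold MAF gate re-applied on combined counts (default 0.10).
#' @return List: `table` (contig, pos, pi_within, pi_total, fst), `median`,
#'   `mean`, and `af_percentile` (the percentile, within this distribution,
#'   below which all non-fixed SNPs fall; descriptive position of the
#'   alternatively fixed class).
#' @export
combined_fst_distribution <- function(st, maf_threshold = 0.10) {
  morphs <- unique(st$pools$morph)
  stopifnot(length(morphs) == 2)
  i1 <- st$pools$morph == morphs[1]
  i2 <- st$pools$morph == morphs[2]
  maj1 <- rowSums(st$n_major[, i1, drop = FALSE])
  min1 <- rowSums(st$n_minor[, i1, drop = FALSE])
  maj2 <- rowSums(st$n_major[, i2, drop = FALSE])
  min2 <- rowSums(st$n_minor[, i2, drop = FALSE])
  tot_min <- min1 + min2
  tot <- maj1 + min1 + maj2 + min2
  maf <- ifelse(tot > 0, pmin(tot_min, maj1 + maj2) / tot, 0)
  keep <- tot > 0 & tot_min > 0 & maf >= maf_threshold
  p1 <- maj1[keep] / (maj1 + min1)[keep]
  p2 <- maj2[keep] / (maj2 + min2)[keep]
  f <- pairwise_fst(p1, p2)
  tab <- cbind(st$snps[keep, c("contig", "pos")], f)
  n_fixed <- sum(f$fst == 1)
  list(table = tab,
       median = stats::median(f$fst),
       mean = mean(f$fst),
       af_percentile = if (nrow(tab) > 0) 100 * (1 - n_fixed / nrow(tab)) else NA_real_)
}

## af-SNP detection ----------------------------------------------------------

#' Flag alternatively fixed SNPs
#'
#' A SNP is alternatively fixed (af-SNP) iff every pool is monomorphic and
#' the two morphs are fixed for different alleles; equivalently, SNP-wise
#' F_st is 0 in every within-morph pool comparison and 1 in every
#' across-morph comparison (the equivalence is exercised by the test suite).
#' Sites not covered in every pool are never flagged.
#'
#' @param st A `snp_table` with a two-morph pool sheet.
#' @return The `snp_table` with its `af_snp` column filled.
#' @export
detect_af_snps <- function(st) {
  morphs <- unique(st$pools$morph)
  stopifnot(length(morphs) == 2)
  i1 <- which(st$pools$morph == morphs[1])
  i2 <- which(st$pools$morph == morphs[2])
  p <- st$p
  if (nrow(p) == 0) {
    st$snps$af_snp <- logical(0)
    return(st)
  }
  mono <- rowSums(is.na(p) | (p != 0 & p != 1)) == 0
  same1 <- apply(p[, i1, drop = FALSE], 1, function(v) length(unique(v)) == 1)
  same2 <- apply(p[, i2, drop = FALSE], 1, function(v) length(unique(v)) == 1)
  diff12 <- p[, i1[1]] != p[, i2[1]]
  st$snps$af_snp <- mono & same1 & same2 & !is.na(diff12) & diff12
  st
}

#' af-SNP flag via the F_st criterion (reference formulation)
#'
#' Direct evaluation of the definition "F_st = 0 in all within-morph pool
#' comparisons and F_st = 1 in all across-morph comparisons". Quadratic in
#' the pool count; used to validate [detect_af_snps()]'s equivalent
#' monomorphic-fixation shortcut.
#'
#' @param st A `snp_table`.
#' @return Logical vector, one flag per SNP.
#' @export
af_snps_by_fst <- function(st) {
  morphs <- unique(st$pools$morph)
  P <- nrow(st$pools)
  n <- nrow(st$snps)
  flag <- rep(TRUE, n)
  for (a in seq_len(P - 1)) {
    for (b in (a + 1):P) {
      f <- pairwise_fst(st$p[, a], st$p[, b])$fst
      want <- if (st$pools$morph[a] == st$pools$morph[b]) 0 else 1
      flag <- flag & !is.na(f) & f == want
    }
  }
  flag
}
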