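# Shared fixture builders and independent oracles.

# Build a pool_sites object from a list of P x 4 (A,T,C,G) count matrices,
# one per site, on a single contig.
build_sites <- function(site_counts, morphs = c("wood", "wood", "wood",
                                                "rock", "rock", "rock")) {
  P <- length(morphs)
  n <- length(site_counts)
  counts <- array(0L, dim = c(n, P, 6))
  for (i in seq_len(n)) counts[i, , 1:4] <- as.integer(site_counts[[i]])
  pools <- data.frame(pool = paste0("p", seq_len(P)), morph = morphs,
                      stringsAsFactors = FALSE)
  pool_sites(data.frame(contig = "t1", pos = seq_len(n),
                        ref = "A", stringsAsFactors = FALSE),
             counts, pools)
}

# one site, every pool monomorphic: wood fixed for `a1`, rock for `a2`
fixed_site <- function(depth = 20, a1 = "A", a2 = "C") {
  m <- matrix(0L, 6, 4, dimnames = list(NULL, c("A", "T", "C", "G")))
  m[1:3, a1] <- depth
  m[4:6, a2] <- depth
  m
}

# Independent two-sided Fisher oracle: hypergeometric enumeration, summing
# outcomes at most as probable as the observed table (R's relative tolerance).
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  pr <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Textbook Pearson chi-squared without continuity correction.
chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - e)^2 / e)
  list(chisq = x2, p = pchisq(x2, df = 1, lower.tail = FALSE))
}

# Brute-force longest-ORF oracle: walk every ATG codon by codon to its first
# in-frame stop; longest complete span wins, leftmost on ties.
orf_oracle <- function(seq, min_len = 30) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (i in seq_len(max(0, n - 2))) {
    if (paste(chars[i:(i + 2)], collapse = "") != "ATG") next
    j <- i
    while (j + 2 <= n) {
      cod <- paste(chars[j:(j + 2)], collapse = "")
      if (cod %in% stops) {
        len <- j + 2 - i + 1
        if (len >= min_len && !any(chars[i:(j + 2)] == "N")) {
          if (is.null(best) || len > best$len) best <- list(start = i, end = j + 2, len = len)
        }
        break
      }
      j <- j + 3
    }
  }
  best
}

# small sample sheet for one tissue, 3 + 3 pools
one_tissue_sheet <- function(tissue = "radula") {
  data.frame(sample = paste0("s", 1:6),
             morph = rep(c("wood", "rock"), each = 3),
             tissue = tissue, pool = rep(1:3, 2), stringsAsFactors = FALSE)
}
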