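test_that("coverage standardization subsamples to the target and drops thin sites", {
  # site 1: coverage 25 -> subsampled to 20; site 2: one pool at 19 -> removed;
  # site 3: exactly 20 everywhere -> unchanged
  s1 <- matrix(0L, 6, 4, dimnames = list(NULL, c("A","T","C","G")))
  s1[, "A"] <- 20L; s1[, "C"] <- 5L
  s2 <- s1; s2[3, ] <- 0L; s2[3, "A"] <- 19L
  s3 <- matrix(0L, 6, 4, dimnames = list(NULL, c("A","T","C","G")))
  s3[, "A"] <- 12L; s3[, "G"] <- 8L
  ps <- build_sites(list(s1, s2, s3))
  std <- standardize_coverage(ps, target = 20, seed = 11)
  expect_identical(std$info$pos, c(1L, 3L))
  expect_true(all(site_coverage(std) == 20))
  # subsample of a 25-deep A/C site keeps 15..20 A reads
  expect_true(all(std$counts[1, , "A"] >= 15 & std$counts[1, , "A"] <= 20))
  # coverage-20 site passes through untouched
  expect_identical(std$counts[2, , 1:4], ps$counts[3, , 1:4])
})

test_that("subsampled counts never exceed originals and are seed-stable", {
  set.seed(33)
  sites <- replicate(40, {
    m <- matrix(rpois(24, 8), 6, 4)
    m[, 1] <- m[, 1] + 20L
    m
  }, simplify = FALSE)
  ps <- build_sites(sites)
  a <- standardize_coverage(ps, 20, seed = 5)
  b <- standardize_coverage(ps, 20, seed = 5)
  expect_identical(a$counts, b$counts)
  kept <- match(paste(a$info$contig, a$info$pos), paste(ps$info$contig, ps$info$pos))
  expect_true(all(a$counts[, , 1:4] <= ps$counts[kept, , 1:4]))
  expect_true(all(site_coverage(a) == 20))
})

test_that("subsampling streams do not depend on site order", {
  set.seed(7)
  sites <- replicate(10, matrix(rpois(24, 30), 6, 4), simplify = FALSE)
  ps <- build_sites(sites)
  rev_ps <- pool_sites(ps$info[10:1, ], ps$counts[10:1, , ], ps$pools)
  a <- standardize_coverage(ps, 20, seed = 9)
  b <- standardize_coverage(rev_ps, 20, seed = 9)
  ord <- match(paste(a$info$pos), paste(b$info$pos))
  expect_identical(a$counts, b$counts[ord, , , drop = FALSE])
})

test_that("SNP calling applies the MAF gate at the combined-pool level", {
  mk <- function(a, c) {
    m <- matrix(0L, 6, 4, dimnames = list(NULL, c("A","T","C","G")))
    m[, "A"] <- as.integer(a / 6); m[, "C"] <- as.integer(c / 6)
    m
  }
  # combined 108/12 -> MAF exactly 10%, kept (boundary is >=);
  # 114/6 -> 5%, dropped; monomorphic dropped
  ps <- build_sites(list(mk(108, 12), mk(114, 6), mk(120, 0)))
  st <- call_snps(ps, maf_threshold = 0.10)
  expect_identical(nrow(st$snps), 1L)
  expect_identical(st$snps$pos, 1L)
  expect_equal(st$snps$maf, 0.1)
  expect_identical(st$snps$major, "A")
  expect_identical(st$snps$minor, "C")
})

test_that("third-ranked alleles are demoted and their reads discarded", {
  m <- matrix(0L, 6, 4, dimnames = list(NULL, c("A","T","C","G")))
  m[, "A"] <- 17L; m[, "C"] <- 2L; m[, "G"] <- 1L  # 102 A, 12 C, 6 G combined
  st <- call_snps(build_sites(list(m)), maf_threshold = 0.10)
  expect_identical(st$snps$major, "A")
  expect_identical(st$snps$minor, "C")
  expect_equal(st$snps$maf, 12 / 114)   # G reads excluded from the denominator
  expect_true(all(st$n_major[1, ] + st$n_minor[1, ] == 19L))
})

test_that("F_st components match the heterozygosity formulas", {
  # hand-evaluated: p1 = 0.75, p2 = 0.25
  f <- pairwise_fst(0.75, 0.25)
  expect_equal(f$pi_within, 0.375)
  expect_equal(f$pi_total, 0.5)
  expect_equal(f$fst, 0.25)
  # endpoints are exact
  expect_identical(pairwise_fst(1, 0)$fst, 1)
  expect_identical(pairwise_fst(0.5, 0.5)$fst, 0)
  expect_identical(pairwise_fst(1, 1)$fst, 0)
})

test_that("estimator agrees with an independent formula evaluation on 1000 sites", {
  set.seed(202)
  p1 <- round(runif(1000, 0, 1), 3)
  p2 <- round(runif(1000, 0, 1), 3)
  got <- pairwise_fst(p1, p2)
  # independent oracle, written from the definition
  h <- function(p) 1 - p^2 - (1 - p)^2
  hs <- (h(p1) + h(p2)) / 2
  ht <- h((p1 + p2) / 2)
  exp_fst <- ifelse(ht == 0, 0, (ht - hs) / ht)
  expect_lt(max(abs(got$fst - exp_fst)), 1e-12)
  expect_lt(max(abs(got$pi_within - hs)), 1e-12)
  expect_lt(max(abs(got$pi_total - ht)), 1e-12)
})

test_that("median F_st matrix is symmetric with zero diagonal and right medians", {
  st <- call_snps(build_sites(list(fixed_site(20, "A", "C"),
                                   fixed_site(20, "A", "G"),
                                   fixed_site(20, "T", "C"))))
  m <- median_fst_matrix(st)
  expect_identical(unname(diag(m)), rep(0, 6))
  expect_identical(m, t(m))
  expect_true(all(m[1:3, 4:6] == 1))   # across-morph comparisons all fixed
  expect_true(all(m[1:3, 1:3][upper.tri(m[1:3, 1:3])] == 0))
  # median over {0.1, 0.2, 0.9}-style mixtures: direct check on frequencies
  p <- cbind(c(0.9, 0.8, 0.1), c(0.6, 0.6, 0.05))
  f <- pairwise_fst(p[, 1], p[, 2])$fst
  st2 <- st; st2$p <- cbind(p, p, p)  # 6 pools, 3 SNPs
  m2 <- median_fst_matrix(st2)
  expect_equal(m2[1, 2], median(f))
})

test_that("combined-morph F_st uses summed counts at 60x and re-applies MAF", {
  st <- detect_af_snps(call_snps(build_sites(list(fixed_site(20)))))
  cmb <- combined_fst_distribution(st)
  expect_identical(nrow(cmb$table), 1L)
  expect_identical(cmb$table$fst, 1)
  expect_identical(cmb$median, 1)
  # identical pools give fst 0
  m <- matrix(0L, 6, 4); m[, 1] <- 10L; m[, 3] <- 10L
  st0 <- call_snps(build_sites(list(m)))
  expect_identical(combined_fst_distribution(st0)$median, 0)
})

test_that("combined F_st is near zero when all variation is shared", {
  cfg <- sim_config(n_genes = 60, seed = 31, af_snp_fraction = 0,
                    shared_maf_beta = c(2, 2))
  ps <- simulate_pool_alleles(cfg, simulate_transcripts(cfg))
  std <- standardize_coverage(ps, 20, seed = 1)
  st <- call_snps(std)
  cmb <- combined_fst_distribution(st)
  expect_gt(nrow(cmb$table), 200)
  expect_lt(cmb$median, 0.02)  # binomial sampling noise only
})

test_that("af-SNP detector: definition, counterexamples, and F_st equivalence", {
  near_fixed <- fixed_site(20)
  near_fixed[1, "A"] <- 19L; near_fixed[1, "C"] <- 1L  # one wood pool 19:1
  shared <- matrix(0L, 6, 4); shared[, 1] <- 10L; shared[, 3] <- 10L
  st <- detect_af_snps(call_snps(build_sites(list(fixed_site(20), near_fixed, shared))))
  expect_identical(st$snps$af_snp, c(TRUE, FALSE, FALSE))
  # fst-criterion formulation agrees
  expect_identical(unname(af_snps_by_fst(st)), st$snps$af_snp)
})

test_that("detector and F_st criterion agree across random and planted sites", {
  cfg <- sim_config(n_genes = 50, seed = 77, af_snp_fraction = 0.1)
  ps <- simulate_pool_alleles(cfg, simulate_transcripts(cfg))
  std <- standardize_coverage(ps, 20, seed = 2)
  st <- detect_af_snps(call_snps(std))
  expect_identical(unname(af_snps_by_fst(st)), st$snps$af_snp)
  expect_gt(sum(st$snps$af_snp), 0)
})

test_that("planted af-SNPs raise across-morph divergence above within-morph", {
  # all non-planted variation is shared (one frequency per site for both
  # morphs), so within- and across-morph pool pairs face identically
  # distributed sampling noise; the planted 1% af-SNP mass is the only
  # systematic across-morph signal. It shifts pair means robustly, and pair
  # medians weakly (the median moves by less than one quantile step).
  cfg <- sim_config(n_genes = 400, seed = 55, af_snp_fraction = 0.01)
  ps <- simulate_pool_alleles(cfg, simulate_transcripts(cfg))
  std <- standardize_coverage(ps, 20, seed = 3)
  st <- call_snps(std)
  wood <- which(st$pools$morph == "wood")
  rock <- which(st$pools$morph == "rock")
  pair_mean <- function(a, b) {
    ok <- !is.na(st$p[, a]) & !is.na(st$p[, b])
    mean(pairwise_fst(st$p[ok, a], st$p[ok, b])$fst)
  }
  within <- c(apply(utils::combn(wood, 2), 2, function(x) pair_mean(x[1], x[2])),
              apply(utils::combn(rock, 2), 2, function(x) pair_mean(x[1], x[2])))
  across <- as.numeric(outer(wood, rock, Vectorize(pair_mean)))
  expect_gt(min(across), max(within))
  m <- median_fst_matrix(st)
  med_within <- c(m[wood, wood][upper.tri(m[wood, wood])],
                  m[rock, rock][upper.tri(m[rock, rock])])
  med_across <- as.numeric(m[wood, rock])
  expect_gte(median(med_across), median(med_within))
})

test_that("adding an af-SNP never decreases the across-morph median", {
  set.seed(404)
  sites <- replicate(101, matrix(rpois(24, 30), 6, 4), simplify = FALSE)
  ps <- build_sites(sites)
  std <- standardize_coverage(ps, 20, seed = 4)
  st <- call_snps(std)
  cmb0 <- combined_fst_distribution(st)
  with_af <- build_sites(c(sites, list(fixed_site(20))))
  std2 <- standardize_coverage(with_af, 20, seed = 4)
  cmb1 <- combined_fst_distribution(call_snps(std2))
  expect_gte(cmb1$median, cmb0$median)
})
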