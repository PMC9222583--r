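test_that("library-size normalization: identical, scaled, and planted-DE samples", {
  set.seed(5)
  mu <- rlnorm(400, log(100), 1)
  a <- rpois(400, mu)
  y <- cbind(s1 = a, s2 = a)
  rownames(y) <- sprintf("g%03d", 1:400)
  ls <- normalize_libsizes(y)
  expect_equal(ls[["s1"]], ls[["s2"]])

  y2 <- cbind(s1 = a + 1L, s2 = 2L * (a + 1L))
  ls2 <- normalize_libsizes(y2)
  expect_equal(ls2[["s2"]] / ls2[["s1"]], 2, tolerance = 1e-12)

  # 5% of genes strongly up in sample 2 must not drag the size factor
  y3 <- y2
  y3[1:20, "s2"] <- y3[1:20, "s2"] * 50L
  ls3 <- normalize_libsizes(y3)
  lr <- log2(y3[-(1:20), "s2"] / ls3[["s2"]]) - log2(y3[-(1:20), "s1"] / ls3[["s1"]])
  expect_lt(abs(median(lr)), 0.05)

  expect_error(normalize_libsizes(cbind(a, rep(0L, 400))), "all-zero")
})

test_that("dispersion estimation: Poisson, NB, and constant counts", {
  set.seed(6)
  n <- 5000
  mu <- rlnorm(n, log(100), 1)
  yp <- matrix(rpois(n * 6, rep(mu, 6)), n, 6)
  expect_lte(estimate_dispersion(yp, normalize_libsizes(yp)), 0.02)

  ynb <- matrix(rnbinom(n * 6, mu = rep(mu, 6), size = 5), n, 6)
  phi <- estimate_dispersion(ynb, normalize_libsizes(ynb))
  expect_gt(phi, 0.2 * 0.7)
  expect_lt(phi, 0.2 * 1.3)

  yc <- matrix(50L, 100, 4)
  expect_identical(estimate_dispersion(yc, rep(200, 4)), 0)
  expect_error(estimate_dispersion(matrix(1L, 10, 4), rep(10, 4)), "mean >= 5")
})

test_that("exact test: symmetry, strong signal, and the enumeration oracle", {
  expect_identical(nb_exact_test(c(10, 12, 11), c(11, 12, 10), 0.05)$p, 1)
  expect_identical(nb_exact_test(c(0, 0, 0), c(0, 0, 0), 0.1),
                   list(p = 1, log2fc = 0))

  r <- nb_exact_test(c(100, 100, 100), c(800, 800, 800), 0.01)
  expect_lt(r$p, 1e-10)
  expect_equal(r$log2fc, 3, tolerance = 0.01)
  expect_gt(nb_exact_test(c(0, 0, 0), c(50, 60, 55), 0.1)$log2fc, 0)
  expect_lt(nb_exact_test(c(50, 60, 55), c(0, 0, 0), 0.1)$log2fc, 0)

  # oracle: build each group-sum pmf by explicit per-sample convolution,
  # then apply the doubled-tail rule on the conditional split distribution
  conv_pmf <- function(n_s, phi, m, tmax) {
    f <- dnbinom(0:tmax, size = 1 / phi, mu = m)
    g <- f
    for (i in seq_len(n_s - 1)) {
      g <- convolve(g, rev(f), type = "open")[1:(tmax + 1)]
    }
    g
  }
  set.seed(77)
  for (i in 1:20) {
    y1 <- rnbinom(3, mu = 30, size = 10)
    y2 <- rnbinom(3, mu = 60, size = 10)
    phi <- 0.1
    T <- sum(y1, y2)
    m <- T / 6
    f1 <- conv_pmf(3, phi, m, T)
    f2 <- conv_pmf(3, phi, m, T)
    joint <- f1 * rev(f2)
    joint <- joint / sum(joint)
    s1 <- sum(y1)
    p_oracle <- min(1, 2 * min(sum(joint[1:(s1 + 1)]), sum(joint[(s1 + 1):(T + 1)])))
    got <- nb_exact_test(y1, y2, phi)
    expect_equal(got$p, p_oracle, tolerance = 1e-8)
  }
})

test_that("tier classification enforces both the FDR and fold-change gates", {
  grid <- expand.grid(fdr = c(1e-12, 1e-11, 1e-9, 1e-3, 5e-2, 0.5),
                      afc = c(3, 3.9, 4, 6, 20))
  de <- data.frame(gene = sprintf("g%02d", seq_len(nrow(grid))),
                   tissue = sprintf("t%02d", seq_len(nrow(grid))),  # fdr == p
                   log2fc = log2(grid$afc) * rep_len(c(1, -1), nrow(grid)),
                   p = grid$fdr, stringsAsFactors = FALSE)
  got <- classify_tiers(de)
  expect_equal(got$fdr, got$p)
  want <- ifelse(grid$afc < 4, "none",
                 ifelse(grid$fdr <= 1e-10, "highlyDE",
                        ifelse(grid$fdr <= 1e-2, "DE", "none")))
  expect_identical(got$tier, want)
  # highlyDE implies the DE thresholds: nesting by construction
  expect_true(all(got$fdr[got$tier == "highlyDE"] <= 1e-2))
})

test_that("BH adjustment is per tissue and monotone in p", {
  set.seed(8)
  de <- data.frame(gene = rep(sprintf("g%03d", 1:100), 3),
                   tissue = rep(c("radula", "mantle", "foot"), each = 100),
                   log2fc = 0, p = runif(300))
  got <- classify_tiers(de)
  for (t in unique(de$tissue)) {
    d <- got[got$tissue == t, ]
    expect_equal(d$fdr, p.adjust(d$p, "BH"))
    o <- order(d$p)
    expect_true(all(diff(d$fdr[o]) >= -1e-15))
  }
})

test_that("FPKM formula and expression flags", {
  sheet <- one_tissue_sheet()
  y <- matrix(0L, 3, 6, dimnames = list(c("g1", "g2", "g3"), sheet$sample))
  y["g1", ] <- 10L; y["g3", ] <- 5L
  lens <- c(g1 = 1000, g2 = 1000, g3 = 500)
  fp <- fpkm_summary(y, lens, sheet, libsizes = rep(1e6, 6))
  expect_equal(unname(fp$fpkm["g1", 1]), 10)
  expect_equal(unname(fp$fpkm["g3", 1]), 10)   # 5 / (0.5 kb x 1 M)
  fp2 <- fpkm_summary(y, lens, sheet, libsizes = rep(5e5, 6))
  expect_equal(unname(fp2$fpkm["g3", 1]), 20)  # 5 / (0.5 kb x 0.5 M)
  s <- fp$summary
  expect_true(all(s$expressed[s$gene == "g1"]))
  expect_false(any(s$expressed[s$gene == "g2"]))
  expect_identical(expressed_genes(s, "radula"), c("g1", "g3"))
  expect_identical(expressed_genes(s, "radula", both_morphs = TRUE), c("g1", "g3"))
})

test_that("mapping-bias Fisher test matches the hypergeometric oracle", {
  af <- rep(c(TRUE, FALSE), c(100, 100))
  de <- c(rep(c(TRUE, FALSE), c(20, 80)), rep(c(TRUE, FALSE), c(5, 95)))
  got <- mapping_bias_test(de, af)
  expect_equal(got$p, fisher_oracle(matrix(c(20, 5, 80, 95), 2)), tolerance = 1e-12)
  # equal proportions give p = 1
  de2 <- rep(rep(c(TRUE, FALSE), c(10, 90)), 2)
  expect_equal(mapping_bias_test(de2, af)$p, 1)
  expect_warning(mapping_bias_test(rep(TRUE, 200), af), "degenerate")
})

test_that("mapping-bias p-values are uniform when the flags are independent", {
  set.seed(9)
  ps <- replicate(300, {
    af <- runif(400) < 0.2
    de <- runif(400) < 0.15
    mapping_bias_test(de, af)$p
  })
  # Fisher p-values are discrete and conservative: the empirical cdf must not
  # exceed the uniform cdf by more than sampling noise at any level
  for (q in c(0.01, 0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(ps <= q), q + 3 * sqrt(q * (1 - q) / length(ps)))
  # and the p-values are not degenerate: small values do occur
  expect_gt(mean(ps <= 0.5), 0.2)
})

test_that("allele-collapse check flags near-identical opposite pairs only", {
  set.seed(10)
  base <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  mutate <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(seq_along(ch), n)
    ch[at] <- vapply(ch[at], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
    paste(ch, collapse = "")
  }
  seqs <- c(up1 = base, down1 = mutate(base, 12),      # ~98% identity
            up2 = paste(sample(c("A","C","G","T"), 600, TRUE), collapse = ""),
            down2 = paste(sample(c("A","C","G","T"), 600, TRUE), collapse = ""))
  de_high <- data.frame(gene = names(seqs), tissue = "radula",
                        log2fc = c(3, -3, 4, -4), stringsAsFactors = FALSE)
  got <- allele_collapse_check(seqs, de_high)
  expect_true(any(got$pairs$gene_up == "up1" & got$pairs$gene_down == "down1"))
  expect_false(any(got$pairs$gene_up == "up2" & got$pairs$gene_down == "down2"))
  expect_equal(unname(got$fraction["radula"]), 0.5)
  # identical sequences with opposite direction are always flagged
  got2 <- allele_collapse_check(c(a = base, b = base),
                                data.frame(gene = c("a", "b"), tissue = "foot",
                                           log2fc = c(2.5, -2.5)))
  expect_identical(nrow(got2$pairs), 1L)
  expect_equal(got2$pairs$identity, 1)
})
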