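# compact tiered-DE table builder
de_row <- function(gene, tissue, tier = "none", log2fc = 3, p = 1e-4,
                   fdr = switch(tier, highlyDE = 1e-12, DE = 1e-3, 0.5)) {
  data.frame(gene = gene, tissue = tissue, log2fc = log2fc, p = p,
             fdr = fdr, tier = tier, stringsAsFactors = FALSE)
}

expr_rows <- function(genes, tissues = c("radula", "mantle", "foot")) {
  do.call(rbind, lapply(tissues, function(t)
    do.call(rbind, lapply(c("wood", "rock"), function(m)
      data.frame(gene = genes, tissue = t, morph = m, mean_fpkm = 5,
                 expressed = TRUE, stringsAsFactors = FALSE)))))
}

test_that("universal sets collect genes DE in all three tissues only", {
  de <- rbind(de_row("g1", "radula", "DE"), de_row("g1", "mantle", "DE"),
              de_row("g1", "foot", "highlyDE"),
              de_row("g2", "radula", "DE"), de_row("g2", "mantle", "DE"),
              de_row("g2", "foot"),
              de_row("g3", "radula", "highlyDE"), de_row("g3", "mantle", "highlyDE"),
              de_row("g3", "foot", "highlyDE"))
  u <- universal_sets(de)
  expect_setequal(u$universal_de, c("g1", "g3"))
  expect_identical(u$universal_highly_de, "g3")
  e <- universal_sets(de[0, ])
  expect_length(e$universal_de, 0)
})

test_that("tissue proportions exclude universal genes from both sides", {
  genes <- sprintf("g%02d", 1:40)
  # g01 universally DE; g02 DE in radula only
  de <- rbind(de_row("g01", "radula", "DE"), de_row("g01", "mantle", "DE"),
              de_row("g01", "foot", "DE"), de_row("g02", "radula", "DE"))
  de <- rbind(de, do.call(rbind, lapply(setdiff(genes, c("g01", "g02")),
                                        function(g) de_row(g, "radula"))))
  es <- expr_rows(genes)
  u <- universal_sets(de)
  pr <- tissue_de_proportions(de, es, u)
  rad <- pr$per_tissue[pr$per_tissue$tissue == "radula" &
                         pr$per_tissue$tier == "DE", ]
  expect_identical(rad$n_expressed, 39L)   # g01 excluded from the denominator
  expect_identical(rad$n_de, 1L)           # only g02 counts
  # introducing a brand-new universally DE gene changes no tissue proportion
  de2 <- rbind(de, de_row("g41", "radula", "DE"), de_row("g41", "mantle", "DE"),
               de_row("g41", "foot", "DE"))
  es2 <- rbind(es, expr_rows("g41"))
  pr2 <- tissue_de_proportions(de2, es2, universal_sets(de2))
  expect_equal(pr2$per_tissue$proportion, pr$per_tissue$proportion)
  # identical proportions give percent difference 0 and p = 1
  same <- pr2$pairwise[pr2$pairwise$tier == "DE" &
                         pr2$pairwise$tissue_a == "mantle", ]
  expect_equal(same$percent_difference, 0)
  expect_equal(same$p, 1)
})

test_that("pairwise tissue Fisher tests match the hypergeometric oracle", {
  genes <- sprintf("g%03d", 1:200)
  de <- rbind(do.call(rbind, lapply(genes[1:30], function(g) de_row(g, "radula", "DE"))),
              do.call(rbind, lapply(genes[1:8], function(g) de_row(g, "mantle", "DE"))),
              do.call(rbind, lapply(genes, function(g) de_row(g, "foot"))))
  pr <- tissue_de_proportions(de, expr_rows(genes), universal_sets(de))
  rm <- pr$pairwise[pr$pairwise$tier == "DE" & pr$pairwise$tissue_a == "radula" &
                      pr$pairwise$tissue_b == "mantle", ]
  expect_equal(rm$p, fisher_oracle(matrix(c(30, 8, 170, 192), 2)), tolerance = 1e-12)
  expect_equal(rm$percent_difference, (30 / 200 - 8 / 200) / (8 / 200) * 100)
})

test_that("af-SNP frequencies use non-universally expressed denominators", {
  genes <- sprintf("g%02d", 1:30)
  es <- expr_rows(genes)
  # g01..g05 radula-only, g06..g08 mantle-only, g09..g10 foot-only;
  # everything else universally expressed
  es$expressed[es$gene %in% genes[1:5] & es$tissue != "radula"] <- FALSE
  es$expressed[es$gene %in% genes[6:8] & es$tissue != "mantle"] <- FALSE
  es$expressed[es$gene %in% genes[9:10] & es$tissue != "foot"] <- FALSE
  af <- data.frame(contig = c("g01", "g01", "g02", "g10"), pos = c(5L, 9L, 3L, 7L))
  eff <- data.frame(contig = af$contig, pos = af$pos, location = "coding",
                    effect = c("non-synonymous", "synonymous",
                               "non-synonymous", "synonymous"),
                    stringsAsFactors = FALSE)
  fr <- tissue_afsnp_frequency(af, eff, es)
  rad <- fr$per_tissue[fr$per_tissue$tissue == "radula", ]
  expect_identical(rad$n_genes, rep(5L, 3))          # universal genes excluded
  expect_identical(rad$n_af_snps[rad$scope == "all"], 3L)   # g10 is universal
  expect_identical(rad$n_bearing[rad$scope == "all"], 2L)
  expect_identical(rad$n_af_snps[rad$scope == "nonsynonymous"], 2L)
  # no af-SNPs at all: frequencies 0, Fisher p 1
  fr0 <- tissue_afsnp_frequency(af[0, ], eff[0, ], es)
  expect_true(all(fr0$per_tissue$frequency == 0))
  expect_true(all(fr0$pairwise$p == 1))
  expect_true(all(fr0$pairwise$percent_difference == 0))
  # all genes universally expressed: report empty with warnings (one per
  # tissue and scope)
  w <- capture_warnings(out <- tissue_afsnp_frequency(af, eff, expr_rows(genes)))
  expect_gt(length(w), 0)
  expect_true(all(grepl("universally expressed", w)))
  expect_null(out$per_tissue)
})

test_that("top-quantile composition: shares, ties, and cut arithmetic", {
  set.seed(11)
  de <- data.frame(gene = rep(sprintf("g%03d", 1:100), 3),
                   tissue = rep(c("radula", "mantle", "foot"), each = 100),
                   log2fc = rnorm(300), p = runif(300))
  tq <- top_quantile_composition(de, fractions = 0.01)
  expect_identical(sum(tq$n), 3L)  # top 1% of 300 entries is exactly 3
  expect_equal(sum(tq$share), 1, tolerance = 1e-12)
  # a tissue with stochastically smaller p dominates the top fraction
  de$p[de$tissue == "radula"] <- de$p[de$tissue == "radula"] / 50
  tq2 <- top_quantile_composition(de, fractions = 0.05)
  expect_gt(tq2$share[tq2$tissue == "radula"], 1 / 3)
  expect_equal(sum(tq2$share), 1, tolerance = 1e-12)
  expect_warning(top_quantile_composition(de[1:20, ], fractions = 0.01), "fewer")
})

test_that("highly-DE x af-SNP overlap counts and exclusivity", {
  genes <- sprintf("g%02d", 1:20)
  de <- rbind(de_row("g01", "radula", "highlyDE"),
              de_row("g02", "radula", "highlyDE"),
              de_row("g02", "mantle", "highlyDE"),
              de_row("g03", "mantle", "highlyDE"),
              de_row("g04", "foot"))  # keeps foot in the tissue universe
  af <- data.frame(contig = c("g01", "g02"), pos = c(4L, 6L))
  eff <- data.frame(contig = af$contig, pos = af$pos, location = "coding",
                    effect = c("non-synonymous", "synonymous"),
                    stringsAsFactors = FALSE)
  ov <- de_afsnp_overlap(de, af, eff, expr_rows(genes), universal_sets(de))
  rad <- ov$per_tissue[ov$per_tissue$tissue == "radula", ]
  expect_identical(rad$n_overlap, 2L)
  expect_identical(rad$n_overlap_exclusive, 1L)  # g02 also highly DE in mantle
  expect_identical(rad$n_nonsynonymous, 1L)
  expect_identical(rad$n_synonymous, 1L)
  # disjoint sets give zero overlap
  ov0 <- de_afsnp_overlap(de, data.frame(contig = "g19", pos = 1L), eff[0, ],
                          expr_rows(genes), universal_sets(de))
  expect_true(all(ov0$per_tissue$n_overlap == 0))
})
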