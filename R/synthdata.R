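## Synthetic-data generator: transcripts with planted ORFs, pool-seq allele
## counts with planted alternatively fixed SNPs, negative-binomial expression
## with planted fold changes, and landmark configurations with a planted
## mean-shape displacement. Every generator records its ground truth so the
## downstream detectors can be scored exactly.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic study design. Defaults emulate the
#' pooled-transcriptome design the pipeline targets: two ecomorphs (wood,
#' rock) x three tissues (radula, mantle, foot) x three pools per morph,
#' pool-seq allele counts at Poisson depth around `mean_coverage`, and 37
#' landmarked specimens (19 from wood, 18 from rock substrate).
#'
#' @param n_genes Number of genes/transcripts.
#' @param n_pools_per_morph Pools per ecomorph (>= 2).
#' @param tissues Three tissue labels.
#' @param mean_coverage Expected reads per site per pool (Poisson depth).
#' @param nb_dispersion Negative-binomial dispersion phi (>= 0; 0 = Poisson).
#' @param baseline_log_expression Named vector `c(meanlog, sdlog)` of the
#'   per-gene log expression mean.
#' @param tissue_effect_sd SD of the per-gene, per-tissue log-expression shift.
#' @param de_fraction_per_tissue Fraction of genes planted DE per tissue.
#' @param universal_de_fraction Fraction planted DE in all tissues.
#' @param planted_log2fc Planted log2 fold change (rock vs wood) for DE genes.
#' @param expression_cap Upper cap on the expected count of a gene in one
#'   sample; bounds the dynamic range of the generator.
#' @param snp_rate_per_kb Expected biallelic SNPs per kb of transcript.
#' @param af_snp_fraction Fraction of SNPs planted alternatively fixed.
#' @param shared_maf_beta Beta(a, b) parameters for the shared-variation
#'   allele frequency (one frequency per site, common to both morphs).
#' @param monomorphic_rate_per_kb Expected monomorphic filler sites per kb.
#' @param transcript_length Named vector `c(meanlog, sdlog)` of log-normal
#'   transcript lengths (nt).
#' @param orf_fraction Fraction of each transcript covered by its planted ORF.
#' @param min_orf_nt Minimum ORF length in nucleotides (start + stop included).
#' @param landmark_n Landmarks per specimen (>= 3).
#' @param n_specimens_per_substrate Named counts `c(wood=, rock=)`.
#' @param morph_concordance Probability a specimen's radula morph matches its
#'   substrate.
#' @param shape_effect Radial mean-shape displacement of the rock morph.
#' @param shape_noise_sd Isotropic per-landmark Gaussian noise SD.
#' @param seed Integer seed fixing all generator output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_pools_per_morph = 3,
                       tissues = c("radula", "mantle", "foot"),
                       mean_coverage = 30,
                       nb_dispersion = 0.1,
                       baseline_log_expression = c(meanlog = log(20), sdlog = 2.5),
                       tissue_effect_sd = 2,
                       de_fraction_per_tissue = 0.05,
                       universal_de_fraction = 0.01,
                       planted_log2fc = 3,
                       expression_cap = 2e4,
                       snp_rate_per_kb = 10,
                       af_snp_fraction = 0.012,
                       shared_maf_beta = c(2, 2),
                       monomorphic_rate_per_kb = 20,
                       transcript_length = c(meanlog = log(900), sdlog = 0.25),
                       orf_fraction = 0.6,
                       min_orf_nt = 30,
                       landmark_n = 12,
                       n_specimens_per_substrate = c(wood = 19, rock = 18),
                       morph_concordance = 0.9,
                       shape_effect = 0.15,
                       shape_noise_sd = 0.02,
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fr <- c("de_fraction_per_tissue", "universal_de_fraction", "af_snp_fraction",
          "orf_fraction", "morph_concordance")
  for (f in fr) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stopf("%s must lie in [0, 1]", f)
  }
  if (cfg$n_genes < 1) stopf("n_genes must be >= 1")
  if (cfg$n_pools_per_morph < 2) stopf("n_pools_per_morph must be >= 2")
  if (length(cfg$tissues) != 3) stopf("exactly three tissues are expected")
  if (cfg$mean_coverage <= 0) stopf("mean_coverage must be positive")
  if (cfg$nb_dispersion < 0) stopf("nb_dispersion must be >= 0")
  if (cfg$landmark_n < 3) stopf("landmark_n must be >= 3")
  if (any(cfg$shared_maf_beta <= 0)) stopf("shared_maf_beta must be positive")
  # an ORF needs start + stop: reject configs whose shortest plausible
  # transcript cannot host a >= min_orf_nt ORF
  min_len <- exp(cfg$transcript_length[["meanlog"]] -
                   4 * cfg$transcript_length[["sdlog"]])
  if (min_len * cfg$orf_fraction < cfg$min_orf_nt)
    stopf("orf_fraction too small: planted ORFs could be < %d nt", cfg$min_orf_nt)
  invisible(cfg)
}

.STOPS <- c("TAA", "TAG", "TGA")

# all complete ATG..stop spans (first in-frame stop), used to guarantee that
# the planted ORF is the unique longest one on each synthetic transcript
.orf_spans <- function(chars) {
  n <- length(chars)
  out <- NULL
  for (f in 0:2) {
    starts <- seq.int(1L + f, n - 2L, by = 3L)
    if (length(starts) == 0) next
    cod <- paste0(chars[starts], chars[starts + 1], chars[starts + 2])
    atg <- which(cod == "ATG")
    stp <- which(cod %in% .STOPS)
    if (length(atg) == 0 || length(stp) == 0) next
    nxt <- findInterval(atg, stp) + 1L
    ok <- nxt <= length(stp)
    if (!any(ok)) next
    s <- starts[atg[ok]]
    e <- starts[stp[nxt[ok]]] + 2L
    out <- rbind(out, cbind(start = s, end = e))
  }
  out
}

.rand_codons <- function(n) {
  # interior codons: any codon except a stop
  all64 <- apply(expand.grid(NUCS, NUCS, NUCS, stringsAsFactors = FALSE),
                 1, paste0, collapse = "")
  sample(setdiff(all64, .STOPS), n, replace = TRUE)
}

#' Simulate transcripts with one planted ORF each
#'
#' Each transcript carries exactly one complete open reading frame
#' (ATG ... stop, length a multiple of 3) covering roughly `orf_fraction` of
#' its length, embedded in random flanking sequence. Flanks are re-drawn until
#' the planted ORF is the unique longest complete ORF on the transcript, so
#' the recorded coordinates are unambiguous ground truth for the ORF finder.
#'
#' @param config A [sim_config()].
#' @return List with `sequences` (named character vector) and `orfs`
#'   (data.frame: transcript, start, end; 1-based inclusive).
#' @export
simulate_transcripts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "transcripts"), {
    n <- config$n_genes
    ids <- sprintf("g%05d", seq_len(n))
    lens <- pmax(90L, as.integer(round(stats::rlnorm(
      n, config$transcript_length[["meanlog"]],
      config$transcript_length[["sdlog"]]))))
    seqs <- character(n)
    orf_start <- integer(n)
    orf_end <- integer(n)
    for (i in seq_len(n)) {
      len <- lens[i]
      n_cod <- max(10L, as.integer(len * config$orf_fraction) %/% 3L)
      orf_nt <- 3L * n_cod
      if (orf_nt < config$min_orf_nt)
        stopf("orf_fraction yields an ORF of %d nt (< %d) for a %d nt transcript",
              orf_nt, config$min_orf_nt, len)
      rest <- len - orf_nt
      for (try in 1:100) {
        orf <- c("ATG", .rand_codons(n_cod - 2L), sample(.STOPS, 1))
        up <- sample(0:rest, 1)
        flank5 <- sample(NUCS, up, replace = TRUE)
        flank3 <- sample(NUCS, rest - up, replace = TRUE)
        chars <- c(flank5, unlist(strsplit(orf, "")), flank3)
        spans <- .orf_spans(chars)
        lens_sp <- spans[, "end"] - spans[, "start"] + 1L
        longest <- max(lens_sp)
        planted <- which(spans[, "start"] == up + 1L & spans[, "end"] == up + orf_nt)
        if (length(planted) == 1 && lens_sp[planted] == longest &&
            sum(lens_sp == longest) == 1) {
          seqs[i] <- paste(chars, collapse = "")
          orf_start[i] <- up + 1L
          orf_end[i] <- up + orf_nt
          break
        }
        if (try == 100) stopf("could not place a unique longest ORF (gene %s)", ids[i])
      }
    }
    names(seqs) <- ids
    list(sequences = seqs,
         orfs = data.frame(transcript = ids, start = orf_start, end = orf_end,
                           stringsAsFactors = FALSE))
  })
}

#' Simulate per-site, per-pool allele counts
#'
#' Emits a pool-seq site table over the given transcripts: shared biallelic
#' SNPs (one Beta-drawn allele frequency per site, common to both morphs;
#' per-pool counts binomial at Poisson depth), planted alternatively fixed
#' SNPs (all pools of one morph fixed for one allele, all pools of the other
#' morph fixed for the alternative), and monomorphic filler sites. One of the
#' two alleles always equals the transcript base at that position.
#'
#' @param config A [sim_config()].
#' @param transcripts Output of [simulate_transcripts()] (or a named character
#'   vector of sequences).
#' @return A `pool_sites` object (see [pool_sites()]) with attribute
#'   `truth_af`: data.frame(transcript, position) of planted af-SNPs.
#' @export
simulate_pool_alleles <- function(config, transcripts) {
  stopifnot(inherits(config, "sim_config"))
  seqs <- if (is.list(transcripts)) transcripts$sequences else transcripts
  if (length(seqs) == 0) stopf("transcripts must be non-empty")
  if (config$mean_coverage <= 0) stopf("zero coverage configured")
  np <- config$n_pools_per_morph
  pools <- data.frame(
    pool = c(paste0("wood_p", seq_len(np)), paste0("rock_p", seq_len(np))),
    morph = rep(c("wood", "rock"), each = np),
    stringsAsFactors = FALSE)
  P <- nrow(pools)
  wood_idx <- which(pools$morph == "wood")
  rock_idx <- which(pools$morph == "rock")

  with_seed(derive_seed(config$seed, "alleles"), {
    recs <- vector("list", length(seqs))
    af_list <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
      id <- names(seqs)[i]
      chars <- strsplit(seqs[[i]], "")[[1]]
      L <- length(chars)
      n_snp <- stats::rpois(1, L / 1000 * config$snp_rate_per_kb)
      n_mono <- stats::rpois(1, L / 1000 * config$monomorphic_rate_per_kb)
      n_snp <- min(n_snp, L)
      pos_all <- sample.int(L, min(L, n_snp + n_mono))
      snp_pos <- sort(pos_all[seq_len(n_snp)])
      mono_pos <- sort(pos_all[setdiff(seq_along(pos_all), seq_len(n_snp))])
      pos <- sort(c(snp_pos, mono_pos))
      nsite <- length(pos)
      if (nsite == 0) next
      is_snp <- pos %in% snp_pos
      counts <- array(0L, dim = c(nsite, P, 6),
                      dimnames = list(NULL, pools$pool, SYNC_COLS))
      depth <- matrix(stats::rpois(nsite * P, config$mean_coverage),
                      nrow = nsite, ncol = P)
      is_af <- is_snp & stats::runif(nsite) < config$af_snp_fraction
      for (s in seq_len(nsite)) {
        ref <- chars[pos[s]]
        if (!is_snp[s]) {
          counts[s, , ref] <- depth[s, ]
        } else {
          alt <- sample(setdiff(NUCS, ref), 1)
          if (is_af[s]) {
            # alternative fixation: morphs fixed for different alleles
            a_wood <- sample(c(ref, alt))  # random orientation
            counts[s, wood_idx, a_wood[1]] <- depth[s, wood_idx]
            counts[s, rock_idx, a_wood[2]] <- depth[s, rock_idx]
          } else {
            p <- stats::rbeta(1, config$shared_maf_beta[1], config$shared_maf_beta[2])
            nref <- stats::rbinom(P, depth[s, ], p)
            counts[cbind(s, seq_len(P), match(ref, SYNC_COLS))] <- nref
            counts[cbind(s, seq_len(P), match(alt, SYNC_COLS))] <- depth[s, ] - nref
          }
        }
      }
      recs[[i]] <- list(info = data.frame(contig = id, pos = pos,
                                          ref = chars[pos],
                                          stringsAsFactors = FALSE),
                        counts = counts)
      if (any(is_af))
        af_list[[i]] <- data.frame(transcript = id, position = pos[is_af],
                                   stringsAsFactors = FALSE)
    }
    recs <- recs[!vapply(recs, is.null, logical(1))]
    info <- do.call(rbind, lapply(recs, `[[`, "info"))
    counts <- do.call(abind_sites, lapply(recs, `[[`, "counts"))
    truth_af <- do.call(rbind, af_list[!vapply(af_list, is.null, logical(1))])
    if (is.null(truth_af))
      truth_af <- data.frame(transcript = character(), position = integer())
    ps <- pool_sites(info, counts, pools)
    attr(ps, "truth_af") <- truth_af
    ps
  })
}

# rbind 3-d site arrays along the site dimension
abind_sites <- function(...) {
  arrs <- list(...)
  ns <- vapply(arrs, function(a) dim(a)[1], integer(1))
  out <- array(0L, dim = c(sum(ns), dim(arrs[[1]])[2], dim(arrs[[1]])[3]),
               dimnames = c(list(NULL), dimnames(arrs[[1]])[2:3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Simulate a gene x sample fragment-count matrix
#'
#' Counts are negative binomial with per-gene log-normal baseline expression,
#' per-gene-per-tissue shifts, and a planted `planted_log2fc` fold change
#' (rock vs wood) for the true-DE gene/tissue pairs; universally DE genes
#' receive the shift in all three tissues. Sample annotations carry
#' (morph, tissue, pool).
#'
#' @param config A [sim_config()].
#' @param gene_lengths Optional named lengths (nt); defaults to
#'   transcript-length draws so FPKM is computable without the sequences.
#' @return List: `counts` (integer matrix), `samples` (data.frame),
#'   `gene_lengths`, and `truth` with `de` (gene, tissue, direction) and
#'   `universal` (gene, direction).
#' @export
simulate_counts <- function(config, gene_lengths = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$nb_dispersion < 0) stopf("nb_dispersion must be >= 0")
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  with_seed(derive_seed(config$seed, "counts"), {
    if (is.null(gene_lengths)) {
      gene_lengths <- pmax(90L, as.integer(round(stats::rlnorm(
        n, config$transcript_length[["meanlog"]],
        config$transcript_length[["sdlog"]]))))
      names(gene_lengths) <- genes
    }
    np <- config$n_pools_per_morph
    samples <- expand.grid(pool = seq_len(np), tissue = config$tissues,
                           morph = c("wood", "rock"),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    samples <- samples[, c("morph", "tissue", "pool")]
    samples$sample <- sprintf("%s_%s_p%d", samples$morph, samples$tissue, samples$pool)

    base <- stats::rnorm(n, config$baseline_log_expression[["meanlog"]],
                         config$baseline_log_expression[["sdlog"]])
    teff <- matrix(stats::rnorm(n * 3, 0, config$tissue_effect_sd), n, 3,
                   dimnames = list(genes, config$tissues))

    n_univ <- round(config$universal_de_fraction * n)
    univ <- sort(sample.int(n, n_univ))
    univ_dir <- sample(c(-1, 1), n_univ, replace = TRUE)
    de <- list()
    shift <- matrix(0, n, 3, dimnames = list(genes, config$tissues))
    for (t in config$tissues) {
      pool_avail <- setdiff(seq_len(n), univ)
      n_de <- min(round(config$de_fraction_per_tissue * n), length(pool_avail))
      idx <- sort(pool_avail[sample.int(length(pool_avail), n_de)])
      dir <- sample(c(-1, 1), length(idx), replace = TRUE)
      shift[idx, t] <- dir * config$planted_log2fc * log(2)
      de[[t]] <- data.frame(gene = genes[idx], tissue = rep(t, length(idx)),
                            direction = dir, stringsAsFactors = FALSE)
    }
    shift[univ, ] <- univ_dir * config$planted_log2fc * log(2)

    counts <- matrix(0L, n, nrow(samples),
                     dimnames = list(genes, samples$sample))
    for (j in seq_len(nrow(samples))) {
      mu <- exp(base + teff[, samples$tissue[j]] +
                  if (samples$morph[j] == "rock") shift[, samples$tissue[j]] else 0)
      mu <- pmin(mu, config$expression_cap)
      counts[, j] <- if (config$nb_dispersion == 0) stats::rpois(n, mu)
                     else stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
    }
    list(counts = counts,
         samples = samples[, c("sample", "morph", "tissue", "pool")],
         gene_lengths = gene_lengths,
         truth = list(de = do.call(rbind, de),
                      universal = data.frame(gene = genes[univ],
                                             direction = univ_dir,
                                             stringsAsFactors = FALSE)))
  })
}

#' Simulate 2-D landmark configurations
#'
#' Specimens are a common base polygon; rock-morph specimens additionally get
#' a radial displacement of magnitude `shape_effect` on a designated subset of
#' landmarks. Isotropic Gaussian noise is added, then a random similarity
#' nuisance (rotation in `[0, 2pi)`, log-scale in `[-1, 1]`, translation) is
#' applied, which generalized Procrustes analysis must remove.
#'
#' @param config A [sim_config()].
#' @return List: `coords` (n x k x 2 array), `labels` (specimen, substrate,
#'   morph), `truth_classes` (named morph vector).
#' @export
simulate_landmarks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$landmark_n
  if (k < 3) stopf("landmark_n must be >= 3")
  with_seed(derive_seed(config$seed, "landmarks"), {
    ns <- config$n_specimens_per_substrate
    substrate <- rep(names(ns), ns)
    n <- length(substrate)
    morph <- ifelse(stats::runif(n) < config$morph_concordance, substrate,
                    ifelse(substrate == "wood", "rock", "wood"))
    ids <- sprintf("sp%02d", seq_len(n))
    theta <- 2 * pi * (seq_len(k) - 1) / k
    base <- cbind(cos(theta), sin(theta))
    disp_idx <- seq_len(ceiling(k / 3))  # landmarks carrying the morph effect
    coords <- array(0, dim = c(n, k, 2), dimnames = list(ids, NULL, c("x", "y")))
    for (i in seq_len(n)) {
      sh <- base
      if (morph[i] == "rock")
        sh[disp_idx, ] <- sh[disp_idx, ] * (1 + config$shape_effect)
      sh <- sh + matrix(stats::rnorm(2 * k, 0, config$shape_noise_sd), k, 2)
      ang <- stats::runif(1, 0, 2 * pi)
      sc <- exp(stats::runif(1, -1, 1))
      R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      sh <- sc * sh %*% R
      sh <- sweep(sh, 2, stats::runif(2, -5, 5), "+")
      coords[i, , ] <- sh
    }
    truth <- morph
    names(truth) <- ids
    list(coords = coords,
         labels = data.frame(specimen = ids, substrate = substrate,
                             morph = morph, stringsAsFactors = FALSE),
         truth_classes = truth)
  })
}

#' Run all four generators under one configuration
#'
#' @param config A [sim_config()].
#' @return List with `transcripts`, `sites`, `expression`, `landmarks`, and
#'   the collected ground `truth`.
#' @export
simulate_all <- function(config) {
  tx <- simulate_transcripts(config)
  sites <- simulate_pool_alleles(config, tx)
  expr <- simulate_counts(config,
                          gene_lengths = stats::setNames(nchar(tx$sequences),
                                                         names(tx$sequences)))
  lm <- simulate_landmarks(config)
  list(transcripts = tx, sites = sites, expression = expr, landmarks = lm,
       truth = list(orfs = tx$orfs,
                    af_snps = attr(sites, "truth_af"),
                    de = expr$truth$de,
                    universal_de = expr$truth$universal,
                    shape_classes = lm$truth_classes))
}
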