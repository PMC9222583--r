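## Longest-ORF identification and synonymous/non-synonymous classification of
## SNPs within it, plus per-gene densities of non-synonymous alternatively
## fixed SNPs.

#' Find the longest complete ORF on the forward strand
#'
#' Scans the forward strand only (libraries are strand-specific): an ORF is a
#' complete ATG ... stop span in one frame, stop codon included, at least
#' `min_len` nt. The longest such span is returned, the leftmost on ties;
#' candidates containing N are skipped.
#'
#' @param seq A single sequence (character scalar over A/C/G/T/N).
#' @param min_len Minimum ORF length in nt (default 30).
#' @return data.frame(start, end, n_codons) with one row, or `NULL` when no
#'   complete ORF qualifies.
#' @export
find_longest_orf <- function(seq, min_len = 30) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  best <- NULL
  for (f in 0:2) {
    if (n - f < 3) next
    starts <- seq.int(1L + f, n - 2L, by = 3L)
    cod <- paste0(chars[starts], chars[starts + 1], chars[starts + 2])
    atg <- which(cod == "ATG")
    stp <- which(cod %in% .STOPS)
    if (length(atg) == 0 || length(stp) == 0) next
    nxt <- findInterval(atg, stp) + 1L
    ok <- nxt <= length(stp)
    if (!any(ok)) next
    s <- starts[atg[ok]]
    e <- starts[stp[nxt[ok]]] + 2L
    len <- e - s + 1L
    for (c_i in order(-len, s)) {
      if (len[c_i] < min_len) break
      span <- chars[s[c_i]:e[c_i]]
      if (any(span == "N")) next  # candidate skipped
      cand <- data.frame(start = s[c_i], end = e[c_i], n_codons = len[c_i] %/% 3L)
      if (is.null(best) ||
          (cand$end - cand$start > best$end - best$start) ||
          (cand$end - cand$start == best$end - best$start && cand$start < best$start))
        best <- cand
      break  # within a frame the first valid candidate in this order wins
    }
  }
  best
}

#' Annotate the longest ORF of every transcript
#'
#' @param seqs Named character vector of transcript sequences.
#' @param min_len Minimum ORF length in nt.
#' @return data.frame(transcript, start, end, n_codons); transcripts without
#'   a complete ORF are excluded (their number is reported in a message).
#' @export
annotate_orfs <- function(seqs, min_len = 30) {
  res <- lapply(seqs, find_longest_orf, min_len = min_len)
  has <- !vapply(res, is.null, logical(1))
  if (any(!has))
    message(sum(!has), " transcript(s) without a complete ORF were excluded")
  if (!any(has))
    return(data.frame(transcript = character(), start = integer(),
                      end = integer(), n_codons = integer()))
  out <- do.call(rbind, res[has])
  out <- data.frame(transcript = names(seqs)[has], out,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Classify SNP effects within annotated ORFs
#'
#' For each SNP on a transcript with an annotated ORF: positions outside the
#' ORF are `noncoding`; inside, the affected codon is built twice -- once with
#' the major and once with the minor allele, the other two positions taken
#' from the transcript -- and the translations compared under the standard
#' genetic code. Codons containing N yield effect `not-applicable`.
#'
#' @param snps data.frame with columns contig, pos, major, minor (e.g.
#'   `snp_table$snps`).
#' @param orfs ORF annotation from [annotate_orfs()].
#' @param seqs Named character vector of transcript sequences.
#' @return data.frame: contig, pos, location (`noncoding`/`coding`), effect
#'   (`synonymous`/`non-synonymous`/`not-applicable`, `NA` for noncoding),
#'   codon_index, major_codon, minor_codon, major_aa, minor_aa. SNPs on
#'   transcripts without an ORF get location `noncoding`.
#' @export
classify_snp_effects <- function(snps, orfs, seqs) {
  code <- Biostrings::GENETIC_CODE
  n <- nrow(snps)
  out <- data.frame(contig = snps$contig, pos = snps$pos,
                    location = "noncoding", effect = NA_character_,
                    codon_index = NA_integer_,
                    major_codon = NA_character_, minor_codon = NA_character_,
                    major_aa = NA_character_, minor_aa = NA_character_,
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  om <- match(snps$contig, orfs$transcript)
  for (i in seq_len(n)) {
    oi <- om[i]
    if (is.na(oi)) next
    s0 <- orfs$start[oi]; e0 <- orfs$end[oi]
    pos <- snps$pos[i]
    sq <- seqs[[snps$contig[i]]]
    if (pos < 1 || pos > nchar(sq)) stopf("SNP position %d outside %s", pos, snps$contig[i])
    if (pos < s0 || pos > e0) next
    out$location[i] <- "coding"
    ci <- (pos - s0) %/% 3L
    off <- (pos - s0) %% 3L
    cstart <- s0 + 3L * ci
    codon <- strsplit(substr(sq, cstart, cstart + 2L), "")[[1]]
    maj <- codon; maj[off + 1L] <- snps$major[i]
    mnr <- codon; mnr[off + 1L] <- snps$minor[i]
    majc <- paste(maj, collapse = ""); mnrc <- paste(mnr, collapse = "")
    out$codon_index[i] <- ci + 1L
    out$major_codon[i] <- majc
    out$minor_codon[i] <- mnrc
    if (any(maj == "N") || any(mnr == "N")) {
      out$effect[i] <- "not-applicable"
      next
    }
    aa1 <- unname(code[majc]); aa2 <- unname(code[mnrc])
    out$major_aa[i] <- aa1
    out$minor_aa[i] <- aa2
    out$effect[i] <- if (identical(aa1, aa2)) "synonymous" else "non-synonymous"
  }
  out
}

#' Per-gene density of non-synonymous af-SNPs and fold enrichments
#'
#' Density is non-synonymous af-SNPs per kb of ORF. Folds are computed
#' against (a) the mean density over all transcripts with an ORF and (b) the
#' mean over transcripts carrying at least one af-SNP of any class.
#'
#' @param orfs ORF annotation from [annotate_orfs()].
#' @param effects Effect table from [classify_snp_effects()].
#' @param af_flags Logical vector aligned with `effects` rows marking af-SNPs.
#' @return data.frame: gene, orf_kb, n_nonsyn_af, density, fold_vs_all,
#'   fold_vs_af_bearing, sorted by descending density.
#' @export
af_snp_density <- function(orfs, effects, af_flags) {
  stopifnot(nrow(effects) == length(af_flags))
  orf_kb <- 3 * orfs$n_codons / 1000
  af <- effects[af_flags & !is.na(af_flags), , drop = FALSE]
  ns <- af[!is.na(af$effect) & af$effect == "non-synonymous", , drop = FALSE]
  n_ns <- table(factor(ns$contig, levels = orfs$transcript))
  n_af_any <- table(factor(af$contig, levels = orfs$transcript))
  density <- as.numeric(n_ns) / orf_kb
  mean_all <- mean(density)
  bearing <- as.numeric(n_af_any) > 0
  mean_af <- if (any(bearing)) mean(density[bearing]) else NA_real_
  out <- data.frame(gene = orfs$transcript, orf_kb = orf_kb,
                    n_nonsyn_af = as.integer(n_ns), density = density,
                    fold_vs_all = if (mean_all > 0) density / mean_all else NA_real_,
                    fold_vs_af_bearing = if (!is.na(mean_af) && mean_af > 0)
                      density / mean_af else NA_real_,
                    stringsAsFactors = FALSE)
  out[order(-out$density, out$gene), , drop = FALSE]
}
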