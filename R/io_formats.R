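## Readers/writers for the formats the pipeline touches: PoPoolation2-style
## sync allele counts, FASTA, TPS landmark files, and TSV count matrices with
## a CSV sample sheet. All writers emit LF endings; sync/TSV are tab-delimited.

#' Per-site, per-pool allele counts
#'
#' Container for pool-seq site data: a site table (contig, 1-based position,
#' reference base), an integer count array `[site, pool, A/T/C/G/N/del]`, and
#' a pool sheet (pool id, morph). Coverage is the A+T+C+G sum; N and deletion
#' counts are carried but never enter coverage or allele calling.
#'
#' @param info data.frame with columns contig, pos, ref.
#' @param counts Integer array `[n_sites, n_pools, 6]`.
#' @param pools data.frame with columns pool, morph.
#' @return An object of class `pool_sites`.
#' @export
pool_sites <- function(info, counts, pools) {
  stopifnot(nrow(info) == dim(counts)[1], nrow(pools) == dim(counts)[2],
            dim(counts)[3] == 6)
  if (any(counts < 0)) stopf("negative allele counts")
  dimnames(counts) <- list(NULL, pools$pool, SYNC_COLS)
  structure(list(info = info, counts = counts, pools = pools),
            class = "pool_sites")
}

#' @export
print.pool_sites <- function(x, ...) {
  cat(sprintf("pool_sites: %d sites x %d pools (%s)\n", nrow(x$info),
              nrow(x$pools), paste(unique(x$pools$morph), collapse = "/")))
  invisible(x)
}

#' Per-pool site coverage (A+T+C+G)
#' @param ps A `pool_sites` object.
#' @return Integer matrix sites x pools.
#' @export
site_coverage <- function(ps) {
  cov <- ps$counts[, , "A", drop = FALSE] + ps$counts[, , "T", drop = FALSE] +
    ps$counts[, , "C", drop = FALSE] + ps$counts[, , "G", drop = FALSE]
  matrix(cov, nrow = dim(ps$counts)[1], dimnames = dimnames(ps$counts)[1:2])
}

## sync ----------------------------------------------------------------------

#' Write a sync file (contig, pos, ref, per-pool A:T:C:G:N:del)
#' @param ps A `pool_sites` object.
#' @param path Output path.
#' @export
write_sync <- function(ps, path) {
  P <- nrow(ps$pools)
  cols <- vapply(seq_len(P), function(j)
    paste(ps$counts[, j, 1], ps$counts[, j, 2], ps$counts[, j, 3],
          ps$counts[, j, 4], ps$counts[, j, 5], ps$counts[, j, 6], sep = ":"),
    character(nrow(ps$info)))
  lines <- do.call(paste, c(list(ps$info$contig, ps$info$pos, ps$info$ref),
                            split(cols, col(cols)), list(sep = "\t")))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Parse a sync file
#'
#' The pool count is inferred from the first record and enforced on every
#' later line; ragged lines and malformed count tuples raise errors naming
#' the offending line.
#'
#' @param path Path to a tab-separated sync file.
#' @param pools Optional pool sheet (pool, morph); defaults to anonymous pools.
#' @return A `pool_sites` object (empty file gives zero sites).
#' @export
parse_sync <- function(path, pools = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    P <- if (is.null(pools)) 0L else nrow(pools)
    return(pool_sites(data.frame(contig = character(), pos = integer(),
                                 ref = character()),
                      array(0L, dim = c(0, P, 6)),
                      pools %||% data.frame(pool = character(), morph = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (nf[1] < 4) stopf("sync line 1: expected >= 4 tab-separated fields")
  P <- nf[1] - 3L
  bad <- which(nf != nf[1])
  if (length(bad))
    stopf("sync line %d: %d pool columns, expected %d", bad[1], nf[bad[1]] - 3L, P)
  m <- matrix(unlist(fields), ncol = nf[1], byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) stopf("sync line %d: non-integer position", which(is.na(pos))[1])
  counts <- array(0L, dim = c(length(lines), P, 6))
  for (j in seq_len(P)) {
    tup <- strsplit(m[, j + 3], ":", fixed = TRUE)
    if (any(lengths(tup) != 6))
      stopf("sync line %d: count tuple must have 6 fields",
            which(lengths(tup) != 6)[1])
    v <- suppressWarnings(as.integer(unlist(tup)))
    if (anyNA(v) || any(v < 0))
      stopf("sync: malformed count tuple in pool column %d", j)
    counts[, j, ] <- matrix(v, ncol = 6, byrow = TRUE)
  }
  if (is.null(pools))
    pools <- data.frame(pool = paste0("pool", seq_len(P)),
                        morph = NA_character_, stringsAsFactors = FALSE)
  if (nrow(pools) != P) stopf("pool sheet has %d pools, sync has %d", nrow(pools), P)
  pool_sites(data.frame(contig = m[, 1], pos = pos, ref = m[, 3],
                        stringsAsFactors = FALSE),
             counts, pools)
}

## FASTA ---------------------------------------------------------------------

#' Parse a FASTA file of transcripts
#'
#' Identifiers are the first whitespace token of each header; sequences are
#' upper-cased and U is mapped to T. Duplicate identifiers and empty
#' sequences are errors.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
parse_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stopf("duplicate FASTA id: %s", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (any(!nzchar(seqs)))
    stopf("empty sequence for FASTA id: %s", ids[!nzchar(seqs)][1])
  names(seqs) <- ids
  seqs
}

#' Write sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path, sep = "\n")
  invisible(path)
}

## TPS -----------------------------------------------------------------------

#' Parse a TPS landmark file
#'
#' Accepts blocks of `LM=k` followed by k "x y" coordinate lines and an
#' `ID=` line (a `SCALE=` line, if present, is ignored). All specimens must
#' share the same landmark count.
#'
#' @param path TPS path.
#' @return List with `coords` (n x k x 2 array) and `ids`.
#' @export
parse_tps <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(list(coords = array(0, dim = c(0, 0, 2)), ids = character()))
  i <- 1L
  specs <- list()
  ids <- character()
  while (i <= length(lines)) {
    if (!grepl("^LM=", lines[i])) stopf("TPS line %d: expected LM=", i)
    k <- suppressWarnings(as.integer(sub("^LM=", "", lines[i])))
    if (is.na(k) || k < 1) stopf("TPS line %d: bad landmark count", i)
    if (i + k > length(lines)) stopf("TPS: truncated coordinate block at line %d", i)
    xy <- do.call(rbind, lapply(lines[(i + 1):(i + k)], function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]]))
      if (length(v) != 2 || anyNA(v)) stopf("TPS: non-numeric coordinate: '%s'", l)
      v
    }))
    i <- i + k + 1L
    id <- NA_character_
    while (i <= length(lines) && !grepl("^LM=", lines[i])) {
      if (grepl("^ID=", lines[i])) id <- sub("^ID=", "", lines[i])
      i <- i + 1L
    }
    if (is.na(id)) id <- sprintf("specimen%d", length(specs) + 1L)
    specs[[length(specs) + 1L]] <- xy
    ids <- c(ids, id)
  }
  ks <- vapply(specs, nrow, integer(1))
  if (length(unique(ks)) > 1)
    stopf("TPS: landmark counts differ across specimens (%s)",
          paste(unique(ks), collapse = ", "))
  coords <- array(0, dim = c(length(specs), ks[1], 2),
                  dimnames = list(ids, NULL, c("x", "y")))
  for (s in seq_along(specs)) coords[s, , ] <- specs[[s]]
  list(coords = coords, ids = ids)
}

#' Write a TPS landmark file
#' @param coords n x k x 2 array.
#' @param ids Specimen identifiers (defaults to array dimnames).
#' @param path Output path.
#' @export
write_tps <- function(coords, path, ids = dimnames(coords)[[1]]) {
  n <- dim(coords)[1]; k <- dim(coords)[2]
  if (is.null(ids)) ids <- sprintf("specimen%d", seq_len(n))
  blocks <- vapply(seq_len(n), function(i) {
    paste(c(sprintf("LM=%d", k),
            sprintf("%.6f %.6f", coords[i, , 1], coords[i, , 2]),
            sprintf("ID=%s", ids[i])), collapse = "\n")
  }, character(1))
  writeLines(blocks, path, sep = "\n")
  invisible(path)
}

## counts + sample sheet -----------------------------------------------------

#' Parse a gene x sample count matrix against a sample sheet
#'
#' @param path TSV with gene ids in the first column and sample ids as header.
#' @param sheet data.frame with columns sample, morph, tissue, pool.
#' @return Integer matrix, genes in file order, samples in sheet order.
#' @export
parse_counts <- function(path, sheet) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  extra <- setdiff(colnames(m), sheet$sample)
  if (length(extra)) stopf("unknown sample(s) in counts header: %s",
                           paste(extra, collapse = ", "))
  missing <- setdiff(sheet$sample, colnames(m))
  if (length(missing)) stopf("sample(s) missing from counts header: %s",
                             paste(missing, collapse = ", "))
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stopf("counts must be non-negative integers")
  storage.mode(m) <- "integer"
  m <- m[, sheet$sample, drop = FALSE]
  rownames(m) <- genes
  m
}

#' Write a count matrix as TSV
#' @param counts Gene x sample matrix with dimnames.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet (CSV: sample, morph, tissue, pool)
#' @param path CSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  sh <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "morph", "tissue", "pool")
  if (!all(need %in% names(sh)))
    stopf("sample sheet must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(sh[, c("morph", "tissue", "pool")]))
    stopf("duplicate (morph, tissue, pool) in sample sheet")
  sh
}

#' @rdname read_sample_sheet
#' @param sheet data.frame to write.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
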