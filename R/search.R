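#' BLAT-like k-mer seed-and-extend search
#'
#' Finds local alignments of a proviral consensus against a genome. An index
#' of exact k-mers is built over the genome (window `k`, stepping by `step`);
#' every overlapping consensus k-mer is looked up, hits are chained by
#' diagonal, chains are extended outwards through isolated mismatches, and
#' segments below `min_identity` or `min_len` are discarded. Both strands
#' are searched. The defaults mirror the classical DNA BLAT parameters
#' (11-mers stepping by 5, 95 percent identity, 25 bp minimum).
#'
#' Substitution-style divergence keeps a copy on a single diagonal, so each
#' chain yields one ungapped alignment record; loci fragmented by internal
#' deletions or nested insertions produce several records that
#' [assemble_loci()] merges.
#'
#' @param genome FASTA path, named character vector, or
#'   `Biostrings::DNAStringSet`.
#' @param reference a [proviral_reference()].
#' @param k k-mer width (<= 32).
#' @param step index stepping over the genome.
#' @param min_identity minimum match/(match+mismatch) per record.
#' @param min_len minimum record length in bp.
#' @param max_seed_gap seeds on one diagonal further apart than this start a
#'   new chain.
#' @param occ_cap genome k-mers occurring more often than this are skipped
#'   (a minimal guard against low-complexity seeds).
#' @return an `erv_alignments` data.frame (see [read_psl()]).
#' @export
kmer_search <- function(genome, reference, k = 11, step = 5,
                        min_identity = 0.95, min_len = 25,
                        max_seed_gap = 200, occ_cap = 64) {
  stopifnot(inherits(reference, "proviral_reference"))
  if (k > 32) stopf("k must be <= 32")
  if (k < 4 || step < 1 || min_len < 1) stopf("invalid search parameters")
  seqs <- read_genome(genome)
  if (!length(seqs) || all(nchar(seqs) < k)) return(empty_alignments())
  rl <- nchar(reference$sequence)

  # genome k-mer index: kmer -> (chrom index, 1-based position)
  idx_chrom <- integer(0); idx_pos <- integer(0); idx_kmer <- character(0)
  for (ci in seq_along(seqs)) {
    L <- nchar(seqs[[ci]])
    if (L < k) next
    starts <- seq.int(1L, L - k + 1L, by = step)
    idx_kmer <- c(idx_kmer, substring(seqs[[ci]], starts, starts + k - 1L))
    idx_chrom <- c(idx_chrom, rep.int(ci, length(starts)))
    idx_pos <- c(idx_pos, starts)
  }
  occ <- table(idx_kmer)
  keep <- !(idx_kmer %in% names(occ)[occ > occ_cap])
  index <- split(seq_along(idx_kmer)[keep], idx_kmer[keep])

  out <- list()
  for (strand in c("+", "-")) {
    qseq <- if (strand == "+") reference$sequence else
      revcomp(reference$sequence)
    qstarts <- seq_len(rl - k + 1L)
    qkmers <- substring(qseq, qstarts, qstarts + k - 1L)
    hit_lists <- index[qkmers]
    nh <- lengths(hit_lists); nh[is.na(names(hit_lists))] <- 0L
    if (!sum(nh)) next
    qpos <- rep.int(qstarts, nh)
    gi <- unlist(hit_lists[nh > 0], use.names = FALSE)
    chrom_i <- idx_chrom[gi]; gpos <- idx_pos[gi]
    diag <- gpos - qpos
    ord <- order(chrom_i, diag, qpos)
    chrom_i <- chrom_i[ord]; gpos <- gpos[ord]; qpos <- qpos[ord]
    diag <- diag[ord]
    newchain <- c(TRUE, chrom_i[-1] != chrom_i[-length(chrom_i)] |
                    diag[-1] != diag[-length(diag)] |
                    (qpos[-1] - qpos[-length(qpos)]) > max_seed_gap)
    chain <- cumsum(newchain)
    for (ch in split(seq_along(chain), chain)) {
      ci <- chrom_i[ch[1]]
      qs <- qpos[ch[1]]; qe <- qpos[ch[length(ch)]] + k - 1L
      d <- diag[ch[1]]
      ext <- extend_segment(qseq, seqs[[ci]], qs, qe, d)
      if (is.null(ext)) next
      len <- ext$qe - ext$qs + 1L
      ident <- ext$match / len
      if (len < min_len || ident < min_identity) next
      # convert to 0-based; query coords to plus-strand consensus
      q0 <- ext$qs - 1L; q1 <- ext$qe
      if (strand == "-") { tmp <- q0; q0 <- rl - q1; q1 <- rl - tmp }
      t0 <- ext$qs + d - 1L; t1 <- ext$qe + d
      out[[length(out) + 1L]] <- data.frame(
        q_name = reference$name, t_name = names(seqs)[ci], strand = strand,
        match = ext$match, mismatch = len - ext$match,
        q_gap_count = 0L, q_gap_bases = 0L,
        t_gap_count = 0L, t_gap_bases = 0L,
        q_size = rl, q_start = q0, q_end = q1,
        t_size = nchar(seqs[[ci]]), t_start = t0, t_end = t1,
        blocks = I(list(cbind(qs = q0, ts = t0, len = len))),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_alignments())
  res <- do.call(rbind, out)
  # a chain broken by the seed-gap rule can yield duplicate/contained
  # segments after extension; drop records contained in another on the
  # same chromosome, strand and diagonal
  keep <- rep(TRUE, nrow(res))
  dg <- res$t_start - res$q_start
  grp <- paste(res$t_name, res$strand, dg)
  for (g in split(seq_len(nrow(res)), grp)) {
    if (length(g) == 1) next
    for (i in g) for (j in g) {
      if (i != j && keep[i] && keep[j] &&
          res$t_start[j] <= res$t_start[i] && res$t_end[j] >= res$t_end[i] &&
          (res$t_end[j] - res$t_start[j]) > (res$t_end[i] - res$t_start[i]))
        keep[i] <- FALSE
    }
  }
  alignment_records(res[keep, , drop = FALSE])
}

# Extend an ungapped segment on a fixed diagonal in both directions using
# score-based (X-drop style) trimming: +1 per match, -2 per mismatch, stop
# when the running score falls `xdrop` below its maximum, and trim back to
# the maximum-score position. Divergent proviral sequence scores positive
# on average (up to ~30 percent divergence) so extension reaches the true
# edge, while random flanking sequence scores -1.25/bp on average so
# overshoot is a few bases at most. Coordinates are 1-based on the
# (strand-oriented) query; the target position of query base q is q + d.
# Returns list(qs, qe, match) or NULL.
extend_segment <- function(qseq, tseq, qs, qe, d, xdrop = 30L,
                           window = 400L) {
  tl <- nchar(tseq); ql <- nchar(qseq)
  qv <- strsplit(substr(qseq, max(1L, qs - window),
                        min(ql, qe + window)), "")[[1]]
  off <- max(1L, qs - window) - 1L
  tlo <- max(1L, qs + d - window); thi <- min(tl, qe + d + window)
  tv <- strsplit(substr(tseq, tlo, thi), "")[[1]]
  toff <- tlo - 1L
  eq <- function(q) {
    qi <- q - off; ti <- q + d - toff
    if (q < 1L || q > ql || q + d < 1L || q + d > tl ||
        qi < 1L || qi > length(qv) || ti < 1L || ti > length(tv))
      return(NA)
    qv[qi] == tv[ti]
  }
  walk <- function(from, dir) {
    score <- 0; best <- 0; bestq <- from; q <- from
    repeat {
      q <- q + dir
      m <- eq(q)
      if (is.na(m)) break
      score <- score + if (m) 1 else -2
      if (m && score > best) { best <- score; bestq <- q }
      if (score < best - xdrop) break
    }
    bestq
  }
  best_qe <- walk(qe, 1L)
  best_qs <- walk(qs, -1L)
  qr <- best_qs:best_qe
  mv <- (qr - off) >= 1 & (qr - off) <= length(qv) &
    (qr + d - toff) >= 1 & (qr + d - toff) <= length(tv)
  if (!all(mv)) return(NULL)
  match <- sum(qv[qr - off] == tv[qr + d - toff])
  list(qs = best_qs, qe = best_qe, match = match)
}

# Accept FASTA path, DNAStringSet, or named character vector.
read_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet"))
    return(setNames(as.character(genome), names(genome)))
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    dna <- Biostrings::readDNAStringSet(genome)
    nm <- sub("\\s.*$", "", names(dna))
    return(setNames(as.character(dna), nm))
  }
  if (is.character(genome) && !is.null(names(genome)))
    return(toupper(genome))
  stopf("genome must be a FASTA path, DNAStringSet, or named character vector")
}
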