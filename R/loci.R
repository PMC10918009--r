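# Union of closed integer intervals given as a 2-column matrix; returns a
# matrix with the same columns, sorted and merged.
merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    j <- nrow(out)
    if (iv[i, 1] <= out[j, 2] + 1L) out[j, 2] <- max(out[j, 2], iv[i, 2])
    else out <- rbind(out, iv[i, , drop = FALSE])
  }
  out
}

range_bin_label <- function(coverage_fraction) {
  lo <- pmin(floor(coverage_fraction * 10) * 10, 90)
  sprintf("[%d%%-%d%%)", lo, lo + 10)
}

#' Assemble alignment records into proviral loci
#'
#' Records on the same chromosome and strand whose genomic intervals lie
#' within `merge_gap` of each other and whose consensus intervals are
#' collinear are merged into one locus (nested insertions and internal
#' deletions fragment a single locus into several local alignments).
#' Coverage is the fraction of the consensus covered by the union of
#' aligned blocks; the query-gap fraction is the consensus missing inside
#' the aligned span, `Qgap/(match+mismatch+Qgap)`.
#'
#' Indel flags follow kb-scale structural evidence: `Deletion` when the
#' query-gap fraction reaches `deletion_threshold`, `Insertion` when the
#' genomic span exceeds the aligned bases by at least `insertion_threshold`
#' (foreign sequence nested inside the locus).
#'
#' @param records an `erv_alignments` data.frame from [kmer_search()] or
#'   [read_psl()], all against one reference.
#' @param reference the [proviral_reference()] searched with.
#' @param merge_gap maximum genomic distance (bp) between records merged
#'   into one locus.
#' @param deletion_threshold query-gap fraction at or above which a locus is
#'   flagged `Deletion`.
#' @param insertion_threshold extra genomic bp at or above which a locus is
#'   flagged `Insertion`.
#' @return an `erv_loci` data.frame, sorted by coverage descending (ties by
#'   chromosome, start), with columns `name`, `chrom`, `strand`, `start`,
#'   `end`, `length`, `coverage_fraction`, `q_gap_fraction`, `range_bin`,
#'   `indel_flags`, `context` (NA here; filled by [classify_context()]),
#'   and a `ref_blocks` list-column of consensus intervals covered
#'   (1-based inclusive).
#' @export
assemble_loci <- function(records, reference, merge_gap = 2000,
                          deletion_threshold = 0.10,
                          insertion_threshold = 1000) {
  stopifnot(inherits(reference, "proviral_reference"))
  rl <- nchar(reference$sequence)
  if (nrow(records) && length(unique(records$q_name)) > 1)
    stopf("records mix multiple references: %s",
          paste(unique(records$q_name), collapse = ", "))
  loci <- list()
  if (nrow(records)) {
    grp <- paste(records$t_name, records$strand)
    for (g in split(seq_len(nrow(records)), grp)) {
      r <- records[g, , drop = FALSE]
      r <- r[order(r$t_start), , drop = FALSE]
      # gap between adjacent records measured as the implied foreign
      # sequence: genomic gap minus any unaligned consensus between them,
      # so a nested insert of exactly merge_gap bp still merges even when
      # a few divergent edge bases went unaligned
      gap_t <- r$t_start[-1] - cummax(r$t_end)[-nrow(r)]
      gap_q <- if (r$strand[1] == "+")
        r$q_start[-1] - r$q_end[-nrow(r)] else
        r$q_start[-nrow(r)] - r$q_end[-1]
      cluster <- cumsum(c(TRUE, gap_t - pmax(0, gap_q) > merge_gap |
                            !collinear_step(r)))
      for (cl in split(seq_len(nrow(r)), cluster)) {
        loci[[length(loci) + 1L]] <-
          build_locus(r[cl, , drop = FALSE], rl, deletion_threshold,
                      insertion_threshold)
      }
    }
  }
  out <- if (length(loci)) do.call(rbind, loci) else
    data.frame(name = character(0), chrom = character(0),
               strand = character(0), start = integer(0), end = integer(0),
               length = integer(0), coverage_fraction = numeric(0),
               q_gap_fraction = numeric(0), range_bin = character(0),
               indel_flags = character(0), context = character(0),
               ref_blocks = I(list()))
  o <- order(-out$coverage_fraction, out$chrom, out$start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("erv_loci", "data.frame")
  out
}

# TRUE at position i (i>1) when record i continues the previous record's
# consensus interval in the orientation implied by the strand.
collinear_step <- function(r) {
  if (nrow(r) < 2) return(logical(0))
  if (r$strand[1] == "+")
    r$q_start[-1] >= r$q_start[-nrow(r)]
  else
    r$q_end[-1] <= r$q_end[-nrow(r)]
}

build_locus <- function(r, rl, deletion_threshold, insertion_threshold) {
  qb <- do.call(rbind, lapply(r$blocks, function(b)
    cbind(b[, "qs"], b[, "qs"] + b[, "len"] - 1L)))
  qb <- merge_intervals(qb)
  covered <- sum(qb[, 2] - qb[, 1] + 1L)
  span <- max(qb[, 2]) - min(qb[, 1]) + 1L
  qgap <- span - covered + sum(r$q_gap_bases)
  tb <- do.call(rbind, lapply(r$blocks, function(b)
    cbind(b[, "ts"], b[, "ts"] + b[, "len"] - 1L)))
  tb <- merge_intervals(tb)
  t_covered <- sum(tb[, 2] - tb[, 1] + 1L)
  start <- min(r$t_start) + 1L
  end <- max(r$t_end)
  t_extra <- (end - start + 1L) - t_covered
  flags <- c(if (t_extra >= insertion_threshold) "Insertion",
             if (qgap / (covered + qgap) >= deletion_threshold) "Deletion")
  data.frame(
    name = sprintf("%s:%d-%d", r$t_name[1], start, end),
    chrom = r$t_name[1], strand = r$strand[1],
    start = start, end = end, length = end - start + 1L,
    coverage_fraction = covered / rl,
    q_gap_fraction = qgap / (covered + qgap),
    range_bin = range_bin_label(covered / rl),
    indel_flags = if (length(flags)) paste(flags, collapse = ",") else
      NA_character_,
    context = NA_character_,
    ref_blocks = I(list(cbind(start = qb[, 1] + 1L, end = qb[, 2] + 1L))),
    stringsAsFactors = FALSE)
}

#' @export
print.erv_loci <- function(x, ...) {
  cat(sprintf("%d proviral locus/loci\n", nrow(x)))
  if (nrow(x)) {
    df <- x[, c("name", "strand", "length", "coverage_fraction",
                "q_gap_fraction", "range_bin", "indel_flags", "context")]
    df$coverage_fraction <- sprintf("%.2f%%", 100 * df$coverage_fraction)
    df$q_gap_fraction <- sprintf("%.2f%%", 100 * df$q_gap_fraction)
    print.data.frame(head(df, 20), row.names = FALSE)
    if (nrow(x) > 20) cat(sprintf("... and %d more\n", nrow(x) - 20))
  }
  invisible(x)
}

#' Write / read a locus table
#'
#' Tab-separated locus table mirroring the printed provirus-distribution
#' columns (percentages at two decimals), with the consensus intervals
#' covered serialized in a `ref_blocks` column. `write_locus_bed` emits a
#' BED6 companion (0-based half-open, coverage percent as score).
#'
#' @param loci an `erv_loci` data.frame.
#' @param path output path.
#' @export
write_locus_table <- function(loci, path) {
  df <- as.data.frame(loci)
  df$coverage_pct <- round_half_up(100 * df$coverage_fraction, 2)
  df$q_gap_pct <- round_half_up(100 * df$q_gap_fraction, 2)
  df$ref_blocks <- vapply(df$ref_blocks, function(b)
    paste(sprintf("%d-%d", b[, 1], b[, 2]), collapse = ";"), "")
  cols <- c("name", "chrom", "strand", "start", "end", "length",
            "coverage_pct", "range_bin", "q_gap_pct", "indel_flags",
            "context", "ref_blocks")
  write.table(df[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_locus_table
#' @export
read_locus_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$coverage_fraction <- df$coverage_pct / 100
  df$q_gap_fraction <- df$q_gap_pct / 100
  df$ref_blocks <- I(lapply(strsplit(df$ref_blocks, ";"), function(p) {
    m <- do.call(rbind, lapply(strsplit(p, "-"), as.integer))
    colnames(m) <- c("start", "end")
    m
  }))
  class(df) <- c("erv_loci", "data.frame")
  df
}

#' @rdname write_locus_table
#' @export
write_locus_bed <- function(loci, path) {
  df <- as.data.frame(loci)
  bed <- data.frame(df$chrom, df$start - 1L, df$end, df$name,
                    round_half_up(100 * df$coverage_fraction, 0), df$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
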