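# PSL alignment records are kept as a data.frame with one row per local
# alignment (query = proviral consensus, target = genome) and a `blocks`
# list-column of matrices with columns qs, ts, len. Block coordinates are
# 0-based; qs is always in plus-strand consensus coordinates (for minus-
# strand records blocks ascend on the target and descend on the query).

alignment_records <- function(df) {
  needed <- c("q_name", "t_name", "strand", "match", "mismatch",
              "q_gap_count", "q_gap_bases", "t_gap_count", "t_gap_bases",
              "q_size", "q_start", "q_end", "t_size", "t_start", "t_end",
              "blocks")
  stopifnot(all(needed %in% names(df)))
  class(df) <- c("erv_alignments", "data.frame")
  df
}

empty_alignments <- function() {
  alignment_records(data.frame(
    q_name = character(0), t_name = character(0), strand = character(0),
    match = integer(0), mismatch = integer(0), q_gap_count = integer(0),
    q_gap_bases = integer(0), t_gap_count = integer(0),
    t_gap_bases = integer(0), q_size = integer(0), q_start = integer(0),
    q_end = integer(0), t_size = integer(0), t_start = integer(0),
    t_end = integer(0), blocks = I(list()), stringsAsFactors = FALSE))
}

#' Read a PSL alignment file
#'
#' Parses the 21-column PSL format (with or without the 5-line header) into
#' alignment records. For minus-strand rows, per-block query starts (which
#' PSL stores in reverse-complement coordinates) are normalized to
#' plus-strand consensus coordinates.
#'
#' @param path PSL file path.
#' @return an `erv_alignments` data.frame; zero rows for an empty file.
#' @export
read_psl <- function(path) {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1], "psLayout")) lines <- lines[-(1:5)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_alignments())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 21)
      stopf("PSL parse error at line %d: expected 21 columns, found %d",
            i, length(f))
    num <- suppressWarnings(as.integer(f[c(1:8, 11:13, 15:18)]))
    if (anyNA(num))
      stopf("PSL parse error at line %d: non-numeric field", i)
    sizes <- as.integer(strsplit(f[19], ",")[[1]])
    qst <- as.integer(strsplit(f[20], ",")[[1]])
    tst <- as.integer(strsplit(f[21], ",")[[1]])
    if (anyNA(sizes) || anyNA(qst) || anyNA(tst) ||
        length(sizes) != num[15] || length(qst) != num[15] ||
        length(tst) != num[15])
      stopf("PSL parse error at line %d: malformed block lists", i)
    q_size <- num[9]
    if (f[9] == "-") qst <- q_size - (qst + sizes)  # normalize to plus strand
    data.frame(
      q_name = f[10], t_name = f[14], strand = f[9],
      match = num[1], mismatch = num[2],
      q_gap_count = num[5], q_gap_bases = num[6],
      t_gap_count = num[7], t_gap_bases = num[8],
      q_size = q_size, q_start = num[10], q_end = num[11],
      t_size = num[12], t_start = num[13], t_end = num[14],
      blocks = I(list(cbind(qs = qst, ts = tst, len = sizes))),
      stringsAsFactors = FALSE)
  })
  alignment_records(do.call(rbind, rows))
}

#' Write alignment records as PSL
#'
#' Inverse of [read_psl()]: emits headerless 21-column PSL, restoring the
#' reverse-complement per-block query coordinates for minus-strand records.
#'
#' @param records an `erv_alignments` data.frame.
#' @param path output path.
#' @export
write_psl <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    b <- r$blocks[[1]]
    qst <- b[, "qs"]
    if (r$strand == "-") qst <- r$q_size - (qst + b[, "len"])
    writeLines(paste(
      r$match, r$mismatch, 0L, 0L, r$q_gap_count, r$q_gap_bases,
      r$t_gap_count, r$t_gap_bases, r$strand, r$q_name, r$q_size,
      r$q_start, r$q_end, r$t_name, r$t_size, r$t_start, r$t_end,
      nrow(b),
      paste0(paste(b[, "len"], collapse = ","), ","),
      paste0(paste(qst, collapse = ","), ","),
      paste0(paste(b[, "ts"], collapse = ","), ","),
      sep = "\t"), con)
  }
  invisible(path)
}
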