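REGION_NAMES <- c("5'LTR", "gag", "pro", "pol", "env", "3'LTR")
INTERNAL_REGIONS <- c("gag", "pro", "pol", "env")

#' Default HML-8 proviral region layout
#'
#' Coordinate layout of the 10485-bp MER11A-HERVK11-MER11A consensus model:
#' two flanking long terminal repeats (LTRs) and the four internal open
#' reading frames. ORF junctions overlap (gag/pro, pro/pol, pol/env), which
#' is normal for retroviral coding layouts; region arithmetic treats each
#' region independently.
#'
#' @return data.frame with columns `region`, `start`, `end`
#'   (1-based inclusive reference coordinates).
#' @export
default_proviral_layout <- function() {
  data.frame(
    region = REGION_NAMES,
    start  = c(1L, 1422L, 3341L, 4303L, 6890L, 9220L),
    end    = c(1266L, 3530L, 4345L, 7032L, 9217L, 10485L),
    stringsAsFactors = FALSE
  )
}

validate_layout <- function(layout, seq_length = NULL) {
  if (!is.data.frame(layout) ||
      !all(c("region", "start", "end") %in% names(layout)))
    stopf("layout must be a data.frame with columns region, start, end")
  if (!setequal(layout$region, REGION_NAMES))
    stopf("layout must cover exactly the six regions: %s",
          paste(REGION_NAMES, collapse = ", "))
  layout <- layout[match(REGION_NAMES, layout$region), ]
  if (any(layout$start < 1) || any(layout$end < layout$start))
    stopf("layout intervals must satisfy 1 <= start <= end")
  total <- layout$end[layout$region == "3'LTR"]
  if (layout$start[layout$region == "5'LTR"] != 1L)
    stopf("5'LTR must start at reference position 1")
  if (is.null(seq_length)) seq_length <- total
  if (any(layout$end > seq_length))
    stopf("layout interval ends at %d, beyond reference length %d",
          max(layout$end), seq_length)
  i5 <- which(layout$region == "5'LTR"); i3 <- which(layout$region == "3'LTR")
  if (layout$end[i5] >= layout$start[i3])
    stopf("5'LTR and 3'LTR intervals overlap")
  if (layout$end[i3] != seq_length)
    stopf("3'LTR must end at the reference length (%d)", seq_length)
  layout
}

#' Construct a proviral reference object
#'
#' Bundles a consensus nucleotide sequence with its six-region layout
#' (5'LTR, gag, pro, pol, env, 3'LTR). All coordinates are 1-based inclusive
#' on the consensus.
#'
#' @param sequence character scalar of A/C/G/T (ambiguity codes permitted).
#' @param layout data.frame as from [default_proviral_layout()].
#' @param name reference name.
#' @return object of class `proviral_reference` with elements `name`,
#'   `sequence`, `layout`.
#' @export
proviral_reference <- function(sequence,
                               layout = default_proviral_layout(),
                               name = "consensus") {
  sequence <- toupper(as.character(sequence))
  layout <- validate_layout(layout, nchar(sequence))
  structure(list(name = name, sequence = sequence, layout = layout),
            class = "proviral_reference")
}

#' @export
print.proviral_reference <- function(x, ...) {
  cat(sprintf("Proviral reference '%s': %d bp\n", x$name, nchar(x$sequence)))
  for (i in seq_len(nrow(x$layout)))
    cat(sprintf("  %-6s %5d-%5d (%d bp)\n", x$layout$region[i],
                x$layout$start[i], x$layout$end[i],
                x$layout$end[i] - x$layout$start[i] + 1L))
  invisible(x)
}

region_length <- function(reference, region) {
  lay <- reference$layout
  i <- match(region, lay$region)
  lay$end[i] - lay$start[i] + 1L
}

#' Generate a random proviral reference sequence for a layout
#'
#' Draws a uniform-random A/C/G/T sequence of the layout's total length.
#' Used by the simulator; real analyses supply the Dfam consensus instead.
#'
#' @param layout region layout data.frame; total length is the 3'LTR end.
#' @param seed integer RNG seed; the same seed always yields the same
#'   sequence.
#' @param name reference name.
#' @return a [proviral_reference()] object.
#' @export
generate_reference <- function(layout = default_proviral_layout(), seed = 1,
                               name = "synthetic-consensus") {
  layout <- validate_layout(layout)
  n <- layout$end[layout$region == "3'LTR"]
  seq <- with_seed(seed, random_dna(n))
  proviral_reference(seq, layout, name = name)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Read / write a region layout table
#'
#' Tab-separated with columns `region`, `start`, `end`.
#'
#' @param path file path.
#' @return `read_layout` returns the validated layout data.frame.
#' @export
read_layout <- function(path) {
  validate_layout(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_layout
#' @param layout layout data.frame to write.
#' @export
write_layout <- function(layout, path) {
  write.table(validate_layout(layout), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Mutate a sequence by independent random substitutions
#'
#' Each site is substituted with probability `divergence`; the replacement is
#' drawn uniformly from the three other bases, so the expected proportion of
#' sites differing from the input (the p-distance) equals `divergence`. This
#' forward-simulates the neutral divergence that molecular-clock dating must
#' recover. No indels are introduced.
#'
#' @param seq nucleotide string.
#' @param divergence per-site substitution probability in \[0, 0.5\].
#' @param seed integer RNG seed.
#' @return mutated sequence of the same length.
#' @export
mutate_sequence <- function(seq, divergence, seed = 1) {
  if (!is.numeric(divergence) || divergence < 0 || divergence > 0.5)
    stopf("divergence must lie in [0, 0.5], got %s", format(divergence))
  if (divergence == 0) return(seq)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    x <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(x)) < divergence)
    if (length(hit)) {
      # draw one of the 3 other bases via an offset in 1..3
      off <- sample.int(3L, length(hit), replace = TRUE)
      cur <- match(x[hit], bases)
      cur[is.na(cur)] <- 1L  # ambiguity codes mutate as if A
      x[hit] <- bases[((cur - 1L + off) %% 4L) + 1L]
    }
    paste(x, collapse = "")
  })
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
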