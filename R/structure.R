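#' Per-region integrity profile of a locus
#'
#' Maps the consensus intervals covered by a locus onto the six-region
#' proviral layout and reports, for each region, the fraction of the
#' region's reference length that is aligned. Bases in overlapping ORF
#' junctions (gag/pro, pro/pol, pol/env) count toward both regions, each
#' region being profiled independently.
#'
#' @param blocks 2-column matrix of consensus intervals covered (1-based
#'   inclusive), e.g. a `ref_blocks` entry from [assemble_loci()].
#' @param reference a [proviral_reference()].
#' @param name locus name carried into the result.
#' @return named numeric vector of six fractions in \[0, 1\] with class
#'   `region_profile` and attribute `name`.
#' @export
profile_regions <- function(blocks, reference, name = NA_character_) {
  stopifnot(inherits(reference, "proviral_reference"))
  blocks <- as.matrix(blocks)
  if (!nrow(blocks)) {
    frac <- setNames(rep(0, 6), REGION_NAMES)
    return(structure(frac, class = "region_profile", name = name))
  }
  rl <- nchar(reference$sequence)
  if (any(blocks < 1) || any(blocks > rl))
    stopf("block interval outside reference [1, %d]", rl)
  blocks <- merge_intervals(blocks[, 1:2, drop = FALSE])
  lay <- reference$layout
  frac <- vapply(REGION_NAMES, function(r) {
    i <- match(r, lay$region)
    ov <- sum(interval_overlap(blocks[, 1], blocks[, 2],
                               lay$start[i], lay$end[i]))
    ov / (lay$end[i] - lay$start[i] + 1)
  }, 0)
  structure(frac, class = "region_profile", name = name)
}

#' @export
print.region_profile <- function(x, ...) {
  nm <- attr(x, "name")
  cat(sprintf("Region integrity%s:\n",
              if (is.na(nm)) "" else paste0(" for ", nm)))
  print(round_half_up(100 * unclass(x), 2))
  invisible(x)
}

#' Profile every locus in a table
#'
#' @param loci an `erv_loci` data.frame with a `ref_blocks` column.
#' @param reference a [proviral_reference()].
#' @return data.frame with one row per locus and one column per region
#'   (fractions in \[0,1\]), classed `region_profiles`.
#' @export
profile_loci <- function(loci, reference) {
  mat <- t(vapply(seq_len(nrow(loci)), function(i)
    unclass(profile_regions(loci$ref_blocks[[i]], reference)),
    setNames(numeric(6), REGION_NAMES)))
  out <- data.frame(name = loci$name, mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_profiles", "data.frame")
  out
}

as_profile_matrix <- function(profiles) {
  if (inherits(profiles, "region_profiles") || is.data.frame(profiles)) {
    m <- as.matrix(profiles[, REGION_NAMES, drop = FALSE])
  } else if (is.list(profiles)) {
    if (!length(profiles))
      return(matrix(numeric(0), 0, 6,
                    dimnames = list(NULL, REGION_NAMES)))
    m <- do.call(rbind, lapply(profiles, function(p)
      unclass(p)[REGION_NAMES]))
  } else m <- matrix(unclass(profiles)[REGION_NAMES], nrow = 1,
                     dimnames = list(NULL, REGION_NAMES))
  m
}

#' Count complete region deletions
#'
#' A region is completely deleted from a locus when exactly zero reference
#' bases of that region are aligned (no epsilon).
#'
#' @param profiles a `region_profiles` data.frame, list of
#'   [profile_regions()] results, or a single profile.
#' @return named integer vector: per-region count of loci with zero
#'   coverage.
#' @export
count_complete_deletions <- function(profiles) {
  m <- as_profile_matrix(profiles)
  if (!nrow(m)) return(setNames(integer(6), REGION_NAMES))
  setNames(colSums(m == 0), REGION_NAMES)
}

#' Detect a solo LTR
#'
#' Solo LTRs are single LTRs left behind when homologous recombination
#' between a provirus's two LTRs deletes the internal coding sequence. A
#' profile is a solo-LTR call when at least one LTR retains
#' `min_ltr_cov` of its reference length while all four internal regions
#' have exactly zero coverage.
#'
#' @param profile a [profile_regions()] result (or named fraction vector).
#' @param min_ltr_cov minimum LTR coverage fraction.
#' @return logical.
#' @export
detect_solo_ltr <- function(profile, min_ltr_cov = 0.5) {
  p <- unclass(profile)[REGION_NAMES]
  max(p["5'LTR"], p["3'LTR"]) >= min_ltr_cov &&
    all(p[INTERNAL_REGIONS] == 0)
}

#' Length summary of a locus table
#'
#' Mean length over all loci (rounded to the nearest bp); minimum and
#' maximum over loci without an `Insertion` flag, whose genomic span
#' reflects proviral content rather than nested foreign sequence. Bins
#' count loci by 10-percent coverage bins and by the coarse coverage
#' classes (>70 percent, 40-70 percent, <40 percent of the reference).
#'
#' @param loci an `erv_loci` data.frame (needs `length`,
#'   `coverage_fraction`, `range_bin`, `indel_flags`).
#' @return list with `n`, `mean_bp`, `min_bp`, `max_bp`, `bin_counts`,
#'   `class_counts`, classed `length_summary`.
#' @export
summarize_lengths <- function(loci) {
  if (!nrow(loci)) stopf("no loci to summarize")
  no_ins <- !grepl("Insertion", ifelse(is.na(loci$indel_flags), "",
                                       loci$indel_flags))
  lens <- loci$length
  cov <- loci$coverage_fraction
  bins <- table(loci$range_bin)
  structure(list(
    n = nrow(loci),
    mean_bp = round_half_up(mean(lens), 0),
    min_bp = min(lens[no_ins]),
    max_bp = max(lens[no_ins]),
    bin_counts = setNames(as.integer(bins), names(bins)),
    class_counts = c(`>70%` = sum(cov > 0.70),
                     `40-70%` = sum(cov >= 0.40 & cov <= 0.70),
                     `<40%` = sum(cov < 0.40))),
    class = "length_summary")
}

#' @export
print.length_summary <- function(x, ...) {
  cat(sprintf("%d loci: mean %d bp, min %d bp, max %d bp\n",
              x$n, x$mean_bp, x$min_bp, x$max_bp))
  cat("coverage classes: ",
      paste(sprintf("%s: %d", names(x$class_counts), x$class_counts),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a region-integrity table
#'
#' TSV with one row per locus and six percentage columns (two decimals).
#'
#' @param profiles a `region_profiles` data.frame from [profile_loci()].
#' @param path output path.
#' @export
write_integrity_table <- function(profiles, path) {
  df <- data.frame(name = profiles$name,
                   round_half_up(100 * as_profile_matrix(profiles), 2),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
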