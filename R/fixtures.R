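FIXTURE_FILES <- c(
  table1 = "table1_loci.tsv",
  table2 = "table2_integrity.tsv",
  table3 = "table3_ages.tsv")

FIXTURE_MD5 <- c(
  table1 = "7d229f03238d5a3fb78441e2f9aebf93",
  table2 = "d6f08a9d745c26d860915f0061f080b8",
  table3 = "075995092142c6f0597a83b5edc49c6f")

#' Load a packaged locus-catalog fixture
#'
#' Three published-catalog tables ship with the package as TSV
#' transcriptions, checksummed against drift: `table1` — the 76-locus
#' provirus distribution (position, length, coverage, query-gap fraction,
#' indel flags, genomic context); `table2` — per-locus integrity of the six
#' proviral regions (percent of each reference region aligned); `table3` —
#' per-region divergences from consensus and clock ages for the 46 datable
#' elements. Printed values are preserved exactly; derived convenience
#' columns (`name`, fraction-scale copies of percentages) are added.
#'
#' @param table one of `"table1"`, `"table2"`, `"table3"`.
#' @return data.frame; `table1` additionally carries class `erv_loci`
#'   (without `ref_blocks`), `table2` class `region_profiles`.
#' @export
load_fixture <- function(table = c("table1", "table2", "table3")) {
  table <- match.arg(table)
  path <- system.file("extdata", FIXTURE_FILES[[table]],
                      package = "ervscape", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(FIXTURE_MD5[[table]])))
    stopf("fixture %s fails its checksum (%s); packaged data has drifted",
          FIXTURE_FILES[[table]], sum)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (table == "table1") {
    df$name <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
    df$length <- df$length_bp
    df$coverage_fraction <- df$coverage_pct / 100
    df$q_gap_fraction <- df$qgap_pct / 100
    df$indel_flags <- df$indel
    class(df) <- c("erv_loci", "data.frame")
  } else if (table == "table2") {
    df$name <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
    pct <- c(ltr5_pct = "5'LTR", gag_pct = "gag", pro_pct = "pro",
             pol_pct = "pol", env_pct = "env", ltr3_pct = "3'LTR")
    for (col in names(pct)) df[[pct[[col]]]] <- df[[col]] / 100
    class(df) <- c("region_profiles", "data.frame")
  } else {
    df$name <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  }
  df
}
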