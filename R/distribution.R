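#' Nongap chromosome lengths from a genome
#'
#' Assembly length per chromosome minus runs of N, the denominator used for
#' expected insertion counts.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @return named numeric vector of nongap lengths.
#' @export
nongap_lengths <- function(genome) {
  seqs <- read_genome(genome)
  vapply(seqs, function(s)
    nchar(s) - sum(strsplit(s, "")[[1]] %in% c("N", "n")), 0)
}

#' Expected insertion counts per chromosome
#'
#' Under random integration, the expected number of loci on a chromosome is
#' proportional to its nongap length: `e = Cl * N / Tl`, with `Cl` the
#' chromosome nongap length, `N` the total number of loci, and `Tl` the
#' summed nongap length.
#'
#' @param nongap named vector of per-chromosome nongap lengths (bp).
#' @param n total number of observed loci.
#' @return named numeric vector of expected counts summing to `n`.
#' @export
expected_counts <- function(nongap, n) {
  if (!length(nongap)) stopf("empty chromosome length map")
  if (any(nongap <= 0)) stopf("nongap lengths must be positive")
  if (n < 0) stopf("n must be non-negative")
  nongap * n / sum(nongap)
}

#' Chi-square goodness-of-fit test of observed vs expected counts
#'
#' `statistic = sum((o - e)^2 / e)` on `k - 1` degrees of freedom, with the
#' p-value from the upper chi-square tail.
#'
#' @param observed,expected named vectors over the same chromosomes.
#' @return list(statistic, df, p_value).
#' @export
chisq_gof <- function(observed, expected) {
  if (!setequal(names(observed), names(expected)))
    stopf("observed and expected must cover the same chromosomes")
  expected <- expected[names(observed)]
  if (any(expected <= 0)) stopf("expected counts must be positive")
  k <- length(observed)
  if (k < 2) stopf("degenerate test: need at least 2 categories")
  stat <- sum((observed - expected)^2 / expected)
  df <- k - 1
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Per-chromosome enrichment / depletion flags
#'
#' For each chromosome, a 1-df chi-square of that chromosome against the
#' pooled remainder; `enriched` when observed > expected with p < alpha,
#' `depleted` when observed < expected with p < alpha, else `ns`. The fold
#' is observed/expected. Raw p-values are used by default, mirroring how
#' per-chromosome excesses are usually reported; `adjust = "BH"` applies
#' Benjamini-Hochberg across chromosomes.
#'
#' @param observed,expected named count vectors.
#' @param alpha significance level.
#' @param adjust `"none"` or `"BH"`.
#' @return data.frame with `chrom`, `observed`, `expected`, `fold`,
#'   `p_value`, `flag`.
#' @export
per_chrom_flags <- function(observed, expected, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!setequal(names(observed), names(expected)))
    stopf("observed and expected must cover the same chromosomes")
  expected <- expected[names(observed)]
  if (any(expected <= 0)) stopf("expected counts must be positive")
  N <- sum(observed); E <- sum(expected)
  p <- vapply(seq_along(observed), function(i) {
    o2 <- c(observed[i], N - observed[i])
    e2 <- c(expected[i], E - expected[i])
    stat <- sum((o2 - e2)^2 / e2)
    pchisq(stat, 1, lower.tail = FALSE)
  }, 0)
  if (adjust == "BH") p <- p.adjust(p, "BH")
  flag <- ifelse(p >= alpha, "ns",
                 ifelse(observed > expected, "enriched", "depleted"))
  data.frame(chrom = names(observed), observed = as.numeric(observed),
             expected = as.numeric(expected),
             fold = as.numeric(observed) / as.numeric(expected),
             p_value = p, flag = flag, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Test for nonrandom chromosomal integration
#'
#' Convenience wrapper: expected counts from nongap lengths, the global
#' goodness-of-fit test, and per-chromosome flags.
#'
#' @param loci an `erv_loci` data.frame (uses its `chrom` column), or a
#'   named vector of observed counts.
#' @param nongap named vector of nongap chromosome lengths.
#' @param alpha significance level for the flags.
#' @param adjust multiple-testing adjustment for the flags.
#' @return list(observed, expected, global = list(statistic, df, p_value),
#'   per_chrom), classed `distribution_test`.
#' @export
distribution_test <- function(loci, nongap, alpha = 0.05,
                              adjust = c("none", "BH")) {
  observed <- if (is.data.frame(loci)) {
    tab <- table(factor(loci$chrom, levels = names(nongap)))
    setNames(as.numeric(tab), names(tab))
  } else loci[names(nongap)]
  expected <- expected_counts(nongap, sum(observed))
  structure(list(
    observed = observed, expected = expected,
    global = chisq_gof(observed, expected),
    per_chrom = per_chrom_flags(observed, expected, alpha, adjust)),
    class = "distribution_test")
}

#' @export
print.distribution_test <- function(x, ...) {
  cat(sprintf("Global chi-square = %.3f, df = %d, p = %.3g\n",
              x$global$statistic, x$global$df, x$global$p_value))
  sig <- x$per_chrom[x$per_chrom$flag != "ns", , drop = FALSE]
  if (nrow(sig)) {
    cat("Significant chromosomes:\n")
    print.data.frame(sig, row.names = FALSE, digits = 3)
  } else cat("No chromosome significant at the chosen level\n")
  invisible(x)
}
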