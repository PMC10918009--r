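split_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)

#' Majority-rule consensus of aligned sequences
#'
#' Per column, the most frequent non-gap base; a column where gaps are the
#' majority is emitted as a gap. Ties between bases are broken by the fixed
#' order A < C < G < T for determinism. The consensus stands in for an
#' ancestral-sequence reconstruction when estimating the divergence of each
#' element from the group ancestor.
#'
#' @param seqs character vector of equal-length aligned sequences (gap
#'   character `-`), length >= 2.
#' @param tie_rule only `"fixed-order"` is implemented.
#' @return consensus sequence string.
#' @export
build_consensus <- function(seqs, tie_rule = "fixed-order") {
  if (length(seqs) < 2) stopf("need at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1)
    stopf("ragged alignment: sequences differ in length")
  m <- do.call(rbind, split_chars(seqs))
  bases <- c("A", "C", "G", "T")
  apply_col <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    gaps <- sum(col %in% c("-", "."))
    if (gaps > length(col) / 2) return("-")
    cnt <- vapply(bases, function(b) sum(col == b), 0L)
    if (all(cnt == 0)) return("N")
    bases[which.max(cnt)]  # which.max takes the first (A<C<G<T) on ties
  }, "")
  paste(apply_col, collapse = "")
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among sites where both sequences carry an
#' unambiguous base (pairwise deletion of gaps and Ns).
#'
#' @param a,b equal-length aligned sequences.
#' @return fraction in \[0, 1\].
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stopf("sequences differ in length")
  x <- split_chars(a)[[1]]; y <- split_chars(b)[[1]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(ok)) stopf("no comparable sites")
  sum(x[ok] != y[ok]) / sum(ok)
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' `d = -(3/4) ln(1 - (4/3) p)`; exposed as an optional model-corrected
#' alternative to the raw p-distance for the clock.
#'
#' @inheritParams p_distance
#' @return corrected distance.
#' @export
jc_distance <- function(a, b) {
  p <- p_distance(a, b)
  if (p >= 0.75) stopf("saturated pair: p = %.3f out of JC domain", p)
  -0.75 * log(1 - 4 * p / 3)
}

#' Integration age from divergence under the neutral clock
#'
#' At a neutral substitution rate of `rate` percent per nucleotide per
#' million years (default 0.2), an internal region diverging from the group
#' consensus by fraction `D` is `T = (D*100)/rate` million years old. The
#' two LTRs of a provirus were identical at integration and diverge from
#' each other at twice the rate, so LTR-LTR divergence is halved:
#' `T = (D*100)/rate/2`.
#'
#' @param D divergence as a fraction in \[0, 1\].
#' @param method `"internal"` (element vs consensus) or `"ltr-ltr"`.
#' @param rate clock rate in percent per nucleotide per Myr.
#' @return age in million years.
#' @export
age_from_divergence <- function(D, method = c("internal", "ltr-ltr"),
                                rate = 0.2) {
  method <- match.arg(method)
  if (any(D < 0 | D > 1)) stopf("divergence must lie in [0, 1]")
  if (rate <= 0) stopf("clock rate must be positive")
  age <- D * 100 / rate
  if (method == "ltr-ltr") age <- age / 2
  age
}

#' Per-element age from region divergences
#'
#' Averages the available internal-region divergences (gag, pro, pol, env;
#' absent regions are skipped) without intermediate rounding, then applies
#' the internal-region clock.
#'
#' @param region_divergences named numeric vector or list with any of
#'   `gag`, `pro`, `pol`, `env`; `NA` or missing entries are ignored.
#' @param name element name.
#' @param rate clock rate in percent per nucleotide per Myr.
#' @return object of class `age_estimate`: list with `name`,
#'   `region_divergences`, `mean_divergence`, `age_myr`, `method`.
#' @export
element_age <- function(region_divergences, name = NA_character_,
                        rate = 0.2) {
  d <- unlist(region_divergences)
  d <- d[names(d) %in% INTERNAL_REGIONS]
  d <- d[!is.na(d)]
  if (!length(d)) stopf("no region divergences available")
  mean_d <- mean(d)
  structure(list(name = name, region_divergences = d,
                 mean_divergence = mean_d,
                 age_myr = age_from_divergence(mean_d, "internal", rate),
                 method = "internal-vs-consensus"),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("%s: mean divergence %.4f over {%s} -> %.2f Myr (%s)\n",
              if (is.na(x$name)) "element" else x$name,
              x$mean_divergence,
              paste(names(x$region_divergences), collapse = ", "),
              round_half_up(x$age_myr, 2), x$method))
  invisible(x)
}

#' Summary statistics over age estimates
#'
#' @param estimates list of [element_age()] results or a numeric vector of
#'   ages in Myr.
#' @return list(mean, median, min, max) at two decimals (half-up), classed
#'   `age_summary`.
#' @export
summarize_ages <- function(estimates) {
  ages <- if (is.numeric(estimates)) estimates else
    vapply(estimates, function(e) e$age_myr, 0)
  if (!length(ages)) stopf("no age estimates to summarize")
  structure(list(mean = round_half_up(mean(ages), 2),
                 median = round_half_up(median(ages), 2),
                 min = round_half_up(min(ages), 2),
                 max = round_half_up(max(ages), 2),
                 n = length(ages)),
            class = "age_summary")
}

#' @export
print.age_summary <- function(x, ...) {
  cat(sprintf(
    "%d elements: mean %.2f, median %.2f, min %.2f, max %.2f Myr\n",
    x$n, x$mean, x$median, x$min, x$max))
  invisible(x)
}

#' Region divergences of aligned elements from their consensus
#'
#' For one internal region: given a gapped alignment of the region across
#' elements, builds the majority consensus and returns each element's
#' p-distance (or Jukes-Cantor distance) from it. Elements whose ungapped
#' region length is below `min_fraction` of the reference region length are
#' dropped, mirroring the dating eligibility rule (region length must
#' exceed 90 percent of the reference region).
#'
#' @param aligned named character vector of aligned region sequences.
#' @param reference a [proviral_reference()].
#' @param region one of `gag`, `pro`, `pol`, `env`.
#' @param min_fraction eligibility threshold on ungapped length.
#' @param model `"p"` or `"JC"`.
#' @return named numeric vector of divergences for the eligible elements.
#' @export
region_divergences <- function(aligned, reference, region,
                               min_fraction = 0.9, model = c("p", "JC")) {
  model <- match.arg(model)
  region <- match.arg(region, INTERNAL_REGIONS)
  reflen <- region_length(reference, region)
  ungapped <- nchar(gsub("[-.]", "", aligned))
  eligible <- ungapped > min_fraction * reflen
  aligned <- aligned[eligible]
  if (length(aligned) < 2)
    stopf("fewer than 2 elements eligible for region %s", region)
  cons <- build_consensus(aligned)
  dist_fun <- if (model == "p") p_distance else jc_distance
  vapply(aligned, dist_fun, 0, b = cons)
}
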