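#' GREAT-style regulatory domains
#'
#' Each gene gets a basal domain around its TSS (`up` bp upstream, `down`
#' bp downstream, strand-aware) and an extended domain growing from the
#' basal domain on each side up to `max_ext` bp, stopping earlier at the
#' nearest other gene's basal domain boundary. The extension never shrinks
#' below the basal domain (when a neighbor's basal domain already overlaps,
#' extension in that direction is zero) and is clipped at chromosome ends.
#'
#' @param models a [gene_models()] object.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param up,down basal window in bp upstream/downstream of the TSS.
#' @param max_ext maximum extension in bp on each side.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `basal_start`, `basal_end`, `ext_start`, `ext_end`.
#' @export
regulatory_domains <- function(models, chrom_lengths, up = 5000,
                               down = 1000, max_ext = 1000000) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  bad <- !g$chrom %in% names(chrom_lengths)
  if (any(bad)) stopf("unknown chromosome(s): %s",
                      paste(unique(g$chrom[bad]), collapse = ", "))
  L <- chrom_lengths[g$chrom]
  if (any(g$tss < 1 | g$tss > L)) stopf("TSS outside chromosome bounds")
  plus <- g$strand != "-"
  basal_start <- pmax(1, ifelse(plus, g$tss - up, g$tss - down))
  basal_end <- pmin(L, ifelse(plus, g$tss + down, g$tss + up))
  ext_start <- numeric(nrow(g)); ext_end <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    same <- which(g$chrom == g$chrom[i])
    same <- setdiff(same, i)
    lo <- max(1, basal_start[i] - max_ext)
    hi <- min(L[i], basal_end[i] + max_ext)
    # stop at the nearest neighbor basal boundary on each side
    left_bounds <- basal_end[same][basal_end[same] < basal_start[i]]
    if (length(left_bounds)) lo <- max(lo, max(left_bounds))
    right_bounds <- basal_start[same][basal_start[same] > basal_end[i]]
    if (length(right_bounds)) hi <- min(hi, min(right_bounds))
    # overlapping neighbor basal domains freeze extension on that side
    ov_left <- any(basal_start[same] < basal_start[i] &
                     basal_end[same] >= basal_start[i])
    ov_right <- any(basal_end[same] > basal_end[i] &
                      basal_start[same] <= basal_end[i])
    if (ov_left) lo <- basal_start[i]
    if (ov_right) hi <- basal_end[i]
    ext_start[i] <- min(lo, basal_start[i])
    ext_end[i] <- max(hi, basal_end[i])
  }
  data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             tss = g$tss, basal_start = basal_start, basal_end = basal_end,
             ext_start = ext_start, ext_end = ext_end, row.names = NULL,
             stringsAsFactors = FALSE)
}

DISTANCE_BINS <- c("<5 kb", "5-50 kb", "50-500 kb", ">500 kb")

bin_distance <- function(abs_dist) {
  cut(abs_dist, breaks = c(-1, 5000, 50000, 500000, Inf),
      labels = DISTANCE_BINS)
}

#' Associate LTR loci with regulatory domains
#'
#' One association per (locus, gene) pair whose extended regulatory domain
#' overlaps the locus interval. The distance is measured from the locus
#' midpoint to the TSS (signed in genome coordinates, binned on the
#' absolute value); orientation is upstream/downstream of the TSS relative
#' to the gene's strand.
#'
#' @param loci data.frame with `name`, `chrom`, `start`, `end` (an
#'   `erv_loci` table or any interval table).
#' @param domains output of [regulatory_domains()].
#' @return data.frame with `locus`, `gene_id`, `distance`, `abs_distance`,
#'   `bin`, `orientation`.
#' @export
associate_ltrs <- function(loci, domains) {
  out <- list()
  for (i in seq_len(nrow(loci))) {
    hit <- domains$chrom == loci$chrom[i] &
      domains$ext_start <= loci$end[i] & domains$ext_end >= loci$start[i]
    if (!any(hit)) next
    d <- domains[hit, , drop = FALSE]
    mid <- floor((loci$start[i] + loci$end[i]) / 2)
    dist <- mid - d$tss
    upstream <- ifelse(d$strand == "-", dist > 0, dist < 0)
    out[[length(out) + 1L]] <- data.frame(
      locus = loci$name[i], gene_id = d$gene_id, distance = dist,
      abs_distance = abs(dist),
      bin = as.character(bin_distance(abs(dist))),
      orientation = ifelse(upstream, "upstream", "downstream"),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(locus = character(0), gene_id = character(0),
                      distance = numeric(0), abs_distance = numeric(0),
                      bin = character(0), orientation = character(0)))
  do.call(rbind, out)
}

#' Select LTR loci eligible for regulatory association
#'
#' Keeps loci whose best LTR coverage (5' or 3') exceeds `min_ltr_cov` of
#' the reference LTR length.
#'
#' @param loci an `erv_loci` data.frame with `ref_blocks`.
#' @param reference a [proviral_reference()].
#' @param min_ltr_cov minimum LTR coverage fraction (default 0.7).
#' @return the eligible subset of `loci`.
#' @export
eligible_ltr_loci <- function(loci, reference, min_ltr_cov = 0.7) {
  keep <- vapply(seq_len(nrow(loci)), function(i) {
    p <- profile_regions(loci$ref_blocks[[i]], reference)
    max(p["5'LTR"], p["3'LTR"]) > min_ltr_cov
  }, TRUE)
  loci[keep, , drop = FALSE]
}

#' Read a GMT category file
#'
#' One category per line: id, description, then member gene ids,
#' tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors (names are category ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line: %s", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  out
}

#' Over-representation analysis with BH FDR
#'
#' For each category (filtered to `min_size`..`max_size` members within the
#' universe), the hypergeometric upper-tail probability of drawing at least
#' the observed overlap when sampling `length(genes)` genes from the
#' universe. FDR is Benjamini-Hochberg across the tested categories;
#' results are sorted by FDR then p and truncated to `top`.
#'
#' @param genes character vector of genes of interest (subset of universe).
#' @param categories named list of character vectors (gene sets).
#' @param universe character vector of all eligible genes.
#' @param min_size,max_size category size filter (within-universe size).
#' @param top number of rows to return.
#' @return data.frame with `category`, `size`, `overlap`,
#'   `enrichment_ratio`, `p_value`, `fdr`.
#' @export
ora_enrichment <- function(genes, categories, universe, min_size = 5,
                           max_size = 2000, top = 10) {
  if (!length(universe)) stopf("empty universe")
  universe <- unique(universe)
  genes <- unique(genes)
  if (!all(genes %in% universe))
    stopf("gene list contains ids outside the universe")
  cats <- lapply(categories, function(cc) intersect(unique(cc), universe))
  sizes <- lengths(cats)
  keep <- sizes >= min_size & sizes <= max_size
  cats <- cats[keep]; sizes <- sizes[keep]
  if (!length(cats))
    return(data.frame(category = character(0), size = integer(0),
                      overlap = integer(0), enrichment_ratio = numeric(0),
                      p_value = numeric(0), fdr = numeric(0)))
  N <- length(universe); n <- length(genes)
  overlap <- vapply(cats, function(cc) length(intersect(cc, genes)), 0L)
  p <- phyper(overlap - 1, sizes, N - sizes, n, lower.tail = FALSE)
  ratio <- (overlap / n) / (sizes / N)
  fdr <- p.adjust(p, "BH")
  out <- data.frame(category = names(cats), size = sizes,
                    overlap = overlap, enrichment_ratio = ratio,
                    p_value = p, fdr = fdr, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(out$fdr, out$p_value, out$category), , drop = FALSE]
  head(out, top)
}
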