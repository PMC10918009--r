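#' Gene model container
#'
#' Holds gene intervals and their exons, with the transcription start site
#' (TSS) derived from strand: gene start on `+`, gene end on `-`.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (1-based inclusive).
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @return object of class `gene_models`: list(genes, exons) with a `tss`
#'   column added to `genes`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)),
            all(c("gene_id", "chrom", "start", "end") %in% names(exons)))
  bad <- !exons$gene_id %in% genes$gene_id
  if (any(bad)) stopf("exons reference unknown gene ids: %s",
                      paste(unique(exons$gene_id[bad]), collapse = ", "))
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("Gene models: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA (one per gene) and exon features with ID/Parent links.
#'
#' @param models a [gene_models()] object.
#' @param path output path.
#' @export
write_gff3 <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- models$genes
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    writeLines(sprintf("%s\tervscape\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom[i], g$start[i], g$end[i], g$strand[i], gid),
               con)
    mid <- paste0(gid, ".t1")
    writeLines(sprintf("%s\tervscape\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chrom[i], g$start[i], g$end[i], g$strand[i], mid,
                       gid), con)
    ex <- models$exons[models$exons$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      writeLines(sprintf("%s\tervscape\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         ex$chrom[j], ex$start[j], ex$end[j], g$strand[i],
                         mid), con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Uses rtracklayer to parse the file; `gene` features define gene intervals
#' and `exon` features are attached to genes through their mRNA parents.
#'
#' @param path GFF3 file.
#' @return a [gene_models()] object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  gg <- gr[typ == "gene"]
  genes <- data.frame(
    gene_id = as.character(gg$ID),
    chrom = as.character(GenomicRanges::seqnames(gg)),
    strand = as.character(GenomicRanges::strand(gg)),
    start = GenomicRanges::start(gg), end = GenomicRanges::end(gg),
    stringsAsFactors = FALSE)
  mr <- gr[typ == "mRNA"]
  m2g <- setNames(vapply(mr$Parent, function(p) as.character(p)[1], ""),
                  as.character(mr$ID))
  ee <- gr[typ == "exon"]
  parent <- vapply(ee$Parent, function(p) as.character(p)[1], "")
  gene_of <- ifelse(parent %in% names(m2g), m2g[parent], parent)
  exons <- data.frame(
    gene_id = unname(gene_of),
    chrom = as.character(GenomicRanges::seqnames(ee)),
    start = GenomicRanges::start(ee), end = GenomicRanges::end(ee),
    stringsAsFactors = FALSE)
  gene_models(genes, exons)
}

CONTEXT_LABELS <- c("intergenic", "intron", "exonic&intronic",
                    "genic&intergenic", "exon")

#' Classify a locus against gene annotation
#'
#' Assigns one of the genomic-context labels used in proviral locus tables:
#' `intergenic` (no gene overlap), `intron` (fully inside a gene but touching
#' no exon), `exon` (fully inside an exon), `exonic&intronic` (inside a gene,
#' overlapping both exon and intron), `genic&intergenic` (crossing a gene
#' boundary). Classification is strand-agnostic; overlap with any gene
#' counts, and exon takes precedence over intron base-wise.
#'
#' @param chrom,start,end locus interval (1-based inclusive).
#' @param models a [gene_models()] object.
#' @return a single context label.
#' @export
classify_context <- function(chrom, start, end, models) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes[models$genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) {
    if (!chrom %in% models$genes$chrom)
      warning(sprintf("chromosome %s absent from annotation; intergenic",
                      chrom), call. = FALSE)
    return("intergenic")
  }
  ov <- interval_overlap(g$start, g$end, start, end) > 0
  if (!any(ov)) return("intergenic")
  g <- g[ov, , drop = FALSE]
  inside <- any(g$start <= start & g$end >= end)
  if (!inside) return("genic&intergenic")
  e <- models$exons[models$exons$chrom == chrom &
                      models$exons$gene_id %in% g$gene_id, , drop = FALSE]
  eo <- interval_overlap(e$start, e$end, start, end)
  if (!nrow(e) || all(eo == 0)) return("intron")
  if (any(e$start <= start & e$end >= end)) return("exon")
  "exonic&intronic"
}

#' Summarize context labels
#'
#' Counts and percentages (two decimals, half-up) per context label.
#' Label whitespace is normalized so printed variants like
#' `"genic &intergenic"` pool with `"genic&intergenic"`.
#'
#' @param labels character vector of context labels.
#' @return data.frame with columns `context`, `count`, `percent`, classed
#'   `context_summary`.
#' @export
summarize_context <- function(labels) {
  if (!length(labels)) stopf("no labels to summarize")
  labels <- gsub("[[:space:]]+", "", labels)
  tab <- table(factor(labels, levels = unique(c(CONTEXT_LABELS, labels))))
  tab <- tab[tab > 0 | names(tab) %in% CONTEXT_LABELS]
  out <- data.frame(context = names(tab), count = as.integer(tab),
                    percent = round_half_up(100 * as.integer(tab) /
                                              length(labels), 2),
                    stringsAsFactors = FALSE)
  class(out) <- c("context_summary", "data.frame")
  out
}
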