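#' Describe one planted proviral insertion
#'
#' An insertion plan says where a (possibly truncated, diverged) copy of the
#' proviral reference is spliced into a synthetic chromosome. Kept intervals
#' are reference coordinates (1-based inclusive) retained in the copy;
#' everything between them is deleted, emulating the truncation classes seen
#' in real proviral loci (LTR loss, internal ORF loss, solo LTRs). Nested
#' inserts are foreign segments spliced inside the copy, emulating
#' kb-scale secondary insertions.
#'
#' @param chrom chromosome name.
#' @param position 1-based insertion point in the pre-insertion chromosome;
#'   the copy is inserted before this position.
#' @param strand `"+"` or `"-"`; minus-strand copies are reverse-complemented.
#' @param kept two-column matrix or data.frame of kept reference intervals
#'   (start, end), disjoint and ascending.
#' @param divergence per-site substitution probability in \[0, 0.5\].
#' @param nested data.frame with columns `offset` (1-based position in the
#'   concatenated kept sequence after which the foreign segment is spliced)
#'   and `length` (foreign bp), or NULL.
#' @param context requested genomic context for this locus, one of
#'   `"intergenic"`, `"intron"`, `"exon"`, `"exonic&intronic"`,
#'   `"genic&intergenic"`; the simulator places a gene model realizing it.
#' @param seed integer seed for this plan's mutations and foreign sequence.
#' @return object of class `insertion_plan`.
#' @export
insertion_plan <- function(chrom, position, strand = "+",
                           kept = cbind(1L, 10485L), divergence = 0,
                           nested = NULL, context = "intergenic", seed = 1) {
  kept <- as.matrix(kept)
  if (ncol(kept) != 2) stopf("kept must have two columns (start, end)")
  storage.mode(kept) <- "integer"
  if (any(kept[, 1] > kept[, 2])) stopf("kept intervals must have start <= end")
  if (nrow(kept) > 1) {
    o <- order(kept[, 1])
    kept <- kept[o, , drop = FALSE]
    if (any(kept[-1, 1] <= kept[-nrow(kept), 2]))
      stopf("kept intervals must be disjoint and ascending")
  }
  if (divergence < 0 || divergence > 0.5)
    stopf("divergence must lie in [0, 0.5]")
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  if (!is.null(nested)) {
    nested <- as.data.frame(nested)
    if (!all(c("offset", "length") %in% names(nested)))
      stopf("nested must have columns offset and length")
  }
  context <- match.arg(context, c("intergenic", "intron", "exon",
                                  "exonic&intronic", "genic&intergenic"))
  structure(list(chrom = chrom, position = as.integer(position),
                 strand = strand, kept = kept, divergence = divergence,
                 nested = nested, context = context, seed = as.integer(seed)),
            class = "insertion_plan")
}

# Realize the inserted sequence for one plan. Returns list(seq, kept_len,
# nested_len).
realize_insert <- function(reference, plan) {
  segs <- vapply(seq_len(nrow(plan$kept)), function(i)
    substr(reference$sequence, plan$kept[i, 1], plan$kept[i, 2]), "")
  body <- paste(segs, collapse = "")
  kept_len <- nchar(body)
  body <- mutate_sequence(body, plan$divergence,
                          seed = child_seed(plan$seed, 1))
  nested_len <- 0L
  if (!is.null(plan$nested) && nrow(plan$nested)) {
    nst <- plan$nested[order(plan$nested$offset, decreasing = TRUE), ,
                       drop = FALSE]
    for (i in seq_len(nrow(nst))) {
      fo <- with_seed(child_seed(plan$seed, 100 + i),
                      random_dna(nst$length[i]))
      off <- min(max(0L, as.integer(nst$offset[i])), nchar(body))
      body <- paste0(substr(body, 1, off), fo,
                     substr(body, off + 1, nchar(body)))
      nested_len <- nested_len + nst$length[i]
    }
  }
  if (plan$strand == "-") body <- revcomp(body)
  list(seq = body, kept_len = kept_len, nested_len = nested_len)
}

# Structural class of a plan given the reference layout.
plan_class <- function(reference, plan) {
  lay <- reference$layout
  cov <- vapply(REGION_NAMES, function(r) {
    i <- match(r, lay$region)
    sum(interval_overlap(plan$kept[, 1], plan$kept[, 2],
                         lay$start[i], lay$end[i]))
  }, 0)
  internal <- sum(cov[INTERNAL_REGIONS])
  ltr <- max(cov["5'LTR"], cov["3'LTR"])
  if (internal == 0 && ltr > 0) "solo-LTR" else "provirus"
}

#' Plant proviral copies into synthetic chromosomes
#'
#' Builds uniform-random background chromosomes, splices in each plan's
#' realized copy, writes the genome FASTA, a GFF3 of gene models realizing
#' each plan's requested genomic context (plus optional background genes),
#' and a truth table recording the realized coordinates and all plan
#' parameters. Everything is deterministic for a fixed seed.
#'
#' @param reference a [proviral_reference()].
#' @param plans list of [insertion_plan()] objects.
#' @param chrom_lengths named integer vector of pre-insertion chromosome
#'   lengths.
#' @param seed master integer seed for background sequence and gene placement.
#' @param out_dir output directory (created if needed).
#' @param background_gene_density target fraction of each chromosome covered
#'   by additional background genes placed away from planted loci; 0 disables.
#' @return object of class `genome_bundle`: list with `genome`, `genes`,
#'   `truth` (file paths), `truth_df` (the truth table), and `chrom_lengths`
#'   (post-insertion).
#' @export
plant_loci <- function(reference, plans, chrom_lengths, seed = 1,
                       out_dir = tempfile("bundle"),
                       background_gene_density = 0.1) {
  stopifnot(inherits(reference, "proviral_reference"))
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stopf("chrom_lengths must be a named vector")
  for (p in plans) {
    if (!inherits(p, "insertion_plan")) stopf("plans must be insertion_plan objects")
    if (!p$chrom %in% names(chrom_lengths))
      stopf("plan chromosome '%s' not in chrom_lengths", p$chrom)
    if (p$position < 1 || p$position > chrom_lengths[[p$chrom]] + 1)
      stopf("plan position %d outside chromosome %s", p$position, p$chrom)
    if (max(p$kept) > nchar(reference$sequence))
      stopf("kept interval end %d beyond reference length %d",
            max(p$kept), nchar(reference$sequence))
  }
  # same-position plans would produce overlapping realized intervals
  key <- vapply(plans, function(p) paste(p$chrom, p$position), "")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    ij <- which(key == d)
    stopf("plans %d and %d overlap at %s", ij[1], ij[2], d)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  chrom_seqs <- with_seed(child_seed(seed, 0), {
    setNames(lapply(chrom_lengths, random_dna), names(chrom_lengths))
  })

  truth <- list()
  for (chrom in names(chrom_lengths)) {
    idx <- which(vapply(plans, function(p) p$chrom, "") == chrom)
    if (!length(idx)) next
    idx <- idx[order(vapply(plans[idx], function(p) p$position, 0L))]
    shift <- 0L
    pieces <- character(0)
    cursor <- 1L
    seq0 <- chrom_seqs[[chrom]]
    for (i in idx) {
      p <- plans[[i]]
      ins <- realize_insert(reference, p)
      start <- p$position + shift
      pieces <- c(pieces, substr(seq0, cursor, p$position - 1L), ins$seq)
      cursor <- p$position
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = chrom, start = start,
        end = start + nchar(ins$seq) - 1L, strand = p$strand,
        name = sprintf("%s:%d-%d", chrom, start,
                       start + nchar(ins$seq) - 1L),
        divergence = p$divergence,
        kept = paste(sprintf("%d-%d", p$kept[, 1], p$kept[, 2]),
                     collapse = ";"),
        kept_bp = ins$kept_len, nested_bp = ins$nested_len,
        class = plan_class(reference, p), context = p$context,
        stringsAsFactors = FALSE)
      shift <- shift + nchar(ins$seq)
    }
    pieces <- c(pieces, substr(seq0, cursor, nchar(seq0)))
    chrom_seqs[[chrom]] <- paste(pieces, collapse = "")
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), name = character(0),
               divergence = numeric(0), kept = character(0),
               kept_bp = integer(0), nested_bp = integer(0),
               class = character(0), context = character(0))
  # BED-convention companions (0-based half-open)
  truth_df$start0 <- truth_df$start - 1L
  truth_df$end0 <- truth_df$end

  new_lengths <- vapply(chrom_seqs, nchar, 0L)
  genes <- place_genes(truth_df, plans, new_lengths,
                       density = background_gene_density,
                       seed = child_seed(seed, 2))

  genome_path <- file.path(out_dir, "genome.fa")
  dna <- Biostrings::DNAStringSet(unlist(chrom_seqs))
  names(dna) <- names(chrom_seqs)
  Biostrings::writeXStringSet(dna, genome_path)

  genes_path <- file.path(out_dir, "genes.gff3")
  write_gff3(genes, genes_path)

  truth_path <- file.path(out_dir, "truth.tsv")
  write.table(truth_df, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  structure(list(genome = genome_path, genes = genes_path,
                 truth = truth_path, truth_df = truth_df,
                 chrom_lengths = new_lengths),
            class = "genome_bundle")
}

# Build gene models realizing each plan's requested context, plus background
# genes away from loci. Returns a gene_models object.
place_genes <- function(truth_df, plans, chrom_lengths, density, seed) {
  genes <- list(); exons <- list(); gid <- 0L
  margin <- 3000L
  add_gene <- function(chrom, gs, ge, strand, ex) {
    gid <<- gid + 1L
    id <- sprintf("gene%04d", gid)
    genes[[gid]] <<- data.frame(gene_id = id, chrom = chrom, strand = strand,
                                start = gs, end = ge, stringsAsFactors = FALSE)
    exons[[length(exons) + 1L]] <<- data.frame(
      gene_id = id, chrom = chrom, start = ex[, 1], end = ex[, 2],
      stringsAsFactors = FALSE)
    id
  }
  occupied <- list()  # per chrom, matrix of blocked intervals for bg genes
  block <- function(chrom, s, e)
    occupied[[chrom]] <<- rbind(occupied[[chrom]], c(s, e))

  with_seed(seed, {
    for (i in seq_len(nrow(truth_df))) {
      tr <- truth_df[i, ]
      L <- chrom_lengths[[tr$chrom]]
      ls <- tr$start; le <- tr$end; len <- le - ls + 1L
      strand <- sample(c("+", "-"), 1)
      block(tr$chrom, max(1L, ls - margin - 2000L), min(L, le + margin + 2000L))
      if (tr$context == "intergenic") next
      gs <- max(1L, ls - 2000L); ge <- min(L, le + 2000L)
      if (tr$context == "intron") {
        ex <- rbind(c(gs, min(gs + 200L, ls - 1L)),
                    c(max(le + 1L, ge - 200L), ge))
      } else if (tr$context == "exon") {
        ex <- rbind(c(gs, gs + 50L),
                    c(max(1L, ls - 100L), min(L, le + 100L)),
                    c(ge - 50L, ge))
      } else if (tr$context == "exonic&intronic") {
        ex <- rbind(c(gs, gs + 50L),
                    c(max(1L, ls - 100L), ls + min(500L, len %/% 2L)),
                    c(ge - 50L, ge))
      } else if (tr$context == "genic&intergenic") {
        ge <- ls + len %/% 2L           # gene ends inside the locus
        ex <- rbind(c(gs, gs + 200L), c(ge - 50L, ge))
      }
      add_gene(tr$chrom, gs, ge, strand, ex)
    }
    # background genes on gene-free ground
    if (density > 0) {
      for (chrom in names(chrom_lengths)) {
        L <- chrom_lengths[[chrom]]
        target <- density * L
        placed <- 0
        tries <- 0L
        while (placed < target && tries < 200L) {
          tries <- tries + 1L
          glen <- sample(3000:8000, 1)
          gs <- sample.int(max(1L, L - glen), 1)
          ge <- gs + glen - 1L
          occ <- occupied[[chrom]]
          if (!is.null(occ) &&
              any(interval_overlap(occ[, 1], occ[, 2], gs, ge) > 0)) next
          strand <- sample(c("+", "-"), 1)
          nex <- sample(2:4, 1)
          bnd <- sort(sample(seq(gs + 100L, ge - 100L), 2L * nex))
          ex <- cbind(bnd[seq(1, 2 * nex, 2)], bnd[seq(2, 2 * nex, 2)])
          ex[1, 1] <- gs; ex[nex, 2] <- ge
          add_gene(chrom, gs, ge, strand, ex)
          block(chrom, gs, ge)
          placed <- placed + glen
        }
      }
    }
  })
  genes_df <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(0), chrom = character(0),
               strand = character(0), start = integer(0), end = integer(0))
  exons_df <- if (length(exons)) do.call(rbind, exons) else
    data.frame(gene_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0))
  gene_models(genes_df, exons_df)
}

#' Simulate a standard study bundle
#'
#' One call producing the synthetic conditions used throughout the test
#' suite: five 120-kb chromosomes carrying `n_loci` planted proviral
#' copies (four per chromosome), cycling through divergence levels,
#' truncation classes (full-length, LTR-less internal, 5'-truncated,
#' env+3'LTR fragment, solo LTR), strands, genomic contexts, and two loci
#' with 2-kb nested foreign insertions.
#'
#' @param out_dir output directory for the bundle files.
#' @param seed master integer seed.
#' @param n_loci number of planted loci (max 20 under the default
#'   chromosome sizing).
#' @param divergences divergence levels cycled over the plans.
#' @param reference optional [proviral_reference()]; generated from
#'   `seed` when NULL.
#' @return list with `bundle` (a `genome_bundle`), `reference`, `plans`.
#' @export
simulate_study_bundle <- function(out_dir = tempfile("study"), seed = 1,
                                  n_loci = 20,
                                  divergences = c(0, 0.02, 0.05, 0.08),
                                  reference = NULL) {
  if (is.null(reference))
    reference <- generate_reference(seed = child_seed(seed, 7))
  chroms <- setNames(rep(120000L, 5), paste0("chr", 1:5))
  positions <- c(15000L, 45000L, 75000L, 105000L)
  kept_classes <- list(
    cbind(1L, 10485L),            # full-length
    cbind(1422L, 9217L),          # internal ORFs only (both LTRs lost)
    cbind(3000L, 10485L),         # 5'-truncated
    cbind(6890L, 10485L),         # env + 3'LTR fragment
    cbind(9220L, 10485L))         # solo 3'LTR
  contexts <- c("intergenic", "intron", "exon", "exonic&intronic",
                "genic&intergenic")
  plans <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    ci <- ((i - 1L) %% length(chroms)) + 1L
    pi <- ((i - 1L) %/% length(chroms)) + 1L
    nested <- if (i %in% c(1L, 6L))
      data.frame(offset = 5000L, length = 2000L) else NULL
    plans[[i]] <- insertion_plan(
      chrom = names(chroms)[ci], position = positions[pi],
      strand = if (i %% 2 == 0) "-" else "+",
      kept = kept_classes[[((i - 1L) %% length(kept_classes)) + 1L]],
      divergence = divergences[((i - 1L) %% length(divergences)) + 1L],
      nested = nested,
      context = contexts[((i - 1L) %% length(contexts)) + 1L],
      seed = child_seed(seed, 50 + i))
  }
  bundle <- plant_loci(reference, plans, chroms,
                       seed = child_seed(seed, 9), out_dir = out_dir)
  ref_fa <- file.path(out_dir, "reference.fa")
  dna <- Biostrings::DNAStringSet(setNames(reference$sequence,
                                           reference$name))
  Biostrings::writeXStringSet(dna, ref_fa)
  write_layout(reference$layout, file.path(out_dir, "layout.tsv"))
  list(bundle = bundle, reference = reference, plans = plans,
       reference_fasta = ref_fa,
       layout_path = file.path(out_dir, "layout.tsv"))
}
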