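#' Pipeline run configuration
#'
#' Collects all paths and parameters for [run_pipeline()]. Defaults are the
#' pipeline's standard operating point: BLAT-style search parameters
#' (k = 11, step = 5), a 2 kb merge gap, the 0.2 %/nt/Myr neutral clock,
#' GREAT basal 5 kb/1 kb with 1 Mb extension, and 500 bootstrap replicates.
#'
#' @param genome genome FASTA path.
#' @param reference proviral reference: a [proviral_reference()] object or
#'   a FASTA path (first record).
#' @param layout layout TSV path (ignored when `reference` is an object).
#' @param annotation optional GFF3 gene annotation path.
#' @param categories optional GMT category map path for enrichment.
#' @param out_dir output directory.
#' @param seed global integer seed.
#' @param k,step,min_identity,min_len search parameters ([kmer_search()]).
#' @param merge_gap,deletion_threshold,insertion_threshold locus assembly
#'   parameters ([assemble_loci()]).
#' @param clock_rate substitution rate, percent per nucleotide per Myr.
#' @param min_region_fraction dating eligibility threshold.
#' @param bootstrap_reps phylogeny bootstrap replicates.
#' @param great_up,great_down,great_max_ext GREAT association rule.
#' @param min_ltr_cov LTR coverage needed for regulatory association.
#' @param alpha significance level for distribution flags.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(genome, reference, layout = NULL, annotation = NULL,
                       categories = NULL, out_dir = tempfile("ervscape"),
                       seed = 1, k = 11, step = 5, min_identity = 0.95,
                       min_len = 25, merge_gap = 2000,
                       deletion_threshold = 0.10,
                       insertion_threshold = 1000, clock_rate = 0.2,
                       min_region_fraction = 0.9, bootstrap_reps = 500,
                       great_up = 5000, great_down = 1000,
                       great_max_ext = 1000000, min_ltr_cov = 0.7,
                       alpha = 0.05) {
  if (clock_rate <= 0) stopf("clock rate must be positive")
  if (min_identity <= 0 || min_identity > 1 ||
      deletion_threshold < 0 || deletion_threshold > 1 ||
      min_region_fraction < 0 || min_region_fraction > 1 ||
      min_ltr_cov < 0 || min_ltr_cov > 1)
    stopf("fraction-valued thresholds must lie in [0, 1]")
  cfg <- list(genome = genome, reference = reference, layout = layout,
              annotation = annotation, categories = categories,
              out_dir = out_dir, seed = as.integer(seed), k = k,
              step = step, min_identity = min_identity, min_len = min_len,
              merge_gap = merge_gap,
              deletion_threshold = deletion_threshold,
              insertion_threshold = insertion_threshold,
              clock_rate = clock_rate,
              min_region_fraction = min_region_fraction,
              bootstrap_reps = bootstrap_reps, great_up = great_up,
              great_down = great_down, great_max_ext = great_max_ext,
              min_ltr_cov = min_ltr_cov, alpha = alpha)
  class(cfg) <- "run_config"
  cfg
}

#' Serialize / parse a run configuration
#'
#' JSON round-trip: `parse(serialize(cfg))` is identity for path/scalar
#' configs.
#'
#' @param cfg a [run_config()].
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  ser <- unclass(cfg)
  ser$reference <- if (inherits(cfg$reference, "proviral_reference"))
    list(name = cfg$reference$name, sequence = cfg$reference$sequence,
         layout = cfg$reference$layout) else cfg$reference
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(x$reference))
    x$reference <- proviral_reference(x$reference$sequence,
                                      as.data.frame(x$reference$layout),
                                      name = x$reference$name)
  do.call(run_config, x)
}

resolve_reference <- function(cfg) {
  if (inherits(cfg$reference, "proviral_reference")) return(cfg$reference)
  seqs <- read_genome(cfg$reference)
  layout <- if (!is.null(cfg$layout)) read_layout(cfg$layout) else
    default_proviral_layout()
  proviral_reference(seqs[[1]], layout, name = names(seqs)[1])
}

# Project each locus onto reference coordinates: a gapped string of the
# reference's length holding the locus's aligned genomic bases (reverse-
# complemented for minus-strand loci), '-' where uncovered. Records must
# come from the same search that produced `loci`.
locus_alignments <- function(loci, records, genome, reference) {
  seqs <- read_genome(genome)
  rl <- nchar(reference$sequence)
  out <- setNames(character(nrow(loci)), loci$name)
  for (i in seq_len(nrow(loci))) {
    row <- loci[i, ]
    sel <- records$t_name == row$chrom & records$strand == row$strand &
      records$t_start >= row$start - 1L & records$t_end <= row$end
    chars <- rep("-", rl)
    for (j in which(sel)) {
      b <- records$blocks[[j]]
      for (bi in seq_len(nrow(b))) {
        seg <- substr(seqs[[row$chrom]], b[bi, "ts"] + 1L,
                      b[bi, "ts"] + b[bi, "len"])
        if (row$strand == "-") seg <- revcomp(seg)
        pos <- (b[bi, "qs"] + 1L):(b[bi, "qs"] + b[bi, "len"])
        chars[pos] <- strsplit(seg, "")[[1]]
      }
    }
    out[i] <- paste(chars, collapse = "")
  }
  out
}

extract_region <- function(aligned, reference, region) {
  lay <- reference$layout
  i <- match(region, lay$region)
  substr(aligned, lay$start[i], lay$end[i])
}

#' Run the full annotation pipeline
#'
#' Discovery (k-mer search + locus assembly), per-region integrity and
#' solo-LTR calls, context classification (when annotation is given),
#' the chromosomal distribution test, consensus-based clock dating,
#' NJ phylogeny over near-full-length elements, and GREAT-style
#' regulatory association with enrichment (when annotation/categories are
#' given). Writes per-stage TSVs and a consolidated `summary.json` under
#' the output directory; identical config + seed give identical outputs.
#'
#' @param cfg a [run_config()].
#' @return list of stage results (invisibly also written to disk), classed
#'   `ervscape_run`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  reference <- stage("reference", resolve_reference(cfg))

  records <- stage("discover", kmer_search(
    cfg$genome, reference, k = cfg$k, step = cfg$step,
    min_identity = cfg$min_identity, min_len = cfg$min_len))
  loci <- stage("discover", assemble_loci(
    records, reference, merge_gap = cfg$merge_gap,
    deletion_threshold = cfg$deletion_threshold,
    insertion_threshold = cfg$insertion_threshold))
  write_locus_table(loci, file.path(cfg$out_dir, "loci.tsv"))
  write_locus_bed(loci, file.path(cfg$out_dir, "loci.bed"))

  profiles <- stage("profile", profile_loci(loci, reference))
  write_integrity_table(profiles, file.path(cfg$out_dir, "integrity.tsv"))
  deletions <- count_complete_deletions(profiles)
  solo <- vapply(seq_len(nrow(loci)), function(i)
    detect_solo_ltr(profile_regions(loci$ref_blocks[[i]], reference)),
    TRUE)
  lengths_sum <- if (nrow(loci)) summarize_lengths(loci) else NULL

  context_sum <- NULL
  if (!is.null(cfg$annotation)) {
    models <- stage("context", read_gene_models(cfg$annotation))
    loci$context <- vapply(seq_len(nrow(loci)), function(i)
      classify_context(loci$chrom[i], loci$start[i], loci$end[i], models),
      "")
    write_locus_table(loci, file.path(cfg$out_dir, "loci.tsv"))
    if (nrow(loci)) context_sum <- summarize_context(loci$context)
  }

  dist_res <- NULL
  if (nrow(loci)) {
    nongap <- stage("distribution", nongap_lengths(cfg$genome))
    dist_res <- stage("distribution",
                      distribution_test(loci, nongap, alpha = cfg$alpha))
  }

  ages <- NULL; age_sum <- NULL
  if (nrow(loci) >= 2) {
    aligned <- stage("date",
                     locus_alignments(loci, records, cfg$genome, reference))
    div_by_region <- list()
    for (region in INTERNAL_REGIONS) {
      reg <- vapply(aligned, extract_region, "", reference = reference,
                    region = region)
      res <- try(region_divergences(reg, reference, region,
                                    min_fraction = cfg$min_region_fraction),
                 silent = TRUE)
      if (!inherits(res, "try-error")) div_by_region[[region]] <- res
    }
    if (length(div_by_region)) {
      all_names <- unique(unlist(lapply(div_by_region, names)))
      ages <- list()
      for (nm in all_names) {
        dv <- vapply(INTERNAL_REGIONS, function(r)
          if (!is.null(div_by_region[[r]]) &&
              nm %in% names(div_by_region[[r]]))
            div_by_region[[r]][[nm]] else NA_real_, 0)
        ages[[nm]] <- element_age(dv, name = nm, rate = cfg$clock_rate)
      }
      age_sum <- summarize_ages(ages)
      age_df <- data.frame(
        name = names(ages),
        t(vapply(ages, function(a) c(
          setNames(a$region_divergences[INTERNAL_REGIONS],
                   INTERNAL_REGIONS),
          mean_div = a$mean_divergence, age_myr = a$age_myr),
          setNames(numeric(6), c(INTERNAL_REGIONS, "mean_div",
                                 "age_myr")))),
        check.names = FALSE, row.names = NULL)
      write.table(age_df, file.path(cfg$out_dir, "ages.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }

  phylo_res <- NULL
  if (nrow(loci) >= 3) {
    aligned <- locus_alignments(loci, records, cfg$genome, reference)
    ungapped <- nchar(gsub("-", "", aligned))
    near_full <- aligned[ungapped >= 0.8 * nchar(reference$sequence)]
    if (length(near_full) >= 3) {
      phylo_res <- stage("phylo", bootstrap_support(
        near_full, model = "p", reps = cfg$bootstrap_reps,
        seed = child_seed(cfg$seed, 31)))
      ape::write.tree(phylo_res$tree,
                      file.path(cfg$out_dir, "tree.nwk"))
    }
  }

  reg_res <- NULL
  if (!is.null(cfg$categories)) {
    if (is.null(cfg$annotation))
      stopf("stage 'regulate' failed: categories given without annotation")
    models <- read_gene_models(cfg$annotation)
    chrom_lengths <- vapply(read_genome(cfg$genome), nchar, 0)
    domains <- stage("regulate",
                     regulatory_domains(models, chrom_lengths,
                                        up = cfg$great_up,
                                        down = cfg$great_down,
                                        max_ext = cfg$great_max_ext))
    elig <- eligible_ltr_loci(loci, reference,
                              min_ltr_cov = cfg$min_ltr_cov)
    assoc <- associate_ltrs(elig, domains)
    cats <- read_gmt(cfg$categories)
    enr <- if (nrow(assoc))
      ora_enrichment(unique(assoc$gene_id), cats, models$genes$gene_id)
    else NULL
    write.table(assoc, file.path(cfg$out_dir, "associations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    reg_res <- list(domains = domains, associations = assoc,
                    enrichment = enr)
  }

  summary <- list(
    parameters = unclass(cfg)[setdiff(names(cfg), "reference")],
    n_loci = nrow(loci),
    length_summary = if (!is.null(lengths_sum)) unclass(lengths_sum),
    complete_deletions = as.list(deletions),
    n_solo_ltr = sum(solo),
    context_summary = context_sum,
    distribution = if (!is.null(dist_res)) list(
      statistic = dist_res$global$statistic, df = dist_res$global$df,
      p_value = dist_res$global$p_value,
      flags = dist_res$per_chrom),
    age_summary = if (!is.null(age_sum)) unclass(age_sum),
    phylogeny = if (!is.null(phylo_res)) list(
      n_taxa = length(phylo_res$taxa), reps = phylo_res$reps,
      supports = as.list(phylo_res$supports)),
    regulatory = if (!is.null(reg_res)) list(
      n_eligible_ltr = length(unique(reg_res$associations$locus)),
      n_associations = nrow(reg_res$associations),
      n_genes = length(unique(reg_res$associations$gene_id)))
  )
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  structure(list(reference = reference, records = records, loci = loci,
                 profiles = profiles, deletions = deletions,
                 solo_ltr = solo, length_summary = lengths_sum,
                 context_summary = context_sum, distribution = dist_res,
                 ages = ages, age_summary = age_sum,
                 phylogeny = phylo_res, regulatory = reg_res,
                 summary = summary, out_dir = cfg$out_dir),
            class = "ervscape_run")
}

#' @export
print.ervscape_run <- function(x, ...) {
  cat(sprintf("ervscape run: %d loci (outputs in %s)\n",
              nrow(x$loci), x$out_dir))
  if (!is.null(x$length_summary)) print(x$length_summary)
  if (!is.null(x$age_summary)) print(x$age_summary)
  invisible(x)
}
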