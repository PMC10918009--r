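# Shared synthetic study bundle, built once per test run.
study_cache <- new.env(parent = emptyenv())

study_bundle <- function(seed = 1) {
  key <- paste0("seed", seed)
  if (is.null(study_cache[[key]])) {
    study_cache[[key]] <- simulate_study_bundle(
      out_dir = file.path(tempdir(), paste0("study-", seed)), seed = seed)
  }
  study_cache[[key]]
}

# Discovery of the study bundle, cached alongside it. The bundle plants
# copies up to 8 percent diverged, so the search runs at the matching
# identity floor (~1 - max divergence).
study_discovery <- function(seed = 1) {
  key <- paste0("disc", seed)
  if (is.null(study_cache[[key]])) {
    sb <- study_bundle(seed)
    rec <- kmer_search(sb$bundle$genome, sb$reference, min_identity = 0.90)
    loci <- assemble_loci(rec, sb$reference)
    study_cache[[key]] <- list(records = rec, loci = loci)
  }
  study_cache[[key]]
}

# Match each truth row to discovered loci by interval overlap; returns a
# vector of locus indices (NA when not recovered uniquely).
match_truth <- function(loci, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    j <- which(loci$chrom == truth$chrom[i] & loci$start <= truth$end[i] &
                 loci$end >= truth$start[i])
    if (length(j) == 1) j else NA_integer_
  }, 0L)
}

# A small aligned sequence family: `n` copies of a random base sequence,
# each mutated at `divergence`.
mutated_family <- function(n, len, divergence, seed = 1,
                           prefix = "copy") {
  base <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = ""))
  copies <- vapply(seq_len(n), function(i)
    mutate_sequence(base, divergence, seed = seed + 1000 + i), "")
  list(base = base, copies = setNames(copies, paste0(prefix, seq_len(n))))
}
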