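make_psl_line <- function(matches = 100, mis = 4, qnum = 1, qbase = 10,
                          tnum = 0, tbase = 0, strand = "+",
                          qname = "cons", qsize = 10485, qstart = 0,
                          qend = 114, tname = "chr1", tsize = 50000,
                          tstart = 1000, tend = 1114,
                          sizes = "60,54,", qst = "0,60,",
                          tst = "1000,1060,") {
  paste(matches, mis, 0, 0, qnum, qbase, tnum, tbase, strand, qname,
        qsize, qstart, qend, tname, tsize, tstart, tend, 2, sizes, qst,
        tst, sep = "\t")
}

test_that("PSL fields map onto alignment records", {
  path <- tempfile(fileext = ".psl")
  writeLines(make_psl_line(), path)
  rec <- read_psl(path)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$match, 100)
  expect_equal(rec$mismatch, 4)
  expect_equal(rec$q_gap_count, 1)
  expect_equal(rec$q_gap_bases, 10)
  expect_equal(rec$blocks[[1]][, "len"], c(60, 54))
})

test_that("PSL parsing rejects malformed input and accepts empty files", {
  empty <- tempfile(); file.create(empty)
  expect_equal(nrow(read_psl(empty)), 0)

  bad <- tempfile()
  writeLines(paste(rep("1", 20), collapse = "\t"), bad)
  expect_error(read_psl(bad), "line 1")

  nonnum <- tempfile()
  writeLines(sub("^100", "abc", make_psl_line()), nonnum)
  expect_error(read_psl(nonnum), "line 1")
})

test_that("PSL records round-trip through write and read", {
  sd <- study_discovery()
  path <- tempfile(fileext = ".psl")
  write_psl(sd$records, path)
  back <- read_psl(path)
  for (col in c("q_name", "t_name", "strand", "match", "mismatch",
                "q_gap_bases", "t_gap_bases", "q_start", "q_end",
                "t_start", "t_end"))
    expect_equal(back[[col]], sd$records[[col]], ignore_attr = TRUE)
  for (i in seq_len(nrow(back)))
    expect_equal(unname(back$blocks[[i]]), unname(sd$records$blocks[[i]]))
})

test_that("an exact planted copy is found in full with zero mismatches", {
  ref <- generate_reference(seed = 21)
  bg <- with_seed(31, paste(sample(c("A", "C", "G", "T"), 30000,
                                   replace = TRUE), collapse = ""))
  genome <- c(chrZ = paste0(substr(bg, 1, 15000), ref$sequence,
                            substr(bg, 15001, 30000)))
  rec <- kmer_search(genome, ref)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$mismatch, 0)
  expect_equal(rec$q_start, 0)
  expect_equal(rec$q_end, 10485)
  expect_equal(rec$t_start, 15000)
})

test_that("random genomes yield no spurious records", {
  ref <- generate_reference(seed = 22)
  for (s in 1:10) {
    genome <- c(chrR = with_seed(1000 + s,
      paste(sample(c("A", "C", "G", "T"), 100000, replace = TRUE),
            collapse = "")))
    rec <- kmer_search(genome, ref, min_len = 25)
    expect_equal(nrow(rec), 0)
  }
})

test_that("coverage and gap fractions follow the locus-table formulas", {
  ref <- generate_reference(seed = 23)
  rec1 <- data.frame(
    q_name = "cons", t_name = "chr1", strand = "+",
    match = 8600L, mismatch = 281L, q_gap_count = 0L, q_gap_bases = 0L,
    t_gap_count = 0L, t_gap_bases = 0L, q_size = 10485L,
    q_start = 0L, q_end = 8881L, t_size = 100000L,
    t_start = 1000L, t_end = 9881L,
    blocks = I(list(cbind(qs = 0L, ts = 1000L, len = 8881L))))
  loci <- assemble_loci(rec1, ref)
  expect_equal(loci$coverage_fraction, 8881 / 10485)
  expect_equal(round_half_up(100 * loci$coverage_fraction, 2), 84.70)
  expect_equal(loci$range_bin, "[80%-90%)")
  expect_true(is.na(loci$indel_flags))
  expect_equal(loci$name, "chr1:1001-9881")

  # an internal deletion of 12% of the aligned span flags Deletion
  rec2 <- rbind(rec1, rec1)
  rec2$blocks <- I(list(cbind(qs = 0L, ts = 1000L, len = 4000L),
                        cbind(qs = 4546L, ts = 5546L, len = 4335L)))
  rec2$q_start <- c(0L, 4546L); rec2$q_end <- c(4000L, 8881L)
  rec2$t_start <- c(1000L, 5546L); rec2$t_end <- c(5000L, 9881L)
  loci2 <- assemble_loci(rec2, ref)
  expect_equal(nrow(loci2), 1)
  expect_equal(loci2$q_gap_fraction, 546 / 8881)
  loci3 <- assemble_loci(rec2, ref, deletion_threshold = 0.06)
  expect_equal(loci3$indel_flags, "Deletion")
})

test_that("nearby collinear records merge; mixed references error", {
  ref <- generate_reference(seed = 24)
  rec <- data.frame(
    q_name = "cons", t_name = "chr1", strand = "+",
    match = c(2000L, 2000L), mismatch = c(0L, 0L),
    q_gap_count = 0L, q_gap_bases = 0L, t_gap_count = 0L,
    t_gap_bases = 0L, q_size = 10485L,
    q_start = c(0L, 2000L), q_end = c(2000L, 4000L),
    t_size = 100000L, t_start = c(1000L, 3100L),
    t_end = c(3000L, 5100L),
    blocks = I(list(cbind(qs = 0L, ts = 1000L, len = 2000L),
                    cbind(qs = 2000L, ts = 3100L, len = 2000L))))
  merged <- assemble_loci(rec, ref, merge_gap = 1000)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, 1001)
  expect_equal(merged$end, 5100)
  split <- assemble_loci(rec, ref, merge_gap = 50)
  expect_equal(nrow(split), 2)

  mixed <- rec
  mixed$q_name <- c("consA", "consB")
  expect_error(assemble_loci(mixed, ref), "multiple references")
})

test_that("coverage is monotone under added records and bounded by 1", {
  ref <- generate_reference(seed = 25)
  base <- data.frame(
    q_name = "cons", t_name = "chr1", strand = "+",
    match = 3000L, mismatch = 0L, q_gap_count = 0L, q_gap_bases = 0L,
    t_gap_count = 0L, t_gap_bases = 0L, q_size = 10485L,
    q_start = 0L, q_end = 3000L, t_size = 100000L,
    t_start = 1000L, t_end = 4000L,
    blocks = I(list(cbind(qs = 0L, ts = 1000L, len = 3000L))))
  cov1 <- assemble_loci(base, ref)$coverage_fraction
  for (extra_q in c(2000L, 3000L, 5000L)) {
    rec <- rbind(base, base)
    rec$q_start[2] <- extra_q; rec$q_end[2] <- extra_q + 3000L
    rec$t_start[2] <- 4100L; rec$t_end[2] <- 7100L
    rec$blocks <- I(list(cbind(qs = 0L, ts = 1000L, len = 3000L),
                         cbind(qs = extra_q, ts = 4100L, len = 3000L)))
    cov2 <- assemble_loci(rec, ref)$coverage_fraction
    expect_gte(cov2, cov1)
    expect_lte(cov2, 1)
  }
})

test_that("every planted locus is recovered and none invented", {
  sd <- study_discovery()
  sb <- study_bundle()
  tr <- sb$bundle$truth_df
  idx <- match_truth(sd$loci, tr)
  expect_false(anyNA(idx))                      # recall 1.0
  expect_equal(sort(idx), seq_len(nrow(sd$loci))) # no false loci
  # strands recovered
  expect_equal(sd$loci$strand[idx], tr$strand)
})
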