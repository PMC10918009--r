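ref64 <- generate_reference(seed = 64)

test_that("region fractions follow interval arithmetic on the layout", {
  p_full <- profile_regions(cbind(1L, 10485L), ref64)
  expect_equal(as.numeric(unclass(p_full)), rep(1, 6))

  p_solo <- profile_regions(cbind(9220L, 10485L), ref64)
  expect_equal(unclass(p_solo)[["3'LTR"]], 1)
  expect_equal(unname(unclass(p_solo)[1:5]), rep(0, 5))

  p_head <- profile_regions(cbind(1L, 2000L), ref64)
  expect_equal(unclass(p_head)[["5'LTR"]], 1)
  expect_equal(unclass(p_head)[["gag"]], (2000 - 1422 + 1) / 2109)
  expect_equal(unclass(p_head)[["pro"]], 0)

  # junction bases count toward both regions
  p_junc <- profile_regions(cbind(3341L, 3530L), ref64)
  expect_equal(unclass(p_junc)[["gag"]], 190 / 2109)
  expect_equal(unclass(p_junc)[["pro"]], 190 / 1005)

  expect_error(profile_regions(cbind(1L, 10486L), ref64), "outside")
})

test_that("region fractions are monotone as blocks accumulate", {
  blocks <- rbind(c(500L, 1500L), c(2000L, 4000L), c(6000L, 9000L),
                  c(9500L, 10485L))
  prev <- rep(0, 6)
  for (k in seq_len(nrow(blocks))) {
    cur <- unclass(profile_regions(blocks[seq_len(k), , drop = FALSE],
                                   ref64))
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("complete-deletion counts reproduce the published catalog", {
  t2 <- load_fixture("table2")
  counts <- count_complete_deletions(t2)
  expect_equal(unname(counts),
               c(63L, 43L, 34L, 19L, 11L, 25L), ignore_attr = TRUE)
  # complement invariant: zeros + nonzeros = n per region
  m <- as.matrix(t2[, c("5'LTR", "gag", "pro", "pol", "env", "3'LTR")])
  expect_equal(unname(counts + colSums(m > 0)), rep(76L, 6),
               ignore_attr = TRUE)

  expect_equal(unname(count_complete_deletions(list())), rep(0L, 6))
  full <- profile_regions(cbind(1L, 10485L), ref64)
  expect_equal(unname(count_complete_deletions(list(full))), rep(0L, 6))
})

test_that("solo LTRs require an intact-enough LTR and empty internals", {
  mk <- function(...) {
    v <- setNames(rep(0, 6), c("5'LTR", "gag", "pro", "pol", "env",
                               "3'LTR"))
    args <- list(...)
    v[names(args)] <- unlist(args)
    structure(v, class = "region_profile", name = "toy")
  }
  expect_true(detect_solo_ltr(mk(`3'LTR` = 0.75)))
  expect_false(detect_solo_ltr(mk(`3'LTR` = 1.0, env = 0.10)))
  expect_false(detect_solo_ltr(mk()))
  expect_false(detect_solo_ltr(mk(`3'LTR` = 0.4)))
  expect_true(detect_solo_ltr(mk(`5'LTR` = 0.6)))
})

test_that("solo-LTR calls on the study bundle match the planted classes", {
  sd <- study_discovery()
  sb <- study_bundle()
  tr <- sb$bundle$truth_df
  idx <- match_truth(sd$loci, tr)
  calls <- vapply(idx, function(j)
    detect_solo_ltr(profile_regions(sd$loci$ref_blocks[[j]],
                                    sb$reference)), TRUE)
  expect_equal(calls, tr$class == "solo-LTR", ignore_attr = TRUE)
})

test_that("profiled fractions match planted kept intervals closely", {
  sd <- study_discovery()
  sb <- study_bundle()
  tr <- sb$bundle$truth_df
  idx <- match_truth(sd$loci, tr)
  lay <- sb$reference$layout
  for (i in seq_len(nrow(tr))) {
    kept <- do.call(rbind, lapply(strsplit(strsplit(tr$kept[i], ";")[[1]],
                                           "-"), as.integer))
    want <- vapply(seq_len(6), function(r) {
      ov <- sum(pmax(0, pmin(kept[, 2], lay$end[r]) -
                       pmax(kept[, 1], lay$start[r]) + 1))
      ov / (lay$end[r] - lay$start[r] + 1)
    }, 0)
    got <- unclass(profile_regions(sd$loci$ref_blocks[[idx[i]]],
                                   sb$reference))
    expect_true(all(abs(got - want) <= 0.01),
                label = sprintf("profile within 0.01 for %s", tr$name[i]))
  }
})

test_that("length summaries reproduce the published catalog statistics", {
  t1 <- load_fixture("table1")
  ls <- summarize_lengths(t1)
  expect_equal(ls$n, 76)
  expect_equal(ls$mean_bp, 4378)
  expect_equal(ls$max_bp, 9158)
  expect_equal(ls$min_bp, 875)
  expect_equal(unname(ls$class_counts),
               c(9L, 21L, 46L), ignore_attr = TRUE)
  expect_equal(sum(ls$bin_counts), ls$n)
})

test_that("length summary degenerate and small cases", {
  one <- data.frame(length = 100L, coverage_fraction = 0.01,
                    range_bin = "[0%-10%)", indel_flags = NA_character_)
  s1 <- summarize_lengths(one)
  expect_equal(c(s1$mean_bp, s1$min_bp, s1$max_bp), c(100, 100, 100))
  two <- data.frame(length = c(100L, 300L),
                    coverage_fraction = c(0.01, 0.02),
                    range_bin = "[0%-10%)",
                    indel_flags = NA_character_)
  expect_equal(summarize_lengths(two)$mean_bp, 200)
  expect_error(summarize_lengths(one[0, ]), "no loci")
})
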