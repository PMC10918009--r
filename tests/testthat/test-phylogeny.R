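test_that("distance matrices honor the three models", {
  seqs <- c(a = strrep("ACGT", 25), b = strrep("ACGT", 25),
            c = strrep("AGGT", 25))
  d_p <- distance_matrix(seqs, "p")
  expect_equal(diag(d_p), c(a = 0, b = 0, c = 0))
  expect_equal(d_p["a", "b"], 0)
  expect_equal(d_p["a", "c"], 0.25)
  expect_true(isSymmetric(d_p))

  d_jc <- distance_matrix(seqs, "JC")
  expect_equal(d_jc["a", "c"], -0.75 * log(2 / 3), tolerance = 1e-12)

  # C->T differences are transitions: K2P separates them from transversions
  seqs2 <- c(a = strrep("C", 100), b = strrep("T", 76),
             c = strrep("C", 100))
  seqs2["b"] <- paste0(strrep("T", 20), strrep("C", 80))
  d_k <- distance_matrix(seqs2, "K2P")
  p <- 0.2
  expect_equal(d_k["a", "b"], -0.5 * log(1 - 2 * p), tolerance = 1e-12)

  sat <- c(a = strrep("A", 100), b = strrep("C", 100),
           c = strrep("G", 100))
  expect_error(distance_matrix(sat, "JC"), "saturated pair \\(a, b\\)")
  expect_error(distance_matrix(seqs[1:2], "p"), "at least 3")
})

test_that("three-taxon branch lengths follow the closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                      tr$edge[, 2])], tr$tip.label)
  expect_equal(bl, c(x = 0, y = 2, z = 4))
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  bad <- d; bad[1, 2] <- 5
  expect_error(nj_tree(bad), "symmetric")
})

test_that("NJ exactly recovers every additive 4- and 5-taxon topology", {
  for (n in c(4, 5)) {
    for (case in additive_cases(n)) {
      tr <- nj_tree(case$d)
      expect_setequal(tree_splits_oracle(tr), case$splits)
      # cross-check against the reference NJ implementation
      ref_tr <- ape::nj(case$d)
      expect_setequal(tree_splits_oracle(ref_tr), case$splits)
    }
  }
})

test_that("well-separated clades earn high bootstrap support", {
  base <- with_seed(201, paste(sample(c("A", "C", "G", "T"), 2000,
                                      replace = TRUE), collapse = ""))
  other <- mutate_sequence(base, 0.30, seed = 202)
  cladeA <- vapply(1:5, function(i)
    mutate_sequence(base, 0.01, seed = 210 + i), "")
  cladeB <- vapply(1:5, function(i)
    mutate_sequence(other, 0.01, seed = 220 + i), "")
  aln <- setNames(c(cladeA, cladeB),
                  c(paste0("a", 1:5), paste0("b", 1:5)))
  bt <- bootstrap_support(aln, reps = 100, seed = 7)
  key <- paste(paste0("b", 1:5), collapse = "|")
  expect_true(key %in% names(bt$supports))
  expect_gte(bt$supports[[key]], 95)
  # reproducible for a fixed seed
  bt2 <- bootstrap_support(aln, reps = 100, seed = 7)
  expect_identical(bt$supports, bt2$supports)
  # supports with a single replicate are all-or-nothing
  bt1 <- bootstrap_support(aln, reps = 1, seed = 3)
  expect_true(all(bt1$supports %in% c(0, 100)))
})

test_that("bootstrap supports are invariant to taxon input order", {
  fam <- mutated_family(6, 800, 0.10, seed = 301, prefix = "s")
  aln <- fam$copies
  bt <- bootstrap_support(aln, reps = 50, seed = 11)
  perm <- with_seed(12, sample(names(aln)))
  btp <- bootstrap_support(aln[perm], reps = 50, seed = 11)
  common <- intersect(names(bt$supports), names(btp$supports))
  expect_setequal(names(bt$supports), names(btp$supports))
  expect_equal(bt$supports[common], btp$supports[common])
})

test_that("queries are assigned to the group they cluster with", {
  set <- with_seed(401, {
    lapply(1:10, function(i)
      paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
            collapse = ""))
  })
  groups <- paste0("HML-", 1:10)
  panel <- setNames(vapply(set, identity, ""), paste0("ref", 1:10))
  hml8 <- panel[["ref8"]]
  queries <- c(q1 = mutate_sequence(hml8, 0.05, seed = 402),
               q2 = panel[["ref10"]],
               q3 = with_seed(403,
                 paste(sample(c("A", "C", "G", "T"), 1500,
                              replace = TRUE), collapse = "")))
  got <- assign_group(queries, panel, groups, reps = 100, seed = 5)
  expect_equal(got[["q1"]], "HML-8")
  expect_equal(got[["q2"]], "HML-10")
  expect_equal(got[["q3"]], "unassigned")
  expect_error(assign_group(queries, character(0), character(0)),
               "empty")
})

test_that("two planted subtype clusters are both strongly supported", {
  # type a / type b style structure: two gag sub-clusters,
  # intra-divergence 0.03, inter-divergence 0.15
  base <- with_seed(501, paste(sample(c("A", "C", "G", "T"), 2000,
                                      replace = TRUE), collapse = ""))
  anc_a <- mutate_sequence(base, 0.075, seed = 502)
  anc_b <- mutate_sequence(base, 0.075, seed = 503)
  type_a <- vapply(1:4, function(i)
    mutate_sequence(anc_a, 0.015, seed = 510 + i), "")
  type_b <- vapply(1:4, function(i)
    mutate_sequence(anc_b, 0.015, seed = 520 + i), "")
  aln <- setNames(c(type_a, type_b),
                  c(paste0("a", 1:4), paste0("b", 1:4)))
  bt <- bootstrap_support(aln, reps = 100, seed = 9)
  key_b <- paste(paste0("b", 1:4), collapse = "|")
  expect_true(key_b %in% names(bt$supports))
  expect_gte(bt$supports[[key_b]], 95)
})

test_that("alignments round-trip through the external-ML escape hatch", {
  fam <- mutated_family(4, 100, 0.05, seed = 601, prefix = "x")
  fa <- tempfile(fileext = ".fa")
  export_for_ml(fam$copies, fa, "fasta")
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(back), fam$copies)
  ph <- tempfile(fileext = ".phy")
  export_for_ml(fam$copies, ph, "phylip")
  first <- readLines(ph)[1]
  expect_equal(first, "4 100")
  nwk <- tempfile(fileext = ".nwk")
  d <- distance_matrix(fam$copies, "p")
  ape::write.tree(nj_tree(d), nwk)
  expect_s3_class(import_tree(nwk), "phylo")
})
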