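lone_gene <- function(tss = 2000000L, strand = "+", chrom = "chr1") {
  gene_models(
    data.frame(gene_id = "g1", chrom = chrom, strand = strand,
               start = if (strand == "+") tss else tss - 10000L,
               end = if (strand == "+") tss + 10000L else tss),
    data.frame(gene_id = "g1", chrom = chrom,
               start = tss, end = tss + 100L))
}

test_that("basal and extended domains follow the stated rule", {
  m <- lone_gene()
  d <- regulatory_domains(m, c(chr1 = 1e7))
  expect_equal(d$basal_start, 1995000)
  expect_equal(d$basal_end, 2001000)
  expect_equal(d$ext_start, 995000)
  expect_equal(d$ext_end, 3001000)

  # two plus-strand genes: extension stops at the neighbor basal start
  m2 <- gene_models(
    data.frame(gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
               start = c(100000L, 110000L), end = c(104000L, 118000L)),
    data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
               start = c(100000L, 110000L), end = c(100100L, 110100L)))
  d2 <- regulatory_domains(m2, c(chr1 = 1e7))
  expect_equal(d2$ext_end[d2$gene_id == "g1"], 105000)
  expect_equal(d2$ext_start[d2$gene_id == "g2"], 101000)

  # near-origin gene: extension clipped at position 1
  m3 <- lone_gene(tss = 2000L)
  d3 <- regulatory_domains(m3, c(chr1 = 1e7))
  expect_equal(d3$ext_start, 1)
  expect_equal(d3$basal_start, 1)

  expect_error(regulatory_domains(m, c(chrZ = 1e7)), "unknown")
})

test_that("minus-strand basal windows flip around the TSS", {
  m <- lone_gene(strand = "-")
  d <- regulatory_domains(m, c(chr1 = 1e7))
  expect_equal(d$tss, 2000000)
  expect_equal(d$basal_start, 1999000)   # 1000 downstream (leftward)
  expect_equal(d$basal_end, 2005000)     # 5000 upstream (rightward)
})

test_that("domain construction matches the brute-force oracle", {
  for (s in 1:10) {
    n <- with_seed(s, sample(10:50, 1))
    genes <- with_seed(s * 13, data.frame(
      gene_id = paste0("g", seq_len(n)),
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      start = sort(sample.int(9e6, n))))
    genes$end <- genes$start + with_seed(s * 17,
                                         sample(1000:20000, n,
                                                replace = TRUE))
    m <- gene_models(genes, data.frame(
      gene_id = genes$gene_id, chrom = genes$chrom,
      start = genes$start, end = genes$start + 100L))
    lens <- c(c1 = 1e7, c2 = 1e7)
    got <- regulatory_domains(m, lens)
    want <- great_oracle(m$genes, lens)
    expect_equal(got$basal_start, want$basal_start)
    expect_equal(got$basal_end, want$basal_end)
    expect_equal(got$ext_start, want$ext_start)
    expect_equal(got$ext_end, want$ext_end)
    # rule invariants: basal within extended, extended inside chromosome
    expect_true(all(got$ext_start <= got$basal_start))
    expect_true(all(got$ext_end >= got$basal_end))
    expect_true(all(got$ext_start >= 1 & got$ext_end <= 1e7))
  }
})

test_that("associations bin the midpoint-to-TSS distance", {
  m <- lone_gene()
  d <- regulatory_domains(m, c(chr1 = 1e7))
  ltr <- data.frame(name = "L1", chrom = "chr1",
                    start = 1969500L, end = 1970500L)
  a <- associate_ltrs(ltr, d)
  expect_equal(nrow(a), 1)
  expect_equal(a$distance, -30000)
  expect_equal(a$bin, "5-50 kb")
  expect_equal(a$orientation, "upstream")

  # LTR on a gene-free chromosome associates with nothing
  none <- associate_ltrs(data.frame(name = "L2", chrom = "chr9",
                                    start = 100L, end = 200L), d)
  expect_equal(nrow(none), 0)

  # an LTR straddling two abutting domains yields two associations
  m2 <- gene_models(
    data.frame(gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
               start = c(1000000L, 1400000L),
               end = c(1010000L, 1410000L)),
    data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
               start = c(1000000L, 1400000L),
               end = c(1000100L, 1400100L)))
  d2 <- regulatory_domains(m2, c(chr1 = 1e7))
  both <- associate_ltrs(data.frame(name = "L3", chrom = "chr1",
                                    start = 1197000L, end = 1198000L), d2)
  expect_equal(sort(both$gene_id), c("g1", "g2"))
})

test_that("domain association equals the all-pairs interval oracle", {
  for (s in 1:5) {
    n <- 20
    genes <- with_seed(s * 31, data.frame(
      gene_id = paste0("g", seq_len(n)), chrom = "c1",
      strand = sample(c("+", "-"), n, replace = TRUE),
      start = sort(sample.int(9e6, n))))
    genes$end <- genes$start + 5000L
    m <- gene_models(genes, data.frame(gene_id = genes$gene_id,
                                       chrom = "c1",
                                       start = genes$start,
                                       end = genes$start + 100L))
    d <- regulatory_domains(m, c(c1 = 1e7))
    ltrs <- with_seed(s * 37, data.frame(
      name = paste0("L", 1:15), chrom = "c1",
      start = sample.int(9e6, 15)))
    ltrs$end <- ltrs$start + 900L
    got <- associate_ltrs(ltrs, d)
    got_pairs <- sort(paste(got$locus, got$gene_id))
    want_pairs <- character(0)
    for (i in seq_len(nrow(ltrs))) for (j in seq_len(nrow(d)))
      if (ltrs$start[i] <= d$ext_end[j] && ltrs$end[i] >= d$ext_start[j])
        want_pairs <- c(want_pairs,
                        paste(ltrs$name[i], d$gene_id[j]))
    expect_equal(got_pairs, sort(want_pairs))
  }
})

test_that("LTR eligibility requires >70% of a reference LTR", {
  sd <- study_discovery()
  sb <- study_bundle()
  elig <- eligible_ltr_loci(sd$loci, sb$reference)
  covs <- vapply(seq_len(nrow(sd$loci)), function(i) {
    p <- profile_regions(sd$loci$ref_blocks[[i]], sb$reference)
    max(p["5'LTR"], p["3'LTR"])
  }, 0)
  expect_equal(elig$name, sd$loci$name[covs > 0.7])
})

test_that("hypergeometric p-values match exact enumeration", {
  universe <- paste0("u", 1:20)
  cat5 <- universe[1:5]
  res <- ora_enrichment(universe[1:5], list(hit = cat5), universe,
                        min_size = 2)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$overlap, 5L)
  expect_equal(res$p_value,
               ora_enum_oracle(universe[1:5], cat5, universe),
               tolerance = 1e-12)

  # randomized cases against the enumeration oracle, universe <= 25
  for (s in 1:5) {
    uni <- paste0("g", 1:with_seed(s, sample(15:25, 1)))
    genes <- with_seed(s * 3, sample(uni, 5))
    cats <- with_seed(s * 7, list(
      c1 = sample(uni, 6), c2 = sample(uni, 9), c3 = sample(uni, 12)))
    res <- ora_enrichment(genes, cats, uni, min_size = 2, top = 10)
    for (k in seq_len(nrow(res))) {
      expect_equal(
        res$p_value[k],
        ora_enum_oracle(genes, cats[[res$category[k]]], uni),
        tolerance = 1e-9)
    }
  }
})

test_that("category-equals-universe is never enriched", {
  uni <- paste0("u", 1:30)
  res <- ora_enrichment(uni[1:6], list(all = uni), uni, max_size = 2000)
  expect_equal(res$enrichment_ratio, 1)
  expect_equal(res$p_value, 1)
})

test_that("BH FDR matches the hand-computed step-up", {
  p <- c(0.01, 0.02, 0.03)
  expect_equal(p.adjust(p, "BH"), rep(0.03, 3))
  expect_equal(p.adjust(p, "BH"), bh_oracle(p))
  p2 <- c(0.005, 0.01, 0.04, 0.04, 0.5)
  expect_equal(p.adjust(p2, "BH"), bh_oracle(p2))
  # the enrichment table carries BH values
  uni <- paste0("u", 1:25)
  cats <- list(a = uni[1:6], b = uni[3:11], c = uni[10:21])
  res <- ora_enrichment(uni[1:5], cats, uni, min_size = 2)
  expect_equal(res$fdr, bh_oracle(res$p_value), tolerance = 1e-12)
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
})

test_that("ORA validates its inputs and filters category sizes", {
  uni <- paste0("u", 1:20)
  expect_error(ora_enrichment("x1", list(a = uni[1:5]), character(0)),
               "empty universe")
  expect_error(ora_enrichment("zzz", list(a = uni[1:5]), uni),
               "outside the universe")
  res <- ora_enrichment(uni[1:5], list(tiny = uni[1:2]), uni,
                        min_size = 5)
  expect_equal(nrow(res), 0)
})

test_that("GMT category maps parse", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("set1\tdesc\tg1\tg2\tg3", "set2\tdesc\tg2\tg4"), path)
  gmt <- read_gmt(path)
  expect_equal(names(gmt), c("set1", "set2"))
  expect_equal(gmt$set2, c("g2", "g4"))
  bad <- tempfile(); writeLines("only\ttwo", bad)
  expect_error(read_gmt(bad), "malformed")
})
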