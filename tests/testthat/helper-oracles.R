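# Independent oracles used by the acceptance and unit tests. These
# deliberately use brute-force enumeration rather than the package's own
# code paths.

# Exact hypergeometric upper tail by enumerating every subset of the
# universe of the list's size (universe <= 25).
ora_enum_oracle <- function(genes, category, universe) {
  n <- length(genes)
  obs <- length(intersect(genes, category))
  combos <- utils::combn(universe, n)
  hits <- apply(combos, 2, function(s) length(intersect(s, category)) >= obs)
  mean(hits)
}

# Benjamini-Hochberg step-up computed by hand from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# GREAT regulatory domains by per-gene all-pairs scan, written from the
# stated rule: basal = TSS-up..TSS+down (strand-aware); extension grows to
# at most max_ext per side, stopping at the nearest other basal boundary,
# never below basal, clipped to the chromosome.
great_oracle <- function(genes, chrom_lengths, up = 5000, down = 1000,
                         max_ext = 1000000) {
  n <- nrow(genes)
  res <- data.frame(gene_id = genes$gene_id, basal_start = NA_real_,
                    basal_end = NA_real_, ext_start = NA_real_,
                    ext_end = NA_real_)
  tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  for (i in seq_len(n)) {
    L <- chrom_lengths[[genes$chrom[i]]]
    if (genes$strand[i] == "-") {
      bs <- tss[i] - down; be <- tss[i] + up
    } else {
      bs <- tss[i] - up; be <- tss[i] + down
    }
    bs <- max(1, bs); be <- min(L, be)
    lo <- max(1, bs - max_ext); hi <- min(L, be + max_ext)
    for (j in seq_len(n)) {
      if (j == i || genes$chrom[j] != genes$chrom[i]) next
      if (genes$strand[j] == "-") {
        obs <- tss[j] - down; obe <- tss[j] + up
      } else {
        obs <- tss[j] - up; obe <- tss[j] + down
      }
      obs <- max(1, obs); obe <- min(L, obe)
      if (obe < bs && obe > lo) lo <- obe
      if (obs > be && obs < hi) hi <- obs
      if (obe >= bs && obs < bs) lo <- bs   # neighbor basal overlaps ours
      if (obs <= be && obe > be) hi <- be
    }
    res$basal_start[i] <- bs; res$basal_end[i] <- be
    res$ext_start[i] <- min(lo, bs); res$ext_end[i] <- max(hi, be)
  }
  res
}

# All additive-tree distance matrices for the labeled unrooted topologies
# on 4 or 5 taxa, with distinct branch lengths so each topology is
# identifiable. Returns list of (matrix, splits) where splits are the
# non-trivial bipartitions as sorted "a|b" strings of the smaller side
# excluding taxon "t1".
additive_cases <- function(n_taxa) {
  taxa <- paste0("t", seq_len(n_taxa))
  anchor <- sort(taxa)[1]
  enc <- function(side) {
    if (anchor %in% side) side <- setdiff(taxa, side)
    paste(sort(side), collapse = "|")
  }
  cases <- list()
  if (n_taxa == 4) {
    pairings <- list(c(2, 3, 4), c(3, 2, 4), c(4, 2, 3))
    for (p in pairings) {
      # topology ((t1, tp1), (tp2, tp3)) with external lengths 1..4 and
      # internal length 2
      ext <- c(1, 2, 3, 4)
      d <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
      partner <- p[1]; others <- p[2:3]
      pairdist <- function(i, j) {
        same1 <- (i == 1 | i == partner) && (j == 1 | j == partner)
        same2 <- all(c(i, j) %in% others)
        ext[i] + ext[j] + if (same1 || same2) 0 else 2
      }
      for (i in 1:3) for (j in (i + 1):4)
        d[i, j] <- d[j, i] <- pairdist(i, j)
      cases[[length(cases) + 1L]] <-
        list(d = d, splits = enc(taxa[sort(c(1, partner))]))
    }
  } else if (n_taxa == 5) {
    # every labeled unrooted 5-taxon tree is a caterpillar: a cherry
    # {a,b} - internal - c - internal - cherry {d,e}
    combs <- utils::combn(5, 2)
    seen <- character(0)
    for (ci in seq_len(ncol(combs))) {
      ab <- combs[, ci]
      rest <- setdiff(1:5, ab)
      for (c_mid in rest) {
        de <- setdiff(rest, c_mid)
        key <- paste(paste(sort(ab), collapse = ","),
                     paste(sort(de), collapse = ","))
        rkey <- paste(paste(sort(de), collapse = ","),
                      paste(sort(ab), collapse = ","))
        if (rkey %in% seen) next
        seen <- c(seen, key)
        ext <- c(1, 2, 3, 4, 5)
        path <- numeric(5)  # distance from each leaf's attachment node
        d <- matrix(0, 5, 5, dimnames = list(taxa, taxa))
        # attachment nodes: x (ab cherry), m (c), y (de cherry);
        # internal lengths x-m = 2, m-y = 3
        node_of <- integer(5)
        node_of[ab] <- 1L; node_of[c_mid] <- 2L; node_of[de] <- 3L
        nd <- matrix(c(0, 2, 5,
                       2, 0, 3,
                       5, 3, 0), 3, 3)
        for (i in 1:4) for (j in (i + 1):5)
          d[i, j] <- d[j, i] <- ext[i] + ext[j] +
            nd[node_of[i], node_of[j]]
        cases[[length(cases) + 1L]] <- list(
          d = d,
          splits = c(enc(taxa[sort(ab)]), enc(taxa[sort(de)])))
      }
    }
  }
  cases
}

# Non-trivial splits of an ape tree, canonically encoded to match
# additive_cases(): each internal edge as the leaf side not containing the
# alphabetically first taxon.
tree_splits_oracle <- function(tree) {
  taxa <- tree$tip.label
  anchor <- sort(taxa)[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (s in pp) {
    side <- labs[s]
    if (anchor %in% side) side <- setdiff(taxa, side)
    if (length(side) >= 2 && length(side) <= length(taxa) - 2)
      out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}
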