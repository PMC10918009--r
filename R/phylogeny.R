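#' Pairwise distance matrix from an alignment
#'
#' Pairwise-deletion distances under the uncorrected p-distance, the
#' Jukes-Cantor correction, or Kimura's two-parameter model.
#'
#' @param seqs named character vector of equal-length aligned sequences,
#'   >= 3 taxa.
#' @param model `"p"`, `"JC"` or `"K2P"`.
#' @return symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
distance_matrix <- function(seqs, model = c("p", "JC", "K2P")) {
  model <- match.arg(model)
  n <- length(seqs)
  if (n < 3) stopf("need at least 3 taxa")
  if (length(unique(nchar(seqs))) != 1)
    stopf("sequences differ in length")
  if (is.null(names(seqs))) names(seqs) <- paste0("t", seq_len(n))
  chars <- split_chars(seqs)
  bases <- c("A", "C", "G", "T")
  purine <- c("A", "G")
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    x <- chars[[i]]; y <- chars[[j]]
    ok <- x %in% bases & y %in% bases
    if (!any(ok)) stopf("no comparable sites for pair (%s, %s)",
                        names(seqs)[i], names(seqs)[j])
    x <- x[ok]; y <- y[ok]
    diff <- x != y
    p <- mean(diff)
    val <- switch(model,
      p = p,
      JC = {
        if (p >= 0.75) stopf("saturated pair (%s, %s): p = %.3f",
                             names(seqs)[i], names(seqs)[j], p)
        -0.75 * log(1 - 4 * p / 3)
      },
      K2P = {
        ts <- mean(diff & (x %in% purine) == (y %in% purine))
        tv <- p - ts
        w1 <- 1 - 2 * ts - tv; w2 <- 1 - 2 * tv
        if (w1 <= 0 || w2 <= 0)
          stopf("saturated pair (%s, %s) under K2P",
                names(seqs)[i], names(seqs)[j])
        -0.5 * log(w1) - 0.25 * log(w2)
      })
    d[i, j] <- d[j, i] <- val
  }
  d
}

# Saitou-Nei neighbor joining over a distance matrix. Ties in the Q matrix
# are broken by the lowest (i, j) index pair; negative branch lengths are
# clamped to zero. `node_label` optionally labels each internal node from
# its descendant leaf set (used to decorate bootstrap supports).
# Returns list(newick, splits): splits are the leaf sets of internal edges.
nj_core <- function(d, node_label = NULL) {
  labs <- rownames(d)
  n <- length(labs)
  clamped <- FALSE
  nwk <- labs
  leafsets <- as.list(labs)
  splits <- list()
  active <- seq_len(n)
  D <- d
  fmt <- function(x) sprintf("%.10g", max(0, x))
  while (length(active) > 3) {
    m <- length(active)
    Dm <- D[active, active]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    bi <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- Dm[i, j] - bi
    if (bi < 0 || bj < 0) clamped <- TRUE
    ai <- active[i]; aj <- active[j]
    newset <- c(leafsets[[ai]], leafsets[[aj]])
    splits[[length(splits) + 1L]] <- newset
    lab <- if (is.null(node_label)) "" else node_label(newset)
    newnwk <- sprintf("(%s:%s,%s:%s)%s", nwk[ai], fmt(bi), nwk[aj],
                      fmt(bj), lab)
    # distances from the new node to the remaining clusters
    rest <- active[-c(i, j)]
    newd <- (D[ai, rest] + D[aj, rest] - Dm[i, j]) / 2
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    D[u, rest] <- newd; D[rest, u] <- newd
    nwk <- c(nwk, newnwk)
    leafsets[[u]] <- newset
    active <- c(rest, u)
  }
  a <- active
  if (length(a) == 3) {
    b1 <- (D[a[1], a[2]] + D[a[1], a[3]] - D[a[2], a[3]]) / 2
    b2 <- (D[a[1], a[2]] + D[a[2], a[3]] - D[a[1], a[3]]) / 2
    b3 <- (D[a[1], a[3]] + D[a[2], a[3]] - D[a[1], a[2]]) / 2
    if (min(b1, b2, b3) < 0) clamped <- TRUE
    newick <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[a[1]], fmt(b1),
                      nwk[a[2]], fmt(b2), nwk[a[3]], fmt(b3))
  } else if (length(a) == 2) {
    newick <- sprintf("(%s:%s,%s:%s);", nwk[a[1]],
                      fmt(D[a[1], a[2]] / 2), nwk[a[2]],
                      fmt(D[a[1], a[2]] / 2))
  } else stopf("need at least 3 taxa")
  list(newick = newick, splits = splits, clamped = clamped)
}

# Canonical encoding of a bipartition: the side NOT containing the
# alphabetically first taxon, sorted and joined. Trivial splits (a single
# leaf on one side) encode to NA.
encode_split <- function(leafset, taxa) {
  anchor <- sort(taxa)[1]
  side <- if (anchor %in% leafset) setdiff(taxa, leafset) else leafset
  if (length(side) < 2 || length(side) > length(taxa) - 2)
    return(NA_character_)
  paste(sort(side), collapse = "|")
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with deterministic tie-breaking (lowest
#' index pair in the Q matrix). Negative branch lengths are clamped to zero
#' with a warning, per common practice.
#'
#' @param d symmetric distance matrix with taxon dimnames.
#' @return an `ape::phylo` tree (unrooted).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stopf("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stopf("distance matrix is not symmetric")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  res <- nj_core(d)
  if (res$clamped)
    warning("negative branch length(s) clamped to 0", call. = FALSE)
  ape::read.tree(text = res$newick)
}

#' Bootstrap support for NJ splits
#'
#' Resamples alignment columns with replacement `reps` times, rebuilds the
#' NJ tree per replicate, and reports for each internal split of the
#' original tree the percentage of replicate trees containing it.
#'
#' @param aligned named character vector of equal-length aligned sequences.
#' @param model distance model passed to [distance_matrix()].
#' @param reps number of bootstrap replicates.
#' @param seed integer RNG seed.
#' @return list of class `bootstrap_tree`: `tree` (phylo with node labels =
#'   supports), `newick`, `supports` (named by canonical split), `reps`.
#' @export
bootstrap_support <- function(aligned, model = "p", reps = 500, seed = 1) {
  if (reps < 1) stopf("reps must be >= 1")
  len <- unique(nchar(aligned))
  if (length(len) != 1) stopf("sequences differ in length")
  if (len < 2) stopf("alignment must have at least 2 columns")
  taxa <- names(aligned)
  d0 <- distance_matrix(aligned, model)
  orig <- nj_core(d0)
  keys <- vapply(orig$splits, encode_split, "", taxa = taxa)
  counts <- setNames(rep(0, sum(!is.na(keys))), keys[!is.na(keys)])
  chars <- do.call(rbind, split_chars(aligned))
  with_seed(seed, {
    for (b in seq_len(reps)) {
      cols <- sample.int(len, len, replace = TRUE)
      rseqs <- setNames(apply(chars[, cols, drop = FALSE], 1, paste,
                              collapse = ""), taxa)
      rb <- try(nj_core(distance_matrix(rseqs, model)), silent = TRUE)
      if (inherits(rb, "try-error")) next
      rkeys <- vapply(rb$splits, encode_split, "", taxa = taxa)
      hit <- names(counts) %in% rkeys
      counts[hit] <- counts[hit] + 1
    }
  })
  supports <- 100 * counts / reps
  labeler <- function(leafset) {
    k <- encode_split(leafset, taxa)
    if (is.na(k) || !k %in% names(supports)) "" else
      sprintf("%.4g", supports[[k]])
  }
  res <- nj_core(d0, node_label = labeler)
  structure(list(tree = ape::read.tree(text = res$newick),
                 newick = res$newick, supports = supports, reps = reps,
                 taxa = taxa),
            class = "bootstrap_tree")
}

#' @export
print.bootstrap_tree <- function(x, ...) {
  cat(sprintf("NJ tree over %d taxa, %d bootstrap replicates\n",
              length(x$taxa), x$reps))
  if (length(x$supports)) {
    cat("internal split supports (%):\n")
    for (k in names(x$supports))
      cat(sprintf("  {%s}: %.4g\n", gsub("\\|", ", ", k), x$supports[[k]]))
  }
  invisible(x)
}

#' Assign query sequences to reference groups
#'
#' Builds a bootstrapped NJ tree over the queries plus a labeled reference
#' panel and assigns each query the group of the smallest supported cluster
#' (split side) it shares with panel members of a single group; queries in
#' no such cluster are `"unassigned"`.
#'
#' @param queries named character vector of aligned query sequences.
#' @param panel named character vector of aligned panel sequences (same
#'   alignment coordinates as the queries).
#' @param panel_groups character vector of group labels, parallel to
#'   `panel` (e.g. HML subtype names and outgroup labels).
#' @param model distance model.
#' @param reps bootstrap replicates.
#' @param support_threshold minimum split support (percent).
#' @param seed integer RNG seed.
#' @return named character vector: query -> group label or `"unassigned"`.
#' @export
assign_group <- function(queries, panel, panel_groups, model = "p",
                         reps = 100, support_threshold = 70, seed = 1) {
  if (!length(panel)) stopf("empty reference panel")
  if (length(panel) != length(panel_groups))
    stopf("panel and panel_groups lengths differ")
  if (!length(queries)) stopf("no query sequences")
  all_seqs <- c(queries, panel)
  bt <- bootstrap_support(all_seqs, model = model, reps = reps, seed = seed)
  taxa <- names(all_seqs)
  group_of <- setNames(panel_groups, names(panel))
  sides <- lapply(names(bt$supports), function(k) {
    side <- strsplit(k, "|", fixed = TRUE)[[1]]
    list(side = side, comp = setdiff(taxa, side), sup = bt$supports[[k]])
  })
  vapply(names(queries), function(q) {
    cand <- list()
    for (s in sides) {
      if (s$sup < support_threshold) next
      for (set in list(s$side, s$comp))
        if (q %in% set) cand[[length(cand) + 1L]] <- set
    }
    if (length(cand)) {
      cand <- cand[order(lengths(cand))]
      for (set in cand) {
        refs <- intersect(set, names(panel))
        if (!length(refs)) next
        gl <- unique(group_of[refs])
        if (length(gl) == 1) return(gl)
        break  # smallest cluster with panel members is mixed
      }
    }
    "unassigned"
  }, "")
}

#' Export an alignment for external ML tree inference
#'
#' The pipeline's own trees are distance-based; maximum-likelihood
#' inference (e.g. GTR+G+I with NNI search) is delegated to external tools.
#' This writes the alignment in FASTA or relaxed PHYLIP and
#' [import_tree()] reads the resulting newick back.
#'
#' @param aligned named character vector of aligned sequences.
#' @param path output path.
#' @param format `"fasta"` or `"phylip"`.
#' @export
export_for_ml <- function(aligned, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    for (nm in names(aligned))
      writeLines(c(paste0(">", nm), aligned[[nm]]), con)
  } else {
    writeLines(sprintf("%d %d", length(aligned), nchar(aligned[[1]])), con)
    for (nm in names(aligned))
      writeLines(paste(nm, aligned[[nm]]), con)
  }
  invisible(path)
}

#' @rdname export_for_ml
#' @export
import_tree <- function(path) ape::read.tree(path)
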