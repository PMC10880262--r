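# Neighbor-joining phylogenies of satellite monomers under Jukes-Cantor
# distances. The NJ algorithm is implemented here (Saitou-Nei Q-criterion
# with deterministic tie-breaks); ape supplies tree parsing/serialization.

#' Jukes-Cantor distance
#'
#' `d = -(3/4) * log(1 - 4p/3)` for mismatch proportion `p`.
#'
#' @param p Observed mismatch proportion(s), `0 <= p < 0.75`.
#' @param cap If supplied, saturated values (`p >= 0.75`) return `cap`
#'   instead of raising an error.
#' @return Distance(s) `d >= p`.
#' @export
jc_distance <- function(p, cap = NULL) {
  if (any(p < 0)) stopf("mismatch proportion must be >= 0")
  sat <- p >= 0.75
  if (any(sat) && is.null(cap)) {
    stopf("Jukes-Cantor distance saturates at p >= 0.75 (got %.3f); supply a cap",
          max(p))
  }
  d <- rep(cap %||% NA_real_, length(p))
  d[!sat] <- -0.75 * log(1 - 4 * p[!sat] / 3)
  d
}

#' Inverse Jukes-Cantor transform
#'
#' @param d Jukes-Cantor distance(s).
#' @return Mismatch proportion(s) `p`.
#' @export
jc_inverse <- function(d) 0.75 * (1 - exp(-4 * d / 3))

#' Pairwise Jukes-Cantor distance matrix
#'
#' Mismatch proportions come from pairwise global alignments
#' (substitutions over columns where both sequences have a base; gap
#' columns are excluded from `p`).
#'
#' @param sequences Character vector of >= 3 DNA sequences.
#' @param labels Sequence labels (default names or `seq_1`...).
#' @param cap Saturation cap passed to [jc_distance()] (default 5; a
#'   warning is issued when used).
#' @return Symmetric matrix of JC distances with zero diagonal.
#' @export
pairwise_distances <- function(sequences, labels = NULL, cap = 5) {
  n <- length(sequences)
  if (n < 3) stopf("need >= 3 sequences")
  labels <- labels %||% names(sequences) %||% sprintf("seq_%d", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(sequences[i]), Biostrings::DNAString(sequences[j]),
        type = "global", substitutionMatrix = .edit_matrix(),
        gapOpening = 4, gapExtension = 1)
      pa <- split_bases(as.character(Biostrings::alignedPattern(aln)))
      sa <- split_bases(as.character(Biostrings::alignedSubject(aln)))
      both <- pa != "-" & sa != "-"
      p <- if (any(both)) mean(pa[both] != sa[both]) else 0
      if (p >= 0.75) {
        warn(sprintf("pair (%s, %s) saturated (p = %.2f); capping distance at %g",
                     labels[i], labels[j], p, cap))
      }
      D[i, j] <- D[j, i] <- jc_distance(p, cap = cap)
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining: iterative joins by the Q
#' criterion, branch lengths from the usual formulas, negative lengths
#' clamped to zero, and ties broken deterministically toward the smallest
#' pair of node indices (original input order). The result is an unrooted
#' tree serialized through a trifurcating root.
#'
#' @param D Symmetric distance matrix with labeled rows/columns (n >= 3).
#' @return An `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stopf("distance matrix must be symmetric")
  }
  n <- nrow(D)
  if (n < 3) stopf("need >= 3 taxa")
  labels <- rownames(D) %||% sprintf("t%d", seq_len(n))
  frag <- labels
  ord <- seq_len(n)            # original-order rank of each active node
  next_rank <- n + 1L
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    # deterministic tie-break: smallest (i, j) in original node order
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ranks <- cbind(pmin(ord[cand[, 1]], ord[cand[, 2]]),
                   pmax(ord[cand[, 1]], ord[cand[, 2]]))
    pick <- order(ranks[, 1], ranks[, 2])[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    bi <- max(bi, 0); bj <- max(bj, 0)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], bi, frag[j], bj)
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    D <- D2
    frag <- c(frag[keep], newfrag)
    ord <- c(ord[keep], next_rank)
    next_rank <- next_rank + 1L
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  b1 <- max((d12 + d13 - d23) / 2, 0)
  b2 <- max((d12 + d23 - d13) / 2, 0)
  b3 <- max((d13 + d23 - d12) / 2, 0)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    frag[1], b1, frag[2], b2, frag[3], b3)
  ape::read.tree(text = newick)
}

#' Build a monomer tree
#'
#' Distance + NJ convenience wrapper; when more than `n_max` monomers are
#' given a seeded random subsample of `n_max` is used (the convention for
#' class-level trees is 30 per class).
#'
#' @param monomers Monomer tibble with `sequence` (and optionally
#'   `ordinal` used for labels).
#' @param n_max Maximum number of leaves (default 30).
#' @param seed Subsampling seed.
#' @param cap Saturation cap for [pairwise_distances()].
#' @return An `ape::phylo` tree.
#' @export
monomer_tree <- function(monomers, n_max = 30L, seed = 1L, cap = 5) {
  if (nrow(monomers) > n_max) {
    set.seed(as.integer(seed))
    monomers <- monomers[sort(sample.int(nrow(monomers), n_max)), ]
  }
  labels <- if ("label" %in% names(monomers)) monomers$label
            else sprintf("m%03d", monomers$ordinal %||% seq_len(nrow(monomers)))
  neighbor_joining(pairwise_distances(monomers$sequence, labels, cap = cap))
}

# tip sets for every edge of the tree, via one postorder pass
edge_tip_sets <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (t in seq_len(ntip)) sets[[t]] <- t
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  list(tree = tree, sets = sets)
}

#' Check whether a binary grouping forms a clade partition
#'
#' Tests whether some edge of the tree bipartitions the leaves exactly
#' into the two groups, and reports the best achievable bipartition
#' agreement (purity) over all edges.
#'
#' @param tree An `ape::phylo` tree.
#' @param groups Named vector (names = tip labels) with exactly two
#'   distinct values.
#' @return List: `separated` (logical), `purity` (max agreement fraction
#'   in `[0.5, 1]`), `best_edge_tips` (tip labels on one side of the best
#'   edge).
#' @export
clade_partition_check <- function(tree, groups) {
  tips <- tree$tip.label
  if (!all(tips %in% names(groups))) stopf("groups must cover every tip label")
  g <- groups[tips]
  lv <- unique(g)
  if (length(lv) != 2) stopf("groups must have exactly two levels")
  in_g1 <- g == lv[1]
  n <- length(tips)
  ets <- edge_tip_sets(tree)
  best <- 0; best_side <- integer()
  for (e in seq_len(nrow(ets$tree$edge))) {
    side <- ets$sets[[ets$tree$edge[e, 2]]]
    a <- rep(FALSE, n); a[side] <- TRUE
    agree <- (sum(a & in_g1) + sum(!a & !in_g1)) / n
    pur <- max(agree, 1 - agree)
    if (pur > best) { best <- pur; best_side <- side }
  }
  list(separated = best >= 1 - 1e-12, purity = best,
       best_edge_tips = tips[best_side])
}
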