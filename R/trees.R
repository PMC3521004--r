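#' Pairwise p-distance matrix from an alignment
#'
#' `d(i, j)` is the fraction of mismatching residues over the columns where
#' neither row has a gap.  A pair with no comparable column is an error (the
#' alignment cannot place those sequences relative to each other).
#'
#' @param msa Alignment (named character vector of gapped rows, >= 2 rows).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = row names.
#' @export
p_distance <- function(msa) {
  mat <- msa_matrix(msa)
  n <- nrow(mat)
  stopifnot(n >= 2)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      keep <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(keep)) {
        stop("no comparable columns between ", rownames(mat)[i],
             " and ", rownames(mat)[j])
      }
      d[i, j] <- d[j, i] <- mean(mat[i, keep] != mat[j, keep])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via `ape::nj()`); additive input
#' matrices are recovered exactly.  Negative branch-length estimates, which
#' NJ can produce on non-additive input, are clamped to zero and flagged in
#' the returned tree's `clamped` attribute.
#'
#' @param dm Symmetric distance matrix with labelled dimnames (>= 2 taxa).
#' @return An `ape` `phylo` tree (a two-taxon input gives the trivial
#'   cherry).
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  stopifnot(nrow(dm) >= 2, isSymmetric(unname(dm)), all(diag(dm) == 0))
  if (nrow(dm) == 2) {
    return(ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                         rownames(dm)[1], dm[1, 2] / 2,
                                         rownames(dm)[2], dm[1, 2] / 2)))
  }
  tr <- ape::nj(stats::as.dist(dm))
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- sum(neg)
  tr
}

#' Robinson-Foulds distance between two trees
#'
#' Count of non-trivial bipartitions present in exactly one of the two trees
#' (via `phangorn::RF.dist()`); both trees must share the same leaf set.
#' Used as the quantitative surrogate for visual tree-topology congruence.
#'
#' @param t1,t2 `phylo` trees on the same tips.
#' @return Integer symmetric-difference count.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets")
  }
  phangorn::RF.dist(t1, t2, check.labels = TRUE)
}

#' Genus monophyly in an unrooted tree
#'
#' A genus is monophyletic when some edge of the (unrooted) tree bipartitions
#' the leaves into exactly that genus versus everything else; the test is
#' therefore invariant to rerooting.  Genera with a single leaf are trivially
#' monophyletic and excluded from the fraction.
#'
#' @param tree A `phylo` tree.
#' @param genera Named character vector mapping every tip label to a genus.
#' @return List with `fraction` (monophyletic share of multi-leaf genera),
#'   `violators` (genera split across the tree) and `tested` (the multi-leaf
#'   genera).
#' @export
genus_monophyly <- function(tree, genera) {
  tips <- tree$tip.label
  if (!all(tips %in% names(genera))) stop("every tip needs a genus label")
  genera <- genera[tips]
  pp <- ape::prop.part(tree)   # clades as tip-index sets
  splits <- t(vapply(pp, function(cl) {
    v <- integer(length(tips)); v[cl] <- 1L; v
  }, integer(length(tips))))   # clades x tips membership
  gen <- unique(genera)
  multi <- gen[vapply(gen, function(g) sum(genera == g) >= 2, TRUE)]
  if (length(multi) == 0) {
    return(list(fraction = NA_real_, violators = character(),
                tested = character()))
  }
  is_mono <- vapply(multi, function(g) {
    want <- as.integer(genera == g)
    any(apply(splits, 1, function(row) {
      all(row == want) || all(row == 1L - want)
    }))
  }, TRUE)
  list(fraction = mean(is_mono),
       violators = multi[!is_mono],
       tested = multi)
}

#' Write a tree in Newick format
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
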