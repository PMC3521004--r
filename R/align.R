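#' Alignment parameters
#'
#' Bundles the substitution matrix and affine gap costs used by
#' [global_align()] and [progressive_msa()].  The gap model is
#' `cost(L) = gap_open + (L - 1) * gap_extend` for a gap of length `L`,
#' terminal gaps included (true global alignment).  Defaults follow the
#' ClustalW-style settings used for seed alignments in curli annotation work:
#' gap opening cost 15, extension cost 1; repeat-region alignments use
#' `gap_open = 50` to keep the 22-residue units intact.
#'
#' @param matrix Substitution matrix: `"blosum62"` (default), `"blosum45"`,
#'   or a numeric matrix with amino-acid dimnames.
#' @param gap_open Positive gap opening cost (charged for the first gapped
#'   position).
#' @param gap_extend Positive gap extension cost (each further position).
#' @return A list of class `align_params`.
#' @export
align_params <- function(matrix = "blosum62", gap_open = 15, gap_extend = 1) {
  stopifnot(gap_open > 0, gap_extend > 0)
  sub <- if (is.character(matrix)) substitution_matrix(matrix) else as.matrix(matrix)
  if (!isSymmetric(unname(sub))) stop("substitution matrix must be symmetric")
  structure(list(matrix = sub, gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

#' @noRd
substitution_matrix <- function(name = c("blosum62", "blosum45")) {
  name <- match.arg(tolower(name), c("blosum62", "blosum45"))
  env <- new.env()
  utils::data(list = toupper(name), package = "Biostrings", envir = env)
  get(toupper(name), envir = env)
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch over the full lengths of both sequences.  The score is
#' the maximum of `sum(matrix[a_i, b_j]) - sum_gaps(gap_open + (L - 1) *
#' gap_extend)` over all global alignments; ties in the traceback prefer the
#' diagonal, then a gap in `b`, then a gap in `a`.
#'
#' @param a,b Ungapped amino-acid strings (non-empty).
#' @param params An [align_params()] object.
#' @return List with `gapped_a`, `gapped_b` (equal-length gapped strings, no
#'   all-gap column) and `score`.
#' @export
global_align <- function(a, b, params = align_params()) {
  stopifnot(inherits(params, "align_params"))
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  sub <- params$matrix
  if (!all(c(ca, cb) %in% rownames(sub))) {
    stop("sequence letters missing from the substitution matrix")
  }
  S <- sub[ca, cb, drop = FALSE]
  res <- .affine_align_cpp(S, params$gap_open, params$gap_extend)
  ops <- res$ops
  ga <- character(length(ops)); gb <- character(length(ops))
  ia <- 0L; ib <- 0L
  for (t in seq_along(ops)) {
    if (ops[t] != 2L) { ia <- ia + 1L; ga[t] <- ca[ia] } else ga[t] <- "-"
    if (ops[t] != 1L) { ib <- ib + 1L; gb[t] <- cb[ib] } else gb[t] <- "-"
  }
  list(gapped_a = paste(ga, collapse = ""),
       gapped_b = paste(gb, collapse = ""),
       score = res$score)
}

# p-distance between the two rows of one pairwise alignment
pair_pdist <- function(aln) {
  x <- strsplit(aln$gapped_a, "", fixed = TRUE)[[1]]
  y <- strsplit(aln$gapped_b, "", fixed = TRUE)[[1]]
  keep <- x != "-" & y != "-"
  if (!any(keep)) return(1)
  mean(x[keep] != y[keep])
}

#' Guide tree for progressive alignment
#'
#' Neighbor-joining tree on pairwise p-distances computed from
#' [global_align()] of every sequence pair.  Used to order profile merges in
#' [progressive_msa()].
#'
#' @param seqs Named character vector of >= 2 ungapped sequences.
#' @param params Alignment parameters.
#' @return An `ape` `phylo` tree whose tips are `names(seqs)`.
#' @export
guide_tree <- function(seqs, params = align_params()) {
  n <- length(seqs)
  stopifnot(n >= 2, !is.null(names(seqs)))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- pair_pdist(global_align(seqs[[i]], seqs[[j]], params))
    }
  }
  if (n == 2) {
    return(ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                         names(seqs)[1], d[1, 2] / 2,
                                         names(seqs)[2], d[1, 2] / 2)))
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Average-of-pairs score matrix between two profiles (character matrices).
# Gaps are excluded from each column's residue pool; a column pair scores the
# mean substitution score over all residue pairs.
profile_score_matrix <- function(A, B, sub) {
  alpha <- rownames(sub)
  countcols <- function(M) {
    apply(M, 2, function(col) {
      col <- col[col != "-"]
      tabulate(match(col, alpha), nbins = length(alpha))
    })
  }
  CA <- countcols(A)  # alpha x ncolA
  CB <- countcols(B)
  nA <- colSums(CA); nB <- colSums(CB)
  S <- t(CA) %*% sub %*% CB
  sweep(sweep(S, 1, pmax(nA, 1), "/"), 2, pmax(nB, 1), "/")
}

align_profiles <- function(A, B, params) {
  S <- profile_score_matrix(A, B, params$matrix)
  res <- .affine_align_cpp(S, params$gap_open, params$gap_extend)
  ops <- res$ops
  out <- matrix("-", nrow(A) + nrow(B), length(ops))
  ia <- 0L; ib <- 0L
  for (t in seq_along(ops)) {
    if (ops[t] != 2L) { ia <- ia + 1L; out[seq_len(nrow(A)), t] <- A[, ia] }
    if (ops[t] != 1L) { ib <- ib + 1L; out[nrow(A) + seq_len(nrow(B)), t] <- B[, ib] }
  }
  rownames(out) <- c(rownames(A), rownames(B))
  out
}

#' Progressive multiple sequence alignment
#'
#' Profile-profile progressive alignment in guide-tree order (a ClustalW-like
#' scheme): pairwise p-distances define a neighbor-joining guide tree, and
#' profiles are merged at each internal node with average-of-pairs column
#' scoring under the affine gap model of `params`.  Exact ClustalW output
#' equivalence is not attempted; pairwise merge steps are score-optimal under
#' the stated profile scoring.
#'
#' @param seqs Named character vector of >= 2 ungapped sequences.
#' @param params Alignment parameters ([align_params()]).
#' @return Named character vector of gapped rows (an alignment as accepted by
#'   [as_msa()]), rows in input order; ungapping any row reproduces its input.
#' @export
progressive_msa <- function(seqs, params = align_params()) {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names")
  as_char_mat <- function(nm) {
    matrix(strsplit(seqs[[nm]], "", fixed = TRUE)[[1]], nrow = 1,
           dimnames = list(nm, NULL))
  }
  if (length(seqs) == 2) {
    aln <- global_align(seqs[[1]], seqs[[2]], params)
    out <- setNames(c(aln$gapped_a, aln$gapped_b), names(seqs))
    return(as_msa(out))
  }
  tr <- guide_tree(seqs, params)
  tr <- stats::reorder(tr, "postorder")
  n_tip <- length(tr$tip.label)
  prof <- vector("list", n_tip + tr$Nnode)
  for (i in seq_len(n_tip)) prof[[i]] <- as_char_mat(tr$tip.label[i])
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    prof[[parent]] <- if (is.null(prof[[parent]])) prof[[child]]
                      else align_profiles(prof[[parent]], prof[[child]], params)
  }
  root <- n_tip + 1L
  M <- prof[[root]]
  rows <- setNames(apply(M, 1, paste, collapse = ""), rownames(M))
  as_msa(rows[names(seqs)])
}
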