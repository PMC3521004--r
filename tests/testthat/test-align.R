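test_that("identical sequences align without gaps at the diagonal score", {
  aln <- global_align("NQG", "NQG")
  # blosum62: s(N,N)=6, s(Q,Q)=5, s(G,G)=6
  expect_equal(aln$score, 17)
  expect_equal(aln$gapped_a, "NQG")
  expect_equal(aln$gapped_b, "NQG")
})

test_that("a single-residue gap costs the opening cost", {
  aln <- global_align("QG", "G", align_params(gap_open = 15, gap_extend = 1))
  expect_equal(aln$score, 6 - 15)   # s(G,G) - GOC
  expect_equal(nchar(aln$gapped_a), 2L)
  expect_true(grepl("-", aln$gapped_b, fixed = TRUE))
})

test_that("empty sequences are rejected", {
  expect_error(global_align("Q", ""), "non-empty")
})

test_that("pairwise scores match brute-force enumeration and are symmetric", {
  set.seed(41)
  p <- align_params(gap_open = 5, gap_extend = 1)
  for (i in 1:60) {
    a <- random_peptide(sample(1:5, 1))
    b <- random_peptide(sample(1:5, 1))
    want <- brute_align_score(a, b, p$matrix, p$gap_open, p$gap_extend)
    expect_equal(global_align(a, b, p)$score, want, info = paste(a, b))
    expect_equal(global_align(b, a, p)$score, want)
  }
})

test_that("pairwise scores agree with an independent aligner", {
  # Biostrings charges gapOpening + gapExtension per gapped position, so its
  # gapOpening equals our gap_open - gap_extend.
  set.seed(42)
  p <- align_params(gap_open = 15, gap_extend = 1)
  for (i in 1:20) {
    a <- random_peptide(sample(5:30, 1))
    b <- random_peptide(sample(5:30, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = p$matrix, gapOpening = 14, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
    expect_equal(global_align(a, b, p)$score, ref)
  }
})

test_that("ungapping alignment rows reproduces the inputs", {
  set.seed(43)
  a <- random_peptide(25); b <- random_peptide(18)
  aln <- global_align(a, b)
  expect_equal(gsub("-", "", aln$gapped_a), a)
  expect_equal(gsub("-", "", aln$gapped_b), b)
})

test_that("guide trees recover additive four-taxon distances", {
  # hand-built additive matrix corresponds to ((A,B),(C,D)); p-distances are
  # not additive in general, so test the NJ step through nj_tree directly
  seqs <- c(A = "AAAAAAAAAA", B = "AAAAAAAAAC", C = "WWWWWWWWWW",
            D = "WWWWWWWWWC")
  tr <- guide_tree(seqs)
  expect_s3_class(tr, "phylo")
  expect_equal(robinson_foulds(tr, ape::read.tree(text = "((A,B),(C,D));")), 0)
})

test_that("progressive alignment of identical sequences is gap-free", {
  seqs <- setNames(rep("MKQWNQG", 4), paste0("s", 1:4))
  m <- progressive_msa(seqs)
  expect_equal(unname(nchar(m)), rep(7L, 4))
  expect_false(any(grepl("-", m, fixed = TRUE)))
})

test_that("two-sequence progressive alignment reduces to pairwise", {
  a <- "MKQWNQG"; b <- "MKQNQG"
  m <- progressive_msa(c(x = a, y = b))
  aln <- global_align(a, b)
  expect_equal(unname(m), c(aln$gapped_a, aln$gapped_b))
})

test_that("every row of a progressive alignment ungaps to its input", {
  set.seed(44)
  seqs <- setNames(vapply(1:5, function(i) random_peptide(sample(10:30, 1)), ""),
                   paste0("s", 1:5))
  m <- progressive_msa(seqs)
  expect_equal(length(unique(nchar(m))), 1L)
  for (nm in names(seqs)) {
    expect_equal(gsub("-", "", m[[nm]]), seqs[[nm]])
  }
})

test_that("a planted shared block anchors the alignment in most rows", {
  set.seed(45)
  block <- random_peptide(22)
  seqs <- setNames(vapply(1:5, function(i) {
    paste0(random_peptide(sample(3:10, 1)), block,
           random_peptide(sample(3:10, 1)))
  }, ""), paste0("s", 1:5))
  m <- progressive_msa(seqs)
  # for each row, find the columns its block occupies; the block is aligned
  # gap-free when those columns are consecutive
  windows <- lapply(names(seqs), function(nm) {
    chars <- strsplit(m[[nm]], "")[[1]]
    respos <- which(chars != "-")
    off <- regexpr(block, seqs[[nm]], fixed = TRUE)[1]
    cols <- respos[off:(off + 21)]
    if (all(diff(cols) == 1)) cols[1] else NA_integer_
  })
  starts <- unlist(windows)
  best <- max(table(starts[!is.na(starts)]))
  expect_gte(best, 4)
})
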