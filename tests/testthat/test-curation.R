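test_that("validation reports reproduce the hits/correct/missing arithmetic", {
  v <- validate(letters[1:8], c(letters[1:7], "x", "y", "z"), "toy")
  expect_equal(v$hits, 8L)
  expect_equal(v$correct_str, "7/8 (88%)")
  expect_equal(v$missing_str, "3/10 (30%)")
  ids <- sprintf("p%03d", 1:172)
  v2 <- validate(ids, ids, "CsgF")
  expect_equal(v2$hits, 172L)
  expect_equal(v2$correct_str, "172/172 (100%)")
  expect_equal(v2$missing_str, "0/172 (0%)")
  v3 <- validate(c("a", "b"), c("c", "d"))
  expect_equal(v3$correct_str, "0/2 (0%)")
  expect_equal(v3$missing_str, "2/2 (100%)")
  expect_error(validate("a", character()), "empty truth")
})

test_that("validation reports format as tab-separated table rows", {
  v <- validate(sprintf("p%d", 1:172), sprintf("p%d", 1:172), "CsgF")
  expect_equal(format(v), "CsgF\t172\t172/172 (100%)\t0/172 (0%)")
})

make_hits <- function(ids, scores) {
  data.frame(target_id = ids, bit_score = scores, start = 0L,
             end = 10L, model_start = 1L, model_end = 5L,
             evalue_surrogate = 1e-3, stringsAsFactors = FALSE)
}

test_that("the two-clause curation rule accepts and rejects as specified", {
  rep3 <- paste(rep("AAAAAAQAGAANAAAAAAAAAA", 3), collapse = "")
  ids <- c("ab1", "f1", "g1", paste0("fill", 1:6), "lone")
  feats <- data.frame(contig = "c1", start = (seq_along(ids) - 1L) * 400L,
                      end = (seq_along(ids) - 1L) * 400L + 300L,
                      strand = "+", locus_id = ids,
                      label = NA_character_, stringsAsFactors = FALSE)
  genome_of <- setNames(rep("g1", length(ids)), ids)
  seqs <- setNames(c(rep3, rep("MKQWACDEFGHIK", length(ids) - 1)), ids)
  fb <- list(g1 = feats)
  # CsgA/B candidate with 3 repeats, no accepted neighbors: repeat clause
  d1 <- curate_hits(make_hits("ab1", 50), "csgAB", genome_of, fb,
                    accepted_ids = character(), sequences = seqs, cutoff = 20)
  expect_equal(d1$decision, "accepted")
  expect_equal(d1$reason, "repeat clause")
  # CsgF candidate adjacent to an accepted homolog: neighborhood clause
  d2 <- curate_hits(make_hits("f1", 50), "csgF", genome_of, fb,
                    accepted_ids = "ab1", sequences = seqs, cutoff = 20)
  expect_equal(d2$decision, "accepted")
  expect_equal(d2$reason, "neighborhood clause")
  # isolated low-repeat candidate: rejected
  d3 <- curate_hits(make_hits("lone", 50), "csgF", genome_of, fb,
                    accepted_ids = "ab1", sequences = seqs, cutoff = 20)
  expect_equal(d3$decision, "rejected")
  # below cutoff: rejected regardless of neighborhood
  d4 <- curate_hits(make_hits("f1", 10), "csgF", genome_of, fb,
                    accepted_ids = "ab1", sequences = seqs, cutoff = 20)
  expect_equal(d4$decision, "rejected")
  expect_equal(d4$reason, "below cutoff")
  # unannotated genome: held as unplaceable, not dropped
  d5 <- curate_hits(make_hits("f1", 50), "csgF",
                    setNames("gX", "f1"), fb, accepted_ids = "ab1",
                    sequences = seqs, cutoff = 20)
  expect_equal(d5$decision, "unplaceable")
})

test_that("a proteome equal to the seeds converges in one iteration", {
  curliscan:::with_seed(90, {
    unit <- curliscan:::new_repeat_unit(rep(0.05, 20))
    seedprot <- vapply(1:4, function(i) {
      sample_repeat_protein(4, unit, unit, nterm = 0, cterm = 0)$sequence
    }, "")
  })
  seeds <- list(csgAB = as_msa(setNames(seedprot, paste0("s", 1:4))))
  proteome <- data.frame(id = paste0("p", 1:4), description = "",
                         sequence = seedprot, stringsAsFactors = FALSE)
  feats <- data.frame(contig = "c1", start = (0:3) * 400L,
                      end = (0:3) * 400L + 300L, strand = "+",
                      locus_id = paste0("p", 1:4), label = NA_character_,
                      stringsAsFactors = FALSE)
  res <- iterate_search(seeds, list(g1 = proteome), list(g1 = feats),
                        params = curation_params(n_calibration_decoys = 100,
                                                 cutoff_fpr = 0.01),
                        seed = 7)
  expect_equal(res$n_iterations, 1L)
  expect_true(res$converged)
  expect_setequal(res$homologs$target_id, proteome$id)
})

test_that("an empty proteome yields an empty homolog set in one iteration", {
  seeds <- list(csgAB = as_msa(c(s1 = "NQGWNQGW", s2 = "NQGWNQGW")))
  res <- iterate_search(seeds, list(), list())
  expect_equal(nrow(res$homologs), 0L)
  expect_equal(res$n_iterations, 1L)
  expect_true(res$converged)
})

test_that("iteration is deterministic and the homolog set never shrinks", {
  curliscan:::with_seed(91, {
    unit <- curliscan:::new_repeat_unit(rep(0.05, 20))
    seedprot <- vapply(1:4, function(i) {
      sample_repeat_protein(4, unit, unit, nterm = 0, cterm = 0)$sequence
    }, "")
    target <- sample_repeat_protein(6, unit, unit)$sequence
    decoy <- sample_decoy(150)
  })
  seeds <- list(csgAB = as_msa(setNames(seedprot, paste0("s", 1:4))))
  proteome <- data.frame(id = c("hit", "junk"), description = "",
                         sequence = c(target, decoy), stringsAsFactors = FALSE)
  feats <- data.frame(contig = "c1", start = c(0L, 5000L),
                      end = c(300L, 5300L), strand = "+",
                      locus_id = c("hit", "junk"), label = NA_character_,
                      stringsAsFactors = FALSE)
  p <- curation_params(n_calibration_decoys = 100, cutoff_fpr = 0.01)
  r1 <- iterate_search(seeds, list(g = proteome), list(g = feats), p, seed = 3)
  r2 <- iterate_search(seeds, list(g = proteome), list(g = feats), p, seed = 3)
  expect_identical(r1$homologs, r2$homologs)
  expect_true("hit" %in% r1$homologs$target_id)
  expect_false("junk" %in% r1$homologs$target_id)
})
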