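test_that("match emissions follow the pseudocount estimator", {
  # column {Q,Q,N,N}, uniform background, weight 1: P(Q) = (2 + 0.05)/5
  msa <- as_msa(c(a = "Q", b = "Q", c = "N", d = "N"))
  hmm <- build_profile(msa)
  expect_equal(hmm$n_match, 1L)
  expect_equal(unname(hmm$match_emissions[1, "Q"]), 2.05 / 5)
  expect_equal(unname(hmm$match_emissions[1, "N"]), 2.05 / 5)
  expect_equal(unname(hmm$match_emissions[1, "A"]), 0.05 / 5)
})

test_that("vanishing pseudocounts converge to the observed residue", {
  hmm <- build_profile(as_msa(c(a = "NQ")), pseudocount_weight = 1e-9)
  expect_equal(unname(hmm$match_emissions[1, "N"]), 1, tolerance = 1e-8)
  expect_equal(unname(hmm$match_emissions[2, "Q"]), 1, tolerance = 1e-8)
})

test_that("mostly-gapped columns become inserts, all-gap alignments error", {
  msa <- as_msa(c(a = "N-Q", b = "N-Q", c = "NAQ", d = "N-Q"))
  hmm <- build_profile(msa)   # middle column is 3/4 gaps -> insert
  expect_equal(hmm$n_match, 2L)
  expect_error(build_profile(as_msa(c(a = "--", b = "A-", c = "-A", d = "--"))),
               "no consensus columns")
})

test_that("profile building is invariant to row order", {
  set.seed(50)
  rows <- setNames(vapply(1:5, function(i) random_peptide(12), ""),
                   paste0("r", 1:5))
  h1 <- build_profile(as_msa(rows))
  h2 <- build_profile(as_msa(rev(rows)))
  expect_equal(h1$match_emissions, h2$match_emissions)
  expect_equal(h1$trans, h2$trans)
})

test_that("a single-state model scores its residue at the background odds", {
  emis <- matrix(1e-12, 1, 20); emis[1, which(curliscan:::AA20 == "Q")] <- 1
  emis <- emis / sum(emis)
  hmm <- profile_hmm("q", emis, rep(0.05, 20), rep(0.05, 20),
                     list(tMM = numeric(0), tMI = numeric(0), tMD = numeric(0),
                          tIM = numeric(0), tII = numeric(0),
                          tDM = numeric(0), tDD = numeric(0)))
  v <- viterbi(hmm, "Q")
  expect_equal(v$bit_score, log2(1 / 0.05), tolerance = 1e-6)
  expect_equal(v$path, "M")
})

test_that("two equally scoring paths add one bit to the forward score", {
  emis <- matrix(1e-12, 1, 20); emis[1, which(curliscan:::AA20 == "Q")] <- 1
  emis <- emis / sum(emis)
  hmm <- profile_hmm("q", emis, rep(0.05, 20), rep(0.05, 20),
                     list(tMM = numeric(0), tMI = numeric(0), tMD = numeric(0),
                          tIM = numeric(0), tII = numeric(0),
                          tDM = numeric(0), tDD = numeric(0)))
  # "QQ": the model can sit on either residue, two paths of equal score
  v <- viterbi(hmm, "QQ")$bit_score
  f <- forward(hmm, "QQ")
  expect_equal(f, v + 1, tolerance = 1e-6)
})

test_that("viterbi and forward match brute-force path enumeration", {
  set.seed(51)
  for (i in 1:40) {
    hmm <- random_small_hmm(max_states = 3)
    seq <- random_peptide(sample(1:6, 1))
    scores <- brute_hmm_path_scores(hmm, seq)
    expect_equal(viterbi(hmm, seq)$bit_score, max(scores),
                 tolerance = 1e-9)
    m <- max(scores)
    expect_equal(forward(hmm, seq), m + log2(sum(2^(scores - m))),
                 tolerance = 1e-9)
  }
})

test_that("forward dominates viterbi on arbitrary inputs", {
  set.seed(52)
  for (i in 1:20) {
    hmm <- random_small_hmm(max_states = 3)
    seq <- random_peptide(sample(2:12, 1))
    expect_gte(forward(hmm, seq) + 1e-9, viterbi(hmm, seq)$bit_score)
  }
})

test_that("junk sequences score at or below zero bits", {
  msa <- as_msa(c(a = "WWWWWW", b = "WWWWWW", c = "WWWWWW"))
  hmm <- build_profile(msa)
  expect_lte(viterbi(hmm, "AAAAAAAA")$bit_score, 0)
})

test_that("search ranks the model consensus first and reports coordinates", {
  set.seed(53)
  cons <- random_peptide(30)
  msa <- as_msa(setNames(rep(cons, 3), paste0("r", 1:3)))
  hmm <- build_profile(msa)
  proteome <- data.frame(
    id = c("self", "d1", "d2"),
    description = "",
    sequence = c(paste0(random_peptide(8), cons, random_peptide(5)),
                 random_peptide(40), random_peptide(40)))
  hits <- search_hmm(hmm, proteome, cutoff_bits = 10)
  expect_equal(hits$target_id[1], "self")
  expect_equal(hits$start[1], 8)
  expect_equal(hits$end[1], 38)
  expect_equal(hits$evalue_surrogate,
               nrow(proteome) * 2^(-hits$bit_score))
})

test_that("empty proteomes search to an empty hit table", {
  hmm <- build_profile(as_msa(c(a = "NQGW", b = "NQGW")))
  hits <- search_hmm(hmm, data.frame(id = character(), description = character(),
                                     sequence = character()),
                     cutoff_bits = 0)
  expect_equal(nrow(hits), 0L)
})

test_that("calibration returns the upper empirical quantile of decoy scores", {
  set.seed(54)
  hmm <- build_profile(as_msa(setNames(rep(random_peptide(25), 3),
                                       paste0("r", 1:3))))
  decoys <- data.frame(id = paste0("d", 1:200), description = "",
                       sequence = vapply(1:200, function(i) random_peptide(80), ""))
  scores <- sort(vapply(decoys$sequence,
                        function(s) viterbi(hmm, s)$bit_score, 0))
  expect_equal(calibrate(hmm, decoys, fpr = 0), max(scores))
  cut01 <- calibrate(hmm, decoys, fpr = 0.01)
  expect_equal(cut01, unname(scores[floor(200 * 0.99) + 1]))
  expect_lte(mean(scores >= cut01), 0.01 + 1 / 200)
  # identical decoys: cutoff equals the common score
  same <- decoys; same$sequence <- rep(decoys$sequence[1], 200)
  expect_equal(calibrate(hmm, same, fpr = 0.05),
               viterbi(hmm, decoys$sequence[1])$bit_score)
  expect_error(calibrate(hmm, decoys[1:50, ], 0.01), ">= 100 decoys")
})
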