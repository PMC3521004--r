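feat <- function(start, end, strand, id, label = NA_character_,
                 contig = "c1") {
  data.frame(contig = contig, start = start, end = end, strand = strand,
             locus_id = id, label = label, stringsAsFactors = FALSE)
}

test_that("operon calling follows the intergenic gap and strand rules", {
  two_close <- rbind(feat(0, 300, "+", "a"), feat(350, 600, "+", "b"))
  expect_length(call_operons(two_close, max_gap = 200), 1L)
  two_far <- rbind(feat(0, 300, "+", "a"), feat(800, 1100, "+", "b"))
  expect_length(call_operons(two_far, max_gap = 200), 2L)
  opposite <- rbind(feat(0, 300, "+", "a"), feat(320, 600, "-", "b"))
  expect_length(call_operons(opposite, max_gap = 200), 2L)
})

test_that("operon calling partitions the gene set", {
  set.seed(70)
  n <- 30
  starts <- cumsum(sample(50:800, n))
  feats <- do.call(rbind, lapply(seq_len(n), function(i) {
    feat(starts[i], starts[i] + 40, sample(c("+", "-"), 1),
         paste0("g", i))
  }))
  ops <- call_operons(feats)
  expect_setequal(unlist(lapply(ops, `[[`, "locus_id")), feats$locus_id)
  expect_equal(sum(vapply(ops, nrow, 0L)), n)
})

# canonical layouts (coordinates in genome order; minus-strand operons have
# their transcription start at the right edge)
divergent <- rbind(
  feat(0, 300, "-", "g1", "csgG"), feat(350, 650, "-", "g2", "csgF"),
  feat(700, 1000, "-", "g3", "csgE"), feat(1050, 1350, "-", "g4", "csgD"),
  feat(1650, 1950, "+", "g5", "csgB"), feat(2000, 2300, "+", "g6", "csgA"),
  feat(2350, 2650, "+", "g7", "csgC"))

test_that("the E. coli-like divergent two-operon layout is recognised", {
  cls <- classify_architecture(call_operons(divergent))
  expect_equal(cls$class, "divergent_two_operon")
  expect_equal(cls$csgD_location, "in_operon")
})

test_that("the same blocks co-oriented classify as co_oriented_two_operon", {
  co <- divergent
  co$strand <- "+"
  co$label <- c("csgD", "csgE", "csgF", "csgG", "csgB", "csgA", "csgC")
  cls <- classify_architecture(call_operons(co))
  expect_equal(cls$class, "co_oriented_two_operon")
})

test_that("csgD divergent from a single csgBAEFG operon is recognised", {
  single <- rbind(
    feat(0, 300, "-", "g1", "csgD"),
    feat(600, 900, "+", "g2", "csgB"), feat(950, 1250, "+", "g3", "csgA"),
    feat(1300, 1600, "+", "g4", "csgE"), feat(1650, 1950, "+", "g5", "csgF"),
    feat(2000, 2300, "+", "g6", "csgG"))
  cls <- classify_architecture(call_operons(single))
  expect_equal(cls$class, "single_operon_csgD_divergent")
  expect_equal(cls$csgD_location, "detached")
})

test_that("classification is invariant to translation and strand flip", {
  base <- classify_architecture(call_operons(divergent))$class
  shifted <- divergent
  shifted$start <- shifted$start + 10000L
  shifted$end <- shifted$end + 10000L
  expect_equal(classify_architecture(call_operons(shifted))$class, base)
  L <- 5000L
  flipped <- divergent
  flipped$start <- L - divergent$end
  flipped$end <- L - divergent$start
  flipped$strand <- ifelse(divergent$strand == "+", "-", "+")
  expect_equal(classify_architecture(call_operons(flipped))$class, base)
})

test_that("genomes without csg labels cannot be classified", {
  plain <- rbind(feat(0, 300, "+", "a"), feat(350, 600, "+", "b"))
  expect_error(classify_architecture(call_operons(plain)), "no csg")
})

test_that("content profiles report presence flags and paralog counts", {
  alpha <- content_profile(c("csgA/B", "csgA/B", "csgF", "csgG", "csgH"),
                           taxon = "alpha")
  expect_false(alpha$csgC); expect_false(alpha$csgD); expect_false(alpha$csgE)
  expect_true(alpha$csgH)
  expect_equal(alpha$n_csgAB_paralogs, 2L)
  six <- content_profile(rep("csgA/B", 6))
  expect_equal(six$n_csgAB_paralogs, 6L)
  none <- content_profile(character())
  expect_false(any(unlist(none[, c("csgAB", "csgC", "csgD", "csgE",
                                   "csgF", "csgG", "csgH")])))
})

test_that("csgH adjacency uses the gene-order window", {
  near <- rbind(feat(0, 300, "+", "h", "csgH"),
                feat(350, 650, "+", "ab", "csgA/B"))
  expect_true(csgH_adjacency(near))
  genes <- do.call(rbind, lapply(0:10, function(i) {
    feat(i * 400, i * 400 + 300, "+", paste0("g", i))
  }))
  genes$label[1] <- "csgH"; genes$label[11] <- "csgA/B"
  expect_false(csgH_adjacency(genes, window = 3))
  expect_true(is.na(csgH_adjacency(near[near$label != "csgH", ])))
})

test_that("CsgA/CsgB roles resolve only inside the Gammaproteobacteria", {
  op <- call_operons(rbind(feat(0, 300, "+", "b"), feat(350, 650, "+", "a"),
                           feat(700, 1000, "+", "c")))[[1]]
  roles <- assign_csgAB_roles(op, c("b", "a"), "Gammaproteobacteria")
  expect_equal(roles$role[roles$locus_id == "b"], "csgB")
  expect_equal(roles$role[roles$locus_id == "a"], "csgA")
  # minus strand: transcription order reverses
  opm <- call_operons(rbind(feat(0, 300, "-", "x"), feat(350, 650, "-", "y")))[[1]]
  rm <- assign_csgAB_roles(opm, c("x", "y"), "Gammaproteobacteria")
  expect_equal(rm$role[rm$locus_id == "y"], "csgB")
  other <- assign_csgAB_roles(op, c("b", "a"), "Bacteroidetes")
  expect_true(all(other$role == "csgA/B"))
  single <- assign_csgAB_roles(op, "b", "Gammaproteobacteria")
  expect_equal(single$role, "csgA/B")
  expect_true(single$low_confidence)
})
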