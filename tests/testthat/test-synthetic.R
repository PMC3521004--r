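test_that("benchmarks are a pure function of the seed", {
  b1 <- synth_benchmark(seed = 5)
  b2 <- synth_benchmark(seed = 5)
  expect_identical(b1$truth_proteins, b2$truth_proteins)
  expect_identical(lapply(b1$genomes, `[[`, "proteome"),
                   lapply(b2$genomes, `[[`, "proteome"))
  b3 <- synth_benchmark(seed = 6)
  expect_false(identical(b1$truth_proteins$locus_id,
                         b3$truth_proteins$locus_id) &&
               identical(b1$genomes[[1]]$proteome$sequence,
                         b3$genomes[[1]]$proteome$sequence))
})

test_that("the generator does not disturb the caller's RNG state", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(synth_benchmark(seed = 9)); after <- runif(1)
  expect_identical(before, after)
})

test_that("ten genomes cover the five architecture classes twice", {
  b <- synth_benchmark(seed = 2)
  expect_equal(length(b$genomes), 10L)
  expect_equal(as.vector(table(b$truth_genomes$class)), rep(2L, 5))
  expect_equal(length(unique(b$truth_genomes$genus)), 5L)
})

test_that("planted repeat starts are always recovered by the scanner", {
  b <- synth_benchmark(seed = 3)
  ab <- b$truth_proteins[b$truth_proteins$family == "csgAB", ]
  for (i in seq_len(nrow(ab))) {
    g <- ab$genome[i]
    seq <- b$genomes[[g]]$proteome$sequence[
      b$genomes[[g]]$proteome$id == ab$locus_id[i]]
    planted <- as.integer(strsplit(ab$repeat_starts[i], ",")[[1]])
    found <- scan_repeats(seq)$start
    expect_true(all(planted %in% found), info = ab$locus_id[i])
  }
})

test_that("repeat proteins respect the requested unit count", {
  curliscan:::with_seed(11, {
    unit <- curliscan:::new_repeat_unit(rep(0.05, 20))
    p1 <- sample_repeat_protein(1, unit, unit)
    expect_length(p1$starts, 1L)
    expect_false(architecture(list(id = "x", sequence = p1$sequence))$functional)
    p22 <- sample_repeat_protein(22, unit, unit)
    expect_length(p22$starts, 22L)
    expect_gte(architecture(list(id = "x",
                                 sequence = p22$sequence))$n_repeats, 22L)
  })
})

test_that("decoys are guaranteed motif-free and reproducible", {
  curliscan:::with_seed(12, {
    for (i in 1:20) {
      d <- sample_decoy(220)
      expect_equal(nrow(scan_repeats(d)), 0L)
    }
  })
  d1 <- curliscan:::with_seed(13, sample_decoy(150))
  d2 <- curliscan:::with_seed(13, sample_decoy(150))
  expect_identical(d1, d2)
})

test_that("truth tables are consistent with the emitted genomes", {
  b <- synth_benchmark(seed = 4)
  all_ids <- unlist(lapply(b$genomes, function(g) g$proteome$id))
  expect_false(anyDuplicated(all_ids) > 0)
  expect_setequal(b$truth_proteins$locus_id, all_ids)
  for (g in names(b$genomes)) {
    expect_setequal(b$genomes[[g]]$features$locus_id,
                    b$genomes[[g]]$proteome$id)
  }
})

test_that("written benchmarks re-parse through the io module cleanly", {
  dir <- withr::local_tempdir()
  b <- synth_benchmark(seed = 8, dir = dir)
  expect_no_warning({
    for (g in names(b$genomes)) {
      p <- read_fasta(file.path(dir, paste0(g, ".faa")))
      f <- read_features_tsv(file.path(dir, paste0(g, ".features.tsv")))
      expect_equal(p$sequence, b$genomes[[g]]$proteome$sequence)
      expect_equal(f, b$genomes[[g]]$features)
    }
    seeds <- read_msa(file.path(dir, "seeds", "csgAB.aln.fasta"))
  })
  expect_length(seeds, 4L)
})

test_that("planted operon layouts classify to their architecture class", {
  b <- synth_benchmark(seed = 7)
  for (gid in names(b$genomes)) {
    f <- b$genomes[[gid]]$features
    tp <- b$truth_proteins[b$truth_proteins$genome == gid, ]
    f$label <- tp$label[match(f$locus_id, tp$locus_id)]
    cls <- classify_architecture(call_operons(f))
    expect_equal(cls$class,
                 b$truth_genomes$class[b$truth_genomes$genome == gid],
                 info = gid)
  }
})

test_that("alpha-like genomes reproduce their planted content profile", {
  b <- synth_benchmark(seed = 2)
  g_alpha <- b$truth_genomes$genome[b$truth_genomes$class == "single_operon"][1]
  tp <- b$truth_proteins[b$truth_proteins$genome == g_alpha, ]
  f <- b$genomes[[g_alpha]]$features
  f$label <- tp$label[match(f$locus_id, tp$locus_id)]
  prof <- content_profile(f$label)
  expect_true(prof$csgAB && prof$csgF && prof$csgG && prof$csgH)
  expect_false(prof$csgC || prof$csgD || prof$csgE)
  expect_true(csgH_adjacency(f))
})
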