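#' Simulation parameters for synthetic curli genomes
#'
#' The generator emulates the statistical structure curli annotation relies
#' on, with a three-level divergence hierarchy: a family-wide consensus per
#' csg family, genus-level variants of it, and strain-level copies.  Repeat
#' proteins are built from 22-residue units with literal Q/G/N anchors;
#' non-anchor positions of a genus's unit consensus keep the family
#' consensus residue with probability `flank_conservation`, and every
#' repeat protein carries a fixed fraction of units (at least two) drawn
#' near the family-wide consensus so that a model trained on seed repeat
#' regions is guaranteed a conserved anchor block.
#'
#' @param seed Integer seed; every simulation is reproducible from it.
#' @param n_genomes Number of genomes (two per architecture class by
#'   default).
#' @param n_decoys Decoy proteins interspersed per genome.
#' @param decoy_length Length range of decoy proteins.
#' @param repeats_range Allowed repeats-per-protein range; genus repeat
#'   counts are spread across it (6, 10, 14, 18, 22 by default), mirroring
#'   the observed span from short enterobacterial subunits to 22-repeat
#'   homologs.
#' @param flank_conservation Identity of genus unit-consensus flanks to the
#'   family-wide repeat consensus (anchors are always literal).
#' @param strain_conservation Per-position identity of strain-level copies
#'   to their genus consensus.
#' @param family_length Named lengths of the non-repeat csg family proteins
#'   (rough real-protein scale; the accessory families differ in size).
#' @param genus_divergence Per-position resampling rate between a family (or
#'   lineage) consensus and a genus-level variant of it.
#' @param mid_drift Resampling rate between the family consensus and the
#'   "mid" lineage consensus of the two-tier families (csgF/csgG): deep
#'   enough that mid-tier members sit near the edge of what the seed models
#'   detect, shallow enough that they are still found.
#' @param remote_fresh_drift Resampling rate applied, on top of the mid
#'   lineage, to the positions where the mid lineage still agrees with the
#'   family consensus.  The remote lineage therefore shares all of the mid
#'   lineage's drift (so models that have absorbed mid-tier members score it
#'   well) while being too far from the family consensus for the seed
#'   models -- the structure that forces multi-round convergence.
#' @param tier_noise Genus- and strain-level resampling rate used for the
#'   two-tier families in the mid/remote genera (low: these lineages are
#'   tight clades, which is what makes the tier structure crisp).
#' @param background Background amino-acid distribution (uniform by
#'   default); the decoy null is defined by it.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(seed = 1, n_genomes = 10, n_decoys = 12,
                       decoy_length = c(80, 300),
                       repeats_range = c(2, 22),
                       flank_conservation = 0.3,
                       strain_conservation = 0.9,
                       family_length = c(csgC = 110, csgD = 200, csgE = 130,
                                         csgF = 240, csgG = 260, csgH = 150),
                       genus_divergence = 0.12,
                       mid_drift = 0.53,
                       remote_fresh_drift = 0.5,
                       tier_noise = 0.04,
                       background = rep(0.05, 20)) {
  stopifnot(n_genomes > 0, n_decoys >= 0,
            flank_conservation >= 0, flank_conservation <= 1,
            strain_conservation >= 0, strain_conservation <= 1,
            abs(sum(background) - 1) < 1e-9)
  structure(list(seed = seed, n_genomes = n_genomes, n_decoys = n_decoys,
                 decoy_length = decoy_length, repeats_range = repeats_range,
                 flank_conservation = flank_conservation,
                 strain_conservation = strain_conservation,
                 family_length = family_length,
                 genus_divergence = genus_divergence,
                 mid_drift = mid_drift,
                 remote_fresh_drift = remote_fresh_drift,
                 tier_noise = tier_noise,
                 background = background),
            class = "sim_params")
}

random_aa <- function(n, background = rep(0.05, 20)) {
  paste(sample(AA20, n, replace = TRUE, prob = background), collapse = "")
}

# Resample each position with probability `rate` (uniform replacement, so the
# realised substitution rate is rate * 19/20); positions in `keep` are fixed.
mutate_seq <- function(seq, rate, keep = integer(), alphabet = AA20) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  hit[keep] <- FALSE
  chars[hit] <- sample(alphabet, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

# Anchor positions of the 22-mer unit, 1-based: Q at 7, G at 9, N at 12.
UNIT_ANCHORS <- c(7L, 9L, 12L)

new_repeat_unit <- function(background) {
  u <- strsplit(random_aa(22, background), "", fixed = TRUE)[[1]]
  u[UNIT_ANCHORS] <- c("Q", "G", "N")
  paste(u, collapse = "")
}

# genus variant of a repeat unit: flanks keep the family residue with
# probability `cons`, anchors stay literal
genus_repeat_unit <- function(family_unit, cons) {
  mutate_seq(family_unit, rate = 1 - cons, keep = UNIT_ANCHORS)
}

#' Sample a synthetic curli repeat protein
#'
#' Concatenates `k` 22-residue repeat units end-to-end between random N- and
#' C-terminal segments.  About a third of the units (never fewer than two)
#' are "core" units drawn near the family-wide unit consensus -- so
#' seed-trained models always have a conserved target, and the conserved
#' fraction is comparable across proteins of different repeat counts -- and
#' the rest are drawn near the genus unit consensus; all units keep the
#' literal Q/G/N anchors.  Planted window starts are returned alongside the
#' sequence.
#'
#' @param k Number of repeat units (>= 1).
#' @param genus_unit Genus-level 22-mer unit consensus.
#' @param family_unit Family-wide 22-mer unit consensus.
#' @param params [sim_params()].
#' @param nterm,cterm Lengths of the random terminal segments.
#' @return List with `sequence` and `starts` (0-based planted window
#'   starts).
#' @export
sample_repeat_protein <- function(k, genus_unit, family_unit,
                                  params = sim_params(),
                                  nterm = 20, cterm = 10) {
  stopifnot(k >= 1)
  mut <- 1 - params$strain_conservation
  core <- seq_len(min(k, max(2L, ceiling(k / 3))))
  units <- vapply(seq_len(k), function(i) {
    base <- if (i %in% core) family_unit else genus_unit
    mutate_seq(base, rate = mut, keep = UNIT_ANCHORS)
  }, "")
  seq <- paste0(random_aa(nterm, params$background),
                paste(units, collapse = ""),
                random_aa(cterm, params$background))
  list(sequence = seq, starts = nterm + (seq_len(k) - 1L) * 22L)
}

#' Sample a motif-free decoy protein
#'
#' I.i.d. background sequence, rejection-sampled until [scan_repeats()]
#' reports zero matches, so decoys are guaranteed negatives for the motif
#' scanner.
#'
#' @param len Decoy length.
#' @param params [sim_params()].
#' @param max_tries Rejection cap; exceeding it signals absurd parameters.
#' @return The decoy sequence string.
#' @export
sample_decoy <- function(len, params = sim_params(), max_tries = 1000) {
  for (i in seq_len(max_tries)) {
    s <- random_aa(len, params$background)
    if (nrow(scan_repeats(s)) == 0) return(s)
  }
  stop("could not sample a motif-free decoy in ", max_tries, " tries")
}

# operon layouts per architecture class: blocks of (strand, labels in
# transcription order, intergenic gap before the block)
class_layout <- function(class) {
  switch(class,
    divergent_two_operon = list(
      list(strand = "-", labels = c("csgD", "csgE", "csgF", "csgG"), gap = 0),
      list(strand = "+", labels = c("csgB", "csgA", "csgC"), gap = 300)),
    co_oriented_two_operon = list(
      list(strand = "+", labels = c("csgD", "csgE", "csgF", "csgG"), gap = 0),
      list(strand = "+", labels = c("csgB", "csgA", "csgC"), gap = 400)),
    divergent_csgD_detached = list(
      list(strand = "-", labels = "csgD", gap = 0),
      list(strand = "+", labels = c("csgE", "csgF", "csgG"), gap = 300),
      list(strand = "+", labels = c("csgB", "csgA"), gap = 2500)),
    single_operon_csgD_divergent = list(
      list(strand = "-", labels = "csgD", gap = 0),
      list(strand = "+", labels = c("csgB", "csgA", "csgE", "csgF", "csgG"),
           gap = 300)),
    single_operon = list(
      list(strand = "+", labels = c("csgH", "csgA/B", "csgA/B",
                                    "csgF", "csgG"), gap = 0)),
    stop("unknown architecture class: ", class)
  )
}

ARCH_CLASSES <- c("divergent_two_operon", "co_oriented_two_operon",
                  "divergent_csgD_detached", "single_operon_csgD_divergent",
                  "single_operon")

#' Build one synthetic genome
#'
#' Places the csg gene cluster of the requested architecture class on a
#' single contig, interspersed with decoy genes, and emits the matching
#' proteome and truth rows.  Gene coordinates are 0-based half-open with
#' gene length `3 * protein length`; minus-strand operons are laid out so
#' that their transcription order runs right to left.  Draws from the
#' ambient RNG stream (callers seed it; [synth_benchmark()] does).
#'
#' @param genome_id Genome identifier (also the contig name prefix).
#' @param genus Genus label recorded in the truth table.
#' @param class Architecture class (one of the five canonical layouts).
#' @param k Repeat units per csgA/B protein in this genus.
#' @param family_material List with per-family genus-level consensus
#'   sequences (`genus_fam`), the genus repeat unit (`genus_unit`) and the
#'   family-wide repeat unit (`family_unit`).
#' @param params [sim_params()].
#' @return List with `proteome` (record data frame), `features` (unlabelled
#'   feature table), `truth_proteins`, `truth_genome`.
#' @export
build_genome <- function(genome_id, genus, class, k, family_material,
                         params = sim_params()) {
  layout <- class_layout(class)
  contig <- paste0(contig_name(genome_id))
  cursor <- 500L
  feats <- list(); prots <- list(); truth <- list()
  gi <- 0L; ab_seen <- 0L
  add_gene <- function(label, strand, seq, starts = integer()) {
    gi <<- gi + 1L
    id <- sprintf("%s_g%03d", genome_id, gi)
    glen <- 3L * nchar(seq)
    feats[[gi]] <<- data.frame(contig = contig, start = cursor,
                               end = cursor + glen, strand = strand,
                               locus_id = id, label = NA_character_,
                               stringsAsFactors = FALSE)
    prots[[gi]] <<- data.frame(id = id, description = "",
                               sequence = seq, stringsAsFactors = FALSE)
    truth[[gi]] <<- data.frame(genome = genome_id, genus = genus,
                               locus_id = id,
                               family = if (is.na(label)) "decoy" else norm_family(label),
                               label = label,
                               repeat_starts = paste(starts, collapse = ","),
                               stringsAsFactors = FALSE)
    cursor <<- cursor + glen
  }
  for (block in layout) {
    cursor <- cursor + as.integer(block$gap)
    labels <- block$labels
    genome_order <- if (block$strand == "-") rev(labels) else labels
    first <- TRUE
    for (lab in genome_order) {
      if (!first) cursor <- cursor + 50L
      first <- FALSE
      if (is_ab_label(lab)) {
        units <- family_material$genus_unit
        if (!is.list(units)) units <- list(units)
        ab_seen <- ab_seen + 1L            # paralogs cycle over unit lineages
        unit <- units[[(ab_seen - 1L) %% length(units) + 1L]]
        rp <- sample_repeat_protein(k, unit,
                                    family_material$family_unit, params)
        add_gene(lab, block$strand, rp$sequence, rp$starts)
      } else {
        fam_cons <- family_material$genus_fam[[lab]]
        rate <- family_material$strain_rate[[lab]] %||%
          (1 - params$strain_conservation)
        add_gene(lab, block$strand, mutate_seq(fam_cons, rate))
      }
    }
  }
  for (d in seq_len(params$n_decoys)) {
    cursor <- cursor + 1500L
    len <- sample(params$decoy_length[1]:params$decoy_length[2], 1)
    add_gene(NA_character_, if (d %% 2 == 0) "-" else "+",
             sample_decoy(len, params))
  }
  features <- do.call(rbind, feats)
  list(proteome = do.call(rbind, prots),
       features = features,
       truth_proteins = do.call(rbind, truth),
       truth_genome = data.frame(genome = genome_id, genus = genus,
                                 class = class, k = k,
                                 stringsAsFactors = FALSE))
}

contig_name <- function(genome_id) paste0(genome_id, "_ctg1")

# csgA, csgB and csgA/B all belong to the combined subunit family
norm_family <- function(label) ifelse(is_ab_label(label), "csgAB", label)

SEARCH_FAMILIES <- c("csgAB", "csgC", "csgD", "csgE", "csgF", "csgG", "csgH")

#' Generate the full synthetic benchmark
#'
#' Ten genomes (two per architecture class, one genus per class) with
#' planted csg clusters, decoys, seed alignments per family, 16S-like
#' marker sequences and complete truth tables.  Two features exercise the
#' harder parts of the method: the genomes of the co-oriented class carry
#' "remote"-tier csgF and csgG homologs drawn around a drifted lineage
#' consensus, so they are only reachable after the search models have been
#' broadened with the near-tier homologs (multi-round convergence); and the
#' second genome of the single-operon genus draws its repeat units from a
#' separate lineage, planting a genus that splits into two clusters in the
#' Csg tree while staying coherent in the 16S tree.
#'
#' @param seed Integer seed; the run is a pure function of it.
#' @param params [sim_params()]; its `seed` is overridden by `seed`.
#' @param dir Optional directory: when given, per-genome `.faa` and
#'   `.features.tsv`, seed alignments, 16S FASTA and truth tables are
#'   written there.
#' @return List with `genomes` (per-genome list of `proteome`/`features`),
#'   `seeds` (per-family seed alignments, named character vectors),
#'   `truth_proteins`, `truth_genomes`, `ssu` (named 16S sequences),
#'   `split_genus`, `remote_genomes`, `params`.
#' @export
synth_benchmark <- function(seed = 1, params = sim_params(seed = seed),
                            dir = NULL) {
  params$seed <- seed
  with_seed(seed, {
    n_classes <- length(ARCH_CLASSES)
    genus_k <- c(6L, 10L, 14L, 18L, 22L)
    genus_k <- pmin(pmax(genus_k, params$repeats_range[1]),
                    params$repeats_range[2])
    genera <- paste0("Genus", seq_len(n_classes))
    # family-wide consensus material
    fam_names <- c("csgC", "csgD", "csgE", "csgF", "csgG", "csgH")
    fam_cons <- setNames(lapply(fam_names, function(f)
      random_aa(params$family_length[[f]], params$background)), fam_names)
    family_unit <- new_repeat_unit(params$background)
    # divergence ladder for the two-tier families: the mid lineage drifts
    # from the family consensus but stays detectable from seed models; the
    # remote lineage keeps all of the mid drift and resamples only positions
    # where mid still agrees with the family, so it is invisible to seed
    # models but well covered once the mid-tier homologs are in the model
    tier_fams <- c("csgF", "csgG")
    mid_cons <- setNames(lapply(tier_fams, function(f)
      mutate_seq(fam_cons[[f]], params$mid_drift)), tier_fams)
    remote_cons <- setNames(lapply(tier_fams, function(f) {
      fam <- strsplit(fam_cons[[f]], "")[[1]]
      mid <- strsplit(mid_cons[[f]], "")[[1]]
      keep_drift <- which(mid != fam)        # shared drift stays
      mutate_seq(mid_cons[[f]], params$remote_fresh_drift, keep = keep_drift)
    }), tier_fams)
    # seed alignments: 4 near-consensus members per family (equal length,
    # gap-free, so the rows are already aligned)
    seeds <- list()
    for (f in fam_names) {
      rows <- vapply(1:4, function(i) mutate_seq(fam_cons[[f]], 0.03), "")
      seeds[[f]] <- as_msa(setNames(rows, paste0(f, "_seed", 1:4)))
    }
    seed_ab_rows <- vapply(1:4, function(i) {
      p <- sample_repeat_protein(4, family_unit, family_unit, params,
                                 nterm = 0, cterm = 0)
      p$sequence
    }, "")
    seeds[["csgAB"]] <- as_msa(setNames(seed_ab_rows, paste0("csgAB_seed", 1:4)))
    # per-genus material
    split_genus <- genera[n_classes]   # second genome uses lineage2 units
    # the divergence ladder needs both its rungs: only plant the remote
    # tier (co-oriented class) when the mid-tier genera are generated too
    use_tiers <- params$n_genomes >= 8
    remote_genus <- if (use_tiers) genera[2] else NA_character_
    mid_genera <- if (use_tiers) genera[3:4] else character()
    genus_material <- lapply(seq_len(n_classes), function(ci) {
      strain_rate <- setNames(rep(1 - params$strain_conservation,
                                  length(fam_names)), fam_names)
      gf <- lapply(fam_names, function(f) {
        base <- fam_cons[[f]]
        rate <- params$genus_divergence
        if (f %in% tier_fams &&
            genera[ci] %in% c(remote_genus, mid_genera)) {
          base <- if (genera[ci] == remote_genus) remote_cons[[f]]
                  else mid_cons[[f]]
          rate <- params$tier_noise
          strain_rate[f] <<- params$tier_noise
        }
        mutate_seq(base, rate)
      })
      list(genus_fam = setNames(gf, fam_names),
           strain_rate = strain_rate,
           genus_unit = genus_repeat_unit(family_unit,
                                          params$flank_conservation),
           family_unit = family_unit)
    })
    # the split-genus lineage: the second genome of the last genus draws
    # its subunit paralogs from an independent unit lineage, so they form
    # their own tight cluster elsewhere in the Csg tree, far from their
    # genus mates -- the genus splits into two distant clusters while its
    # 16S stays coherent
    lineage2_unit <- new_repeat_unit(params$background)
    split_material <- list(
      genus_fam = genus_material[[n_classes]]$genus_fam,
      strain_rate = genus_material[[n_classes]]$strain_rate,
      genus_unit = lineage2_unit,
      family_unit = family_unit)
    # genomes: two per class
    genomes <- list(); tp <- list(); tg <- list(); ssu <- character()
    ssu_base <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                      collapse = "")
    gidx <- 0L
    for (ci in seq_len(min(n_classes, params$n_genomes))) {
      genus_ssu <- mutate_seq(ssu_base, 0.2, alphabet = c("A", "C", "G", "T"))
      for (rep_i in 1:2) {
        gidx <- gidx + 1L
        if (gidx > params$n_genomes) break
        gid <- sprintf("g%02d", gidx)
        material <- if (genera[ci] == split_genus && rep_i == 2)
          split_material else genus_material[[ci]]
        gb <- build_genome(gid, genera[ci], ARCH_CLASSES[ci], genus_k[ci],
                           material, params)
        genomes[[gid]] <- gb[c("proteome", "features")]
        tp[[gid]] <- gb$truth_proteins
        tg[[gid]] <- gb$truth_genome
        ssu[gid] <- mutate_seq(genus_ssu, 0.03,
                               alphabet = c("A", "C", "G", "T"))
      }
    }
    out <- list(genomes = genomes,
                seeds = seeds,
                truth_proteins = do.call(rbind, tp),
                truth_genomes = do.call(rbind, tg),
                ssu = ssu,
                split_genus = split_genus,
                remote_genomes = if (is.na(remote_genus)) character() else
                  names(genomes)[do.call(rbind, tg)$genus == remote_genus],
                params = params)
    rownames(out$truth_proteins) <- NULL
    rownames(out$truth_genomes) <- NULL
    if (!is.null(dir)) write_benchmark(out, dir)
    out
  })
}

# write the benchmark to plain-text files re-parseable by the io module
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (gid in names(bench$genomes)) {
    write_fasta(bench$genomes[[gid]]$proteome,
                file.path(dir, paste0(gid, ".faa")))
    write_features_tsv(bench$genomes[[gid]]$features,
                       file.path(dir, paste0(gid, ".features.tsv")))
  }
  dir.create(file.path(dir, "seeds"), showWarnings = FALSE)
  for (f in names(bench$seeds)) {
    write_msa(bench$seeds[[f]], file.path(dir, "seeds", paste0(f, ".aln.fasta")))
  }
  write_fasta(data.frame(id = names(bench$ssu), description = "",
                         sequence = unname(bench$ssu)),
              file.path(dir, "ssu.fasta"))
  write.table(bench$truth_proteins, file.path(dir, "truth_proteins.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bench$truth_genomes, file.path(dir, "truth_genomes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
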