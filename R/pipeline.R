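#' Run the full curli annotation pipeline
#'
#' End-to-end orchestration: iterative profile-HMM search and curation
#' ([iterate_search()]), labelling of gene features from the accepted
#' homolog set, operon calling and architecture classification, gene-content
#' profiles and csgH adjacency, per-proteome repeat tables, Csg and 16S
#' neighbor-joining trees with Robinson-Foulds congruence and genus
#' monophyly, and (when a truth table is supplied) per-family validation
#' reports plus overall sensitivity/specificity.  All randomness (decoy
#' calibration) derives from `seed`; rerunning with the same inputs and seed
#' reproduces every output.
#'
#' @param proteomes Named list (by genome) of protein record data frames.
#' @param features Named list (by genome) of feature tables.
#' @param seeds Named list of per-family seed alignments (`csgAB` for the
#'   combined repeat family).
#' @param ssu Optional named character vector of pre-aligned (equal-length)
#'   16S sequences, one per genome.
#' @param genera Optional named character vector mapping genomes to genera
#'   (enables the genus-monophyly report).
#' @param truth Optional truth table with columns `locus_id` and `family`
#'   (`"decoy"` rows define the specificity denominator).
#' @param params [curation_params()].
#' @param seed Integer seed for calibration decoys.
#' @param max_gap Operon-calling intergenic gap (bp).
#' @param divergence_window Divergent-promoter window (bp).
#' @param out_dir Optional output directory for TSV/Newick/model artifacts.
#' @return List with `homologs`, `models`, `n_iterations`, `converged`,
#'   `architecture` (per-genome class calls), `content` (per-genome
#'   profiles), `repeats` (per-protein repeat table), `trees` (`csg`,
#'   `ssu`), `congruence` (RF distance and monophyly), `validation`
#'   (per-family reports), `summary` (sensitivity/specificity/counts),
#'   `decisions`.
#' @export
run_pipeline <- function(proteomes, features, seeds, ssu = NULL,
                         genera = NULL, truth = NULL,
                         params = curation_params(), seed = 1,
                         max_gap = 200, divergence_window = 1000,
                         out_dir = NULL) {
  res <- iterate_search(seeds, proteomes, features, params = params,
                        seed = seed)
  hom <- res$homologs
  # CsgA/B homologs without at least the minimum repeat count are assumed
  # non-functional subunits; they stay in the homolog table but do not label
  # genes for operon/content analysis
  functional_ab <- hom$family != "csgAB" |
    hom$n_repeats >= params$min_repeats_for_AB
  lab <- hom[functional_ab, , drop = FALSE]
  label_of <- setNames(ifelse(lab$family == "csgAB", "csgA/B", lab$family),
                       lab$target_id)
  # operon architecture and content per genome
  arch_rows <- list(); content_rows <- list()
  for (g in names(features)) {
    feats <- features[[g]]
    feats$label <- unname(label_of[feats$locus_id])
    ops <- call_operons(feats, max_gap = max_gap)
    cls <- tryCatch(
      classify_architecture(ops, divergence_window = divergence_window),
      error = function(e) list(class = NA_character_,
                               csgD_location = "absent"))
    arch_rows[[g]] <- data.frame(genome = g, class = cls$class,
                                 csgD_location = cls$csgD_location,
                                 stringsAsFactors = FALSE)
    prof <- content_profile(feats$label, taxon = g)
    prof$csgH_adjacent <- csgH_adjacency(feats)
    content_rows[[g]] <- prof
  }
  architecture <- do.call(rbind, arch_rows)
  content <- do.call(rbind, content_rows)
  rownames(architecture) <- rownames(content) <- NULL
  # repeat tables
  repeats <- do.call(rbind, lapply(names(proteomes), function(g) {
    tb <- repeat_table(proteomes[[g]])
    if (nrow(tb) > 0) tb$genome <- g
    tb
  }))
  # trees: one representative CsgA/B repeat region per genome
  trees <- list(csg = NULL, ssu = NULL)
  congruence <- list(rf = NA_real_, monophyly = NULL)
  ab <- hom[hom$family == "csgAB" & functional_ab, , drop = FALSE]
  if (nrow(ab) > 0) {
    regions <- setNames(vapply(seq_len(nrow(ab)), function(i) {
      s <- proteome_seq(proteomes, ab$genome[i], ab$target_id[i])
      paste(extract_repeat_regions(list(sequence = s), scan_repeats(s)),
            collapse = "")
    }, ""), ab$target_id)
    regions <- regions[nzchar(regions)]
    rep_params <- align_params(gap_open = 50, gap_extend = 1)
    if (length(regions) >= 3) {
      # subunit tree over every functional CsgA/B homolog; genus labels
      # come through each protein's genome
      aln <- progressive_msa(regions, rep_params)
      trees$csg <- nj_tree(p_distance(aln))
      if (!is.null(genera)) {
        prot_genus <- setNames(
          unname(genera[ab$genome[match(names(regions), ab$target_id)]]),
          names(regions))
        congruence$monophyly <- genus_monophyly(trees$csg, prot_genus)
      }
    }
    # one representative (longest repeat region) per genome for the
    # genome-level tree compared against the 16S tree
    reps <- character()
    for (g in unique(ab$genome)) {
      ids <- intersect(ab$target_id[ab$genome == g], names(regions))
      if (length(ids) == 0) next
      reps[g] <- regions[ids[which.max(nchar(regions[ids]))]]
    }
    if (length(reps) >= 3 && !is.null(ssu)) {
      common <- intersect(names(reps), names(ssu))
      if (length(common) >= 3) {
        genome_tree <- nj_tree(p_distance(
          progressive_msa(reps[common], rep_params)))
        trees$ssu <- nj_tree(p_distance(as_msa(ssu[common])))
        trees$csg_genome <- genome_tree
        congruence$rf <- robinson_foulds(genome_tree, trees$ssu)
      }
    }
  }
  # validation against truth
  validation <- list(); summary <- list()
  if (!is.null(truth)) {
    csg_truth <- truth[truth$family != "decoy", , drop = FALSE]
    decoy_ids <- truth$locus_id[truth$family == "decoy"]
    for (fam in sort(unique(csg_truth$family))) {
      validation[[fam]] <- validate(hom$target_id[hom$family == fam],
                                    csg_truth$locus_id[csg_truth$family == fam],
                                    model_name = fam)
    }
    accepted_ids <- hom$target_id
    sens <- length(intersect(accepted_ids, csg_truth$locus_id)) /
      nrow(csg_truth)
    spec <- 1 - length(intersect(accepted_ids, decoy_ids)) /
      max(length(decoy_ids), 1)
    summary <- list(sensitivity = sens, specificity = spec,
                    n_accepted = length(accepted_ids),
                    n_truth = nrow(csg_truth),
                    n_decoys = length(decoy_ids),
                    n_iterations = res$n_iterations,
                    converged = res$converged)
  }
  out <- list(homologs = hom, models = res$models,
              n_iterations = res$n_iterations, converged = res$converged,
              architecture = architecture, content = content,
              repeats = repeats, trees = trees, congruence = congruence,
              validation = validation, summary = summary,
              decisions = res$decisions)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

proteome_seq <- function(proteomes, genome, id) {
  df <- proteomes[[genome]]
  df$sequence[df$id == id][1]
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df) && nrow(df) > 0) {
      write.table(df, file.path(out_dir, name), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  wt(out$homologs, "homologs.tsv")
  wt(out$architecture, "architecture.tsv")
  wt(out$content, "content.tsv")
  wt(out$repeats, "repeats.tsv")
  wt(out$decisions, "run.log.tsv")
  if (length(out$validation) > 0) {
    lines <- c("Model\tHits\tCorrect hits\tMissing hits",
               vapply(out$validation, format, ""))
    writeLines(lines, file.path(out_dir, "validation.tsv"))
  }
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  for (fam in names(out$models)) {
    write_hmm(out$models[[fam]],
              file.path(out_dir, "models", paste0(fam, ".hmm")))
  }
  dir.create(file.path(out_dir, "trees"), showWarnings = FALSE)
  if (!is.null(out$trees$csg)) {
    write_newick(out$trees$csg, file.path(out_dir, "trees", "csg.nwk"))
  }
  if (!is.null(out$trees$ssu)) {
    write_newick(out$trees$ssu, file.path(out_dir, "trees", "ssu.nwk"))
  }
  invisible(out_dir)
}

#' Run the pipeline from a YAML configuration file
#'
#' The config holds input paths and parameter blocks:
#' \preformatted{
#' seed: 1
#' out_dir: results
#' proteomes: fixtures            # directory of <genome>.faa
#' features: fixtures             # <genome>.features.tsv or .gff
#' seeds: fixtures/seeds          # <family>.aln.fasta
#' ssu: fixtures/ssu.fasta        # optional
#' truth: fixtures/truth_proteins.tsv   # optional
#' curation:                      # optional overrides
#'   max_iterations: 10
#'   neighborhood_window: 5
#'   min_repeats_for_AB: 2
#'   cutoff_fpr: 0.001
#' operons:
#'   max_gap: 200
#'   divergence_window: 1000
#' }
#' Unknown keys are rejected before any computation.
#'
#' @param config_path Path to the YAML file.
#' @return The [run_pipeline()] result list, invisibly.
#' @export
run_pipeline_config <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  known <- c("seed", "out_dir", "proteomes", "features", "seeds", "ssu",
             "truth", "genera", "curation", "operons")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) stop("unknown config keys: ", paste(extra, collapse = ", "))
  need <- c("proteomes", "features", "seeds", "out_dir")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0) stop("missing config keys: ", paste(miss, collapse = ", "))
  faa <- list.files(cfg$proteomes, pattern = "\\.faa$", full.names = TRUE)
  if (length(faa) == 0) {
    message("no proteomes found: nothing to do")
    return(invisible(NULL))
  }
  genomes <- sub("\\.faa$", "", basename(faa))
  proteomes <- setNames(lapply(faa, read_fasta), genomes)
  features <- setNames(lapply(genomes, function(g) {
    tsv <- file.path(cfg$features, paste0(g, ".features.tsv"))
    gff <- file.path(cfg$features, paste0(g, ".gff"))
    if (file.exists(tsv)) read_features_tsv(tsv)
    else if (file.exists(gff)) read_gff(gff)
    else stop("no annotation for genome ", g)
  }), genomes)
  seed_files <- list.files(cfg$seeds, pattern = "\\.aln\\.fasta$",
                           full.names = TRUE)
  seeds <- setNames(lapply(seed_files, read_msa),
                    sub("\\.aln\\.fasta$", "", basename(seed_files)))
  ssu <- NULL
  if (!is.null(cfg$ssu) && file.exists(cfg$ssu)) {
    df <- read_fasta(cfg$ssu)
    ssu <- setNames(df$sequence, df$id)
  }
  truth <- NULL; genera <- NULL
  if (!is.null(cfg$truth) && file.exists(cfg$truth)) {
    truth <- read.delim(cfg$truth, stringsAsFactors = FALSE)
    if (all(c("genome", "genus") %in% names(truth))) {
      genera <- setNames(truth$genus, truth$genome)
      genera <- genera[!duplicated(names(genera))]
    }
  }
  cur <- do.call(curation_params, cfg$curation %||% list())
  op <- cfg$operons %||% list()
  res <- run_pipeline(proteomes, features, seeds, ssu = ssu,
                      genera = genera, truth = truth, params = cur,
                      seed = cfg$seed %||% 1,
                      max_gap = op$max_gap %||% 200,
                      divergence_window = op$divergence_window %||% 1000,
                      out_dir = cfg$out_dir)
  invisible(res)
}
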