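#' Curation parameters
#'
#' Controls the mechanized stand-in for manual hit curation: a hit is
#' accepted when its bit score passes the decoy-calibrated cutoff AND it
#' either has another accepted csg homolog within `neighborhood_window`
#' genes, or (for CsgA/B candidates) carries at least `min_repeats_for_AB`
#' minimalistic repeats.  `cutoff_fpr` is the per-model decoy
#' false-positive rate used by [calibrate()]; the default is deliberately
#' strict (0.001) because a genome screen tests every model against every
#' protein, so the per-test rate has to be far below 1/(models x proteins)
#' for the expected number of score-passing decoys per run to stay near
#' zero.
#'
#' @param max_iterations Iteration cap for [iterate_search()].
#' @param neighborhood_window Gene-order window for the neighborhood clause.
#' @param min_repeats_for_AB Minimum repeat windows for the CsgA/B clause.
#' @param cutoff_fpr Decoy false-positive rate for cutoff calibration.
#' @param n_calibration_decoys Decoys drawn per run for calibration.
#' @return List of class `curation_params`.
#' @export
curation_params <- function(max_iterations = 10, neighborhood_window = 5,
                            min_repeats_for_AB = 2, cutoff_fpr = 0.001,
                            n_calibration_decoys = 1000) {
  stopifnot(max_iterations >= 1, neighborhood_window >= 1,
            min_repeats_for_AB >= 1, cutoff_fpr >= 0, cutoff_fpr < 1,
            n_calibration_decoys >= 100)
  structure(list(max_iterations = max_iterations,
                 neighborhood_window = neighborhood_window,
                 min_repeats_for_AB = min_repeats_for_AB,
                 cutoff_fpr = cutoff_fpr,
                 n_calibration_decoys = n_calibration_decoys),
            class = "curation_params")
}

# gene-order rank of every locus within its contig
gene_ranks <- function(features) {
  ranks <- integer(nrow(features))
  for (ctg in unique(features$contig)) {
    sel <- features$contig == ctg
    ranks[sel] <- rank(features$start[sel], ties.method = "first")
  }
  data.frame(locus_id = features$locus_id, contig = features$contig,
             rank = ranks, stringsAsFactors = FALSE)
}

#' Curate homology hits with the two-clause rule
#'
#' Mechanizes gene-neighborhood curation: a hit is accepted iff its bit
#' score is at or above `cutoff` and either (a) another accepted csg
#' homolog lies within `neighborhood_window` genes on the same contig, or
#' (b) the hit is a CsgA/B candidate with at least `min_repeats_for_AB`
#' minimalistic repeat windows.  Hits whose genome has no annotation are
#' held as `unplaceable` rather than silently dropped.  Every decision is
#' returned with its evidence.
#'
#' @param hits Hit table from [search_hmm()].
#' @param family Family label of the searching model (`"csgAB"` enables the
#'   repeat clause).
#' @param genome_of Named vector mapping protein ids to genome ids.
#' @param features_by_genome Named list of feature tables.
#' @param accepted_ids Protein ids currently accepted in any csg family
#'   (the neighborhood evidence base).
#' @param sequences Named vector of protein sequences (for repeat counts).
#' @param cutoff Bit-score cutoff.
#' @param params [curation_params()].
#' @return Data frame of decisions: `target_id`, `family`, `genome`,
#'   `bit_score`, `cutoff`, `has_neighbor`, `n_repeats`, `decision`
#'   (`accepted` / `rejected` / `unplaceable`), `reason`.
#' @export
curate_hits <- function(hits, family, genome_of, features_by_genome,
                        accepted_ids, sequences, cutoff,
                        params = curation_params()) {
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    id <- hits$target_id[i]
    score <- hits$bit_score[i]
    genome <- genome_of[[id]] %||% NA_character_
    n_rep <- nrow(scan_repeats(sequences[[id]]))
    feats <- if (!is.na(genome)) features_by_genome[[genome]] else NULL
    if (is.null(feats) || !(id %in% feats$locus_id)) {
      return(data.frame(target_id = id, family = family, genome = genome,
                        bit_score = score, cutoff = cutoff,
                        has_neighbor = NA, n_repeats = n_rep,
                        decision = "unplaceable",
                        reason = "no annotation for this protein",
                        stringsAsFactors = FALSE))
    }
    ranks <- gene_ranks(feats)
    me <- ranks[ranks$locus_id == id, ]
    nb <- ranks[ranks$locus_id %in% setdiff(accepted_ids, id) &
                  ranks$contig == me$contig, ]
    has_neighbor <- nrow(nb) > 0 &&
      any(abs(nb$rank - me$rank) <= params$neighborhood_window)
    repeat_ok <- family == "csgAB" && n_rep >= params$min_repeats_for_AB
    ok_score <- score >= cutoff
    decision <- if (ok_score && (has_neighbor || repeat_ok)) "accepted" else "rejected"
    reason <- if (!ok_score) "below cutoff"
      else if (repeat_ok) "repeat clause"
      else if (has_neighbor) "neighborhood clause"
      else "isolated: no csg neighbor and insufficient repeats"
    data.frame(target_id = id, family = family, genome = genome,
               bit_score = score, cutoff = cutoff,
               has_neighbor = has_neighbor, n_repeats = n_rep,
               decision = decision, reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||%
    data.frame(target_id = character(), family = character(),
               genome = character(), bit_score = numeric(),
               cutoff = numeric(), has_neighbor = logical(),
               n_repeats = integer(), decision = character(),
               reason = character(), stringsAsFactors = FALSE)
}

#' Iterative homolog search to convergence
#'
#' The core annotation loop: build a profile HMM per family from the
#' current (seed + accepted) alignment, calibrate its cutoff on decoys,
#' search all proteomes, curate the new hits, extend the homolog set,
#' realign, rebuild -- repeated until no further homologs are identified or
#' `max_iterations` is reached.  The accepted set only ever grows, so the
#' loop is monotone and terminates.  The CsgA/B family is handled on repeat
#' regions only: accepted members contribute their concatenated
#' minimalistic-repeat regions (not their full sequence) to the model,
#' realigned with the high gap-opening cost that keeps repeat units intact.
#'
#' @param seeds Named list of seed alignments, one per family; the CsgA/B
#'   entry must be named `csgAB`.
#' @param proteomes Named list (by genome) of protein record data frames.
#' @param features Named list (by genome) of feature tables (may be
#'   incomplete; hits without annotation are held unplaceable).
#' @param params [curation_params()].
#' @param seed Integer seed for the calibration decoys (the only source of
#'   randomness).
#' @return List with `homologs` (accepted set: `target_id`, `genome`,
#'   `family`, `bit_score`, `reason`, `probative`), `models` (calibrated
#'   `profile_hmm`s), `n_iterations` (productive rounds), `converged`,
#'   `decisions` (full decision log), `msas` (final training alignments).
#' @export
iterate_search <- function(seeds, proteomes, features,
                           params = curation_params(), seed = 1) {
  stopifnot(length(seeds) >= 1, !is.null(names(seeds)))
  all_prots <- do.call(rbind, lapply(names(proteomes), function(g) {
    df <- proteomes[[g]]
    if (nrow(df) > 0) df$genome <- g
    df
  }))
  if (is.null(all_prots) || nrow(all_prots) == 0) {
    return(list(homologs = empty_homologs(), models = list(),
                n_iterations = 1L, converged = TRUE,
                decisions = NULL, msas = seeds))
  }
  genome_of <- setNames(all_prots$genome, all_prots$id)
  sequences <- setNames(all_prots$sequence, all_prots$id)
  # derive a decorrelated stream for the decoys: reusing `seed` directly
  # would replay the same RNG draws as any generator run with that seed
  calib_seed <- (1664525 * (abs(seed) %% 2147483647) + 1013904223) %% 2147483647
  calib <- with_seed(calib_seed, {
    lens <- sample(100:400, params$n_calibration_decoys, replace = TRUE)
    data.frame(id = paste0("decoy", seq_along(lens)), description = "",
               sequence = vapply(lens, random_aa, ""),
               stringsAsFactors = FALSE)
  })
  families <- names(seeds)
  if ("csgAB" %in% families) {     # repeat family first: it feeds the
    families <- c("csgAB", setdiff(families, "csgAB"))  # neighborhood clause
  }
  accepted <- list()   # per family: decision rows of accepted hits
  decisions <- list()
  models <- list()
  msas <- seeds
  changed_rounds <- 0L
  converged <- FALSE
  for (it in seq_len(params$max_iterations)) {
    new_this_round <- 0L
    known <- unlist(lapply(accepted, function(d) d$target_id))
    # rebuild and search all family models, then assign each candidate to
    # its best-scoring family before curation (a protein passing several
    # models belongs to the one that explains it best)
    fam_hits <- list()
    for (fam in families) {
      msas[[fam]] <- family_alignment(fam, seeds[[fam]],
                                      accepted[[fam]], sequences)
      hmm <- build_profile(msas[[fam]], name = fam)
      hmm$score_cutoff <- calibrate(hmm, calib, fpr = params$cutoff_fpr)
      models[[fam]] <- hmm
      hits <- search_hmm(hmm, all_prots)
      hits <- hits[!(hits$target_id %in% known), , drop = FALSE]
      if (nrow(hits) > 0) hits$family <- fam
      fam_hits[[fam]] <- hits
    }
    pooled <- do.call(rbind, fam_hits)
    if (!is.null(pooled) && nrow(pooled) > 0) {
      pooled$fam_order <- match(pooled$family, families)
      pooled <- pooled[order(pooled$target_id, -pooled$bit_score,
                             pooled$fam_order), ]
      pooled <- pooled[!duplicated(pooled$target_id), , drop = FALSE]
    }
    for (fam in families) {
      hits <- pooled[pooled$family == fam, , drop = FALSE]
      if (is.null(hits) || nrow(hits) == 0) next
      known <- unlist(lapply(accepted, function(d) d$target_id))
      dec <- curate_hits(hits, fam, genome_of, features,
                         accepted_ids = known, sequences = sequences,
                         cutoff = models[[fam]]$score_cutoff, params = params)
      dec$iteration <- it
      decisions[[length(decisions) + 1]] <- dec
      acc <- dec[dec$decision == "accepted", , drop = FALSE]
      if (nrow(acc) > 0) {
        accepted[[fam]] <- rbind(accepted[[fam]], acc)
        new_this_round <- new_this_round + nrow(acc)
      }
    }
    if (new_this_round > 0) {
      changed_rounds <- changed_rounds + 1L
    } else {
      converged <- TRUE
      break
    }
  }
  homologs <- do.call(rbind, unname(accepted)) %||% empty_homologs()
  if (nrow(homologs) > 0) {
    homologs <- homologs[, c("target_id", "genome", "family", "bit_score",
                             "n_repeats", "reason")]
    # CsgD hits are kept but flagged: the family is too large for the model
    # to be probative of curli systems on its own
    homologs$probative <- homologs$family != "csgD"
    rownames(homologs) <- NULL
  }
  list(homologs = homologs, models = models,
       n_iterations = max(1L, changed_rounds),
       converged = converged,
       decisions = do.call(rbind, decisions),
       msas = msas)
}

empty_homologs <- function() {
  data.frame(target_id = character(), genome = character(),
             family = character(), bit_score = numeric(),
             n_repeats = integer(), reason = character(),
             probative = logical(), stringsAsFactors = FALSE)
}

# training alignment for one family: seed rows plus accepted members
# (repeat regions only for csgAB), deduplicated, realigned when needed
family_alignment <- function(fam, seed_msa, accepted, sequences) {
  rows <- setNames(ungap(seed_msa), names(seed_msa))
  for (id in accepted$target_id) {
    s <- sequences[[id]]
    if (fam == "csgAB") {
      m <- scan_repeats(s)
      regions <- extract_repeat_regions(list(sequence = s), m)
      s <- paste(regions, collapse = "")
    }
    if (nzchar(s)) rows[id] <- s   # repeat-free members contribute nothing
  }
  rows <- rows[!duplicated(rows)]   # non-redundant: exact duplicates out
  if (length(rows) == 1) return(as_msa(rows))
  if (length(unique(nchar(rows))) == 1 && length(unique(rows)) == 1) {
    return(as_msa(rows))
  }
  gap_open <- if (fam == "csgAB") 50 else 15
  progressive_msa(rows, align_params(gap_open = gap_open, gap_extend = 1))
}

#' Validation report against a truth set
#'
#' The standard hits / correct hits / missing hits bookkeeping: `hits` is
#' the number of predictions, correct hits are predictions present in the
#' truth set (reported over the number of predictions), missing hits are
#' truth members not predicted (reported over the truth-set size).
#' Percentages are rounded to integers.
#'
#' @param predicted Character vector of predicted ids.
#' @param truth Non-empty character vector of truth ids.
#' @param model_name Name for the report row.
#' @return List of class `validation_report`: `model`, `hits`, `correct`,
#'   `correct_total`, `missing`, `missing_total`, plus formatted strings
#'   `correct_str` and `missing_str` like `"172/172 (100%)"`.
#' @export
validate <- function(predicted, truth, model_name = "model") {
  if (length(truth) == 0) stop("empty truth set")
  predicted <- unique(predicted)
  truth <- unique(truth)
  hits <- length(predicted)
  correct <- length(intersect(predicted, truth))
  missing <- length(setdiff(truth, predicted))
  pct <- function(num, den) if (den == 0) 0L else as.integer(round(100 * num / den))
  structure(list(model = model_name, hits = hits,
                 correct = correct, correct_total = hits,
                 missing = missing, missing_total = length(truth),
                 correct_str = sprintf("%d/%d (%d%%)", correct, hits,
                                       pct(correct, hits)),
                 missing_str = sprintf("%d/%d (%d%%)", missing, length(truth),
                                       pct(missing, length(truth)))),
            class = "validation_report")
}

#' @export
format.validation_report <- function(x, ...) {
  paste(x$model, x$hits, x$correct_str, x$missing_str, sep = "\t")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Model\tHits\tCorrect hits\tMissing hits\n")
  cat(format(x), "\n")
  invisible(x)
}
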