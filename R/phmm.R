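#' Build a profile HMM from a multiple sequence alignment
#'
#' Columns with a gap fraction below 0.5 become match states (the classic
#' profile-HMM heuristic); the remaining columns are treated as insertions.
#' Match emissions are estimated with background-proportional pseudocounts,
#' `p(a) = (count_a + w * bg_a) / (n + w)` where `n` counts observed residues
#' in the column, and converted to log-odds against the background at scoring
#' time.  State transitions are estimated from the gap structure of the
#' alignment with Laplace (+1) smoothing over each state's outgoing options.
#' The ambiguity letter `X` is ignored when counting emissions and scores 0
#' bits at search time.
#'
#' @param msa Alignment (named character vector of equal-length gapped rows).
#' @param name Model name.
#' @param background Length-20 background distribution (default uniform).
#' @param pseudocount_weight Total pseudocount mass `w` added per column
#'   (default 1).
#' @return A [profile_hmm()] object.
#' @export
build_profile <- function(msa, name = "model",
                          background = rep(0.05, 20),
                          pseudocount_weight = 1) {
  mat <- msa_matrix(msa)
  stopifnot(length(background) == 20, abs(sum(background) - 1) < 1e-9,
            pseudocount_weight >= 0)
  gapfrac <- colMeans(mat == "-")
  is_match <- gapfrac < 0.5
  K <- sum(is_match)
  if (K == 0) stop("no consensus columns: every column is mostly gaps")
  match_cols <- which(is_match)
  w <- pseudocount_weight
  emis <- matrix(0, K, 20, dimnames = list(NULL, AA20))
  for (k in seq_len(K)) {
    col <- mat[, match_cols[k]]
    counts <- tabulate(match(col, AA20), nbins = 20)  # gaps and X drop out
    n <- sum(counts)
    emis[k, ] <- (counts + w * background) / (n + w)
  }
  trans <- estimate_transitions(mat, match_cols)
  profile_hmm(name, emis, insert_emissions = background,
              background = background, trans = trans)
}

# Transition estimation between consecutive match columns.  Each row
# contributes one path segment per match-column pair: match residue = M,
# match gap = D; residues in intervening insert columns attach to the left
# match state as inserts.  Laplace +1 smoothing on every outgoing option.
estimate_transitions <- function(mat, match_cols) {
  K <- length(match_cols)
  empty <- function() rep(0, max(K - 1, 0))
  cMM <- empty(); cMI <- empty(); cMD <- empty()
  cIM <- empty(); cII <- empty()
  cDM <- empty(); cDD <- empty()
  if (K > 1) {
    for (k in seq_len(K - 1)) {
      a <- match_cols[k]; b <- match_cols[k + 1]
      between <- if (b - a > 1) mat[, (a + 1):(b - 1), drop = FALSE] else NULL
      for (r in seq_len(nrow(mat))) {
        here_m <- mat[r, a] != "-"
        next_m <- mat[r, b] != "-"
        n_ins <- if (is.null(between)) 0L else sum(between[r, ] != "-")
        if (here_m) {
          if (n_ins > 0) {
            cMI[k] <- cMI[k] + 1
            cII[k] <- cII[k] + (n_ins - 1)
            cIM[k] <- cIM[k] + 1
          } else if (next_m) cMM[k] <- cMM[k] + 1
          else cMD[k] <- cMD[k] + 1
        } else {
          if (next_m) cDM[k] <- cDM[k] + 1 else cDD[k] <- cDD[k] + 1
        }
      }
    }
  }
  norm3 <- function(x, y, z) {
    tot <- x + y + z + 3
    list((x + 1) / tot, (y + 1) / tot, (z + 1) / tot)
  }
  norm2 <- function(x, y) {
    tot <- x + y + 2
    list((x + 1) / tot, (y + 1) / tot)
  }
  m <- norm3(cMM, cMI, cMD)
  i <- norm2(cIM, cII)
  d <- norm2(cDM, cDD)
  list(tMM = m[[1]], tMI = m[[2]], tMD = m[[3]],
       tIM = i[[1]], tII = i[[2]],
       tDM = d[[1]], tDD = d[[2]])
}

# batch bit scores for many sequences under one model (score-only kernel)
hmm_scores <- function(hmm, sequences) {
  tab <- hmm_log_tables(hmm)
  codes <- lapply(sequences, function(s) encode_aa(sanitize_aa(s)) - 1L)
  as.numeric(.hmm_score_batch_cpp(tab$lmE,
                                  tab$lt$tMM, tab$lt$tMI, tab$lt$tMD,
                                  tab$lt$tIM, tab$lt$tII,
                                  tab$lt$tDM, tab$lt$tDD, codes))
}

# log2 emission and transition tables for the DP kernels
hmm_log_tables <- function(hmm) {
  lmE <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  lmE <- cbind(lmE, X = 0)  # ambiguity letter is scored as background
  lt <- lapply(hmm$trans, log2)
  list(lmE = lmE, lt = lt)
}

#' Viterbi alignment of a sequence to a profile HMM
#'
#' Local alignment with free flanks: the best-scoring path enters the model
#' at any match state (uniform entry over the `K` match states), follows
#' match/insert/delete transitions, and exits from any match state (uniform
#' exit).  Residues outside the aligned interval cost nothing; insert states
#' emit background, so only match emissions and transitions contribute.
#' Scores are log-odds in bits.  Tie-breaks prefer match over insert over
#' delete states.
#'
#' @param hmm A `profile_hmm`.
#' @param seq Non-empty amino-acid string.
#' @return List with `bit_score`, `start`/`end` (0-based half-open target
#'   interval), `model_start`/`model_end` (1-based match-state span) and
#'   `path` (state letters `M`/`I`/`D` along the core alignment).
#' @export
viterbi <- function(hmm, seq) {
  stopifnot(inherits(hmm, "profile_hmm"), nzchar(seq))
  tab <- hmm_log_tables(hmm)
  codes <- encode_aa(sanitize_aa(seq)) - 1L
  res <- .hmm_viterbi_cpp(tab$lmE,
                          tab$lt$tMM, tab$lt$tMI, tab$lt$tMD,
                          tab$lt$tIM, tab$lt$tII,
                          tab$lt$tDM, tab$lt$tDD, codes)
  list(bit_score = res$score,
       start = res$start, end = res$end,
       model_start = res$model_start, model_end = res$model_end,
       path = c("M", "I", "D")[res$states])
}

#' Forward log-odds score of a sequence under a profile HMM
#'
#' Same local model as [viterbi()] but summing probability over all core
#' alignments instead of maximizing, so `forward(hmm, seq) >= viterbi
#' bit_score` always.
#'
#' @inheritParams viterbi
#' @return Forward log-odds score in bits.
#' @export
forward <- function(hmm, seq) {
  stopifnot(inherits(hmm, "profile_hmm"), nzchar(seq))
  tab <- hmm_log_tables(hmm)
  codes <- encode_aa(sanitize_aa(seq)) - 1L
  .hmm_forward_cpp(tab$lmE,
                   tab$lt$tMM, tab$lt$tMI, tab$lt$tMD,
                   tab$lt$tIM, tab$lt$tII,
                   tab$lt$tDM, tab$lt$tDD, codes)
}

#' Search a proteome with a profile HMM
#'
#' Scores every target with [viterbi()] and reports the best local hit per
#' target at or above the bit-score cutoff, sorted by descending score.  The
#' E-value surrogate is the empirical-null expectation
#' `n_targets * 2^(-bit_score)`; it is decoy-calibrated bookkeeping, not a
#' fitted extreme-value statistic.
#'
#' @param hmm A `profile_hmm`.
#' @param proteome Data frame of protein records ([read_fasta()]).
#' @param cutoff_bits Bit-score cutoff; defaults to the model's calibrated
#'   `score_cutoff` (error if neither is set).
#' @return Data frame with columns `target_id`, `bit_score`, `start`, `end`,
#'   `model_start`, `model_end`, `evalue_surrogate`.
#' @export
search_hmm <- function(hmm, proteome, cutoff_bits = NULL) {
  stopifnot(inherits(hmm, "profile_hmm"), is.data.frame(proteome))
  cutoff <- cutoff_bits %||% hmm$score_cutoff
  if (is.na(cutoff) || !is.finite(cutoff)) {
    stop("no finite bit-score cutoff: calibrate the model or pass cutoff_bits")
  }
  n <- nrow(proteome)
  if (n == 0) return(empty_hits())
  scores <- hmm_scores(hmm, proteome$sequence)   # fast score-only pass
  keep <- which(scores >= cutoff)
  if (length(keep) == 0) return(empty_hits())
  rows <- lapply(keep, function(i) {             # full DP only for hits
    v <- viterbi(hmm, proteome$sequence[i])
    data.frame(target_id = proteome$id[i], bit_score = v$bit_score,
               start = v$start, end = v$end,
               model_start = v$model_start, model_end = v$model_end,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits <- hits[order(-hits$bit_score, hits$target_id), , drop = FALSE]
  hits$evalue_surrogate <- n * 2^(-hits$bit_score)
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(target_id = character(), bit_score = numeric(),
             start = integer(), end = integer(),
             model_start = integer(), model_end = integer(),
             evalue_surrogate = numeric(), stringsAsFactors = FALSE)
}

#' Calibrate a bit-score cutoff on decoy sequences
#'
#' Scores a decoy set and returns the empirical `(1 - fpr)` quantile of the
#' per-decoy best bit scores, taken as the smallest decoy score such that the
#' fraction of decoys scoring at or above it does not exceed `fpr` (upper
#' empirical quantile; with `fpr = 0` this is the decoy maximum).
#'
#' @param hmm A `profile_hmm`.
#' @param decoys Data frame of at least 100 decoy protein records.
#' @param fpr Tolerated decoy false-positive rate (default 0.01).
#' @return The cutoff in bits.  Assign it to `hmm$score_cutoff` to make it
#'   the model default.
#' @export
calibrate <- function(hmm, decoys, fpr = 0.01) {
  stopifnot(inherits(hmm, "profile_hmm"), fpr >= 0, fpr < 1)
  if (nrow(decoys) < 100) {
    stop("calibration needs >= 100 decoys, got ", nrow(decoys))
  }
  scores <- hmm_scores(hmm, decoys$sequence)
  n <- length(scores)
  idx <- min(n, floor(n * (1 - fpr)) + 1)
  sort(scores)[idx]
}
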