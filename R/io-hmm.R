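#' Construct a profile HMM object
#'
#' Low-level constructor validating the probabilistic invariants: every
#' emission distribution and every per-state transition distribution must sum
#' to 1 (tolerance 1e-9).  Most users build models from alignments with
#' [build_profile()] instead.
#'
#' @param name Model name.
#' @param match_emissions `K x 20` matrix of match emission probabilities,
#'   columns in alphabet order `ACDEFGHIKLMNPQRSTVWY`.
#' @param insert_emissions Length-20 insert emission distribution.
#' @param background Length-20 background amino-acid distribution.
#' @param trans List of transition probability vectors `tMM`, `tMI`, `tMD`,
#'   `tIM`, `tII`, `tDM`, `tDD`, each of length `K - 1` (transitions out of
#'   state `k` into state `k + 1`'s block).
#' @param score_cutoff Bit-score acceptance cutoff (`NA` until calibrated).
#' @return An object of class `profile_hmm`.
#' @export
profile_hmm <- function(name, match_emissions, insert_emissions, background,
                        trans, score_cutoff = NA_real_) {
  K <- nrow(match_emissions)
  stopifnot(K >= 1, ncol(match_emissions) == 20,
            length(insert_emissions) == 20, length(background) == 20)
  chk1 <- function(x, what) {
    if (any(abs(x - 1) > 1e-9)) stop(what, " must sum to 1")
  }
  chk1(rowSums(match_emissions), "match emission rows")
  chk1(sum(insert_emissions), "insert emissions")
  chk1(sum(background), "background")
  need <- c("tMM", "tMI", "tMD", "tIM", "tII", "tDM", "tDD")
  stopifnot(all(need %in% names(trans)))
  if (K > 1) {
    stopifnot(all(vapply(trans[need], length, 0L) == K - 1))
    chk1(trans$tMM + trans$tMI + trans$tMD, "match transition rows")
    chk1(trans$tIM + trans$tII, "insert transition rows")
    chk1(trans$tDM + trans$tDD, "delete transition rows")
  }
  colnames(match_emissions) <- AA20
  structure(list(name = name, n_match = K,
                 match_emissions = match_emissions,
                 insert_emissions = setNames(insert_emissions, AA20),
                 background = setNames(background, AA20),
                 trans = trans[need], score_cutoff = score_cutoff),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile HMM '", x$name, "': ", x$n_match, " match states, cutoff ",
      formatC(x$score_cutoff, digits = 3), " bits\n", sep = "")
  invisible(x)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a profile HMM to its plain-text format
#'
#' The format is a small key/value + table dialect specific to this package
#' (it is not HMMER's): header keys `NAME`, `NMATCH`, `CUTOFF`, `ALPHABET`,
#' then one line each for `BACKGROUND` and `INSERT`, `K` `MATCH` rows, and
#' `K - 1` `TRANS` rows (`MM MI MD IM II DM DD`), closed by `END`.  Numbers
#' are written with 17 significant digits so a write/read round trip
#' reproduces all probabilities to within 1e-12 relative error.
#'
#' @param hmm A `profile_hmm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hmm <- function(hmm, path) {
  stopifnot(inherits(hmm, "profile_hmm"))
  K <- hmm$n_match
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("CURLISCAN-HMM 1")
  w("NAME ", hmm$name)
  w("NMATCH ", K)
  w("CUTOFF ", if (is.na(hmm$score_cutoff)) "NA" else fmt_num(hmm$score_cutoff))
  w("ALPHABET ", paste(AA20, collapse = ""))
  w("BACKGROUND ", paste(fmt_num(hmm$background), collapse = " "))
  w("INSERT ", paste(fmt_num(hmm$insert_emissions), collapse = " "))
  for (k in seq_len(K)) {
    w("MATCH ", paste(fmt_num(hmm$match_emissions[k, ]), collapse = " "))
  }
  if (K > 1) {
    tr <- hmm$trans
    for (k in seq_len(K - 1)) {
      w("TRANS ", paste(fmt_num(c(tr$tMM[k], tr$tMI[k], tr$tMD[k],
                                  tr$tIM[k], tr$tII[k],
                                  tr$tDM[k], tr$tDD[k])), collapse = " "))
    }
  }
  w("END")
  invisible(path)
}

#' Read a profile HMM written by [write_hmm()]
#'
#' @param path Path to the model file.
#' @return A `profile_hmm`.
#' @export
read_hmm <- function(path) {
  lines <- readLines(path)
  fail <- function(i, msg) stop("HMM parse error at line ", i, ": ", msg)
  if (length(lines) == 0 || lines[1] != "CURLISCAN-HMM 1") {
    fail(1, "missing CURLISCAN-HMM 1 magic")
  }
  kv <- function(i, key) {
    if (i > length(lines) || !startsWith(lines[i], paste0(key, " "))) {
      fail(i, paste("expected", key))
    }
    sub(paste0("^", key, " "), "", lines[i])
  }
  nums <- function(i, key, n) {
    x <- suppressWarnings(as.numeric(strsplit(kv(i, key), " +")[[1]]))
    if (length(x) != n || anyNA(x)) fail(i, paste("expected", n, "numbers"))
    x
  }
  name <- kv(2, "NAME")
  K <- as.integer(kv(3, "NMATCH"))
  if (is.na(K) || K < 1) fail(3, "bad NMATCH")
  cut_raw <- kv(4, "CUTOFF")
  cutoff <- if (cut_raw == "NA") NA_real_ else as.numeric(cut_raw)
  if (kv(5, "ALPHABET") != paste(AA20, collapse = "")) fail(5, "bad alphabet")
  bg <- nums(6, "BACKGROUND", 20)
  ins <- nums(7, "INSERT", 20)
  match <- matrix(0, K, 20)
  for (k in seq_len(K)) match[k, ] <- nums(7 + k, "MATCH", 20)
  trans <- list(tMM = numeric(0), tMI = numeric(0), tMD = numeric(0),
                tIM = numeric(0), tII = numeric(0),
                tDM = numeric(0), tDD = numeric(0))
  if (K > 1) {
    tm <- matrix(0, K - 1, 7)
    for (k in seq_len(K - 1)) tm[k, ] <- nums(7 + K + k, "TRANS", 7)
    trans <- list(tMM = tm[, 1], tMI = tm[, 2], tMD = tm[, 3],
                  tIM = tm[, 4], tII = tm[, 5], tDM = tm[, 6], tDD = tm[, 7])
  }
  endline <- 7 + K + max(K - 1, 0) + 1
  if (endline > length(lines) || lines[endline] != "END") {
    fail(endline, "missing END")
  }
  profile_hmm(name, match, ins, bg, trans, cutoff)
}
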