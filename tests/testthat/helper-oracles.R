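# Independent brute-force oracles used by the property and acceptance tests.
# These enumerate explicitly and share no code with the package's DP kernels.

AA20_T <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")

random_peptide <- function(len) {
  paste(sample(AA20_T, len, replace = TRUE), collapse = "")
}

# --- exhaustive global affine alignment score ------------------------------
# Recursion over (i, j, state of previous column); gap of length L costs
# goc + (L - 1) * gec; terminal gaps charged.
brute_align_score <- function(a, b, sub, goc, gec) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, sub[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      cost <- if (prev == "X") gec else goc
      best <- max(best, -cost + rec(i + 1, j, "X"))
    }
    if (j <= m) {
      cost <- if (prev == "Y") gec else goc
      best <- max(best, -cost + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "M")
}

# --- exhaustive profile-HMM path enumeration -------------------------------
# Enumerates every core alignment (enter at any match state, traverse
# M/I/D, exit at any match state; flanks free; uniform entry/exit 1/K;
# insert emissions are background so they add only transition costs).
# Returns the vector of all path scores in bits.
brute_hmm_path_scores <- function(hmm, seq) {
  K <- hmm$n_match
  x <- strsplit(seq, "")[[1]]
  L <- length(x)
  le <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  lt <- lapply(hmm$trans, log2)
  lent <- -log2(K)
  scores <- numeric(0)
  # from_match(k, i, s): path currently sits on M_k having just emitted x[i]
  from_match <- function(k, i, s) {
    scores[length(scores) + 1] <<- s + lent    # exit here
    if (k < K) {
      if (i < L) {   # M_k -> M_{k+1}
        from_match(k + 1, i + 1, s + lt$tMM[k] + le[k + 1, x[i + 1]])
      }
      # M_k -> I_k^m -> M_{k+1}: m inserted residues then a match emission
      for (m in seq_len(max(L - i - 1, 0))) {
        nxt <- i + m + 1
        if (nxt <= L) {
          s2 <- s + lt$tMI[k] + (m - 1) * lt$tII[k] + lt$tIM[k] +
            le[k + 1, x[nxt]]
          from_match(k + 1, nxt, s2)
        }
      }
      # M_k -> D_{k+1} -> ... -> D_{k2-1} -> M_{k2}
      if (i < L) {
        for (k2 in (k + 2):(K + 1)) {
          if (k2 > K) break
          s2 <- s + lt$tMD[k]
          if (k2 > k + 2) {
            s2 <- s2 + sum(lt$tDD[(k + 1):(k2 - 2)])
          }
          s2 <- s2 + lt$tDM[k2 - 1] + le[k2, x[i + 1]]
          from_match(k2, i + 1, s2)
        }
      }
    }
  }
  for (i in seq_len(L)) {
    for (k in seq_len(K)) {
      from_match(k, i, lent + le[k, x[i]])
    }
  }
  scores
}

brute_viterbi <- function(hmm, seq) max(brute_hmm_path_scores(hmm, seq))
brute_forward <- function(hmm, seq) {
  s <- brute_hmm_path_scores(hmm, seq)
  m <- max(s)
  m + log2(sum(2^(s - m)))
}

# random small profile HMM via build_profile on a random gappy alignment
random_small_hmm <- function(max_states = 3) {
  repeat {
    ncol <- sample(2:5, 1)
    nrow <- sample(2:4, 1)
    rows <- vapply(seq_len(nrow), function(i) {
      chars <- sample(AA20_T, ncol, replace = TRUE)
      gaps <- runif(ncol) < 0.25
      chars[gaps] <- "-"
      paste(chars, collapse = "")
    }, "")
    if (all(nchar(gsub("-", "", rows)) > 0)) {
      hmm <- tryCatch(build_profile(setNames(rows, paste0("r", seq_len(nrow)))),
                      error = function(e) NULL)
      if (!is.null(hmm) && hmm$n_match <= max_states) return(hmm)
    }
  }
}

# --- independent triple-anchor motif oracle --------------------------------
brute_scan_starts <- function(seq) {
  n <- nchar(seq)
  if (n < 22) return(integer())
  starts <- integer()
  for (s in 0:(n - 22)) {
    if (substr(seq, s + 7, s + 7) == "Q" &&
        substr(seq, s + 9, s + 9) == "G" &&
        substr(seq, s + 12, s + 12) == "N") {
      starts <- c(starts, s)
    }
  }
  starts
}

# random additive tree and its exact leaf distance matrix
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(n) runif(n, 0.5, 3))
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  list(tree = tr, dm = cophenetic(tr))
}
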