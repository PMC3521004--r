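#' The minimalistic curli repeat motif
#'
#' The 22-residue motif X6QXGX2NX10: six arbitrary residues, a literal
#' glutamine, one arbitrary residue, a literal glycine, two arbitrary
#' residues, a literal asparagine, and ten arbitrary residues.  Within a
#' window starting at 0-based position `s`, the anchors sit at `s + 6` (Q),
#' `s + 8` (G) and `s + 11` (N).  Wildcard positions match any of the 20
#' residues and the ambiguity letter `X`; the anchors must be literal.
#'
#' @param prefix_len,q_offset,g_offset,n_offset,suffix_len Motif geometry in
#'   residues; the defaults encode X6QXGX2NX10 and are rarely changed.
#' @return List of class `repeat_motif` with the offsets and total `window`
#'   length.
#' @export
repeat_motif <- function(prefix_len = 6, q_offset = 6, g_offset = 8,
                         n_offset = 11, suffix_len = 10) {
  window <- prefix_len + 1 + (g_offset - q_offset - 1) + 1 +
    (n_offset - g_offset - 1) + 1 + suffix_len
  stopifnot(q_offset == prefix_len, g_offset > q_offset, n_offset > g_offset)
  structure(list(prefix_len = prefix_len, q_offset = q_offset,
                 g_offset = g_offset, n_offset = n_offset,
                 suffix_len = suffix_len, window = window),
            class = "repeat_motif")
}

#' Scan a sequence for minimalistic curli repeats
#'
#' Tests every window start position, so mutually overlapping
#' ("superimposed") repeats are all reported -- a left-to-right consuming
#' regular-expression search would miss the second of two motif windows that
#' overlap inside one larger repeat unit.
#'
#' @param seq Amino-acid string.
#' @param motif A [repeat_motif()].
#' @return Data frame with one row per match: `start` (0-based window start),
#'   `end` (`start + window`, half-open), sorted by `start`.  Empty for
#'   sequences shorter than the window.
#' @export
scan_repeats <- function(seq, motif = repeat_motif()) {
  w <- motif$window
  n <- nchar(seq)
  if (n < w) {
    return(data.frame(start = integer(), end = integer()))
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  starts0 <- 0:(n - w)
  hit <- chars[starts0 + motif$q_offset + 1] == "Q" &
    chars[starts0 + motif$g_offset + 1] == "G" &
    chars[starts0 + motif$n_offset + 1] == "N"
  data.frame(start = starts0[hit], end = starts0[hit] + w)
}

#' Repeat architecture of one protein
#'
#' Summarises the minimalistic-repeat content of a protein: the ordered
#' matches, their count, how many match pairs overlap, inter-start spacings,
#' and whether the protein looks like a functional curli subunit.  Proteins
#' with no or only one repeat window are flagged non-functional, since a
#' single repeat unit cannot form the amyloid core.
#'
#' @param protein One protein record (a one-row data frame or a list with
#'   `id` and `sequence`).
#' @param motif A [repeat_motif()].
#' @return List of class `repeat_architecture` with `protein_id`, `matches`
#'   (data frame from [scan_repeats()]), `n_repeats`, `overlapping_pairs`,
#'   `spacings` (differences of consecutive starts) and `functional`
#'   (`n_repeats >= 2`).
#' @export
architecture <- function(protein, motif = repeat_motif()) {
  m <- scan_repeats(protein$sequence, motif)
  n <- nrow(m)
  overlapping <- 0L
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      overlapping <- overlapping + sum(m$start[(i + 1):n] < m$end[i])
    }
  }
  structure(list(protein_id = protein$id,
                 matches = m,
                 n_repeats = n,
                 overlapping_pairs = overlapping,
                 spacings = if (n > 1) diff(m$start) else integer(),
                 functional = n >= 2),
            class = "repeat_architecture")
}

#' Extract (merged) repeat regions from a protein
#'
#' Merges overlapping or near-adjacent motif windows (gap `<= merge_gap`
#' residues) into maximal regions and returns the region subsequences in
#' order.  These regions are the training material for the combined CsgA/B
#' repeat model, which is built solely from repeat regions because the
#' remainder of these proteins cannot be aligned confidently.
#'
#' @param protein Protein record with `sequence`.
#' @param matches Match table from [scan_repeats()].
#' @param merge_gap Maximum residue gap between windows merged into one
#'   region (default 0: only touching/overlapping windows merge).
#' @return Character vector of region subsequences (possibly empty).
#' @export
extract_repeat_regions <- function(protein, matches, merge_gap = 0) {
  if (nrow(matches) == 0) return(character())
  m <- matches[order(matches$start), ]
  reg_start <- m$start[1]; reg_end <- m$end[1]
  out <- character()
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      if (m$start[i] - reg_end <= merge_gap) {
        reg_end <- max(reg_end, m$end[i])
      } else {
        out <- c(out, substr(protein$sequence, reg_start + 1, reg_end))
        reg_start <- m$start[i]; reg_end <- m$end[i]
      }
    }
  }
  c(out, substr(protein$sequence, reg_start + 1, reg_end))
}

#' Per-column consensus profile of aligned repeat regions
#'
#' For each alignment column, the residue (or gap) frequency distribution,
#' the modal residue, and a conservation tier: `100` if one residue fills the
#' whole column, `80`/`50` at those fractions or more, otherwise `none`.
#' Gaps count in the denominator, so a half-gapped column cannot reach tier
#' 100.  This reproduces the conservation-tier annotation used for per-genus
#' repeat consensus sequences.
#'
#' @param aligned_repeats Alignment of repeat regions (named character
#'   vector).
#' @return Data frame with one row per column: `column`, `consensus` (modal
#'   residue, gaps excluded from the mode unless the column is all gaps),
#'   `frequency` (modal residue fraction of all rows) and `tier` (one of
#'   `"none"`, `"50"`, `"80"`, `"100"`).
#' @export
repeat_consensus <- function(aligned_repeats) {
  mat <- msa_matrix(aligned_repeats)
  n <- nrow(mat)
  rows <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    resid <- col[col != "-"]
    if (length(resid) == 0) {
      return(data.frame(column = j, consensus = "-", frequency = 0,
                        tier = "none", stringsAsFactors = FALSE))
    }
    tab <- sort(table(resid), decreasing = TRUE)
    cons <- names(tab)[1]
    f <- unname(tab[1]) / n
    tier <- if (f == 1) "100" else if (f >= 0.8) "80" else if (f >= 0.5) "50" else "none"
    data.frame(column = j, consensus = cons, frequency = f, tier = tier,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Repeat architecture table for a whole proteome
#'
#' @param proteome Protein records data frame.
#' @param motif A [repeat_motif()].
#' @return Data frame with one row per protein: `protein_id`, `n_repeats`,
#'   `starts` (comma-separated 0-based), `overlapping_pairs`, `functional`.
#' @export
repeat_table <- function(proteome, motif = repeat_motif()) {
  rows <- lapply(seq_len(nrow(proteome)), function(i) {
    a <- architecture(proteome[i, ], motif)
    data.frame(protein_id = a$protein_id, n_repeats = a$n_repeats,
               starts = paste(a$matches$start, collapse = ","),
               overlapping_pairs = a$overlapping_pairs,
               functional = a$functional, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||% data.frame()
}
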