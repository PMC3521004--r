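# Shared internals: amino-acid alphabet, sequence coding, seed scoping.

# 20 canonical residues; X is the ambiguity letter accepted everywhere.
AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
AAX <- c(AA20, "X")

#' @noRd
aa_index <- local({
  idx <- integer(0)
  function() {
    if (length(idx) == 0) {
      idx <<- setNames(seq_along(AAX), AAX)
    }
    idx
  }
})

# Encode an amino-acid string to 1-based codes over AAX (X = 21).
encode_aa <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  codes <- aa_index()[chars]
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop("non-amino-acid letters in sequence: ", paste(bad, collapse = ", "))
  }
  unname(codes)
}

# Replace letters outside the 20-aa alphabet (plus X) by X, warning once.
# Metagenome-derived inputs routinely carry B/Z/J/U/O/*; they are not errors.
sanitize_aa <- function(seq, id = NULL) {
  up <- toupper(seq)
  pat <- paste0("[^", paste(AAX, collapse = ""), "]")
  if (grepl(pat, up)) {
    warning("letters outside the amino-acid alphabet mapped to X",
            if (!is.null(id)) paste0(" in ", id), call. = FALSE)
    up <- gsub(pat, "X", up)
  }
  up
}

# Run code with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards, so generators never leak global state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
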