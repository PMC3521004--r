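#' Read a multiple sequence alignment
#'
#' Reads an alignment from aligned FASTA or Stockholm format.  The result is a
#' named character vector of equal-length gapped rows (gap character `-`);
#' Stockholm `#=G*` annotation lines are ignored, `.` gaps are normalised to
#' `-`.
#'
#' @param path Path to the alignment file.
#' @param dialect `"fasta"` (aligned FASTA) or `"stockholm"`.
#' @return Named character vector of gapped rows, in file order.
#' @export
read_msa <- function(path, dialect = c("fasta", "stockholm")) {
  dialect <- match.arg(dialect)
  rows <- switch(dialect,
    fasta = {
      ss <- Biostrings::readBStringSet(path)
      setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
    },
    stockholm = read_stockholm(path)
  )
  as_msa(rows)
}

# Stockholm is a simple block format; neither Biostrings nor ape reads it,
# so the (tiny) parser lives here.  Sequence lines are "<name> <chunk>";
# lines starting with '#' are annotation, '//' terminates.
read_stockholm <- function(path) {
  lines <- readLines(path)
  acc <- list()
  order <- character()
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || startsWith(ln, "#") || startsWith(ln, "//")) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed Stockholm line: ", ln)
    nm <- parts[1]
    if (is.null(acc[[nm]])) {
      acc[[nm]] <- parts[2]
      order <- c(order, nm)
    } else {
      acc[[nm]] <- paste0(acc[[nm]], parts[2])
    }
  }
  rows <- toupper(gsub(".", "-", unlist(acc[order]), fixed = TRUE))
  setNames(rows, order)
}

#' Validate and normalise an alignment
#'
#' @param rows Named character vector of gapped sequences.
#' @return The validated alignment (named character vector).
#' @export
as_msa <- function(rows) {
  if (length(rows) == 0) stop("empty alignment")
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("alignment rows must be named")
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    bad <- names(rows)[widths != widths[1]]
    stop("ragged alignment rows: ", paste(bad, collapse = ", "))
  }
  rows
}

#' Write an alignment as aligned FASTA
#'
#' @param msa Named character vector of gapped rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  msa <- as_msa(msa)
  Biostrings::writeXStringSet(Biostrings::BStringSet(msa), path)
  invisible(path)
}

#' @noRd
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

# alignment as a character matrix (rows x columns)
msa_matrix <- function(msa) {
  msa <- as_msa(msa)
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  rownames(mat) <- names(msa)
  mat
}
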