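#' Read a protein FASTA file
#'
#' Parses a (possibly gzipped) protein FASTA file into a data frame of
#' records.  Sequences are upper-cased; letters outside the 20-residue
#' alphabet plus `X` are mapped to `X` with a warning, since predicted
#' metagenome proteins routinely contain ambiguity codes and stop characters.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` (first whitespace-delimited header
#'   token, unique), `description` (remainder of the header, possibly empty)
#'   and `sequence`.  Input order is preserved.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) {
    return(data.frame(id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  headers <- names(ss)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(ss)
  if (anyDuplicated(id)) {
    stop("duplicate FASTA ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id: ", paste(id[!nzchar(seqs)], collapse = ", "))
  }
  if (any(grepl("-", seqs, fixed = TRUE))) {
    stop("gap characters in unaligned FASTA input")
  }
  seqs <- vapply(seq_along(seqs), function(i) sanitize_aa(seqs[i], id[i]), "")
  data.frame(id = id, description = description, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  desc <- records$description %||% rep("", nrow(records))
  hdr <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  ss <- Biostrings::BStringSet(setNames(records$sequence, hdr))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
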