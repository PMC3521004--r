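#' Read gene features from GFF3
#'
#' Imports `gene`/`CDS` rows from a GFF3 file and returns a feature table in
#' the package's internal coordinate convention: 0-based, half-open.  GFF3
#' files are 1-based inclusive, so a row `11 40` becomes `start = 10,
#' end = 40`.  The locus identifier is taken from the `locus_tag` attribute
#' when present, otherwise from `ID`; an optional `gene` attribute carrying a
#' csg gene name (csgA..csgH) is kept as `label`.
#'
#' @param path Path to a GFF3 file.
#' @param types Feature types to keep (default `gene` and `CDS`).
#' @return Data frame with columns `contig`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `locus_id`, `label` (NA when absent), in file order.
#' @export
read_gff <- function(path, types = c("gene", "CDS")) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% types]
  if (length(gr) == 0) {
    return(empty_features())
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) {
    stop("unstranded feature(s) in GFF: strand must be + or -")
  }
  meta <- S4Vectors::mcols(gr)
  locus <- if ("locus_tag" %in% names(meta)) as.character(meta$locus_tag) else rep(NA_character_, length(gr))
  idcol <- if ("ID" %in% names(meta)) as.character(meta$ID) else rep(NA_character_, length(gr))
  locus <- ifelse(is.na(locus) | !nzchar(locus), idcol, locus)
  label <- if ("gene" %in% names(meta)) as.character(meta$gene) else rep(NA_character_, length(gr))
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,   # 1-based incl -> 0-based half-open
    end = BiocGenerics::end(gr),
    strand = strand,
    locus_id = locus,
    label = label,
    stringsAsFactors = FALSE
  )
}

#' Write gene features to GFF3
#'
#' Inverse of [read_gff()]: internal 0-based half-open coordinates are written
#' back as 1-based inclusive GFF3 `gene` rows.
#'
#' @param features Feature data frame (see [read_gff()] for columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(features, path) {
  check_features(features)
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand
  )
  gr$type <- "gene"
  gr$ID <- features$locus_id
  gr$locus_tag <- features$locus_id
  if (!all(is.na(features$label))) gr$gene <- features$label
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a minimal tab-separated feature table
#'
#' Accepted as a lighter-weight alternative to GFF3 for fixtures and synthetic
#' genomes: columns `contig`, `start`, `end`, `strand`, `locus_id`, `label`,
#' with coordinates already 0-based half-open.
#'
#' @param path Path to a TSV file with a header row.
#' @return Feature data frame as from [read_gff()].
#' @export
read_features_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(label = "character"))
  need <- c("contig", "start", "end", "strand", "locus_id", "label")
  if (!all(need %in% names(df))) {
    stop("feature TSV must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$label[!is.na(df$label) & !nzchar(df$label)] <- NA_character_
  check_features(df)
  df
}

#' @noRd
write_features_tsv <- function(features, path) {
  check_features(features)
  write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

empty_features <- function() {
  data.frame(contig = character(), start = integer(), end = integer(),
             strand = character(), locus_id = character(),
             label = character(), stringsAsFactors = FALSE)
}

check_features <- function(features) {
  stopifnot(is.data.frame(features))
  if (nrow(features) == 0) return(invisible(features))
  if (any(features$start < 0) || any(features$start >= features$end)) {
    stop("invalid feature coordinates: need 0 <= start < end")
  }
  if (!all(features$strand %in% c("+", "-"))) {
    stop("feature strand must be '+' or '-'")
  }
  invisible(features)
}
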