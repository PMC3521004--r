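CSG_LABELS <- c("csgA", "csgB", "csgA/B", "csgC", "csgD",
                "csgE", "csgF", "csgG", "csgH")

is_ab_label <- function(x) x %in% c("csgA", "csgB", "csgA/B")

#' Group gene features into operons
#'
#' An operon is taken to be a maximal run of same-contig, same-strand genes
#' whose intergenic gaps do not exceed `max_gap` base pairs.  Annotations do
#' not state transcription units, so this distance rule is an explicit,
#' configurable surrogate.
#'
#' @param features Feature data frame ([read_gff()] columns) for one genome.
#' @param max_gap Maximum intergenic distance in bp within one operon
#'   (default 200).
#' @return List of operons; each is a feature data frame sorted by `start`
#'   with attribute `strand` and `contig`.  Every input gene is in exactly
#'   one operon.
#' @export
call_operons <- function(features, max_gap = 200) {
  check_features(features)
  if (nrow(features) == 0) return(list())
  features <- features[order(features$contig, features$start), ]
  brk <- c(TRUE, features$contig[-1] != features$contig[-nrow(features)] |
             features$strand[-1] != features$strand[-nrow(features)] |
             features$start[-1] - features$end[-nrow(features)] > max_gap)
  grp <- cumsum(brk)
  lapply(split(features, grp), function(op) {
    rownames(op) <- NULL
    attr(op, "strand") <- op$strand[1]
    attr(op, "contig") <- op$contig[1]
    op
  })
}

op_span <- function(op) c(min(op$start), max(op$end))
op_labels <- function(op) op$label[!is.na(op$label) & op$label %in% CSG_LABELS]

# Two operons transcribe away from a shared intergenic region iff the
# left-hand one is on the minus strand and the right-hand one on plus, with
# their proximal ends (the two promoters) within `window` bp.
is_divergent_pair <- function(op1, op2, window) {
  if (attr(op1, "contig") != attr(op2, "contig")) return(FALSE)
  if (attr(op1, "strand") == attr(op2, "strand")) return(FALSE)
  s1 <- op_span(op1); s2 <- op_span(op2)
  left <- if (s1[1] <= s2[1]) op1 else op2
  right <- if (s1[1] <= s2[1]) op2 else op1
  if (attr(left, "strand") != "-" || attr(right, "strand") != "+") return(FALSE)
  gap <- op_span(right)[1] - op_span(left)[2]
  gap >= 0 && gap <= window
}

#' Classify the csg operon architecture of a genome
#'
#' Matches the operon layout of the csg gene cluster against the recurring
#' architecture classes seen across curli-positive bacteria:
#' \describe{
#'   \item{divergent_two_operon}{csgBA(C)-like and csgDEFG-like operons
#'     transcribed away from a shared intergenic region (the E. coli /
#'     Salmonella layout).}
#'   \item{co_oriented_two_operon}{the same two operons, but transcribed in
#'     the same direction.}
#'   \item{divergent_csgD_detached}{csgD alone as its own transcription
#'     unit, divergent from the csgEFG operon, with the subunit operon
#'     separate.}
#'   \item{single_operon_csgD_divergent}{one operon carrying the subunit and
#'     accessory genes (csgBAEFG-like) with csgD divergently oriented next to
#'     it.}
#'   \item{single_operon}{all csg genes in one operon.}
#'   \item{other}{anything else.}
#' }
#'
#' @param operons Operon list from [call_operons()]; member genes carry csg
#'   labels in their `label` column.
#' @param divergence_window Maximum distance in bp between the proximal ends
#'   of two divergently transcribed operons (default 1000).
#' @return List of class `architecture_call`: `class`, `csgD_location`
#'   (`"in_operon"`, `"detached"`, `"absent"`), and `operons` (the csg-bearing
#'   operons).
#' @export
classify_architecture <- function(operons, divergence_window = 1000) {
  keep <- vapply(operons, function(op) length(op_labels(op)) > 0, TRUE)
  csg_ops <- operons[keep]
  if (length(csg_ops) == 0) stop("no csg-labelled genes in any operon")
  # a lone accessory gene in its own operon (no subunit, no csgD) does not
  # define a layout; ignore such singletons when other csg operons exist
  if (length(csg_ops) > 1) {
    singleton <- vapply(csg_ops, function(op) {
      l <- op_labels(op)
      length(l) == 1 && !is_ab_label(l) && l != "csgD"
    }, TRUE)
    if (any(!singleton)) csg_ops <- csg_ops[!singleton]
  }
  labs <- lapply(csg_ops, op_labels)
  all_labs <- unlist(labs)
  has_d <- "csgD" %in% all_labs
  d_only <- vapply(labs, function(l) length(l) > 0 && all(l == "csgD"), TRUE)
  csgD_location <- if (!has_d) "absent" else if (any(d_only)) "detached" else "in_operon"
  ab_op <- vapply(labs, function(l) any(is_ab_label(l)), TRUE)
  efg_op <- vapply(labs, function(l) any(l %in% c("csgE", "csgF", "csgG")), TRUE)
  n <- length(csg_ops)
  cls <- "other"
  if (n == 1) {
    cls <- "single_operon"
  } else if (n == 2 && any(d_only)) {
    dop <- csg_ops[[which(d_only)]]
    main <- csg_ops[[which(!d_only)]]
    if (any(is_ab_label(op_labels(main))) &&
        any(op_labels(main) %in% c("csgE", "csgF", "csgG")) &&
        is_divergent_pair(dop, main, divergence_window)) {
      cls <- "single_operon_csgD_divergent"
    }
  } else if (n == 2 && sum(ab_op) == 1 && sum(efg_op & !ab_op) == 1) {
    o1 <- csg_ops[[which(ab_op)]]
    o2 <- csg_ops[[which(efg_op & !ab_op)]]
    if (attr(o1, "strand") == attr(o2, "strand")) {
      cls <- "co_oriented_two_operon"
    } else if (is_divergent_pair(o1, o2, divergence_window)) {
      cls <- "divergent_two_operon"
    }
  } else if (n == 3 && any(d_only)) {
    dop <- csg_ops[[which(d_only)[1]]]
    efg_idx <- which(efg_op & !d_only)
    if (length(efg_idx) == 1 &&
        is_divergent_pair(dop, csg_ops[[efg_idx]], divergence_window)) {
      cls <- "divergent_csgD_detached"
    }
  }
  structure(list(class = cls, csgD_location = csgD_location,
                 operons = csg_ops),
            class = "architecture_call")
}

#' Gene-content profile of one genome
#'
#' Presence flags for each csg gene family plus the csgA/B paralog count.
#' csgA, csgB and the ambiguous csgA/B label all count towards the `csgAB`
#' flag and the paralog count.
#'
#' @param labels Character vector of csg family labels called in one genome
#'   (possibly empty; NAs ignored).
#' @param taxon Optional taxon name carried through to the output.
#' @return One-row data frame: `taxon`, logical flags `csgAB`, `csgC` ..
#'   `csgH`, and `n_csgAB_paralogs`.
#' @export
content_profile <- function(labels, taxon = NA_character_) {
  labels <- labels[!is.na(labels)]
  data.frame(taxon = taxon,
             csgAB = any(is_ab_label(labels)),
             csgC = "csgC" %in% labels,
             csgD = "csgD" %in% labels,
             csgE = "csgE" %in% labels,
             csgF = "csgF" %in% labels,
             csgG = "csgG" %in% labels,
             csgH = "csgH" %in% labels,
             n_csgAB_paralogs = sum(is_ab_label(labels)),
             stringsAsFactors = FALSE)
}

#' Is csgH adjacent to a csgA/B gene?
#'
#' In csgH-carrying genomes the gene sits next to the subunit gene; this
#' checks whether any csgH gene lies within `window` genes (gene-order
#' distance on the same contig) of a csgA/B gene.
#'
#' @param features Labelled feature data frame for one genome.
#' @param window Gene-order window (default 3).
#' @return `TRUE`/`FALSE`, or `NA` when the genome has no csgH gene
#'   (not applicable).
#' @export
csgH_adjacency <- function(features, window = 3) {
  check_features(features)
  h <- which(!is.na(features$label) & features$label == "csgH")
  if (length(h) == 0) return(NA)
  ok <- FALSE
  for (ctg in unique(features$contig[h])) {
    sub <- features[features$contig == ctg, ]
    sub <- sub[order(sub$start), ]
    hi <- which(!is.na(sub$label) & sub$label == "csgH")
    abi <- which(!is.na(sub$label) & is_ab_label(sub$label))
    if (length(abi) > 0 &&
        any(outer(hi, abi, function(a, b) abs(a - b)) <= window)) {
      ok <- TRUE
    }
  }
  ok
}

#' Assign CsgA/CsgB roles to the repeat genes of an operon
#'
#' CsgA (major subunit) and CsgB (nucleator) can only be told apart inside
#' the Gammaproteobacteria, where the operon layout is csgBA(C)-like: the
#' repeat gene proximal to the operon's transcription start is the nucleator
#' csgB and the next one csgA.  Everywhere else the genes are reported with
#' the ambiguous label `csgA/B`.
#'
#' @param operon One operon (feature data frame from [call_operons()]).
#' @param repeat_ids `locus_id`s of the operon's repeat-bearing genes.
#' @param taxon_class Taxonomic class of the genome (role assignment only
#'   happens for `"Gammaproteobacteria"`).
#' @return Data frame `locus_id`, `role`, `low_confidence` for the repeat
#'   genes in transcription order.
#' @export
assign_csgAB_roles <- function(operon, repeat_ids,
                               taxon_class = "unknown") {
  ord <- order(operon$start)
  if (attr(operon, "strand") == "-") ord <- rev(ord)  # transcription order
  genes <- operon$locus_id[ord]
  rep_genes <- genes[genes %in% repeat_ids]
  if (length(rep_genes) == 0) stop("operon contains no repeat-bearing gene")
  if (identical(taxon_class, "Gammaproteobacteria") && length(rep_genes) >= 2) {
    role <- c("csgB", "csgA", rep("csgA/B", length(rep_genes) - 2))
    low <- rep(FALSE, length(rep_genes))
  } else {
    role <- rep("csgA/B", length(rep_genes))
    low <- rep(identical(taxon_class, "Gammaproteobacteria"),
               length(rep_genes))
  }
  data.frame(locus_id = rep_genes, role = role, low_confidence = low,
             stringsAsFactors = FALSE)
}
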