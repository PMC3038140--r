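# Marker curation: gene-identity evidence between marker pairs, the
# redundant-vs-paralog distinction based on map distance, annotation
# acceptance thresholds, and GO level-3 category summaries.
#
# Evidence codes follow the single-letter convention: B = derived from the
# same cDNA clone, A = same UniGene cluster ID, C = near-identical sequence
# alignment (>= 99% identity over > 185 bp, applicable only when one marker
# of the pair is a non-P. taeda EST or a genomic sequence).

.aln_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

.nz <- function(x) !is.na(x) & nzchar(as.character(x))

#' Gene-identity evidence between two annotated markers
#'
#' @param a,b One-row data frames (or lists) with fields `marker`,
#'   `clone_id`, `unigene_id`, `species`, `marker_type`.
#' @param aln Optional alignment summary for the pair: a list or one-row
#'   data frame with `percent_identity`, `span_bp` and optionally `kind`
#'   (`"nucleotide"` assumed).
#' @param taeda_species Species string counting as the focal species
#'   (default `"Pinus taeda"`).
#' @return `"B"`, `"A"`, `"C"` (precedence B > A > C) or `NA_character_`
#'   when the pair shares no gene-identity evidence.
#' @export
shared_gene_evidence <- function(a, b, aln = NULL,
                                 taeda_species = "Pinus taeda") {
  a <- as.list(a); b <- as.list(b)
  if (.nz(a$clone_id) && .nz(b$clone_id) && a$clone_id == b$clone_id)
    return("B")
  if (.nz(a$unigene_id) && .nz(b$unigene_id) &&
      a$unigene_id == b$unigene_id)
    return("A")
  if (!is.null(aln)) {
    aln <- as.list(aln)
    kind_ok <- is.null(aln$kind) || identical(aln$kind, "nucleotide")
    restriction <- isTRUE(a$species != taeda_species) ||
      isTRUE(b$species != taeda_species) ||
      isTRUE(a$marker_type == "genomic-SSR") ||
      isTRUE(b$marker_type == "genomic-SSR")
    if (kind_ok && isTRUE(aln$percent_identity >= 99) &&
        isTRUE(aln$span_bp > 185) && restriction)
      return("C")
  }
  NA_character_
}

#' Classify a mapped marker pair as redundant, paralog or independent
#'
#' Two markers with shared gene-identity evidence assay the same locus
#' (redundant) when they map to the same linkage group within
#' `threshold` cM, and paralogous loci when they map farther apart or to
#' different groups. Without evidence the pair is independent.
#'
#' @param evidence Evidence code from [shared_gene_evidence()] (`NA` for
#'   none).
#' @param lg_a,pos_a,lg_b,pos_b Linkage group and cM position of each
#'   marker (`NA` position or group = unmapped, an error).
#' @param threshold Redundancy distance threshold in cM (default 3;
#'   "within" is read inclusively, so redundant requires distance <=
#'   threshold and paralog requires > threshold or different groups).
#' @return A list: `status` (`"redundant"`, `"paralog"` or
#'   `"independent"`), `distance_cM` (`Inf` for cross-group pairs) and
#'   `evidence`.
#' @export
classify_pair <- function(evidence, lg_a, pos_a, lg_b, pos_b,
                          threshold = 3) {
  if (is.na(lg_a) || is.na(lg_b) || is.na(pos_a) || is.na(pos_b))
    stop("both markers must be mapped", call. = FALSE)
  same_lg <- as.character(lg_a) == as.character(lg_b)
  d <- if (same_lg) abs(pos_a - pos_b) else Inf
  status <- if (is.na(evidence)) "independent"
  else if (same_lg && d <= threshold) "redundant"
  else "paralog"
  list(status = status, distance_cM = d, evidence = evidence)
}

#' Redundancy / paralogy calls over all mapped marker pairs
#'
#' Evaluates [shared_gene_evidence()] and [classify_pair()] for every pair
#' of mapped annotated markers and returns the evidence-positive pairs.
#'
#' @param annotations Data frame with columns `marker`, `clone_id`,
#'   `unigene_id`, `species`, `marker_type` (missing values as `NA` or
#'   `""`).
#' @param map Data frame (or [genetic_map()]) with columns `lg`, `marker`,
#'   `pos`; unmapped annotated markers are ignored.
#' @param alignments Optional data frame with columns `marker_a`,
#'   `marker_b`, `percent_identity`, `span_bp` and optionally `kind`.
#' @param threshold Redundancy distance threshold in cM.
#' @param taeda_species Focal species string (see
#'   [shared_gene_evidence()]).
#' @return Data frame with one row per evidence-positive pair: `marker_a`,
#'   `marker_b`, `evidence`, `lg_a`, `pos_a`, `lg_b`, `pos_b`,
#'   `distance_cM`, `status`.
#' @export
call_redundancy <- function(annotations, map, alignments = NULL,
                            threshold = 3, taeda_species = "Pinus taeda") {
  ann <- annotations[annotations$marker %in% map$marker, , drop = FALSE]
  n <- nrow(ann)
  empty <- data.frame(marker_a = character(), marker_b = character(),
                      evidence = character(), lg_a = character(),
                      pos_a = numeric(), lg_b = character(),
                      pos_b = numeric(), distance_cM = numeric(),
                      status = character(), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  idx <- utils::combn(n, 2L)
  ia <- idx[1L, ]; ib <- idx[2L, ]
  blank2na <- function(x) {
    x <- as.character(x); x[!.nz(x)] <- NA_character_; x
  }
  clone <- blank2na(ann$clone_id)
  uni <- blank2na(ann$unigene_id)
  ev <- rep(NA_character_, length(ia))
  ev[!is.na(uni[ia]) & !is.na(uni[ib]) & uni[ia] == uni[ib]] <- "A"
  ev[!is.na(clone[ia]) & !is.na(clone[ib]) & clone[ia] == clone[ib]] <- "B"
  if (!is.null(alignments) && nrow(alignments)) {
    aln <- alignments
    if (is.null(aln$kind)) aln$kind <- "nucleotide"
    good <- aln[aln$kind == "nucleotide" & aln$percent_identity >= 99 &
                  aln$span_bp > 185, , drop = FALSE]
    if (nrow(good)) {
      key <- .aln_key(good$marker_a, good$marker_b)
      pair_key <- .aln_key(ann$marker[ia], ann$marker[ib])
      foreign <- (!is.na(ann$species[ia]) &
                    ann$species[ia] != taeda_species) |
        (!is.na(ann$species[ib]) & ann$species[ib] != taeda_species) |
        ann$marker_type[ia] %in% "genomic-SSR" |
        ann$marker_type[ib] %in% "genomic-SSR"
      hit <- pair_key %in% key & foreign & is.na(ev)
      ev[hit] <- "C"
    }
  }
  keep <- !is.na(ev)
  if (!any(keep)) return(empty)
  ia <- ia[keep]; ib <- ib[keep]; ev <- ev[keep]
  pos <- map$pos[match(ann$marker, map$marker)]
  lg <- as.character(map$lg[match(ann$marker, map$marker)])
  same <- lg[ia] == lg[ib]
  d <- ifelse(same, abs(pos[ia] - pos[ib]), Inf)
  res <- data.frame(marker_a = ann$marker[ia], marker_b = ann$marker[ib],
                    evidence = ev, lg_a = lg[ia], pos_a = pos[ia],
                    lg_b = lg[ib], pos_b = pos[ib], distance_cM = d,
                    status = ifelse(same & d <= threshold,
                                    "redundant", "paralog"),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Group paralogous markers into sets
#'
#' Connected components over the paralog edges of a pair-call table: each
#' component is one tentative paralog family (typically one shared UniGene
#' cluster or clone family).
#'
#' @param calls Pair-call table from [call_redundancy()] (only rows with
#'   `status == "paralog"` are used).
#' @return A list: `n_sets`, `n_markers` and `membership` (data frame with
#'   columns `marker` and `set`).
#' @export
group_paralogs <- function(calls) {
  edges <- calls[calls$status == "paralog", c("marker_a", "marker_b"),
                 drop = FALSE]
  if (!nrow(edges))
    return(list(n_sets = 0L, n_markers = 0L,
                membership = data.frame(marker = character(),
                                        set = integer(),
                                        stringsAsFactors = FALSE)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  membership <- data.frame(marker = names(comp$membership),
                           set = as.integer(comp$membership),
                           stringsAsFactors = FALSE)
  membership <- membership[order(membership$set, membership$marker), ]
  rownames(membership) <- NULL
  list(n_sets = comp$no, n_markers = nrow(membership),
       membership = membership)
}

#' Choose which member of a redundant pair to exclude
#'
#' The member with the poorer goodness-of-fit (larger chi-square
#' contribution to its ordered group) is dropped; ties are broken
#' lexicographically on the marker name.
#'
#' @param marker_a,marker_b Marker ids of the redundant pair.
#' @param fit_a,fit_b Per-marker chi-square contributions (`NA` =
#'   unavailable).
#' @return A list: `drop` (marker id or `NA`), `tie` (logical),
#'   `unresolved` (`TRUE` when a fit statistic is missing).
#' @export
choose_redundant_drop <- function(marker_a, marker_b, fit_a, fit_b) {
  if (is.na(fit_a) || is.na(fit_b))
    return(list(drop = NA_character_, tie = FALSE, unresolved = TRUE))
  if (fit_a > fit_b)
    return(list(drop = marker_a, tie = FALSE, unresolved = FALSE))
  if (fit_b > fit_a)
    return(list(drop = marker_b, tie = FALSE, unresolved = FALSE))
  list(drop = min(marker_a, marker_b), tie = TRUE, unresolved = FALSE)
}

#' Acceptance rule for a UniGene cluster assignment
#'
#' A BLASTn hit supports assigning a marker to a transcript cluster when the
#' alignment identity exceeds 85% and the alignment spans at least 220
#' nucleotides.
#'
#' @param percent_identity Alignment identity in percent.
#' @param span_bp Alignment span in nucleotides.
#' @return Logical vector.
#' @examples
#' accept_unigene_assignment(c(86, 85, 99), c(220, 500, 100))
#' @export
accept_unigene_assignment <- function(percent_identity, span_bp) {
  percent_identity > 85 & span_bp >= 220
}

#' Acceptance rule for a reference-protein assignment
#'
#' A protein alignment supports a reference-protein (and hence GO)
#' assignment when amino acid identity exceeds 45% and the alignment spans
#' more than 45% of the marker's translated amino acid length.
#'
#' @param percent_identity Amino acid identity in percent.
#' @param span_aa Alignment span in amino acids.
#' @param query_aa_len Length of the marker's translated sequence in amino
#'   acids.
#' @return Logical vector.
#' @export
accept_refprotein_assignment <- function(percent_identity, span_aa,
                                         query_aa_len) {
  percent_identity > 45 & span_aa > 0.45 * query_aa_len
}

#' Summary of GO level-3 functional categories
#'
#' Percentages of functional GO assignments per level-3 category (level 1
#' of the lineage being the ontology root 'all'). Markers carrying only the
#' `"molecular_function"` stub, or no GO term, are excluded from the
#' functional percentages; a functional term without a recorded level-3
#' lineage raises a per-marker warning.
#'
#' @param annotations Data frame with columns `marker`, `go_term` and
#'   `go_level3` (the standardized level-3 ancestor category).
#' @param stub GO term treated as a non-functional stub assignment.
#' @return Data frame with columns `category`, `n` and `percent`, sorted by
#'   decreasing `n`; zero rows when no functional assignment exists.
#' @export
go_level_summary <- function(annotations, stub = "molecular_function") {
  need <- c("marker", "go_term", "go_level3")
  if (!all(need %in% names(annotations)))
    stop("annotations needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  functional <- annotations[.nz(annotations$go_term) &
                              annotations$go_term != stub, , drop = FALSE]
  nolin <- !.nz(functional$go_level3)
  if (any(nolin)) {
    warning("functional GO term without level-3 lineage for marker(s): ",
            paste(functional$marker[nolin], collapse = ", "),
            call. = FALSE)
    functional <- functional[!nolin, , drop = FALSE]
  }
  if (!nrow(functional))
    return(data.frame(category = character(), n = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  tab <- table(functional$go_level3)
  res <- data.frame(category = names(tab), n = as.integer(tab),
                    percent = 100 * as.integer(tab) / nrow(functional),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$n, res$category), ]
  rownames(res) <- NULL
  res
}
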