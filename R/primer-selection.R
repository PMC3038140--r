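# Size-distributed primer-pair selection.
#
# One pair is kept per SSR-containing sequence, chosen from ranked design
# candidates so that dinucleotide-SSR amplicons preferentially fall in
# 100-299 bp while longer-motif amplicons preferentially exceed 299 bp.
# Distributing amplicon sizes this way lets markers of different classes be
# multiplexed in one genotyping assay without overlapping allele ranges.

#' Primer design parameter set
#'
#' The primer design configuration carried as metadata alongside candidate
#' lists (the design engine itself is external). Defaults: primer size
#' 18/20/24 nt (min/opt/max), GC 20-80%, Tm 56/60/64 C, 3' complementarity
#' 3 nt, any complementarity 8 nt, amplicon 100-500 bp.
#'
#' @param primer_size `c(min, opt, max)` primer length in nt.
#' @param gc_percent `c(min, max)` GC content in percent.
#' @param tm `c(min, opt, max)` melting temperature in degrees C.
#' @param end_complementarity 3'-end self-complementarity limit in nt.
#' @param any_complementarity Any-position self-complementarity limit in nt.
#' @param amplicon `c(min, max)` product size in bp.
#' @return A list of class `primer_design_config`.
#' @export
primer_design_config <- function(primer_size = c(18, 20, 24),
                                 gc_percent = c(20, 80),
                                 tm = c(56, 60, 64),
                                 end_complementarity = 3,
                                 any_complementarity = 8,
                                 amplicon = c(100, 500)) {
  structure(list(primer_size = primer_size, gc_percent = gc_percent,
                 tm = tm, end_complementarity = end_complementarity,
                 any_complementarity = any_complementarity,
                 amplicon = amplicon),
            class = "primer_design_config")
}

.check_candidates <- function(candidates) {
  need <- c("pair_quality", "amplicon_len")
  miss <- setdiff(need, names(candidates))
  if (length(miss))
    stop("candidate table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(candidates$flanks_target)) candidates$flanks_target <- TRUE
  if (is.null(candidates$pair_id))
    candidates$pair_id <- as.character(seq_len(nrow(candidates)))
  if (any(!is.finite(candidates$pair_quality)))
    stop("pair_quality must be finite", call. = FALSE)
  candidates
}

#' Select one primer pair for an SSR locus
#'
#' Applies the size-distributed selection rule to a set of design candidates
#' for one sequence. Candidates not flanking the intended SSR are discarded
#' first. For dinucleotide SSRs (`unit_len == 2`) the best-quality (lowest
#' penalty) pair with an amplicon of 100-299 bp is chosen; if no candidate
#' falls in that window, the pair with the shortest amplicon above 299 bp.
#' For longer motifs (`unit_len >= 3`) the best-quality pair with an amplicon
#' above 299 bp is chosen; failing that, the pair with the longest amplicon
#' of at most 299 bp. Quality ties are broken by shorter amplicon, then by
#' `pair_id`.
#'
#' @param candidates Data frame with columns `pair_quality` (penalty, lower
#'   is better), `amplicon_len` (bp) and optionally `flanks_target`
#'   (logical) and `pair_id`.
#' @param unit_len Repeat unit length of the target SSR (2-6).
#' @return The selected candidate as a one-row data frame, or `NULL` when no
#'   flanking candidate is selectable.
#' @examples
#' cand <- data.frame(pair_quality = c(0.10, 0.20),
#'                    amplicon_len = c(350, 250))
#' select_primer_pair(cand, unit_len = 2)  # the 250 bp pair
#' @export
select_primer_pair <- function(candidates, unit_len) {
  if (length(unit_len) != 1L || is.na(unit_len) || !(unit_len %in% 2:6))
    stop("unit_len must be a single value in 2..6", call. = FALSE)
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  candidates <- .check_candidates(candidates)
  cand <- candidates[candidates$flanks_target %in% TRUE, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  pick <- function(d, ord) d[ord, , drop = FALSE][1L, , drop = FALSE]
  amp <- cand$amplicon_len
  if (unit_len == 2L) {
    inwin <- cand[amp >= 100 & amp <= 299, , drop = FALSE]
    if (nrow(inwin))
      return(pick(inwin, order(inwin$pair_quality, inwin$amplicon_len,
                               inwin$pair_id)))
    over <- cand[amp > 299, , drop = FALSE]
    if (nrow(over))
      return(pick(over, order(over$amplicon_len, over$pair_quality,
                              over$pair_id)))
    return(NULL)
  }
  over <- cand[amp > 299, , drop = FALSE]
  if (nrow(over))
    return(pick(over, order(over$pair_quality, over$amplicon_len,
                            over$pair_id)))
  # "less than 299" read as <= 299 so a 299 bp amplicon is not unselectable
  under <- cand[amp <= 299, , drop = FALSE]
  if (nrow(under))
    return(pick(under, order(-under$amplicon_len, under$pair_quality,
                             under$pair_id)))
  NULL
}

#' Select primer pairs for many sequences
#'
#' Runs [select_primer_pair()] once per `seq_id`, looking up each sequence's
#' target SSR unit length in `ssr_table` (the first locus per sequence, in
#' table order, is the design target).
#'
#' @param candidates Data frame of all candidates with a `seq_id` column plus
#'   the columns required by [select_primer_pair()].
#' @param ssr_table Data frame with columns `seq_id` and `unit_len`, e.g.
#'   from [scan_ssrs()].
#' @return A data frame with one row per `seq_id` in `candidates`: `seq_id`,
#'   `status` (`"selected"`, `"no_flanking"`, or `"missing_unit_len"`),
#'   `pair_id`, `pair_quality`, `amplicon_len` (NA unless selected).
#' @export
batch_select <- function(candidates, ssr_table) {
  if (is.null(candidates$seq_id))
    stop("candidates need a seq_id column", call. = FALSE)
  if (is.null(ssr_table$seq_id) || is.null(ssr_table$unit_len))
    stop("ssr_table needs seq_id and unit_len columns", call. = FALSE)
  unit_of <- ssr_table$unit_len[!duplicated(ssr_table$seq_id)]
  names(unit_of) <- ssr_table$seq_id[!duplicated(ssr_table$seq_id)]
  ids <- unique(candidates$seq_id)
  rows <- lapply(ids, function(id) {
    base <- data.frame(seq_id = id, status = NA_character_,
                       pair_id = NA_character_, pair_quality = NA_real_,
                       amplicon_len = NA_real_, stringsAsFactors = FALSE)
    if (!id %in% names(unit_of)) {
      base$status <- "missing_unit_len"
      return(base)
    }
    sel <- select_primer_pair(
      candidates[candidates$seq_id == id, , drop = FALSE],
      unit_len = unit_of[[id]])
    if (is.null(sel)) {
      base$status <- "no_flanking"
      return(base)
    }
    base$status <- "selected"
    base$pair_id <- as.character(sel$pair_id)
    base$pair_quality <- sel$pair_quality
    base$amplicon_len <- sel$amplicon_len
    base
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
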