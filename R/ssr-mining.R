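# Perfect-SSR detection with canonical motif normalisation.
#
# A locus is a maximal uninterrupted (perfect) run of a period-minimal
# 2-6 bp unit that meets its class-specific minimum length in bp. Compound
# repeats (adjacent distinct units) and imperfect repeats (runs separated
# by an interrupting base) are reported as separate loci.

.SSR_ALPHABET <- c("A", "C", "G", "T")

#' Minimum run lengths for SSR detection
#'
#' Builds the table of minimum tandem-run lengths (in bp) that a perfect
#' repeat of a given unit length must reach to be reported. The defaults are
#' the classical enrichment-panel criteria: dinucleotides 12 bp,
#' trinucleotides 15 bp, tetranucleotides 16 bp, pentanucleotides 20 bp and
#' hexanucleotides 24 bp.
#'
#' @param min_di,min_tri,min_tetra,min_penta,min_hexa Minimum run length in
#'   bp for unit lengths 2 through 6.
#' @return A named integer vector with names `"2"` to `"6"`.
#' @examples
#' ssr_criteria()
#' ssr_criteria(min_di = 14)
#' @export
ssr_criteria <- function(min_di = 12L, min_tri = 15L, min_tetra = 16L,
                         min_penta = 20L, min_hexa = 24L) {
  v <- c(`2` = min_di, `3` = min_tri, `4` = min_tetra,
         `5` = min_penta, `6` = min_hexa)
  if (any(is.na(v)) || any(v != round(v)))
    stop("minimum run lengths must be whole numbers of bp", call. = FALSE)
  v <- as.integer(round(v))
  names(v) <- as.character(2:6)
  # a reported locus must contain at least two full units
  if (any(v < 2L * (2:6)))
    stop("each minimum run length must cover at least two repeat units",
         call. = FALSE)
  v
}

.check_motif <- function(motif, max_len = 6L) {
  if (!is.character(motif) || anyNA(motif))
    stop("motif must be a character vector without NA", call. = FALSE)
  n <- nchar(motif)
  if (any(n < 1L) || any(n > max_len))
    stop("motif length must be between 1 and ", max_len, call. = FALSE)
  bad <- grepl("[^ACGT]", motif)
  if (any(bad))
    stop("invalid motif (non-ACGT character): ",
         paste(motif[bad], collapse = ", "), call. = FALSE)
  invisible(motif)
}

.revcomp_chr <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

.rotations <- function(x) {
  k <- nchar(x)
  vapply(seq_len(k),
         function(i) paste0(substr(x, i, k), substr(x, 1, i - 1L)),
         character(1))
}

#' Canonical (alphabetically minimum) form of a repeat motif
#'
#' All cyclic rotations of a repeat unit, and all rotations of its reverse
#' complement, describe the same tandem repeat; e.g. (TAA)n, (ATA)n, (AAT)n
#' and their reverse complements (TTA)n, (TAT)n, (ATT)n are all one motif
#' class. The canonical representative is the lexicographically smallest of
#' those strings, so e.g. `canonical_motif("TAA")` is `"AAT"` and
#' `canonical_motif("GT")` is `"AC"`.
#'
#' @param motif Character vector of repeat units (1-6 bp, ACGT only).
#' @return Character vector of canonical motifs, same length as `motif`.
#' @examples
#' canonical_motif(c("TAA", "GT", "AC"))
#' @export
canonical_motif <- function(motif) {
  .check_motif(motif)
  vapply(motif, function(m) {
    min(c(.rotations(m), .rotations(.revcomp_chr(m))))
  }, character(1), USE.NAMES = FALSE)
}

#' Is a motif period-minimal?
#'
#' A unit is period-minimal when it is not a whole-number repetition of a
#' shorter unit. A perfect (AT)n stretch would otherwise also be reported as
#' (ATAT)n and (ATATAT)n; restricting reporting to period-minimal units keeps
#' each physical repeat in exactly one motif class.
#'
#' @param motif Character vector of repeat units (1-6 bp, ACGT only).
#' @return Logical vector.
#' @examples
#' is_period_minimal(c("ATAT", "AAT", "ATATAT"))
#' @export
is_period_minimal <- function(motif) {
  .check_motif(motif)
  vapply(motif, function(m) {
    k <- nchar(m)
    if (k == 1L) return(TRUE)
    divs <- seq_len(k - 1L)
    divs <- divs[k %% divs == 0L]
    !any(vapply(divs, function(d) {
      strrep(substr(m, 1L, d), k %/% d) == m
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

.as_dna_string <- function(seq) {
  if (inherits(seq, "DNAString")) seq <- as.character(seq)
  if (inherits(seq, "DNAStringSet")) {
    if (length(seq) != 1L)
      stop("expected a single sequence", call. = FALSE)
    seq <- as.character(seq[[1L]])
  }
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("seq must be a single DNA string", call. = FALSE)
  toupper(seq)
}

.empty_ssr_table <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
              motif = character(), canonical_motif = character(),
              unit_len = integer(), repeat_count = integer(),
              length_bp = integer(), stringsAsFactors = FALSE)
}

#' Find perfect SSRs in one sequence
#'
#' Scans the forward strand of a DNA sequence for maximal perfect tandem
#' repeats of period-minimal 2-6 bp units meeting the bp thresholds in
#' `criteria`. Only uninterrupted runs are counted: compound repeats such as
#' (TC)8(TA)6 yield two loci, as do interrupted repeats such as (TA)21 G
#' (AT)6. Trailing partial units are trimmed, any non-ACGT character (N,
#' ambiguity codes) terminates a run, and mononucleotide runs are never
#' reported. Reverse-strand scanning is redundant because motifs are also
#' reported in canonical form.
#'
#' @param seq A DNA string (character scalar or [Biostrings::DNAString]);
#'   lowercase is accepted and uppercased.
#' @param seq_id Identifier written into the output.
#' @param criteria Minimum run lengths, from [ssr_criteria()].
#' @return A data frame with one row per locus, columns `seq_id`, `start`,
#'   `end` (1-based inclusive), `motif` (unit as written in the sequence),
#'   `canonical_motif`, `unit_len`, `repeat_count` and `length_bp`, sorted by
#'   (`start`, `unit_len`).
#' @examples
#' find_perfect_ssrs(paste0("GGG", strrep("TC", 8), strrep("TA", 6), "GGG"))
#' @export
find_perfect_ssrs <- function(seq, seq_id = "seq", criteria = ssr_criteria()) {
  seq <- .as_dna_string(seq)
  if (!is.character(seq_id) || length(seq_id) != 1L || is.na(seq_id) ||
      !nzchar(seq_id))
    stop("seq_id must be a non-empty string", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  ok <- chars %in% .SSR_ALPHABET
  out <- vector("list", 5L)
  for (k in 2:6) {
    min_bp <- criteria[[as.character(k)]]
    if (n < min_bp) next
    idx <- seq_len(n - k)
    eq <- chars[idx] == chars[idx + k] & ok[idx] & ok[idx + k]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & (r$lengths + k >= min_bp)
    if (!any(keep)) next
    starts <- starts[keep]
    run_bp <- r$lengths[keep] + k
    count <- run_bp %/% k
    len <- count * k
    sel <- len >= min_bp
    if (!any(sel)) next
    starts <- starts[sel]; count <- count[sel]; len <- len[sel]
    unit <- substring(seq, starts, starts + k - 1L)
    minimal <- is_period_minimal(unit)
    if (!any(minimal)) next
    starts <- starts[minimal]; count <- count[minimal]
    len <- len[minimal]; unit <- unit[minimal]
    out[[k - 1L]] <- data.frame(
      seq_id = seq_id, start = starts, end = starts + len - 1L,
      motif = unit, canonical_motif = canonical_motif(unit),
      unit_len = as.integer(k), repeat_count = as.integer(count),
      length_bp = as.integer(len), stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.empty_ssr_table())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$unit_len), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.as_named_seqs <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    seqs <- as.character(x)
    if (is.null(names(seqs)))
      names(seqs) <- paste0("seq", seq_along(seqs))
    return(seqs)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(toupper(x))
  }
  stop("sequences must be a DNAStringSet or a named character vector",
       call. = FALSE)
}

#' Scan a set of sequences for perfect SSRs
#'
#' @param x A [Biostrings::DNAStringSet] (e.g. from [read_fasta()]) or a
#'   named character vector of DNA sequences.
#' @param criteria Minimum run lengths, from [ssr_criteria()].
#' @return A data frame in the layout of [find_perfect_ssrs()], rows from all
#'   sequences combined in input order.
#' @export
scan_ssrs <- function(x, criteria = ssr_criteria()) {
  seqs <- .as_named_seqs(x)
  # FASTA headers may carry descriptions; the id is the first word
  ids <- sub("\\s.*$", "", names(seqs))
  hits <- mapply(find_perfect_ssrs, seqs, ids,
                 MoreArgs = list(criteria = criteria), SIMPLIFY = FALSE)
  res <- do.call(rbind, c(hits, list(.empty_ssr_table())))
  rownames(res) <- NULL
  res
}

#' Summarise SSR content of a sequence set
#'
#' Counts how many sequences contain at least one SSR under `criteria`,
#' tallies loci per canonical motif, and reports the SSR-positive fraction.
#'
#' @inheritParams scan_ssrs
#' @return A list with `n_sequences`, `n_with_ssr`, `fraction`
#'   (`n_with_ssr / n_sequences`), `motif_counts` (named integer vector of
#'   locus counts per canonical motif) and `loci` (the full locus table).
#' @export
summarize_ssr_content <- function(x, criteria = ssr_criteria()) {
  if (!length(x)) stop("no input sequences", call. = FALSE)
  seqs <- .as_named_seqs(x)
  loci <- scan_ssrs(seqs, criteria)
  pos <- length(unique(loci$seq_id))
  counts <- table(loci$canonical_motif)
  motif_counts <- stats::setNames(as.integer(counts), names(counts))
  list(n_sequences = length(seqs), n_with_ssr = pos,
       fraction = pos / length(seqs),
       motif_counts = motif_counts[order(names(motif_counts))],
       loci = loci)
}

#' SSR-positive fraction from summary counts
#'
#' Convenience for expressing tabulated screening results (sequences with at
#' least one SSR out of sequences screened) as a fraction.
#'
#' @param n_positive Number of SSR-positive sequences.
#' @param n_total Number of sequences screened.
#' @return `n_positive / n_total`.
#' @examples
#' ssr_positive_fraction(1485, 52911)  # ~0.028
#' @export
ssr_positive_fraction <- function(n_positive, n_total) {
  if (n_total <= 0 || n_positive < 0 || n_positive > n_total)
    stop("need 0 <= n_positive <= n_total and n_total > 0", call. = FALSE)
  n_positive / n_total
}

#' Read a multi-FASTA file of DNA sequences
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()].
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write an SSR locus table as TSV
#'
#' @param loci Locus table from [scan_ssrs()] or [find_perfect_ssrs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ssr_table <- function(loci, path) {
  utils::write.table(loci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
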