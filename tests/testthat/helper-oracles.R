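# Independent oracles used to cross-check the package implementations.
# These deliberately use different mechanisms from the package code paths.

# --- brute-force SSR oracle -------------------------------------------------
# Enumerates, via zero-width lookahead regexes, the greedy perfect tandem run
# starting at every position for every unit length, keeps the left-maximal
# ones (no single-base extension of the same period to the left), and filters
# by period-minimality and the bp thresholds.

oracle_minimal <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && strrep(substr(unit, 1L, d), k / d) == unit)
      return(FALSE)
  }
  TRUE
}

oracle_ssr_scan <- function(seq, criteria = ssr_criteria()) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  acgt <- chars %in% c("A", "C", "G", "T")
  rows <- list()
  for (k in 2:6) {
    pat <- sprintf("(?=(([ACGT]{%d})\\2+))", k)
    m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    cs <- attr(m, "capture.start")[, 1L]
    cl <- attr(m, "capture.length")[, 1L]
    # left-maximal: position i-1 must not continue the same period
    prev_ok <- cs == 1L |
      !(acgt[pmax(cs - 1L, 1L)] & acgt[pmax(cs - 1L + k, 1L)] &
          chars[pmax(cs - 1L, 1L)] == chars[pmax(cs - 1L + k, 1L)])
    unit <- substring(seq, cs, cs + k - 1L)
    keep <- prev_ok & cl >= criteria[[as.character(k)]] &
      vapply(unit, oracle_minimal, logical(1))
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = cs[keep], end = cs[keep] + cl[keep] - 1L,
      motif = unit[keep], unit_len = k,
      repeat_count = cl[keep] %/% k, length_bp = cl[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), unit_len = integer(),
                      repeat_count = integer(), length_bp = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res <- res[order(res$start, res$unit_len), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# random repeat-rich sequence: background segments interleaved with tandem
# blocks of random 1-6 bp units, plus occasional Ns
rand_repeatish <- function(len) {
  out <- character(0)
  cur <- 0L
  while (cur < len) {
    frag <- if (stats::runif(1) < 0.3) {
      k <- sample(1:6, 1L)
      unit <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                    collapse = "")
      strrep(unit, sample(2:12, 1L))
    } else {
      paste(sample(c("A", "C", "G", "T", "N"), sample(20:60, 1L),
                   replace = TRUE, prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
            collapse = "")
    }
    out <- c(out, frag)
    cur <- cur + nchar(frag)
  }
  substr(paste(out, collapse = ""), 1L, len)
}

ssr_key <- function(d) {
  paste(d$start, d$end, d$motif, d$unit_len, d$repeat_count, sep = "|")
}

# --- primer-selection rule oracle -------------------------------------------
# Literal, candidate-by-candidate evaluation of the size-distributed
# selection sentences; assumes distinct qualities and amplicon lengths so
# tie-break rules never engage.

oracle_select <- function(cand, unit_len) {
  cand <- cand[cand$flanks_target, , drop = FALSE]
  if (!nrow(cand)) return(NA_character_)
  amp <- cand$amplicon_len
  if (unit_len == 2) {
    win <- cand[amp >= 100 & amp <= 299, , drop = FALSE]
    if (nrow(win)) return(win$pair_id[which.min(win$pair_quality)])
    over <- cand[amp > 299, , drop = FALSE]
    if (nrow(over)) return(over$pair_id[which.min(over$amplicon_len)])
    return(NA_character_)
  }
  over <- cand[amp > 299, , drop = FALSE]
  if (nrow(over)) return(over$pair_id[which.min(over$pair_quality)])
  under <- cand[amp <= 299, , drop = FALSE]
  if (nrow(under)) return(under$pair_id[which.max(under$amplicon_len)])
  NA_character_
}

rand_candidate_set <- function(n, seq_id = "s") {
  data.frame(seq_id = seq_id,
             pair_id = sprintf("%s_p%d", seq_id, seq_len(n)),
             pair_quality = round(sample(seq(0.01, 5, by = 0.01), n), 2),
             amplicon_len = sample(100:500, n),
             flanks_target = stats::runif(n) < 0.8,
             stringsAsFactors = FALSE)
}
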