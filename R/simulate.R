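# Seeded simulators producing inputs with the statistical structure each
# analysis stage assumes, plus machine-readable truth tables, so the whole
# pipeline is testable without external data. All outputs are synthetic
# stand-ins for the field data they emulate: a diversity panel of unrelated
# individuals, CP full-sib segregation matrices, a 12-linkage-group map,
# and marker annotation tables with planted redundant pairs and paralog
# families. Every generator is reproducible from its `seed`.

# Motifs historically targeted by SSR enrichment libraries; all are
# period-minimal and in canonical form.
.ENRICHMENT_MOTIFS <- c("AC", "AAC", "AAG", "AAT", "ACC", "ACG", "AGG",
                        "ATC", "AAAC", "AAAT", "AGAT")

# Realistic relative linkage-group sizes for a 12-chromosome conifer map;
# scaled so the observed spans total 1,429 cM.
.DEFAULT_LG_LENGTHS <- c(142, 137, 132, 128, 125, 122, 119, 116, 113,
                         109, 97, 89)

.set_seed <- function(seed) {
  if (!is.null(seed)) {
    if (length(seed) != 1L || is.na(seed)) stop("bad seed", call. = FALSE)
    set.seed(as.integer(seed))
  }
}

# Regex-based perfect-repeat scan used by the sequence generator to reject
# accidental SSRs in background sequence and to verify planted truth.
# Zero-width lookahead captures the greedy run starting at every position;
# only left-maximal starts (the preceding base does not continue the same
# period) are kept, so overlapping runs cannot shadow one another.
.regex_ssr_scan <- function(seq, criteria = ssr_criteria()) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  acgt <- chars %in% .SSR_ALPHABET
  rows <- list()
  for (k in 2:6) {
    pat <- sprintf("(?=(([ACGT]{%d})\\2+))", k)
    m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    starts <- attr(m, "capture.start")[, 1L]
    lens <- attr(m, "capture.length")[, 1L]
    prev <- pmax(starts - 1L, 1L)
    left_max <- starts == 1L |
      !(acgt[prev] & acgt[prev + k] & chars[prev] == chars[prev + k])
    unit <- substring(seq, starts, starts + k - 1L)
    keep <- left_max & lens >= criteria[[as.character(k)]] &
      is_period_minimal(unit)
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = starts[keep], end = starts[keep] + lens[keep] - 1L,
      motif = unit[keep], unit_len = k,
      repeat_count = lens[keep] %/% k, length_bp = lens[keep],
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

.random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# background with no SSR under `criteria`, by rejection
.clean_background <- function(len, criteria, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    bg <- .random_dna(len)
    if (!nrow(.regex_ssr_scan(bg, criteria))) return(bg)
  }
  stop("could not generate SSR-free background", call. = FALSE)
}

.chr1 <- function(x, i) substr(x, i, i)

# Build one insert and its truth rows (positions relative to insert start).
# Compound and imperfect inserts are constrained so junctions cannot merge
# or re-phase the planted runs.
.build_insert <- function(kind, criteria, motifs) {
  reps_for <- function(m) {
    k <- nchar(m)
    min_units <- ceiling(criteria[[as.character(k)]] / k)
    min_units + sample(0:6, 1L)
  }
  truth_row <- function(m, r, at) {
    k <- nchar(m)
    data.frame(start = at, end = at + r * k - 1L, motif = m,
               canonical_motif = canonical_motif(m), unit_len = k,
               repeat_count = r, length_bp = r * k,
               stringsAsFactors = FALSE)
  }
  if (kind == "perfect") {
    m <- sample(motifs, 1L)
    r <- reps_for(m)
    return(list(seq = strrep(m, r), truth = truth_row(m, r, 1L)))
  }
  if (kind == "compound") {
    repeat {
      mm <- sample(motifs, 2L)
      m1 <- mm[1L]; m2 <- mm[2L]
      k1 <- nchar(m1); k2 <- nchar(m2)
      block2_prefix <- substr(strrep(m2, ceiling(k1 / k2)), 1L, k1)
      ok <- block2_prefix != m1 &&                       # no run-1 growth
        .chr1(m1, k1) != .chr1(m2, k2)                   # no run-2 re-phase
      if (ok) break
    }
    r1 <- reps_for(m1); r2 <- reps_for(m2)
    return(list(seq = paste0(strrep(m1, r1), strrep(m2, r2)),
                truth = rbind(truth_row(m1, r1, 1L),
                              truth_row(m2, r2, r1 * k1 + 1L))))
  }
  if (kind == "imperfect") {
    m <- sample(motifs, 1L)
    k <- nchar(m)
    forbidden <- c(.chr1(m, 1L), .chr1(m, k), .chr1(m, max(k - 1L, 1L)))
    x <- sample(setdiff(c("A", "C", "G", "T"), forbidden), 1L)
    r1 <- reps_for(m); r2 <- reps_for(m)
    return(list(seq = paste0(strrep(m, r1), x, strrep(m, r2)),
                truth = rbind(truth_row(m, r1, 1L),
                              truth_row(m, r2, r1 * k + 2L))))
  }
  stop("unknown insert kind: ", kind, call. = FALSE)
}

#' Simulate sequences with planted SSRs
#'
#' Generates random uniform-ACGT sequences, rejection-sampled to be free of
#' accidental SSRs, and plants one perfect, compound (two adjacent distinct
#' units) or imperfect (two runs split by one interrupting base) repeat per
#' sequence. Each planted sequence is verified against an internal
#' regex-based repeat scan so that the recorded truth is exhaustive: a
#' correct scanner must recover exactly the truth rows.
#'
#' @param n_sequences Number of sequences.
#' @param seq_len Sequence length in bp.
#' @param kind Insert types to plant, sampled uniformly per sequence; any
#'   subset of `"perfect"`, `"compound"`, `"imperfect"`.
#' @param motifs Pool of repeat units to plant (canonical, period-minimal).
#' @param criteria Mining criteria the plants must satisfy.
#' @param seed Random seed.
#' @return A list: `sequences` (named character vector) and `truth` (data
#'   frame in the layout of [find_perfect_ssrs()]).
#' @export
sim_ssr_sequences <- function(n_sequences = 100, seq_len = 600,
                              kind = c("perfect", "compound", "imperfect"),
                              motifs = .ENRICHMENT_MOTIFS,
                              criteria = ssr_criteria(), seed = NULL) {
  .set_seed(seed)
  kind <- match.arg(kind, several.ok = TRUE)
  idx <- seq.int(n_sequences)
  seqs <- character(n_sequences)
  names(seqs) <- sprintf("synth%04d", idx)
  truths <- vector("list", n_sequences)
  for (i in idx) {
    done <- FALSE
    for (try in 1:50) {
      ins <- .build_insert(sample(kind, 1L), criteria, motifs)
      ilen <- nchar(ins$seq)
      if (ilen + 2L > seq_len)
        stop("seq_len too short for planted insert", call. = FALSE)
      bg <- .clean_background(seq_len, criteria)
      at <- sample(2:(seq_len - ilen), 1L)   # keep 1 bp of background flanks
      full <- paste0(substr(bg, 1L, at - 1L), ins$seq,
                     substr(bg, at + ilen, seq_len))
      truth <- ins$truth
      truth$start <- truth$start + at - 1L
      truth$end <- truth$end + at - 1L
      found <- .regex_ssr_scan(full, criteria)
      same <- nrow(found) == nrow(truth) &&
        all(found$start == truth$start) && all(found$end == truth$end) &&
        all(found$motif == truth$motif)
      if (same) {
        seqs[i] <- full
        truth <- cbind(seq_id = names(seqs)[i], truth,
                       stringsAsFactors = FALSE)
        truths[[i]] <- truth
        done <- TRUE
        break
      }
    }
    if (!done)
      stop("planting collision not resolved after 50 tries", call. = FALSE)
  }
  truth <- do.call(rbind, truths)
  truth <- truth[, c("seq_id", "start", "end", "motif", "canonical_motif",
                     "unit_len", "repeat_count", "length_bp")]
  rownames(truth) <- NULL
  list(sequences = seqs, truth = truth)
}

#' Simulate motif-free sequences
#'
#' Random uniform-ACGT sequences rejection-sampled against the internal
#' repeat scan so they contain no SSR under `criteria`.
#'
#' @inheritParams sim_ssr_sequences
#' @return Named character vector of sequences.
#' @export
sim_clean_sequences <- function(n_sequences = 100, seq_len = 600,
                                criteria = ssr_criteria(), seed = NULL) {
  .set_seed(seed)
  idx <- seq.int(n_sequences)
  seqs <- vapply(idx, function(i) .clean_background(seq_len, criteria),
                 character(1))
  names(seqs) <- sprintf("clean%04d", idx)
  seqs
}

# Allele-frequency profile with expected gene diversity (1 - sum p^2)
# exactly `target`: k alleles, one at p1 >= 1/k and the rest equifrequent.
.freq_profile <- function(target) {
  if (target <= 0) return(1)
  if (target >= 0.9) stop("diversity target too high", call. = FALSE)
  k <- ceiling(1 / (1 - target)) + 1L
  disc <- 1 - k + k * (1 - target) * (k - 1)
  p1 <- (1 + sqrt(max(disc, 0))) / k
  c(p1, rep((1 - p1) / (k - 1L), k - 1L))
}

#' Simulate a diploid SSR diversity panel
#'
#' Draws Hardy-Weinberg genotypes for a panel of unrelated diploid
#' individuals at two classes of SSR loci (transcribed EST-SSRs, anonymous
#' genomic-SSRs) whose generating allele frequencies are constructed so
#' that the expected gene diversity of each polymorphic locus is a draw
#' centred on the class target. Defaults emulate a 14-individual range-wide
#' panel with 94 polymorphic EST-SSRs (plus 8 monomorphic ones) at mean
#' diversity 0.43 and 83 polymorphic genomic-SSRs at mean 0.72.
#'
#' @param n_individuals Panel size.
#' @param n_est,n_genomic Numbers of polymorphic EST-SSR and genomic-SSR
#'   loci.
#' @param n_monomorphic_est Additional monomorphic EST-SSR loci.
#' @param he_est,he_genomic Class mean diversity targets.
#' @param he_spread Half-width of the uniform per-locus spread around the
#'   class target.
#' @param missing_rate Per-call missing probability.
#' @param seed Random seed.
#' @return A list: `genotypes` (long data frame for [locus_diversity()]),
#'   `loci` (truth: `locus`, `class`, `polymorphic`, `target_he`, `k`) and
#'   `classes` (the `locus`/`class` table).
#' @export
sim_genotype_panel <- function(n_individuals = 14, n_est = 94,
                               n_genomic = 83, n_monomorphic_est = 8,
                               he_est = 0.43, he_genomic = 0.72,
                               he_spread = 0.10, missing_rate = 0.02,
                               seed = NULL) {
  .set_seed(seed)
  loci <- data.frame(
    locus = c(sprintf("estSSR_%03d", seq_len(n_est + n_monomorphic_est)),
              sprintf("gSSR_%03d", seq_len(n_genomic))),
    class = rep(c("EST-SSR", "genomic-SSR"),
                c(n_est + n_monomorphic_est, n_genomic)),
    polymorphic = rep(c(TRUE, FALSE, TRUE),
                      c(n_est, n_monomorphic_est, n_genomic)),
    stringsAsFactors = FALSE)
  target <- ifelse(loci$class == "EST-SSR", he_est, he_genomic)
  target <- target + stats::runif(nrow(loci), -he_spread, he_spread)
  target[!loci$polymorphic] <- 0
  loci$target_he <- target
  inds <- sprintf("ind%02d", seq_len(n_individuals))
  geno <- vector("list", nrow(loci))
  ks <- integer(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    p <- .freq_profile(loci$target_he[i])
    ks[i] <- length(p)
    alleles <- seq(150, by = 2, length.out = length(p))
    a1 <- alleles[sample.int(length(p), n_individuals, replace = TRUE,
                             prob = p)]
    a2 <- alleles[sample.int(length(p), n_individuals, replace = TRUE,
                             prob = p)]
    miss <- stats::runif(n_individuals) < missing_rate
    a1[miss] <- NA; a2[miss] <- NA
    geno[[i]] <- data.frame(individual = inds, locus = loci$locus[i],
                            allele1 = a1, allele2 = a2,
                            stringsAsFactors = FALSE)
  }
  loci$k <- ks
  genotypes <- do.call(rbind, geno)
  rownames(genotypes) <- NULL
  list(genotypes = genotypes, loci = loci,
       classes = loci[, c("locus", "class")])
}

.distort_probs <- function(p, shift) {
  stopifnot(shift >= 0, shift / (length(p) - 1L) < min(p[-1L]))
  q <- p
  q[1L] <- q[1L] + shift
  q[-1L] <- q[-1L] - shift / (length(q) - 1L)
  q
}

#' Simulate CP-pedigree segregation data
#'
#' Draws per-progeny genotype classes for outbred CP full-sib markers under
#' Mendelian expectations, with optional planted segregation distortion,
#' planted high-missing progeny samples, marker-level missingness, null
#' annotation flags, and an optional duplicated-sample cohort for identity
#' matching. All planted properties are recorded in truth tables.
#'
#' @param n_markers,n_progeny Matrix dimensions.
#' @param cross_types Pool of cross configurations sampled per marker.
#' @param distorted_frac Fraction of markers planted with distortion.
#' @param distortion_shift Probability mass moved to the first genotype
#'   class of a distorted marker (e.g. 0.3 turns a 1:1 testcross into
#'   80:20).
#' @param missing_range Range of per-marker missing-call rates.
#' @param null_frac Fraction of markers annotated as segregating null
#'   alleles (a pass-through QC exclusion flag).
#' @param n_high_missing Number of progeny samples planted with exactly
#'   `high_missing_frac` missing markers.
#' @param high_missing_frac Missing fraction of the planted samples.
#' @param n_shared Samples duplicated into a second, relabelled cohort for
#'   [match_samples()] testing (0 = no cohort).
#' @param seed Random seed.
#' @return A list: `seg` (a [seg_data()]), `truth_markers` (with planted
#'   `distorted` and `null_allele` flags), `truth_samples` (planted missing
#'   fractions), and when `n_shared > 0` `cohort_b` (samples x markers call
#'   matrix with scrambled labels) plus `identity` (label -> true sample).
#' @export
sim_pedigree <- function(n_markers = 100, n_progeny = 170,
                         cross_types = names(.CP_CLASSES),
                         distorted_frac = 0, distortion_shift = 0.3,
                         missing_range = c(0, 0.05), null_frac = 0,
                         n_high_missing = 0, high_missing_frac = 0.45,
                         n_shared = 0, seed = NULL) {
  .set_seed(seed)
  mk <- sprintf("M%04d", seq_len(n_markers))
  ct <- sample(cross_types, n_markers, replace = TRUE)
  distorted <- seq_len(n_markers) %in%
    sample(n_markers, round(distorted_frac * n_markers))
  nulls <- seq_len(n_markers) %in%
    sample(n_markers, round(null_frac * n_markers))
  miss_rate <- stats::runif(n_markers, missing_range[1L], missing_range[2L])
  calls <- matrix(NA_character_, n_markers, n_progeny,
                  dimnames = list(mk, sprintf("P%03d", seq_len(n_progeny))))
  for (i in seq_len(n_markers)) {
    p <- cp_expected_ratios(ct[i])
    if (distorted[i]) p[] <- .distort_probs(as.numeric(p), distortion_shift)
    g <- sample(names(p), n_progeny, replace = TRUE, prob = p)
    g[stats::runif(n_progeny) < miss_rate[i]] <- NA
    calls[i, ] <- g
  }
  high <- character(0)
  if (n_high_missing > 0) {
    high <- sample(colnames(calls), n_high_missing)
    k_miss <- round(high_missing_frac * n_markers)
    for (s in high) calls[sample(n_markers, k_miss), s] <- NA
  }
  markers <- data.frame(marker = mk, cross_type = ct, null_allele = nulls,
                        stringsAsFactors = FALSE)
  out <- list(
    seg = seg_data(markers, calls),
    truth_markers = data.frame(marker = mk, cross_type = ct,
                               distorted = distorted, null_allele = nulls,
                               missing_rate = miss_rate,
                               stringsAsFactors = FALSE),
    truth_samples = data.frame(
      sample = colnames(calls),
      planted_high_missing = colnames(calls) %in% high,
      stringsAsFactors = FALSE))
  if (n_shared > 0) {
    shared <- sample(setdiff(colnames(calls), high), n_shared)
    prof <- t(calls[, shared, drop = FALSE])
    perm <- sample(n_shared)
    labels <- sprintf("B%03d", seq_len(n_shared))
    cohort_b <- prof[perm, , drop = FALSE]
    rownames(cohort_b) <- labels
    out$cohort_b <- cohort_b
    out$identity <- data.frame(label = labels, sample = shared[perm],
                               stringsAsFactors = FALSE)
  }
  out
}

.apportion <- function(n, weights, min_each = 2L) {
  q <- n * weights / sum(weights)
  m <- floor(q)
  need <- n - sum(m)
  if (need > 0) {
    ord <- order(-(q - m))
    m[ord[seq_len(need)]] <- m[ord[seq_len(need)]] + 1
  }
  while (any(m < min_each)) {
    i <- which.min(m); j <- which.max(m)
    m[i] <- m[i] + 1L; m[j] <- m[j] - 1L
  }
  as.integer(m)
}

#' Simulate a multi-group genetic map
#'
#' Places markers on linkage groups, either anchored (first marker at 0,
#' last at the group length, interior markers uniform — the convention of
#' reported map tables, whose spans equal the group lengths) or fully
#' uniform. Marker counts are apportioned to groups proportionally to
#' length (largest remainder). Defaults emulate a 12-group, 429-marker,
#' 1,429 cM conifer map.
#'
#' @param n_markers Total marker count.
#' @param group_lengths Linkage-group lengths in cM.
#' @param total_length Optional rescaling of `group_lengths` to this total.
#' @param placement `"anchored"` or `"uniform"`.
#' @param seed Random seed.
#' @return A list: `map` (a [genetic_map()]) and `group_lengths` /
#'   `marker_counts` (the generating truth).
#' @export
sim_genetic_map <- function(n_markers = 429,
                            group_lengths = .DEFAULT_LG_LENGTHS,
                            total_length = NULL,
                            placement = c("anchored", "uniform"),
                            seed = NULL) {
  .set_seed(seed)
  placement <- match.arg(placement)
  lens <- group_lengths
  if (!is.null(total_length)) lens <- lens * total_length / sum(lens)
  m <- .apportion(n_markers, lens)
  rows <- lapply(seq_along(lens), function(g) {
    pos <- if (placement == "anchored") {
      c(0, sort(stats::runif(m[g] - 2L, 0, lens[g])), lens[g])
    } else {
      sort(stats::runif(m[g], 0, lens[g]))
    }
    data.frame(lg = g, marker = sprintf("LG%02d_M%03d", g, seq_len(m[g])),
               pos = pos, stringsAsFactors = FALSE)
  })
  list(map = genetic_map(do.call(rbind, rows)),
       group_lengths = lens, marker_counts = m)
}

.GO_WEIGHTS <- c(
  "catalytic activity" = 0.28,
  "binding" = 0.18,
  "transporter activity" = 0.14,
  "structural molecule activity" = 0.12,
  "nucleic acid binding transcription factor activity" = 0.10,
  "oxidoreductase activity" = 0.10,
  "metabolic process" = 0.08)

#' Simulate marker annotation, map and alignment tables
#'
#' Builds an annotation table with planted redundant marker pairs (shared
#' gene evidence, mapped within `threshold` cM on one linkage group),
#' planted paralog families (shared UniGene cluster or clone, members
#' mapped to different groups or more than `threshold` cM apart), and
#' independent markers, together with the matching map positions, the
#' alignment summaries backing sequence-identity evidence, and GO level-3
#' category assignments.
#'
#' @param n_redundant Number of planted redundant pairs.
#' @param n_paralog_sets,n_paralog_markers Number of planted paralog
#'   families and total markers across them (set sizes >= 2).
#' @param n_independent Markers with no shared gene evidence.
#' @param n_lgs,lg_len Map dimensions (groups, group length in cM).
#' @param threshold Redundancy distance threshold in cM.
#' @param go_weights Named category weights for functional GO level-3
#'   assignments.
#' @param stub_frac Fraction of markers given only the
#'   `"molecular_function"` stub.
#' @param seed Random seed.
#' @return A list: `annotations`, `map`, `alignments`, and `truth` (a list
#'   with `redundant_pairs`, `paralog_membership`).
#' @export
sim_marker_annotations <- function(n_redundant = 28, n_paralog_sets = 21,
                                   n_paralog_markers = 58,
                                   n_independent = 40, n_lgs = 12,
                                   lg_len = 130, threshold = 3,
                                   go_weights = .GO_WEIGHTS,
                                   stub_frac = 0.3, seed = NULL) {
  .set_seed(seed)
  if (n_paralog_markers < 2L * n_paralog_sets)
    stop("paralog sets need at least 2 markers each", call. = FALSE)
  ann <- list(); map <- list(); aln <- list()
  red_truth <- list()
  add_ann <- function(marker, clone = NA, uni = NA,
                      species = "Pinus taeda", type = "ESTP") {
    data.frame(marker = marker, genbank_acc = NA_character_,
               clone_id = as.character(clone),
               unigene_id = as.character(uni), species = species,
               marker_type = type, stringsAsFactors = FALSE)
  }
  # planted redundant pairs
  for (i in seq_len(n_redundant)) {
    ev <- sample(c("A", "B", "C"), 1L)
    a <- sprintf("RED%02da", i); b <- sprintf("RED%02db", i)
    lg <- sample(n_lgs, 1L)
    p1 <- stats::runif(1, 0, lg_len - threshold)
    p2 <- p1 + stats::runif(1, 0, threshold)
    if (ev == "B") {
      cl <- sprintf("CL_RED%02d", i)
      ann[[length(ann) + 1L]] <- rbind(add_ann(a, clone = cl),
                                       add_ann(b, clone = cl))
    } else if (ev == "A") {
      un <- sprintf("Syn.%d", 1000L + i)
      ann[[length(ann) + 1L]] <- rbind(add_ann(a, uni = un),
                                       add_ann(b, uni = un))
    } else {
      ann[[length(ann) + 1L]] <- rbind(
        add_ann(a, type = "EST-SSR"),
        add_ann(b, type = "genomic-SSR"))
      aln[[length(aln) + 1L]] <- data.frame(
        marker_a = a, marker_b = b,
        percent_identity = stats::runif(1, 99, 100),
        span_bp = sample(186:400, 1L), kind = "nucleotide",
        stringsAsFactors = FALSE)
    }
    map[[length(map) + 1L]] <- data.frame(
      lg = c(lg, lg), marker = c(a, b), pos = c(p1, p2),
      stringsAsFactors = FALSE)
    red_truth[[length(red_truth) + 1L]] <- data.frame(
      marker_a = a, marker_b = b, evidence = ev,
      stringsAsFactors = FALSE)
  }
  # planted paralog families
  sizes <- rep(2L, n_paralog_sets)
  extra <- n_paralog_markers - sum(sizes)
  while (extra > 0) {
    i <- sample(n_paralog_sets, 1L)
    sizes[i] <- sizes[i] + 1L
    extra <- extra - 1L
  }
  para_truth <- list()
  for (s in seq_len(n_paralog_sets)) {
    members <- sprintf("PAR%02d_%d", s, seq_len(sizes[s]))
    use_clone <- stats::runif(1) < 0.5
    key <- if (use_clone) sprintf("CL_PAR%02d", s)
    else sprintf("Syn.%d", 2000L + s)
    ann[[length(ann) + 1L]] <- do.call(rbind, lapply(members, function(m) {
      if (use_clone) add_ann(m, clone = key, type = "RFLP")
      else add_ann(m, uni = key)
    }))
    lgs <- integer(0); pos <- numeric(0)
    for (j in seq_len(sizes[s])) {
      repeat {
        lg <- sample(n_lgs, 1L)
        p <- stats::runif(1, 0, lg_len)
        same <- which(lgs == lg)
        if (!length(same) || all(abs(pos[same] - p) > threshold + 0.5))
          break
      }
      lgs <- c(lgs, lg); pos <- c(pos, p)
    }
    map[[length(map) + 1L]] <- data.frame(lg = lgs, marker = members,
                                          pos = pos,
                                          stringsAsFactors = FALSE)
    para_truth[[length(para_truth) + 1L]] <- data.frame(
      marker = members, set = s, stringsAsFactors = FALSE)
  }
  # independent markers
  if (n_independent > 0) {
    ind <- sprintf("IND%03d", seq_len(n_independent))
    ann[[length(ann) + 1L]] <- do.call(rbind, lapply(
      seq_len(n_independent),
      function(i) add_ann(ind[i], uni = sprintf("Syn.%d", 3000L + i))))
    map[[length(map) + 1L]] <- data.frame(
      lg = sample(n_lgs, n_independent, replace = TRUE), marker = ind,
      pos = stats::runif(n_independent, 0, lg_len),
      stringsAsFactors = FALSE)
  }
  annotations <- do.call(rbind, ann)
  # GO assignments: a stub fraction, the rest weighted level-3 categories
  n_ann <- nrow(annotations)
  stubbed <- stats::runif(n_ann) < stub_frac
  cat3 <- sample(names(go_weights), n_ann, replace = TRUE,
                 prob = go_weights)
  annotations$go_term <- ifelse(stubbed, "molecular_function", cat3)
  annotations$go_level3 <- ifelse(stubbed, NA_character_, cat3)
  rownames(annotations) <- NULL
  list(annotations = annotations,
       map = genetic_map(do.call(rbind, map)),
       alignments = if (length(aln)) do.call(rbind, aln) else
         data.frame(marker_a = character(), marker_b = character(),
                    percent_identity = numeric(), span_bp = numeric(),
                    kind = character(), stringsAsFactors = FALSE),
       truth = list(redundant_pairs = do.call(rbind, red_truth),
                    paralog_membership = do.call(rbind, para_truth)))
}
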