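# Genetic-map summary statistics: observed and Chakravarti-adjusted genome
# length, coverage probability, marker intervals, and a Poisson test of
# marker distribution over fixed-width map intervals.

#' Construct a genetic map table
#'
#' @param x Data frame with columns `lg` (linkage group id), `marker` and
#'   `pos` (position in cM, >= 0).
#' @return The validated data frame, sorted by (`lg`, `pos`), with class
#'   `genetic_map`.
#' @export
genetic_map <- function(x) {
  need <- c("lg", "marker", "pos")
  if (!all(need %in% names(x)))
    stop("map needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  x$pos <- as.numeric(x$pos)
  if (anyNA(x$pos) || any(x$pos < 0))
    stop("positions must be non-negative cM values", call. = FALSE)
  if (anyDuplicated(x$marker))
    stop("duplicated marker id(s) in map", call. = FALSE)
  x <- x[order(x$lg, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("genetic_map", "data.frame")
  x
}

.map_groups <- function(map) split(map$pos, map$lg)

#' Observed linkage-group lengths
#'
#' The observed length of a group is the span between its first and last
#' marker positions. Groups with fewer than two markers have no defined
#' length.
#'
#' @param map A [genetic_map()].
#' @return Data frame with columns `lg`, `m` (marker count) and `length_cM`.
#' @export
observed_length <- function(map) {
  groups <- .map_groups(map)
  m <- vapply(groups, length, integer(1))
  if (any(m < 2))
    stop("linkage group(s) with fewer than 2 markers: ",
         paste(names(groups)[m < 2], collapse = ", "), call. = FALSE)
  data.frame(lg = names(groups), m = m,
             length_cM = vapply(groups, function(p) max(p) - min(p),
                                numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genome length and coverage estimate (Chakravarti method 4)
#'
#' Adjusts each linkage group's observed span by the factor
#' \eqn{(m + 1)/(m - 1)} (m = markers on the group) and sums over groups to
#' estimate total genome length; the moment correction accounts for the
#' chromosome ends extending beyond the terminal markers.
#'
#' @param map A [genetic_map()]; every group needs at least 2 markers.
#' @return A list: `L_obs` (sum of observed spans, cM), `L_est` (adjusted
#'   genome length, cM), `m_total`, `coverage_frac` (`L_obs / L_est`),
#'   `per_group` (data frame with per-group spans, counts and adjusted
#'   lengths).
#' @examples
#' m <- genetic_map(data.frame(lg = 1, marker = c("a", "b", "c"),
#'                             pos = c(0, 4, 10)))
#' estimate_genome_length(m)$L_est  # 10 * (3+1)/(3-1) = 20
#' @export
estimate_genome_length <- function(map) {
  per <- observed_length(map)
  per$adjusted_cM <- per$length_cM * (per$m + 1) / (per$m - 1)
  list(L_obs = sum(per$length_cM), L_est = sum(per$adjusted_cM),
       m_total = sum(per$m),
       coverage_frac = sum(per$length_cM) / sum(per$adjusted_cM),
       per_group = per)
}

#' Map coverage probability
#'
#' Probability `c = 1 - exp(-2 d m / L)` that a random genome locus lies
#' within `d` cM of one of `m` markers randomly distributed over a genome
#' of length `L` cM.
#'
#' @param d Mapping interval in cM (> 0).
#' @param m Number of mapped markers (> 0).
#' @param L Genome length in cM (> 0).
#' @return The coverage probability in (0, 1).
#' @examples
#' coverage_probability(d = 10, m = 429, L = 1515)  # ~0.9965
#' @export
coverage_probability <- function(d, m, L) {
  if (any(d <= 0) || any(m <= 0) || any(L <= 0))
    stop("d, m and L must be positive", call. = FALSE)
  1 - exp(-2 * d * m / L)
}

#' Average marker interval of a map
#'
#' @param map A [genetic_map()].
#' @return A list: `overall` (total observed length / total marker count,
#'   cM) and `per_group_mean` (mean over groups of span / markers).
#' @export
marker_interval <- function(map) {
  per <- observed_length(map)
  if (sum(per$m) == 0) stop("map has no markers", call. = FALSE)
  list(overall = sum(per$length_cM) / sum(per$m),
       per_group_mean = mean(per$length_cM / per$m))
}

#' Marker conversion rate
#'
#' Fraction of evaluated primer pairs that yielded mapped loci, in percent.
#'
#' @param n_mapped Number of mapped loci of a marker class.
#' @param n_evaluated Number of primer pairs evaluated for that class.
#' @return Percent conversion, `100 * n_mapped / n_evaluated`.
#' @examples
#' conversion_rate(84, 873)
#' @export
conversion_rate <- function(n_mapped, n_evaluated) {
  if (any(n_evaluated <= 0) || any(n_mapped < 0) ||
      any(n_mapped > n_evaluated))
    stop("need 0 <= n_mapped <= n_evaluated and n_evaluated > 0",
         call. = FALSE)
  100 * n_mapped / n_evaluated
}

#' Poisson test of marker distribution over map intervals
#'
#' Parses each linkage group, starting at its first marker, into half-open
#' `width`-cM intervals (a final partial interval is kept, so all markers
#' are conserved), concatenates the intervals of all groups, and counts how
#' many intervals contain x markers. Under random marker placement the
#' counts follow a Poisson law P(x) = mu^x e^-mu / x! with mu the mean
#' number of markers per interval; expected interval counts are N * P(x).
#' Observed and expected counts-per-x are then compared.
#'
#' With `method = "counts"` (default) the observed and expected count
#' vectors, indexed by x = 0..x_max, are compared with the two-sample
#' Kolmogorov-Smirnov test. With `method = "intervals"` the N per-interval
#' marker counts are compared two-sample against an equal-size sample of
#' Poisson(mu) quantiles.
#'
#' @param map A [genetic_map()].
#' @param width Interval width in cM (default 10).
#' @param method Sample construction for the K-S comparison (see above).
#' @param x_max Largest marker-per-interval count tallied; defaults to the
#'   maximum observed.
#' @return A list: `width`, `n_intervals`, `mu`, `interval_counts` (markers
#'   per interval, concatenated over groups), `observed` and `expected`
#'   (named vectors over x = 0..x_max), `D`, `p`, `method`.
#' @export
interval_count_test <- function(map, width = 10,
                                method = c("counts", "intervals"),
                                x_max = NULL) {
  method <- match.arg(method)
  if (length(width) != 1L || is.na(width) || width <= 0)
    stop("width must be a positive cM value", call. = FALSE)
  groups <- .map_groups(map)
  if (!length(groups)) stop("empty map", call. = FALSE)
  counts <- unlist(lapply(groups, function(p) {
    idx <- floor((p - min(p)) / width)
    tabulate(idx + 1L, nbins = max(idx) + 1L)
  }), use.names = FALSE)
  n_int <- length(counts)
  mu <- sum(counts) / n_int
  if (is.null(x_max)) x_max <- max(counts)
  x <- 0:x_max
  observed <- vapply(x, function(v) sum(counts == v), numeric(1))
  expected <- n_int * stats::dpois(x, mu)
  names(observed) <- names(expected) <- x
  ks <- if (method == "counts") {
    suppressWarnings(stats::ks.test(observed, expected))
  } else {
    # per-interval counts against an equal-size Poisson quantile sample
    ref <- stats::qpois((seq_len(n_int) - 0.5) / n_int, mu)
    suppressWarnings(stats::ks.test(counts, ref))
  }
  list(width = width, n_intervals = n_int, mu = mu,
       interval_counts = counts, observed = observed, expected = expected,
       D = unname(ks$statistic), p = ks$p.value, method = method)
}

#' Read a genetic map from a TSV file
#'
#' Expects a header with columns `lg` (or `group`), `marker` and `pos` (or
#' `position`).
#'
#' @param path Path to the TSV file.
#' @return A [genetic_map()].
#' @export
read_map_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  names(x)[names(x) == "group"] <- "lg"
  names(x)[names(x) == "position"] <- "pos"
  genetic_map(x)
}

#' Read a MapChart-dialect map file
#'
#' Parses the chart-input text layout: a `group <id>` header line starts
#' each linkage group, followed by `marker position` rows; blank lines and
#' `;` comments are ignored.
#'
#' @param path Path to the map text file.
#' @return A [genetic_map()].
#' @export
read_mapchart <- function(path) {
  lines <- trimws(sub(";.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  lg <- NA_character_
  rows <- list()
  for (ln in lines) {
    if (grepl("^group\\s+", ln, ignore.case = TRUE)) {
      lg <- trimws(sub("^group\\s+", "", ln, ignore.case = TRUE))
      next
    }
    if (is.na(lg)) stop("marker line before any group header", call. = FALSE)
    parts <- strsplit(ln, "\\s+")[[1L]]
    if (length(parts) < 2L)
      stop("malformed map line: ", ln, call. = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      lg = lg, marker = parts[1L], pos = as.numeric(parts[2L]),
      stringsAsFactors = FALSE)
  }
  genetic_map(do.call(rbind, rows))
}
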