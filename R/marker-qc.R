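# Quality control of CP-pedigree segregation data: Mendelian expectations
# per cross configuration, segregation-distortion chi-square tests,
# marker/sample missingness filters, and multi-locus sample-identity
# matching across genotyping cohorts.

.CP_CLASSES <- list(
  abxcd = c("ac", "ad", "bc", "bd"),
  efxeg = c("ee", "ef", "eg", "fg"),
  hkxhk = c("hh", "hk", "kk"),
  lmxll = c("lm", "ll"),
  nnxnp = c("nn", "np"))

.CP_PROBS <- list(
  abxcd = c(0.25, 0.25, 0.25, 0.25),
  efxeg = c(0.25, 0.25, 0.25, 0.25),
  hkxhk = c(0.25, 0.50, 0.25),
  lmxll = c(0.50, 0.50),
  nnxnp = c(0.50, 0.50))

#' Expected genotype-class ratios for a CP cross configuration
#'
#' In an outbred cross-pollination (CP) full-sib family each parent may
#' carry up to two distinct alleles. The fully informative configurations
#' ab x cd and ef x eg segregate four classes at 1/4 each; the intercross
#' hk x hk segregates hh:hk:kk at 1/4:1/2:1/4; the testcross configurations
#' lm x ll and nn x np segregate two classes at 1/2 each.
#'
#' @param cross_type One of `"abxcd"`, `"efxeg"`, `"hkxhk"`, `"lmxll"`,
#'   `"nnxnp"` (a `<abxcd>`-style token is also accepted).
#' @return Named numeric vector of genotype-class probabilities.
#' @examples
#' cp_expected_ratios("lmxll")
#' @export
cp_expected_ratios <- function(cross_type) {
  ct <- gsub("[<> ]", "", tolower(cross_type))
  if (length(ct) != 1L || !ct %in% names(.CP_CLASSES))
    stop("unsupported cross type: ", cross_type, call. = FALSE)
  stats::setNames(.CP_PROBS[[ct]], .CP_CLASSES[[ct]])
}

.normalize_calls <- function(calls) {
  calls <- tolower(as.character(calls))
  calls[calls %in% c("--", "-", ".", "..", "", "u", "na")] <- NA
  calls
}

#' Segregation-distortion chi-square test for one marker
#'
#' Pearson chi-square (no continuity correction) of observed genotype-class
#' counts among non-missing progeny against the Mendelian expectations of
#' the marker's cross configuration; `df = classes - 1`. A marker is flagged
#' distorted when `p < p_threshold`; no multiple-testing adjustment is
#' applied.
#'
#' @param calls Character vector of per-progeny genotype class codes
#'   (e.g. `"lm"`, `"ll"`); `NA`, `"--"` or `"."` mark missing calls.
#' @param cross_type Cross configuration, see [cp_expected_ratios()].
#' @param p_threshold Distortion flag threshold on the p-value.
#' @return A list: `chi2`, `df`, `p`, `n` (non-missing progeny),
#'   `missing_frac`, `distorted`.
#' @examples
#' distortion_test(rep(c("lm", "ll"), c(80, 20)), "lmxll")
#' @export
distortion_test <- function(calls, cross_type, p_threshold = 0.005) {
  exp_p <- cp_expected_ratios(cross_type)
  calls0 <- .normalize_calls(calls)
  obs_calls <- calls0[!is.na(calls0)]
  if (!length(obs_calls))
    stop("no non-missing progeny calls", call. = FALSE)
  foreign <- setdiff(unique(obs_calls), names(exp_p))
  if (length(foreign))
    stop("genotype code(s) not allowed under ", cross_type, ": ",
         paste(foreign, collapse = ", "), call. = FALSE)
  obs <- vapply(names(exp_p), function(cl) sum(obs_calls == cl), numeric(1))
  expd <- exp_p * length(obs_calls)
  if (any(expd <= 0))
    stop("degenerate expectation (zero expected count)", call. = FALSE)
  chi2 <- sum((obs - expd)^2 / expd)
  df <- length(exp_p) - 1L
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p, n = length(obs_calls),
       missing_frac = mean(is.na(calls0)),
       distorted = p < p_threshold)
}

#' Build a segregation data set
#'
#' @param markers Data frame with columns `marker`, `cross_type` and
#'   optionally `null_allele` (logical annotation that the marker segregates
#'   null alleles) and `pedigree`.
#' @param calls Character matrix of genotype codes, markers in rows (rownames
#'   = marker ids), progeny in columns; `NA` for missing.
#' @return A list of class `seg_data`.
#' @export
seg_data <- function(markers, calls) {
  if (is.null(markers$marker) || is.null(markers$cross_type))
    stop("markers needs 'marker' and 'cross_type' columns", call. = FALSE)
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(markers))
    stop("calls must have one row per marker", call. = FALSE)
  rownames(calls) <- markers$marker
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("P", seq_len(ncol(calls)))
  structure(list(markers = markers, calls = calls), class = "seg_data")
}

#' @export
print.seg_data <- function(x, ...) {
  cat("CP segregation data:", nrow(x$calls), "markers x",
      ncol(x$calls), "progeny\n")
  invisible(x)
}

#' Marker-level QC of a segregation data set
#'
#' Runs [distortion_test()] per marker and applies the marker exclusion
#' rules: excessive segregation distortion (`p < distortion_p`), excessive
#' marker missingness (`missing_frac > marker_missing`), and a pass-through
#' exclusion for markers annotated as segregating null alleles.
#'
#' @param seg A [seg_data()] object.
#' @param distortion_p Distortion p-value threshold (default 0.005).
#' @param marker_missing Marker missingness threshold (default 0.70).
#' @return Data frame with one row per marker: `marker`, `chi2`, `df`, `p`,
#'   `missing_frac`, flags `distorted`, `excess_missing`, `null_allele`, and
#'   `keep` (no flag raised).
#' @export
qc_segregation <- function(seg, distortion_p = 0.005,
                           marker_missing = 0.70) {
  stopifnot(inherits(seg, "seg_data"))
  nulls <- if (!is.null(seg$markers$null_allele))
    seg$markers$null_allele %in% TRUE else rep(FALSE, nrow(seg$markers))
  rows <- lapply(seq_len(nrow(seg$markers)), function(i) {
    dt <- distortion_test(seg$calls[i, ], seg$markers$cross_type[i],
                          p_threshold = distortion_p)
    data.frame(marker = seg$markers$marker[i], chi2 = dt$chi2, df = dt$df,
               p = dt$p, missing_frac = dt$missing_frac,
               distorted = dt$distorted,
               excess_missing = dt$missing_frac > marker_missing,
               null_allele = nulls[i], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$keep <- !(res$distorted | res$excess_missing | res$null_allele)
  rownames(res) <- NULL
  res
}

#' Drop progeny samples with excessive missing data
#'
#' @param calls Genotype call matrix, markers in rows and samples in
#'   columns (as in a [seg_data()] object).
#' @param threshold Maximum tolerated per-sample missing fraction
#'   (default 0.40); samples strictly above it are dropped.
#' @return A list: `retained` and `dropped` (sample name vectors) and
#'   `report` (data frame of per-sample missing fractions).
#' @export
filter_samples <- function(calls, threshold = 0.40) {
  calls <- as.matrix(calls)
  if (!ncol(calls)) stop("empty call matrix", call. = FALSE)
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("P", seq_len(ncol(calls)))
  miss <- colMeans(is.na(calls) | calls %in% c("--", "-", ".", ""))
  report <- data.frame(sample = colnames(calls), missing_frac = miss,
                       dropped = miss > threshold,
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(retained = report$sample[!report$dropped],
       dropped = report$sample[report$dropped],
       report = report)
}

#' Verify sample identities between genotyping cohorts
#'
#' Compares multi-locus genotype profiles between two cohorts over their
#' shared markers. For each sample pair the concordance is the fraction of
#' identical calls among markers non-missing in both profiles; a pair is
#' declared the same individual when concordance is exactly 1 over at least
#' `min_loci` compared markers.
#'
#' @param calls_a,calls_b Character matrices of genotype calls with samples
#'   in rows (rownames = sample ids) and markers in columns.
#' @param min_loci Minimum number of compared loci for a match call.
#' @return Data frame over all sample pairs: `sample_a`, `sample_b`,
#'   `n_compared`, `concordance` (`NA` when no shared non-missing locus:
#'   incomparable), `matched`.
#' @export
match_samples <- function(calls_a, calls_b, min_loci = 5) {
  calls_a <- as.matrix(calls_a); calls_b <- as.matrix(calls_b)
  shared <- intersect(colnames(calls_a), colnames(calls_b))
  if (!length(shared))
    stop("no shared markers between cohorts", call. = FALSE)
  a <- calls_a[, shared, drop = FALSE]
  b <- calls_b[, shared, drop = FALSE]
  grid <- expand.grid(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)))
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(r) {
    pa <- a[grid$ia[r], ]; pb <- b[grid$ib[r], ]
    ok <- !is.na(pa) & !is.na(pb)
    n <- sum(ok)
    conc <- if (n) mean(pa[ok] == pb[ok]) else NA_real_
    data.frame(sample_a = rownames(a)[grid$ia[r]],
               sample_b = rownames(b)[grid$ib[r]],
               n_compared = n, concordance = conc,
               matched = !is.na(conc) && conc == 1 && n >= min_loci,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Read a JoinMap-style loc file
#'
#' Parses the CP-population 'loc' dialect: header assignments (`name =`,
#' `popt = CP`, `nloc =`, `nind =`), then one record per marker consisting
#' of the marker name, a `<crosstype>` token, and `nind` genotype codes
#' (which may continue over following lines). `--` codes become `NA`.
#'
#' @param path Path to the loc file.
#' @return A [seg_data()] object; the population name is kept as attribute
#'   `"name"`.
#' @export
read_loc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub(";.*$", "", lines)            # strip comments
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("=", lines, fixed = TRUE)
  header <- lines[hdr]
  get <- function(key) {
    m <- grep(paste0("^", key, "\\s*="), header, value = TRUE)
    if (!length(m)) return(NA_character_)
    trimws(sub("^[^=]*=", "", m[1L]))
  }
  popt <- get("popt")
  if (!is.na(popt) && toupper(popt) != "CP")
    stop("only CP populations are supported (popt = ", popt, ")",
         call. = FALSE)
  nind <- as.integer(get("nind"))
  if (is.na(nind)) stop("loc header lacks nind", call. = FALSE)
  tokens <- unlist(strsplit(paste(lines[!hdr], collapse = " "), "\\s+"))
  markers <- character(); cross <- character(); calls <- list()
  i <- 1L
  while (i <= length(tokens)) {
    mk <- tokens[i]
    ct <- tokens[i + 1L]
    if (is.na(ct) || !grepl("^<.+>$", ct))
      stop("malformed loc record near marker ", mk, call. = FALSE)
    geno <- tokens[(i + 2L):(i + 1L + nind)]
    if (length(geno) != nind || anyNA(geno))
      stop("marker ", mk, " has fewer than nind genotype codes",
           call. = FALSE)
    markers <- c(markers, mk)
    cross <- c(cross, gsub("[<>]", "", ct))
    calls[[length(calls) + 1L]] <- .normalize_calls(geno)
    i <- i + 2L + nind
  }
  mat <- do.call(rbind, calls)
  seg <- seg_data(data.frame(marker = markers, cross_type = cross,
                             stringsAsFactors = FALSE), mat)
  attr(seg, "name") <- get("name")
  seg
}

#' Write a segregation data set as a JoinMap-style loc file
#'
#' @param seg A [seg_data()] object.
#' @param path Output file path.
#' @param name Population name written to the header.
#' @return `path`, invisibly.
#' @export
write_loc <- function(seg, path, name = "pop") {
  stopifnot(inherits(seg, "seg_data"))
  calls <- seg$calls
  calls[is.na(calls)] <- "--"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("name =", name), "popt = CP",
               paste("nloc =", nrow(calls)),
               paste("nind =", ncol(calls))), con)
  for (i in seq_len(nrow(calls))) {
    writeLines(paste(seg$markers$marker[i],
                     paste0("<", seg$markers$cross_type[i], ">"),
                     paste(calls[i, ], collapse = " ")), con)
  }
  invisible(path)
}
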