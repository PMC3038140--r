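# Per-locus allele frequencies, Nei's unbiased gene diversity, and
# class comparisons for a diversity panel of unrelated diploid individuals.

#' Allele frequencies at one locus
#'
#' Counts allele copies over the 2n chromosomes of the non-missing diploid
#' calls. A call is missing when either allele is `NA`.
#'
#' @param allele1,allele2 Vectors (one element per individual) of allele
#'   labels, typically fragment sizes; `NA` marks a missing call.
#' @return A list with `freqs` (named numeric vector summing to 1) and `n`
#'   (number of non-missing diploid individuals).
#' @examples
#' allele_frequencies(c(150, 150, 152), c(150, 152, 152))
#' @export
allele_frequencies <- function(allele1, allele2) {
  if (length(allele1) != length(allele2))
    stop("allele vectors must have equal length", call. = FALSE)
  keep <- !is.na(allele1) & !is.na(allele2)
  if (!any(keep))
    stop("no non-missing diploid calls at this locus", call. = FALSE)
  copies <- c(as.character(allele1[keep]), as.character(allele2[keep]))
  counts <- table(copies)
  list(freqs = stats::setNames(as.numeric(counts) / length(copies),
                               names(counts)),
       n = sum(keep))
}

#' Nei's unbiased gene diversity
#'
#' Small-sample corrected expected heterozygosity,
#' \eqn{\hat H_e = \frac{2n}{2n-1}\bigl(1 - \sum_i p_i^2\bigr)}, where n is
#' the number of diploid individuals scored. Exactly zero for a monomorphic
#' locus.
#'
#' @param freqs Numeric vector of allele frequencies (must sum to 1).
#' @param n Diploid sample size (>= 2).
#' @return The unbiased gene diversity estimate.
#' @examples
#' unbiased_gene_diversity(c(0.5, 0.5), n = 14)  # (28/27) * 0.5
#' @export
unbiased_gene_diversity <- function(freqs, n) {
  if (length(n) != 1L || is.na(n) || n < 2)
    stop("insufficient sample: n must be >= 2", call. = FALSE)
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9)
    stop("freqs must be non-negative and sum to 1", call. = FALSE)
  (2 * n / (2 * n - 1)) * (1 - sum(freqs^2))
}

#' Per-locus diversity statistics for a genotype panel
#'
#' @param genotypes Long-format data frame with columns `individual`,
#'   `locus`, `allele1`, `allele2` (`NA` alleles mark missing calls).
#' @param classes Optional data frame with columns `locus` and `class`
#'   (e.g. `"EST-SSR"` / `"genomic-SSR"`) to carry a marker class label.
#' @return Data frame with one row per locus: `locus`, `class`, `n`, `k`
#'   (allele count), `he_unbiased` and `polymorphic` (`k > 1`). Loci with no
#'   scorable call, or scored in fewer than two individuals, are dropped
#'   with a warning.
#' @export
locus_diversity <- function(genotypes, classes = NULL) {
  need <- c("individual", "locus", "allele1", "allele2")
  if (!all(need %in% names(genotypes)))
    stop("genotypes needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  loci <- unique(as.character(genotypes$locus))
  rows <- lapply(loci, function(l) {
    g <- genotypes[genotypes$locus == l, , drop = FALSE]
    af <- tryCatch(allele_frequencies(g$allele1, g$allele2),
                   error = function(e) NULL)
    if (is.null(af) || af$n < 2) return(NULL)
    data.frame(locus = l, n = af$n, k = length(af$freqs),
               he_unbiased = unbiased_gene_diversity(af$freqs, af$n),
               polymorphic = length(af$freqs) > 1L,
               stringsAsFactors = FALSE)
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped))
    warning(sum(dropped), " locus/loci dropped (fewer than 2 scored calls)",
            call. = FALSE)
  res <- do.call(rbind, rows[!dropped])
  if (is.null(res)) stop("no usable loci", call. = FALSE)
  if (!is.null(classes)) {
    res$class <- classes$class[match(res$locus, classes$locus)]
  } else {
    res$class <- NA_character_
  }
  res <- res[, c("locus", "class", "n", "k", "he_unbiased", "polymorphic")]
  rownames(res) <- NULL
  res
}

#' Compare mean gene diversity between two marker classes
#'
#' Two-sample pooled-variance (Student) t test of per-locus diversity
#' values, with `df = n_a + n_b - 2` and a 95% confidence interval for the
#' difference of means (`mean_b - mean_a`).
#'
#' @param he_a,he_b Numeric vectors of per-locus diversity values for the
#'   two classes (each length >= 2).
#' @return A list: `mean_a`, `mean_b`, `diff`, `ci95` (length-2 vector),
#'   `t`, `df`, `p` (two-sided).
#' @export
compare_diversity <- function(he_a, he_b) {
  n_a <- length(he_a); n_b <- length(he_b)
  if (n_a < 2 || n_b < 2)
    stop("each class needs at least two loci", call. = FALSE)
  m_a <- mean(he_a); m_b <- mean(he_b)
  df <- n_a + n_b - 2L
  sp2 <- ((n_a - 1) * stats::var(he_a) + (n_b - 1) * stats::var(he_b)) / df
  if (sp2 <= 0)
    stop("degenerate (zero) pooled variance", call. = FALSE)
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  diff <- m_b - m_a
  t <- diff / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  ci <- diff + c(-1, 1) * stats::qt(0.975, df) * se
  list(mean_a = m_a, mean_b = m_b, diff = diff, ci95 = ci,
       t = t, df = df, p = p)
}

#' Read a genotype panel TSV
#'
#' Expects a wide table with individuals in rows and two columns per locus
#' named `<locus>.1` and `<locus>.2` (first column `individual`), and
#' returns the long format used by [locus_diversity()]. The string in
#' `missing` (besides empty cells) is read as a missing allele.
#'
#' @param path Path to the TSV file.
#' @param missing Character code for a missing allele (default `"-"`).
#' @return Long-format genotype data frame.
#' @export
read_genotypes <- function(path, missing = "-") {
  wide <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
  if (names(wide)[1L] != "individual")
    stop("first column must be 'individual'", call. = FALSE)
  cols <- names(wide)[-1L]
  loci <- unique(sub("\\.[12]$", "", cols))
  rows <- lapply(loci, function(l) {
    a1 <- wide[[paste0(l, ".1")]]
    a2 <- wide[[paste0(l, ".2")]]
    a1[a1 %in% c(missing, "")] <- NA
    a2[a2 %in% c(missing, "")] <- NA
    data.frame(individual = wide$individual, locus = l,
               allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
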