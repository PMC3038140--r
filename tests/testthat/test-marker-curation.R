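ann_row <- function(marker, clone = NA, uni = NA,
                    species = "Pinus taeda", type = "ESTP") {
  list(marker = marker, clone_id = clone, unigene_id = uni,
       species = species, marker_type = type)
}

test_that("gene-identity evidence follows the B > A > C precedence", {
  a <- ann_row("x", clone = "cl1", uni = "Pta.598")
  b <- ann_row("y", clone = "cl1", uni = "Pta.598")
  expect_identical(shared_gene_evidence(a, b), "B")
  b2 <- ann_row("y", uni = "Pta.598")
  expect_identical(shared_gene_evidence(a, b2), "A")
  # near-identical sequences, one genomic marker: evidence C
  g <- ann_row("g", type = "genomic-SSR")
  e <- ann_row("e", type = "EST-SSR")
  aln <- list(percent_identity = 99, span_bp = 188, kind = "nucleotide")
  expect_identical(shared_gene_evidence(g, e, aln), "C")
  # C requires the species/type restriction
  e2 <- ann_row("e2", type = "EST-SSR")
  expect_true(is.na(shared_gene_evidence(e, e2, aln)))
  e3 <- ann_row("e3", species = "Pinus pinaster", type = "EST-SSR")
  expect_identical(shared_gene_evidence(e, e3, aln), "C")
  # and sufficient identity and span
  expect_true(is.na(shared_gene_evidence(
    g, e, list(percent_identity = 98, span_bp = 188))))
  expect_true(is.na(shared_gene_evidence(
    g, e, list(percent_identity = 99, span_bp = 185))))
  expect_true(is.na(shared_gene_evidence(ann_row("u"), ann_row("v"))))
})

test_that("pairs classify as redundant within 3 cM and paralog beyond or across groups", {
  # markers 8 cM apart on one group: paralogs despite shared evidence
  p1 <- classify_pair("A", 5, 99, 5, 107)
  expect_identical(p1$status, "paralog")
  expect_equal(p1$distance_cM, 8)
  p2 <- classify_pair("B", 3, 68, 3, 55)
  expect_identical(p2$status, "paralog")
  expect_equal(p2$distance_cM, 13)
  expect_identical(classify_pair("A", 2, 10, 2, 10)$status, "redundant")
  expect_identical(classify_pair("A", 2, 10, 2, 13)$status, "redundant")
  expect_identical(classify_pair("A", 2, 10, 2, 13.01)$status, "paralog")
  expect_identical(classify_pair("A", 2, 10, 3, 10)$status, "paralog")
  expect_true(is.infinite(classify_pair("A", 2, 10, 3, 10)$distance_cM))
  expect_identical(classify_pair(NA, 2, 10, 2, 11)$status, "independent")
  # symmetry
  expect_identical(classify_pair("A", 5, 99, 5, 107)$status,
                   classify_pair("A", 5, 107, 5, 99)$status)
  expect_error(classify_pair("A", 1, NA, 1, 3), "mapped")
})

test_that("redundancy calls over a table recover planted truth exactly", {
  sim <- sim_marker_annotations(n_redundant = 10, n_paralog_sets = 5,
                                n_paralog_markers = 14, n_independent = 15,
                                seed = 43)
  calls <- call_redundancy(sim$annotations, sim$map, sim$alignments)
  red <- calls[calls$status == "redundant", ]
  truth <- sim$truth$redundant_pairs
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(key(red$marker_a, red$marker_b),
                  key(truth$marker_a, truth$marker_b))
  expect_identical(
    red$evidence[match(key(truth$marker_a, truth$marker_b),
                       key(red$marker_a, red$marker_b))],
    truth$evidence)
  # no pair is both; every evidence-positive pair is exactly one status
  expect_true(all(calls$status %in% c("redundant", "paralog")))
  # paralog families group into the planted sets
  gp <- group_paralogs(calls)
  expect_equal(gp$n_sets, 5L)
  expect_equal(gp$n_markers, 14L)
  got_sets <- split(gp$membership$marker, gp$membership$set)
  want_sets <- split(sim$truth$paralog_membership$marker,
                     sim$truth$paralog_membership$set)
  sig <- function(sets) sort(vapply(sets, function(s)
    paste(sort(s), collapse = "+"), character(1)))
  expect_identical(sig(got_sets), sig(want_sets))
})

test_that("no shared evidence yields no calls and no paralog sets", {
  sim <- sim_marker_annotations(n_redundant = 0, n_paralog_sets = 2,
                                n_paralog_markers = 4, n_independent = 10,
                                seed = 47)
  only_ind <- sim$annotations[grepl("^IND", sim$annotations$marker), ]
  calls <- call_redundancy(only_ind, sim$map)
  expect_equal(nrow(calls), 0L)
  expect_equal(group_paralogs(calls)$n_sets, 0L)
})

test_that("the poorer-fitting member of a redundant pair is dropped", {
  expect_identical(choose_redundant_drop("a", "b", 1.2, 0.3)$drop, "a")
  expect_identical(choose_redundant_drop("a", "b", 0.1, 0.9)$drop, "b")
  tie <- choose_redundant_drop("b", "a", 0.5, 0.5)
  expect_identical(tie$drop, "a")
  expect_true(tie$tie)
  expect_true(choose_redundant_drop("a", "b", NA, 1)$unresolved)
  # agreement with direct comparison on random fit values
  set.seed(51)
  for (i in 1:25) {
    f <- runif(2)
    got <- choose_redundant_drop("m1", "m2", f[1], f[2])$drop
    expect_identical(got, c("m1", "m2")[which.max(f)])
  }
})

test_that("annotation acceptance thresholds are strict where stated", {
  expect_true(accept_unigene_assignment(86, 220))
  expect_false(accept_unigene_assignment(85, 500))
  expect_false(accept_unigene_assignment(99, 100))
  expect_true(accept_refprotein_assignment(50, 60, 100))
  expect_false(accept_refprotein_assignment(45, 90, 100))
  expect_false(accept_refprotein_assignment(80, 40, 100))
  expect_false(accept_refprotein_assignment(80, 45, 100))  # span > 45%
})

test_that("GO level-3 summary excludes stubs and reports category percentages", {
  ann <- data.frame(
    marker = paste0("m", 1:10),
    go_term = c(rep("catalytic activity", 3), rep("binding", 2),
                rep("transporter activity", 2),
                rep("molecular_function", 3)),
    go_level3 = c(rep("catalytic activity", 3), rep("binding", 2),
                  rep("transporter activity", 2), rep(NA, 3)),
    stringsAsFactors = FALSE)
  s <- go_level_summary(ann)
  expect_equal(sum(s$n), 7L)
  expect_equal(s$percent[s$category == "catalytic activity"], 300 / 7)
  expect_equal(sum(s$percent), 100)
  stubs <- ann[ann$go_term == "molecular_function", ]
  expect_equal(nrow(go_level_summary(stubs)), 0L)
  # planted 46-of-100 in the two dominant categories
  ann2 <- data.frame(
    marker = paste0("g", 1:100),
    go_term = rep(c("catalytic activity", "binding", "other a", "other b"),
                  c(30, 16, 40, 14)),
    stringsAsFactors = FALSE)
  ann2$go_level3 <- ann2$go_term
  s2 <- go_level_summary(ann2)
  expect_equal(sum(s2$percent[s2$category %in%
                                c("catalytic activity", "binding")]), 46)
  # missing lineage for a functional term warns and is excluded
  ann$go_level3[1] <- NA
  expect_warning(s3 <- go_level_summary(ann), "level-3")
  expect_equal(sum(s3$n), 6L)
})
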