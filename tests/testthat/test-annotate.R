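toy_summaries <- function() {
  data.frame(
    site_id = c("MT001_C23", "MT001_C43", "CY001_C5"),
    protein_id = c("MT001", "MT001", "CY001"),
    residue = c(23L, 43L, 5L),
    condition = "H2O2_10mM", n_present = 2L,
    mean_ratio = c(13.3, 3.0, 1.2), cv = 0.1, flags = "",
    stringsAsFactors = FALSE
  )
}

test_that("filter_mitochondrial joins, counts and warns on orphans", {
  ann <- read_annotations(toy_annotations())
  res <- filter_mitochondrial(toy_summaries(), ann)
  expect_equal(nrow(res$summaries), 2)
  expect_equal(res$report$n_proteins, 1)
  expect_equal(res$report$n_sites, 2)
  expect_equal(res$report$fraction_mitochondrial, 2 / 3)

  # all-mitochondrial input is the identity
  mito_only <- toy_summaries()[1:2, ]
  expect_equal(filter_mitochondrial(mito_only, ann)$summaries, mito_only)

  # unknown protein warns and counts as non-mitochondrial
  s <- toy_summaries()
  s$protein_id[3] <- "NOPE"
  expect_warning(res <- filter_mitochondrial(s, ann), "absent")
  expect_equal(nrow(res$summaries), 2)

  expect_error(filter_mitochondrial(s, ann[0, ]), "empty")
})

test_that("bin_pathways respects the fixed vocabulary and thresholds", {
  ann <- read_annotations(toy_annotations())
  s <- toy_summaries()  # MT001 is TCA cycle in the fixture
  bins <- bin_pathways(s[1:2, ], ann, high_threshold = 5)
  tca <- bins[bins$pathway_bin == "TCA cycle", ]
  expect_equal(tca$n_proteins, 1)
  expect_equal(tca$n_sites, 2)
  expect_equal(tca$n_high_sensitivity, 1)  # 13.3 >= 5, 3.0 < 5
  # counts sum to the number of binned sites; no site in two bins
  expect_equal(sum(bins$n_sites), 2)

  # a protein with no annotation row lands in "other"
  s2 <- s; s2$protein_id <- "NOPE"; s2$site_id <- paste0("NOPE_C", 1:3)
  b2 <- bin_pathways(s2, ann)
  expect_equal(b2$n_sites[b2$pathway_bin == "other"], 3)

  bad <- ann; bad$pathway_bin[1] <- "glycolysis"
  expect_error(bin_pathways(s, bad), "glycolysis")
})

test_that("overrepresentation matches the exhaustive tail oracle", {
  bg <- sprintf("P%02d", 1:20)
  fg <- bg[1:6]
  cats <- list(hit = bg[c(1:4, 15)], miss = bg[16:20])
  res <- overrepresentation(fg, bg, cats)
  # exhaustive enumeration for every category at |bg| <= 30
  for (nm in names(cats)) {
    k <- length(intersect(fg, cats[[nm]]))
    want <- oracle_hyper_tail(k, length(cats[[nm]]), length(bg),
                              length(fg))
    expect_equal(res$p_value[res$category == nm], want,
                 tolerance = 1e-12, info = nm)
  }
  # fold enrichment is the ratio of proportions
  expect_equal(res$fold_enrichment[res$category == "hit"],
               (4 / 6) / (5 / 20))
  expect_error(overrepresentation(c(fg, "ZZ"), bg, cats), "subset")
})

test_that("hypergeometric worked example and fold arithmetic hold", {
  bg <- sprintf("B%03d", 1:100)
  fg <- bg[1:10]
  cat10 <- bg[c(1:5, 96:100)]  # overlap 5 of a 10-member category
  res <- overrepresentation(fg, bg, list(c10 = cat10))
  expect_equal(res$fold_enrichment, 5.0)
  expect_equal(res$p_value, oracle_hyper_tail(5, 10, 100, 10),
               tolerance = 1e-12)  # 6.716e-4 by enumeration
  # overlap at expectation gives fold 1
  res1 <- overrepresentation(bg[1:10], bg, list(c = bg[seq(1, 100, 10)]))
  expect_equal(res1$fold_enrichment, 1.0)
})

test_that("BH adjustment preserves the p-value order", {
  set.seed(61)
  bg <- sprintf("P%03d", 1:60)
  fg <- sample(bg, 15)
  cats <- lapply(1:8, function(i) sample(bg, sample(5:20, 1)))
  names(cats) <- paste0("cat", 1:8)
  res <- overrepresentation(fg, bg, cats)
  expect_true(all(diff(res$q_value) >= -1e-12))  # sorted by p
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_true(all(res$q_value <= 1))
})

test_that("enrichment_report computes fold changes and shares", {
  frac <- data.frame(
    protein_id = sprintf("F%03d", rep(1:481, length.out = 1563)),
    site_id = sprintf("S%04d", 1:1563),
    is_mitochondrial = TRUE, stringsAsFactors = FALSE
  )
  ref <- data.frame(
    protein_id = sprintf("R%03d", rep(1:172, length.out = 278)),
    site_id = sprintf("T%04d", 1:278),
    is_mitochondrial = TRUE, stringsAsFactors = FALSE
  )
  rep <- enrichment_report(frac, ref)
  expect_equal(rep$protein_fold, 481 / 172, tolerance = 1e-12)  # 2.80
  expect_equal(rep$cysteine_fold, 1563 / 278, tolerance = 1e-12)  # 5.62
  # identical tables give fold 1
  same <- enrichment_report(ref, ref)
  expect_equal(same$protein_fold, 1)
  expect_equal(same$cysteine_fold, 1)
  ref$is_mitochondrial <- FALSE
  expect_error(enrichment_report(frac, ref), "zero mitochondrial")
})
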