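test_that("gd score reproduces the linear decision function", {
  expect_equal(gd_score(0, 0.432), 0)
  expect_equal(gd_score(1000, 0.10), 0.000355 * 1000 + 0.10 - 0.432)
  expect_gt(gd_score(1000, 0.10), 0)
  expect_equal(gd_score(100, 0.20), -0.1965)
  expect_error(gd_score(10, 1.2), "pga")
  expect_error(gd_score(-1, 0.2), "ns")
})

test_that("sample calls respect the ambiguous margin", {
  cl <- gd_classifier()
  expect_equal(cl$ambiguous_margin, 0.216)
  x <- tibble::tibble(sample_id = c("a", "b", "c"),
                      ns = c(0, 0, 0), pga = c(0.432 + 0.3, 0.432, 0.432 - 0.3))
  calls <- classify_gd(x, cl)
  expect_equal(calls$call, c("GD", "ambiguous", "nonGD"))
  expect_equal(calls$confident, c(TRUE, FALSE, TRUE))
})

test_that("sample calls are monotone in ns and pga", {
  cl <- gd_classifier()
  ord <- c(nonGD = 1, ambiguous = 2, GD = 3)
  set.seed(48)
  for (i in 1:50) {
    ns <- sample(0:2000, 1); p <- runif(1)
    c1 <- classify_gd(tibble::tibble(ns = ns, pga = p), cl)$call
    c2 <- classify_gd(tibble::tibble(ns = ns + sample(1:500, 1),
                                     pga = min(1, p + runif(1, 0, 0.3))), cl)$call
    expect_gte(ord[c2], ord[c1])
  }
})

test_that("patient status follows the clonal/subclonal rules incl. tie -> GD", {
  mk <- function(calls) tibble::tibble(sample_id = seq_along(calls),
                                       call = calls)
  p1 <- classify_gd_patient(mk(c("GD", "GD", "ambiguous")))
  expect_equal(p1$status, "clonal_GD")
  expect_equal(p1$calls$corrected_call, c("GD", "GD", "GD"))

  p2 <- classify_gd_patient(mk(c("GD", "nonGD", "ambiguous")))
  expect_equal(p2$status, "subclonal_GD")
  expect_equal(p2$calls$corrected_call[3], "GD") # 1-1 tie corrects to GD

  p3 <- classify_gd_patient(mk(c("GD", "nonGD", "nonGD", "ambiguous")))
  expect_equal(p3$calls$corrected_call[4], "nonGD") # majority confident call

  expect_equal(classify_gd_patient(mk("nonGD"))$status, "clonal_nonGD")
  expect_equal(classify_gd_patient(mk(c("ambiguous", "ambiguous")))$status,
               "unresolved")
  expect_error(classify_gd_patient(mk(character(0))), "no sample")

  # permutation invariance
  set.seed(49)
  calls <- c("GD", "nonGD", "ambiguous", "GD", "ambiguous")
  base <- classify_gd_patient(mk(calls))
  for (i in 1:10) {
    perm <- sample(calls)
    got <- classify_gd_patient(mk(perm))
    expect_equal(got$status, base$status)
  }
})

test_that("GD enrichment test equals hypergeometric enumeration", {
  # equal proportions are not enriched
  expect_equal(gd_enrichment_test(5, 10, 5, 10)$p_value, 1)
  set.seed(50)
  for (i in 1:30) {
    n_a <- sample(3:15, 1); n_b <- sample(3:15, 1)
    gd_a <- sample(0:n_a, 1); gd_b <- sample(0:n_b, 1)
    got <- gd_enrichment_test(gd_a, n_a, gd_b, n_b)$p_value
    want <- oracle_fisher_p(gd_a, n_a - gd_a, gd_b, n_b - gd_b)
    expect_equal(got, want, tolerance = 1e-8)
    # symmetry under swapping groups
    expect_equal(got, gd_enrichment_test(gd_b, n_b, gd_a, n_a)$p_value)
    expect_gt(got, 0); expect_lte(got, 1)
  }
  expect_error(gd_enrichment_test(5, 3, 1, 10), "counts")
})

test_that("cohort classification ties samples to patients", {
  x <- tibble::tibble(
    patient = c("P1", "P1", "P2", "P2"),
    sample_id = c("P1a", "P1b", "P2a", "P2b"),
    ns = c(1500, 1400, 100, 120),
    pga = c(0.5, 0.45, 0.05, 0.3)
  )
  res <- classify_gd_cohort(x)
  expect_equal(res$patients$status[res$patients$patient == "P1"], "clonal_GD")
  expect_equal(res$patients$status[res$patients$patient == "P2"],
               "clonal_nonGD")
  expect_equal(nrow(res$samples), 4)
})

test_that("raw classifier separates simulated GD from diploid carcinomas", {
  # generator truth: GD patients carry the empirical GD signature (roughly
  # doubled altered-genome fraction); the raw sign of the decision function
  # (no ambiguous zone) is what the published accuracies refer to
  raw <- gd_classifier(ambiguous_margin = 0)
  spec_gd <- cohort_spec(n_patients = 1, n_regions = 2, stage = "carcinoma",
                         gd_prob = 1)
  spec_di <- cohort_spec(n_patients = 1, n_regions = 2, stage = "carcinoma",
                         gd_prob = 0)
  correct <- 0; total <- 0
  for (s in 1:10) {
    for (spec in list(spec_gd, spec_di)) {
      pat <- gen_patient(spec, seed = 6000 + s, patient = "P")
      stats <- dplyr::inner_join(pga(pat$cn), count_segments(pat$cn),
                                 by = "sample_id")
      calls <- classify_gd(dplyr::rename(stats, ns = n_segments), raw)
      truth <- if (pat$truth$gd) "GD" else "nonGD"
      correct <- correct + sum(calls$call == truth)
      total <- total + nrow(calls)
    }
  }
  expect_gte(correct / total, 0.9)
})
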