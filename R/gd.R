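#' Genome-doubling classifier parameters
#'
#' A linear classifier on the number of copy-number segments (NS) and the
#' percentage of genome altered (PGA, as a fraction): a sample is called
#' genome-doubled when `coef_ns * NS + PGA + intercept > 0`. Published
#' coefficients were trained on consortium segment calls re-binned to mimic
#' shallow WGS; they are constants here, not refit. Scores within
#' `ambiguous_margin` of zero are called ambiguous (default half the
#' magnitude of the intercept).
#'
#' @param coef_ns Coefficient on the segment count.
#' @param intercept Intercept of the decision function.
#' @param ambiguous_margin Half-width of the ambiguous zone in score units.
#' @return A list of class `"gd_classifier"`.
#' @export
gd_classifier <- function(coef_ns = 0.000355, intercept = -0.432,
                          ambiguous_margin = 0.5 * abs(intercept)) {
  if (ambiguous_margin < 0) abort("ambiguous_margin must be >= 0")
  structure(list(coef_ns = coef_ns, intercept = intercept,
                 ambiguous_margin = ambiguous_margin),
            class = "gd_classifier")
}

#' Genome-doubling decision score
#'
#' `coef_ns * ns + pga + intercept`; positive scores fall on the
#' genome-doubled side of the decision boundary.
#'
#' @param ns Number of segments (nonnegative integer-ish).
#' @param pga Percentage of genome altered as a fraction in `[0, 1]`.
#' @param classifier A [gd_classifier()].
#' @return Numeric score(s).
#' @examples
#' gd_score(0, 0.432) # exactly on the boundary
#' @export
gd_score <- function(ns, pga, classifier = gd_classifier()) {
  if (any(ns < 0)) abort("ns must be >= 0")
  if (any(pga < 0 | pga > 1)) abort("pga must lie in [0, 1]")
  classifier$coef_ns * ns + pga + classifier$intercept
}

#' Classify samples as genome-doubled
#'
#' Scores each sample with [gd_score()] and calls `GD` above the ambiguous
#' margin, `nonGD` below its negation, and `ambiguous` in between; a call is
#' `confident` when not ambiguous.
#'
#' @param x Tibble with columns `sample_id`, `ns`, `pga` (fraction), or the
#'   result of joining [count_segments()] and [pga()].
#' @inheritParams gd_score
#' @return `x` with added `score`, `call`, `confident` columns.
#' @export
classify_gd <- function(x, classifier = gd_classifier()) {
  sc <- gd_score(x$ns, x$pga, classifier)
  call <- ifelse(sc > classifier$ambiguous_margin, "GD",
                 ifelse(sc < -classifier$ambiguous_margin, "nonGD", "ambiguous"))
  dplyr::mutate(tibble::as_tibble(x), score = sc, call = call,
                confident = call != "ambiguous")
}

#' Patient-level genome-doubling status
#'
#' Aggregates per-sample GD calls into a patient status and corrects
#' ambiguous samples:
#' a patient is `clonal_nonGD` if at least one sample is confidently nonGD
#' and none confidently GD (and vice versa for `clonal_GD`); `subclonal_GD`
#' when both confident calls occur; `unresolved` when every sample is
#' ambiguous. In clonal patients ambiguous samples are corrected to the
#' clonal call; in subclonal patients they take the majority confident call,
#' with ties corrected to GD.
#'
#' @param calls Tibble with at least `call` (and usually `sample_id`), as
#'   returned by [classify_gd()].
#' @return List of class `"gd_patient"`: `status` and `calls` (input with a
#'   `corrected_call` column).
#' @export
classify_gd_patient <- function(calls) {
  if (nrow(calls) == 0) abort("no sample calls")
  cl <- calls$call
  n_gd <- sum(cl == "GD"); n_non <- sum(cl == "nonGD")
  status <- if (n_gd > 0 && n_non > 0) "subclonal_GD"
    else if (n_gd > 0) "clonal_GD"
    else if (n_non > 0) "clonal_nonGD"
    else "unresolved"
  corrected <- cl
  amb <- cl == "ambiguous"
  if (status == "clonal_GD") corrected[amb] <- "GD"
  if (status == "clonal_nonGD") corrected[amb] <- "nonGD"
  if (status == "subclonal_GD") {
    corrected[amb] <- if (n_gd >= n_non) "GD" else "nonGD"
  }
  structure(list(status = status,
                 calls = dplyr::mutate(tibble::as_tibble(calls),
                                       corrected_call = corrected)),
            class = "gd_patient")
}

#' Cohort-level genome-doubling classification
#'
#' Runs [classify_gd()] per sample and [classify_gd_patient()] per patient.
#'
#' @param x Tibble with `patient`, `sample_id`, `ns`, `pga`.
#' @inheritParams gd_score
#' @return List with `samples` (per-sample calls incl. `corrected_call`) and
#'   `patients` (tibble `patient`, `status`).
#' @export
classify_gd_cohort <- function(x, classifier = gd_classifier()) {
  calls <- classify_gd(x, classifier)
  by_pat <- split(calls, calls$patient)
  res <- purrr::map(by_pat, classify_gd_patient)
  list(samples = dplyr::bind_rows(purrr::map(res, "calls")),
       patients = tibble::tibble(patient = names(res),
                                 status = unname(purrr::map_chr(res,
                                                                "status"))))
}

#' Fisher exact test for genome-doubling enrichment
#'
#' Two-sided Fisher exact test comparing GD frequencies between two groups
#' (e.g. adenoma components versus early-cancer components).
#'
#' @param gd_a,n_a GD count and total in group A.
#' @param gd_b,n_b GD count and total in group B.
#' @return Tibble: `p_value`, `odds_ratio`.
#' @export
gd_enrichment_test <- function(gd_a, n_a, gd_b, n_b) {
  if (any(c(gd_a, n_a, gd_b, n_b) < 0) || gd_a > n_a || gd_b > n_b) {
    abort("counts must satisfy 0 <= gd <= n")
  }
  tab <- matrix(c(gd_a, n_a - gd_a, gd_b, n_b - gd_b), nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab)
  tibble::tibble(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}
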