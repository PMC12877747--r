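#' Expected B-allele frequency of a major-haplotype SNP
#'
#' For a segment with allele-specific copy numbers `(nMaj, nMin)` and tumor
#' purity `rho`, a SNP phased to the major haplotype is expected at BAF
#' `(rho * nMaj + (1 - rho)) / (rho * (nMaj + nMin) + 2 * (1 - rho))`; the
#' minor haplotype is the complement. With purity 1 a trisomy gives the
#' familiar 0.67 / 0.33 split.
#'
#' @param n_maj,n_min Allele-specific copy numbers, `n_maj >= n_min >= 0`.
#' @param rho Purity in `(0, 1]`.
#' @return Expected major-haplotype BAF.
#' @export
expected_baf <- function(n_maj, n_min, rho = 1) {
  (rho * n_maj + (1 - rho)) / (rho * (n_maj + n_min) + 2 * (1 - rho))
}

#' Phase SNPs to major/minor haplotypes from BAF
#'
#' Within segments showing allelic imbalance (`n_maj != n_min`), SNPs whose
#' mean BAF across glands exceeds 0.5 are phased to the major haplotype and
#' those below to the minor haplotype; SNPs with mean BAF within `margin` of
#' 0.5 are left unphased. Balanced segments cannot be phased and their SNPs
#' are returned unphased with a warning.
#'
#' @param baf Tibble with columns `snp`, `segment`, `baf` (one row per SNP
#'   per gland; multiple glands are pooled by the mean).
#' @param segments Tibble with `segment`, `n_maj`, `n_min`.
#' @param margin Dead zone around BAF 0.5 (default 0.05).
#' @return Tibble: `snp`, `segment`, `mean_baf`, `haplotype` (`"major"`,
#'   `"minor"` or `NA` for unphased).
#' @export
phase_snps <- function(baf, segments, margin = 0.05) {
  seg <- dplyr::select(segments, "segment", "n_maj", "n_min")
  if (any(seg$n_maj < seg$n_min)) abort("need n_maj >= n_min")
  out <- baf |>
    dplyr::group_by(.data$snp, .data$segment) |>
    dplyr::summarise(mean_baf = mean(.data$baf), .groups = "drop") |>
    dplyr::left_join(seg, by = "segment")
  if (anyNA(out$n_maj)) abort("every SNP must map to a known segment")
  balanced <- out$n_maj == out$n_min
  if (any(balanced)) {
    warn("SNPs in balanced segments (n_maj == n_min) cannot be phased")
  }
  out$haplotype <- dplyr::case_when(
    balanced ~ NA_character_,
    abs(out$mean_baf - 0.5) <= margin ~ NA_character_,
    out$mean_baf > 0.5 ~ "major",
    TRUE ~ "minor"
  )
  dplyr::select(out, "snp", "segment", "mean_baf", "haplotype")
}

#' Exact binomial test for allelic imbalance
#'
#' Two-sided exact binomial test of whether the ratio of reads supporting
#' the two alleles departs from 0.5.
#'
#' @param a,b Read counts supporting each allele, `a + b >= 1`.
#' @return Two-sided p-value.
#' @export
binomial_imbalance_test <- function(a, b) {
  if (a < 0 || b < 0 || a + b < 1) abort("need nonnegative counts, a + b >= 1")
  stats::binom.test(a, a + b, p = 0.5)$p.value
}

#' Fisher test of segment allele counts against expected imbalance
#'
#' Compares observed major/minor phased read counts in a segment with the
#' counts expected under the inferred allele-specific copy number: the
#' expected row is `(n_maj, n_min)` scaled to the observed total and
#' rounded, and the 2x2 table is assessed by a two-sided Fisher exact test.
#'
#' @param obs_maj,obs_min Observed phased read counts.
#' @param n_maj,n_min Inferred allele-specific copy numbers,
#'   `n_maj + n_min >= 1`.
#' @return Tibble: `p_value`, `expected_maj`, `expected_min`.
#' @export
segment_phase_test <- function(obs_maj, obs_min, n_maj, n_min) {
  if (n_maj + n_min < 1) abort("n_maj + n_min must be >= 1")
  if (obs_maj < 0 || obs_min < 0 || obs_maj + obs_min < 1) {
    abort("need observed counts with positive total")
  }
  total <- obs_maj + obs_min
  exp_maj <- round(total * n_maj / (n_maj + n_min))
  exp_min <- total - exp_maj
  tab <- matrix(c(obs_maj, obs_min, exp_maj, exp_min), nrow = 2,
                byrow = TRUE)
  tibble::tibble(p_value = stats::fisher.test(tab)$p.value,
                 expected_maj = exp_maj, expected_min = exp_min)
}
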