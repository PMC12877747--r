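stage_presets <- function(stage) {
  switch(stage,
    adenoma = list(target_pga = 0.085, target_subclonal = 0.60,
                   gd_prob = 1 / 19),
    early = list(target_pga = 0.253, target_subclonal = 0.40,
                 gd_prob = 13 / 39),
    carcinoma = list(target_pga = 0.272, target_subclonal = 0.25,
                     gd_prob = 16 / 81),
    abort("stage must be adenoma, early or carcinoma")
  )
}

#' Synthetic cohort specification
#'
#' Parameters of the synthetic multi-region cohort generator. Stage presets
#' encode the cohort regimes of colorectal progression: adenomas with low
#' PGA but high CNA subclonality, carcinomas with high PGA but low
#' subclonality, early cancers in between; per-stage genome-doubling
#' probabilities follow the observed cohort frequencies (1/19 adenomas,
#' 13/39 early cancers, 16/81 carcinomas). Any preset value can be
#' overridden.
#'
#' @param n_patients Number of patients.
#' @param n_regions Regions (samples) per patient.
#' @param stage `"adenoma"`, `"early"` or `"carcinoma"`.
#' @param target_pga Clonal PGA target (fraction).
#' @param target_subclonal Target proportion of the altered genome that is
#'   subclonal.
#' @param gd_prob Probability a patient is genome-doubled.
#' @param purity_range Per-sample purity range (uniform draw).
#' @param logr_sd Gaussian SD of the log2-ratio noise.
#' @param grid Bin grid (default [default_bin_grid()]).
#' @param size_sampler CNA length sampler shared with the simulator.
#' @param gd_after_frac Fraction of the clonal PGA accrued before the
#'   genome doubling is applied, for GD patients.
#' @param gd_pga_factor Multiplier on the clonal PGA target for
#'   genome-doubled patients (capped at 0.9). Genome doubling both doubles
#'   the dosage of pre-existing alterations and is associated with a
#'   markedly higher altered-genome fraction, the signature the GD
#'   classifier relies on.
#' @param max_cn Copy cap.
#' @return List of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_patients = 10, n_regions = 4,
                        stage = c("carcinoma", "adenoma", "early"),
                        target_pga = NULL, target_subclonal = NULL,
                        gd_prob = NULL, purity_range = c(0.5, 1),
                        logr_sd = 0.05, grid = default_bin_grid(),
                        size_sampler = cna_length_sampler(),
                        gd_after_frac = 0.5, gd_pga_factor = 2,
                        max_cn = 8) {
  stage <- match.arg(stage)
  pre <- stage_presets(stage)
  target_pga <- target_pga %||% pre$target_pga
  target_subclonal <- target_subclonal %||% pre$target_subclonal
  gd_prob <- gd_prob %||% pre$gd_prob
  if (target_pga < 0 || target_pga > 1 ||
      target_subclonal < 0 || target_subclonal > 1) {
    abort("targets must lie in [0, 1]")
  }
  if (n_regions < 2 && target_subclonal > 0) {
    abort("subclonal target > 0 needs at least 2 regions")
  }
  structure(list(n_patients = n_patients, n_regions = n_regions,
                 stage = stage, target_pga = target_pga,
                 target_subclonal = target_subclonal, gd_prob = gd_prob,
                 purity_range = purity_range, logr_sd = logr_sd,
                 grid = grid, size_sampler = size_sampler,
                 gd_after_frac = gd_after_frac,
                 gd_pga_factor = gd_pga_factor, max_cn = max_cn),
            class = "cohort_spec")
}

draw_one_event <- function(grid_info, size_fun) {
  s <- sample.int(grid_info$n, 1L)
  len <- size_fun(1L)
  e <- if (is.infinite(len)) grid_info$last[s] else
    min(s + len - 1, grid_info$last[s])
  s <- if (is.infinite(len)) grid_info$first[s] else s
  cbind(start_bin = s, end_bin = e, delta = sample(c(-1, 1), 1L))
}

grid_info <- function(grid) {
  cb <- chrom_bounds(grid)
  list(n = nrow(grid), first = cb$first[cb$id], last = cb$last[cb$id])
}

#' Generate one synthetic patient
#'
#' Builds a clonal (trunk) karyotype by accruing CNA events on a diploid
#' genome until the clonal PGA reaches the target, applying a whole-genome
#' doubling part-way for GD patients, then adds region-private events until
#' the realised proportion of subclonal alterations reaches its target.
#' Every event, the GD flag, the baseline ploidy and the per-region purities
#' are recorded as ground truth.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (mandatory for reproducibility).
#' @param patient Patient id used in sample names.
#' @return List: `cn` (wide bin table, one column per region) and `truth`
#'   (trunk/private events, `gd`, `ploidy`, `purity`, realised targets).
#' @export
gen_patient <- function(spec, seed, patient = "P1") {
  set.seed(seed)
  gi <- grid_info(spec$grid)
  gd <- runif(1) < spec$gd_prob
  target_pga <- if (gd) min(0.9, spec$target_pga * spec$gd_pga_factor) else
    spec$target_pga
  cn <- rep(2, gi$n)
  trunk <- list(); doubled <- FALSE; gd_at <- NA_integer_
  current_pga <- function(v) mean(v != lower_median(v))
  guard <- 0
  while (current_pga(if (gd && !doubled) cn * 2 else cn) < target_pga &&
         guard < 2000) {
    guard <- guard + 1
    if (gd && !doubled &&
        current_pga(cn) >= spec$gd_after_frac * target_pga) {
      cn <- cn * 2
      doubled <- TRUE
      gd_at <- length(trunk)
    }
    ev <- draw_one_event(gi, spec$size_sampler)
    cn <- apply_events(cn, ev, spec$max_cn)
    trunk <- c(trunk, list(ev))
  }
  if (gd && !doubled) { cn <- cn * 2; doubled <- TRUE; gd_at <- length(trunk) }
  regions <- matrix(cn, gi$n, spec$n_regions)
  colnames(regions) <- sprintf("%s_R%d", patient, seq_len(spec$n_regions))
  private <- rep(list(list()), spec$n_regions)
  realised_sub <- function() {
    s <- state_matrix(regions, apply(regions, 2, lower_median))
    altered <- rowSums(s != 0) > 0
    if (!any(altered)) return(0)
    mean(apply(s[altered, , drop = FALSE], 1, function(v) any(v != v[1])))
  }
  guard <- 0
  while (spec$n_regions >= 2 && realised_sub() < spec$target_subclonal &&
         guard < 2000) {
    guard <- guard + 1
    r <- sample.int(spec$n_regions, 1)
    ev <- draw_one_event(gi, spec$size_sampler)
    regions[, r] <- apply_events(regions[, r], ev, spec$max_cn)
    private[[r]] <- c(private[[r]], list(ev))
  }
  purity <- runif(spec$n_regions, spec$purity_range[1], spec$purity_range[2])
  names(purity) <- colnames(regions)
  tbl <- bin_table(spec$grid, regions)
  list(cn = tbl,
       truth = list(patient = patient, gd = gd, gd_after_event = gd_at,
                    trunk_events = trunk, private_events = private,
                    ploidy = lower_median(cn), purity = purity,
                    clonal_pga = current_pga(cn),
                    realised_subclonal = realised_sub()))
}

#' Generate a synthetic multi-region cohort
#'
#' Seeded generation of `n_patients` patients via [gen_patient()]; per-
#' patient seeds are derived deterministically from `seed`.
#'
#' @inheritParams gen_patient
#' @param seed Integer seed.
#' @return List: `patients` (named list of [gen_patient()] outputs),
#'   `manifest` (tibble `patient`, `sample_id`, `stage`, `purity`, `gd`).
#' @export
gen_cohort <- function(spec, seed) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, spec$n_patients)
  ids <- sprintf("PT%03d", seq_len(spec$n_patients))
  patients <- purrr::map2(seeds, ids, function(s, id)
    gen_patient(spec, seed = s, patient = id))
  names(patients) <- ids
  manifest <- purrr::map_dfr(patients, function(p) {
    tibble::tibble(patient = p$truth$patient,
                   sample_id = names(p$truth$purity),
                   stage = spec$stage,
                   purity = unname(p$truth$purity),
                   gd = p$truth$gd)
  })
  list(patients = patients, manifest = manifest)
}

#' Noisy log2-ratio profiles from integer copy numbers
#'
#' Inverse of [logr_to_cn()] plus Gaussian noise:
#' `logr = log2((rho * cn + 2(1 - rho)) / (rho * psi + 2(1 - rho))) + N(0, sd)`,
#' median-centred per sample by default (the representation shallow WGS
#' provides before ploidy fitting). Note that median-centring renormalises
#' the profile to the sample's modal copy state: the ploidy recoverable
#' from centred data is the baseline (median) copy number, not `psi`. Use
#' `center = FALSE` to keep the stated `psi` as the normalisation constant.
#'
#' @param x Wide bin table of integer copy numbers.
#' @param rho Purity per sample (named vector or scalar).
#' @param psi Tumor ploidy used as normalisation constant.
#' @param noise_sd Gaussian noise SD.
#' @param center Median-centre each sample's log2 ratios?
#' @param seed Optional integer seed.
#' @return Wide bin table of log2 ratios.
#' @export
gen_logr <- function(x, rho = 1, psi = 2, noise_sd = 0.05, center = TRUE,
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- cn_matrix(x)
  ids <- colnames(m)
  if (length(rho) == 1 && is.null(names(rho))) {
    rho <- setNames(rep(rho, length(ids)), ids)
  }
  lr <- vapply(ids, function(id) {
    v <- cn_to_logr(m[, id], rho[[id]], psi) +
      rnorm(nrow(m), 0, noise_sd)
    if (center) v - median(v) else v
  }, numeric(nrow(m)))
  bin_table(x, lr, ids)
}

#' Synthetic SNP BAF fixture with known phase
#'
#' Draws per-SNP alternate-allele counts from a binomial at the expected
#' BAF implied by the segment's allele-specific copy number and purity, with
#' the true haplotype of every SNP recorded.
#'
#' @param segments Tibble with `segment`, `n_maj`, `n_min`, `n_snps`.
#' @param depth Read depth per SNP per gland.
#' @param rho Purity.
#' @param n_glands Number of glands observed per SNP.
#' @param seed Optional integer seed.
#' @return Tibble: `snp`, `segment`, `gland`, `truth` (major/minor),
#'   `alt_count`, `depth`, `baf`.
#' @export
gen_baf_fixture <- function(segments, depth = 30, rho = 1, n_glands = 3,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (depth < 1) abort("depth must be >= 1")
  purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    sg <- segments[i, ]
    eb <- expected_baf(sg$n_maj, sg$n_min, rho)
    truth <- sample(c("major", "minor"), sg$n_snps, replace = TRUE)
    purrr::map_dfr(seq_len(sg$n_snps), function(j) {
      p <- if (truth[j] == "major") eb else 1 - eb
      alt <- rbinom(n_glands, depth, p)
      tibble::tibble(snp = sprintf("%s_snp%03d", sg$segment, j),
                     segment = sg$segment,
                     gland = sprintf("gland%02d", seq_len(n_glands)),
                     truth = truth[j], alt_count = alt, depth = depth,
                     baf = alt / depth)
    })
  })
}
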