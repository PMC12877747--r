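#' Convert log2 ratios to (real-valued) copy number
#'
#' ASCAT-style transformation for tumor content `rho` and tumor ploidy
#' `psi`: `cn = (2^logr * (2(1 - rho) + rho * psi) - 2(1 - rho)) / rho`.
#' Values may be negative for noisy bins; integer calling rounds and clips
#' at 0. The inverse is [cn_to_logr()].
#'
#' @param logr Numeric log2 ratios.
#' @param rho Purity in `(0, 1]`.
#' @param psi Ploidy `> 0`.
#' @return Real copy numbers.
#' @export
logr_to_cn <- function(logr, rho, psi) {
  if (rho <= 0 || rho > 1) abort("rho must lie in (0, 1]")
  if (psi <= 0) abort("psi must be > 0")
  (2^logr * (2 * (1 - rho) + rho * psi) - 2 * (1 - rho)) / rho
}

#' @rdname logr_to_cn
#' @param cn Copy numbers.
#' @export
cn_to_logr <- function(cn, rho, psi) {
  if (rho <= 0 || rho > 1) abort("rho must lie in (0, 1]")
  log2((rho * cn + 2 * (1 - rho)) / (rho * psi + 2 * (1 - rho)))
}

#' Best purity for a sample at a fixed ploidy
#'
#' Grid search over purities: the goodness of fit of `(rho, psi)` is the
#' mean squared deviation of the implied real copy numbers from their
#' nearest nonnegative integer.
#'
#' @param logr Numeric log2 ratios of one sample.
#' @param psi Candidate ploidy.
#' @param purity_grid Candidate purities.
#' @return Tibble: `rho`, `fit_error`.
#' @export
fit_sample_purity <- function(logr, psi, purity_grid) {
  if (length(purity_grid) == 0) abort("empty purity grid")
  err <- vapply(purity_grid, function(r) {
    cn <- logr_to_cn(logr, r, psi)
    mean((cn - pmax(round(cn), 0))^2)
  }, 0)
  # low purities can alias to an equally integral solution; among ties the
  # highest purity (fewest implied alterations) is preferred
  ties <- which(err <= min(err) + 1e-12)
  best <- ties[which.max(purity_grid[ties])]
  tibble::tibble(rho = purity_grid[best], fit_error = err[best])
}

purity_grid_for <- function(class, step = 0.01,
                            min_purity = c(region = 0.5, bulk = 0.2)) {
  lo <- unname(min_purity[class])
  if (is.na(lo)) abort("sample_class must be 'region' or 'bulk'")
  seq(lo, 1, by = step)
}

#' Multi-sample ploidy grid search from log2 ratios
#'
#' For each candidate ploidy, finds every sample's best purity (mean squared
#' rounding error of implied copy numbers) and the mean pairwise Euclidean
#' distance between the samples' ploidy-normalised integer copy numbers
#' (`round(cn)/psi`), excluding from the distance any bin where either
#' sample's log2 ratio exceeds 1 (an amplification guard). Both measures
#' are min-max scaled to `[0, 1]` over the ploidy grid and candidate
#' solutions are ranked by their Euclidean distance from the origin
#' `(0, 0)`, so the chosen ploidy fits well within each sample and gives
#' consistent profiles across samples. Microdissected "region" samples are
#' searched from purity 0.5, "bulk" samples from 0.2.
#'
#' A caveat inherent to log-ratio-only fitting: a whole-genome `+1`
#' reinterpretation of the data at a suitably lower purity reproduces the
#' log2 ratios exactly, so candidate solutions one copy above the truth can
#' rank first when every sample's aliased purity stays inside the allowed
#' range. Inspect [tidy.ploidy_fit()] and use `choice = 2` /
#' `psi_offsets` in [call_absolute_cn()] for the manually curated
#' alternative, as was required for some aliased patients in practice.
#'
#' @param x Wide bin table of median-centred log2 ratios (one patient).
#' @param sample_class Named character vector (`"region"`/`"bulk"`) per
#'   sample, or a single class for all; defaults to `"region"`.
#' @param psi_grid Candidate ploidies (default 1.5 to 4 by 0.05).
#' @param purity_step Purity grid step.
#' @param logr_amp_cutoff Bins with log2 ratio above this value are excluded
#'   from the cross-sample distance.
#' @return Object of class `"ploidy_fit"`: per-ploidy score table (see
#'   [tidy.ploidy_fit()]), per-sample purities, and the input.
#' @export
rank_ploidies <- function(x, sample_class = "region",
                          psi_grid = seq(1.5, 4, by = 0.05),
                          purity_step = 0.01, logr_amp_cutoff = 1) {
  m <- cn_matrix(x)
  ids <- colnames(m)
  if (length(sample_class) == 1 && is.null(names(sample_class))) {
    sample_class <- setNames(rep(sample_class, length(ids)), ids)
  }
  if (!all(ids %in% names(sample_class))) {
    abort("sample_class must name every sample")
  }
  grids <- purrr::map(ids, ~purity_grid_for(sample_class[[.x]],
                                            step = purity_step))
  single <- ncol(m) < 2
  if (single) warn("single sample: cross-sample distance is 0 by definition")
  amp <- m > logr_amp_cutoff
  pairs <- if (!single) utils::combn(ncol(m), 2) else NULL
  per_psi <- purrr::map_dfr(psi_grid, function(psi) {
    fits <- purrr::map2_dfr(seq_along(ids), grids, function(j, pg)
      fit_sample_purity(m[, j], psi, pg))
    cn_int <- vapply(seq_along(ids), function(j)
      pmax(round(logr_to_cn(m[, j], fits$rho[j], psi)), 0),
      numeric(nrow(m)))
    cross <- if (single) 0 else {
      mean(vapply(seq_len(ncol(pairs)), function(k) {
        i <- pairs[1, k]; j <- pairs[2, k]
        keep <- !(amp[, i] | amp[, j])
        sqrt(sum(((cn_int[keep, i] - cn_int[keep, j]) / psi)^2))
      }, 0))
    }
    tibble::tibble(psi = psi, mean_fit_error = mean(fits$fit_error),
                   cross_distance = cross,
                   purity = list(setNames(fits$rho, ids)))
  })
  minmax <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
  }
  per_psi$scaled_fit <- minmax(per_psi$mean_fit_error)
  per_psi$scaled_distance <- minmax(per_psi$cross_distance)
  per_psi$score <- sqrt(per_psi$scaled_fit^2 + per_psi$scaled_distance^2)
  per_psi$rank <- rank(per_psi$score, ties.method = "first")
  structure(list(table = per_psi, sample_class = sample_class, input = x),
            class = "ploidy_fit")
}

#' @export
print.ploidy_fit <- function(x, ...) {
  top <- dplyr::arrange(x$table, .data$rank)[1, ]
  cat("<ploidy_fit>", nrow(x$table), "candidate ploidies; rank-1 psi =",
      top$psi, "(score", signif(top$score, 3), ")\n")
  invisible(x)
}

#' @method tidy ploidy_fit
#' @export
tidy.ploidy_fit <- function(x, ...) {
  dplyr::select(x$table, "psi", "mean_fit_error", "cross_distance",
                "scaled_fit", "scaled_distance", "score", "rank")
}

#' @method glance ploidy_fit
#' @export
glance.ploidy_fit <- function(x, ...) {
  top <- dplyr::arrange(x$table, .data$rank)[1, ]
  tibble::tibble(psi = top$psi, score = top$score,
                 mean_fit_error = top$mean_fit_error,
                 cross_distance = top$cross_distance,
                 n_candidates = nrow(x$table))
}

#' Integer copy-number calls at a chosen ploidy solution
#'
#' Calls integer copy numbers at the rank-`choice` solution of a
#' [rank_ploidies()] fit. Manual curation is explicit: `choice = 2` selects
#' the second-best solution, and `psi_offsets` applies per-sample ploidy
#' adjustments (e.g. +/-0.4) with the purity refit at the adjusted ploidy.
#'
#' @param fit A `"ploidy_fit"`.
#' @param choice Solution rank to use (default 1).
#' @param psi_offsets Optional named numeric vector of per-sample ploidy
#'   offsets.
#' @param purity_step Purity grid step for refits.
#' @return Wide bin table of integer copy numbers, with attributes `psi`
#'   and `purity`.
#' @export
call_absolute_cn <- function(fit, choice = 1, psi_offsets = NULL,
                             purity_step = 0.01) {
  row <- dplyr::filter(fit$table, .data$rank == choice)
  if (nrow(row) != 1) abort("no solution at that rank")
  x <- fit$input
  m <- cn_matrix(x)
  ids <- colnames(m)
  psi0 <- row$psi
  rho <- row$purity[[1]]
  psi <- setNames(rep(psi0, length(ids)), ids)
  if (!is.null(psi_offsets)) {
    for (id in names(psi_offsets)) {
      psi[id] <- psi[id] + psi_offsets[[id]]
      pg <- purity_grid_for(fit$sample_class[[id]], step = purity_step)
      rho[id] <- fit_sample_purity(m[, id], psi[id], pg)$rho
    }
  }
  cn <- vapply(ids, function(id)
    pmax(round(logr_to_cn(m[, id], rho[id], psi[id])), 0),
    numeric(nrow(m)))
  out <- bin_table(x, cn, ids)
  attr(out, "psi") <- psi
  attr(out, "purity") <- rho
  out
}
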