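divergence_metric_names <- c("FracDiffBins", "FracDiffAltBins", "GeneDoseFDB",
                             "GeneDoseFDAB", "GeneticDistance",
                             "BreakpointDivergence")

# per-sample breakpoint set: boundary positions (between bin i and i+1, within
# chromosomes) where the gain/loss/baseline state changes
state_breakpoints <- function(s, ch) {
  n <- length(s)
  if (n < 2) return(integer(0))
  which(ch[-1] == ch[-n] & s[-1] != s[-n])
}

# core pairwise computation on integer cn vectors + integer state vectors
pair_metric <- function(metric, cna, cnb, sa, sb, ch, w) {
  switch(metric,
    FracDiffBins = mean(sa != sb),
    FracDiffAltBins = {
      den <- sum(sa != 0 | sb != 0)
      if (den == 0) 0 else sum(sa != sb) / den
    },
    GeneDoseFDB = sum(w * (sa != sb)) / sum(w),
    GeneDoseFDAB = {
      den <- sum(w * (sa != 0 | sb != 0))
      if (den == 0) 0 else sum(w * (sa != sb)) / den
    },
    GeneticDistance = sum(abs(cna - cnb)) / length(cna),
    BreakpointDivergence = {
      ba <- state_breakpoints(sa, ch)
      bb <- state_breakpoints(sb, ch)
      u <- union(ba, bb)
      if (length(u) == 0) 0 else
        (length(setdiff(ba, bb)) + length(setdiff(bb, ba))) / length(u)
    },
    abort(paste0("unknown metric '", metric, "'"))
  )
}

#' Pairwise CNA divergence between samples
#'
#' Computes one or more pairwise divergence statistics over every unordered
#' sample pair of a bin table. Gain/loss/baseline states are called against
#' each sample's own baseline ploidy (so a clonally genome-doubled pair is not
#' maximally divergent); pass `baseline` to impose a shared reference.
#'
#' Metrics:
#' \describe{
#'   \item{FracDiffBins}{bins with different state / all bins.}
#'   \item{FracDiffAltBins}{bins with different state / bins non-baseline in
#'     at least one of the pair ("proportion of aberrant genome subclonal");
#'     0 when neither sample has an alteration.}
#'   \item{GeneDoseFDB, GeneDoseFDAB}{the same two ratios with each bin
#'     weighted by its gene content.}
#'   \item{GeneticDistance}{sum of absolute integer copy-number differences,
#'     divided by the number of bins.}
#'   \item{BreakpointDivergence}{state-change boundary positions present in
#'     exactly one sample of the pair, as a proportion of boundaries present
#'     in either (0 if neither has a breakpoint).}
#' }
#'
#' @param x Bin table of integer copy numbers.
#' @param metric Metric name(s); default all six.
#' @param weights Optional per-bin nonnegative gene-count weights (numeric
#'   vector of grid length); required only by the GeneDose metrics, which fall
#'   back to unit weights when omitted.
#' @param baseline As in [pga()].
#' @return Long tibble: `sample_a`, `sample_b`, `metric`, `value`.
#' @export
pairwise_divergence <- function(x, metric = divergence_metric_names,
                                weights = NULL, baseline = NULL) {
  metric <- match.arg(metric, divergence_metric_names, several.ok = TRUE)
  m <- cn_matrix(x)
  if (ncol(m) < 2) abort("need at least two samples")
  bl <- resolve_baseline(m, baseline)
  s <- state_matrix(m, bl)
  ch <- chrom_index(x)
  w <- weights %||% rep(1, nrow(m))
  if (length(w) != nrow(m) || any(w < 0) || sum(w) <= 0) {
    abort("weights must be nonnegative, of grid length, with positive sum")
  }
  ids <- colnames(m)
  pairs <- utils::combn(length(ids), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tibble::tibble(
      sample_a = ids[i], sample_b = ids[j], metric = metric,
      value = unname(vapply(metric, pair_metric, 0, cna = m[, i],
                            cnb = m[, j], sa = s[, i], sb = s[, j],
                            ch = ch, w = w))
    )
  })
}

cross_pairs <- function(a, b) {
  if (is.null(b) || setequal(a, b)) {
    if (length(a) < 2) abort("need at least two samples for within-set pairs")
    p <- utils::combn(a, 2)
    tibble::tibble(sample_a = p[1, ], sample_b = p[2, ])
  } else {
    tidyr::expand_grid(sample_a = a, sample_b = b)
  }
}

#' Divergence between (or within) sample groups
#'
#' The mean (and min-max range) of a pairwise divergence metric over all
#' cross pairs between two sample sets, or over all unordered within-set
#' pairs when a single set is given. With the default metric
#' (`FracDiffAltBins`, the proportion of the aberrant genome that is
#' subclonal) this is the "divergence" summary used to compare lesions and
#' timepoints.
#'
#' @param x Bin table of integer copy numbers.
#' @param samples_a,samples_b Character vectors of sample ids; `samples_b`
#'   omitted (or equal to `samples_a`) means within-set pairs.
#' @param metric One metric name.
#' @inheritParams pairwise_divergence
#' @return One-row tibble: `metric`, `mean`, `min`, `max`, `n_pairs`.
#' @export
divergence <- function(x, samples_a = sample_cols(x), samples_b = NULL,
                       metric = "FracDiffAltBins", weights = NULL,
                       baseline = NULL) {
  if (length(samples_a) == 0 || (!is.null(samples_b) && length(samples_b) == 0)) {
    abort("empty sample set")
  }
  pv <- pairwise_divergence(x[, c("chrom", "start", "end",
                                  union(samples_a, samples_b))],
                            metric = metric, weights = weights,
                            baseline = baseline)
  pr <- cross_pairs(samples_a, samples_b)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  vals <- pv$value[match(key(pr$sample_a, pr$sample_b),
                         key(pv$sample_a, pv$sample_b))]
  tibble::tibble(metric = metric, mean = mean(vals),
                 min = min(vals), max = max(vals), n_pairs = length(vals))
}

#' Proportion of the altered genome that is subclonal
#'
#' Among bins non-baseline in at least one sample, the fraction whose
#' gain/loss/baseline state vector is not identical across all samples.
#' States are called against each sample's own baseline ploidy.
#'
#' @inheritParams pga
#' @return A single fraction in `[0, 1]` (0 when no bin is altered).
#' @export
proportion_subclonal <- function(x, baseline = NULL) {
  m <- cn_matrix(x)
  if (ncol(m) < 2) abort("need at least two samples")
  s <- state_matrix(m, resolve_baseline(m, baseline))
  altered <- rowSums(s != 0) > 0
  if (!any(altered)) return(0)
  disc <- apply(s[altered, , drop = FALSE], 1, function(v) any(v != v[1]))
  mean(disc)
}

#' Mean absolute PGA difference between sample groups
#'
#' Mean over cross pairs of the absolute difference in percentage genome
#' altered, in percentage points.
#'
#' @inheritParams divergence
#' @return One-row tibble: `mean_pga_diff_pp`, `n_pairs`.
#' @export
mean_pga_difference <- function(x, samples_a = sample_cols(x),
                                samples_b = NULL, baseline = NULL) {
  p <- pga(x, baseline = baseline)
  pv <- setNames(p$pga, p$sample_id)
  pr <- cross_pairs(samples_a, samples_b)
  d <- abs(pv[pr$sample_a] - pv[pr$sample_b]) * 100
  tibble::tibble(mean_pga_diff_pp = mean(d), n_pairs = length(d))
}
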