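# small grids and profiles shared across tests

tiny_grid <- function(bins_per_chrom = c(6, 4)) {
  chrom <- rep(as.character(seq_along(bins_per_chrom)), bins_per_chrom)
  start <- unlist(lapply(bins_per_chrom, function(n) (seq_len(n) - 1) * 10))
  bin_grid(chrom, start, start + 10)
}

tbl_of <- function(grid, ...) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  bin_table(grid, m)
}

random_cn_table <- function(n_bins_per_chrom = c(8, 6, 5), n_samples = 3,
                            states = 0:5) {
  g <- tiny_grid(n_bins_per_chrom)
  m <- matrix(sample(states, nrow(g) * n_samples, replace = TRUE),
              nrow(g), n_samples,
              dimnames = list(NULL, paste0("s", seq_len(n_samples))))
  bin_table(g, m)
}

diploid_go <- function(grid) {
  bin_table(grid, matrix(2, nrow(grid), 1, dimnames = list(NULL, "go")))
}

# brute-force oracles, written independently of the implementation ------

oracle_median_low <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else v[n / 2]
}

oracle_states <- function(cn, baseline) {
  out <- character(length(cn))
  for (i in seq_along(cn)) {
    out[i] <- if (cn[i] > baseline) "gain"
      else if (cn[i] < baseline) "loss" else "baseline"
  }
  out
}

oracle_segments <- function(cn, chrom) {
  total <- 0L
  for (cc in unique(chrom)) {
    v <- cn[chrom == cc]
    runs <- 1L
    for (i in seq_along(v)[-1]) if (v[i] != v[i - 1]) runs <- runs + 1L
    total <- total + runs
  }
  total
}

oracle_breakpoints <- function(states, chrom) {
  out <- integer(0)
  for (i in seq_along(states)[-1]) {
    if (chrom[i] == chrom[i - 1] && states[i] != states[i - 1]) {
      out <- c(out, i - 1L)
    }
  }
  out
}

# the six divergence metrics as explicit per-bin loops
oracle_pair_metric <- function(metric, cna, cnb, chrom, w = rep(1, length(cna))) {
  bla <- oracle_median_low(cna); blb <- oracle_median_low(cnb)
  sa <- oracle_states(cna, bla); sb <- oracle_states(cnb, blb)
  diff_n <- 0; alt_n <- 0; wdiff <- 0; walt <- 0; gd <- 0
  for (i in seq_along(cna)) {
    if (sa[i] != sb[i]) { diff_n <- diff_n + 1; wdiff <- wdiff + w[i] }
    if (sa[i] != "baseline" || sb[i] != "baseline") {
      alt_n <- alt_n + 1; walt <- walt + w[i]
    }
    gd <- gd + abs(cna[i] - cnb[i])
  }
  switch(metric,
    FracDiffBins = diff_n / length(cna),
    FracDiffAltBins = if (alt_n == 0) 0 else diff_n / alt_n,
    GeneDoseFDB = wdiff / sum(w),
    GeneDoseFDAB = if (walt == 0) 0 else wdiff / walt,
    GeneticDistance = gd / length(cna),
    BreakpointDivergence = {
      ba <- oracle_breakpoints(sa, chrom); bb <- oracle_breakpoints(sb, chrom)
      u <- union(ba, bb)
      if (length(u) == 0) 0 else
        length(c(setdiff(ba, bb), setdiff(bb, ba))) / length(u)
    }
  )
}

# two-sided Fisher exact p by full enumeration over tables with fixed margins
oracle_fisher_p <- function(a, b, c_, d_) {
  n <- a + b + c_ + d_
  r1 <- a + b; c1 <- a + c_
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1))
  }, 0)
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sided exact binomial p against 0.5 by enumeration
oracle_binom_p <- function(a, b) {
  n <- a + b
  probs <- vapply(0:n, function(x) exp(lchoose(n, x) - n * log(2)), 0)
  p_obs <- probs[a + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# naive branch-event extraction: scan bins, open/close runs
oracle_branch_events <- function(pv, cv, chrom) {
  out <- NULL
  state <- function(i) sign(cv[i] - pv[i])
  i <- 1
  while (i <= length(pv)) {
    if (state(i) != 0) {
      j <- i
      while (j < length(pv) && chrom[j + 1] == chrom[i] &&
             state(j + 1) == state(i)) j <- j + 1
      out <- rbind(out, data.frame(start_bin = i, end_bin = j,
                                   direction = if (state(i) > 0) "gain"
                                               else "loss"))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# run a simulation, retrying with shifted seeds on stochastic extinction
sim_to_target <- function(cfg, seed) {
  # the event budget bounds rare near-critical meanders under strong
  # selection; stalled runs are retried like extinct ones
  for (s in seed + 1000L * (0:19)) {
    sim <- simulate_cin(cfg, seed = s, max_events = 60000)
    if (sim$outcome == "reached_target") return(sim)
  }
  stop("no viable run in 20 attempts")
}
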