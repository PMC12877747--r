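#' Karyotype fitness landscape
#'
#' A single-peak landscape over karyotype space. A gland with karyotype `G`
#' has net growth rate `(b0 - d0) / (1 + alpha * d(G, Go))` where `d` is the
#' L1 distance over bins to the optimal karyotype `Go`. `alpha = 0` gives a
#' flat (neutral) landscape; larger `alpha` imposes stronger negative
#' selection on karyotypes away from the optimum. The fitness change is
#' absorbed either by the birth rate (`mode = "birth"`: death fixed at `d0`)
#' or the death rate (`mode = "death"`: birth fixed at `b0`).
#'
#' @param go Optimal karyotype: a bin table with exactly one sample column.
#' @param alpha Selection strength, `>= 0`.
#' @param b0,d0 Birth/death rate of the optimal karyotype per unit time,
#'   `b0 > d0 >= 0`.
#' @param mode Which rate absorbs the fitness change.
#' @return A list of class `"fitness_landscape"`.
#' @export
fitness_landscape <- function(go, alpha, b0 = 1, d0 = 0.2,
                              mode = c("birth", "death")) {
  mode <- match.arg(mode)
  m <- cn_matrix(go)
  if (ncol(m) != 1) abort("go must carry exactly one sample column")
  if (alpha < 0) abort("alpha must be >= 0")
  if (!(b0 > d0 && d0 >= 0)) abort("need b0 > d0 >= 0")
  structure(list(grid = go[c("chrom", "start", "end")], go = as.numeric(m),
                 alpha = alpha, b0 = b0, d0 = d0, mode = mode),
            class = "fitness_landscape")
}

rates_for <- function(kary, landscape) {
  d <- sum(abs(kary - landscape$go))
  net <- (landscape$b0 - landscape$d0) / (1 + landscape$alpha * d)
  if (landscape$mode == "birth") c(landscape$d0 + net, landscape$d0)
  else c(landscape$b0, landscape$b0 - net)
}

#' Birth and death rate of a karyotype
#'
#' @param karyotype Bin table with one sample column, on the landscape grid.
#' @param landscape A [fitness_landscape()].
#' @return Tibble: `distance`, `birth`, `death`, `net_growth`.
#' @export
net_growth <- function(karyotype, landscape) {
  check_shared_grid(karyotype, landscape$grid)
  k <- as.numeric(cn_matrix(karyotype))
  r <- rates_for(k, landscape)
  tibble::tibble(distance = sum(abs(k - landscape$go)),
                 birth = r[1], death = r[2], net_growth = r[1] - r[2])
}

#' CNA length sampler
#'
#' Bundled mixture used when an empirical length distribution is not
#' supplied: with probability `p_whole` the event spans the whole chromosome
#' it starts on; otherwise its length in bins is `1 + Geometric`, with the
#' given mean. Lengths are truncated at the chromosome end on application.
#'
#' @param mean_len Mean length in bins of the non-whole-chromosome component.
#' @param p_whole Probability of a whole-chromosome event.
#' @param lengths Optional vector of empirical lengths (in bins) to resample
#'   from instead of the mixture.
#' @return A function `f(n)` returning `n` lengths; `Inf` encodes a
#'   whole-chromosome event.
#' @export
cna_length_sampler <- function(mean_len = 20, p_whole = 0.3, lengths = NULL) {
  if (!is.null(lengths)) {
    lengths <- as.numeric(lengths)
    if (any(lengths < 1)) abort("empirical lengths must be >= 1 bin")
    return(function(n) sample(lengths, n, replace = TRUE))
  }
  function(n) {
    ifelse(runif(n) < p_whole, Inf, 1 + stats::rgeom(n, 1 / mean_len))
  }
}

# events as a k x 3 matrix (start_bin, end_bin, delta); NULL when k = 0
draw_events_mat <- function(mu, n_bins, chrom_first, chrom_last, size_fun) {
  k <- rpois(1L, mu)
  if (k == 0L) return(NULL)
  s <- sample.int(n_bins, k, replace = TRUE)
  len <- size_fun(k)
  e <- ifelse(is.infinite(len), chrom_last[s], pmin(s + len - 1, chrom_last[s]))
  s <- ifelse(is.infinite(len), chrom_first[s], s)
  cbind(start_bin = s, end_bin = e,
        delta = sample(c(-1, 1), k, replace = TRUE))
}

apply_events <- function(kary, ev, max_cn) {
  for (r in seq_len(nrow(ev))) {
    idx <- ev[r, 1]:ev[r, 2]
    if (ev[r, 3] > 0) {
      v <- kary[idx]
      kary[idx] <- ifelse(v > 0, pmin(v + 1, max_cn), 0)
    } else {
      kary[idx] <- pmax(kary[idx] - 1, 0)
    }
  }
  kary
}

#' Draw the CNAs of one gland division
#'
#' The number of events is Poisson with mean `mu`; each event starts at a
#' uniformly chosen bin, takes its length from the sampler (truncated at the
#' chromosome end, or spanning the whole chromosome for the whole-chromosome
#' component), and gains or loses one copy with equal probability. Events
#' never span two chromosomes.
#'
#' @param mu CNA rate per gland division (Poisson mean).
#' @param grid A [bin_grid()].
#' @param size_sampler Length sampler, see [cna_length_sampler()].
#' @return Tibble: `start_bin`, `end_bin`, `delta` (0 rows when no event).
#' @export
draw_cnas <- function(mu, grid, size_sampler = cna_length_sampler()) {
  if (mu < 0) abort("mu must be >= 0")
  cb <- chrom_bounds(grid)
  ev <- draw_events_mat(mu, nrow(grid), cb$first[cb$id], cb$last[cb$id],
                        size_sampler)
  if (is.null(ev)) {
    return(tibble::tibble(start_bin = integer(0), end_bin = integer(0),
                          delta = numeric(0)))
  }
  tibble::as_tibble(ev)
}

#' Simulation configuration
#'
#' @param landscape A [fitness_landscape()].
#' @param mu CNA rate per gland division (Poisson mean), `>= 0`.
#' @param size_sampler CNA length sampler ([cna_length_sampler()]).
#' @param founder Founder karyotype: one-sample bin table on the landscape
#'   grid; defaults to the optimal karyotype.
#' @param n_target Population size at which the simulation stops.
#' @param max_cn Copy-number cap per bin; bins at 0 copies cannot be
#'   regained.
#' @param both_daughters Should both daughters of a division draw CNAs
#'   independently (default), or only one?
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(landscape, mu, size_sampler = cna_length_sampler(),
                       founder = NULL, n_target = 5000, max_cn = 8,
                       both_daughters = TRUE) {
  if (mu < 0) abort("mu must be >= 0")
  if (n_target < 1) abort("n_target must be >= 1")
  if (max_cn < 1) abort("max_cn must be >= 1")
  fvec <- if (is.null(founder)) landscape$go else {
    check_shared_grid(founder, landscape$grid)
    as.numeric(cn_matrix(founder))
  }
  structure(list(landscape = landscape, mu = mu, size_sampler = size_sampler,
                 founder = fvec, n_target = n_target, max_cn = max_cn,
                 both_daughters = both_daughters),
            class = "sim_config")
}

#' Simulate gland-level CNA evolution
#'
#' Exact stochastic (Gillespie) simulation of a birth-death branching process
#' starting from one founder gland (or a supplied initial population) until
#' the population reaches `n_target` or goes extinct. At each division every
#' daughter (both, by default) independently draws a Poisson number of CNAs.
#' Glands sharing a karyotype lineage are grouped into clones: the state is a
#' clone table with counts, per-clone rates from the fitness landscape, a
#' parent pointer and the CNA events that created each clone, which together
#' form the exact genealogy of karyotype lineages. Runs are reproducible
#' given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @param init Optional initial population (list with `kary` matrix and
#'   integer `n`), e.g. from [bottleneck()]; overrides the founder.
#' @param max_events Budget on the number of birth/death events; a run that
#'   exhausts it before reaching `n_target` returns with outcome
#'   `"stalled"` (parameter regimes where even the fittest karyotype cannot
#'   sustain growth sit near criticality and would otherwise run without
#'   bound).
#' @return An object of class `"cin_sim"`; see [sample_glands()], [tidy()],
#'   [glance()].
#' @export
simulate_cin <- function(config, seed = NULL, init = NULL,
                         max_events = Inf) {
  if (!is.null(seed)) set.seed(seed)
  ls <- config$landscape
  grid <- ls$grid
  C <- nrow(grid)
  cb <- chrom_bounds(grid)
  cfirst <- cb$first[cb$id]; clast <- cb$last[cb$id]
  size_fun <- config$size_sampler
  mu <- config$mu; max_cn <- config$max_cn

  cap <- 256L
  kary <- matrix(0, cap, C)
  parent <- integer(cap); n <- integer(cap)
  b <- numeric(cap); d <- numeric(cap); t_born <- numeric(cap)
  events <- vector("list", cap)

  if (is.null(init)) {
    init <- list(kary = matrix(config$founder, 1, C), n = 1L)
  }
  K <- nrow(init$kary)
  while (cap < K) cap <- cap * 2L
  if (cap > nrow(kary)) {
    kary <- matrix(0, cap, C); parent <- integer(cap); n <- integer(cap)
    b <- numeric(cap); d <- numeric(cap); t_born <- numeric(cap)
    events <- vector("list", cap)
  }
  for (i in seq_len(K)) {
    kary[i, ] <- init$kary[i, ]
    n[i] <- init$n[i]; parent[i] <- 0L
    r <- rates_for(kary[i, ], ls); b[i] <- r[1]; d[i] <- r[2]
  }
  N <- sum(n[seq_len(K)])
  t <- 0

  grow <- function() {
    cap2 <- cap * 2L
    kary2 <- matrix(0, cap2, C); kary2[seq_len(cap), ] <- kary
    kary <<- kary2
    parent <<- c(parent, integer(cap)); n <<- c(n, integer(cap))
    b <<- c(b, numeric(cap)); d <<- c(d, numeric(cap))
    t_born <<- c(t_born, numeric(cap))
    events2 <- vector("list", cap2); events2[seq_len(cap)] <- events
    events <<- events2
    cap <<- cap2
  }

  new_clone <- function(par, ev) {
    if (K + 1L > cap) grow()
    K <<- K + 1L
    kk <- apply_events(kary[par, ], ev, max_cn)
    kary[K, ] <<- kk
    parent[K] <<- par; n[K] <<- 1L; t_born[K] <<- t
    events[[K]] <<- ev
    r <- rates_for(kk, ls); b[K] <<- r[1]; d[K] <<- r[2]
  }

  # only living clones carry rate mass; iterating over them (rather than
  # every lineage ever created) keeps the per-event cost bounded by the
  # population size
  alive <- which(n[seq_len(K)] > 0L)
  outcome <- "reached_target"
  n_events <- 0
  repeat {
    if (N == 0) { outcome <- "extinct"; break }
    if (N >= config$n_target) break
    if (n_events >= max_events) { outcome <- "stalled"; break }
    n_events <- n_events + 1
    tot <- n[alive] * (b[alive] + d[alive])
    Tsum <- sum(tot)
    t <- t + rexp(1L, Tsum)
    i <- alive[sample.int(length(alive), 1L, prob = tot)]
    if (runif(1L) < b[i] / (b[i] + d[i])) {
      # division: parent replaced by two daughters
      n[i] <- n[i] - 1L; N <- N + 1L
      n_draw <- if (config$both_daughters) 2L else 1L
      for (dau in 1:2) {
        ev <- if (dau <= n_draw) {
          draw_events_mat(mu, C, cfirst, clast, size_fun)
        } else NULL
        if (is.null(ev)) n[i] <- n[i] + 1L else {
          new_clone(i, ev)
          alive <- c(alive, K)
        }
      }
      if (n[i] == 0L) alive <- alive[alive != i]
    } else {
      n[i] <- n[i] - 1L; N <- N - 1L
      if (n[i] == 0L) alive <- alive[alive != i]
    }
  }

  ii <- seq_len(K)
  structure(list(grid = grid, kary = kary[ii, , drop = FALSE],
                 parent = parent[ii], n = n[ii], t_born = t_born[ii],
                 events = events[ii], time = t, population = N,
                 outcome = outcome, config = config, seed = seed),
            class = "cin_sim")
}

#' @export
print.cin_sim <- function(x, ...) {
  cat("<cin_sim> ", x$outcome, ": population ", x$population,
      ", ", length(x$n), " karyotype lineages, t = ", signif(x$time, 4),
      "\n", sep = "")
  invisible(x)
}

#' Replay the event log of a clone
#'
#' Reconstructs a clone's karyotype by applying its ancestral CNA events, in
#' order, to the founder karyotype. Used to verify that every karyotype in
#' the population is consistent with the logged genealogy.
#'
#' @param sim A `"cin_sim"`.
#' @param clone Clone index.
#' @return Integer karyotype vector.
#' @export
replay_karyotype <- function(sim, clone) {
  chain <- integer(0)
  i <- clone
  while (i != 0L) { chain <- c(i, chain); i <- sim$parent[i] }
  k <- sim$kary[chain[1], ]
  for (i in chain[-1]) k <- apply_events(k, sim$events[[i]], sim$config$max_cn)
  k
}

#' Sample glands from a simulated population
#'
#' Uniform sample of `n` glands without replacement from the final
#' population; reproducible given `seed`.
#'
#' @param sim A `"cin_sim"`.
#' @param n Number of glands.
#' @param seed Optional integer seed.
#' @return Wide bin table with one column per gland; the originating clone
#'   index of each gland is stored in attribute `"clones"`.
#' @export
sample_glands <- function(sim, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n > sim$population) abort("n exceeds the population size")
  pool <- rep.int(seq_along(sim$n), sim$n)
  cl <- sort(sample(pool, n))
  m <- t(sim$kary[cl, , drop = FALSE])
  colnames(m) <- sprintf("gland_%03d", seq_len(n))
  out <- bin_table(sim$grid, m)
  attr(out, "clones") <- cl
  out
}

#' Population bottleneck
#'
#' Uniformly samples `k` glands without replacement from the final
#' population (e.g. a 10-cell metastatic bottleneck). The result can be
#' passed as `init` to [simulate_cin()] to regrow the population.
#'
#' @inheritParams sample_glands
#' @param k Number of surviving glands, `1 <= k <= population`.
#' @return List with `kary` (karyotype matrix of surviving clones) and `n`
#'   (their counts), of class `"gland_population"`.
#' @export
bottleneck <- function(sim, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (k < 1 || k > sim$population) abort("k must lie in [1, population]")
  pool <- rep.int(seq_along(sim$n), sim$n)
  cl <- sample(pool, k)
  cnt <- table(cl)
  idx <- as.integer(names(cnt))
  structure(list(kary = sim$kary[idx, , drop = FALSE],
                 n = as.integer(cnt), source_clones = idx),
            class = "gland_population")
}

#' Mean distance to the fitness optimum
#'
#' Population-weighted mean L1 karyotype distance to the landscape optimum.
#'
#' @param sim A `"cin_sim"`.
#' @return A single number.
#' @export
mean_dist_to_optimum <- function(sim) {
  go <- sim$config$landscape$go
  alive <- sim$n > 0
  dd <- rowSums(abs(sweep(sim$kary[alive, , drop = FALSE], 2, go)))
  sum(dd * sim$n[alive]) / sum(sim$n[alive])
}

#' Long event log of a simulation
#'
#' @param sim A `"cin_sim"`.
#' @return Tibble: `clone`, `parent`, `t_born`, `start_bin`, `end_bin`,
#'   `delta` (one row per CNA event).
#' @export
event_log <- function(sim) {
  rows <- purrr::map_dfr(seq_along(sim$events), function(i) {
    ev <- sim$events[[i]]
    if (is.null(ev)) return(NULL)
    tibble::tibble(clone = i, parent = sim$parent[i], t_born = sim$t_born[i],
                   start_bin = ev[, 1], end_bin = ev[, 2], delta = ev[, 3])
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(clone = integer(0), parent = integer(0),
                           t_born = numeric(0), start_bin = integer(0),
                           end_bin = integer(0), delta = numeric(0))
  }
  rows
}

#' @method tidy cin_sim
#' @export
tidy.cin_sim <- function(x, ...) {
  go <- x$config$landscape$go
  tibble::tibble(
    clone = seq_along(x$n), parent = x$parent, n = x$n, t_born = x$t_born,
    n_events = vapply(x$events, function(e) if (is.null(e)) 0L else nrow(e), 0L),
    dist_to_optimum = rowSums(abs(sweep(x$kary, 2, go))),
    birth = vapply(seq_along(x$n), function(i)
      rates_for(x$kary[i, ], x$config$landscape)[1], 0),
    death = vapply(seq_along(x$n), function(i)
      rates_for(x$kary[i, ], x$config$landscape)[2], 0)
  )
}

#' @method glance cin_sim
#' @export
glance.cin_sim <- function(x, ...) {
  tibble::tibble(population = x$population, n_clones = sum(x$n > 0),
                 n_lineages = length(x$n), time = x$time,
                 outcome = x$outcome,
                 mean_dist_to_optimum = if (x$population > 0)
                   mean_dist_to_optimum(x) else NA_real_)
}
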