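small_go <- function(bins = c(10, 8, 6)) diploid_go(tiny_grid(bins))

test_that("net growth follows the landscape relation", {
  go <- small_go()
  ls <- fitness_landscape(go, alpha = 1, b0 = 1, d0 = 0.5)
  # at the optimum the net growth is exactly b0 - d0
  expect_equal(net_growth(go, ls)$net_growth, 0.5)
  # distance 1 halves it: (1 - 0.5) / (1 + 1 * 1)
  k1 <- go; k1[[4]][1] <- 3
  names(k1)[4] <- "k"
  expect_equal(net_growth(k1, ls)$net_growth, 0.25)
  expect_equal(net_growth(k1, ls)$distance, 1)
  # flat landscape: any karyotype has the optimal net growth
  ls0 <- fitness_landscape(go, alpha = 0, b0 = 1, d0 = 0.5)
  kfar <- go; kfar[[4]] <- kfar[[4]] + 3; names(kfar)[4] <- "k"
  expect_equal(net_growth(kfar, ls0)$net_growth, 0.5)
  # death mode absorbs the change with the same net growth
  lsd <- fitness_landscape(go, alpha = 1, b0 = 1, d0 = 0.5, mode = "death")
  expect_equal(net_growth(k1, lsd)$birth, 1)
  expect_equal(net_growth(k1, lsd)$net_growth, 0.25)
})

test_that("CNA draws respect the Poisson rate and chromosome bounds", {
  g <- tiny_grid(c(10, 8, 6))
  set.seed(52)
  expect_equal(nrow(draw_cnas(0, g)), 0)
  ch <- rep(c("1", "2", "3"), c(10, 8, 6))
  counts <- integer(2000)
  for (i in seq_along(counts)) {
    ev <- draw_cnas(0.2, g)
    counts[i] <- nrow(ev)
    if (nrow(ev) > 0) {
      # an event never spans two chromosomes
      expect_true(all(ch[ev$start_bin] == ch[ev$end_bin]))
      expect_true(all(ev$start_bin <= ev$end_bin))
      expect_true(all(ev$delta %in% c(-1, 1)))
    }
  }
  se <- sqrt(0.2 / length(counts))
  expect_lt(abs(mean(counts) - 0.2), 3 * se)
})

test_that("mu = 0 conserves the founder exactly", {
  go <- small_go()
  cfg <- sim_config(fitness_landscape(go, alpha = 0), mu = 0, n_target = 200)
  sim <- sim_to_target(cfg, seed = 1)
  expect_equal(sim$outcome, "reached_target")
  expect_equal(length(sim$n), 1) # a single lineage, the founder's
  expect_equal(sim$kary[1, ], cn_matrix(go)[, 1], ignore_attr = TRUE)
  g <- sample_glands(sim, 10, seed = 2)
  expect_equal(summarize_profiles(g)$mean_gdist, 0)
})

test_that("simulation is reproducible given a seed", {
  go <- small_go()
  cfg <- sim_config(fitness_landscape(go, alpha = 1), mu = 0.3,
                    n_target = 150)
  a <- simulate_cin(cfg, seed = 9)
  b <- simulate_cin(cfg, seed = 9)
  expect_identical(a$kary, b$kary)
  expect_identical(a$n, b$n)
  expect_identical(a$time, b$time)
  expect_identical(sample_glands(a, 5, seed = 3), sample_glands(b, 5, seed = 3))
})

test_that("karyotypes replay exactly from the event log", {
  go <- small_go()
  cfg <- sim_config(fitness_landscape(go, alpha = 0.5), mu = 0.4,
                    n_target = 200)
  sim <- sim_to_target(cfg, seed = 10)
  for (cl in sample(seq_along(sim$n), min(25, length(sim$n)))) {
    expect_equal(replay_karyotype(sim, cl), sim$kary[cl, ])
  }
  # event log rows match per-clone event matrices
  ev <- event_log(sim)
  expect_equal(nrow(ev),
               sum(vapply(sim$events,
                          function(e) if (is.null(e)) 0L else nrow(e), 0L)))
})

test_that("divergence increases with mu under neutrality", {
  go <- small_go(c(12, 10, 8))
  res <- purrr::map_dbl(c(0.1, 0.4), function(mu) {
    mean(purrr::map_dbl(1:4, function(r) {
      cfg <- sim_config(fitness_landscape(go, alpha = 0), mu = mu,
                        n_target = 400)
      sim <- sim_to_target(cfg, seed = 100 * r + round(1000 * mu))
      summarize_profiles(sample_glands(sim, 20, seed = r))$mean_gdist
    }))
  })
  expect_gt(res[2], res[1])
  expect_gt(res[1], 0)
})

test_that("selection keeps the population near the optimal karyotype", {
  go <- small_go(c(12, 10, 8))
  dist <- purrr::map_dbl(c(0, 10), function(a) {
    mean(purrr::map_dbl(1:4, function(r) {
      cfg <- sim_config(fitness_landscape(go, alpha = a), mu = 0.3,
                        n_target = 400)
      mean_dist_to_optimum(sim_to_target(cfg, seed = 7000 + 10 * a + r))
    }))
  })
  expect_lt(dist[2], dist[1])
})

test_that("a diploid founder climbs toward a nearby aneuploid optimum", {
  # realistic genome, optimum one small-chromosome trisomy away: surviving
  # populations acquire the trisomy and converge on the optimum
  g <- default_bin_grid()
  opt <- rep(2, nrow(g)); opt[g$chrom == "22"] <- 3
  go <- bin_table(g, matrix(opt, ncol = 1, dimnames = list(NULL, "go")))
  founder <- bin_table(g, matrix(2, nrow(g), 1,
                                 dimnames = list(NULL, "f")))
  cfg <- sim_config(fitness_landscape(go, alpha = 5), mu = 0.1,
                    n_target = 1500, founder = founder)
  d0 <- sum(abs(cn_matrix(founder)[, 1] - opt)) # 5 bins away
  final <- purrr::map_dbl(c(38, 56), function(s) {
    sim <- simulate_cin(cfg, seed = s, max_events = 60000)
    expect_equal(sim$outcome, "reached_target")
    mean_dist_to_optimum(sim)
  })
  expect_lt(mean(final), d0)
})

test_that("bottleneck subsamples the population and regrowth continues", {
  go <- small_go()
  cfg <- sim_config(fitness_landscape(go, alpha = 0), mu = 0.3,
                    n_target = 300)
  sim <- sim_to_target(cfg, seed = 11)
  # k = population is the identity on counts
  all_k <- bottleneck(sim, sim$population, seed = 1)
  expect_equal(sum(all_k$n), sim$population)
  bn <- bottleneck(sim, 10, seed = 2)
  expect_equal(sum(bn$n), 10)
  expect_error(bottleneck(sim, sim$population + 1), "k must lie")
  # diversity after a 10-gland bottleneck + regrowth is not above the
  # pre-bottleneck diversity (same final population size)
  pre <- summarize_profiles(sample_glands(sim, 25, seed = 3))$mean_gdist
  post <- purrr::map_dbl(1:5, function(r) {
    b <- bottleneck(sim, 10, seed = 20 + r)
    re <- simulate_cin(sim_config(fitness_landscape(go, alpha = 0), mu = 0,
                                  n_target = 300), seed = r, init = b)
    summarize_profiles(sample_glands(re, 25, seed = r))$mean_gdist
  })
  expect_lte(mean(post), pre)
})

test_that("gland sampling is uniform and bounded", {
  go <- small_go()
  cfg <- sim_config(fitness_landscape(go, alpha = 0), mu = 0.2,
                    n_target = 100)
  sim <- sim_to_target(cfg, seed = 12)
  full <- sample_glands(sim, sim$population, seed = 1)
  expect_equal(length(sample_cols(full)), sim$population)
  expect_error(sample_glands(sim, sim$population + 1), "exceeds")
  expect_identical(sample_glands(sim, 7, seed = 5),
                   sample_glands(sim, 7, seed = 5))
})

test_that("extinction is reported as an outcome, not an error", {
  go <- small_go()
  # death rate nearly equal to birth: frequent extinctions from 1 founder
  ls <- fitness_landscape(go, alpha = 0, b0 = 1, d0 = 0.95)
  extinct <- FALSE
  for (s in 1:40) {
    sim <- simulate_cin(sim_config(ls, mu = 0, n_target = 500), seed = s)
    if (sim$outcome == "extinct") { extinct <- TRUE; break }
  }
  expect_true(extinct)
  expect_equal(sim$population, 0)
})
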