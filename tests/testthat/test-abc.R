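# a cheap deterministic-ish stub standing in for the gland simulator: maps
# (mu, alpha) to a smooth statistic vector plus small Gaussian noise, so the
# ABC machinery can be exercised without birth-death runs
stub_simulator <- function(noise = 0.01) {
  function(mu, alpha) {
    base <- c(mu / (1 + alpha), mu * 2 / (1 + alpha), mu / 2, mu / 10,
              1 - 1 / (1 + mu), 20 + 5 * mu)
    tibble::as_tibble(setNames(as.list(base + rnorm(6, 0, noise)),
                               c("mean_poags", "mean_gdist", "mean_pga",
                                 "sd_pga", "prop_subclonal", "mean_ns")))
  }
}

test_that("summary statistics behave at the boundaries", {
  g <- tiny_grid(c(8, 6))
  x <- tbl_of(g, a = rep(2, 14), b = rep(2, 14))
  s <- summarize_profiles(x)
  expect_equal(s$mean_poags, 0)
  expect_equal(s$mean_gdist, 0)
  expect_equal(s$prop_subclonal, 0)
  expect_equal(s$mean_ns, 2)
  expect_error(summarize_profiles(x[, 1:4]), "two profiles")
  # round trip through TSV leaves the statistics unchanged
  y <- random_cn_table(c(8, 6), 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cn_table(y, path)
  expect_equal(summarize_profiles(read_cn_table(path)),
               summarize_profiles(y))
})

test_that("a replayed prior draw is accepted at any acceptance quantile", {
  set.seed(73)
  sim <- stub_simulator(noise = 0)
  ref <- abc_reference(sim, "selection", n_sims = 100, seed = 74)
  # observe exactly the statistics of draw 17
  obs <- ref[17, summary_stat_names]
  fit <- abc_fit(obs, "selection", ref = ref, accept_quantile = 0.01)
  acc <- tidy(fit)
  expect_true(any(abs(acc$mu - ref$mu[17]) < 1e-12))
  expect_equal(min(fit$draws$distance), 0)
})

test_that("accepted draws stay in the prior support and shrink with eps", {
  set.seed(75)
  sim <- stub_simulator()
  ref <- abc_reference(sim, "selection", n_sims = 300, seed = 76)
  obs <- sim(0.4, 1)
  pr <- list(mu = c(0.1, 1), alpha = c(1e-3, 10))
  fits <- lapply(c(0.3, 0.1, 0.03), function(q)
    abc_fit(obs, "selection", ref = ref, accept_quantile = q, priors = pr))
  for (f in fits) {
    acc <- tidy(f)
    expect_true(all(acc$mu >= pr$mu[1] & acc$mu <= pr$mu[2]))
    expect_true(all(acc$alpha >= pr$alpha[1] & acc$alpha <= pr$alpha[2]))
  }
  # shrinking the acceptance quantile concentrates the posterior
  v <- vapply(fits, function(f) var(tidy(f)$mu), 0)
  expect_true(all(diff(v) <= 1e-9 + 0.05 * abs(v[-3])))
  expect_lte(nrow(tidy(fits[[3]])), nrow(tidy(fits[[1]])))
})

test_that("neutral fits pin alpha at zero", {
  set.seed(77)
  sim <- stub_simulator()
  ref <- abc_reference(sim, "neutral", n_sims = 100, seed = 78)
  expect_true(all(ref$alpha == 0))
  fit <- abc_fit(sim(0.3, 0), "neutral", ref = ref)
  expect_true(all(tidy(fit)$alpha == 0))
})

test_that("a point-mass posterior gives DIC = D(theta-hat) exactly", {
  set.seed(79)
  sim <- stub_simulator(noise = 0)
  ref <- abc_reference(sim, "selection", n_sims = 60, seed = 80)
  obs <- ref[5, summary_stat_names]
  # accept only the zero-distance draw
  fit <- abc_fit(obs, "selection", ref = ref, accept_quantile = 1 / 60)
  acc <- tidy(fit)
  expect_equal(nrow(acc), 1)
  d <- dic(fit)
  expect_equal(d$p_d, 0)
  expect_equal(d$dic, d$deviance_at_point)
})

test_that("deviance falls as the observation approaches the model mean", {
  set.seed(81)
  sim <- stub_simulator(noise = 0.005)
  ref <- abc_reference(sim, "selection", n_sims = 200, seed = 82)
  target <- sim(0.5, 0.5)
  far <- target
  far$mean_poags <- far$mean_poags + 0.5
  far$mean_gdist <- far$mean_gdist + 0.5
  d_near <- dic(abc_fit(target, "selection", ref = ref))
  d_far <- dic(abc_fit(far, "selection", ref = ref))
  expect_lt(d_near$mean_deviance, d_far$mean_deviance)
})

test_that("identical statistic streams make the models indistinguishable", {
  set.seed(83)
  sim <- stub_simulator(noise = 0.01)
  # both "models" simulate from the same neutral stream
  neutral_like <- function(mu, alpha) sim(mu, 0)
  ref_a <- abc_reference(neutral_like, "selection", n_sims = 150, seed = 84)
  set.seed(84) # same parameter draws and stat noise for the neutral bank
  ref_b <- ref_a[, ]
  ref_b$alpha <- 0
  obs <- sim(0.5, 0)
  ms <- model_select(obs, ref_selection = ref_a, ref_neutral = ref_b)
  # identical streams: both models accept exactly the same draws, and the
  # selection model is never preferred (the null-calibrated cutoff absorbs
  # any residual asymmetry of the deviance estimator)
  expect_identical(which(ms$selection$draws$accepted),
                   which(ms$neutral$draws$accepted))
  expect_true(ms$winner %in% c("indistinguishable", "neutral"))
})

test_that("abc errors when every simulation is extinct", {
  sim_na <- function(mu, alpha)
    tibble::as_tibble(setNames(as.list(rep(NA_real_, 6)),
                               summary_stat_names))
  ref <- abc_reference(sim_na, "selection", n_sims = 20, seed = 85)
  obs <- stub_simulator()(0.5, 1)
  expect_error(abc_fit(obs, "selection", ref = ref), "extinct")
})
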