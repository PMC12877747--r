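# a hand-built cherry ((A,B),C) with founder outgroup and labelled internals
cherry_tree <- function() {
  phy <- ape::read.tree(text = "((A:1,B:1)n2:1,C:2,founder:0)n1;")
  g <- tiny_grid(c(6, 5))
  base <- rep(2, 11)
  n1 <- base
  n2 <- base; n2[1:3] <- 3            # intermediate gain on chrom 1
  a <- n2; a[7] <- 1                  # private loss in A
  b <- n2
  cc <- base; cc[10:11] <- 4          # private double gain in C
  karyo <- tbl_of(g, A = a, B = b, C = cc, founder = n1, n1 = n1, n2 = n2)
  event_tree(phy, karyo)
}

test_that("branch events merge contiguous runs and count magnitude once", {
  g <- tiny_grid(c(6, 5))
  p <- tbl_of(g, p = rep(2, 11))
  c_same <- tbl_of(g, c = rep(2, 11))
  expect_equal(nrow(branch_events(p, c_same)), 0)
  # three contiguous bins jumping 2 -> 4 are a single gain event
  v <- rep(2, 11); v[2:4] <- 4
  ev <- branch_events(p, tbl_of(g, c = v))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "gain")
  expect_equal(c(ev$start_bin, ev$end_bin), c(2, 4))
  # runs never merge across the chromosome boundary
  w <- rep(3, 11)
  ev2 <- branch_events(p, tbl_of(g, c = w))
  expect_equal(nrow(ev2), 2)
})

test_that("branch events agree with a naive scan on random profiles", {
  set.seed(58)
  for (i in 1:40) {
    x <- random_cn_table(c(7, 6), 2, states = 1:4)
    m <- cn_matrix(x)
    got <- branch_events_vec(m[, 1], m[, 2], x[c("chrom", "start", "end")])
    want <- oracle_branch_events(m[, 1], m[, 2], x$chrom)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$start_bin, want$start_bin, ignore_attr = TRUE)
      expect_equal(got$end_bin, want$end_bin, ignore_attr = TRUE)
      expect_equal(got$direction, want$direction, ignore_attr = TRUE)
    }
  }
})

test_that("events classify into clonal, intermediate and tip categories", {
  et <- cherry_tree()
  ev <- classify_events(et, samples = c("A", "B", "C"))
  # n1 -> n2 gain is intermediate (below the MRCA n1? no: MRCA of A,B,C is n1,
  # so the n2 branch is internal below the MRCA)
  n2_ev <- dplyr::filter(ev, .data$branch == "n2")
  expect_equal(n2_ev$category, "intermediate")
  expect_equal(dplyr::filter(ev, .data$branch == "A")$category, "tip")
  expect_equal(dplyr::filter(ev, .data$branch == "A")$direction, "loss")
  c_ev <- dplyr::filter(ev, .data$branch == "C")
  expect_equal(c_ev$category, "tip")
  expect_equal(nrow(c_ev), 1) # 2 -> 4 counted once
  # total partition: every event is exactly one category
  expect_true(all(ev$category %in% c("clonal", "intermediate", "tip")))
  # restricting samples to the cherry makes its stem clonal
  ev_ab <- classify_events(et, samples = c("A", "B"))
  expect_equal(dplyr::filter(ev_ab, .data$branch == "n2")$category, "clonal")
  expect_error(classify_events(et, samples = "A"), "MRCA")
})

test_that("star topology with shared alterations yields clonal events", {
  phy <- ape::read.tree(text = "((A:1,B:1,C:1)n2:1,founder:0)n1;")
  g <- tiny_grid(c(6, 5))
  shared <- rep(2, 11); shared[1:4] <- 3
  karyo <- tbl_of(g, A = shared, B = shared, C = shared,
                  founder = rep(2, 11), n1 = rep(2, 11), n2 = shared)
  ev <- classify_events(event_tree(phy, karyo), samples = c("A", "B", "C"))
  expect_equal(unique(ev$category), "clonal")
  expect_equal(nrow(ev), 1)
})

test_that("event frequencies normalise clonal calls to patient ploidy", {
  # tetraploid patient, clonal CN 4 everywhere: no clonal gain after
  # normalisation
  phy <- ape::read.tree(text = "(A:1,B:1,founder:0)n1;")
  g <- tiny_grid(c(6, 5))
  tetra <- rep(4, 11)
  karyo <- tbl_of(g, A = tetra, B = tetra, founder = rep(2, 11), n1 = tetra)
  et <- event_tree(phy, karyo)
  fr <- event_frequency(list(et), "clonal", ploidy = 4,
                        samples = list(c("A", "B")))
  expect_true(all(fr$gain_freq == 0))
  expect_true(all(fr$loss_freq == 0))
  # against the root-diploid reference it would read as all-gained
  fr2 <- event_frequency(list(et), "clonal", ploidy = 2,
                         samples = list(c("A", "B")))
  expect_true(all(fr2$gain_freq == 1))
  expect_error(event_frequency(list(et), "clonal"), "ploidy")
  # no events anywhere -> all frequencies 0
  flat <- tbl_of(g, A = rep(2, 11), B = rep(2, 11), founder = rep(2, 11),
                 n1 = rep(2, 11))
  fr3 <- event_frequency(list(event_tree(phy, flat)), "tip",
                         samples = list(c("A", "B")))
  expect_true(all(fr3$gain_freq == 0) && all(fr3$loss_freq == 0))
})

test_that("simulator genealogy round-trips through the event tree", {
  go <- diploid_go(tiny_grid(c(10, 8)))
  cfg <- sim_config(fitness_landscape(go, alpha = 0), mu = 0.3,
                    n_target = 250)
  sim <- sim_to_target(cfg, seed = 21)
  gl <- sample_glands(sim, 10, seed = 4)
  et <- as_event_tree(sim, gl)
  # tips carry exactly the sampled karyotypes
  km <- cn_matrix(et$karyotypes)
  expect_equal(km[, sample_cols(gl)], cn_matrix(gl), ignore_attr = TRUE)
  # every edge's events replay the child karyotype from the parent
  phy <- et$phy
  labels <- c(phy$tip.label, phy$node.label)
  for (e in seq_len(nrow(phy$edge))) {
    pv <- km[, labels[phy$edge[e, 1]]]
    cv <- km[, labels[phy$edge[e, 2]]]
    ev <- branch_events_vec(pv, cv, et$karyotypes[c("chrom", "start", "end")])
    v <- pv
    for (r in seq_len(nrow(ev))) {
      idx <- ev$start_bin[r]:ev$end_bin[r]
      v[idx] <- cv[idx]
    }
    expect_equal(v, cv)
  }
  # categories partition all classified events
  ev <- classify_events(et, samples = sample_cols(gl))
  if (nrow(ev) > 0) {
    expect_true(all(ev$category %in% c("clonal", "intermediate", "tip")))
  }
})

test_that("tip events on neutral simulations spread evenly over the genome", {
  go <- diploid_go(tiny_grid(c(15, 15)))
  counts <- rep(0, 30)
  for (r in 1:6) {
    cfg <- sim_config(fitness_landscape(go, alpha = 0), mu = 0.4,
                      n_target = 200)
    sim <- sim_to_target(cfg, seed = 600 + r)
    gl <- sample_glands(sim, 12, seed = r)
    et <- as_event_tree(sim, gl)
    ev <- classify_events(et, samples = sample_cols(gl))
    tips <- dplyr::filter(ev, .data$category == "tip")
    for (i in seq_len(nrow(tips))) {
      rng <- tips$start_bin[i]:tips$end_bin[i]
      counts[rng] <- counts[rng] + 1
    }
  }
  # no bin dominates: chi-square GOF against uniform
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})
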