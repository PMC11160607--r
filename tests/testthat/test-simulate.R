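test_that("simulated betas are bounded, correctly shaped, and deterministic", {
  cfg <- sim_config(n_cpgs = 500L, n_per_domain = 20L, seed = 7)
  sim1 <- simulate_cohorts(cfg)
  expect_identical(dim(sim1$beta), c(500L, 80L))
  expect_true(all(sim1$beta > 0 & sim1$beta < 1))
  expect_false(anyNA(sim1$beta))

  sim2 <- simulate_cohorts(sim_config(n_cpgs = 500L, n_per_domain = 20L, seed = 7))
  expect_identical(sim1$beta, sim2$beta)
  expect_identical(sim1$sheet, sim2$sheet)
  expect_identical(sim1$truth$cpgs, sim2$truth$cpgs)

  sim3 <- simulate_cohorts(sim_config(n_cpgs = 500L, n_per_domain = 20L, seed = 8))
  expect_false(identical(sim1$beta, sim3$beta))
})

test_that("noise-free betas equal the squashed ledger reconstruction exactly", {
  sim <- small_sim(noise_sd = 0, batch_sd = 0, factor_sd = 0)
  tr <- sim$truth
  latent <- outer(tr$cpgs$mu, rep(1, nrow(tr$samples))) +
    outer(tr$cpgs$w1, tr$samples$f1) + outer(tr$cpgs$w2, tr$samples$f2)
  offs <- tr$batch$offset[match(sim$sheet$dataset, tr$batch$dataset)]
  latent <- latent + outer(rep(1, nrow(tr$cpgs)), offs)
  expect_equal(unname(sim$beta), plogis(latent), tolerance = 1e-12)

  # deterministic trend: f1 and f2 perfectly track age within tissue_age
  i <- sim$sheet$domain == "tissue_age"
  expect_equal(cor(tr$samples$f1[i], sim$sheet$time_value[i]), 1, tolerance = 1e-12)
  expect_equal(cor(tr$samples$f2[i], sim$sheet$time_value[i]), 1, tolerance = 1e-12)
})

test_that("planted factor trajectories have the designed shapes", {
  sim <- small_sim(factor_sd = 0)
  sheet <- sim$sheet
  f1 <- sim$truth$samples$f1
  f2 <- sim$truth$samples$f2
  pass <- sheet$domain == "passaging"
  rep_ <- sheet$domain == "reprogramming"
  expect_gt(cor(f1[pass], sheet$time_value[pass]), 0.99)
  expect_lt(cor(f1[rep_], sheet$time_value[rep_]), -0.99)
  # refractory: rises to the peak day then reverts
  day <- sheet$time_value[rep_]
  cfg <- sim$truth$config
  pre <- day <= cfg$peak_day
  expect_gt(cor(f2[rep_][pre], day[pre]), 0.99)
  expect_lt(cor(f2[rep_][!pre], day[!pre]), -0.99)
  # transformation carries no time but a binary factor shift
  tr <- sheet$domain == "transformation"
  expect_true(all(is.na(sheet$time_value[tr])))
  shift <- mean(f1[tr][sheet$condition[tr] == "transformed"]) -
    mean(f1[tr][sheet$condition[tr] == "control"])
  expect_equal(shift, cfg$a1[["transformation"]], tolerance = 1e-8)
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(noise_sd = -1), class = "eldar_config_error")
  expect_error(sim_config(noise_sd = NaN), class = "eldar_config_error")
  expect_error(sim_config(reversion_fraction = 1.5), class = "eldar_config_error")
  expect_error(sim_config(loading_sparsity = 0), class = "eldar_config_error")
  expect_error(sim_config(n_cpgs = 0), class = "eldar_config_error")
})

test_that("cumulative_pd evaluates the 3.32 log10 bookkeeping", {
  expect_equal(cumulative_pd(1e5, 1e5, previous_pdl = 4), 4)
  expect_equal(cumulative_pd(1e5, 4e5, previous_pdl = 10),
               10 + 3.32 * log10(4), tolerance = 1e-12)
  expect_warning(dec <- cumulative_pd(2e5, 1e5, previous_pdl = 5), "decreases")
  expect_equal(dec, 5 + 3.32 * log10(0.5), tolerance = 1e-12)
  expect_error(cumulative_pd(0, 1e5), class = "eldar_value_error")
  expect_error(cumulative_pd(1e5, -3), class = "eldar_value_error")
})

test_that("cumulative_pd is additive over consecutive passages", {
  set.seed(42)
  for (i in 1:20) {
    seed1 <- runif(1, 1e4, 1e6); coll1 <- seed1 * runif(1, 1, 8)
    seed2 <- runif(1, 1e4, 1e6); coll2 <- seed2 * runif(1, 1, 8)
    start <- runif(1, 0, 50)
    two_step <- cumulative_pd(seed2, coll2,
                              cumulative_pd(seed1, coll1, start))
    one_step <- start + 3.32 * log10((coll1 / seed1) * (coll2 / seed2))
    expect_equal(two_step, one_step, tolerance = 1e-10)
  }
})

test_that("senescent cPD extrapolates at the pre-senescence rate", {
  expect_equal(estimate_senescent_cpd(0, 100, 55), 55)
  expect_equal(estimate_senescent_cpd(0.1, 30, 60), 63)
  expect_equal(estimate_senescent_cpd(0.2, 0, 48), 48)
  expect_error(estimate_senescent_cpd(-0.1, 10, 50), class = "eldar_value_error")
})

test_that("simulated clocks draw hits from the top |w1| decile, reproducibly", {
  sim <- small_sim()
  ck0 <- simulate_clock(sim$truth, 0, 0, seed = 1)
  expect_identical(nrow(ck0), 0L)

  ck <- simulate_clock(sim$truth, n_hits = 10, n_random = 0, seed = 3)
  aw <- abs(sim$truth$cpgs$w1)
  top_decile <- sim$truth$cpgs$cpg_id[rank(-aw, ties.method = "first") <= 30]
  expect_true(all(ck$cpg_id %in% top_decile))
  expect_identical(ck$cpg_id,
                   simulate_clock(sim$truth, 10, 0, seed = 3)$cpg_id)

  ck2 <- simulate_clock(sim$truth, 10, 20, seed = 5)
  expect_identical(anyDuplicated(ck2$cpg_id), 0L)
  expect_error(simulate_clock(sim$truth, 200, 200, seed = 1),
               class = "eldar_config_error")
})

test_that("null annotation coupling leaves top-loading CpGs at background composition", {
  cfg <- small_config(n_cpgs = 2000L)
  flat <- c(island = 0.25, shore = 0.25, shelf = 0.25, open_sea = 0.25)
  cfg$annotation_coupling$island_relation <-
    lapply(cfg$annotation_coupling$island_relation, function(x) flat)
  sim <- simulate_cohorts(cfg)
  ann <- simulate_annotation(sim$truth, cfg)
  top <- sim$truth$cpgs$cpg_id[order(-abs(sim$truth$cpgs$w1))][1:200]
  res <- fold_enrichment(top, ann, "island_relation")
  # binomial sampling error: sd of a 0.25 proportion at n = 200 is ~0.031
  expect_true(all(abs(res$prop - res$background_prop) < 4 * sqrt(0.25 * 0.75 / 200)))
})

test_that("configured coupling ratio is recovered by direct counting", {
  cfg <- small_config(n_cpgs = 4000L, loading_sparsity = 0.05)
  flat <- c(island = 0.25, shore = 0.25, shelf = 0.25, open_sea = 0.25)
  coup <- lapply(cfg$annotation_coupling$island_relation, function(x) flat)
  coup$w1_pos <- c(island = 0.9, shore = 0.04, shelf = 0.03, open_sea = 0.03)
  cfg$annotation_coupling$island_relation <- coup
  sim <- simulate_cohorts(cfg)
  ann <- simulate_annotation(sim$truth, cfg)
  cls <- loading_class(sim$truth)
  pos_set <- sim$truth$cpgs$cpg_id[cls == "w1_pos"]
  res <- fold_enrichment(pos_set, ann, "island_relation")
  isl <- res[res$category == "island", ]
  # analytic expectation: 0.9 over the class-weighted background island rate
  shares <- table(cls) / length(cls)
  p_bg <- sum(vapply(names(shares), function(cl) coup[[cl]]["island"],
                     numeric(1)) * as.vector(shares))
  expect_equal(isl$fold, 0.9 / p_bg, tolerance = 0.15)
  # and close to the configured probability ratio 0.9 / 0.25 = 3.6
  expect_equal(isl$fold, 3.6, tolerance = 0.2)
})
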