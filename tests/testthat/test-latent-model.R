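test_that("a constant-column matrix carries no latent signal", {
  beta <- matrix(rep(runif(5, 0.2, 0.8), 4), ncol = 4,
                 dimnames = list(sprintf("cg%d", 1:5), sprintf("s%d", 1:4)))
  expect_warning(model <- fit_eldar(beta, 2), "rank-deficient")
  expect_true(all(model$explained_variance == 0))
  score_cols <- grep("^PC", names(model$scores), value = TRUE)
  expect_true(all(vapply(score_cols, function(cc) all(model$scores[[cc]] == 0),
                         logical(1))))
})

test_that("the decomposition reconstructs the centered matrix exactly", {
  beta <- rand_beta(3, 4, seed = 11)
  model <- fit_eldar(beta, 3)
  centered <- t(beta - model$center)
  scores <- as.matrix(model$scores[paste0("PC", 1:3)])
  expect_equal(scores %*% t(model$loadings), centered,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("explained variances match an independent eigendecomposition", {
  for (seed in c(5, 17)) {
    beta <- rand_beta(5, 5, seed = seed)
    model <- fit_eldar(beta, 4)
    ev_oracle <- eigen(stats::cov(t(beta)), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(model$explained_variance, ev_oracle[1:4], tolerance = 1e-8)
    expect_true(all(diff(model$explained_variance) <= 1e-12))
  }
})

test_that("loadings are orthonormal and equivariant to sample permutation", {
  sim <- small_sim()
  parts <- split_cohorts(sim)
  pool <- intersect_and_pool(parts$matrices, parts$sheets)
  model <- fit_eldar(pool$beta, 4, sheet = pool$sheet)
  gram <- crossprod(model$loadings)
  expect_equal(gram, diag(4), tolerance = 1e-8, ignore_attr = TRUE)

  set.seed(3)
  perm <- sample(ncol(pool$beta))
  model_p <- fit_eldar(pool$beta[, perm], 4, sheet = pool$sheet[perm, ])
  # align residual sign indeterminacy (components with ~zero time correlation)
  flip <- sign(colSums(model_p$loadings * model$loadings))
  expect_equal(sweep(model_p$loadings, 2, flip, `*`), model$loadings,
               tolerance = 1e-6)
  expect_equal(sweep(as.matrix(model_p$scores[paste0("PC", 1:4)]), 2, flip, `*`),
               as.matrix(model$scores[perm, paste0("PC", 1:4)]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("sign orientation makes scores rise with tissue age", {
  sim <- small_sim()
  parts <- split_cohorts(sim)
  pool <- intersect_and_pool(parts$matrices, parts$sheets)
  model <- fit_eldar(pool$beta, 4, sheet = pool$sheet)
  expect_true(model$sign_oriented)
  age <- pool$sheet$domain == "tissue_age"
  for (pc in paste0("PC", 1:4)) {
    r <- cor(model$scores[[pc]][age], pool$sheet$time_value[age])
    expect_gte(r, 0)
  }
})

test_that("projection identities hold for every fitted model", {
  for (seed in c(2, 13, 29)) {
    beta <- rand_beta(40, 12, seed = seed)
    model <- fit_eldar(beta, 5)
    # projecting the training matrix reproduces training scores
    proj <- project_cohort(model, beta)
    expect_equal(as.matrix(proj[paste0("PC", 1:5)]),
                 as.matrix(model$scores[paste0("PC", 1:5)]),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_true(all(proj$coverage_fraction == 1))
    # a sample sitting at the training means scores zero everywhere
    mean_cohort <- matrix(model$center, ncol = 1,
                          dimnames = list(model$cpg_ids, "m1"))
    proj0 <- project_cohort(model, mean_cohort)
    expect_equal(unlist(proj0[paste0("PC", 1:5)]), rep(0, 5),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("missing CpGs contribute zero: partial dot product by hand", {
  beta <- matrix(c(0.2, 0.5, 0.8,
                   0.4, 0.6, 0.3), ncol = 2,
                 dimnames = list(c("cgA", "cgB", "cgC"), c("t1", "t2")))
  model <- fit_eldar(beta, 1)
  cohort <- matrix(c(0.3, 0.7), ncol = 1,
                   dimnames = list(c("cgA", "cgC"), c("new1")))
  proj <- project_cohort(model, cohort)
  by_hand <- (0.3 - model$center["cgA"]) * model$loadings["cgA", "PC1"] +
    (0.7 - model$center["cgC"]) * model$loadings["cgC", "PC1"]
  expect_equal(proj$PC1, unname(by_hand), tolerance = 1e-12)
  expect_equal(proj$coverage_fraction, 2 / 3, tolerance = 1e-12)

  disjoint <- matrix(0.5, 1, 1, dimnames = list("cgZ", "n1"))
  expect_error(project_cohort(model, disjoint), class = "eldar_fit_error")
})

test_that("the Pearson engine matches closed-form values", {
  expect_equal(pearson_time_cor(1:5, 1:5)$r, 1)
  expect_equal(pearson_time_cor(1:5, -(1:5))$r, -1)
  res <- pearson_time_cor(c(1, 2, 3), c(1, 2, 4))
  expect_equal(res$r, 0.9819805, tolerance = 1e-6)
  expect_equal(res$n, 3L)
  expect_warning(bad <- pearson_time_cor(c(1, 1, 1), 1:3), "zero variance")
  expect_true(is.na(bad$r))
})

test_that("the time screen excludes untimed cohorts and nails perfect trends", {
  sim <- small_sim()
  parts <- split_cohorts(sim)
  pool <- intersect_and_pool(parts$matrices, parts$sheets)
  model <- fit_eldar(pool$beta, 4, sheet = pool$sheet)
  screen <- correlate_components_with_time(model$scores, pool$sheet)
  expect_false("transformation" %in% screen$domain)
  expect_true(all(screen$r >= -1 & screen$r <= 1))
  expect_true(all(screen$p > 0 & screen$p <= 1))
  expect_identical(nrow(screen), 4L * 3L)

  # a score column equal to time correlates exactly
  fake <- model$scores
  fake$PC1 <- pool$sheet$time_value
  fake$PC1[is.na(fake$PC1)] <- 0
  s2 <- correlate_components_with_time(fake, pool$sheet)
  expect_true(all(abs(s2$r[s2$component == "PC1"] - 1) < 1e-12))
})

test_that("classification follows the threshold rule", {
  mk_screen <- function(r_age, r_pass, r_rep) {
    tibble::tibble(component = "PC1",
                   dataset = c("a", "b", "c"),
                   domain = c("tissue_age", "passaging", "reprogramming"),
                   r = c(r_age, r_pass, r_rep), p = 0.01, n = 10L)
  }
  expect_identical(classify_components(mk_screen(0.73, 0.8, -0.93))$class, "shared")
  expect_identical(classify_components(mk_screen(0, 0, 0))$class, "unclassified")
  expect_identical(classify_components(mk_screen(0.4, 0.45, -0.2))$class, "refractory")
  # thresholds are configurable
  expect_identical(classify_components(mk_screen(0.4, 0.45, -0.2),
                                       t_hi = 0.2, t_lo = 0.1)$class, "shared")
  expect_error(classify_components(mk_screen(1, 1, 1)[1:2, ]),
               class = "eldar_screen_error")
})

test_that("the planted factors are recovered and classified on synthetic pools", {
  res <- run_eldar_pipeline(list(simulation = sim_config(seed = 11)))
  df <- dplyr::inner_join(res$model$scores, res$truth$samples, by = "sample_id")
  pcs <- paste0("PC", 1:5)
  r1 <- vapply(pcs, function(pc) abs(cor(df[[pc]], df$f1)), numeric(1))
  r2 <- vapply(pcs, function(pc) abs(cor(df[[pc]], df$f2)), numeric(1))
  best1 <- pcs[which.max(r1)]
  best2 <- pcs[setdiff(order(r2, decreasing = TRUE), which.max(r1))[1]]
  expect_gte(max(r1), 0.9)
  expect_gte(r2[best2], 0.8)
  cls <- res$classification
  expect_identical(cls$class[cls$component == best1], "shared")
  expect_identical(cls$class[cls$component == best2], "refractory")
})
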