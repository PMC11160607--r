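#' Configuration for the synthetic methylation cohort generator
#'
#' Bundles every tunable of [simulate_cohorts()] into a validated list. The
#' generator plants two latent factors on the logit (M-value-like) scale:
#' a *shared* factor `f1` that rises with donor age and cumulative population
#' doublings (cPD) and falls over OSKM reprogramming time, and a *refractory*
#' factor `f2` that rises with age and cPD but follows a transient
#' rise-then-partial-reversion trajectory under reprogramming. A fourth,
#' untimed transformation domain carries a binary condition shift on both
#' factors.
#'
#' Defaults emulate a small pooled training design: four cohorts of 20
#' samples each (ages 20-90 years, 5-60 cPD, 0-28 days of OSKM expression,
#' and a control/transformed contrast), 2000 CpGs with sparse loadings.
#'
#' @param n_cpgs Number of CpGs simulated.
#' @param n_per_domain Samples per domain (one dataset per domain). Must be
#'   even so the transformation domain splits into control/transformed halves.
#' @param age_range,cpd_range,day_range Time-axis ranges (years, cPD, days).
#' @param a1,a2 Named numeric vectors of per-domain effect sizes for the
#'   shared and refractory factors; names must be the four domains.
#' @param loading_sparsity Fraction of CpGs with a nonzero loading on each
#'   factor, in (0, 1].
#' @param loading_scale Standard deviation of nonzero loadings.
#' @param mu_sd Standard deviation of the per-CpG baseline logit.
#' @param noise_sd Latent-scale (logit) residual noise standard deviation.
#' @param batch_sd Standard deviation of the per-dataset scalar batch offset.
#' @param factor_sd Standard deviation of per-sample jitter added to the
#'   factor trajectories (biological scatter around the trend).
#' @param peak_day Reprogramming day at which the refractory factor peaks.
#' @param reversion_fraction Fraction of the refractory rise reverted by the
#'   end of the reprogramming time course, in \[0, 1\].
#' @param annotation_coupling Per-loading-class category probabilities used
#'   by [simulate_annotation()]; see [default_annotation_coupling()].
#' @param seed Integer seed; identical configs are bit-reproducible.
#'
#' @return A list of class `eldar_sim_config`.
#' @seealso [simulate_cohorts()], [simulate_annotation()], [simulate_clock()]
#' @export
#' @examples
#' cfg <- sim_config(n_cpgs = 200, n_per_domain = 10, seed = 1)
#' sim <- simulate_cohorts(cfg)
#' dim(sim$beta)
sim_config <- function(n_cpgs = 2000,
                       n_per_domain = 20,
                       age_range = c(20, 90),
                       cpd_range = c(5, 60),
                       day_range = c(0, 28),
                       a1 = c(tissue_age = 1, passaging = 1,
                              reprogramming = 1.5, transformation = 1),
                       a2 = c(tissue_age = 1.2, passaging = 0.6,
                              reprogramming = 1.5, transformation = -1),
                       loading_sparsity = 0.2,
                       loading_scale = 1,
                       mu_sd = 1,
                       noise_sd = 0.2,
                       batch_sd = 0.05,
                       factor_sd = 0.05,
                       peak_day = 15,
                       reversion_fraction = 0.8,
                       annotation_coupling = default_annotation_coupling(),
                       seed = 1L) {
  cfg <- list(n_cpgs = as.integer(n_cpgs), n_per_domain = as.integer(n_per_domain),
              age_range = age_range, cpd_range = cpd_range, day_range = day_range,
              a1 = a1, a2 = a2,
              loading_sparsity = loading_sparsity, loading_scale = loading_scale,
              mu_sd = mu_sd, noise_sd = noise_sd, batch_sd = batch_sd,
              factor_sd = factor_sd, peak_day = peak_day,
              reversion_fraction = reversion_fraction,
              annotation_coupling = annotation_coupling, seed = as.integer(seed))
  num <- unlist(cfg[c("age_range", "cpd_range", "day_range", "a1", "a2",
                      "loading_sparsity", "loading_scale", "mu_sd", "noise_sd",
                      "batch_sd", "factor_sd", "peak_day", "reversion_fraction")])
  if (any(!is.finite(num))) {
    abort("sim_config: all numeric fields must be finite.", class = "eldar_config_error")
  }
  if (cfg$n_cpgs < 1L || cfg$n_per_domain < 1L) {
    abort("sim_config: n_cpgs and n_per_domain must be >= 1.", class = "eldar_config_error")
  }
  if (cfg$n_per_domain %% 2L != 0L) {
    abort("sim_config: n_per_domain must be even (transformation domain splits in half).",
          class = "eldar_config_error")
  }
  if (cfg$loading_sparsity <= 0 || cfg$loading_sparsity > 1) {
    abort("sim_config: loading_sparsity must be in (0, 1].", class = "eldar_config_error")
  }
  if (cfg$noise_sd < 0 || cfg$batch_sd < 0 || cfg$factor_sd < 0) {
    abort("sim_config: standard deviations must be >= 0.", class = "eldar_config_error")
  }
  if (cfg$reversion_fraction < 0 || cfg$reversion_fraction > 1) {
    abort("sim_config: reversion_fraction must be in [0, 1].", class = "eldar_config_error")
  }
  for (nm in c("a1", "a2")) {
    if (!all(ELDAR_DOMAINS %in% names(cfg[[nm]]))) {
      abort(paste0("sim_config: ", nm, " must be named with all four domains."),
            class = "eldar_config_error")
    }
  }
  check_coupling(cfg$annotation_coupling)
  structure(cfg, class = "eldar_sim_config")
}

#' Default loading-class to annotation-category coupling
#'
#' Category probabilities per loading class, per annotation track. Classes
#' are `w1_pos`, `w1_neg`, `w2_pos`, `w2_neg` (CpGs whose dominant nonzero
#' loading is on the shared or refractory factor, split by sign) and
#' `background` (CpGs with no nonzero loading). Defaults qualitatively echo
#' the enrichment patterns the analysis is designed to detect: methylation
#' gainers concentrated in islands/shores and bivalent promoters, losers in
#' open sea, quiescent and enhancer states.
#'
#' @return A list with elements `island_relation` and `chrom_state`, each a
#'   named list of per-class probability vectors summing to 1.
#' @export
default_annotation_coupling <- function() {
  island <- list(
    w1_pos     = c(island = 0.48, shore = 0.41, shelf = 0.03, open_sea = 0.08),
    w1_neg     = c(island = 0.06, shore = 0.08, shelf = 0.04, open_sea = 0.82),
    w2_pos     = c(island = 0.25, shore = 0.20, shelf = 0.10, open_sea = 0.45),
    w2_neg     = c(island = 0.10, shore = 0.12, shelf = 0.06, open_sea = 0.72),
    background = c(island = 0.31, shore = 0.23, shelf = 0.09, open_sea = 0.37))
  states <- c("bivalent_promoter", "active_enhancer", "weak_enhancer",
              "acetylated", "quiescent", "gap_artf", "other")
  chrom <- list(
    w1_pos     = c(0.30, 0.08, 0.06, 0.08, 0.18, 0.01, 0.29),
    w1_neg     = c(0.02, 0.15, 0.14, 0.15, 0.40, 0.04, 0.10),
    w2_pos     = c(0.15, 0.12, 0.08, 0.10, 0.25, 0.02, 0.28),
    w2_neg     = c(0.03, 0.20, 0.10, 0.16, 0.30, 0.02, 0.19),
    background = c(0.06, 0.09, 0.08, 0.10, 0.30, 0.02, 0.35))
  chrom <- lapply(chrom, setNames, states)
  list(island_relation = island, chrom_state = chrom)
}

check_coupling <- function(coupling) {
  for (track in names(coupling)) {
    for (cls in names(coupling[[track]])) {
      p <- coupling[[track]][[cls]]
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
        abort(sprintf("annotation_coupling[%s][%s]: probabilities must be >= 0 and sum to 1.",
                      track, cls), class = "eldar_config_error")
      }
    }
  }
  invisible(TRUE)
}

#' Simulate pooled methylation cohorts with two planted latent factors
#'
#' Generates a CpG x sample beta matrix across four cohorts (one dataset per
#' domain), a sample sheet, and a ground-truth ledger sufficient to
#' reconstruct the noise-free latent matrix. Betas are produced as
#' `plogis(mu + w1 * f1 + w2 * f2 + batch + eps)`, so they are strictly
#' inside (0, 1) by construction.
#'
#' The shared factor `f1` rises linearly with age and cPD, falls linearly
#' over reprogramming days, and shifts with the transformed condition. The
#' refractory factor `f2` rises with age and cPD, rises to `peak_day` during
#' reprogramming then linearly reverts by `reversion_fraction`, and shifts
#' (by default in the opposite direction) with transformation. The
#' transformation cohort carries no time value.
#'
#' @param config An [sim_config()] object.
#' @return A list with elements `beta` (numeric matrix, CpGs x samples),
#'   `sheet` (tibble sample sheet), and `truth` (an `eldar_truth` ledger:
#'   tibbles `cpgs` with `mu`, `w1`, `w2`, `samples` with `f1`, `f2`, and
#'   `batch` with per-dataset offsets).
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "eldar_sim_config"))
  set.seed(config$seed)
  n_per <- config$n_per_domain
  n <- 4L * n_per
  domains <- rep(ELDAR_DOMAINS, each = n_per)
  datasets <- rep(c("sim_dermis", "sim_bj_passaging", "sim_ipsc_oskm", "sim_hras"),
                  each = n_per)
  time <- c(seq(config$age_range[1], config$age_range[2], length.out = n_per),
            seq(config$cpd_range[1], config$cpd_range[2], length.out = n_per),
            seq(config$day_range[1], config$day_range[2], length.out = n_per),
            rep(NA_real_, n_per))
  condition <- c(rep("none", 3L * n_per),
                 rep(c("control", "transformed"), each = n_per / 2L))

  tn <- function(x) (x - min(x)) / diff(range(x))
  f1 <- numeric(n)
  f2 <- numeric(n)
  idx <- split(seq_len(n), factor(domains, levels = ELDAR_DOMAINS))
  a1 <- config$a1
  a2 <- config$a2
  f1[idx$tissue_age] <- a1[["tissue_age"]] * tn(time[idx$tissue_age])
  f2[idx$tissue_age] <- a2[["tissue_age"]] * tn(time[idx$tissue_age])
  f1[idx$passaging] <- a1[["passaging"]] * tn(time[idx$passaging])
  f2[idx$passaging] <- a2[["passaging"]] * tn(time[idx$passaging])
  d <- time[idx$reprogramming]
  f1[idx$reprogramming] <- a1[["reprogramming"]] * (1 - tn(d))
  f2[idx$reprogramming] <- a2[["reprogramming"]] *
    refractory_ramp(d, config$peak_day, config$reversion_fraction)
  transformed <- condition[idx$transformation] == "transformed"
  f1[idx$transformation] <- a1[["transformation"]] * transformed
  f2[idx$transformation] <- a2[["transformation"]] * transformed

  f1 <- f1 + rnorm(n, 0, config$factor_sd)
  f2 <- f2 + rnorm(n, 0, config$factor_sd)
  f1 <- f1 - mean(f1)
  f2 <- f2 - mean(f2)

  p <- config$n_cpgs
  w1 <- rnorm(p, 0, config$loading_scale) * (runif(p) < config$loading_sparsity)
  w2 <- rnorm(p, 0, config$loading_scale) * (runif(p) < config$loading_sparsity)
  mu <- rnorm(p, 0, config$mu_sd)
  batch_by_dataset <- rnorm(4L, 0, config$batch_sd)
  names(batch_by_dataset) <- unique(datasets)
  batch <- batch_by_dataset[datasets]

  cpg_ids <- sprintf("cg%06d", seq_len(p))
  sample_ids <- sprintf("%s_s%02d", datasets, sequence(rep(n_per, 4L)))

  latent <- outer(mu, rep(1, n)) + outer(w1, f1) + outer(w2, f2) +
    outer(rep(1, p), unname(batch))
  eps <- matrix(rnorm(p * n, 0, config$noise_sd), nrow = p)
  beta <- plogis(latent + eps)
  dimnames(beta) <- list(cpg_ids, sample_ids)

  sheet <- tibble::tibble(
    sample_id = sample_ids,
    dataset = datasets,
    domain = domains,
    time_value = time,
    time_units = unname(TIME_UNITS[domains]),
    sun_exposed = NA,
    condition = condition)

  truth <- structure(list(
    cpgs = tibble::tibble(cpg_id = cpg_ids, mu = mu, w1 = w1, w2 = w2),
    samples = tibble::tibble(sample_id = sample_ids, f1 = f1, f2 = f2),
    batch = tibble::tibble(dataset = names(batch_by_dataset),
                           offset = unname(batch_by_dataset)),
    config = config), class = "eldar_truth")

  list(beta = beta, sheet = sheet, truth = truth)
}

# Piecewise-linear rise to peak_day, then linear reversion by `reversion`
# of the rise over the remaining days. Values in [0, 1].
refractory_ramp <- function(day, peak_day, reversion) {
  top <- max(day)
  ifelse(day <= peak_day,
         day / peak_day,
         1 - reversion * (day - peak_day) / (top - peak_day))
}

#' Loading class of each simulated CpG
#'
#' Assigns each CpG in a truth ledger to `w1_pos`, `w1_neg`, `w2_pos`,
#' `w2_neg` (by its dominant nonzero loading and that loading's sign) or
#' `background` (no nonzero loading).
#'
#' @param truth An `eldar_truth` ledger from [simulate_cohorts()].
#' @return A character vector, one class per CpG.
#' @export
loading_class <- function(truth) {
  stopifnot(inherits(truth, "eldar_truth"))
  w1 <- truth$cpgs$w1
  w2 <- truth$cpgs$w2
  cls <- rep("background", length(w1))
  use1 <- abs(w1) >= abs(w2) & w1 != 0
  use2 <- abs(w2) > abs(w1) & w2 != 0
  cls[use1] <- ifelse(w1[use1] > 0, "w1_pos", "w1_neg")
  cls[use2] <- ifelse(w2[use2] > 0, "w2_pos", "w2_neg")
  cls
}

#' Simulate a CpG annotation coupled to the planted loadings
#'
#' Draws one island-relation category and one chromatin-state label per CpG
#' from per-class probability tables ([default_annotation_coupling()]),
#' where the class is the CpG's [loading_class()]. With equal probabilities
#' across classes the annotation is independent of the loadings (null
#' coupling).
#'
#' Uses `config$seed + 1L` so the annotation draw is reproducible and
#' independent of the cohort draw.
#'
#' @param truth Ledger from [simulate_cohorts()].
#' @param config The same [sim_config()] used for the simulation.
#' @return A tibble with columns `cpg_id`, `island_relation`, `chrom_state`.
#' @export
simulate_annotation <- function(truth, config) {
  stopifnot(inherits(truth, "eldar_truth"), inherits(config, "eldar_sim_config"))
  set.seed(config$seed + 1L)
  cls <- loading_class(truth)
  draw <- function(track) {
    out <- character(length(cls))
    for (cl in unique(cls)) {
      p <- config$annotation_coupling[[track]][[cl]]
      sel <- cls == cl
      out[sel] <- sample(names(p), sum(sel), replace = TRUE, prob = p)
    }
    out
  }
  tibble::tibble(cpg_id = truth$cpgs$cpg_id,
                 island_relation = draw("island_relation"),
                 chrom_state = draw("chrom_state"))
}

#' Simulate a published-clock-style CpG list
#'
#' Builds a named clock as `n_hits` CpGs sampled from the top decile of
#' `|w1|` (planted shared-factor loading magnitude) plus `n_random` CpGs
#' sampled uniformly from the remainder, without duplicates.
#'
#' @param truth Ledger from [simulate_cohorts()].
#' @param n_hits,n_random Counts of high-loading and random CpGs.
#' @param seed Integer seed for the draw.
#' @param name Clock name.
#' @return A tibble with columns `clock`, `cpg_id`.
#' @export
simulate_clock <- function(truth, n_hits, n_random, seed, name = "sim_clock") {
  stopifnot(inherits(truth, "eldar_truth"))
  if (n_hits < 0 || n_random < 0) {
    abort("simulate_clock: counts must be >= 0.", class = "eldar_config_error")
  }
  n <- nrow(truth$cpgs)
  if (n_hits + n_random > n) {
    abort("simulate_clock: n_hits + n_random exceeds the number of CpGs.",
          class = "eldar_config_error")
  }
  aw <- abs(truth$cpgs$w1)
  top <- rank(-aw, ties.method = "first") <= ceiling(n / 10)
  if (n_hits > sum(top)) {
    abort("simulate_clock: n_hits exceeds the top-decile pool.",
          class = "eldar_config_error")
  }
  set.seed(seed)
  hits <- sample(truth$cpgs$cpg_id[top], n_hits)
  rest <- sample(truth$cpgs$cpg_id[!top], n_random)
  tibble::tibble(clock = name, cpg_id = c(hits, rest))
}

#' Population doubling level from a passage's cell counts
#'
#' Computes `previous_pdl + 3.32 * log10(collected / seeded)`, the standard
#' PDL bookkeeping for serially passaged lines (3.32 = 1/log10(2), so a
#' 2-fold expansion adds one doubling). A contraction (collected < seeded)
#' is allowed but flagged with a warning since it lowers the cumulative
#' count.
#'
#' @param cells_seeded,live_cells_collected Positive cell counts.
#' @param previous_pdl Non-negative PDL carried in from the previous passage
#'   (or the line's original seed level).
#' @return The updated PDL (numeric scalar).
#' @export
#' @examples
#' cumulative_pd(1e5, 4e5, previous_pdl = 10)  # adds ~2 doublings
cumulative_pd <- function(cells_seeded, live_cells_collected, previous_pdl = 0) {
  if (!is.finite(cells_seeded) || !is.finite(live_cells_collected) ||
      cells_seeded <= 0 || live_cells_collected <= 0) {
    abort("cumulative_pd: cell counts must be positive and finite.",
          class = "eldar_value_error")
  }
  if (previous_pdl < 0) {
    abort("cumulative_pd: previous_pdl must be >= 0.", class = "eldar_value_error")
  }
  if (live_cells_collected < cells_seeded) {
    warn("cumulative_pd: fewer cells collected than seeded; PDL decreases.")
  }
  previous_pdl + 3.32 * log10(live_cells_collected / cells_seeded)
}

#' Estimated cPD for senescent samples
#'
#' Senescent cultures stop doubling, so their cPD is extrapolated from the
#' line's average pre-senescence doubling rate: the PDL at senescence onset
#' plus `rate * days` for the time spent in culture beyond onset.
#'
#' @param pre_senescence_doublings_per_day Average doublings/day before
#'   senescence (>= 0).
#' @param days_in_culture Days in culture beyond senescence onset (>= 0).
#' @param pdl_at_senescence PDL at senescence onset.
#' @return Extrapolated cPD (numeric scalar).
#' @export
estimate_senescent_cpd <- function(pre_senescence_doublings_per_day,
                                   days_in_culture, pdl_at_senescence) {
  if (pre_senescence_doublings_per_day < 0 || days_in_culture < 0) {
    abort("estimate_senescent_cpd: rate and days must be >= 0.",
          class = "eldar_value_error")
  }
  pdl_at_senescence + pre_senescence_doublings_per_day * days_in_culture
}
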