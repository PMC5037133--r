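small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_otus = 80, n_env = 10, n_functions = 2,
         depth_range = c(2000, 3000), rarefaction_depth = 2000),
    list(...))
  do.call(sim_config, args)
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_months = 0), "counts")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(missing_month_rate = 1), "missing_month_rate")
  expect_error(sim_config(n_otus = 5, n_env = 2, n_drivers_shared = 13),
               "n_drivers_shared")
  # depths below the downstream rarefaction depth are a config error
  expect_error(sim_config(depth_range = c(12000, 20000)), "rarefaction depth")
})

test_that("identical seeds reproduce identical datasets", {
  d1 <- simulate_dataset(small_cfg(seed = 5))
  d2 <- simulate_dataset(small_cfg(seed = 5))
  expect_identical(d1$sites$site1$otu_rdna$counts,
                   d2$sites$site1$otu_rdna$counts)
  expect_identical(d1$sites$site2$env, d2$sites$site2$env)
  expect_identical(d1$sites$site1$functions, d2$sites$site1$functions)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$sites$site1$aux$ecoplates$M03$absorbance,
                   d2$sites$site1$aux$ecoplates$M03$absorbance)
  d3 <- simulate_dataset(small_cfg(seed = 6))
  expect_false(identical(d1$sites$site1$otu_rdna$counts,
                         d3$sites$site1$otu_rdna$counts))
})

test_that("generated communities are compositional and deep enough", {
  ds <- simulate_dataset(small_cfg(seed = 3))
  for (s in ds$sites) for (tab in list(s$otu_rdna, s$otu_rrna)) {
    expect_true(all(tab$counts >= 0))
    expect_true(all(rowSums(tab$counts) >= 2000))
    rel <- relative_abundance(tab) / 100
    expect_true(all(abs(rowSums(rel) - 1) < 1e-12))
  }
  # every sample id appears in exactly one site x month x fraction slot
  ids <- unlist(lapply(ds$sites, function(s)
    c(rownames(s$otu_rdna$counts), rownames(s$otu_rrna$counts))))
  expect_false(anyDuplicated(ids) > 0)
  expect_false(anyNA(ds$sites$site1$env))
})

test_that("zero noise makes responses exact in the planted predictors", {
  ds <- simulate_dataset(small_cfg(seed = 9, noise_sd = 0,
                                   missing_month_rate = 0))
  for (s in ds$sites) {
    rel <- list(rDNA = relative_abundance(s$otu_rdna),
                rRNA = relative_abundance(s$otu_rrna))
    for (f in names(s$functions)) {
      y <- s$functions[[f]]$value
      expect_false(anyNA(y))
      tr <- ds$truth[ds$truth$`function` == f, ]
      Z <- sapply(seq_len(nrow(tr)), function(j) {
        x <- if (tr$fraction[j] == "env") s$env[, tr$predictor_id[j]]
             else rel[[tr$fraction[j]]][, tr$predictor_id[j]]
        as.vector(scale(x))
      })
      fit <- lm(y ~ Z)
      expect_lt(max(abs(residuals(fit))), 1e-8)
    }
  }
})

test_that("planted marginal correlations carry the planted sign", {
  # effect/noise = 4, 20 seeds, at most 5% sign failures tolerated
  checks <- 0; fails <- 0
  for (seed in 1:20) {
    ds <- simulate_dataset(sim_config(
      n_otus = 100, n_env = 10, n_functions = 1, missing_month_rate = 0,
      effect_size = 2, noise_sd = 0.5,
      depth_range = c(2000, 3000), rarefaction_depth = 2000, seed = seed))
    tr <- ds$truth
    for (s in ds$sites) {
      rel <- list(rDNA = relative_abundance(s$otu_rdna),
                  rRNA = relative_abundance(s$otu_rrna))
      y <- s$functions[[1]]$value
      for (j in seq_len(nrow(tr))) {
        x <- if (tr$fraction[j] == "env") s$env[, tr$predictor_id[j]]
             else rel[[tr$fraction[j]]][, tr$predictor_id[j]]
        checks <- checks + 1
        if (sign(cor(x, y)) != tr$sign[j]) fails <- fails + 1
      }
    }
  }
  expect_lte(fails / checks, 0.05)
})

test_that("missing months are thinned at the configured rate", {
  ds <- simulate_dataset(small_cfg(seed = 2, n_functions = 8,
                                   missing_month_rate = 0.3))
  nas <- unlist(lapply(ds$sites, function(s)
    lapply(s$functions, function(d) is.na(d$value))))
  expect_gt(mean(nas), 0.1)
  expect_lt(mean(nas), 0.5)
})

test_that("ecoplate simulation honors its degenerate limits", {
  kin0 <- data.frame(substrate = 1:31, amplitude = 0, midpoint = 5, rate = 1)
  pl <- simulate_ecoplate(kin0, timepoints = c(0, 2, 4), replicate_sd = 0,
                          seed = 1)
  for (t in c(0, 2, 4)) expect_equal(awcd(pl, t), 0)
  # replicate_sd = 0: triplicate wells identical
  kin <- data.frame(substrate = 1:31, amplitude = seq(0.1, 3.1, 0.1),
                    midpoint = 5, rate = 1)
  pl2 <- simulate_ecoplate(kin, timepoints = c(0, 5, 10), replicate_sd = 0,
                           seed = 1)
  prof <- normalize_plate(pl2, t = 5)
  expect_true(all(apply(prof$replicates, 1, function(v) diff(range(v)) == 0)))
  expect_error(simulate_ecoplate(transform(kin, amplitude = -1), c(0, 1),
                                 seed = 1), "amplitudes")
  expect_identical(
    simulate_ecoplate(kin, c(0, 1), replicate_sd = 0.1, seed = 4)$absorbance,
    simulate_ecoplate(kin, c(0, 1), replicate_sd = 0.1, seed = 4)$absorbance)
})

test_that("oxygen series are linear drawdowns with flagged negatives", {
  flat <- simulate_o2_series(0, 300, 0:3)
  expect_true(all(flat$o2 == 300))
  lin <- simulate_o2_series(5, 300, 0:3)
  expect_equal(respiration_rate(lin)$rate, 5)
  expect_false(attr(lin, "negative_o2"))
  neg <- simulate_o2_series(200, 100, 0:3)
  expect_true(attr(neg, "negative_o2"))
  expect_error(simulate_o2_series(1, -5, 0:3), "o2_0")
})
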