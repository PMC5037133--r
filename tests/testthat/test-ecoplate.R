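test_that("AWCD is the blank-corrected plate mean and is linear", {
  # all wells at blank level -> 0
  expect_equal(awcd(make_plate(0), t = 0), 0)
  # constant blank-corrected value c -> AWCD = c
  expect_equal(awcd(make_plate(0.5), t = 0), 0.5)
  # arbitrary per-well values match the hand-summed oracle
  vals <- function(s, r) sin(s) + 0.1 * r
  pl <- make_plate(vals)
  hand <- sum(outer(1:31, 1:3, Vectorize(vals))) / 93
  expect_equal(awcd(pl, t = 0), hand, tolerance = 1e-12)
  # linearity in the plate values
  pl2 <- make_plate(function(s, r) 2 * vals(s, r))
  expect_equal(awcd(pl2, t = 0), 2 * hand, tolerance = 1e-12)
})

test_that("timepoint selection picks the AWCD closest to target, ties early", {
  mk <- function(awcds) {
    layout <- default_ecoplate_layout()
    ab <- matrix(0.1, nrow(layout), length(awcds),
                 dimnames = list(layout$well, NULL))
    ab[!layout$blank, ] <- rep(0.1 + awcds, each = 93)
    ecoplate_series(ab, seq_along(awcds) - 1, layout)
  }
  expect_equal(select_timepoint(mk(c(0.1, 0.48, 0.9))), 1)
  # tie between 0.4 and 0.6 -> earliest
  expect_equal(select_timepoint(mk(c(0.4, 0.6))), 0)
  # monotone logistic series: agrees with an exhaustive scan
  a <- 1.2 / (1 + exp(-(seq(0, 14, 2) - 6) / 1.5))
  expect_equal(select_timepoint(mk(a)),
               (seq_along(a) - 1)[which.min(abs(a - 0.5))])
})

test_that("AWCD normalization has unit mean and scale invariance", {
  pl <- make_plate(function(s, r) 0.02 * s + 0.05 * r)
  prof <- normalize_plate(pl, t = 0)
  expect_equal(mean(prof$replicates), 1, tolerance = 1e-12)
  # constant plate: every normalized well exactly 1
  pc <- normalize_plate(make_plate(0.7), t = 0)
  expect_true(all(abs(pc$replicates - 1) < 1e-12))
  # scaling all blank-corrected values by k > 0 changes nothing
  pl_k <- make_plate(function(s, r) 3.7 * (0.02 * s + 0.05 * r))
  prof_k <- normalize_plate(pl_k, t = 0)
  expect_equal(prof$replicates, prof_k$replicates, tolerance = 1e-10)
  expect_identical(prof$presence, prof_k$presence)
  # normalized value is the ratio of the corrected well to the AWCD
  expect_equal(prof$replicates[5, 2], (0.02 * 5 + 0.05 * 2) / awcd(pl, 0),
               tolerance = 1e-12)
  # undeveloped plate refuses normalization
  expect_error(normalize_plate(make_plate(0), t = 0), "not developed")
})

test_that("substrate presence requires one replicate at normalized >= 1", {
  m <- rbind(S1 = c(0.2, 0.3, 1.0), S2 = c(0.99, 0.99, 0.99))
  flags <- score_presence(m)
  expect_true(flags["S1"])    # boundary: exactly 1 counts
  expect_false(flags["S2"])
  # monotone: raising any replicate never turns a positive negative
  m2 <- m; m2[, 2] <- m2[, 2] + 5
  expect_true(all(score_presence(m2) >= flags))
})

test_that("substrate distances match naive oracles under both metrics", {
  p2 <- rbind(Jan = c(0, 1), Feb = c(1, 0))
  expect_equal(as.matrix(substrate_distances(p2, "euclidean"))["Jan", "Feb"],
               sqrt(2))
  expect_equal(as.matrix(substrate_distances(rbind(a = 1:5, b = 1:5)))["a", "b"], 0)
  set.seed(8)
  prof <- matrix(runif(5 * 31), 5, dimnames = list(month.abb[1:5], NULL))
  expect_true(all(abs(as.matrix(substrate_distances(prof, "euclidean")) -
                        euclid_oracle(prof)) < 1e-12))
  expect_true(all(abs(as.matrix(substrate_distances(prof, "bray_curtis")) -
                        bray_oracle(prof)) < 1e-12))
  # negative normalized values are floored before Bray-Curtis
  prof[1, 1] <- -0.5
  expect_warning(substrate_distances(prof, "bray_curtis"), "floored")
})

test_that("simulated plates round-trip through scoring", {
  kin <- data.frame(substrate = 1:31, amplitude = 0.3, midpoint = 5,
                    rate = 1)
  # one substrate dominating the plate scores positive, the rest negative
  kin$amplitude[17] <- 0.3 * 31 * 3 # far above plate mean development
  pl <- simulate_ecoplate(kin, timepoints = seq(0, 14, 2), replicate_sd = 0,
                          seed = 3)
  prof <- normalize_plate(pl)
  expect_true(prof$presence[17])
  expect_false(any(prof$presence[-17]))
})
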