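test_that("rare-OTU filtering drops singleton-occurrence and low-read OTUs", {
  counts <- rbind(c(50, 4, 5, 0, 3), # months in rows below
                  c(0, 3, 5, 0, 3),
                  c(0, 2, 0, 0, 4))
  colnames(counts) <- c("single_50", "nine_total", "ten_total", "absent",
                        "ten_spread")
  counts <- counts[, colnames(counts) != "absent"] # otu_table wants any ids
  tab <- make_otu(counts)
  out <- filter_otus(tab)
  # present in one sample only, despite 50 reads: excluded
  expect_false("single_50" %in% colnames(out$counts))
  # 3 samples but 9 reads total: excluded
  expect_false("nine_total" %in% colnames(out$counts))
  # boundary complement: 2 samples, exactly 10 reads: retained
  expect_true("ten_total" %in% colnames(out$counts))
  expect_true("ten_spread" %in% colnames(out$counts))
  # samples never removed
  expect_identical(rownames(out$counts), rownames(tab$counts))
})

test_that("filtering is idempotent on random tables", {
  set.seed(42)
  for (i in 1:5) {
    counts <- matrix(rpois(6 * 40, 2), 6, 40)
    tab <- make_otu(counts)
    once <- filter_otus(tab)
    twice <- filter_otus(once)
    expect_identical(once$counts, twice$counts)
  }
})

test_that("rarefaction subsamples exactly to depth without inventing reads", {
  set.seed(1)
  counts <- matrix(rpois(4 * 30, 20), 4, 30)
  tab <- make_otu(counts)
  depth <- min(rowSums(counts)) - 5
  rar <- rarefy(tab, depth, seed = 7)
  expect_true(all(rowSums(rar$counts) == depth))
  expect_true(all(rar$counts <= tab$counts))
  # deterministic given the seed
  expect_identical(rar$counts, rarefy(tab, depth, seed = 7)$counts)
  # a sample holding exactly depth reads is returned unchanged
  tab1 <- make_otu(matrix(c(3L, 2L, 5L), 1, 3))
  expect_identical(rarefy(tab1, 10, seed = 1)$counts, tab1$counts)
  # shallow samples are named in the error
  expect_error(rarefy(tab, max(rowSums(counts)) + 1, seed = 1),
               rownames(counts)[1])
})

test_that("relative abundances are percentages summing to 100", {
  tab <- make_otu(matrix(c(10L, 30L, 7L, 0L), 2, 2))
  ra <- relative_abundance(tab)
  expect_equal(ra[1, ], c(OTU_001 = 10 / 17 * 100, OTU_002 = 7 / 17 * 100))
  expect_equal(unname(ra[2, ]), c(100, 0))
  set.seed(3)
  ra2 <- relative_abundance(matrix(runif(50, 1, 10), 5))
  expect_true(all(abs(rowSums(ra2) - 100) < 1e-9))
  expect_error(relative_abundance(make_otu(matrix(c(1L, 0L), 2, 1))),
               "zero-sum")
})

test_that("Bray-Curtis matches its formula, hand value, and a naive oracle", {
  m <- rbind(a = c(1, 2), b = c(3, 0))
  expect_equal(as.matrix(bray_curtis(m))["a", "b"], 2 / 3)
  # identical samples -> 0; disjoint supports -> 1
  m2 <- rbind(x = c(1, 2, 0), y = c(1, 2, 0), z = c(0, 0, 5))
  bm <- as.matrix(bray_curtis(m2))
  expect_equal(bm["x", "y"], 0)
  expect_equal(bm["x", "z"], 1)
  set.seed(11)
  r <- matrix(runif(15 * 12), 15)
  rownames(r) <- paste0("s", 1:15)
  expect_true(all(abs(as.matrix(bray_curtis(r)) - bray_oracle(r)) < 1e-12))
  d <- bray_curtis(r)
  expect_true(all(d >= 0 & d <= 1))
  # all-zero pair: defined as 0, with a warning
  z <- rbind(p = c(0, 0), q = c(0, 0), r = c(1, 2))
  expect_warning(dz <- bray_curtis(z), "all-zero")
  expect_equal(as.matrix(dz)["p", "q"], 0)
})

test_that("hierarchical clustering reproduces a brute-force agglomeration", {
  d2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- hierarchical_cluster(d2)
  expect_equal(hc2$height, 0.4)
  # clearly separated pair merges first under every linkage
  d3 <- matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  for (lk in c("complete", "average", "single")) {
    hc <- hierarchical_cluster(d3, lk)
    expect_setequal(hc$merge[1, ], c(-1, -2))
  }
  set.seed(5)
  m <- matrix(runif(36), 6); m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:6), paste0("s", 1:6))
  for (lk in c("complete", "average")) {
    hc <- hierarchical_cluster(m, lk)
    expect_equal(sort(hc$height), linkage_oracle(m, lk), tolerance = 1e-12)
    expect_false(is.unsorted(hc$height))      # monotone heights
    expect_setequal(hc$labels, rownames(m))   # leaves = samples
  }
  expect_error(hierarchical_cluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  nwk <- as_newick(hierarchical_cluster(m))
  expect_match(nwk, "^\\(.*\\);$")
  for (s in rownames(m)) expect_match(nwk, s, fixed = TRUE)
})
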