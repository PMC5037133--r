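# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles are deliberately naive (double loops, exhaustive
# agglomeration) so they share no code with the implementation they check.

# naive double-loop Bray-Curtis
bray_oracle <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- sum(abs(m[i, ] - m[j, ]))
    den <- sum(m[i, ] + m[j, ])
    d[i, j] <- if (den == 0) 0 else num / den
  }
  d
}

# naive pairwise euclidean
euclid_oracle <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  d
}

# O(n^3) agglomerative clustering, returning sorted merge heights
linkage_oracle <- function(D, linkage = "complete") {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  link <- switch(linkage, complete = max, average = mean, single = min)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- link(D[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# textbook sum-formula Pearson correlation
pearson_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# lasso objective on the standardized scale
lasso_objective <- function(Xs, yc, b, lambda) {
  sum((yc - Xs %*% b)^2) / (2 * length(yc)) + lambda * sum(abs(b))
}

# centered design with X'X/n = I, so the lasso has the closed-form
# soft-threshold solution
orthonormal_design <- function(n, p, seed) {
  set.seed(seed)
  M <- matrix(rnorm(n * p), n, p)
  M <- sweep(M, 2, colMeans(M))
  Q <- qr.Q(qr(M))[, seq_len(p)]
  X <- sqrt(n) * Q
  colnames(X) <- paste0("V", seq_len(p))
  X
}

soft_threshold <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)

# small random OTU table
make_otu <- function(counts, site = "site1", fraction = "rDNA") {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("%s_M%02d_%s", site, seq_len(nrow(counts)),
                                fraction)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("OTU_%03d", seq_len(ncol(counts)))
  meta <- data.frame(site = site, month = seq_len(nrow(counts)),
                     fraction = fraction, row.names = rownames(counts))
  otu_table(counts, meta)
}

# EcoPlate series with prescribed blank-corrected substrate-well values;
# `corrected` is either a scalar, or a function(substrate, replicate)
make_plate <- function(corrected, baseline = 0.1, timepoints = c(0, 1)) {
  layout <- default_ecoplate_layout()
  ab <- matrix(baseline, nrow(layout), length(timepoints),
               dimnames = list(layout$well, NULL))
  for (i in seq_len(nrow(layout))) {
    if (!layout$blank[i]) {
      v <- if (is.function(corrected))
        corrected(layout$substrate[i], layout$replicate[i])
      else corrected
      ab[i, ] <- baseline + v
    }
  }
  ecoplate_series(ab, timepoints, layout, sample_id = "fixture")
}

# minimal stand-in carrying just what cross_site_consensus reads
fake_fit <- function(selected, fn = "protease") {
  structure(list(selected = selected, function_name = fn),
            class = "lasso_fit")
}
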