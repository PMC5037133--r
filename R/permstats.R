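as_square_dissim <- function(d, name = "d") {
  m <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-10)))
    stop_bad(name, " must be a square symmetric dissimilarity matrix")
  m
}

#' Mantel test between two distance matrices
#'
#' The statistic is the Pearson correlation between the vectorized strict
#' lower triangles. The null distribution is built by simultaneously
#' permuting rows and columns of the second matrix; the p-value is
#' one-sided (greater) with the add-one convention
#' p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm).
#'
#' @param d1,d2 `dist` objects or square symmetric matrices over the same
#'   labeled samples.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @return Object of class `mantel_result`: `statistic`, `p_value`,
#'   `n_perm`, `seed`.
#' @export
mantel <- function(d1, d2, n_perm = 9999, seed) {
  m1 <- as_square_dissim(d1, "d1")
  m2 <- as_square_dissim(d2, "d2")
  l1 <- rownames(m1) %||% as.character(seq_len(nrow(m1)))
  l2 <- rownames(m2) %||% as.character(seq_len(nrow(m2)))
  if (!identical(dim(m1), dim(m2)) || !setequal(l1, l2))
    stop_bad("d1 and d2 must cover the same samples")
  m2 <- m2[l1, l1]
  n <- nrow(m1)
  v1 <- lower_vec(m1)
  v2 <- lower_vec(m2)
  if (sd(v1) == 0 || sd(v2) == 0)
    stop_bad("constant distance triangle: Mantel r undefined")
  r_obs <- cor(v1, v2)
  lt <- which(lower.tri(m1), arr.ind = TRUE)
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    cor(v1, m2[cbind(p[lt[, 1]], p[lt[, 2]])])
  }, numeric(1)))
  structure(list(statistic = r_obs,
                 p_value = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
                 n_perm = n_perm, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

# one-factor sums of squares from a Gower-centered matrix: total = tr(G),
# among-groups = tr(HG) with H the group-mean projector
permanova_ss <- function(G, groups) {
  ss_total <- sum(diag(G))
  ss_among <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    ss_among <- ss_among + sum(G[i, i]) / length(i)
  }
  c(total = ss_total, among = ss_among, resid = ss_total - ss_among)
}

#' One-factor PERMANOVA
#'
#' Partitions the variance of a dissimilarity matrix among the levels of a
#' single grouping factor. Squared dissimilarities are Gower-centered into
#' an inner-product matrix G; SS_total = tr(G) = sum of squared
#' dissimilarities / n, SS_among comes from the group-mean projector, and
#' pseudo-F = (SS_among/(a-1)) / (SS_resid/(n-a)). The p-value permutes the
#' group labels, one-sided (greater), with the add-one convention.
#'
#' @param d `dist` or square symmetric dissimilarity matrix.
#' @param groups grouping factor (length n, >= 2 non-empty levels).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return Object of class `permanova_result`: `pseudo_f`, `r_squared`,
#'   `ss` (total/among/resid), `df`, `p_value`, `n_perm`, `groups`,
#'   `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed) {
  m <- as_square_dissim(d)
  n <- nrow(m)
  groups <- as.factor(groups)
  if (length(groups) != n) stop_bad("groups must match the matrix dimension")
  a <- nlevels(droplevels(groups))
  if (a < 2L) stop_bad("need at least 2 groups")
  if (a >= n) stop_bad("no residual degrees of freedom (a >= n)")
  A <- -0.5 * m^2
  rm_ <- rowMeans(A); gm <- mean(A)
  G <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  ss <- permanova_ss(G, groups)
  f_obs <- (ss["among"] / (a - 1)) / (ss["resid"] / (n - a))
  f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    gp <- groups[sample.int(n)]
    s <- permanova_ss(G, gp)
    (s["among"] / (a - 1)) / (s["resid"] / (n - a))
  }, numeric(1)))
  structure(list(pseudo_f = unname(f_obs),
                 r_squared = unname(ss["among"] / ss["total"]),
                 ss = ss, df = c(among = a - 1, resid = n - a),
                 p_value = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
                 n_perm = n_perm, groups = levels(groups), seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d permutations)\n",
    x$pseudo_f, x$r_squared, x$p_value, x$n_perm))
  invisible(x)
}
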