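#' Assemble the predictor matrix for one site and one community function
#'
#' Concatenates the proportional abundance (%) of the total (rDNA) and
#' active (rRNA) OTUs with the environmental covariates, aligned on month,
#' keeping only months where the function response was observed. Predictor
#' columns are tagged by class: `rdna:<otu>`, `rrna:<otu>`, `env:<var>`.
#' Zero-variance columns (e.g. OTUs absent in all retained months) are
#' dropped and recorded. Many more columns than rows is the expected
#' regime.
#'
#' @param otu_rdna,otu_rrna [otu_table]s for one site (samples = months).
#' @param env numeric matrix of environmental covariates, months in rows
#'   (rownames = month numbers), variables in columns.
#' @param response the community function: data.frame with columns `month`
#'   and `value` (may contain `NA`), or a vector named by month.
#' @return Object of class `predictor_matrix`: list with `X` (rows =
#'   retained months), `y`, `months`, `tags` (data.frame id/class/tag),
#'   `dropped` (zero-variance tags), `center`, `scale`.
#' @export
assemble_predictors <- function(otu_rdna, otu_rrna, env, response) {
  stopifnot(inherits(otu_rdna, "otu_table"), inherits(otu_rrna, "otu_table"))
  if (is.data.frame(response)) {
    y <- setNames(response$value, response$month)
  } else {
    y <- response
    if (is.null(names(y))) stop_bad("response vector must be named by month")
  }
  env <- as.matrix(env)
  blocks <- list(
    rdna = {
      m <- relative_abundance(otu_rdna)
      rownames(m) <- otu_rdna$metadata$month
      m
    },
    rrna = {
      m <- relative_abundance(otu_rrna)
      rownames(m) <- otu_rrna$metadata$month
      m
    },
    env = env
  )
  months <- Reduce(intersect, lapply(blocks, rownames))
  months <- intersect(months, names(y)[!is.na(y)])
  if (length(months) < 4L)
    stop_bad("fewer than 4 usable months: fit would be meaningless")
  months <- months[order(as.numeric(months))]
  X <- do.call(cbind, lapply(names(blocks), function(b) {
    m <- blocks[[b]][months, , drop = FALSE]
    colnames(m) <- paste0(b, ":", colnames(m))
    m
  }))
  rownames(X) <- months
  xs <- apply(X, 2, function(v) sqrt(mean((v - mean(v))^2)))
  dropped <- colnames(X)[xs == 0]
  if (length(dropped))
    message(length(dropped), " zero-variance predictor column(s) dropped")
  X <- X[, xs > 0, drop = FALSE]
  tags <- data.frame(tag = colnames(X),
                     class = sub(":.*$", "", colnames(X)),
                     id = sub("^[^:]+:", "", colnames(X)))
  structure(list(X = X, y = unname(y[months]), months = as.integer(months),
                 tags = tags, dropped = dropped,
                 center = colMeans(X), scale = xs[xs > 0]),
            class = "predictor_matrix")
}

# standardize columns to mean 0, mean-square 1; zero-variance columns get
# scale NA and are excluded from the solve (their coefficient is 0)
standardize_columns <- function(X) {
  xm <- colMeans(X)
  xs <- sqrt(colMeans(sweep(X, 2, xm)^2))
  usable <- xs > 0
  Xs <- sweep(X[, usable, drop = FALSE], 2, xm[usable])
  Xs <- sweep(Xs, 2, xs[usable], "/")
  list(Xs = Xs, xm = xm, xs = xs, usable = usable)
}

#' Smallest penalty that zeroes every lasso coefficient
#'
#' @param X predictor matrix (or `predictor_matrix`).
#' @param y response (ignored if `X` carries one).
#' @return lambda_max = max_j |x_j' y| / n on the standardized scale.
#' @export
lambda_max <- function(X, y = NULL) {
  if (inherits(X, "predictor_matrix")) { y <- X$y; X <- X$X }
  st <- standardize_columns(as.matrix(X))
  yc <- y - mean(y)
  max(abs(crossprod(st$Xs, yc))) / nrow(st$Xs)
}

# decreasing log-spaced penalty path spanning `decades` below lambda_max
lambda_path <- function(X, y = NULL, n_lambda = 40, decades = 2) {
  lmax <- lambda_max(X, y)
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = n_lambda))
}

#' Fit the lasso by cyclic coordinate descent
#'
#' Minimizes (1/2n) ||y - X beta||^2 + lambda ||beta||_1 with columns
#' standardized internally to unit (population) standard deviation and y
#' centered; soft-threshold coordinate updates cycle over columns in input
#' order until no coefficient moves by more than `tol` in a full sweep.
#' Coefficients are reported back on the original predictor scale with an
#' intercept. Zero-variance columns carry a zero coefficient.
#'
#' @param X numeric predictor matrix or a [assemble_predictors()] result.
#' @param y numeric response (taken from `X` if it is a
#'   `predictor_matrix`).
#' @param lambda penalty, >= 0.
#' @param tol convergence tolerance on the maximum coefficient change
#'   (standardized scale), default 1e-7.
#' @param max_iter sweep limit; non-convergence is an error.
#' @param function_name optional label carried into consensus filtering.
#' @return Object of class `lasso_fit`: `beta` (original scale, named),
#'   `beta_std`, `intercept`, `selected` (tags with nonzero coefficients),
#'   `fitted`, `lambda`, `kkt_residual`, `iterations`, `function_name`.
#' @export
fit_lasso <- function(X, y = NULL, lambda, tol = 1e-7, max_iter = 100000L,
                      function_name = NULL) {
  if (inherits(X, "predictor_matrix")) { y <- X$y; X <- X$X }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (lambda < 0) stop_bad("lambda must be >= 0")
  st <- standardize_columns(X)
  yc <- y - mean(y)
  sol <- cd_lasso_path(st$Xs, yc, lambda, tol, as.integer(max_iter))
  if (!sol$converged[1])
    stop_bad("coordinate descent did not converge in ", max_iter,
             " sweeps (lambda = ", signif(lambda, 4), ")")
  bstd <- setNames(numeric(ncol(X)), colnames(X))
  bstd[st$usable] <- sol$beta[, 1]
  beta <- bstd
  beta[st$usable] <- bstd[st$usable] / st$xs[st$usable]
  intercept <- mean(y) - sum(beta * st$xm)
  fitted <- as.vector(X %*% beta) + intercept
  g <- crossprod(st$Xs, yc - st$Xs %*% sol$beta[, 1]) / nrow(X)
  nz <- sol$beta[, 1] != 0
  kkt <- max(c(0, abs(abs(g[nz]) - lambda), pmax(abs(g[!nz]) - lambda, 0)))
  structure(list(beta = beta, beta_std = bstd, intercept = intercept,
                 selected = names(beta)[beta != 0], fitted = fitted,
                 lambda = lambda, kkt_residual = kkt,
                 iterations = sol$iterations[1],
                 function_name = function_name),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("lasso_fit%s: lambda = %.4g, %d/%d predictors selected\n",
              if (is.null(x$function_name)) "" else paste0(" [", x$function_name, "]"),
              x$lambda, length(x$selected), length(x$beta)))
  invisible(x)
}

#' Choose the lasso penalty by k-fold cross-validation
#'
#' Fits the full penalty path (log-spaced from lambda_max down two
#' decades, warm starts) on each training fold and scores mean squared
#' prediction error on the held-out months. Returns the penalty minimizing
#' CV error (`rule = "min"`) or the largest penalty within one standard
#' error of it (`rule = "1se"`). Fold assignment is deterministic given
#' `seed`.
#'
#' @param X predictor matrix or `predictor_matrix`.
#' @param y response (if not carried by `X`).
#' @param k_folds number of folds, 3 <= k <= n.
#' @param seed integer seed for the fold shuffle.
#' @param rule `"min"` or `"1se"`.
#' @param n_lambda path length (default 40).
#' @return Object of class `cv_lasso`: `lambda` (chosen), `rule`,
#'   `lambda_path`, `cvm`, `cvsd`, `folds`.
#' @export
select_lambda <- function(X, y = NULL, k_folds = NULL, seed, rule = c("min", "1se"),
                          n_lambda = 40) {
  rule <- match.arg(rule)
  if (inherits(X, "predictor_matrix")) { y <- X$y; X <- X$X }
  X <- as.matrix(X)
  n <- nrow(X)
  k_folds <- k_folds %||% min(5L, n - 1L)
  if (k_folds < 3L || k_folds > n)
    stop_bad("k_folds must be in [3, n]")
  path <- lambda_path(X, y, n_lambda = n_lambda)
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  if (any(tabulate(folds, k_folds) == 0) || any(tabulate(folds, k_folds) == n))
    stop_bad("degenerate fold assignment")
  err <- matrix(NA_real_, k_folds, length(path))
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    st <- standardize_columns(X[tr, , drop = FALSE])
    ytr <- y[tr]
    sol <- cd_lasso_path(st$Xs, ytr - mean(ytr), path, 1e-7, 100000L)
    bstd <- matrix(0, ncol(X), length(path))
    bstd[st$usable, ] <- sol$beta
    borig <- bstd
    borig[st$usable, ] <- bstd[st$usable, ] / st$xs[st$usable]
    icept <- mean(ytr) - as.vector(crossprod(borig, st$xm))
    pred <- X[!tr, , drop = FALSE] %*% borig +
      matrix(icept, sum(!tr), length(path), byrow = TRUE)
    err[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cvm <- colMeans(err)
  cvsd <- apply(err, 2, sd) / sqrt(k_folds)
  i_min <- which.min(cvm)
  lambda <- if (rule == "min") path[i_min] else
    path[min(which(cvm <= cvm[i_min] + cvsd[i_min]))]
  structure(list(lambda = lambda, rule = rule, lambda_path = path,
                 cvm = cvm, cvsd = cvsd, folds = folds),
            class = "cv_lasso")
}

#' Pearson correlation of each selected predictor with the response
#'
#' @param X predictor matrix or `predictor_matrix`.
#' @param y response (if not carried by `X`).
#' @param selected character vector of selected column tags.
#' @return Named vector of Pearson r; zero-variance columns are excluded
#'   with a warning.
#' @export
per_variable_correlation <- function(X, y = NULL, selected) {
  if (inherits(X, "predictor_matrix")) { y <- X$y; X <- X$X }
  if (length(selected) == 0L) stop_bad("selected set is empty")
  if (length(y) < 3L) stop_bad("need at least 3 observations")
  miss <- setdiff(selected, colnames(X))
  if (length(miss)) stop_bad("unknown predictor(s): ", paste(miss, collapse = ", "))
  out <- vapply(selected, function(j) {
    v <- X[, j]
    if (sd(v) == 0) return(NA_real_)
    cor(v, y)
  }, numeric(1))
  if (anyNA(out)) {
    warning("zero-variance predictor(s) excluded: ",
            paste(names(out)[is.na(out)], collapse = ", "))
    out <- out[!is.na(out)]
  }
  out
}

#' Cross-site consensus filtering of lasso-selected predictors
#'
#' Retains exactly the predictors that (i) were selected by the lasso at
#' both sites and (ii) carry same-signed per-site Pearson correlations
#' with the function. Agreement between two independent systems is the
#' error control that suppresses spurious p >> n selections. A function
#' with an empty consensus set has "no model".
#'
#' @param fit_site1,fit_site2 [fit_lasso()] results for the same function.
#' @param r_site1,r_site2 named per-variable correlations from
#'   [per_variable_correlation()] (may be empty when nothing was selected).
#' @return data.frame of class `consensus_drivers` with columns
#'   `predictor`, `class`, `r_site1`, `r_site2`; zero rows means no model.
#' @export
cross_site_consensus <- function(fit_site1, fit_site2, r_site1, r_site2) {
  f1 <- fit_site1$function_name; f2 <- fit_site2$function_name
  if (!is.null(f1) && !is.null(f2) && !identical(f1, f2))
    stop_bad("fits are for different functions: ", f1, " vs ", f2)
  both <- intersect(names(r_site1), names(r_site2))
  both <- intersect(both, intersect(fit_site1$selected, fit_site2$selected))
  same_sign <- both[sign(r_site1[both]) == sign(r_site2[both]) &
                      sign(r_site1[both]) != 0]
  out <- data.frame(predictor = same_sign,
                    class = sub(":.*$", "", same_sign),
                    r_site1 = unname(r_site1[same_sign]),
                    r_site2 = unname(r_site2[same_sign]),
                    row.names = NULL)
  if (nrow(out) == 0L) message("no model: consensus set is empty")
  structure(out, class = c("consensus_drivers", "data.frame"),
            function_name = f1 %||% f2)
}

#' Pooled strength metrics for a consensus driver
#'
#' Predictor and response are standardized within each site (removing
#' site-level mean and scale offsets), the per-site pairs are pooled, and
#' the common R-squared is the squared Pearson correlation of the pooled
#' pairs. The RMSPE comes from the pooled single-predictor regression;
#' each residual is mapped back through its own site's response standard
#' deviation so the error keeps the function's units. Strength is
#' "strong" when the common R-squared exceeds 0.4.
#'
#' @param x_site1,y_site1,x_site2,y_site2 raw per-site predictor and
#'   response values for the retained driver.
#' @param r2_cutoff strong/weak boundary on the common R-squared
#'   (default 0.4).
#' @return List: `common_r2`, `rmspe` (function units), `strength`, `n`.
#' @export
consensus_metrics <- function(x_site1, y_site1, x_site2, y_site2,
                              r2_cutoff = 0.4) {
  if (length(x_site1) + length(x_site2) < 4L)
    stop_bad("need at least 4 pooled observations")
  zx <- c(scale(x_site1)[, 1], scale(x_site2)[, 1])
  zy <- c(scale(y_site1)[, 1], scale(y_site2)[, 1])
  sdy <- c(rep(sd(y_site1), length(y_site1)), rep(sd(y_site2), length(y_site2)))
  r <- cor(zx, zy)
  fit <- lm(zy ~ zx)
  resid_units <- residuals(fit) * sdy
  r2 <- r^2
  list(common_r2 = r2,
       rmspe = sqrt(mean(resid_units^2)),
       strength = if (r2 > r2_cutoff) "strong" else "weak",
       n = length(zx))
}

#' Full two-site driver inference for one community function
#'
#' Chains penalty selection by cross-validation, the lasso fit, per-site
#' correlations, cross-site consensus filtering and pooled metrics.
#'
#' @param pm_site1,pm_site2 [assemble_predictors()] results for the same
#'   function at the two sites.
#' @param seed integer seed (fold shuffles derive from it).
#' @param k_folds folds per site (default min(5, n-1) per site).
#' @param rule lambda rule, `"min"` (default) or `"1se"`.
#' @param n_lambda path length.
#' @param function_name label for the function analyzed.
#' @return data.frame of class `consensus_drivers` with columns
#'   `predictor`, `class`, `r_site1`, `r_site2`, `common_r2`, `rmspe`,
#'   `strength`; attributes `lambda` (per site), `folds` (per site).
#' @export
infer_function_drivers <- function(pm_site1, pm_site2, seed, k_folds = NULL,
                                   rule = "min", n_lambda = 40,
                                   function_name = NULL) {
  cvs <- list(
    select_lambda(pm_site1, k_folds = k_folds, seed = sub_seed(seed, 1),
                  rule = rule, n_lambda = n_lambda),
    select_lambda(pm_site2, k_folds = k_folds, seed = sub_seed(seed, 2),
                  rule = rule, n_lambda = n_lambda))
  fits <- list(
    fit_lasso(pm_site1, lambda = cvs[[1]]$lambda, function_name = function_name),
    fit_lasso(pm_site2, lambda = cvs[[2]]$lambda, function_name = function_name))
  rs <- lapply(1:2, function(i) {
    pm <- list(pm_site1, pm_site2)[[i]]
    sel <- fits[[i]]$selected
    if (length(sel) == 0L) return(setNames(numeric(0), character(0)))
    per_variable_correlation(pm, selected = sel)
  })
  cons <- cross_site_consensus(fits[[1]], fits[[2]], rs[[1]], rs[[2]])
  if (nrow(cons)) {
    met <- lapply(cons$predictor, function(p)
      consensus_metrics(pm_site1$X[, p], pm_site1$y,
                        pm_site2$X[, p], pm_site2$y))
    cons$common_r2 <- vapply(met, `[[`, numeric(1), "common_r2")
    cons$rmspe <- vapply(met, `[[`, numeric(1), "rmspe")
    cons$strength <- vapply(met, `[[`, character(1), "strength")
  } else {
    cons$common_r2 <- numeric(0)
    cons$rmspe <- numeric(0)
    cons$strength <- character(0)
  }
  attr(cons, "lambda") <- c(site1 = cvs[[1]]$lambda, site2 = cvs[[2]]$lambda)
  attr(cons, "folds") <- list(site1 = cvs[[1]]$folds, site2 = cvs[[2]]$folds)
  attr(cons, "function_name") <- function_name
  cons
}

#' Score consensus output against a planted truth
#'
#' @param consensus a `consensus_drivers` data.frame.
#' @param truth planted-driver table with columns `function`,
#'   `predictor_id`, `fraction` (`rDNA`/`rRNA`/`env`), `sign`, `beta`.
#' @param function_name which function's planted set to score against.
#' @return List with `tp`, `n_selected`, `n_planted`, `precision`,
#'   `recall` (precision is `NA` when nothing was selected).
#' @export
score_recovery <- function(consensus, truth, function_name) {
  tr <- truth[truth$`function` == function_name, , drop = FALSE]
  frac_tag <- c(rDNA = "rdna", rRNA = "rrna", env = "env")
  planted <- paste0(frac_tag[tr$fraction], ":", tr$predictor_id)
  sel <- consensus$predictor
  tp <- length(intersect(sel, planted))
  list(tp = tp, n_selected = length(sel), n_planted = length(planted),
       precision = if (length(sel)) tp / length(sel) else NA_real_,
       recall = if (length(planted)) tp / length(planted) else NA_real_)
}
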