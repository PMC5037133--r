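#' Bacterial growth efficiency
#'
#' BGE = BP / (BP + BR) * 100: the percentage of processed carbon routed
#' into biomass rather than respired. BP and BR must be in the same carbon
#' units (per volume per time); units are the caller's responsibility and
#' are not converted.
#'
#' @param bp bacterial production (>= 0).
#' @param br bacterial respiration (>= 0), same units as `bp`.
#' @return BGE in percent; `NA` with a warning where bp + br = 0.
#' @export
bge <- function(bp, br) {
  if (any(bp < 0, na.rm = TRUE) || any(br < 0, na.rm = TRUE))
    stop_bad("bp and br must be non-negative")
  tot <- bp + br
  out <- 100 * bp / tot
  zero <- !is.na(tot) & tot == 0
  if (any(zero)) {
    warning("bp + br = 0: BGE undefined, returning NA")
    out[zero] <- NA_real_
  }
  out
}

#' Cell production from thymidine incorporation
#'
#' Converts incorporated 3H-thymidine to cells produced using the empirical
#' conversion factor 1.4e18 cells per mol thymidine.
#'
#' @param mol_thymidine mol thymidine incorporated (>= 0).
#' @param conversion cells per mol (default 1.4e18).
#' @return Cells produced.
#' @export
cells_from_thymidine <- function(mol_thymidine, conversion = 1.4e18) {
  if (any(mol_thymidine < 0, na.rm = TRUE))
    stop_bad("mol_thymidine must be non-negative")
  mol_thymidine * conversion
}

#' Respiration rate from oxygen drawdown
#'
#' Fits ordinary least squares of O2 concentration on incubation time,
#' pooled across replicate bottles (shared slope); the respiration rate is
#' the negative of the slope. With a respiratory quotient of 1, carbon
#' respired equals oxygen consumed mole for mole, so the rate can be read
#' directly in carbon units. Per-bottle slopes are also reported when a
#' bottle column is present.
#'
#' @param o2 data.frame with columns `time`, `o2` and optionally `bottle`.
#' @return List of class `respiration_fit`: `rate` (pooled, units of o2
#'   per unit time), `se` (standard error of the slope), `rate_per_bottle`
#'   (named vector or `NULL`), `positive_slope` (logical warning flag),
#'   `n` observations used.
#' @export
respiration_rate <- function(o2) {
  o2 <- as.data.frame(o2)
  stopifnot(all(c("time", "o2") %in% names(o2)))
  o2 <- o2[complete.cases(o2[c("time", "o2")]), , drop = FALSE]
  if (nrow(o2) < 3L) stop_bad("need at least 3 O2 observations")
  fit <- lm(o2 ~ time, data = o2)
  slope <- unname(coef(fit)[["time"]])
  se <- suppressWarnings(summary(fit)$coefficients["time", "Std. Error"])
  flag <- slope > 0
  if (flag) warning("O2 increases over time: negative respiration rate")
  per_bottle <- NULL
  if ("bottle" %in% names(o2)) {
    per_bottle <- vapply(split(o2, o2$bottle), function(d) {
      if (nrow(d) < 2L) return(NA_real_)
      -unname(coef(lm(o2 ~ time, data = d))[["time"]])
    }, numeric(1))
  }
  structure(list(rate = -slope, se = se, rate_per_bottle = per_bottle,
                 positive_slope = flag, n = nrow(o2)),
            class = "respiration_fit")
}

#' Fit the bioavailable-DOC decay model
#'
#' Nonlinear least squares fit of DOC(t) = RDOC + BDOC * exp(-D_t * t),
#' partitioning dissolved organic carbon into a refractory pool (RDOC),
#' a bioavailable pool (BDOC) consumed at first-order rate D_t (per day).
#' Parameters are bounded below at zero. Starting values: RDOC at the
#' series minimum, BDOC at the observed range, D_t at ln(2) over half the
#' time span. An exactly constant series is degenerate (D_t
#' unidentifiable): the fit returns bdoc = 0, rdoc = mean(doc), d_t = NA.
#'
#' @param times observation times (days), span > 0.
#' @param doc_values DOC concentrations (umol C per liter).
#' @return List of class `doc_decay_fit`: `rdoc`, `bdoc`, `d_t`, `rss`,
#'   `converged`, `bdoc_fraction` = bdoc/(rdoc+bdoc) (share of the initial
#'   total that is bioavailable), `message`.
#' @export
fit_doc_decay <- function(times, doc_values) {
  ok <- complete.cases(times, doc_values)
  times <- times[ok]; doc_values <- doc_values[ok]
  if (length(times) < 4L) stop_bad("need at least 4 DOC observations")
  span <- diff(range(times))
  if (span <= 0) stop_bad("times must span a positive interval")
  if (diff(range(doc_values)) == 0) {
    return(structure(list(rdoc = mean(doc_values), bdoc = 0, d_t = NA_real_,
                          rss = 0, converged = TRUE,
                          bdoc_fraction = 0,
                          message = "constant series: decay unidentifiable"),
                     class = "doc_decay_fit"))
  }
  start <- list(rdoc = max(min(doc_values), 0),
                bdoc = max(diff(range(doc_values)), 1e-6),
                d_t = log(2) / (span / 2))
  fit <- tryCatch(
    minpack.lm::nlsLM(doc ~ rdoc + bdoc * exp(-d_t * time),
                      data = data.frame(time = times, doc = doc_values),
                      start = start, lower = c(0, 0, 1e-10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(rdoc = NA_real_, bdoc = NA_real_, d_t = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          bdoc_fraction = NA_real_,
                          message = conditionMessage(fit)),
                     class = "doc_decay_fit"))
  }
  p <- coef(fit)
  structure(list(rdoc = unname(p["rdoc"]), bdoc = unname(p["bdoc"]),
                 d_t = unname(p["d_t"]),
                 rss = sum(residuals(fit)^2),
                 converged = TRUE,
                 bdoc_fraction = unname(p["bdoc"] / (p["rdoc"] + p["bdoc"])),
                 message = "ok"),
            class = "doc_decay_fit")
}

#' @export
print.doc_decay_fit <- function(x, ...) {
  cat(sprintf("DOC decay fit: RDOC = %.4g, BDOC = %.4g (%.1f%% of total), D_t = %.4g /d [%s]\n",
              x$rdoc, x$bdoc, 100 * x$bdoc_fraction, x$d_t,
              if (x$converged) "converged" else paste("FAILED:", x$message)))
  invisible(x)
}

#' CDOM absorption spectral slope
#'
#' Fits ln a(lambda) = ln a0 - S * lambda over a wavelength window and
#' returns S (per nm), the exponential decline rate of colored dissolved
#' organic matter absorption with wavelength. S over 275-295 nm is a proxy
#' inversely related to DOM molecular weight; steeper spectra give larger
#' S. A nonlinear fit of a0 * exp(-S * (lambda - lambda0)) is available via
#' `method = "nonlinear"`.
#'
#' @param wavelengths wavelengths (nm).
#' @param absorption absorption coefficients, strictly positive within the
#'   window.
#' @param range length-2 window in nm; conventional windows are
#'   c(275, 295), c(300, 450), c(300, 650).
#' @param method `"loglinear"` (default) or `"nonlinear"`.
#' @return The spectral slope S in per nm.
#' @export
spectral_slope <- function(wavelengths, absorption, range = c(275, 295),
                           method = c("loglinear", "nonlinear")) {
  method <- match.arg(method)
  stopifnot(length(range) == 2L)
  inw <- wavelengths >= min(range) & wavelengths <= max(range)
  wl <- wavelengths[inw]; a <- absorption[inw]
  if (length(wl) < 5L) stop_bad("need >= 5 wavelengths inside the window")
  if (any(a <= 0)) stop_bad("non-positive absorption inside the window")
  fit <- lm(log(a) ~ wl)
  s <- -unname(coef(fit)[["wl"]])
  if (method == "nonlinear") {
    wl0 <- min(wl)
    nfit <- minpack.lm::nlsLM(a ~ a0 * exp(-s * (wl - wl0)),
                              data = data.frame(wl = wl, a = a),
                              start = list(a0 = exp(predict(fit))[which.min(wl)],
                                           s = s))
    s <- unname(coef(nfit)[["s"]])
  }
  s
}
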