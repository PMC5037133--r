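#' Configuration for the synthetic dataset generator
#'
#' Defines the study design the generator emulates: two coastal sites
#' sampled monthly over a year, total (rDNA) and active (rRNA) community
#' fractions with ~3,009 OTUs, 35 seasonally correlated environmental
#' covariates, and eight community functions driven by a small planted set
#' of predictors shared across sites with consistent sign.
#'
#' @param n_sites number of sites (default 2).
#' @param n_months months sampled per site (default 12).
#' @param n_otus OTUs per community fraction (default 3009; scale down for
#'   quick experiments).
#' @param n_env environmental covariates (default 35).
#' @param n_functions community functions (default 8).
#' @param n_drivers_shared planted drivers per function, shared across
#'   sites (default 3: two OTUs plus one environmental variable).
#' @param effect_size standardized coefficient magnitude of planted
#'   drivers (default 2).
#' @param noise_sd residual standard deviation on the standardized
#'   response (default 0.5, i.e. effect/noise = 4 at the defaults).
#' @param missing_month_rate probability that a function observation is
#'   missing, completely at random (default 0.25, mirroring the several
#'   months without assay data in a typical field year).
#' @param rho AR(1) month-to-month correlation of latent log abundances
#'   (default 0.6).
#' @param depth_range sequencing depth range per sample; the lower bound
#'   must cover the downstream rarefaction depth.
#' @param rarefaction_depth depth the pipeline will rarefy to (default
#'   16000).
#' @param seed integer seed; all generator randomness derives from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 2L, n_months = 12L, n_otus = 3009L,
                       n_env = 35L, n_functions = 8L, n_drivers_shared = 3L,
                       effect_size = 2, noise_sd = 0.5,
                       missing_month_rate = 0.25, rho = 0.6,
                       depth_range = c(16500L, 24000L),
                       rarefaction_depth = 16000L, seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites), n_months = as.integer(n_months),
              n_otus = as.integer(n_otus), n_env = as.integer(n_env),
              n_functions = as.integer(n_functions),
              n_drivers_shared = as.integer(n_drivers_shared),
              effect_size = effect_size, noise_sd = noise_sd,
              missing_month_rate = missing_month_rate, rho = rho,
              depth_range = as.integer(depth_range),
              rarefaction_depth = as.integer(rarefaction_depth),
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_sites, n_months, n_otus, n_env, n_functions) < 1L))
      stop_bad("all design counts must be >= 1")
    if (n_drivers_shared < 0L || n_drivers_shared > 2L * n_otus + n_env)
      stop_bad("n_drivers_shared must be in [0, 2*n_otus + n_env]")
    if (noise_sd < 0) stop_bad("noise_sd must be >= 0")
    if (missing_month_rate < 0 || missing_month_rate >= 1)
      stop_bad("missing_month_rate must be in [0, 1)")
    if (rho < 0 || rho >= 1) stop_bad("rho must be in [0, 1)")
    if (effect_size < 0) stop_bad("effect_size must be >= 0")
    if (depth_range[1] > depth_range[2]) stop_bad("bad depth_range")
    if (depth_range[1] < rarefaction_depth)
      stop_bad("minimum sequencing depth (", depth_range[1],
               ") is below the rarefaction depth (", rarefaction_depth, ")")
  })
  structure(cfg, class = "sim_config")
}

env_variable_names <- function(n_env) {
  base <- c("temperature", "salinity", "doc", "tdn", "din", "nitrite",
            "ammonium", "phosphate", "silicate", "chl_a", "s275_295",
            "s300_450", "fl_index", "uv_abs254", "cdom_a350")
  if (n_env <= length(base)) return(base[seq_len(n_env)])
  c(base, sprintf("env_%02d", (length(base) + 1):n_env))
}

function_names <- function(n_functions) {
  base <- c("protease", "chitobiase", "lipase", "alpha_glucosidase",
            "beta_glucosidase", "bge", "bp", "bacterial_abundance")
  if (n_functions <= length(base)) return(base[seq_len(n_functions)])
  c(base, sprintf("fn_%02d", (length(base) + 1):n_functions))
}

# latent log-normal abundances with AR(1) seasonal smoothing, multinomial
# read sampling at the drawn depth
simulate_otu_counts <- function(mu, n_months, rho, depth_range, seed) {
  with_seed(seed, {
    p <- length(mu)
    L <- matrix(0, n_months, p)
    L[1, ] <- mu + rnorm(p)
    if (n_months > 1) for (m in 2:n_months)
      L[m, ] <- mu + rho * (L[m - 1, ] - mu) + sqrt(1 - rho^2) * rnorm(p)
    probs <- exp(L)
    probs <- probs / rowSums(probs)
    depths <- sample(seq(depth_range[1], depth_range[2]), n_months,
                     replace = TRUE)
    counts <- t(vapply(seq_len(n_months),
                       function(m) rmultinom(1, depths[m], probs[m, ])[, 1],
                       integer(p)))
    counts
  })
}

#' Generate a complete synthetic study
#'
#' Emits, for every site: total and active OTU tables (compositional
#' counts from log-normal latent abundances with AR(1) seasonal
#' autocorrelation, multinomially sampled at depths above the rarefaction
#' depth), a months x covariates environmental matrix with sinusoidal
#' seasonal structure shared across sites, and one response per community
#' function built as a sparse linear combination of the planted
#' standardized drivers plus Gaussian noise. The planted (predictor, sign)
#' sets are identical across sites; magnitudes vary by site within 20%.
#' Auxiliary fixtures (EcoPlate kinetics, DOC decay, O2 drawdown, growth
#' and CDOM series) are attached per site. Byte-identical for a fixed
#' seed.
#'
#' @param config a [sim_config()].
#' @return Object of class `synthetic_dataset`: list with `sites` (each
#'   holding `otu_rdna`, `otu_rrna`, `env`, `functions`, `aux`), `truth`
#'   (planted-driver table: function, predictor_id, fraction, sign, beta)
#'   and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  seed <- cf$seed
  otu_ids <- sprintf("OTU_%04d", seq_len(cf$n_otus))
  env_ids <- env_variable_names(cf$n_env)
  fn_ids <- function_names(cf$n_functions)
  site_ids <- paste0("site", seq_len(cf$n_sites))
  months <- seq_len(cf$n_months)

  # shared latent abundance means: the same taxa dominate at both sites
  mu <- with_seed(sub_seed(seed, 1), rnorm(cf$n_otus, 0, 2))
  # shared seasonal forcing of the environment
  envpar <- with_seed(sub_seed(seed, 2), list(
    amp = runif(cf$n_env, 0.5, 2),
    phase = runif(cf$n_env, 0, cf$n_months),
    base = rnorm(cf$n_env, 0, 1)))

  # community tables and environment first; the planted truth is then
  # drawn against the realized predictor space
  tabs_by_site <- list(); env_by_site <- list(); rel_by_site <- list()
  for (s in seq_len(cf$n_sites)) {
    tabs <- list()
    for (fi in 1:2) {
      frac <- c("rDNA", "rRNA")[fi]
      counts <- simulate_otu_counts(mu, cf$n_months, cf$rho, cf$depth_range,
                                    sub_seed(seed, 10 + 4 * s + fi))
      rownames(counts) <- sprintf("%s_M%02d_%s", site_ids[s], months, frac)
      colnames(counts) <- otu_ids
      meta <- data.frame(site = site_ids[s], month = months, fraction = frac,
                         row.names = rownames(counts))
      tabs[[frac]] <- otu_table(counts, meta)
    }
    env <- with_seed(sub_seed(seed, 30 + s), {
      e <- vapply(seq_len(cf$n_env), function(v) {
        envpar$base[v] + rnorm(1, 0, 0.5) +
          envpar$amp[v] * sin(2 * pi * (months - envpar$phase[v]) / cf$n_months) +
          rnorm(cf$n_months, 0, 0.5)
      }, numeric(cf$n_months))
      dimnames(e) <- list(months, env_ids)
      e
    })
    tabs_by_site[[s]] <- tabs
    env_by_site[[s]] <- env
    rel_by_site[[s]] <- lapply(tabs, relative_abundance)
  }

  # standardized realized values of a candidate driver at site s
  driver_column <- function(s, id, fraction) {
    x <- switch(fraction,
                rDNA = rel_by_site[[s]]$rDNA[, id],
                rRNA = rel_by_site[[s]]$rRNA[, id],
                env = env_by_site[[s]][, id])
    if (sd(x) == 0) return(NULL)
    as.vector(scale(x))
  }

  # planted truth: same predictors and signs at every site. Driver sets
  # are rejection-sampled to be mutually near-orthogonal in every site
  # (max pairwise |r| 0.35) so the planted marginal signal is
  # identifiable at monthly resolution.
  truth <- with_seed(sub_seed(seed, 3), {
    n_env_drv <- if (cf$n_drivers_shared >= 3L) cf$n_drivers_shared %/% 3L
                 else 0L
    n_otu_drv <- cf$n_drivers_shared - n_env_drv
    # candidates: reliably present but below the dominant taxa whose
    # compositional closure couples them to each other
    ord <- order(mu, decreasing = TRUE)
    hi <- max(2L, ceiling(0.03 * cf$n_otus))
    lo <- min(cf$n_otus, max(hi + n_otu_drv, ceiling(0.15 * cf$n_otus)))
    cand <- otu_ids[ord[hi:lo]]
    do.call(rbind, lapply(fn_ids, function(f) {
      if (cf$n_drivers_shared == 0L) return(NULL)
      for (attempt in 1:200) {
        ids <- c(if (n_otu_drv) sample(cand, n_otu_drv),
                 if (n_env_drv) sample(env_ids, n_env_drv))
        frac <- c(if (n_otu_drv) sample(c("rDNA", "rRNA"), n_otu_drv,
                                        replace = TRUE),
                  rep("env", n_env_drv))
        ok <- TRUE
        for (s in seq_len(cf$n_sites)) {
          Z <- mapply(function(i, fr) driver_column(s, i, fr) %||%
                        rep(NA_real_, cf$n_months), ids, frac)
          if (anyNA(Z)) { ok <- FALSE; break }
          if (ncol(Z) > 1) {
            cc <- cor(Z)
            if (max(abs(cc[upper.tri(cc)])) > 0.35) { ok <- FALSE; break }
          }
        }
        if (ok) break
      }
      data.frame(`function` = f, predictor_id = ids, fraction = frac,
                 sign = sample(c(-1, 1), cf$n_drivers_shared, replace = TRUE),
                 beta = cf$effect_size, check.names = FALSE)
    }))
  })
  if (is.null(truth))
    truth <- data.frame(`function` = character(0), predictor_id = character(0),
                        fraction = character(0), sign = numeric(0),
                        beta = numeric(0), check.names = FALSE)

  site_mult <- with_seed(sub_seed(seed, 4),
                         matrix(runif(cf$n_sites * max(nrow(truth), 1), 0.8, 1.2),
                                nrow = max(nrow(truth), 1)))

  sites <- setNames(vector("list", cf$n_sites), site_ids)
  for (s in seq_len(cf$n_sites)) {
    tabs <- tabs_by_site[[s]]
    env <- env_by_site[[s]]

    # responses: sparse linear model over standardized planted predictors
    fns <- with_seed(sub_seed(seed, 40 + s), {
      rel <- rel_by_site[[s]]
      out <- list()
      for (k in seq_along(fn_ids)) {
        f <- fn_ids[k]
        rows <- which(truth$`function` == f)
        y <- rnorm(cf$n_months, 0, cf$noise_sd)
        for (j in rows) {
          x <- switch(truth$fraction[j],
                      rDNA = rel$rDNA[, truth$predictor_id[j]],
                      rRNA = rel$rRNA[, truth$predictor_id[j]],
                      env = env[, truth$predictor_id[j]])
          if (sd(x) > 0)
            y <- y + truth$sign[j] * truth$beta[j] * site_mult[j, s] *
              as.vector(scale(x))
        }
        miss <- runif(cf$n_months) < cf$missing_month_rate
        y[miss] <- NA_real_
        out[[f]] <- data.frame(month = months, value = y)
      }
      out
    })

    aux <- with_seed(sub_seed(seed, 60 + s), {
      plates <- lapply(months, function(m) {
        kin <- data.frame(substrate = 1:31,
                          amplitude = rlnorm(31, log(0.8), 0.5),
                          midpoint = runif(31, 3, 9),
                          rate = runif(31, 0.5, 1.5))
        simulate_ecoplate(kin, timepoints = seq(0, 14, by = 2),
                          replicate_sd = 0.02,
                          seed = sub_seed(seed, 100 + 50 * s + m),
                          sample_id = sprintf("%s_M%02d", site_ids[s], m))
      })
      names(plates) <- sprintf("M%02d", months)
      doc <- simulate_doc_decay(rdoc = runif(1, 150, 400),
                                bdoc = runif(1, 50, 250),
                                d_t = runif(1, 0.05, 0.2),
                                times = c(0, 1, 2, 4, 7, 10, 14, 21),
                                noise_sd = 2,
                                seed = sub_seed(seed, 200 + s))
      o2 <- simulate_o2_series(rate = runif(1, 2, 8),
                               o2_0 = runif(1, 250, 350),
                               times = 0:3, noise_sd = 1, n_bottles = 4,
                               seed = sub_seed(seed, 210 + s))
      growth <- data.frame(month = months,
                           bp_c = rlnorm(cf$n_months, log(2), 0.6),
                           br_c = rlnorm(cf$n_months, log(5), 0.6),
                           thymidine_mol = rlnorm(cf$n_months, log(2e-12), 0.5))
      wl <- 250:700
      cdom <- data.frame(
        wavelength = wl,
        absorption = runif(1, 2, 8) *
          exp(-runif(1, 0.012, 0.02) * (wl - 250)) *
          exp(rnorm(length(wl), 0, 0.01)))
      list(ecoplates = plates, doc = doc, o2 = o2, growth = growth,
           cdom = cdom)
    })

    sites[[s]] <- list(otu_rdna = tabs$rDNA, otu_rrna = tabs$rRNA,
                       env = env, functions = fns, aux = aux)
  }
  attr(truth, "site_multiplier") <- site_mult
  structure(list(sites = sites, truth = truth, config = cf),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cf <- x$config
  cat(sprintf(
    "synthetic_dataset: %d sites x %d months, %d OTUs x 2 fractions, %d env, %d functions (%d planted drivers each)\n",
    cf$n_sites, cf$n_months, cf$n_otus, cf$n_env, cf$n_functions,
    cf$n_drivers_shared))
  invisible(x)
}

#' Simulate an EcoPlate absorbance time series
#'
#' Substrate wells develop color along a logistic curve on top of the
#' blank baseline; blank wells carry baseline only. Replicate noise is iid
#' Gaussian per well and reading.
#'
#' @param kinetics data.frame with columns `substrate` (1-31),
#'   `amplitude` (asymptotic color, >= 0), `midpoint` (days) and `rate`
#'   (logistic time scale, > 0).
#' @param timepoints reading times in days, >= 2, strictly increasing.
#' @param replicate_sd well noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param baseline blank absorbance level (>= 0, default 0.05).
#' @param layout plate layout (default [default_ecoplate_layout()]).
#' @param sample_id plate label.
#' @return An [ecoplate_series].
#' @export
simulate_ecoplate <- function(kinetics, timepoints, replicate_sd = 0, seed,
                              baseline = 0.05,
                              layout = default_ecoplate_layout(),
                              sample_id = "synthetic_plate") {
  kinetics <- as.data.frame(kinetics)
  stopifnot(all(c("substrate", "amplitude", "midpoint", "rate") %in%
                  names(kinetics)))
  if (length(timepoints) < 2L) stop_bad("need at least 2 timepoints")
  if (replicate_sd < 0) stop_bad("replicate_sd must be >= 0")
  if (baseline < 0) stop_bad("baseline must be >= 0")
  if (any(kinetics$amplitude < 0) || any(kinetics$rate <= 0))
    stop_bad("amplitudes must be >= 0 and rates > 0")
  kin <- kinetics[match(1:31, kinetics$substrate), ]
  if (anyNA(kin$substrate)) stop_bad("kinetics must cover substrates 1..31")
  ab <- with_seed(seed, {
    m <- matrix(baseline, nrow(layout), length(timepoints),
                dimnames = list(layout$well, NULL))
    for (i in seq_len(nrow(layout))) {
      if (!layout$blank[i]) {
        k <- kin[layout$substrate[i], ]
        m[i, ] <- baseline +
          k$amplitude / (1 + exp(-(timepoints - k$midpoint) / k$rate))
      }
    }
    if (replicate_sd > 0)
      m <- m + matrix(rnorm(length(m), 0, replicate_sd), nrow(m))
    m
  })
  ecoplate_series(ab, timepoints, layout, sample_id)
}

#' Simulate a DOC degradation series
#'
#' DOC(t) = RDOC + BDOC * exp(-D_t * t) plus iid Gaussian noise.
#'
#' @param rdoc refractory DOC pool (>= 0, umol C/l).
#' @param bdoc bioavailable DOC pool (>= 0, umol C/l).
#' @param d_t first-order degradation coefficient (> 0, per day).
#' @param times observation days, non-negative, strictly increasing.
#' @param noise_sd observation noise sd (default 0).
#' @param seed integer seed (required when noise_sd > 0).
#' @return data.frame with columns `time`, `doc`.
#' @export
simulate_doc_decay <- function(rdoc, bdoc, d_t, times, noise_sd = 0,
                               seed = NULL) {
  if (rdoc < 0 || bdoc < 0) stop_bad("rdoc and bdoc must be >= 0")
  if (d_t <= 0) stop_bad("d_t must be > 0")
  if (any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop_bad("times must be non-negative and strictly increasing")
  doc <- rdoc + bdoc * exp(-d_t * times)
  if (noise_sd > 0) {
    if (is.null(seed)) stop_bad("seed required when noise_sd > 0")
    doc <- doc + with_seed(seed, rnorm(length(times), 0, noise_sd))
  }
  data.frame(time = times, doc = doc)
}

#' Simulate an oxygen drawdown series
#'
#' Linear O2 consumption o2_0 - rate * t in each replicate bottle plus
#' iid noise. Physically impossible negative concentrations are kept but
#' flagged in the `negative_o2` attribute.
#'
#' @param rate consumption rate (o2 units per unit time).
#' @param o2_0 initial concentration (> 0).
#' @param times observation times, strictly increasing.
#' @param noise_sd observation noise sd (default 0).
#' @param seed integer seed (required when noise_sd > 0).
#' @param n_bottles replicate bottles (default 1).
#' @return data.frame with columns `time`, `o2`, `bottle`; attribute
#'   `negative_o2` is TRUE when any generated concentration is negative.
#' @export
simulate_o2_series <- function(rate, o2_0, times, noise_sd = 0, seed = NULL,
                               n_bottles = 1L) {
  if (o2_0 <= 0) stop_bad("o2_0 must be > 0")
  if (is.unsorted(times, strictly = TRUE))
    stop_bad("times must be strictly increasing")
  base <- o2_0 - rate * times
  out <- do.call(rbind, lapply(seq_len(n_bottles), function(b)
    data.frame(time = times, o2 = base, bottle = b)))
  if (noise_sd > 0) {
    if (is.null(seed)) stop_bad("seed required when noise_sd > 0")
    out$o2 <- out$o2 + with_seed(seed, rnorm(nrow(out), 0, noise_sd))
  }
  attr(out, "negative_o2") <- any(out$o2 < 0)
  out
}
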