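#' Default 96-well EcoPlate layout
#'
#' The standard Biolog EcoPlate carries three replicate blocks, each with 31
#' carbon substrates plus one water blank, in columns 1-4, 5-8 and 9-12.
#' Within a block the water well comes first and substrates 1-31 fill the
#' remaining wells column-wise.
#'
#' @return data.frame with columns `well` (e.g. "A1"), `substrate`
#'   (1-31, `NA` for water), `replicate` (1-3) and `blank` (logical).
#' @export
default_ecoplate_layout <- function() {
  rows <- LETTERS[1:8]
  out <- vector("list", 3L)
  for (rep in 1:3) {
    cols <- (4 * (rep - 1) + 1):(4 * rep)
    wells <- as.vector(outer(rows, cols, function(r, c) paste0(r, c)))
    out[[rep]] <- data.frame(
      well = wells,
      substrate = c(NA_integer_, 1:31),
      replicate = rep,
      blank = c(TRUE, rep(FALSE, 31))
    )
  }
  do.call(rbind, out)
}

#' Construct an EcoPlate absorbance time series
#'
#' @param absorbance numeric matrix, wells x timepoints; rownames are well
#'   ids matching the layout.
#' @param timepoints strictly increasing numeric vector (days).
#' @param layout plate layout as from [default_ecoplate_layout()].
#' @param sample_id identifier for the sampled community.
#' @return Object of class `ecoplate_series`.
#' @export
ecoplate_series <- function(absorbance, timepoints,
                            layout = default_ecoplate_layout(),
                            sample_id = "plate") {
  absorbance <- as.matrix(absorbance)
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) != ncol(absorbance))
    stop_bad("number of timepoints must match absorbance columns")
  if (is.unsorted(timepoints, strictly = TRUE))
    stop_bad("timepoints must be strictly increasing")
  miss <- setdiff(layout$well, rownames(absorbance))
  if (length(miss))
    stop_bad("missing well(s): ", paste(miss, collapse = ", "))
  subs <- layout[!layout$blank, ]
  tab <- table(subs$substrate)
  if (length(tab) != 31L || any(tab != 3L))
    stop_bad("layout must define 31 substrates x 3 replicates")
  if (!all(1:3 %in% layout$replicate[layout$blank]))
    stop_bad("every replicate block needs a blank well")
  structure(list(absorbance = absorbance[layout$well, , drop = FALSE],
                 timepoints = timepoints, layout = layout,
                 sample_id = sample_id),
            class = "ecoplate_series")
}

#' @export
print.ecoplate_series <- function(x, ...) {
  cat(sprintf("ecoplate_series '%s': %d wells x %d timepoints (%.3g-%.3g d)\n",
              x$sample_id, nrow(x$absorbance), length(x$timepoints),
              min(x$timepoints), max(x$timepoints)))
  invisible(x)
}

# index of an observed timepoint, tolerant to floating representation
match_timepoint <- function(series, t) {
  i <- which(abs(series$timepoints - t) < 1e-9)
  if (length(i) != 1L)
    stop_bad("t = ", t, " is not an observed timepoint")
  i
}

# Blank-corrected absorbances R - C for the 93 substrate wells at every
# timepoint. blank = "replicate" subtracts the block's own water well;
# blank = "mean" subtracts the plate-mean blank.
blank_corrected <- function(series, blank = c("replicate", "mean")) {
  blank <- match.arg(blank)
  lay <- series$layout
  ab <- series$absorbance
  bl <- ab[lay$well[lay$blank], , drop = FALSE]
  rownames(bl) <- lay$replicate[lay$blank]
  subs <- lay[!lay$blank, ]
  corr <- ab[subs$well, , drop = FALSE]
  if (blank == "replicate") {
    corr <- corr - bl[as.character(subs$replicate), , drop = FALSE]
  } else {
    corr <- sweep(corr, 2, colMeans(bl))
  }
  attr(corr, "substrate") <- subs$substrate
  attr(corr, "replicate") <- subs$replicate
  corr
}

#' Average well color development
#'
#' AWCD at time t is the plate sum of blank-corrected absorbances over the
#' 93 substrate wells divided by 93 -- the mean color development per well.
#'
#' @param series an [ecoplate_series].
#' @param t an observed timepoint.
#' @param blank blank-correction mode, `"replicate"` (default) or `"mean"`.
#' @return AWCD (absorbance units).
#' @export
awcd <- function(series, t, blank = "replicate") {
  stopifnot(inherits(series, "ecoplate_series"))
  corr <- blank_corrected(series, blank)
  sum(corr[, match_timepoint(series, t)]) / 93
}

#' Choose the reading closest to a target AWCD
#'
#' Incubations are read repeatedly until color development saturates; the
#' reading whose AWCD is nearest `target` (default 0.5) is used for
#' normalization. Ties go to the earliest reading (less evaporation and
#' edge artifact).
#'
#' @inheritParams awcd
#' @param target AWCD aimed for (default 0.5).
#' @return The selected timepoint (days).
#' @export
select_timepoint <- function(series, target = 0.5, blank = "replicate") {
  stopifnot(inherits(series, "ecoplate_series"))
  corr <- blank_corrected(series, blank)
  a <- colSums(corr) / 93
  series$timepoints[which.min(abs(a - target))]
}

#' AWCD-normalized substrate profile
#'
#' Divides every blank-corrected substrate well at the chosen timepoint by
#' the plate AWCD, so the normalized plate mean is 1 and a well at 1 sits
#' exactly at average color development. Substrate values are replicate
#' means; a substrate is scored positive if at least one of its three
#' replicate wells reaches a normalized value >= 1.
#'
#' @inheritParams awcd
#' @param t timepoint to normalize at; default [select_timepoint()].
#' @return Object of class `substrate_profile`: list with `sample_id`,
#'   `timepoint`, `values` (named length-31 vector of replicate means),
#'   `replicates` (31 x 3 matrix) and `presence` (logical, 31).
#' @export
normalize_plate <- function(series, t = NULL, blank = "replicate") {
  stopifnot(inherits(series, "ecoplate_series"))
  if (is.null(t)) t <- select_timepoint(series, blank = blank)
  corr <- blank_corrected(series, blank)
  ti <- match_timepoint(series, t)
  a <- sum(corr[, ti]) / 93
  if (a <= 0) stop_bad("AWCD <= 0 at t = ", t, ": plate not developed")
  z <- corr[, ti] / a
  sub <- attr(corr, "substrate")
  rep <- attr(corr, "replicate")
  reps <- matrix(NA_real_, 31, 3,
                 dimnames = list(sprintf("S%02d", 1:31), paste0("rep", 1:3)))
  reps[cbind(sub, rep)] <- z
  structure(list(sample_id = series$sample_id, timepoint = t,
                 values = rowMeans(reps),
                 replicates = reps,
                 presence = score_presence(reps)),
            class = "substrate_profile")
}

#' Score substrates as utilized
#'
#' A substrate is positive when at least one replicate well reaches a
#' normalized absorbance of 1, i.e. matches or exceeds the plate's average
#' well color development.
#'
#' @param x a `substrate_profile` or a substrates x replicates matrix of
#'   normalized values.
#' @param threshold normalized absorbance cutoff (default 1).
#' @return Named logical vector, one flag per substrate.
#' @export
score_presence <- function(x, threshold = 1) {
  m <- if (inherits(x, "substrate_profile")) x$replicates else as.matrix(x)
  apply(m, 1, function(v) any(v >= threshold, na.rm = TRUE))
}

#' Distances between monthly substrate profiles
#'
#' @param profiles a list of `substrate_profile`s or a months x substrates
#'   matrix of normalized values (rownames label the months).
#' @param metric `"euclidean"` or `"bray_curtis"`. Bray-Curtis requires
#'   non-negative values; negative normalized values (wells paler than
#'   their blank) are floored at 0 with a warning.
#' @return A `dist` object over months.
#' @export
substrate_distances <- function(profiles, metric = c("euclidean", "bray_curtis")) {
  metric <- match.arg(metric)
  m <- if (is.matrix(profiles)) profiles else
    do.call(rbind, lapply(profiles, function(p) {
      stopifnot(inherits(p, "substrate_profile"))
      setNames(p$values, names(p$values))
    }))
  if (!is.matrix(profiles))
    rownames(m) <- vapply(profiles, function(p) p$sample_id, "")
  if (nrow(m) < 2L) stop_bad("need profiles for at least 2 months")
  if (metric == "euclidean") return(dist(m))
  if (any(m < 0)) {
    warning("negative normalized values floored at 0 for Bray-Curtis")
    m[m < 0] <- 0
  }
  bray_curtis(m)
}
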