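#' Salinity panel used throughout the growth workflow
#'
#' Percent NaCl of the six culture media; 0.2 is the standard medium.
#' The optimal range covers 0.2 and 0.6, the pessimal range 1.8, 2.5
#' and 3.3.
#'
#' @return list with \code{all}, \code{optimal}, \code{pessimal} numeric
#'   vectors.
#' @export
salinityPanel <- function() {
  list(all = c(0.2, 0.6, 1.2, 1.8, 2.5, 3.3),
       optimal = c(0.2, 0.6),
       pessimal = c(1.8, 2.5, 3.3))
}

#' Fit the maximal exponential growth rate of one curve
#'
#' Fits N(t) = N0 * exp(mu * t) by least squares on log-fluorescence over
#' every contiguous window of at least \code{minPoints} observations and
#' returns the maximal per-day rate among windows whose coefficient of
#' determination reaches \code{r2Gate}.  When no window passes (or the best
#' passing slope is not positive) the result is a flagged no-growth rate of
#' zero, not an error.
#'
#' @param time_h observation times in hours, strictly increasing.
#' @param fluorescence positive fluorescence values (arbitrary units).
#' @param minPoints minimum window size; default 4.
#' @param r2Gate R-squared acceptance gate; default 0.95.
#' @return list: \code{mu} (per day), \code{window} (index range used),
#'   \code{r2}, \code{noGrowth} flag.
#'
#' @section Errors: fewer than \code{minPoints} observations, non-increasing
#'   times or non-positive fluorescence signal a \code{dataError}.
#' @examples
#' t <- seq(0, 216, by = 24)
#' fitExponentialRate(t, 100 * exp(0.05 * t))$mu  # 1.2 per day
#' @export
fitExponentialRate <- function(time_h, fluorescence, minPoints = 4L,
                               r2Gate = 0.95) {
  n <- length(time_h)
  if (n != length(fluorescence) || n < minPoints)
    .err("dataError",
         sprintf("need >= %d paired observations", minPoints))
  if (any(diff(time_h) <= 0))
    .err("dataError", "times must be strictly increasing")
  if (any(fluorescence <= 0))
    .err("dataError", "fluorescence must be positive")
  y <- log(fluorescence)
  best <- list(mu = -Inf, window = c(NA_integer_, NA_integer_),
               r2 = NA_real_)
  for (i in seq_len(n - minPoints + 1L)) {
    for (j in (i + minPoints - 1L):n) {
      tt <- time_h[i:j]; yy <- y[i:j]
      fit <- stats::lm.fit(cbind(1, tt), yy)
      ssr <- sum(fit$residuals^2)
      sst <- sum((yy - mean(yy))^2)
      r2 <- if (sst < 1e-12) 1 else 1 - ssr / sst
      if (r2 >= r2Gate) {
        mu <- unname(fit$coefficients[2]) * 24   # per hour -> per day
        if (mu > best$mu) best <- list(mu = mu, window = c(i, j), r2 = r2)
      }
    }
  }
  if (!is.finite(best$mu) || best$mu <= 1e-12)
    return(list(mu = 0, window = best$window, r2 = best$r2, noGrowth = TRUE))
  c(best, list(noGrowth = FALSE))
}

#' Per-strain, per-salinity maximal growth rates from a long table
#'
#' Fits every replicate curve with [fitExponentialRate()] and takes the
#' median over replicates, the convention for four-replicate growth
#' designs.
#'
#' @param data data.frame with columns \code{strain}, \code{salinity},
#'   \code{replicate}, \code{time_h}, \code{fluorescence}.
#' @param ... passed to [fitExponentialRate()].
#' @return data.frame with columns \code{strain}, \code{salinity},
#'   \code{mu} (median per-day rate), \code{n_replicates}.
#' @export
growthRateTable <- function(data, ...) {
  need <- c("strain", "salinity", "replicate", "time_h", "fluorescence")
  if (!all(need %in% names(data)))
    .err("formatError", sprintf("growth data needs columns: %s",
                                paste(need, collapse = ", ")))
  sp <- split(data, data[, c("strain", "salinity")], drop = TRUE)
  rows <- lapply(sp, function(d) {
    mus <- vapply(split(d, d$replicate), function(r) {
      r <- r[order(r$time_h), ]
      fitExponentialRate(r$time_h, r$fluorescence, ...)$mu
    }, numeric(1))
    data.frame(strain = d$strain[1], salinity = d$salinity[1],
               mu = stats::median(mus), n_replicates = length(mus),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$strain, out$salinity), ]
  rownames(out) <- NULL
  out
}

#' Relative salinity sensitivity
#'
#' The decline of a strain is its best rate over the optimal salinities
#' (0.2, 0.6\% NaCl) minus its worst rate over the pessimal salinities
#' (1.8, 2.5, 3.3\%), floored at zero; sensitivity expresses that decline
#' as a percentage of the reference strain's decline, so the reference (by
#' construction the most sensitive strain) scores exactly 100.
#'
#' @param rates data.frame with columns \code{strain}, \code{salinity},
#'   \code{mu} (from [growthRateTable()] or planted truth).
#' @param reference id of the reference strain.
#' @param panel salinity panel, see [salinityPanel()].
#' @return data.frame with columns \code{strain}, \code{decline},
#'   \code{sensitivity} (percent).
#'
#' @section Errors: a strain without both an optimal- and a pessimal-range
#'   rate signals a \code{dataError}; a reference decline of zero an
#'   \code{undefinedSensitivityError}.
#' @export
salinitySensitivity <- function(rates, reference, panel = salinityPanel()) {
  if (!reference %in% rates$strain)
    .err("crossReferenceError",
         sprintf("reference strain '%s' absent from rates", reference))
  strains <- unique(rates$strain)
  decline <- vapply(strains, function(s) {
    r <- rates[rates$strain == s, ]
    opt <- r$mu[r$salinity %in% panel$optimal]
    pes <- r$mu[r$salinity %in% panel$pessimal]
    if (!length(opt) || !length(pes))
      .err("dataError",
           sprintf("strain '%s' lacks optimal- or pessimal-range rates", s))
    max(0, max(opt) - min(pes))
  }, numeric(1))
  refDecline <- decline[[reference]]
  if (refDecline <= 0)
    .err("undefinedSensitivityError",
         "reference strain shows no decline; sensitivity undefined")
  data.frame(strain = strains,
             decline = unname(decline),
             sensitivity = unname(100 * decline / refDecline),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify a sensitivity percentage
#'
#' Three-way classification with configurable cutoffs; the defaults
#' (robust below 33, intermediately sensitive below 66, sensitive at 66
#' and above) are explicitly arbitrary, as the class names come from a
#' qualitative grouping without published numeric boundaries.
#'
#' @param sensitivity non-negative percentage(s).
#' @param cutoffs strictly increasing length-2 numeric vector.
#' @return character vector over \code{"robust"},
#'   \code{"intermediately_sensitive"}, \code{"sensitive"}.
#' @export
classifySalinityResponse <- function(sensitivity, cutoffs = c(33, 66)) {
  if (length(cutoffs) != 2L || diff(cutoffs) <= 0)
    .err("usageError", "cutoffs must be two strictly increasing numbers")
  if (any(sensitivity < 0))
    .err("usageError", "sensitivity must be >= 0")
  ifelse(sensitivity < cutoffs[1], "robust",
         ifelse(sensitivity < cutoffs[2], "intermediately_sensitive",
                "sensitive"))
}

#' Box-and-whisker summary of cell shape measurements
#'
#' Median, quartiles and 1.5-IQR whiskers for cell length, width and the
#' length:width ratio; whisker ends are the most extreme observations
#' within 1.5 interquartile ranges of the quartiles, so outliers beyond
#' them shape neither whisker (but stay in the data).
#'
#' @param length_um,width_um per-cell measurements in micrometers (at least
#'   5 cells).
#' @return data.frame with one row per variable (\code{length},
#'   \code{width}, \code{ratio}) and columns \code{lower_whisker},
#'   \code{q1}, \code{median}, \code{q3}, \code{upper_whisker},
#'   \code{n_outliers}.
#'
#' @section Errors: fewer than 5 cells or non-positive measurements signal
#'   a \code{dataError}.
#' @export
cellShapeSummary <- function(length_um, width_um) {
  if (length(length_um) != length(width_um) || length(length_um) < 5L)
    .err("dataError", "need paired measurements for at least 5 cells")
  if (any(length_um <= 0) || any(width_um <= 0))
    .err("dataError", "measurements must be positive")
  vars <- list(length = length_um, width = width_um,
               ratio = length_um / width_um)
  rows <- lapply(names(vars), function(nm) {
    x <- vars[[nm]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lowFence <- q[1] - 1.5 * iqr
    highFence <- q[3] + 1.5 * iqr
    inside <- x >= lowFence & x <= highFence
    data.frame(variable = nm,
               lower_whisker = min(x[inside]), q1 = q[1], median = q[2],
               q3 = q[3], upper_whisker = max(x[inside]),
               n_outliers = sum(!inside), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
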