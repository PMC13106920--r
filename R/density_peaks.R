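#' Gaussian kernel density estimate on a regular grid
#'
#' A thin, validated wrapper around [stats::density()] with the
#' conventions used throughout this package: Gaussian kernel, Silverman's
#' rule-of-thumb bandwidth by default, a 512-point grid extending three
#' bandwidths past the data range, and a check that the curve integrates
#' to one.
#'
#' @param values Numeric vector, at least two finite values with nonzero
#'   spread.
#' @param bandwidth Kernel bandwidth (same units as `values`); default is
#'   Silverman's rule of thumb ([stats::bw.nrd0()]).
#' @param grid_size Number of equally spaced grid points.
#' @return An object of class `"density_curve"`: a list with `grid`,
#'   `density` and `bandwidth`.
#' @export
estimate_density <- function(values, bandwidth = NULL, grid_size = 512L) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop("need at least 2 finite values for a density estimate",
         call. = FALSE)
  }
  if (diff(range(values)) == 0) {
    stop("all values are identical; the density estimate is degenerate",
         call. = FALSE)
  }
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(values)
  d <- stats::density(values, bw = bandwidth, kernel = "gaussian",
                      n = grid_size, cut = 3)
  structure(list(grid = d$x, density = d$y, bandwidth = d$bw),
            class = "density_curve")
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf("<density_curve> %d points on [%.4g, %.4g], bandwidth %.4g\n",
              length(x$grid), min(x$grid), max(x$grid), x$bandwidth))
  invisible(x)
}

# Trapezoidal integral of a curve; used to validate normalization.
trapezoid <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Locate local maxima of a density curve
#'
#' A peak is an interior grid point strictly higher than both neighbours
#' whose *prominence* — height above the higher of the two saddle points
#' separating it from higher terrain (or from the curve ends) — is at
#' least `min_prominence_frac` of the curve maximum. The threshold
#' suppresses floating-point ripple; genuine modes of smooth kernel
#' densities are far above it.
#'
#' @param curve A `"density_curve"` from [estimate_density()].
#' @param min_prominence_frac Minimum prominence as a fraction of the
#'   maximum density.
#' @return A data.frame with one row per peak, sorted by location:
#'   `location`, `height`, `prominence`.
#' @export
find_density_peaks <- function(curve, min_prominence_frac = 0.01) {
  y <- curve$density
  x <- curve$grid
  n <- length(y)
  if (n < 3L) return(data.frame(location = numeric(0), height = numeric(0),
                                prominence = numeric(0)))
  is_peak <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  prominence <- vapply(is_peak, function(i) {
    # walk outwards until terrain exceeds the peak; prominence is measured
    # from the higher of the two valley floors found on the way
    left <- if (i > 1) y[1:(i - 1)] else numeric(0)
    right <- if (i < n) y[(i + 1):n] else numeric(0)
    higher_left <- which(rev(left) > y[i])
    lmin <- if (length(higher_left)) {
      min(rev(left)[1:(higher_left[1] - 1)])
    } else min(left)
    higher_right <- which(right > y[i])
    rmin <- if (length(higher_right)) {
      min(right[1:(higher_right[1] - 1)])
    } else min(right)
    y[i] - max(lmin, rmin)
  }, 0.0)
  keep <- prominence >= min_prominence_frac * max(y)
  out <- data.frame(location = x[is_peak][keep],
                    height = y[is_peak][keep],
                    prominence = prominence[keep])
  out[order(out$location), , drop = FALSE]
}

#' Density curves and peaks per sex and age class
#'
#' Convenience wrapper for descriptive peak tables: estimates a density of
#' the given variable for every sex-by-age-class group and reports its
#' peaks in increasing location order. For inter-onset intervals the first
#' (shortest) peak is the intra-phrase mode and the second the inter-phrase
#' mode, so peaks are additionally labelled by rank.
#'
#' @param values Numeric vector of the variable (t_k in seconds, or r_k).
#' @param sex,age_class Character vectors parallel to `values`.
#' @param ... Passed on to [estimate_density()].
#' @param min_prominence_frac Passed on to [find_density_peaks()].
#' @return A data.frame with columns `sex`, `age_class`, `peak_rank`,
#'   `location`, `height`, `prominence`, `n`.
#' @export
group_density_peaks <- function(values, sex, age_class, ...,
                                min_prominence_frac = 0.01) {
  stopifnot(length(values) == length(sex), length(values) == length(age_class))
  groups <- unique(data.frame(sex = sex, age_class = age_class,
                              stringsAsFactors = FALSE))
  groups <- groups[order(groups$sex, match(groups$age_class,
                                           age_class_levels())), ,
                   drop = FALSE]
  out <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- sex == groups$sex[i] & age_class == groups$age_class[i]
    v <- values[sel]
    if (sum(is.finite(v)) < 2L || diff(range(v[is.finite(v)])) == 0) {
      return(NULL)
    }
    pk <- find_density_peaks(estimate_density(v, ...),
                             min_prominence_frac = min_prominence_frac)
    if (nrow(pk) == 0L) return(NULL)
    data.frame(sex = groups$sex[i], age_class = groups$age_class[i],
               peak_rank = seq_len(nrow(pk)), pk, n = sum(is.finite(v)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(sex = character(0), age_class = character(0),
                      peak_rank = integer(0), location = numeric(0),
                      height = numeric(0), prominence = numeric(0),
                      n = integer(0))
  }
  rownames(out) <- NULL
  out
}
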