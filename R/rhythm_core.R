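#' Compute inter-onset intervals with a meter-perception cap
#'
#' The inter-onset interval t_k is the time from one note's onset to the
#' next note's onset. Intervals longer than `cap` (default 5 s, the usual
#' upper limit for meter perception) are discarded, and a *break* is
#' recorded at the discarded position so that no ratio or triple is ever
#' computed across it: a ratio involving a discarded interval would
#' reintroduce the excluded duration.
#'
#' @param x A [contribution()], or a numeric vector of strictly increasing
#'   onset times in seconds.
#' @param cap Maximum interval duration retained, in seconds.
#' @param drop_adjacent If `TRUE`, the intervals immediately before and
#'   after each over-cap gap are discarded as well (a stricter reading of
#'   the cap rule); by default only the over-cap interval itself is
#'   dropped.
#' @return An object of class `"ioi_sequence"`: a list with `values` (the
#'   retained t_k, in order), `segment` (integer run id; ratios and triples
#'   are only formed within a segment), `break_after` (indices k of
#'   `values` after which a break occurs, including the final index), and
#'   `cap`.
#' @export
#' @examples
#' compute_iois(c(0, 2, 9, 11))   # the 7 s gap is discarded
compute_iois <- function(x, cap = 5.0, drop_adjacent = FALSE) {
  onsets <- if (inherits(x, "contribution")) x$onsets else as.numeric(x)
  if (length(onsets) < 1L) stop("need at least one onset", call. = FALSE)
  if (is.unsorted(onsets, strictly = TRUE)) {
    stop("onsets must be strictly increasing", call. = FALSE)
  }
  if (cap <= 0) stop("`cap` must be positive", call. = FALSE)
  t_all <- diff(onsets)
  keep <- t_all <= cap
  if (drop_adjacent && any(!keep)) {
    over <- which(!keep)
    keep[pmax(over - 1L, 1L)] <- FALSE
    keep[pmin(over + 1L, length(keep))] <- FALSE
  }
  # Segment id increments at every dropped interval; consecutive retained
  # intervals share a segment and may form ratios.
  seg_all <- cumsum(c(1L, as.integer(!keep[-length(keep)])))
  values <- t_all[keep]
  segment <- seg_all[keep]
  if (length(values) > 0L) {
    segment <- as.integer(factor(segment))  # renumber 1..n_segments
    break_after <- which(diff(c(segment, max(segment) + 1L)) != 0L)
  } else {
    segment <- integer(0)
    break_after <- integer(0)
  }
  structure(list(values = values, segment = segment,
                 break_after = break_after, cap = cap),
            class = "ioi_sequence")
}

#' @export
print.ioi_sequence <- function(x, ...) {
  cat(sprintf("<ioi_sequence> %d intervals in %d segment(s), cap %.1f s\n",
              length(x$values),
              if (length(x$segment)) max(x$segment) else 0L, x$cap))
  invisible(x)
}

#' Rhythmic ratios of adjacent inter-onset intervals
#'
#' The rhythmic ratio r_k = t_k / (t_k + t_k+1) describes the local
#' relationship of two adjacent intervals: 1/2 means the two are equal
#' (isochrony), 1/3 means the second is twice the first (1:2), 2/3 means
#' the second is half the first (2:1). Ratios are only formed for pairs
#' within the same segment, never across a break left by the interval cap
#' or across contributions.
#'
#' @param iois An `"ioi_sequence"` from [compute_iois()], or a plain
#'   numeric vector of intervals (treated as one unbroken segment).
#' @return Numeric vector of ratios, each strictly in (0, 1).
#' @export
#' @examples
#' compute_ratios(compute_iois(c(0, 2, 4, 8)))  # 0.5 then 1/3
compute_ratios <- function(iois) {
  if (!inherits(iois, "ioi_sequence")) {
    iois <- list(values = as.numeric(iois),
                 segment = rep(1L, length(iois)))
  }
  v <- iois$values
  if (length(v) < 2L) return(numeric(0))
  if (any(v <= 0)) stop("intervals must be positive", call. = FALSE)
  same_seg <- iois$segment[-length(v)] == iois$segment[-1]
  r <- v[-length(v)] / (v[-length(v)] + v[-1])
  r[same_seg]
}

#' Interval triples for ternary (simplex) representation
#'
#' Each window of three consecutive intervals within one segment is
#' normalized to proportions summing to one; plotted on a ternary diagram
#' these show the three-interval rhythmic structure (the simplex centre
#' 1/3:1/3:1/3 is local isochrony).
#'
#' @inheritParams compute_ratios
#' @return A data.frame with columns `t1`, `t2`, `t3`, the proportions of
#'   the first, second and third interval of each window.
#' @export
compute_triples <- function(iois) {
  if (!inherits(iois, "ioi_sequence")) {
    iois <- list(values = as.numeric(iois),
                 segment = rep(1L, length(iois)))
  }
  v <- iois$values
  n <- length(v)
  if (n < 3L) {
    return(data.frame(t1 = numeric(0), t2 = numeric(0), t3 = numeric(0)))
  }
  i <- seq_len(n - 2L)
  ok <- iois$segment[i] == iois$segment[i + 1L] &
    iois$segment[i + 1L] == iois$segment[i + 2L]
  tot <- v[i] + v[i + 1L] + v[i + 2L]
  out <- data.frame(t1 = (v[i] / tot)[ok], t2 = (v[i + 1L] / tot)[ok],
                    t3 = (v[i + 2L] / tot)[ok])
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# On/off-integer ratio bins

#' The on/off-integer ratio bin scheme
#'
#' For each rhythmic category — 1:2 (reference ratio 1/3), 1:1 (1/2,
#' isochrony) and 2:1 (2/3) — an *on-integer* range is centred on the
#' small-integer ratio and flanked by two *off-integer* control ranges.
#' Boundaries are the exact fractions 1/3.5, 1/3.25, 1/2.75, 1/2.5,
#' 1/2.25 and their reflections 1 - x; published three-decimal displays of
#' these fractions are rounded, so the exact values are authoritative.
#' The six on/off ranges tile the interval \[1/3.5, 1 - 1/3.5\] with no
#' gaps or overlaps; membership is half-open \[lo, hi) except that the
#' global upper endpoint is closed.
#'
#' @return An object of class `"ratio_bin_scheme"`: a data.frame with one
#'   row per sub-range (`category`, `part` = `off_left`/`on`/`off_right`,
#'   `bin` = `on_X`/`off_X`, `lo`, `hi`) and attributes `centers` (the
#'   reference ratios) and `span` (the covered interval).
#' @export
#' @examples
#' default_bin_scheme()
#' bin_widths(default_bin_scheme())
default_bin_scheme <- function() {
  b <- c(1 / 3.5, 1 / 3.25, 1 / 2.75, 1 / 2.5, 1 / 2.25,
         1 - 1 / 2.25, 1 - 1 / 2.5, 1 - 1 / 2.75, 1 - 1 / 3.25, 1 - 1 / 3.5)
  scheme <- data.frame(
    category = rep(c("R12", "R11", "R21"), each = 3L),
    part = rep(c("off_left", "on", "off_right"), times = 3L),
    lo = b[1:9],
    hi = b[2:10],
    stringsAsFactors = FALSE)
  scheme$bin <- ifelse(scheme$part == "on",
                       paste0("on_", scheme$category),
                       paste0("off_", scheme$category))
  scheme <- scheme[, c("category", "part", "bin", "lo", "hi")]
  structure(scheme,
            centers = c(R12 = 1 / 3, R11 = 1 / 2, R21 = 2 / 3),
            span = c(b[1], b[10]),
            class = c("ratio_bin_scheme", "data.frame"))
}

#' Bin labels of a scheme, in category order
#' @param scheme A `"ratio_bin_scheme"`.
#' @return Character vector `on_R12, off_R12, on_R11, off_R11, on_R21,
#'   off_R21`.
#' @export
bin_labels <- function(scheme = default_bin_scheme()) {
  cats <- unique(scheme$category)
  as.vector(rbind(paste0("on_", cats), paste0("off_", cats)))
}

#' Widths of the on- and off-integer bins
#'
#' The off width of a category is the sum of its two flanking sub-ranges.
#' These widths are the exposure of the count model: on/off ranges are
#' unequally wide, so counts are modelled per unit ratio width.
#'
#' @param scheme A `"ratio_bin_scheme"`.
#' @return Named numeric vector of widths in ratio units, one per bin
#'   label.
#' @export
bin_widths <- function(scheme = default_bin_scheme()) {
  w <- tapply(scheme$hi - scheme$lo,
              list(scheme$bin), sum)
  out <- as.numeric(w[bin_labels(scheme)])
  names(out) <- bin_labels(scheme)
  out
}

#' Classify rhythmic ratios into on/off-integer bins
#'
#' Membership is half-open `[lo, hi)`; the single global maximum
#' `1 - 1/3.5` is included in the last off range. Ratios outside the
#' covered span get `NA` (they belong to no rhythmic category).
#'
#' @param r Numeric vector of ratios, each strictly in (0, 1).
#' @param scheme A `"ratio_bin_scheme"`.
#' @return Character vector of bin labels (`"on_R11"`, `"off_R12"`, ...)
#'   or `NA` for unclassified ratios.
#' @export
#' @examples
#' classify_ratio(c(0.5, 0.30, 0.25))
classify_ratio <- function(r, scheme = default_bin_scheme()) {
  r <- as.numeric(r)
  if (any(!is.na(r) & (r <= 0 | r >= 1))) {
    stop("ratios must lie strictly in (0, 1)", call. = FALSE)
  }
  span <- attr(scheme, "span")
  # findInterval on the 10 boundaries gives the sub-range index directly;
  # rightmost.closed keeps the global maximum inside the last sub-range.
  bounds <- c(scheme$lo, span[2])
  idx <- findInterval(r, bounds, rightmost.closed = TRUE)
  out <- rep(NA_character_, length(r))
  inside <- !is.na(r) & idx >= 1L & idx <= nrow(scheme)
  out[inside] <- scheme$bin[idx[inside]]
  out
}

#' Count ratios per on/off-integer bin for one contribution
#'
#' @param r Numeric vector of ratios from a single contribution.
#' @param scheme A `"ratio_bin_scheme"`.
#' @return A list with `counts` (named integer vector over the six bin
#'   labels), `n_unclassified` (ratios outside the covered span), and
#'   `widths` (the scheme's bin widths). Counts plus `n_unclassified`
#'   always equal `length(r)`.
#' @export
count_bins <- function(r, scheme = default_bin_scheme()) {
  lab <- classify_ratio(r, scheme)
  labels <- bin_labels(scheme)
  counts <- vapply(labels, function(b) sum(lab == b, na.rm = TRUE), 0L)
  list(counts = counts,
       n_unclassified = sum(is.na(lab)),
       widths = bin_widths(scheme))
}
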