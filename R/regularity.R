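#' Width-weighted rhythmic regularity
#'
#' Regularity around a small-integer ratio is the proportion of
#' near-category observations that fall on-integer, with each bin's count
#' weighted by that bin's width so that the unequal widths of the on- and
#' off-integer ranges do not bias the proportion:
#'
#'   regularity = (n_on * w_on) / (n_on * w_on + n_off * w_off)
#'
#' A value of 1 means every observation near the ratio fell in the
#' on-integer range; 0 means every one fell off-integer. When a
#' contribution has no observation near the category at all the value is
#' undefined (`NA`).
#'
#' @param n_on,n_off Nonnegative integer counts in the on- and off-integer
#'   ranges of one category for one contribution. Vectorized.
#' @param w_on,w_off Positive widths of the on range and of the combined
#'   off ranges, in ratio units.
#' @return Numeric in \[0, 1\], or `NA` where `n_on + n_off == 0`.
#' @export
#' @examples
#' w <- bin_widths()
#' compute_regularity(10, 10, w[["on_R11"]], w[["off_R11"]])  # 0.5556
compute_regularity <- function(n_on, n_off, w_on, w_off) {
  if (any(n_on < 0) || any(n_off < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  if (any(w_on <= 0) || any(w_off <= 0)) {
    stop("bin widths must be positive", call. = FALSE)
  }
  num <- n_on * w_on
  den <- n_on * w_on + n_off * w_off
  ifelse(n_on + n_off == 0, NA_real_, num / den)
}

#' Per-contribution regularity table for beta modelling
#'
#' Builds one record per contribution and requested rhythmic category from
#' a long bin-count table (as produced by [bin_count_table()]), computing
#' the width-weighted regularity. Records with no observation near the
#' category keep `NA` regularity and are excluded from modelling by the
#' fitting functions. Because the beta distribution has open support,
#' exact 0/1 responses can be shrunk towards 1/2 with the standard
#' compression `y' = (y * (n - 1) + 0.5) / n`, `n` being the number of
#' non-missing records.
#'
#' @param counts Long bin-count table from [bin_count_table()].
#' @param scheme A `"ratio_bin_scheme"`.
#' @param categories Character subset of the scheme's categories to keep;
#'   defaults to the 1:2 and 1:1 categories, the ones typically found
#'   significant in at least two age classes of both sexes.
#' @param shrink_boundary Apply the boundary compression transform
#'   (`regularity_adj` column); raw values are always kept in
#'   `regularity`.
#' @return A data.frame with one row per contribution x category:
#'   `contribution_id`, `individual_id`, `sex`, `age_class`, `category`,
#'   `n_on`, `n_off`, `regularity` and (if requested) `regularity_adj`.
#' @export
prepare_regularity_table <- function(counts, scheme = default_bin_scheme(),
                                     categories = c("R12", "R11"),
                                     shrink_boundary = TRUE) {
  bad <- setdiff(categories, unique(scheme$category))
  if (length(bad) > 0L) {
    stop("category not in scheme: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  w <- bin_widths(scheme)
  meta_cols <- c("contribution_id", "individual_id", "sex", "age_class")
  stopifnot(all(c(meta_cols, "bin", "count") %in% names(counts)))
  contribs <- unique(counts[, meta_cols, drop = FALSE])
  out <- do.call(rbind, lapply(categories, function(cat) {
    on_b <- paste0("on_", cat); off_b <- paste0("off_", cat)
    pick <- function(bin) {
      m <- counts[counts$bin == bin,
                  c("contribution_id", "count"), drop = FALSE]
      m$count[match(contribs$contribution_id, m$contribution_id)]
    }
    n_on <- pick(on_b); n_off <- pick(off_b)
    n_on[is.na(n_on)] <- 0L; n_off[is.na(n_off)] <- 0L
    data.frame(contribs, category = cat, n_on = n_on, n_off = n_off,
               regularity = compute_regularity(n_on, n_off,
                                               w[[on_b]], w[[off_b]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (shrink_boundary) {
    n <- sum(!is.na(out$regularity))
    out$regularity_adj <- (out$regularity * (n - 1) + 0.5) / n
  }
  out
}
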