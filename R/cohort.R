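#' Per-ratio table for a set of contributions
#'
#' Computes intervals (with the cap rule), ratios and bin labels for every
#' contribution and stacks them into one long table.
#'
#' @param contributions List of [contribution()] objects.
#' @param scheme A `"ratio_bin_scheme"`.
#' @param cap Interval cap in seconds, see [compute_iois()].
#' @param drop_adjacent See [compute_iois()].
#' @return A data.frame with columns `contribution_id`, `individual_id`,
#'   `sex`, `age_class`, `k` (index of the ratio within the contribution),
#'   `r` and `bin` (`NA` outside the covered span).
#' @export
ratio_table <- function(contributions, scheme = default_bin_scheme(),
                        cap = 5.0, drop_adjacent = FALSE) {
  rows <- lapply(contributions, function(ctr) {
    r <- compute_ratios(compute_iois(ctr, cap = cap,
                                     drop_adjacent = drop_adjacent))
    if (length(r) == 0L) return(NULL)
    data.frame(contribution_id = ctr$contribution_id,
               individual_id = ctr$individual_id,
               sex = ctr$sex, age_class = ctr$age_class,
               k = seq_along(r), r = r,
               bin = classify_ratio(r, scheme),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(contribution_id = character(0),
                      individual_id = character(0), sex = character(0),
                      age_class = character(0), k = integer(0),
                      r = numeric(0), bin = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Long bin-count table (the count model's input)
#'
#' One row per contribution and bin: the count of ratios in that bin, the
#' bin's width in ratio units (the model's exposure), and the
#' contribution's metadata. Contributions whose ratios all fall outside
#' the covered span still appear, with zero counts.
#'
#' @inheritParams ratio_table
#' @return A data.frame with columns `contribution_id`, `individual_id`,
#'   `sex`, `age_class`, `category`, `on_off` (`"on"`/`"off"`), `bin`,
#'   `count`, `width`.
#' @export
bin_count_table <- function(contributions, scheme = default_bin_scheme(),
                            cap = 5.0, drop_adjacent = FALSE) {
  labels <- bin_labels(scheme)
  w <- bin_widths(scheme)
  rows <- lapply(contributions, function(ctr) {
    r <- compute_ratios(compute_iois(ctr, cap = cap,
                                     drop_adjacent = drop_adjacent))
    cb <- count_bins(r, scheme)
    data.frame(contribution_id = ctr$contribution_id,
               individual_id = ctr$individual_id,
               sex = ctr$sex, age_class = ctr$age_class,
               category = sub("^(on|off)_", "", labels),
               on_off = sub("_.*$", "", labels),
               bin = labels,
               count = as.integer(cb$counts[labels]),
               width = as.numeric(w[labels]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interval and triple tables for a set of contributions
#'
#' @inheritParams ratio_table
#' @return `ioi_table()`: a data.frame with `contribution_id`,
#'   `individual_id`, `sex`, `age_class`, `k`, `t` (interval in seconds).
#'   `triples_table()`: the same metadata plus `t1`, `t2`, `t3`
#'   proportions.
#' @export
ioi_table <- function(contributions, cap = 5.0, drop_adjacent = FALSE) {
  rows <- lapply(contributions, function(ctr) {
    io <- compute_iois(ctr, cap = cap, drop_adjacent = drop_adjacent)
    if (length(io$values) == 0L) return(NULL)
    data.frame(contribution_id = ctr$contribution_id,
               individual_id = ctr$individual_id,
               sex = ctr$sex, age_class = ctr$age_class,
               k = seq_along(io$values), t = io$values,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(contribution_id = character(0),
                      individual_id = character(0), sex = character(0),
                      age_class = character(0), k = integer(0),
                      t = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' @rdname ioi_table
#' @export
triples_table <- function(contributions, cap = 5.0, drop_adjacent = FALSE) {
  rows <- lapply(contributions, function(ctr) {
    tr <- compute_triples(compute_iois(ctr, cap = cap,
                                       drop_adjacent = drop_adjacent))
    if (nrow(tr) == 0L) return(NULL)
    data.frame(contribution_id = ctr$contribution_id,
               individual_id = ctr$individual_id,
               sex = ctr$sex, age_class = ctr$age_class,
               tr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(contribution_id = character(0),
                      individual_id = character(0), sex = character(0),
                      age_class = character(0), t1 = numeric(0),
                      t2 = numeric(0), t3 = numeric(0))
  }
  rownames(out) <- NULL
  out
}
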