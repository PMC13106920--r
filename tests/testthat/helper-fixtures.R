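# Fixture builders shared across test files. Everything is generated in
# code at test time; nothing binary is stored.

# Write a long-format Praat TextGrid with one interval tier. `intervals`
# is a data.frame with columns onset, offset, label; gaps between labelled
# intervals are filled with empty (silence) intervals so the tier tiles
# [0, xmax] like a real Praat annotation.
write_textgrid_fixture <- function(path, tier_name, intervals,
                                   xmax = NULL, encoding = "UTF-8") {
  if (is.null(xmax)) {
    xmax <- if (nrow(intervals)) max(intervals$offset) + 1 else 10
  }
  # tile [0, xmax] with silence around the labelled intervals
  tiles <- list()
  cursor <- 0
  if (nrow(intervals)) {
    for (i in seq_len(nrow(intervals))) {
      if (intervals$onset[i] > cursor) {
        tiles[[length(tiles) + 1L]] <- c(cursor, intervals$onset[i], "")
      }
      tiles[[length(tiles) + 1L]] <-
        c(intervals$onset[i], intervals$offset[i], intervals$label[i])
      cursor <- intervals$offset[i]
    }
  }
  if (cursor < xmax) tiles[[length(tiles) + 1L]] <- c(cursor, xmax, "")

  lines <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "xmin = 0",
    sprintf("xmax = %s", xmax),
    "tiers? <exists>",
    "size = 1",
    "item []:",
    "    item [1]:",
    '        class = "IntervalTier"',
    sprintf('        name = "%s"', tier_name),
    "        xmin = 0",
    sprintf("        xmax = %s", xmax),
    sprintf("        intervals: size = %d", length(tiles)))
  for (i in seq_along(tiles)) {
    lines <- c(lines,
               sprintf("        intervals [%d]:", i),
               sprintf("            xmin = %s", tiles[[i]][1]),
               sprintf("            xmax = %s", tiles[[i]][2]),
               sprintf('            text = "%s"', tiles[[i]][3]))
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (encoding == "UTF-8") {
    writeLines(lines, path, useBytes = TRUE)
  } else if (encoding == "UTF-16LE") {
    con <- file(path, open = "wb")
    writeBin(c(as.raw(0xFF), as.raw(0xFE)), con)
    writeBin(iconv(txt, from = "UTF-8", to = "UTF-16LE", toRaw = TRUE)[[1]],
             con)
    close(con)
  } else {
    stop("unsupported fixture encoding")
  }
  invisible(path)
}

# Independent brute-force bin classifier: explicit if-chains over the
# exact fraction boundaries, sharing no code with classify_ratio().
brute_force_classify <- function(r) {
  vapply(r, function(x) {
    if (x >= 1 / 3.5 && x < 1 / 3.25) return("off_R12")
    if (x >= 1 / 3.25 && x < 1 / 2.75) return("on_R12")
    if (x >= 1 / 2.75 && x < 1 / 2.5) return("off_R12")
    if (x >= 1 / 2.5 && x < 1 / 2.25) return("off_R11")
    if (x >= 1 / 2.25 && x < 1 - 1 / 2.25) return("on_R11")
    if (x >= 1 - 1 / 2.25 && x < 1 - 1 / 2.5) return("off_R11")
    if (x >= 1 - 1 / 2.5 && x < 1 - 1 / 2.75) return("off_R21")
    if (x >= 1 - 1 / 2.75 && x < 1 - 1 / 3.25) return("on_R21")
    if (x >= 1 - 1 / 3.25 && x <= 1 - 1 / 3.5) return("off_R21")
    NA_character_
  }, NA_character_)
}

# Two-contribution fixture used by the onset-table tests.
fixture_contributions <- function() {
  list(
    contribution("c1", "ind1", "F", c(0, 2.0, 4.1), age_years = 6,
                 song_id = "s1"),
    contribution("c2", "ind1", "F", c(0.5, 2.4, 4.4), age_years = 6,
                 song_id = "s2"))
}

# An adult param map with every between-phrase gap kept under the cap
# (the "zero-gap" study condition for the end-to-end significance check).
zero_gap_adult_map <- function() {
  m <- default_param_map("ADULT", c("F", "M"))
  lapply(m, function(p) { p$p_long_pause <- 0; p })
}

# Shared simulator for the offset Poisson design: one row per
# individual x bin, sexes split across individuals, exposure = bin width.
simulate_count_design <- function(n_groups, beta, sigma_u = 0,
                                  seed = 1, sex_effect = 0.3) {
  set.seed(seed)
  w <- bin_widths()
  d <- expand.grid(individual_id = sprintf("g%03d", seq_len(n_groups)),
                   bin = bin_labels(), stringsAsFactors = FALSE)
  d$sex <- ifelse(match(d$individual_id,
                        unique(d$individual_id)) %% 2 == 0, "M", "F")
  d$width <- unname(w[d$bin])
  u <- rnorm(n_groups, 0, sigma_u)
  names(u) <- sprintf("g%03d", seq_len(n_groups))
  d$bin <- factor(d$bin, levels = bin_labels())
  X <- model.matrix(~ bin * sex, data = d)
  stopifnot(ncol(X) == length(beta))
  eta <- log(d$width) + as.vector(X %*% beta) + u[d$individual_id]
  d$count <- rpois(nrow(d), exp(eta))
  list(data = d, X = X)
}

beta_truth <- c(3, -0.3, 0.6, -0.5, 0.4, -0.4,   # intercept + bin effects
                0.3, 0.1, -0.2, 0.15, -0.1, 0.2) # sex + interactions
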