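#' Construct an individual song contribution
#'
#' A *contribution* is one individual's part in a group song: its metadata
#' (individual, sex, age) and the strictly increasing onset times of the
#' notes it emitted. It is the unit of analysis for all downstream rhythm
#' statistics.
#'
#' @param contribution_id Character scalar identifying the contribution.
#' @param individual_id Character scalar identifying the singer.
#' @param sex `"F"` or `"M"`.
#' @param onsets Numeric vector of note onset times in seconds, strictly
#'   increasing, all `>= 0`.
#' @param age_years Age of the singer in years at recording time, or `NA`.
#' @param age_class One of `"YOUNG_0_2"`, `"JUV_3_4"`, `"ADULT"`. Derived
#'   from `age_years` when omitted and the age is known.
#' @param song_id Identifier of the song the contribution belongs to.
#' @param offsets Optional numeric vector of note offsets, same length as
#'   `onsets`, with `offsets[i] >= onsets[i]`.
#' @param labels Optional character vector of note labels (carried through,
#'   unused by the rhythm statistics).
#'
#' @return An object of class `"contribution"` (a list with the fields
#'   above).
#' @export
#' @examples
#' contribution("c1", "ind1", "F", c(0, 2.1, 4.0), age_years = 6)
contribution <- function(contribution_id, individual_id, sex, onsets,
                         age_years = NA_real_, age_class = NULL,
                         song_id = contribution_id, offsets = NULL,
                         labels = NULL) {
  sex <- as.character(sex)
  if (!sex %in% c("F", "M")) {
    stop("`sex` must be \"F\" or \"M\", got \"", sex, "\"", call. = FALSE)
  }
  onsets <- as.numeric(onsets)
  if (length(onsets) == 0L) {
    stop("a contribution must contain at least one note onset", call. = FALSE)
  }
  if (anyNA(onsets) || any(onsets < 0)) {
    stop("onsets must be nonnegative and non-missing", call. = FALSE)
  }
  if (is.unsorted(onsets, strictly = TRUE)) {
    stop("onsets must be strictly increasing (contribution \"",
         contribution_id, "\")", call. = FALSE)
  }
  if (!is.null(offsets)) {
    offsets <- as.numeric(offsets)
    if (length(offsets) != length(onsets)) {
      stop("`offsets` must match `onsets` in length", call. = FALSE)
    }
    if (any(offsets < onsets, na.rm = TRUE)) {
      stop("each offset must be >= its onset", call. = FALSE)
    }
  }
  if (!is.na(age_years) && age_years < 0) {
    stop("`age_years` must be nonnegative", call. = FALSE)
  }
  if (is.null(age_class)) {
    age_class <- if (is.na(age_years)) NA_character_ else
      assign_age_class(age_years)
  }
  if (!is.na(age_class) && !age_class %in% age_class_levels()) {
    stop("unknown age_class \"", age_class, "\"", call. = FALSE)
  }
  if (!is.na(age_class) && !is.na(age_years) &&
      age_class != assign_age_class(age_years)) {
    stop("age_class \"", age_class, "\" inconsistent with age_years ",
         age_years, call. = FALSE)
  }
  structure(
    list(contribution_id = as.character(contribution_id),
         individual_id = as.character(individual_id),
         sex = sex,
         age_years = as.numeric(age_years),
         age_class = age_class,
         song_id = as.character(song_id),
         onsets = onsets,
         offsets = offsets,
         labels = labels),
    class = "contribution")
}

#' @export
print.contribution <- function(x, ...) {
  cat(sprintf("<contribution %s> individual %s (%s, %s), %d notes over %.2f s\n",
              x$contribution_id, x$individual_id, x$sex,
              ifelse(is.na(x$age_class), "age unknown", x$age_class),
              length(x$onsets), diff(range(x$onsets))))
  invisible(x)
}

#' Ordered age-class levels
#'
#' Three developmental stages: up to 2.5 years (`YOUNG_0_2`), from above
#' 2.5 to 4.5 years (`JUV_3_4`), and over 4.5 years (`ADULT`).
#'
#' @return Character vector of the three levels in developmental order.
#' @export
age_class_levels <- function() c("YOUNG_0_2", "JUV_3_4", "ADULT")

#' Assign a developmental age class from an age in years
#'
#' The partition is half-open at the class boundaries: ages up to and
#' including 2.5 years are `YOUNG_0_2`, ages above 2.5 up to and including
#' 4.5 are `JUV_3_4`, and anything older is `ADULT`. (Published class
#' labels of "0-2" and "3-4 years" leave the interval between 2.5 and 2.6
#' unlabelled; here 2.5 is the exact boundary so every age gets a class.)
#'
#' @param age_years Numeric vector of ages in years, all `>= 0`.
#' @return Character vector of age classes, same length as `age_years`.
#' @export
#' @examples
#' assign_age_class(c(0.5, 2.5, 2.6, 4.5, 4.6))
assign_age_class <- function(age_years) {
  age_years <- as.numeric(age_years)
  if (anyNA(age_years)) stop("`age_years` must not be missing", call. = FALSE)
  if (any(age_years < 0)) stop("`age_years` must be nonnegative", call. = FALSE)
  ifelse(age_years <= 2.5, "YOUNG_0_2",
         ifelse(age_years <= 4.5, "JUV_3_4", "ADULT"))
}

# ---------------------------------------------------------------------------
# Praat TextGrid (long text format) parsing

# Read a text file as lines, honouring a UTF-8 or UTF-16 byte-order mark.
# Praat writes both encodings depending on content and platform settings.
read_textgrid_lines <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  enc <- "UTF-8"
  if (length(raw) >= 2) {
    if (raw[1] == as.raw(0xFE) && raw[2] == as.raw(0xFF)) enc <- "UTF-16BE"
    else if (raw[1] == as.raw(0xFF) && raw[2] == as.raw(0xFE)) enc <- "UTF-16LE"
  }
  txt <- iconv(list(raw), from = enc, to = "UTF-8")
  if (is.na(txt)) {
    stop("cannot decode \"", path, "\" as ", enc, call. = FALSE)
  }
  strsplit(txt, "\r\n|\r|\n")[[1]]
}

#' Parse labelled intervals from one tier of a Praat TextGrid
#'
#' Reads the *long* TextGrid text format (UTF-8 or UTF-16) and returns the
#' non-empty-labelled intervals of the named interval tier: one row per
#' annotated note, in increasing onset order. Empty and whitespace-only
#' labels are silence and are dropped. The compact "short" TextGrid format
#' is rejected with a clear message; re-save the grid from Praat as a full
#' text file.
#'
#' @param path Path to a TextGrid file.
#' @param tier_name Name of the interval tier holding the note annotations.
#' @return A data.frame with columns `onset` and `offset` (seconds, as
#'   stored in the file) and `label`.
#' @export
parse_textgrid <- function(path, tier_name) {
  if (!file.exists(path)) {
    stop("TextGrid file not found: \"", path, "\"", call. = FALSE)
  }
  lines <- read_textgrid_lines(path)
  if (!any(grepl("ooTextFile", lines[seq_len(min(3, length(lines)))]))) {
    stop("\"", path, "\" does not look like a Praat TextGrid ",
         "(missing ooTextFile header at line 1)", call. = FALSE)
  }
  # Long format carries `key = value` lines; the short format is bare values.
  if (!any(grepl("=", lines))) {
    stop("\"", path, "\" is in the short TextGrid format, which is not ",
         "supported; open it in Praat and save as a (long) text file",
         call. = FALSE)
  }

  get_field <- function(line) {
    # 'name = "notes"' -> "notes";  'xmin = 0.5' -> "0.5"
    val <- sub("^[^=]*=\\s*", "", line)
    val <- sub("\\s*$", "", val)
    gsub("^\"|\"$", "", val)
  }

  tier_starts <- grep("^\\s*item\\s*\\[\\d+\\]\\s*:?\\s*$", lines)
  if (length(tier_starts) == 0L) {
    stop("no tiers found in \"", path, "\" (malformed TextGrid near line 1)",
         call. = FALSE)
  }
  tier_ends <- c(tier_starts[-1] - 1L, length(lines))

  for (t in seq_along(tier_starts)) {
    block <- lines[tier_starts[t]:tier_ends[t]]
    class_line <- grep("^\\s*class\\s*=", block, value = TRUE)
    name_line <- grep("^\\s*name\\s*=", block, value = TRUE)
    if (length(name_line) == 0L) next
    if (get_field(name_line[1]) != tier_name) next
    if (length(class_line) == 0L ||
        !grepl("IntervalTier", class_line[1], fixed = TRUE)) {
      stop("tier \"", tier_name, "\" in \"", path,
           "\" is not an interval tier", call. = FALSE)
    }
    int_starts <- grep("^\\s*intervals\\s*\\[\\d+\\]\\s*:?\\s*$", block)
    onset <- offset <- numeric(0)
    label <- character(0)
    for (i in seq_along(int_starts)) {
      from <- int_starts[i]
      to <- if (i < length(int_starts)) int_starts[i + 1] - 1L else length(block)
      sub_block <- block[from:to]
      xmin <- grep("^\\s*xmin\\s*=", sub_block, value = TRUE)
      xmax <- grep("^\\s*xmax\\s*=", sub_block, value = TRUE)
      text <- grep("^\\s*text\\s*=", sub_block, value = TRUE)
      if (length(xmin) == 0L || length(xmax) == 0L || length(text) == 0L) {
        stop("malformed interval in tier \"", tier_name, "\" of \"", path,
             "\" near line ", tier_starts[t] + from - 1L, call. = FALSE)
      }
      lo <- suppressWarnings(as.numeric(get_field(xmin[1])))
      hi <- suppressWarnings(as.numeric(get_field(xmax[1])))
      if (is.na(lo) || is.na(hi)) {
        stop("non-numeric interval boundary in \"", path, "\" near line ",
             tier_starts[t] + from - 1L, call. = FALSE)
      }
      lab <- get_field(text[1])
      if (nzchar(trimws(lab))) {
        onset <- c(onset, lo); offset <- c(offset, hi); label <- c(label, lab)
      }
    }
    ord <- order(onset)
    return(data.frame(onset = onset[ord], offset = offset[ord],
                      label = label[ord], stringsAsFactors = FALSE))
  }
  stop("tier \"", tier_name, "\" not found in \"", path, "\"", call. = FALSE)
}

# ---------------------------------------------------------------------------
# Canonical onset table (CSV)

onset_table_columns <- function() {
  c("contribution_id", "individual_id", "sex", "age_years", "age_class",
    "song_id", "onset_s")
}

#' Flatten contributions to the canonical onset table
#'
#' One row per note, sorted by `contribution_id` then `onset_s`, with the
#' header columns `contribution_id, individual_id, sex, age_years,
#' age_class, song_id, onset_s` (plus `offset_s` when any contribution
#' carries offsets).
#'
#' @param contributions A list of [contribution()] objects.
#' @return A data.frame in canonical column order.
#' @export
as_onset_table <- function(contributions) {
  if (length(contributions) == 0L) {
    out <- data.frame(contribution_id = character(0),
                      individual_id = character(0), sex = character(0),
                      age_years = numeric(0), age_class = character(0),
                      song_id = character(0), onset_s = numeric(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  any_offsets <- any(vapply(contributions, function(x) !is.null(x$offsets),
                            logical(1)))
  rows <- lapply(contributions, function(x) {
    n <- length(x$onsets)
    d <- data.frame(contribution_id = rep(x$contribution_id, n),
                    individual_id = rep(x$individual_id, n),
                    sex = rep(x$sex, n),
                    age_years = rep(x$age_years, n),
                    age_class = rep(ifelse(is.na(x$age_class), NA_character_,
                                           x$age_class), n),
                    song_id = rep(x$song_id, n),
                    onset_s = x$onsets,
                    stringsAsFactors = FALSE)
    if (any_offsets) {
      d$offset_s <- if (is.null(x$offsets)) rep(NA_real_, n) else x$offsets
    }
    d
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contribution_id, out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read contributions from an onset table CSV
#'
#' The table must carry the canonical header (see [as_onset_table()]); rows
#' are grouped by `contribution_id` into [contribution()] records with
#' sorted, validated onsets. Duplicate onset times within a contribution
#' are rejected (two notes cannot start at the same instant in one
#' individual's contribution).
#'
#' @param path Path to a CSV file.
#' @return A list of [contribution()] objects, ordered by
#'   `contribution_id`.
#' @export
read_onset_table <- function(path) {
  if (!file.exists(path)) {
    stop("onset table not found: \"", path, "\"", call. = FALSE)
  }
  # sex = "F" must not be parsed as logical FALSE
  cc <- c(contribution_id = "character", individual_id = "character",
          sex = "character", age_class = "character",
          song_id = "character")
  header <- names(utils::read.csv(path, nrows = 1))
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = cc[intersect(names(cc), header)])
  missing_cols <- setdiff(onset_table_columns(), names(d))
  if (length(missing_cols) > 0L) {
    stop("onset table \"", path, "\" lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_sex <- which(!d$sex %in% c("F", "M"))
  if (length(bad_sex) > 0L) {
    stop("unknown sex code \"", d$sex[bad_sex[1]], "\" at data row ",
         bad_sex[1], " of \"", path, "\"", call. = FALSE)
  }
  dup <- duplicated(d[, c("contribution_id", "onset_s")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop("duplicate onset time ", d$onset_s[i], " in contribution \"",
         d$contribution_id[i], "\" (data row ", i, ")", call. = FALSE)
  }
  split_ids <- unique(d$contribution_id)
  out <- lapply(split_ids, function(id) {
    g <- d[d$contribution_id == id, , drop = FALSE]
    g <- g[order(g$onset_s), , drop = FALSE]
    meta_one <- function(col) {
      u <- unique(g[[col]])
      if (length(u) > 1L) {
        stop("contribution \"", id, "\" has conflicting values of ", col,
             call. = FALSE)
      }
      u
    }
    ac <- meta_one("age_class")
    contribution(
      contribution_id = id,
      individual_id = as.character(meta_one("individual_id")),
      sex = meta_one("sex"),
      onsets = g$onset_s,
      age_years = meta_one("age_years"),
      age_class = if (is.na(ac)) NULL else ac,
      song_id = as.character(meta_one("song_id")),
      offsets = if ("offset_s" %in% names(g) && !anyNA(g$offset_s))
        g$offset_s else NULL)
  })
  out[order(vapply(out, `[[`, "", "contribution_id"))]
}

#' Write contributions to the canonical onset table CSV
#'
#' Writing then re-reading is the identity on valid contributions (up to
#' the printed precision of 1e-9 s or better; times are written with full
#' double precision).
#'
#' @param contributions A list of [contribution()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_onset_table <- function(contributions, path) {
  d <- as_onset_table(contributions)
  utils::write.csv(format_numeric_df(d), path, row.names = FALSE, quote = TRUE,
                   na = "")
  invisible(path)
}

# Format numeric columns with 15 significant digits so CSV round-trips keep
# double precision without printing noise digits.
format_numeric_df <- function(d) {
  for (col in names(d)) {
    if (is.numeric(d[[col]])) {
      v <- d[[col]]
      s <- vapply(v, function(x)
        if (is.na(x)) NA_character_ else format(x, digits = 15), "")
      d[[col]] <- s
    }
  }
  d
}
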