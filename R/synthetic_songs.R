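#' Parameters of a synthetic song class
#'
#' The generator emulates the architecture that produces categorical
#' rhythm in phrase-structured song: notes grouped into phrases, with
#' short within-phrase intervals (mean near 2 s) and longer between-phrase
#' intervals (about twice as long), so interval densities are bimodal near
#' 2 s and 4 s and the within/between alternation yields ratios near 1:2,
#' 1:1 and 2:1. Single notes emitted outside phrases (frequent in young
#' females) are followed by long pauses, and a fraction of between-phrase
#' gaps can exceed the analysis cap entirely (juvenile songs have long
#' silences between phrase groups, so few phrase transitions survive the
#' cap). All presets are synthetic inventions tuned to the qualitative
#' developmental pattern, not estimates from recordings.
#'
#' @param mean_within_ioi Mean within-phrase inter-onset interval, seconds.
#' @param cv_within Coefficient of variation of within-phrase intervals.
#' @param between_multiplier Between-phrase mean gap as a multiple of
#'   `mean_within_ioi`.
#' @param cv_between Coefficient of variation of between-phrase gaps.
#' @param units_per_phrase Length-2 numeric `(min, mean)` of the number of
#'   notes per phrase (a shifted Poisson: `min + Poisson(mean - min)`).
#' @param n_phrases_mean Mean number of phrases per contribution (shifted
#'   Poisson, minimum 1).
#' @param p_single_note Probability of inserting a lone note (followed by
#'   a long pause) before a phrase.
#' @param p_long_pause Probability that a between-phrase gap exceeds the
#'   interval cap and is therefore invisible to the ratio analysis.
#' @param label Free-text preset label.
#' @return A list of class `"synthetic_class_params"`.
#' @export
synthetic_class_params <- function(mean_within_ioi = 2.0, cv_within = 0.1,
                                   between_multiplier = 2.0,
                                   cv_between = 0.15,
                                   units_per_phrase = c(2, 5),
                                   n_phrases_mean = 6,
                                   p_single_note = 0.05,
                                   p_long_pause = 0.1,
                                   label = "custom") {
  stopifnot(mean_within_ioi > 0, between_multiplier > 0,
            cv_within >= 0, cv_between >= 0,
            length(units_per_phrase) == 2L, units_per_phrase[1] >= 1,
            units_per_phrase[2] >= units_per_phrase[1],
            n_phrases_mean >= 1,
            p_single_note >= 0, p_single_note <= 1,
            p_long_pause >= 0, p_long_pause <= 1)
  structure(list(mean_within_ioi = mean_within_ioi, cv_within = cv_within,
                 between_multiplier = between_multiplier,
                 cv_between = cv_between,
                 units_per_phrase = units_per_phrase,
                 n_phrases_mean = n_phrases_mean,
                 p_single_note = p_single_note,
                 p_long_pause = p_long_pause, label = label),
            class = "synthetic_class_params")
}

#' Preset generator parameters per age class and sex
#'
#' Adults sing tightly organized phrases: low interval variability, nearly
#' every between-phrase gap short enough to survive the cap, so all three
#' rhythmic categories appear. Juvenile males keep large between-phrase
#' silences (most gaps exceed the cap) and noisy gap durations, so only
#' within-phrase isochrony is left; juvenile females are intermediate,
#' with phrase alternation starting to consolidate. The youngest animals
#' sing short, noisy songs, females with frequent lone notes; young males
#' have no surviving phrase alternation at all. Every preset keeps the
#' within-phrase mean at 2 s and the between-phrase multiplier at 2.
#'
#' @param age_class One of [age_class_levels()].
#' @param sex `"F"` or `"M"`.
#' @return A [synthetic_class_params()] object.
#' @export
#' @examples
#' default_class_params("ADULT", "F")
default_class_params <- function(age_class, sex) {
  stopifnot(age_class %in% age_class_levels(), sex %in% c("F", "M"))
  key <- paste(age_class, sex, sep = ".")
  presets <- list(
    ADULT.F = synthetic_class_params(
      mean_within_ioi = 2.0, cv_within = 0.07, between_multiplier = 2.0,
      cv_between = 0.10, units_per_phrase = c(2, 5), n_phrases_mean = 8,
      p_single_note = 0.05, p_long_pause = 0.10, label = "adult female"),
    ADULT.M = synthetic_class_params(
      mean_within_ioi = 2.0, cv_within = 0.06, between_multiplier = 2.0,
      cv_between = 0.09, units_per_phrase = c(2, 6), n_phrases_mean = 8,
      p_single_note = 0.02, p_long_pause = 0.10, label = "adult male"),
    JUV_3_4.F = synthetic_class_params(
      mean_within_ioi = 2.0, cv_within = 0.12, between_multiplier = 2.0,
      cv_between = 0.20, units_per_phrase = c(1, 4), n_phrases_mean = 6,
      p_single_note = 0.20, p_long_pause = 0.45, label = "juvenile female"),
    JUV_3_4.M = synthetic_class_params(
      mean_within_ioi = 2.0, cv_within = 0.12, between_multiplier = 2.0,
      cv_between = 0.45, units_per_phrase = c(1, 4), n_phrases_mean = 6,
      p_single_note = 0.15, p_long_pause = 0.85, label = "juvenile male"),
    YOUNG_0_2.F = synthetic_class_params(
      mean_within_ioi = 2.0, cv_within = 0.15, between_multiplier = 2.0,
      cv_between = 0.50, units_per_phrase = c(1, 3), n_phrases_mean = 5,
      p_single_note = 0.45, p_long_pause = 0.90, label = "young female"),
    YOUNG_0_2.M = synthetic_class_params(
      mean_within_ioi = 2.0, cv_within = 0.15, between_multiplier = 2.0,
      cv_between = 0.50, units_per_phrase = c(1, 3), n_phrases_mean = 5,
      p_single_note = 0.25, p_long_pause = 1.00, label = "young male"))
  presets[[key]]
}

# Gamma draw parameterized by mean and coefficient of variation; cv = 0 is
# the deterministic limit.
rgamma_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  stats::rgamma(n, shape = 1 / cv^2, scale = mean * cv^2)
}

# A pause guaranteed to exceed the cap (invisible to the ratio analysis).
r_long_pause <- function(n, cap) cap + 1 + stats::rexp(n, rate = 0.5)

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate one phrase-structured song contribution
#'
#' Draws the number of phrases and of notes per phrase from shifted
#' Poisson distributions, within-phrase intervals and between-phrase gaps
#' from gamma distributions with the preset means and coefficients of
#' variation, inserts lone notes (followed by over-cap pauses) with
#' probability `p_single_note`, and replaces a between-phrase gap with an
#' over-cap pause with probability `p_long_pause`. Onsets accumulate from
#' zero and are strictly increasing by construction.
#'
#' @param params A [synthetic_class_params()] object.
#' @param rng_seed Optional integer; when given the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @param contribution_id,individual_id,song_id Identifiers for the
#'   resulting record.
#' @param sex,age_years Metadata for the resulting record; defaults are
#'   placeholders for standalone use.
#' @param tempo_multiplier Multiplies all interval means (the
#'   individual-level random effect of [simulate_cohort()]).
#' @param cap The analysis interval cap the over-cap pauses must exceed,
#'   seconds.
#' @return A [contribution()] object.
#' @export
simulate_contribution <- function(params, rng_seed = NULL,
                                  contribution_id = "sim_1",
                                  individual_id = "sim_ind_1",
                                  sex = "F", age_years = NA_real_,
                                  song_id = contribution_id,
                                  tempo_multiplier = 1.0, cap = 5.0) {
  stopifnot(inherits(params, "synthetic_class_params"), tempo_multiplier > 0)
  with_local_seed(rng_seed, {
    m_within <- params$mean_within_ioi * tempo_multiplier
    m_between <- m_within * params$between_multiplier
    n_phrases <- 1L + stats::rpois(1, params$n_phrases_mean - 1)
    iois <- numeric(0)
    for (p in seq_len(n_phrases)) {
      if (stats::runif(1) < params$p_single_note) {
        # a lone note, then a pause too long to enter the ratio analysis
        iois <- c(iois, r_long_pause(1, cap))
      }
      n_units <- params$units_per_phrase[1] +
        stats::rpois(1, params$units_per_phrase[2] - params$units_per_phrase[1])
      if (n_units > 1L) {
        iois <- c(iois, rgamma_cv(n_units - 1L, m_within, params$cv_within))
      }
      if (p < n_phrases) {
        gap <- if (stats::runif(1) < params$p_long_pause) {
          r_long_pause(1, cap)
        } else {
          rgamma_cv(1, m_between, params$cv_between)
        }
        iois <- c(iois, gap)
      }
    }
    if (length(iois) == 0L) iois <- numeric(0)  # single lone note possible
    onsets <- cumsum(c(0, iois))
    contribution(contribution_id = contribution_id,
                 individual_id = individual_id, sex = sex,
                 onsets = onsets, age_years = age_years,
                 song_id = song_id)
  })
}

#' Representative ages used for simulated individuals, by class
#' @param age_class Character vector of age classes.
#' @return Numeric ages in years consistent with each class.
#' @export
representative_age <- function(age_class) {
  unname(c(YOUNG_0_2 = 1.5, JUV_3_4 = 3.5, ADULT = 8.0)[age_class])
}

#' Simulate a cohort of contributions across age/sex cells
#'
#' Each cell of `param_map` gets `n_individuals` singers; each singer
#' carries a lognormal tempo multiplier (random intercept on the log
#' interval scale, SD `tempo_sd`) shared across its `contributions_each`
#' contributions — the grouping structure the mixed models assume.
#'
#' @param param_map Named list of [synthetic_class_params()], with names
#'   `"AGECLASS.SEX"` (e.g. `"ADULT.F"`); see [default_param_map()].
#' @param n_individuals Individuals per cell.
#' @param contributions_each Contributions per individual.
#' @param seed Integer seed governing the whole cohort.
#' @param tempo_sd SD of the lognormal individual tempo multiplier; 0
#'   makes all individuals share the preset means exactly.
#' @param cap Interval cap passed to [simulate_contribution()].
#' @return A list of [contribution()] objects.
#' @export
simulate_cohort <- function(param_map, n_individuals = 10,
                            contributions_each = 3, seed = 1,
                            tempo_sd = 0.1, cap = 5.0) {
  if (length(param_map) == 0L) stop("`param_map` is empty", call. = FALSE)
  stopifnot(n_individuals >= 1, contributions_each >= 1)
  with_local_seed(seed, {
    out <- list()
    for (cell in names(param_map)) {
      parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
      if (length(parts) != 2L || !parts[1] %in% age_class_levels() ||
          !parts[2] %in% c("F", "M")) {
        stop("param_map name \"", cell,
             "\" is not of the form AGECLASS.SEX", call. = FALSE)
      }
      age_class <- parts[1]; sex <- parts[2]
      for (i in seq_len(n_individuals)) {
        ind_id <- sprintf("ind_%s_%s_%02d", age_class, sex, i)
        tempo <- exp(stats::rnorm(1, 0, tempo_sd))
        for (j in seq_len(contributions_each)) {
          cid <- sprintf("%s_c%02d", ind_id, j)
          out[[cid]] <- simulate_contribution(
            param_map[[cell]], rng_seed = NULL,
            contribution_id = cid, individual_id = ind_id, sex = sex,
            age_years = representative_age(age_class), song_id = cid,
            tempo_multiplier = tempo, cap = cap)
        }
      }
    }
    out
  })
}

#' Default parameter map over requested age classes and sexes
#'
#' @param age_classes Subset of [age_class_levels()].
#' @param sexes Subset of `c("F", "M")`.
#' @return Named list of presets keyed `"AGECLASS.SEX"`, suitable for
#'   [simulate_cohort()].
#' @export
default_param_map <- function(age_classes = age_class_levels(),
                              sexes = c("F", "M")) {
  cells <- expand.grid(age_class = age_classes, sex = sexes,
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i)
    default_class_params(cells$age_class[i], cells$sex[i]))
  names(out) <- paste(cells$age_class, cells$sex, sep = ".")
  out
}
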