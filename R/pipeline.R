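#' Build a validated pipeline run configuration
#'
#' @param out_dir Output directory for tables, figures and the manifest.
#' @param input_csv Optional onset-table CSV; when `NULL` a synthetic
#'   cohort is generated instead.
#' @param synthetic List of generator settings used when `input_csv` is
#'   `NULL`: `age_classes`, `sexes`, `n_individuals`, `contributions_each`,
#'   `tempo_sd`.
#' @param cap Interval cap in seconds.
#' @param alpha Significance level for the LRT and contrasts.
#' @param categories Rhythmic categories carried into the regularity
#'   models.
#' @param nagq Quadrature nodes for the Poisson fits (1 = Laplace).
#' @param seed Integer seed governing all randomness of the run.
#' @param figures Render figures after the tables.
#' @param drop_adjacent See [compute_iois()].
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(out_dir, input_csv = NULL,
                       synthetic = list(), cap = 5.0, alpha = 0.05,
                       categories = c("R12", "R11"), nagq = 1L,
                       seed = 1L, figures = FALSE, drop_adjacent = FALSE) {
  stopifnot(is.numeric(cap), cap > 0, is.numeric(alpha),
            alpha > 0, alpha < 1)
  syn_defaults <- list(age_classes = age_class_levels(),
                       sexes = c("F", "M"), n_individuals = 10L,
                       contributions_each = 3L, tempo_sd = 0.1)
  unknown <- setdiff(names(synthetic), names(syn_defaults))
  if (length(unknown) > 0L) {
    stop("unknown synthetic setting(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  syn <- utils::modifyList(syn_defaults, synthetic)
  structure(list(out_dir = out_dir, input_csv = input_csv, synthetic = syn,
                 cap = cap, alpha = alpha, categories = categories,
                 nagq = as.integer(nagq), seed = as.integer(seed),
                 figures = isTRUE(figures),
                 drop_adjacent = isTRUE(drop_adjacent)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds the fields of [run_config()] at top level, with the
#' generator settings under a `synthetic:` block.
#'
#' @param path YAML file path.
#' @param out_dir Overrides the file's `out_dir` when given.
#' @return A `"run_config"` object.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  if (is.null(raw$out_dir)) stop("config lacks `out_dir`", call. = FALSE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, raw)
}

write_table <- function(d, dir, name) {
  utils::write.csv(format_numeric_df(d), file.path(dir, name),
                   row.names = FALSE, na = "")
}

log_stage <- function(stage, rows_in, rows_out, t0, verbose) {
  if (verbose) {
    message(sprintf("[%s] rows in: %s, rows out: %s, elapsed: %.2fs",
                    stage, rows_in, rows_out,
                    as.numeric(proc.time()[3]) - t0))
  }
}

# Stage wrapper: failures abort with the stage name while partial
# outputs already written stay in place.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage \"", stage, "\" failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

tidy_fit <- function(fit, label) {
  if (is.null(fit)) return(NULL)
  data.frame(model = label, fit$coefficients,
             sigma2_u = fit$sigma2_u, phi = fit$phi,
             logLik = fit$logLik, converged = fit$converged,
             n_obs = fit$n_obs, n_groups = fit$n_groups,
             stringsAsFactors = FALSE)
}

#' Run the full rhythm-ontogeny pipeline
#'
#' Reads (or simulates) contributions, then writes to the output
#' directory: the canonical onset table; interval, ratio, bin-count and
#' triple tables; per-age-class Poisson peak models with likelihood ratio
#' tests, Tukey contrasts, zero-inflation checks and the significance
#' map; the regularity table and per-category beta models; density
#' curves and peaks per sex and age class for both intervals and ratios;
#' optionally the figures; and a JSON manifest with the configuration,
#' seed and convergence flags. Reruns with an identical configuration
#' produce byte-identical tables.
#'
#' @param config A [run_config()] (or a YAML path understood by
#'   [read_run_config()]).
#' @param verbose Emit per-stage log lines.
#' @return The output directory, invisibly; its contents are the result.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(proc.time()[3])
  scheme <- default_bin_scheme()

  # --- input ---------------------------------------------------------------
  if (!is.null(config$input_csv)) {
    contribs <- read_onset_table(config$input_csv)
  } else {
    syn <- config$synthetic
    contribs <- simulate_cohort(
      default_param_map(syn$age_classes, syn$sexes),
      n_individuals = syn$n_individuals,
      contributions_each = syn$contributions_each,
      seed = config$seed, tempo_sd = syn$tempo_sd, cap = config$cap)
  }
  write_onset_table(contribs, file.path(config$out_dir, "onsets.csv"))
  log_stage("input", length(contribs), length(contribs), t0, verbose)

  # --- rhythm tables -------------------------------------------------------
  iois <- ioi_table(contribs, cap = config$cap,
                    drop_adjacent = config$drop_adjacent)
  ratios <- ratio_table(contribs, scheme, cap = config$cap,
                        drop_adjacent = config$drop_adjacent)
  counts <- bin_count_table(contribs, scheme, cap = config$cap,
                            drop_adjacent = config$drop_adjacent)
  triples <- triples_table(contribs, cap = config$cap,
                           drop_adjacent = config$drop_adjacent)
  write_table(iois, config$out_dir, "iois.csv")
  write_table(ratios, config$out_dir, "ratios.csv")
  write_table(counts, config$out_dir, "bin_counts.csv")
  write_table(triples, config$out_dir, "triples.csv")
  write_table(as.data.frame(scheme), config$out_dir, "bin_scheme.csv")
  log_stage("rhythm", length(contribs), nrow(ratios), t0, verbose)

  # --- densities and peaks -------------------------------------------------
  tk_peaks <- group_density_peaks(iois$t, iois$sex, iois$age_class)
  rk_peaks <- group_density_peaks(ratios$r, ratios$sex, ratios$age_class)
  write_table(cbind(variable = rep("t_k", nrow(tk_peaks)), tk_peaks),
              config$out_dir, "tk_peaks.csv")
  write_table(cbind(variable = rep("r_k", nrow(rk_peaks)), rk_peaks),
              config$out_dir, "rk_peaks.csv")
  log_stage("density_peaks", nrow(iois), nrow(tk_peaks) + nrow(rk_peaks),
            t0, verbose)

  # --- peak-significance models --------------------------------------------
  peak_fits <- with_stage("peak_models",
                          fit_peak_models(counts, nagq = config$nagq))
  sig_map <- detect_significant_categories(peak_fits, alpha = config$alpha)
  write_table(sig_map, config$out_dir, "significance_map.csv")
  fit_rows <- do.call(rbind, lapply(names(peak_fits), function(ac) {
    tidy_fit(peak_fits[[ac]]$full, paste0("poisson_full_", ac))
  }))
  if (!is.null(fit_rows)) {
    write_table(fit_rows, config$out_dir, "poisson_models.csv")
  }
  lrt_rows <- do.call(rbind, lapply(names(peak_fits), function(ac) {
    l <- peak_fits[[ac]]$lrt
    zi <- peak_fits[[ac]]$zero_inflation
    data.frame(age_class = ac, lrt_statistic = l$statistic, lrt_df = l$df,
               lrt_p = l$p,
               zi_ratio = if (is.null(zi)) NA_real_ else zi$ratio,
               zi_inflated = if (is.null(zi)) NA else zi$inflated,
               stringsAsFactors = FALSE)
  }))
  write_table(lrt_rows, config$out_dir, "poisson_lrt.csv")
  contrast_rows <- do.call(rbind, lapply(names(peak_fits), function(ac) {
    ct <- peak_fits[[ac]]$contrasts
    if (is.null(ct)) return(NULL)
    data.frame(age_class = ac, ct, stringsAsFactors = FALSE)
  }))
  if (!is.null(contrast_rows)) {
    write_table(contrast_rows, config$out_dir, "poisson_contrasts.csv")
  }
  log_stage("peak_models", nrow(counts), nrow(sig_map), t0, verbose)

  # --- regularity ----------------------------------------------------------
  reg <- prepare_regularity_table(counts, scheme,
                                  categories = config$categories)
  write_table(reg, config$out_dir, "regularity.csv")
  beta_rows <- NULL; beta_converged <- logical(0)
  for (cat in config$categories) {
    sub <- reg[reg$category == cat & !is.na(reg$regularity), , drop = FALSE]
    if (nrow(sub) < 10L) next
    terms <- c(if (length(unique(sub$sex)) > 1L) "sex",
               if (length(unique(sub$age_class)) > 1L) "age_class")
    if (length(terms) == 0L) next
    fixed <- paste(terms, collapse = " * ")
    full <- fit_beta_glmm(sub, model_spec("regularity_adj", fixed,
                                          group = "contribution_id",
                                          family = "beta"))
    null <- fit_beta_glmm(sub, model_spec("regularity_adj", "1",
                                          group = "contribution_id",
                                          family = "beta"))
    l <- likelihood_ratio_test(full, null)
    beta_converged <- c(beta_converged, full$converged)
    beta_rows <- rbind(beta_rows,
                       data.frame(category = cat,
                                  tidy_fit(full, paste0("beta_full_", cat)),
                                  lrt_statistic = l$statistic,
                                  lrt_df = l$df, lrt_p = l$p,
                                  stringsAsFactors = FALSE))
  }
  if (!is.null(beta_rows)) {
    write_table(beta_rows, config$out_dir, "beta_models.csv")
  }
  log_stage("regularity", nrow(reg),
            if (is.null(beta_rows)) 0L else nrow(beta_rows), t0, verbose)

  # --- figures -------------------------------------------------------------
  panels <- NULL
  if (config$figures) {
    panels <- render_figures(config$out_dir)
    log_stage("figures", nrow(panels), nrow(panels), t0, verbose)
  }

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package = "songrhythm",
    version = as.character(utils::packageVersion("songrhythm")),
    config = unclass(config),
    n_contributions = length(contribs),
    n_ratios = nrow(ratios),
    poisson_converged = vapply(peak_fits, function(pf)
      if (is.null(pf$full)) NA else pf$full$converged, NA),
    beta_converged = beta_converged)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(config$out_dir)
}

# ---------------------------------------------------------------------------
# Figures

ternary_xy <- function(t1, t2, t3) {
  # equilateral-triangle coordinates: vertices t1 = (0,0), t2 = (1,0),
  # t3 = (0.5, sqrt(3)/2)
  data.frame(x = t2 + t3 / 2, y = t3 * sqrt(3) / 2)
}

#' Render the standard figure set from a completed run directory
#'
#' Three figures, each faceted by sex and age class: the interval (t_k)
#' density, the ratio (r_k) density with the on-integer ranges shaded
#' light and the off-integer ranges dark, and the ternary scatter of
#' interval triples. Written in vector (PDF) and raster (PNG) form.
#' Groups with too few observations for a density are skipped with a
#' warning.
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @return A data.frame listing the rendered panels (`figure`, `sex`,
#'   `age_class`), invisibly usable for bookkeeping.
#' @export
render_figures <- function(run_dir) {
  need <- c("iois.csv", "ratios.csv", "triples.csv", "bin_scheme.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing) > 0L) {
    stop("run directory lacks table(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  iois <- utils::read.csv(file.path(run_dir, "iois.csv"))
  ratios <- utils::read.csv(file.path(run_dir, "ratios.csv"))
  triples <- utils::read.csv(file.path(run_dir, "triples.csv"))
  scheme <- utils::read.csv(file.path(run_dir, "bin_scheme.csv"))

  order_classes <- function(d) {
    d$age_class <- factor(d$age_class, levels = age_class_levels())
    d
  }
  iois <- order_classes(iois); ratios <- order_classes(ratios)
  triples <- order_classes(triples)

  dens_df <- function(d, col) {
    groups <- unique(d[, c("sex", "age_class")])
    out <- lapply(seq_len(nrow(groups)), function(i) {
      v <- d[[col]][d$sex == groups$sex[i] & d$age_class == groups$age_class[i]]
      if (length(v) < 2L || diff(range(v)) == 0) {
        warning("skipping density panel for ", groups$sex[i], "/",
                groups$age_class[i], ": too few observations",
                call. = FALSE)
        return(NULL)
      }
      cv <- estimate_density(v)
      data.frame(sex = groups$sex[i], age_class = groups$age_class[i],
                 x = cv$grid, y = cv$density)
    })
    do.call(rbind, out)
  }

  save_both <- function(plot, name) {
    ggplot2::ggsave(file.path(run_dir, paste0(name, ".pdf")), plot,
                    width = 9, height = 6)
    ggplot2::ggsave(file.path(run_dir, paste0(name, ".png")), plot,
                    width = 9, height = 6, dpi = 150)
  }

  panels <- NULL
  td <- dens_df(iois, "t")
  if (!is.null(td)) {
    p_t <- ggplot2::ggplot(td, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_vline(xintercept = c(2, 4), linetype = "dashed",
                          colour = "grey60") +
      ggplot2::geom_line() +
      ggplot2::facet_grid(sex ~ age_class) +
      ggplot2::labs(x = "inter-onset interval t_k (s)", y = "density") +
      ggplot2::theme_minimal()
    save_both(p_t, "fig_tk_density")
    panels <- rbind(panels, data.frame(figure = "tk_density",
                                       unique(td[, c("sex", "age_class")])))
  }

  rd <- dens_df(ratios, "r")
  if (!is.null(rd)) {
    bands <- data.frame(lo = scheme$lo, hi = scheme$hi,
                        on = scheme$part == "on")
    p_r <- ggplot2::ggplot(rd, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_rect(data = bands,
                         ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                      ymin = -Inf, ymax = Inf,
                                      fill = .data$on),
                         inherit.aes = FALSE, alpha = 0.35) +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "gold",
                                            `FALSE` = "grey40"),
                                 labels = c(`TRUE` = "on-integer",
                                            `FALSE` = "off-integer"),
                                 name = NULL) +
      ggplot2::geom_line() +
      ggplot2::facet_grid(sex ~ age_class) +
      ggplot2::labs(x = "rhythmic ratio r_k", y = "density") +
      ggplot2::theme_minimal()
    save_both(p_r, "fig_rk_density")
    panels <- rbind(panels, data.frame(figure = "rk_density",
                                       unique(rd[, c("sex", "age_class")])))
  }

  if (nrow(triples) > 0L) {
    xy <- ternary_xy(triples$t1, triples$t2, triples$t3)
    tri <- data.frame(triples, xy)
    edge <- data.frame(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
    p_3 <- ggplot2::ggplot(tri, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_path(data = edge, inherit.aes = FALSE,
                         ggplot2::aes(x = .data$x, y = .data$y),
                         colour = "grey50") +
      ggplot2::geom_point(size = 0.4, alpha = 0.4) +
      ggplot2::facet_grid(sex ~ age_class) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = NULL, y = NULL,
                    title = "interval triples (t1 lower-left, t2 lower-right, t3 top)") +
      ggplot2::theme_void()
    save_both(p_3, "fig_ternary")
    panels <- rbind(panels, data.frame(figure = "ternary",
                                       unique(tri[, c("sex", "age_class")])))
  }
  if (!is.null(panels)) rownames(panels) <- NULL
  invisible(panels)
}
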