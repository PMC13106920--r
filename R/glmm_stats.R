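#' Specification of a mixed model for rhythm data
#'
#' Captures the two model families used in the pipeline: an offset Poisson
#' count model for on/off-integer peak significance (response `count`,
#' fixed effects `bin * sex`, exposure = bin width, random intercept per
#' individual) and a beta model for rhythmic regularity (response in
#' (0,1), fixed effects `sex * age_class`, random intercept per
#' contribution or individual).
#'
#' @param response Name of the response column.
#' @param fixed Right-hand-side fixed-effect formula as a string, e.g.
#'   `"bin * sex"`; `"1"` for an intercept-only (null) model.
#' @param offset Name of the exposure column entering as `offset(log(.))`,
#'   or `NULL`.
#' @param group Name of the random-intercept grouping column, or `NULL`
#'   for no random effect (the fixed-effects-only fit, equivalent to the
#'   mixed model with the intercept variance pinned at zero).
#' @param family `"poisson"` (log link) or `"beta"` (logit link).
#' @return A list of class `"model_spec"`.
#' @export
model_spec <- function(response, fixed, offset = NULL, group = NULL,
                       family = c("poisson", "beta")) {
  family <- match.arg(family)
  structure(list(response = response, fixed = fixed, offset = offset,
                 group = group, family = family),
            class = "model_spec")
}

spec_formula <- function(spec, random = TRUE) {
  rhs <- spec$fixed
  if (!is.null(spec$offset)) {
    rhs <- paste0(rhs, " + offset(log(", spec$offset, "))")
  }
  if (random && !is.null(spec$group)) {
    rhs <- paste0(rhs, " + (1 | ", spec$group, ")")
  }
  stats::as.formula(paste(spec$response, "~", rhs))
}

check_spec_columns <- function(rows, spec) {
  need <- c(spec$response, spec$offset, spec$group)
  vars <- setdiff(all.vars(stats::as.formula(paste("~", spec$fixed))), "1")
  need <- c(need, vars)
  missing <- setdiff(need, names(rows))
  if (length(missing) > 0L) {
    stop("model data lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

n_fixed_params <- function(fit) nrow(fit$coefficients)

new_glmm_fit <- function(model, spec, sigma2_u, phi, converged, messages,
                         data = NULL) {
  co <- if (inherits(model, "glmmTMB")) {
    summary(model)$coefficients$cond
  } else if (inherits(model, "merMod")) {
    summary(model)$coefficients
  } else {
    summary(model)$coefficients
  }
  coefficients <- data.frame(term = rownames(co), estimate = co[, 1],
                             se = co[, 2], statistic = co[, 3],
                             p = co[, ncol(co)], row.names = NULL,
                             stringsAsFactors = FALSE)
  frame <- stats::model.frame(model)
  n_groups <- if (is.null(spec$group)) 0L else
    length(unique(frame[[spec$group]]))
  structure(list(model = model, spec = spec, coefficients = coefficients,
                 sigma2_u = sigma2_u, phi = phi,
                 logLik = as.numeric(stats::logLik(model)),
                 vcov = if (inherits(model, "glmmTMB"))
                   as.matrix(stats::vcov(model)$cond) else
                     as.matrix(stats::vcov(model)),
                 converged = converged, messages = messages,
                 data = data, n_obs = nrow(frame), n_groups = n_groups),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit: %s> %d obs, %d group(s), logLik %.2f%s\n",
              x$spec$family, x$n_obs, x$n_groups, x$logLik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$coefficients, digits = 4)
  if (!is.null(x$spec$group)) {
    cat(sprintf("random intercept variance (%s): %.4g\n",
                x$spec$group, x$sigma2_u))
  }
  if (x$spec$family == "beta") cat(sprintf("precision phi: %.4g\n", x$phi))
  invisible(x)
}

#' Fit the offset Poisson mixed model for bin counts
#'
#' Maximizes the marginal likelihood of
#' `count ~ bin * sex + offset(log(width)) + (1 | individual)` (or
#' whatever the spec describes) with a log link, using the Laplace
#' approximation by default; `nagq > 1` switches to adaptive
#' Gauss-Hermite quadrature. With `group = NULL` in the spec an ordinary
#' Poisson regression is fitted — the exact variance-pinned-at-zero limit
#' of the mixed model.
#'
#' @param rows Long bin-count table ([bin_count_table()]) or any data
#'   frame holding the spec's columns. The response must be nonnegative
#'   integers.
#' @param spec A [model_spec()] with `family = "poisson"`; default is the
#'   peak-significance model.
#' @param nagq Number of adaptive quadrature nodes (1 = Laplace).
#' @return A `"glmm_fit"` object. Non-convergence is flagged in
#'   `$converged` (and optimizer messages kept in `$messages`), never
#'   silently ignored.
#' @export
fit_poisson_glmm <- function(rows,
                             spec = model_spec("count", "bin * sex",
                                               offset = "width",
                                               group = "individual_id",
                                               family = "poisson"),
                             nagq = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "poisson") {
    stop("`spec` must have family = \"poisson\"", call. = FALSE)
  }
  check_spec_columns(rows, spec)
  y <- rows[[spec$response]]
  if (any(y < 0) || any(y != round(y))) {
    stop("Poisson response must be nonnegative integers", call. = FALSE)
  }
  rows <- as.data.frame(rows)
  if (is.character(rows[["bin"]])) {
    rows$bin <- factor(rows$bin, levels = intersect(bin_labels(),
                                                    unique(rows$bin)))
  }
  if (is.null(spec$group)) {
    model <- stats::glm(spec_formula(spec, random = FALSE), data = rows,
                        family = stats::poisson())
    return(new_glmm_fit(model, spec, sigma2_u = 0, phi = NA_real_,
                        converged = model$converged, messages = character(0),
                        data = rows))
  }
  # bobyqa with a generous evaluation budget avoids the spurious
  # gradient warnings the default optimizer emits on wide factorial fits
  model <- lme4::glmer(spec_formula(spec), data = rows,
                       family = stats::poisson(), nAGQ = nagq,
                       control = lme4::glmerControl(
                         optimizer = "bobyqa",
                         optCtrl = list(maxfun = 1e5)))
  msgs <- unlist(model@optinfo$conv$lme4$messages)
  if (is.null(msgs)) msgs <- character(0)
  converged <- model@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  vc <- lme4::VarCorr(model)
  sigma2_u <- as.numeric(vc[[spec$group]][1, 1])
  new_glmm_fit(model, spec, sigma2_u = sigma2_u, phi = NA_real_,
               converged = converged, messages = msgs, data = rows)
}

#' Fit the beta mixed model for rhythmic regularity
#'
#' Beta likelihood with a logit link for the mean and a common precision
#' `phi`, plus a random intercept on the spec's grouping factor (the
#' individual contribution, as the regularity analysis prescribes). Note
#' that with one observation per contribution and category the intercept
#' variance is only weakly identified against `phi`; a warning is issued
#' in that case and individual-level grouping is available by changing
#' `spec$group`.
#'
#' @param rows Regularity table ([prepare_regularity_table()]); rows with
#'   missing response are dropped. The response must be strictly inside
#'   (0, 1) — apply the boundary compression transform first if it touches
#'   0 or 1.
#' @param spec A [model_spec()] with `family = "beta"`; default models
#'   `regularity_adj ~ sex * age_class` with a contribution-level random
#'   intercept.
#' @return A `"glmm_fit"` object.
#' @export
fit_beta_glmm <- function(rows,
                          spec = model_spec("regularity_adj",
                                            "sex * age_class",
                                            group = "contribution_id",
                                            family = "beta")) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "beta") {
    stop("`spec` must have family = \"beta\"", call. = FALSE)
  }
  check_spec_columns(rows, spec)
  rows <- as.data.frame(rows)
  rows <- rows[!is.na(rows[[spec$response]]), , drop = FALSE]
  y <- rows[[spec$response]]
  if (any(y <= 0 | y >= 1)) {
    stop("beta response must lie strictly in (0, 1); apply the boundary ",
         "transform (see prepare_regularity_table) to exact 0/1 values",
         call. = FALSE)
  }
  if (!is.null(spec$group) &&
      max(table(rows[[spec$group]])) == 1L) {
    warning("each level of \"", spec$group, "\" has a single observation; ",
            "the random-intercept variance is only weakly identified ",
            "against the beta precision", call. = FALSE)
  }
  model <- glmmTMB::glmmTMB(spec_formula(spec), data = rows,
                            family = glmmTMB::beta_family())
  converged <- isTRUE(model$fit$convergence == 0) &&
    isTRUE(model$sdr$pdHess)
  sigma2_u <- if (is.null(spec$group)) 0 else {
    vc <- glmmTMB::VarCorr(model)$cond
    as.numeric(vc[[spec$group]][1, 1])
  }
  new_glmm_fit(model, spec, sigma2_u = sigma2_u,
               phi = stats::sigma(model), converged = converged,
               messages = character(0), data = rows)
}

#' Likelihood ratio test of nested model fits
#'
#' Twice the log-likelihood difference (clamped at zero) against a
#' chi-square with degrees of freedom equal to the difference in
#' fixed-effect parameter count. Both fits must be maximum-likelihood
#' fits to the same rows.
#'
#' @param full,null `"glmm_fit"` objects; `null` nested in `full`.
#' @return A list with `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, null) {
  stopifnot(inherits(full, "glmm_fit"), inherits(null, "glmm_fit"))
  if (full$n_obs != null$n_obs) {
    stop("full and null fits use different numbers of rows (",
         full$n_obs, " vs ", null$n_obs, ")", call. = FALSE)
  }
  df <- n_fixed_params(full) - n_fixed_params(null)
  if (df < 0) {
    stop("`null` has more fixed parameters than `full`; models are not ",
         "nested as given", call. = FALSE)
  }
  statistic <- max(0, 2 * (full$logLik - null$logLik))
  list(statistic = statistic, df = df,
       p = if (df == 0) 1 else
         stats::pchisq(statistic, df = df, lower.tail = FALSE))
}

#' Tukey-adjusted pairwise contrasts of a factor's marginal means
#'
#' Estimated marginal means per factor level (averaged over companion
#' factors with equal weights, on the link scale), all pairwise Wald
#' contrasts, and p-values adjusted by the studentized-range (Tukey)
#' method over the family of `k(k-1)/2` comparisons.
#'
#' @param fit A converged `"glmm_fit"`.
#' @param factor Name of the factor to compare.
#' @param by Optional conditioning factor: contrasts are computed within
#'   each of its levels (e.g. bin contrasts within each sex).
#' @param adjust Multiplicity adjustment, default `"tukey"`.
#' @param allow_unconverged Permit contrasts from a fit whose optimizer
#'   did not report clean convergence (used by pipeline summaries, which
#'   record the flag instead of stopping).
#' @return A data.frame with columns `contrast`, the `by` factor (if
#'   any), `estimate` (link scale), `se`, `statistic`, `p_adj`.
#' @export
pairwise_contrasts <- function(fit, factor, by = NULL, adjust = "tukey",
                               allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!fit$converged && !allow_unconverged) {
    stop("refusing to compute contrasts from an unconverged fit; ",
         "inspect fit$messages (or set allow_unconverged = TRUE)",
         call. = FALSE)
  }
  vars <- all.vars(stats::as.formula(paste("~", fit$spec$fixed)))
  if (!factor %in% vars) {
    stop("factor \"", factor, "\" is not in the model's fixed effects",
         call. = FALSE)
  }
  spec_formula <- if (is.null(by)) stats::as.formula(paste("~", factor))
  else stats::as.formula(paste("~", factor, "|", by))
  em <- emmeans::emmeans(fit$model, spec_formula, data = fit$data)
  pr <- summary(emmeans::contrast(em, method = "pairwise", adjust = adjust))
  out <- data.frame(contrast = as.character(pr$contrast),
                    stringsAsFactors = FALSE)
  if (!is.null(by)) out[[by]] <- as.character(pr[[by]])
  out$estimate <- pr$estimate
  out$se <- pr$SE
  out$statistic <- if (!is.null(pr$z.ratio)) pr$z.ratio else pr$t.ratio
  out$p_adj <- pr$p.value
  out
}

#' Observed versus model-expected zero counts
#'
#' Under the fitted Poisson model the expected number of zero responses
#' is `sum(exp(-mu_i))` with `mu_i` the conditional fitted means. An
#' observed/expected ratio clearly above 1 indicates zero inflation the
#' model cannot account for.
#'
#' @param fit A Poisson `"glmm_fit"`.
#' @param tol Flag threshold: inflation is flagged when
#'   `ratio > 1 + tol`.
#' @return A list with `observed_zeros`, `expected_zeros`, `ratio`
#'   (0 when no zeros are observed) and `inflated`.
#' @export
check_zero_inflation <- function(fit, tol = 0.05) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (fit$spec$family != "poisson") {
    stop("zero-inflation check applies to Poisson fits only", call. = FALSE)
  }
  mu <- stats::fitted(fit$model)
  y <- stats::model.frame(fit$model)[[fit$spec$response]]
  observed <- sum(y == 0)
  expected <- sum(exp(-mu))
  ratio <- if (observed == 0) 0 else observed / expected
  list(observed_zeros = observed, expected_zeros = expected,
       ratio = ratio, inflated = ratio > 1 + tol)
}

#' Fit peak-significance models for every age class
#'
#' For each age class present in the long bin-count table, fits the full
#' offset Poisson mixed model (`count ~ bin * sex` when both sexes are
#' present, `count ~ bin` otherwise), the null model (random intercept
#' and offset only), the likelihood ratio test between them, and the
#' Tukey-adjusted pairwise bin contrasts within sex. Age classes whose
#' counts are all zero are returned as degenerate results (LRT p = 1, no
#' contrasts) rather than fitted.
#'
#' @param counts Long bin-count table from [bin_count_table()].
#' @param nagq Quadrature nodes for [fit_poisson_glmm()].
#' @return A named list (one element per age class) of lists with
#'   `full`, `null`, `lrt`, `contrasts`, `zero_inflation`.
#' @export
fit_peak_models <- function(counts, nagq = 1L) {
  stopifnot(all(c("age_class", "bin", "count", "width", "sex",
                  "individual_id") %in% names(counts)))
  classes <- intersect(age_class_levels(), unique(counts$age_class))
  out <- lapply(classes, function(ac) {
    rows <- counts[counts$age_class == ac, , drop = FALSE]
    if (sum(rows$count) == 0) {
      return(list(full = NULL, null = NULL,
                  lrt = list(statistic = 0,
                             df = length(unique(rows$bin)) - 1L, p = 1),
                  contrasts = NULL, zero_inflation = NULL))
    }
    two_sexes <- length(unique(rows$sex)) == 2L
    fixed <- if (two_sexes) "bin * sex" else "bin"
    full <- fit_poisson_glmm(
      rows, model_spec("count", fixed, offset = "width",
                       group = "individual_id", family = "poisson"),
      nagq = nagq)
    null <- fit_poisson_glmm(
      rows, model_spec("count", "1", offset = "width",
                       group = "individual_id", family = "poisson"),
      nagq = nagq)
    contrasts <- pairwise_contrasts(full, "bin",
                                    by = if (two_sexes) "sex" else NULL,
                                    allow_unconverged = TRUE)
    list(full = full, null = null,
         lrt = likelihood_ratio_test(full, null),
         contrasts = contrasts,
         zero_inflation = check_zero_inflation(full))
  })
  names(out) <- classes
  out
}

#' Which rhythmic categories are significantly on-integer?
#'
#' A category counts as significant for a sex within an age class when
#' (a) the full count model beats the null by likelihood ratio test at
#' `alpha`, and (b) the on-vs-off contrast for that category within that
#' sex is positive (more on-integer than off-integer per unit ratio
#' width) with Tukey-adjusted p below `alpha`.
#'
#' @param peak_fits Result of [fit_peak_models()].
#' @param alpha Significance level.
#' @return A data.frame with one row per age class x sex x category:
#'   `age_class`, `sex`, `category`, `estimate`, `p_adj`, `lrt_p`,
#'   `significant`.
#' @export
detect_significant_categories <- function(peak_fits, alpha = 0.05) {
  stopifnot(length(peak_fits) > 0)
  rows <- list()
  for (ac in names(peak_fits)) {
    pf <- peak_fits[[ac]]
    cats <- c("R12", "R11", "R21")
    if (is.null(pf$contrasts)) {
      rows[[ac]] <- data.frame(age_class = ac,
                               sex = rep(c("F", "M"), each = length(cats)),
                               category = rep(cats, 2L),
                               estimate = NA_real_, p_adj = NA_real_,
                               lrt_p = pf$lrt$p, significant = FALSE,
                               stringsAsFactors = FALSE)
      next
    }
    ct <- pf$contrasts
    sexes <- if ("sex" %in% names(ct)) unique(ct$sex) else NA_character_
    per_sex <- lapply(sexes, function(sx) {
      sub <- if (is.na(sx)) ct else ct[ct$sex == sx, , drop = FALSE]
      found <- lapply(cats, function(cat) {
        lab_fwd <- paste0("on_", cat, " - off_", cat)
        lab_rev <- paste0("off_", cat, " - on_", cat)
        i <- match(lab_fwd, sub$contrast)
        sign <- 1
        if (is.na(i)) { i <- match(lab_rev, sub$contrast); sign <- -1 }
        if (is.na(i)) {
          return(data.frame(category = cat, estimate = NA_real_,
                            p_adj = NA_real_, stringsAsFactors = FALSE))
        }
        data.frame(category = cat, estimate = sign * sub$estimate[i],
                   p_adj = sub$p_adj[i], stringsAsFactors = FALSE)
      })
      found <- do.call(rbind, found)
      found$sex <- if (is.na(sx)) unique(stats::model.frame(
        pf$full$model)$sex %||% NA_character_) else sx
      found
    })
    res <- do.call(rbind, per_sex)
    res$age_class <- ac
    res$lrt_p <- pf$lrt$p
    res$significant <- !is.na(res$p_adj) & res$estimate > 0 &
      res$p_adj < alpha & res$lrt_p < alpha
    rows[[ac]] <- res[, c("age_class", "sex", "category", "estimate",
                          "p_adj", "lrt_p", "significant")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
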