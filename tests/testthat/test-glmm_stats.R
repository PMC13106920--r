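test_that("intercept-only counts give the closed-form Poisson MLE at the boundary", {
  d <- data.frame(count = c(1L, 2L, 3L),
                  individual_id = c("a", "b", "c"))
  fit <- suppressMessages(
    fit_poisson_glmm(d, model_spec("count", "1", group = "individual_id")))
  expect_equal(fit$sigma2_u, 0, tolerance = 1e-8)
  expect_equal(fit$coefficients$estimate[1], log(2), tolerance = 1e-6)
})

test_that("with no group variance the mixed fit collapses onto plain Poisson regression", {
  sim <- simulate_count_design(30, beta_truth, sigma_u = 0, seed = 52)
  spec_mm <- model_spec("count", "bin * sex", offset = "width",
                        group = "individual_id")
  spec_fe <- model_spec("count", "bin * sex", offset = "width", group = NULL)
  f_mm <- suppressMessages(fit_poisson_glmm(sim$data, spec_mm))
  f_fe <- fit_poisson_glmm(sim$data, spec_fe)
  expect_equal(f_mm$sigma2_u, 0, tolerance = 1e-8)
  expect_equal(f_mm$coefficients$estimate, f_fe$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(f_mm$logLik, f_fe$logLik, tolerance = 1e-6)
  # the fixed-effects route agrees with stats::glm directly
  ref <- stats::glm(count ~ bin * sex + offset(log(width)),
                    data = transform(sim$data,
                                     bin = factor(bin, bin_labels())),
                    family = poisson())
  expect_equal(unname(f_fe$coefficients$estimate), unname(coef(ref)),
               tolerance = 1e-10)
})

test_that("the Poisson mixed model recovers known parameters within 3 SEs", {
  sim <- simulate_count_design(50, beta_truth, sigma_u = 0.5, seed = 53)
  fit <- fit_poisson_glmm(sim$data,
                          model_spec("count", "bin * sex", offset = "width",
                                     group = "individual_id"))
  expect_true(fit$converged)
  err <- abs(fit$coefficients$estimate - beta_truth)
  expect_true(all(err <= 3 * fit$coefficients$se))
  # sigma2_u truth is 0.25; allow broad stochastic tolerance
  expect_gt(fit$sigma2_u, 0.05)
  expect_lt(fit$sigma2_u, 0.8)
})

test_that("Poisson response validation rejects non-counts", {
  d <- data.frame(count = c(1.5, 2), individual_id = c("a", "b"))
  expect_error(fit_poisson_glmm(d, model_spec("count", "1",
                                              group = "individual_id")),
               "nonnegative integers")
  d$count <- c(-1L, 2L)
  expect_error(fit_poisson_glmm(d, model_spec("count", "1",
                                              group = "individual_id")),
               "nonnegative integers")
})

test_that("doubling all bin widths shifts only the intercept, by -log 2", {
  sim <- simulate_count_design(30, beta_truth, sigma_u = 0.3, seed = 54)
  spec <- model_spec("count", "bin * sex", offset = "width",
                     group = "individual_id")
  f1 <- fit_poisson_glmm(sim$data, spec)
  d2 <- sim$data
  d2$width <- d2$width * 2
  f2 <- fit_poisson_glmm(d2, spec)
  delta <- f2$coefficients$estimate - f1$coefficients$estimate
  expect_equal(delta[1], -log(2), tolerance = 1e-4)
  expect_equal(delta[-1], rep(0, 11), tolerance = 1e-4)
  c1 <- pairwise_contrasts(f1, "bin", by = "sex")
  c2 <- pairwise_contrasts(f2, "bin", by = "sex")
  expect_equal(c1$estimate, c2$estimate, tolerance = 1e-4)
})

test_that("the beta fit recovers a known mean without covariates", {
  set.seed(55)
  d <- data.frame(regularity_adj = rbeta(500, 0.7 * 20, 0.3 * 20))
  fit <- fit_beta_glmm(d, model_spec("regularity_adj", "1", group = NULL,
                                     family = "beta"))
  mu_hat <- plogis(fit$coefficients$estimate[1])
  expect_lt(abs(mu_hat - 0.7), 0.03)
  expect_gt(fit$phi, 10)
  expect_lt(fit$phi, 40)
})

test_that("beta responses touching the boundary are rejected with advice", {
  d <- data.frame(regularity_adj = c(0.2, 0, 0.8),
                  contribution_id = c("a", "b", "c"))
  expect_error(fit_beta_glmm(d, model_spec("regularity_adj", "1",
                                           group = "contribution_id",
                                           family = "beta")),
               "boundary transform")
})

test_that("the beta mixed model recovers sex and age effects within 3 SEs", {
  set.seed(56)
  n_ind <- 60; per_ind <- 4
  d <- expand.grid(individual_id = sprintf("i%02d", seq_len(n_ind)),
                   rep = seq_len(per_ind), stringsAsFactors = FALSE)
  d$sex <- ifelse(match(d$individual_id, unique(d$individual_id)) %% 2 == 0,
                  "M", "F")
  d$age_class <- age_class_levels()[
    1 + match(d$individual_id, unique(d$individual_id)) %% 3]
  truth <- c(`(Intercept)` = 0.8, sexM = 0.5, age_classJUV_3_4 = -0.4,
             age_classYOUNG_0_2 = -0.8, `sexM:age_classJUV_3_4` = 0.3,
             `sexM:age_classYOUNG_0_2` = -0.3)
  X <- model.matrix(~ sex * age_class, data = d)
  u <- rnorm(n_ind, 0, 0.3)
  eta <- as.vector(X %*% truth[colnames(X)]) +
    u[match(d$individual_id, unique(d$individual_id))]
  mu <- plogis(eta); phi <- 25
  d$regularity_adj <- rbeta(nrow(d), mu * phi, (1 - mu) * phi)
  fit <- fit_beta_glmm(d, model_spec("regularity_adj", "sex * age_class",
                                     group = "individual_id",
                                     family = "beta"))
  expect_true(fit$converged)
  est <- fit$coefficients
  err <- abs(est$estimate - truth[est$term])
  expect_true(all(err <= 3 * est$se))
})

test_that("a one-observation-per-group design triggers an identifiability warning", {
  set.seed(57)
  d <- data.frame(regularity_adj = rbeta(50, 6, 3),
                  contribution_id = sprintf("c%02d", 1:50))
  expect_warning(
    fit_beta_glmm(d, model_spec("regularity_adj", "1",
                                group = "contribution_id",
                                family = "beta")),
    "weakly identified")
})

test_that("likelihood ratio tests do the right bookkeeping", {
  sim <- simulate_count_design(20, beta_truth, sigma_u = 0.3, seed = 58)
  spec_full <- model_spec("count", "bin * sex", offset = "width",
                          group = "individual_id")
  spec_null <- model_spec("count", "1", offset = "width",
                          group = "individual_id")
  full <- fit_poisson_glmm(sim$data, spec_full)
  null <- fit_poisson_glmm(sim$data, spec_null)
  same <- likelihood_ratio_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  lrt <- likelihood_ratio_test(full, null)
  expect_equal(lrt$df, 11L)     # 6 x 2 interaction design vs intercept
  expect_gte(lrt$statistic, 0)
  expect_error(likelihood_ratio_test(null, full), "not.*nested|nested")
  # differing rows are refused
  null2 <- fit_poisson_glmm(sim$data[-1, ], spec_null)
  expect_error(likelihood_ratio_test(full, null2), "different numbers")
})

test_that("LRT is invariant to factor reparameterization", {
  sim <- simulate_count_design(20, beta_truth, sigma_u = 0.3, seed = 59)
  d2 <- sim$data
  d2$bin <- factor(d2$bin, levels = rev(bin_labels()))
  spec_full <- model_spec("count", "bin * sex", offset = "width",
                          group = "individual_id")
  spec_null <- model_spec("count", "1", offset = "width",
                          group = "individual_id")
  lrt1 <- likelihood_ratio_test(fit_poisson_glmm(sim$data, spec_full),
                                fit_poisson_glmm(sim$data, spec_null))
  # reversed factor coding: same test statistic
  lrt2 <- likelihood_ratio_test(fit_poisson_glmm(d2, spec_full),
                                fit_poisson_glmm(d2, spec_null))
  expect_equal(lrt1$statistic, lrt2$statistic, tolerance = 1e-4)
})

test_that("pairwise contrasts cover the factor's pairs with Tukey adjustment", {
  sim <- simulate_count_design(24, beta_truth, sigma_u = 0.2, seed = 60)
  fit <- fit_poisson_glmm(sim$data,
                          model_spec("count", "bin * sex", offset = "width",
                                     group = "individual_id"))
  ct <- pairwise_contrasts(fit, "bin")
  expect_equal(nrow(ct), 15L)            # 6 * 5 / 2
  expect_true(all(ct$p_adj >= 0 & ct$p_adj <= 1))
  ct_sex <- pairwise_contrasts(fit, "sex")
  expect_equal(nrow(ct_sex), 1L)
  # a single comparison needs no adjustment: p equals the plain Wald p
  expect_equal(ct_sex$p_adj,
               2 * pnorm(-abs(ct_sex$statistic)), tolerance = 1e-8)
  ct_by <- pairwise_contrasts(fit, "bin", by = "sex")
  expect_equal(nrow(ct_by), 30L)         # 15 within each sex
  expect_error(pairwise_contrasts(fit, "nonexistent"), "not in the model")
})

test_that("zero-inflation diagnostics flag structural zeros and pass clean data", {
  sim <- simulate_count_design(40, beta_truth, sigma_u = 0.3, seed = 61)
  spec <- model_spec("count", "bin * sex", offset = "width",
                     group = "individual_id")
  fit <- fit_poisson_glmm(sim$data, spec)
  zi <- check_zero_inflation(fit)
  # data simulated from the model itself: observed/expected near 1
  expect_gt(zi$ratio, 0.85)
  expect_lt(zi$ratio, 1.15)

  # no zeros at all
  d_nz <- sim$data
  d_nz$count <- d_nz$count + 1L
  zi_nz <- check_zero_inflation(fit_poisson_glmm(d_nz, spec))
  expect_equal(zi_nz$observed_zeros, 0L)
  expect_equal(zi_nz$ratio, 0)
  expect_false(zi_nz$inflated)

  # 30% structural zeros injected
  d_zi <- sim$data
  set.seed(62)
  d_zi$count[runif(nrow(d_zi)) < 0.3] <- 0L
  fit_zi <- suppressMessages(fit_poisson_glmm(d_zi, spec))
  expect_true(check_zero_inflation(fit_zi)$inflated)

  beta_fit <- fit_beta_glmm(
    data.frame(regularity_adj = rbeta(50, 5, 2)),
    model_spec("regularity_adj", "1", group = NULL, family = "beta"))
  expect_error(check_zero_inflation(beta_fit), "Poisson")
})

test_that("all-zero counts yield a degenerate, non-significant peak result", {
  w <- bin_widths()
  d <- expand.grid(individual_id = sprintf("g%d", 1:4),
                   bin = bin_labels(), stringsAsFactors = FALSE)
  d$sex <- rep(c("F", "M"), length.out = nrow(d))
  d$age_class <- "YOUNG_0_2"
  d$contribution_id <- paste0(d$individual_id, "_c1")
  d$category <- sub("^(on|off)_", "", d$bin)
  d$on_off <- sub("_.*$", "", d$bin)
  d$width <- unname(w[d$bin])
  d$count <- 0L
  pf <- fit_peak_models(d)
  expect_equal(pf$YOUNG_0_2$lrt$p, 1)
  sig <- detect_significant_categories(pf)
  expect_false(any(sig$significant))
})
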