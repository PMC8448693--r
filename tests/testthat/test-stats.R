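test_that("Holm adjustment matches the step-down hand computation", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  # monotone in, and never below, the raw p-values
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("single contrast with zero replicate variance reduces to the t-test", {
  d <- center_bio_reps(make_endpoint_data(1, k = 1, bio_sd = 0, sd = 5))
  res <- mixed_anova_dunnett(d, control = "control")
  tt <- t.test(response ~ treatment, d, var.equal = TRUE)
  expect_equal(res$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(res$p_raw, tt$p.value, tolerance = 1e-6)
})

test_that("Dunnett adjustment dominates raw p and flags real effects", {
  d <- make_endpoint_data(2, k = 4, shift_arm = "t2", shift = -20)
  res <- mixed_anova_dunnett(d, control = "control")
  expect_true(all(res$p_adj >= res$p_raw - 1e-12))
  expect_true(res$significant[res$contrast == "t2 - control"])
  expect_true(all(res$lower <= res$estimate & res$estimate <= res$upper))
  # flag is consistent with alpha
  expect_equal(res$significant, res$p_adj < 0.05)
})

test_that("a 20% viability drop is detected in most simulations", {
  hits <- vapply(1:25, function(i) {
    d <- make_endpoint_data(700 + i, k = 4, shift_arm = "t1",
                            shift = -20, sd = 5)
    res <- mixed_anova_dunnett(d, control = "control", ci = FALSE)
    res$significant[res$contrast == "t1 - control"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("single biological replicate falls back to fixed effects loudly", {
  d <- make_endpoint_data(3, k = 2, n_bio = 1)
  expect_warning(res <- mixed_anova_dunnett(d, control = "control"),
                 "single biological replicate")
  expect_s3_class(res, "comparison_result")
})

test_that("mixed fit coincides with ordinary ANOVA at the variance boundary", {
  d <- center_bio_reps(make_endpoint_data(4, k = 3, bio_sd = 0))
  res <- mixed_anova_dunnett(d, control = "control")
  fit_lm <- lm(response ~ relevel(factor(treatment), "control"), d)
  expect_equal(res$estimate, unname(coef(fit_lm)[-1]), tolerance = 1e-8)
  expect_equal(res$se,
               unname(sqrt(diag(vcov(fit_lm)))[-1]), tolerance = 1e-8)
})

test_that("repeated-measures curve contrast behaves under null and effect", {
  mk_tc <- function(seed, shift = 0) {
    set.seed(seed)
    g <- expand.grid(replicate = paste0("r", 1:3), time = c(2, 4, 6, 8),
                     treatment = c("ref", "trt"),
                     stringsAsFactors = FALSE)
    g$replicate <- paste(g$treatment, g$replicate)
    g$response <- 3 * g$time + shift * g$time *
      (g$treatment == "trt") + rnorm(nrow(g), 0, 1)
    g
  }
  # null: nominal-rate false positives (spot check across seeds)
  fp <- vapply(1:25, function(i)
    repeated_measures_compare(mk_tc(i), "ref")$significant, logical(1))
  expect_lte(mean(fp), 0.2)
  # strong curve separation is detected
  res <- repeated_measures_compare(mk_tc(99, shift = -1.5), "ref")
  expect_true(res$significant)
  # Holm with two treatments doubles the smaller raw p unless capped
  mk2 <- mk_tc(5)
  extra <- mk_tc(6)
  extra$treatment[extra$treatment == "trt"] <- "trt2"
  extra <- extra[extra$treatment == "trt2", ]
  extra$replicate <- paste("trt2", extra$replicate)
  res2 <- repeated_measures_compare(rbind(mk2, extra), "ref")
  expect_equal(min(res2$p_adj), min(1, 2 * min(res2$p_raw)),
               tolerance = 1e-12)
  expect_error(repeated_measures_compare(mk2, "absent"), "absent")
})

test_that("timepoints not shared by every treatment are dropped with a note", {
  set.seed(10)
  g <- expand.grid(replicate = paste0("r", 1:3), time = c(2, 4, 6, 8),
                   treatment = c("ref", "trt"), stringsAsFactors = FALSE)
  g$replicate <- paste(g$treatment, g$replicate)
  g$response <- 3 * g$time + rnorm(nrow(g))
  g <- g[!(g$treatment == "trt" & g$time == 8), ]
  res <- repeated_measures_compare(g, "ref")
  expect_equal(attr(res, "shared_timepoints"), c(2, 4, 6))
  expect_match(attr(res, "note"), "not shared")
})
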