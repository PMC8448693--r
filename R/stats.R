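#' Mixed-effects ANOVA with Dunnett many-to-one comparisons
#'
#' Fits a linear mixed model with a fixed treatment effect and a random
#' intercept per biological replicate (residual variation at the
#' technical-replicate level), then performs Dunnett-type many-to-one
#' comparisons of every treatment against the designated control using the
#' multivariate-t dependence structure of the contrasts. Degrees of freedom
#' are residual (\code{n - p} fixed-effect coefficients). When the
#' replicate-intercept variance is estimated at its boundary (0) the mixed
#' fit coincides with ordinary least squares, so a single contrast reduces
#' exactly to the pooled two-sample t-test. With a single biological
#' replicate a fixed-effects ANOVA is used instead, with a warning.
#'
#' @param data data.frame with columns \code{response}, \code{treatment},
#'   \code{bio_rep} (and optionally \code{tech_rep}, unused in the model
#'   formula: technical replicates are the residual level).
#' @param control control level of \code{treatment} to compare against.
#' @param alpha significance level (default 0.05).
#' @param alternative \code{"two.sided"}, \code{"less"} or
#'   \code{"greater"}.
#' @param ci compute simultaneous confidence bounds (slower); set FALSE in
#'   large simulation loops.
#' @return data.frame of class \code{"comparison_result"}: one row per
#'   treatment with \code{contrast}, \code{estimate}, \code{se},
#'   \code{p_raw}, \code{p_adj} (Dunnett), \code{lower}, \code{upper}
#'   (simultaneous confidence bounds at \code{1 - alpha}, \code{NA} when
#'   \code{ci = FALSE}) and \code{significant}.
#' @export
mixed_anova_dunnett <- function(data, control, alpha = 0.05,
                                alternative = c("two.sided", "less",
                                                "greater"),
                                ci = TRUE) {
  alternative <- match.arg(alternative)
  req <- c("response", "treatment", "bio_rep")
  if (!all(req %in% names(data)))
    stop("data needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  data$treatment <- stats::relevel(factor(data$treatment), ref = control)
  n_bio <- length(unique(data$bio_rep))
  if (n_bio < 2) {
    warning("single biological replicate: falling back to fixed-effects ",
            "ANOVA", call. = FALSE)
    fit <- stats::lm(response ~ treatment, data = data)
    beta <- stats::coef(fit); V <- stats::vcov(fit)
    df <- fit$df.residual
  } else {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(response ~ treatment + (1 | bio_rep), data = data,
                 REML = TRUE)))
    beta <- lme4::fixef(fit); V <- as.matrix(stats::vcov(fit))
    df <- nrow(data) - length(beta)
  }
  trt <- setdiff(levels(data$treatment), control)
  K <- matrix(0, length(trt), length(beta),
              dimnames = list(paste(trt, "-", control), names(beta)))
  for (i in seq_along(trt))
    K[i, paste0("treatment", trt[i])] <- 1
  gl <- multcomp::glht(multcomp::parm(beta, V, df = df), linfct = K,
                       alternative = alternative)
  sm <- summary(gl)  # single-step (Dunnett) adjustment over multivariate t
  cib <- if (ci) stats::confint(gl, level = 1 - alpha)$confint
         else matrix(NA_real_, nrow(K), 3,
                     dimnames = list(NULL, c("est", "lwr", "upr")))
  t_raw <- sm$test$tstat
  p_raw <- switch(alternative,
                  two.sided = 2 * stats::pt(abs(t_raw), df,
                                            lower.tail = FALSE),
                  less = stats::pt(t_raw, df),
                  greater = stats::pt(t_raw, df, lower.tail = FALSE))
  out <- data.frame(contrast = rownames(K),
                    estimate = unname(sm$test$coefficients),
                    se = unname(sm$test$sigma),
                    p_raw = unname(p_raw),
                    p_adj = pmax(as.numeric(sm$test$pvalues),
                                 unname(p_raw)),
                    lower = unname(cib[, "lwr"]),
                    upper = unname(cib[, "upr"]))
  out$significant <- out$p_adj < alpha
  class(out) <- c("comparison_result", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "df") <- df
  out
}

#' Holm step-down multiple-testing adjustment
#'
#' Step-down Holm adjustment: order the raw p-values increasingly, set
#' \eqn{\tilde p_{(i)} = \max_{j \le i} (m - j + 1) p_{(j)}} capped at 1,
#' and map back to the input order. Delegates to
#' \code{stats::p.adjust(method = "holm")}.
#'
#' @param p raw p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "holm")
}

#' Repeated-measures curve comparison with Holm adjustment
#'
#' Compares cumulative-transport time courses of several treatments against
#' a reference treatment. A linear mixed model with fixed treatment, time
#' and treatment-by-time effects and a random intercept per replicate is
#' fitted (time as a factor: the repeated-measures grid), and each
#' treatment's curve is contrasted with the reference curve by a joint Wald
#' test over that treatment's main-effect and interaction coefficients,
#' F-scaled with residual denominator degrees of freedom for finite-sample
#' calibration. The resulting per-treatment p-values are Holm-adjusted.
#'
#' @param data data.frame with columns \code{response} (e.g. cumulative
#'   percent), \code{treatment}, \code{time}, \code{replicate}.
#' @param reference treatment id serving as the reference curve.
#' @param alpha significance level (default 0.05).
#' @return data.frame of class \code{"comparison_result"}: one row per
#'   non-reference treatment with \code{contrast}, \code{wald_chisq},
#'   \code{df}, \code{p_raw}, \code{p_adj} and \code{significant}.
#' @export
repeated_measures_compare <- function(data, reference, alpha = 0.05) {
  req <- c("response", "treatment", "time", "replicate")
  if (!all(req %in% names(data)))
    stop("data needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!reference %in% data$treatment)
    stop("reference treatment '", reference, "' not in data",
         call. = FALSE)
  # restrict every treatment to the timepoint grid shared by all
  tp_by_trt <- lapply(split(data$time, data$treatment), unique)
  shared <- Reduce(intersect, tp_by_trt)
  dropped <- length(unique(data$time)) - length(shared)
  if (!length(shared))
    stop("no timepoints shared by all treatments", call. = FALSE)
  data <- data[data$time %in% shared, ]
  data$treatment <- stats::relevel(factor(data$treatment),
                                   ref = reference)
  data$time_f <- factor(data$time)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(response ~ treatment * time_f + (1 | replicate),
               data = data, REML = TRUE)))
  beta <- lme4::fixef(fit); V <- as.matrix(stats::vcov(fit))
  trt <- setdiff(levels(data$treatment), reference)
  res <- lapply(trt, function(id) {
    idx <- grep(paste0("^treatment", id, "($|:)"), names(beta))
    b <- beta[idx]; Vi <- V[idx, idx, drop = FALSE]
    w <- as.numeric(t(b) %*% solve(Vi, b))
    r <- length(idx)
    df2 <- nrow(data) - length(beta)
    # F-type scaling of the Wald statistic with residual denominator df:
    # better finite-sample calibration than the chi-square limit at the
    # replicate counts typical of transwell studies
    data.frame(contrast = paste(id, "-", reference), wald_chisq = w,
               df = r,
               p_raw = stats::pf(w / r, r, df2, lower.tail = FALSE))
  })
  out <- do.call(rbind, res)
  out$p_adj <- holm_adjust(out$p_raw)
  out$significant <- out$p_adj < alpha
  class(out) <- c("comparison_result", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "shared_timepoints") <- shared
  if (dropped > 0)
    attr(out, "note") <- paste(dropped,
      "timepoint(s) not shared by all treatments were dropped")
  out
}

#' @export
print.comparison_result <- function(x, digits = 4, ...) {
  cat("Multiple comparisons (alpha =", attr(x, "alpha"), ")\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  if (!is.null(attr(x, "note"))) cat("Note:", attr(x, "note"), "\n")
  invisible(x)
}
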