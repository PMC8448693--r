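#' Relative potency factors from a parallel fit
#'
#' Under the parallel-curve assumption (shared \code{a}, \code{c}, \code{d};
#' compound-specific potency \code{b}) the dose scaling that maps the
#' reference curve exactly onto compound \code{i}'s curve is
#' \deqn{RPF_i = (b_i / b_{ref})^{1/d},}
#' i.e. a dose \code{x} of compound \code{i} is equipotent to
#' \code{RPF_i * x} of the reference. This is the unique definition making
#' dose equivalence exact under the exponential model. The reference maps to
#' 1; compounds excluded from the fit for lack of a cytotoxicity signal map
#' to 0.
#'
#' @param fit a \code{\link{fit_drc_parallel}} result.
#' @return an object of class \code{"rpf_set"}: list with
#'   \code{reference_id} and \code{rpf}, a named vector covering fitted and
#'   no-signal compounds.
#' @export
rpf <- function(fit) {
  stopifnot(inherits(fit, "drc_parallel_fit"))
  d <- fit$shared$d
  if (d <= 0) stop("invalid fit: d <= 0", call. = FALSE)
  b_ref <- fit$b[[fit$reference_id]]
  vals <- (fit$b / b_ref)^(1 / d)
  vals[fit$reference_id] <- 1
  vals <- c(vals, stats::setNames(rep(0, length(fit$no_signal)),
                                  fit$no_signal))
  structure(list(reference_id = fit$reference_id, rpf = vals),
            class = "rpf_set")
}

#' @export
print.rpf_set <- function(x, ...) {
  cat("Relative potency factors (reference:", x$reference_id, ")\n")
  print(signif(x$rpf, 4))
  invisible(x)
}

#' Define a mixture on the active-substance dose axis
#'
#' A mixture is described by its active substance and the dose ratio of each
#' co-formulant to the active: a mixture dose of \code{x} mg/L means the
#' active at \code{x} mg/L and co-formulant \code{i} at \code{ratio_i * x}
#' mg/L (the convention used for plant-protection-product dose axes, where
#' concentrations refer to the contained active ingredient).
#'
#' @param active_id compound id of the active substance.
#' @param ratios named numeric vector of co-formulant-to-active dose ratios
#'   (mg per mg of active); the active itself must not appear (its ratio is
#'   fixed at 1) or, if present, must equal 1.
#' @return an object of class \code{"mixture_spec"}.
#' @export
mixture_spec <- function(active_id, ratios = numeric()) {
  stopifnot(is.character(active_id), length(active_id) == 1L)
  if (length(ratios)) {
    if (is.null(names(ratios)) || any(!nzchar(names(ratios))))
      stop("'ratios' must be a named vector", call. = FALSE)
    if (any(!is.finite(ratios)) || any(ratios < 0))
      stop("'ratios' must be finite and >= 0", call. = FALSE)
    if (active_id %in% names(ratios)) {
      if (ratios[[active_id]] != 1)
        stop("the active substance must have ratio 1", call. = FALSE)
      ratios <- ratios[names(ratios) != active_id]
    }
  }
  structure(list(active_id = active_id,
                 ratios = c(stats::setNames(1, active_id), ratios)),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("Mixture on the", x$active_id, "dose axis; ratios to active:\n")
  print(x$ratios)
  invisible(x)
}

#' Predicted mixture dose-response under concentration addition
#'
#' Concentration addition treats every component as a dilution of the
#' reference compound: at mixture dose \code{x} (active-substance axis) the
#' equivalent reference dose is
#' \deqn{x_{eq}(x) = \sum_i RPF_i \, \rho_i \, x}
#' with \eqn{\rho_i} the dose ratio of component \code{i} to the active
#' (\eqn{\rho_{active} = 1}). The predicted viability is the reference
#' exponential curve evaluated at \code{x_eq}.
#'
#' @param fit a \code{\link{fit_drc_parallel}} result.
#' @param rpf_set relative potencies from \code{\link{rpf}}; computed from
#'   \code{fit} when omitted.
#' @param mixture a \code{\link{mixture_spec}}.
#' @param x dose grid on the active-substance axis, mg/L.
#' @return data.frame with columns \code{conc}, \code{conc_eq} (equivalent
#'   reference dose) and \code{viability} (predicted percent of control).
#' @export
predict_ca <- function(fit, mixture, x, rpf_set = rpf(fit)) {
  stopifnot(inherits(fit, "drc_parallel_fit"),
            inherits(mixture, "mixture_spec"))
  miss <- setdiff(names(mixture$ratios), names(rpf_set$rpf))
  if (length(miss))
    stop("mixture components without an RPF: ",
         paste(miss, collapse = ", "), call. = FALSE)
  scale <- sum(rpf_set$rpf[names(mixture$ratios)] * mixture$ratios)
  x_eq <- scale * x
  data.frame(conc = x, conc_eq = x_eq,
             viability = exp_model(x_eq,
                                   params_for(fit, fit$reference_id)))
}

#' Classify observed mixture data against the concentration-addition curve
#'
#' Compares replicated viability observations of a mixture (or product) with
#' the dose-response predicted under concentration addition. The comparison
#' is restricted to concentrations where the predicted effect lies in the
#' 10-90 percent response window (effect measured as the fraction of the
#' full span from the control level \code{a} down to the asymptote
#' \code{a*c}); outside that window the curve is too flat to carry
#' information. Within the window, each biological replicate contributes its
#' mean residual (observed minus predicted viability), and the replicate
#' means are tested against 0 with a one-sample t-test. Residuals
#' significantly below 0 mean the data lie left of the curve (lower
#' viability than predicted): a more-than-additive mixture effect; above 0,
#' less than additive; otherwise additive. If no observed concentration
#' falls in the window the verdict is \code{"indeterminate"}.
#'
#' @param observed a \code{\link{dr_data}} table for the mixture (single
#'   "compound", concentrations on the active-substance axis).
#' @param fit,mixture,rpf_set as in \code{\link{predict_ca}}.
#' @param alpha significance level of the residual test (default 0.05).
#' @param window predicted-effect window as fractions of the full response
#'   span (default \code{c(0.1, 0.9)}).
#' @return an object of class \code{"additivity_verdict"}: \code{label}
#'   (one of \code{more_than_additive}, \code{additive},
#'   \code{less_than_additive}, \code{indeterminate}), \code{residuals}
#'   (per-concentration mean residuals), \code{replicate_means},
#'   \code{p_value}, \code{alpha}, \code{window}.
#' @export
classify_additivity <- function(observed, fit, mixture,
                                rpf_set = rpf(fit), alpha = 0.05,
                                window = c(0.1, 0.9)) {
  observed <- dr_data(observed)
  a <- fit$shared$a; cc <- fit$shared$c
  pred <- predict_ca(fit, mixture, observed$conc, rpf_set)
  effect <- (a - pred$viability) / (a * (1 - cc))
  in_win <- effect >= window[1] & effect <= window[2]

  res_tab <- data.frame(conc = observed$conc,
                        residual = observed$viability - pred$viability,
                        in_window = in_win)
  if (!any(in_win)) {
    return(structure(list(label = "indeterminate",
                          residuals = res_tab[0, c("conc", "residual")],
                          replicate_means = numeric(), p_value = NA_real_,
                          alpha = alpha, window = window),
                     class = "additivity_verdict"))
  }
  per_conc <- stats::aggregate(residual ~ conc, res_tab[in_win, ],
                               FUN = mean)
  rep_means <- tapply(res_tab$residual[in_win],
                      observed$bio_rep[in_win], mean)
  rep_means <- rep_means[!is.na(rep_means)]
  # degenerate but decisive cases: all residuals (numerically) zero, or a
  # single replicate with no spread
  if (length(rep_means) < 2 || stats::sd(rep_means) < 1e-12) {
    m <- mean(rep_means)
    tol <- 1e-6 * a   # numerically-zero residuals relative to the control
    label <- if (abs(m) < tol) "additive"
             else if (m < 0) "more_than_additive" else "less_than_additive"
    p <- if (abs(m) < tol) 1 else 0
  } else {
    tt <- stats::t.test(rep_means, mu = 0)
    p <- tt$p.value
    label <- if (p >= alpha) "additive"
             else if (mean(rep_means) < 0) "more_than_additive"
             else "less_than_additive"
  }
  structure(list(label = label, residuals = per_conc,
                 replicate_means = rep_means, p_value = p,
                 alpha = alpha, window = window),
            class = "additivity_verdict")
}

#' @export
print.additivity_verdict <- function(x, ...) {
  cat("Concentration-addition verdict:", x$label, "\n")
  if (is.finite(x$p_value))
    cat(sprintf("  residual test p = %.4g (alpha = %g), %d concentrations in %g-%g%% window\n",
                x$p_value, x$alpha, nrow(x$residuals),
                100 * x$window[1], 100 * x$window[2]))
  invisible(x)
}
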