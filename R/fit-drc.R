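#' Fit the exponential model to a single compound
#'
#' Least-squares fit of the four-parameter exponential viability model to the
#' replicate-mean responses of one compound. The model is ill-conditioned in
#' the \code{(b, d)} pair, so fitting uses multi-start Levenberg-Marquardt:
#' \code{b} starts log-spaced over six decades (scaled to the concentration
#' range) crossed with \code{d} starts in \{0.5, 1, 2, 4\}; the best
#' converged start by residual sum of squares wins. Parameters are optimised
#' on transformed scales (\code{log a}, \code{log b}, \code{logit c},
#' \code{log d}) so the invariants \code{a, b, d > 0}, \code{0 < c < 1} hold
#' by construction.
#'
#' Compounds whose replicate-mean response never falls 10 percent or more
#' below their own control mean carry no cytotoxicity signal; fitting such
#' data is refused with an error (these compounds receive a relative potency
#' factor of 0 downstream, see \code{\link{rpf}}).
#'
#' @param data a \code{\link{dr_data}} table containing exactly one compound
#'   (or more, in which case \code{compound} selects one).
#' @param compound optional compound id to select from \code{data}.
#' @param start optional \code{\link{exp_model_params}} used as an additional
#'   start.
#' @param control list of optimiser settings: \code{ftol}, \code{ptol}
#'   (relative tolerances, default 1e-10) and \code{maxiter} (default 500).
#' @return an object of class \code{"drc_fit"} with elements \code{params}
#'   (an \code{exp_model_params}), \code{rss}, \code{converged},
#'   \code{compound}, \code{means} and \code{data}.
#' @seealso \code{\link{fit_drc_parallel}} for the joint parallel-curve fit.
#' @export
fit_drc <- function(data, compound = NULL, start = NULL,
                    control = list()) {
  data <- dr_data(data)
  if (!is.null(compound)) data <- data[data$compound == compound, ]
  ids <- unique(data$compound)
  if (length(ids) != 1L)
    stop("'data' must contain exactly one compound (got ",
         length(ids), "); use the 'compound' argument", call. = FALSE)
  m <- dr_means(data)
  if (length(unique(m$conc)) < 5L)
    stop("need >= 5 distinct concentrations", call. = FALSE)
  if (!has_signal(m))
    stop("no cytotoxicity signal; compound should receive RPF 0",
         call. = FALSE)
  ans <- fit_exp_core(list(m), start = start, control = control)
  structure(list(
    params = exp_model_params(a = ans$a, b = ans$b[1], c = ans$c, d = ans$d),
    rss = ans$rss, converged = ans$converged,
    compound = ids, means = m, data = data), class = "drc_fit")
}

#' Joint parallel-curve fit across compounds
#'
#' Fits the exponential viability model jointly to several compounds with
#' the shape parameters \code{a}, \code{c}, \code{d} shared and the potency
#' \code{b} free per compound (the parallel-curve assumption underlying
#' relative potency factors). Compounds without a cytotoxicity signal (no
#' 10 percent decline below their own control mean) are excluded from the
#' fit and recorded in \code{no_signal}; they receive a relative potency
#' factor of 0. The fit is initialised from per-compound single fits plus a
#' multi-start grid, and refuses to return a partial result if no start
#' converges.
#'
#' @param data a \code{\link{dr_data}} table with one or more compounds.
#' @param reference_id compound id of the reference (index) compound; must
#'   show a cytotoxic signal.
#' @param control optimiser settings as in \code{\link{fit_drc}}.
#' @return an object of class \code{"drc_parallel_fit"}: \code{shared}
#'   (list \code{a}, \code{c}, \code{d}), \code{b} (named vector, one per
#'   fitted compound), \code{reference_id}, \code{no_signal} (character),
#'   \code{rss}, \code{converged}, \code{means}, \code{data}.
#' @export
fit_drc_parallel <- function(data, reference_id, control = list()) {
  data <- dr_data(data)
  ids <- unique(data$compound)
  if (!reference_id %in% ids)
    stop("reference compound '", reference_id, "' not in data",
         call. = FALSE)
  m_all <- dr_means(data)
  m_list <- split(m_all, m_all$compound)
  signal <- vapply(m_list, has_signal, logical(1))
  if (!signal[[reference_id]])
    stop("reference compound '", reference_id,
         "' shows no cytotoxicity signal", call. = FALSE)
  no_signal <- names(signal)[!signal]
  m_fit <- m_list[names(signal)[signal]]

  # initialise from single fits where they succeed
  starts <- lapply(m_fit, function(m)
    tryCatch(fit_exp_core(list(m), control = control),
             error = function(e) NULL))
  ans <- fit_exp_core(m_fit, singles = starts, control = control)
  if (!ans$converged)
    stop("parallel fit did not converge from any start; result withheld",
         call. = FALSE)
  structure(list(
    shared = list(a = ans$a, c = ans$c, d = ans$d),
    b = stats::setNames(ans$b, names(m_fit)),
    reference_id = reference_id, no_signal = no_signal,
    rss = ans$rss, converged = ans$converged,
    means = m_all, data = data), class = "drc_parallel_fit")
}

# ---- optimisation core -----------------------------------------------------
# m_list: list of replicate-mean tables (compound, conc, viability), one per
# compound; shared a, c, d; one log-b per compound. Works for a single
# compound too (fit_drc reduces to it), so the single and parallel paths
# cannot drift apart.
fit_exp_core <- function(m_list, singles = NULL, start = NULL,
                         control = list()) {
  ctl <- utils::modifyList(list(ftol = 1e-10, ptol = 1e-10, maxiter = 500),
                           control)
  k <- length(m_list)
  x <- lapply(m_list, `[[`, "conc")
  y <- lapply(m_list, `[[`, "viability")
  y_all <- unlist(y)

  ctrl_mean <- mean(unlist(mapply(function(xx, yy) yy[xx == 0],
                                  x, y, SIMPLIFY = FALSE)))
  if (!is.finite(ctrl_mean)) ctrl_mean <- max(y_all)
  c0 <- min(0.97, max(0.02, min(y_all) / ctrl_mean))
  x_ref <- stats::median(unlist(lapply(x, function(xx) xx[xx > 0])))

  resid_fun <- function(theta) {
    a <- exp(theta[1]); cc <- stats::plogis(theta[2]); d <- exp(theta[3])
    b <- exp(theta[3 + seq_len(k)])
    unlist(lapply(seq_len(k), function(i)
      y[[i]] - a * (cc - (cc - 1) * exp(-b[i] * x[[i]]^d))))
  }

  make_theta <- function(a, cc, d, b)
    c(log(a), stats::qlogis(min(max(cc, 1e-6), 1 - 1e-6)), log(d), log(b))

  theta_starts <- list()
  # grid: d in {0.5, 1, 2, 4} x b log-spaced over six decades around the
  # concentration scale
  for (d0 in c(0.5, 1, 2, 4))
    for (lam in 10^seq(-3, 3, by = 1))
      theta_starts[[length(theta_starts) + 1L]] <-
        make_theta(ctrl_mean, c0, d0, rep(lam / x_ref^d0, k))
  # starts from per-compound single fits (parallel path)
  ok <- !vapply(singles, is.null, logical(1))
  if (k > 1L && any(ok)) {
    sa <- mean(vapply(singles[ok], `[[`, 0, "a"))
    sc <- mean(vapply(singles[ok], `[[`, 0, "c"))
    sd_ <- exp(mean(log(vapply(singles[ok], `[[`, 0, "d"))))
    sb <- vapply(seq_len(k), function(i)
      if (ok[i]) singles[[i]]$b[1] else 1 / x_ref^sd_, 0)
    theta_starts[[length(theta_starts) + 1L]] <-
      make_theta(sa, sc, sd_, sb)
  }
  if (!is.null(start)) {
    p <- exp_model_params(start)
    theta_starts[[length(theta_starts) + 1L]] <-
      make_theta(p$a, p$c, p$d, rep(p$b, k))
  }

  best <- NULL
  for (th in theta_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           ftol = ctl$ftol, ptol = ctl$ptol,
                           maxiter = ctl$maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12 * max(best$rss, 1))
      best <- list(theta = fit$par, rss = rss,
                   converged = fit$info %in% 1:4)
  }
  if (is.null(best)) stop("all optimiser starts failed", call. = FALSE)
  th <- best$theta
  list(a = exp(th[1]), c = stats::plogis(th[2]), d = exp(th[3]),
       b = exp(th[3 + seq_len(k)]), rss = best$rss,
       converged = best$converged)
}
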