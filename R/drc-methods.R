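#' @export
print.drc_fit <- function(x, ...) {
  cat("Exponential dose-response fit:", x$compound, "\n")
  print(unlist(x$params[c("a", "b", "c", "d")]))
  cat(sprintf("RSS %.6g over %d concentration means; converged: %s\n",
              x$rss, nrow(x$means), x$converged))
  invisible(x)
}

#' @export
coef.drc_fit <- function(object, ...)
  unlist(object$params[c("a", "b", "c", "d")])

#' @export
predict.drc_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$means$conc
       else if (is.data.frame(newdata)) newdata$conc else newdata
  exp_model(x, object$params)
}

#' @export
residuals.drc_fit <- function(object, ...)
  object$means$viability - predict(object)

#' @export
summary.drc_fit <- function(object, ...) {
  structure(list(fit = object,
                 sigma = sqrt(object$rss /
                              max(1, nrow(object$means) - 4))),
            class = "summary.drc_fit")
}

#' @export
print.summary.drc_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Residual SD (concentration means): %.4g\n", x$sigma))
  invisible(x)
}

#' @export
plot.drc_fit <- function(x, n_grid = 200, ...) {
  xr <- range(x$means$conc)
  grid <- seq(xr[1], xr[2], length.out = n_grid)
  plot(x$means$conc, x$means$viability, xlab = "concentration (mg/L)",
       ylab = "viability (% of control)", main = x$compound, ...)
  graphics::lines(grid, exp_model(grid, x$params))
  invisible(x)
}

#' @export
simulate.drc_fit <- function(object, nsim = 1, seed = NULL, sd = 5,
                             bio_sd = 2, ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(2^31 - 1, nsim)
  out <- lapply(seeds, function(s)
    sim_dose_response(object$params,
                      conc = sort(unique(object$means$conc)),
                      compound = object$compound, sd = sd,
                      bio_sd = bio_sd, seed = s))
  if (nsim == 1) out[[1]] else out
}

# ---- parallel fit ----------------------------------------------------------

#' @export
print.drc_parallel_fit <- function(x, ...) {
  cat("Parallel exponential dose-response fit\n")
  cat(sprintf("  shared: a = %.4g, c = %.4g, d = %.4g\n",
              x$shared$a, x$shared$c, x$shared$d))
  cat("  potency b per compound:\n")
  print(signif(x$b, 5))
  if (length(x$no_signal))
    cat("  no cytotoxicity signal (RPF 0):",
        paste(x$no_signal, collapse = ", "), "\n")
  cat(sprintf("  reference: %s; RSS %.6g; converged: %s\n",
              x$reference_id, x$rss, x$converged))
  invisible(x)
}

#' @export
coef.drc_parallel_fit <- function(object, ...)
  c(a = object$shared$a, c = object$shared$c, d = object$shared$d,
    stats::setNames(object$b, paste0("b.", names(object$b))))

# Per-compound parameter set implied by the parallel fit.
params_for <- function(fit, compound) {
  if (!compound %in% names(fit$b))
    stop("compound '", compound, "' was not fitted", call. = FALSE)
  exp_model_params(a = fit$shared$a, b = fit$b[[compound]],
                   c = fit$shared$c, d = fit$shared$d)
}

#' @export
predict.drc_parallel_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$means[
    object$means$compound %in% names(object$b), c("compound", "conc")]
  vapply(seq_len(nrow(newdata)), function(i)
    exp_model(newdata$conc[i], params_for(object, newdata$compound[i])),
    0)
}

#' @export
residuals.drc_parallel_fit <- function(object, ...) {
  m <- object$means[object$means$compound %in% names(object$b), ]
  m$viability - predict(object, newdata = m)
}

#' @export
summary.drc_parallel_fit <- function(object, ...) {
  rs <- residuals(object)
  structure(list(fit = object, rpf = rpf(object),
                 sigma = sqrt(sum(rs^2) / max(1, length(rs) -
                              (3 + length(object$b))))),
            class = "summary.drc_parallel_fit")
}

#' @export
print.summary.drc_parallel_fit <- function(x, ...) {
  print(x$fit)
  cat("Relative potency factors (reference = 1):\n")
  print(signif(x$rpf$rpf, 4))
  cat(sprintf("Residual SD (concentration means): %.4g\n", x$sigma))
  invisible(x)
}

#' @export
plot.drc_parallel_fit <- function(x, n_grid = 200, ...) {
  m <- x$means[x$means$compound %in% names(x$b), ]
  xr <- range(m$conc)
  grid <- seq(xr[1], xr[2], length.out = n_grid)
  plot(m$conc, m$viability, pch = as.integer(factor(m$compound)),
       xlab = "concentration (mg/L)", ylab = "viability (% of control)",
       ...)
  for (id in names(x$b))
    graphics::lines(grid, exp_model(grid, params_for(x, id)),
                    lty = which(names(x$b) == id))
  graphics::legend("topright", legend = names(x$b),
                   pch = seq_along(x$b), lty = seq_along(x$b), bty = "n")
  invisible(x)
}

#' @export
simulate.drc_parallel_fit <- function(object, nsim = 1, seed = NULL,
                                      sd = 5, bio_sd = 2, ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(2^31 - 1, nsim)
  one <- function(s) {
    ss <- fan_seed(s, length(object$b))
    do.call(rbind, lapply(seq_along(object$b), function(i) {
      id <- names(object$b)[i]
      sim_dose_response(params_for(object, id),
                        conc = sort(unique(
                          object$means$conc[object$means$compound == id])),
                        compound = id, sd = sd, bio_sd = bio_sd,
                        seed = ss[i])
    }))
  }
  out <- lapply(seeds, one)
  if (nsim == 1) out[[1]] else out
}
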