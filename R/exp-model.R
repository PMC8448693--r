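#' Four-parameter exponential viability model
#'
#' Evaluates the exponential dose-response model
#' \deqn{y = a \, [c - (c - 1) \exp(-b x^d)]}
#' used for benchmark-dose style modelling of cytotoxicity data. \code{a} is
#' the response of the untreated (solvent) control in percent, \code{c} the
#' maximum fold change of the response (the lower asymptote is \code{a * c};
#' \code{c < 1} for a toxic effect), \code{b} the potency parameter in
#' (mg/L)^-d and \code{d} the steepness. At \code{x = 0} the model equals
#' \code{a}; for \code{c < 1} it decreases monotonically to \code{a * c}.
#'
#' @param x concentration in mg/L, non-negative vector.
#' @param p model parameters: a list or named numeric vector with elements
#'   \code{a}, \code{b}, \code{c}, \code{d} (see
#'   \code{\link{exp_model_params}}).
#' @return numeric vector of predicted viabilities (percent of control).
#' @examples
#' p <- exp_model_params(a = 100, b = 0.01, c = 0.2, d = 1)
#' exp_model(c(0, 100), p) # 100 at x = 0
#' @export
exp_model <- function(x, p) {
  p <- exp_model_params(p)
  if (any(!is.finite(x)) || any(x < 0))
    stop("'x' must be finite and >= 0", call. = FALSE)
  p$a * (p$c - (p$c - 1) * exp(-p$b * x^p$d))
}

#' Validate exponential model parameters
#'
#' Checks and normalises the parameter set of the four-parameter exponential
#' model. Invariants: \code{a > 0}, \code{b > 0}, \code{c >= 0},
#' \code{d > 0}, all finite.
#'
#' @param a control level (percent) or a list/vector carrying all four
#'   parameters.
#' @param b potency, (mg/L)^-d.
#' @param c maximum fold change (dimensionless; \code{c < 1} for toxicity).
#' @param d steepness (dimensionless).
#' @return a list of class \code{"exp_model_params"}.
#' @export
exp_model_params <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.list(a) || (is.numeric(a) && length(a) > 1L)) {
    p <- as.list(a)
    if (!all(c("a", "b", "c", "d") %in% names(p)))
      stop("parameters must be named 'a', 'b', 'c', 'd'", call. = FALSE)
    a <- p$a; b <- p$b; c <- p$c; d <- p$d
  }
  for (nm in c("a", "b", "c", "d")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  if (a <= 0) stop("parameter 'a' must be > 0", call. = FALSE)
  if (b <= 0) stop("parameter 'b' must be > 0", call. = FALSE)
  if (c < 0) stop("parameter 'c' must be >= 0", call. = FALSE)
  if (d <= 0) stop("parameter 'd' must be > 0", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d), class = "exp_model_params")
}

#' @export
print.exp_model_params <- function(x, ...) {
  cat("Exponential dose-response parameters:\n")
  print(unlist(x[c("a", "b", "c", "d")]))
  invisible(x)
}
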