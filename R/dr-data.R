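#' Construct a dose-response dataset
#'
#' Validates a tidy table of replicated viability observations and stamps it
#' with class \code{"dr_data"}. One row per technical-replicate measurement.
#'
#' @param data a data.frame with columns \code{compound} (character),
#'   \code{conc} (concentration, mg/L, >= 0), \code{viability} (percent of
#'   solvent control), \code{bio_rep} and \code{tech_rep} (replicate ids).
#' @return the validated data.frame with class \code{c("dr_data",
#'   "data.frame")}.
#' @export
dr_data <- function(data) {
  req <- c("compound", "conc", "viability", "bio_rep", "tech_rep")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(data$conc)) || any(data$conc < 0))
    stop("'conc' must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(data$viability)))
    stop("'viability' must be finite", call. = FALSE)
  if (any(!nzchar(as.character(data$bio_rep))) ||
      any(!nzchar(as.character(data$tech_rep))))
    stop("replicate ids must be non-empty", call. = FALSE)
  class(data) <- unique(c("dr_data", class(data)))
  data
}

# Replicate-mean responses per compound x concentration. Fitting operates on
# these means; raw replicate-level rows are kept on the fit object for the
# inferential layer.
dr_means <- function(data) {
  agg <- stats::aggregate(viability ~ compound + conc, data = data,
                          FUN = mean)
  agg[order(agg$compound, agg$conc), , drop = FALSE]
}

# A compound shows a cytotoxic signal if its replicate-mean response falls
# at least `decline` (fraction) below its own control (x = 0) mean anywhere.
has_signal <- function(means_one, decline = 0.10) {
  ctrl <- means_one$viability[means_one$conc == 0]
  ctrl <- if (length(ctrl)) mean(ctrl) else max(means_one$viability)
  min(means_one$viability) <= (1 - decline) * ctrl
}
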