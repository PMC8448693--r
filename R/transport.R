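#' Construct a transwell receiver time series
#'
#' Measured receiver-compartment concentrations over time for one analyte,
#' one transport direction and one replicate, together with the volume
#' bookkeeping needed to reconstruct cumulative transported amounts.
#'
#' @param analyte_id analyte identifier.
#' @param direction \code{"AP_to_BL"} or \code{"BL_to_AP"}.
#' @param donor_c0 measured start concentration of the donor, mg/L (> 0).
#' @param V_donor,V_receiver compartment volumes, uL.
#' @param v_sample receiver aliquot volume removed (and replaced with blank
#'   medium) at each sampling event, uL; must be smaller than
#'   \code{V_receiver}.
#' @param t sampling times, h, strictly increasing.
#' @param c_receiver measured receiver concentrations at \code{t}, mg/L.
#' @param replicate replicate id.
#' @return an object of class \code{"transport_series"}.
#' @export
transport_series <- function(analyte_id, direction, donor_c0, V_donor,
                             V_receiver, v_sample, t, c_receiver,
                             replicate = "r1") {
  direction <- match.arg(direction, c("AP_to_BL", "BL_to_AP"))
  check_scalar(donor_c0, "donor_c0", lower = 0, strict_lower = TRUE)
  check_scalar(V_donor, "V_donor", lower = 0, strict_lower = TRUE)
  check_scalar(V_receiver, "V_receiver", lower = 0, strict_lower = TRUE)
  check_scalar(v_sample, "v_sample", lower = 0)
  if (v_sample >= V_receiver)
    stop("'v_sample' must be smaller than 'V_receiver'", call. = FALSE)
  if (length(t) != length(c_receiver))
    stop("'t' and 'c_receiver' lengths differ", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("'t' must be strictly increasing", call. = FALSE)
  structure(list(analyte_id = analyte_id, direction = direction,
                 donor_c0 = donor_c0, V_donor = V_donor,
                 V_receiver = V_receiver, v_sample = v_sample,
                 samples = data.frame(t = t, c_receiver = c_receiver),
                 replicate = replicate),
            class = "transport_series")
}

#' Cumulative transported amount with aliquot-replacement correction
#'
#' Under sink-condition sampling, every aliquot removed from the receiver
#' carries analyte out of the system; the cumulative transported amount at
#' sampling event \eqn{k} re-credits all previously removed analyte:
#' \deqn{Q_k = c_k V_r + \sum_{j<k} c_j v_s}
#' with \eqn{c} in mg/L and volumes in uL (so \eqn{c V} is in ng), reported
#' in ug. Negative measured concentrations are clipped to 0 with a warning.
#'
#' @param series a \code{\link{transport_series}}.
#' @return numeric vector of cumulative amounts, ug, one per timepoint.
#' @export
cumulative_amount <- function(series) {
  stopifnot(inherits(series, "transport_series"))
  conc <- series$samples$c_receiver
  if (any(conc < 0)) {
    warning("negative receiver concentration(s) clipped to 0",
            call. = FALSE)
    conc <- pmax(conc, 0)
  }
  removed_before <- c(0, cumsum(conc * series$v_sample))[seq_along(conc)]
  (conc * series$V_receiver + removed_before) / 1000
}

#' Relative transported amount in percent
#'
#' Cumulative transported amounts expressed relative to the measured initial
#' donor amount: \eqn{100 Q_k / (c_0 V_{donor})}. Values above 100 percent
#' indicate a mass-balance violation and are flagged with a warning.
#'
#' @param Q cumulative amounts, ug (from \code{\link{cumulative_amount}}).
#' @param donor_c0 measured donor start concentration, mg/L.
#' @param V_donor donor volume, uL.
#' @return percentages, one per timepoint.
#' @export
relative_percent <- function(Q, donor_c0, V_donor) {
  if (donor_c0 * V_donor <= 0)
    stop("donor amount must be > 0", call. = FALSE)
  pct <- 100 * Q / (donor_c0 * V_donor / 1000)
  if (any(pct > 100 + 1e-9))
    warning("relative transport above 100%: mass-balance violation",
            call. = FALSE)
  pct
}

#' Efflux ratio at the matched final timepoint
#'
#' Ratio of the secretory (BL to AP) over the absorptive (AP to BL)
#' relative transported percentage at the final common timepoint, reported
#' to 3 decimals. Values above 1 indicate net active secretion.
#'
#' @param secretory_pct relative transported percent in BL-to-AP direction.
#' @param absorptive_pct relative transported percent in AP-to-BL direction.
#' @return the efflux ratio (3 decimals), or \code{NA} if the absorptive
#'   percentage is 0.
#' @export
efflux_ratio <- function(secretory_pct, absorptive_pct) {
  if (absorptive_pct < 0 || secretory_pct < 0)
    stop("percentages must be >= 0", call. = FALSE)
  if (absorptive_pct == 0) return(NA_real_)
  round(secretory_pct / absorptive_pct, 3)
}

#' Apparent permeability coefficient
#'
#' \eqn{P_{app} = (\Delta Q/\Delta t) / (A c_0)} with the flux
#' \eqn{\Delta Q/\Delta t} taken as the ordinary least-squares slope of the
#' cumulative amount versus time over all timepoints (using the full
#' sampling design rather than a two-point difference).
#'
#' @param Q cumulative amounts, ug.
#' @param t timepoints, h.
#' @param A insert area, cm2 (default 1.12).
#' @param c0 initial donor concentration, ug/cm3 (numerically equal to
#'   mg/L).
#' @return a list of class \code{"permeability_result"}: \code{Papp} (cm/s),
#'   \code{slope} (ug/s), \code{A}, \code{c0}.
#' @export
apparent_permeability <- function(Q, t, A = 1.12, c0) {
  if (length(Q) != length(t) || length(t) < 2L)
    stop("need >= 2 matched timepoints", call. = FALSE)
  if (length(unique(t)) < 2L)
    stop("singular time design: all timepoints equal", call. = FALSE)
  check_scalar(A, "A", lower = 0, strict_lower = TRUE)
  check_scalar(c0, "c0", lower = 0, strict_lower = TRUE)
  slope <- unname(stats::coef(stats::lm(Q ~ I(t * 3600)))[2]) # ug/s
  structure(list(Papp = slope / (A * c0), slope = slope, A = A, c0 = c0),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("Papp = %.3e cm/s (slope %.3e ug/s, A = %.3g cm2, c0 = %.3g ug/cm3)\n",
              x$Papp, x$slope, x$A, x$c0))
  invisible(x)
}

#' Barrier-integrity quality control
#'
#' Pass/fail decision for a transwell monolayer from TEER at the start and
#' end of the experiment and the FITC-dextran apparent permeability.
#' Defaults are conventional Caco-2 acceptance values; both are
#' configurable. Missing measurements yield \code{"not assessed"}, never a
#' silent pass.
#'
#' @param teer_0h,teer_8h TEER, Ohm cm2, at 0 h and 8 h.
#' @param fitc_papp FITC-dextran Papp, cm/s.
#' @param teer_min minimum acceptable TEER (default 250 Ohm cm2).
#' @param fitc_papp_max maximum acceptable FITC-dextran Papp (default
#'   1e-6 cm/s).
#' @return a list of class \code{"barrier_qc"} with \code{status}
#'   (\code{"pass"}, \code{"fail"} or \code{"not assessed"}) and the inputs.
#' @export
barrier_qc <- function(teer_0h, teer_8h, fitc_papp, teer_min = 250,
                       fitc_papp_max = 1e-6) {
  vals <- list(teer_0h = teer_0h, teer_8h = teer_8h,
               fitc_papp = fitc_papp)
  missing_any <- any(vapply(vals, function(v)
    is.null(v) || length(v) != 1L || is.na(v), logical(1)))
  status <- if (missing_any) "not assessed"
    else if (teer_0h >= teer_min && teer_8h >= teer_min &&
             fitc_papp <= fitc_papp_max) "pass" else "fail"
  structure(c(vals, list(status = status, teer_min = teer_min,
                         fitc_papp_max = fitc_papp_max)),
            class = "barrier_qc")
}

#' @export
print.barrier_qc <- function(x, ...) {
  cat("Barrier QC:", x$status, "\n")
  invisible(x)
}

#' Summarise replicated bidirectional transport series
#'
#' Reduces a set of \code{\link{transport_series}} replicates (both
#' directions, one analyte) to per-replicate cumulative amounts and relative
#' percentages, their mean and SD per timepoint and direction, and the
#' efflux ratio at the final timepoint computed from the direction means.
#'
#' @param series_list list of \code{\link{transport_series}} objects of one
#'   analyte, covering one or both directions.
#' @return a list of class \code{"transport_summary"}: \code{per_replicate}
#'   (data.frame: direction, replicate, t, Q_ug, pct), \code{by_direction}
#'   (mean and SD of pct per direction and t), \code{efflux_ratio} (or
#'   \code{NA} when a direction is missing).
#' @export
transport_summary <- function(series_list) {
  stopifnot(length(series_list) > 0,
            all(vapply(series_list, inherits, TRUE, "transport_series")))
  per <- do.call(rbind, lapply(series_list, function(s) {
    Q <- cumulative_amount(s)
    data.frame(analyte = s$analyte_id, direction = s$direction,
               replicate = s$replicate, t = s$samples$t, Q_ug = Q,
               pct = relative_percent(Q, s$donor_c0, s$V_donor))
  }))
  agg_m <- stats::aggregate(pct ~ direction + t, per, mean)
  agg_s <- stats::aggregate(pct ~ direction + t, per, stats::sd)
  names(agg_m)[3] <- "mean_pct"; names(agg_s)[3] <- "sd_pct"
  by_dir <- merge(agg_m, agg_s, by = c("direction", "t"))
  t_final <- max(per$t)
  fin <- by_dir[by_dir$t == t_final, ]
  er <- if (all(c("AP_to_BL", "BL_to_AP") %in% fin$direction))
    efflux_ratio(fin$mean_pct[fin$direction == "BL_to_AP"],
                 fin$mean_pct[fin$direction == "AP_to_BL"])
  else NA_real_
  structure(list(per_replicate = per, by_direction = by_dir,
                 efflux_ratio = er, t_final = t_final),
            class = "transport_summary")
}

#' @export
print.transport_summary <- function(x, ...) {
  cat("Transport summary (final timepoint", x$t_final, "h)\n")
  print(x$by_direction)
  cat("Efflux ratio:", x$efflux_ratio, "\n")
  invisible(x)
}
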