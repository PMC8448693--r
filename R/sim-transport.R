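#' Configuration of the two-compartment transwell transport simulator
#'
#' Collects the mechanistic and design parameters of the bidirectional
#' Caco-2 transport simulator. Geometry defaults follow the standard 12-well
#' transwell design (1.12 cm2 insert; 500 uL apical / 1500 uL basolateral;
#' 200 / 600 uL receiver aliquots at 2, 4, 6 and 8 h, replaced with blank
#' medium to maintain sink conditions).
#'
#' The mechanism embodies three effects of surface-active co-formulants:
#' \itemize{
#'   \item saturable inhibition of apically directed efflux: with inhibitor
#'     concentration \eqn{I}, the inhibition fraction is
#'     \eqn{i = I/(IC50 + I)} and the remaining efflux activity
#'     \eqn{e = 1 - i}; the effective permeability is
#'     \eqn{P (1 + \phi e)} in the secretory (BL to AP) direction and
#'     \eqn{P (1 - \phi e)} in the absorptive direction;
#'   \item micellar sequestration above the critical micelle concentration:
#'     the free (transportable) fraction is
#'     \eqn{f_u = 1/(1 + K_{mic} \max(0, S - CMC))} with \eqn{S} the
#'     surfactant concentration;
#'   \item parallel first-order ester hydrolysis of the parent to a
#'     metabolite (rate \code{k_hydrolysis}, per hour, acting in both
#'     compartments), the metabolite being transported with its own efflux
#'     weight \code{phi_met} and no micellar sequestration.
#' }
#'
#' @param P_passive passive permeability, cm/s.
#' @param phi efflux weight of the parent, dimensionless in [0, 1).
#' @param IC50 half-maximal efflux-inhibition concentration, mg/L.
#' @param CMC critical micelle concentration of the surfactant, mg/L.
#' @param K_mic micellar binding constant, L/mg.
#' @param k_hydrolysis first-order metabolite-formation rate, 1/h (0
#'   disables the metabolite).
#' @param phi_met efflux weight of the metabolite, in [0, 1).
#' @param V_ap,V_bl apical and basolateral volumes, uL.
#' @param area insert growth area, cm2.
#' @param sample_ap,sample_bl receiver aliquot volumes, uL, taken from the
#'   AP or BL side respectively.
#' @param timepoints sampling schedule, h, strictly increasing.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise on concentrations (0 = noise free).
#' @param dt integration step, h.
#' @return a list of class \code{"transport_config"}.
#' @export
transport_config <- function(P_passive = 1e-5, phi = 0.55, IC50 = 15,
                             CMC = 10, K_mic = 0.02, k_hydrolysis = 0,
                             phi_met = 0.7, V_ap = 500, V_bl = 1500,
                             area = 1.12, sample_ap = 200,
                             sample_bl = 600,
                             timepoints = c(2, 4, 6, 8),
                             noise_cv = 0, dt = 0.01) {
  check_scalar(P_passive, "P_passive", lower = 0, strict_lower = TRUE)
  check_scalar(phi, "phi", lower = 0, upper = 1 - 1e-9)
  check_scalar(phi_met, "phi_met", lower = 0, upper = 1 - 1e-9)
  check_scalar(IC50, "IC50", lower = 0, strict_lower = TRUE)
  check_scalar(CMC, "CMC", lower = 0)
  check_scalar(K_mic, "K_mic", lower = 0)
  check_scalar(k_hydrolysis, "k_hydrolysis", lower = 0)
  check_scalar(V_ap, "V_ap", lower = 0, strict_lower = TRUE)
  check_scalar(V_bl, "V_bl", lower = 0, strict_lower = TRUE)
  check_scalar(area, "area", lower = 0, strict_lower = TRUE)
  check_scalar(noise_cv, "noise_cv", lower = 0, upper = 1 - 1e-9)
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  if (sample_ap >= V_ap || sample_bl >= V_bl)
    stop("sample volume must be smaller than the receiver volume",
         call. = FALSE)
  if (any(diff(timepoints) <= 0) || any(timepoints <= 0))
    stop("'timepoints' must be positive and strictly increasing",
         call. = FALSE)
  structure(as.list(environment()), class = "transport_config")
}

#' Simulate a bidirectional transwell transport experiment
#'
#' Discrete-time two-compartment simulation (fixed explicit step,
#' \code{config$dt} hours) of parent and optional metabolite transfer across
#' a cell monolayer, with saturable efflux inhibition, micellar free-fraction
#' reduction and scheduled receiver sampling with blank-medium replacement.
#' Total mass (donor + receiver + removed aliquots, parent + metabolite) is
#' conserved by construction; \code{\link{mass_balance}} verifies it.
#' Measurement noise is applied only to reported concentrations, never to
#' the simulated state.
#'
#' @param config a \code{\link{transport_config}}.
#' @param direction \code{"AP_to_BL"} (absorptive) or \code{"BL_to_AP"}
#'   (secretory).
#' @param donor_c0 initial donor concentration of the parent, mg/L.
#' @param inhibitor_conc surfactant/inhibitor concentration, mg/L; drives
#'   both efflux inhibition (via \code{IC50}) and micellar sequestration
#'   (via \code{CMC}, \code{K_mic}).
#' @param seed integer seed for the measurement-noise stream.
#' @param replicate replicate id stamped on the output.
#' @return an object of class \code{"transport_sim"}: measured receiver
#'   samples for parent (and metabolite, if enabled), the measured donor
#'   start concentration, the noise-free compartment ledger and the exact
#'   initial amount, plus the geometry needed by the reduction functions.
#' @export
sim_transport <- function(config, direction = c("AP_to_BL", "BL_to_AP"),
                          donor_c0, inhibitor_conc = 0, seed = 1,
                          replicate = "r1") {
  stopifnot(inherits(config, "transport_config"))
  direction <- match.arg(direction)
  check_scalar(donor_c0, "donor_c0", lower = 0, strict_lower = TRUE)
  check_scalar(inhibitor_conc, "inhibitor_conc", lower = 0)
  set.seed(fan_seed(seed, 1))

  absorptive <- direction == "AP_to_BL"
  V_d <- if (absorptive) config$V_ap else config$V_bl   # uL
  V_r <- if (absorptive) config$V_bl else config$V_ap
  v_s <- if (absorptive) config$sample_bl else config$sample_ap
  V_d_mL <- V_d / 1000; V_r_mL <- V_r / 1000; v_s_mL <- v_s / 1000

  i_frac <- inhibitor_conc / (config$IC50 + inhibitor_conc)
  e <- 1 - i_frac
  dir_fac <- function(phi) if (absorptive) 1 - phi * e else 1 + phi * e
  f_u <- 1 / (1 + config$K_mic * max(0, inhibitor_conc - config$CMC))
  PA <- config$P_passive * 3600 * config$area              # mL/h
  k_par <- PA * dir_fac(config$phi) * f_u
  k_met <- PA * dir_fac(config$phi_met)
  kh <- config$k_hydrolysis

  # state: amounts in ug
  A_d <- donor_c0 * V_d_mL; A_r <- 0; M_d <- 0; M_r <- 0
  initial <- A_d
  removed_parent <- 0; removed_met <- 0
  t_end <- max(config$timepoints)
  n_steps <- ceiling(t_end / config$dt - 1e-9)
  sample_steps <- round(config$timepoints / config$dt)
  samples_p <- numeric(length(config$timepoints))
  samples_m <- numeric(length(config$timepoints))
  si <- 1L

  for (s in seq_len(n_steps)) {
    dt <- config$dt
    # fluxes donor -> receiver (ug/h), concentration-difference driven
    J_p <- k_par * (A_d / V_d_mL - A_r / V_r_mL)
    J_m <- k_met * (M_d / V_d_mL - M_r / V_r_mL)
    dA_d <- -J_p * dt - kh * A_d * dt
    dA_r <-  J_p * dt - kh * A_r * dt
    A_d <- A_d + dA_d; A_r <- A_r + dA_r
    M_d <- M_d + kh * (A_d - dA_d) * dt - J_m * dt
    M_r <- M_r + kh * (A_r - dA_r) * dt + J_m * dt
    if (min(A_d, A_r, M_d, M_r) < -1e-9)
      stop("negative concentration during integration; reduce dt (",
           config$dt, " h) or rates", call. = FALSE)
    if (si <= length(sample_steps) && s == sample_steps[si]) {
      samples_p[si] <- A_r / V_r_mL
      samples_m[si] <- M_r / V_r_mL
      removed_parent <- removed_parent + (A_r / V_r_mL) * v_s_mL
      removed_met <- removed_met + (M_r / V_r_mL) * v_s_mL
      A_r <- A_r * (V_r_mL - v_s_mL) / V_r_mL
      M_r <- M_r * (V_r_mL - v_s_mL) / V_r_mL
      si <- si + 1L
    }
  }

  n_t <- length(config$timepoints)
  meas_p <- samples_p * lnorm_factor(n_t, config$noise_cv)
  meas_m <- samples_m * lnorm_factor(n_t, config$noise_cv)
  meas_c0 <- donor_c0 * lnorm_factor(1, config$noise_cv)

  structure(list(
    direction = direction, replicate = replicate,
    donor_c0 = meas_c0, donor_c0_true = donor_c0,
    V_donor = V_d, V_receiver = V_r, v_sample = v_s,
    timepoints = config$timepoints,
    samples_parent = meas_p, samples_metabolite = meas_m,
    state = list(A_d = A_d, A_r = A_r, M_d = M_d, M_r = M_r,
                 removed_parent = removed_parent,
                 removed_metabolite = removed_met, initial = initial),
    config = config, inhibitor_conc = inhibitor_conc),
    class = "transport_sim")
}

#' Mass balance of a transport simulation
#'
#' Relative mass-balance error: initial donor amount minus everything
#' accounted for (both compartments, parent and metabolite, plus all removed
#' aliquots), over the initial amount. With measurement noise off this must
#' be at integration tolerance (< 1e-6 relative).
#'
#' @param sim a \code{\link{sim_transport}} result.
#' @return relative error (signed).
#' @export
mass_balance <- function(sim) {
  stopifnot(inherits(sim, "transport_sim"))
  st <- sim$state
  acc <- st$A_d + st$A_r + st$M_d + st$M_r +
    st$removed_parent + st$removed_metabolite
  (st$initial - acc) / st$initial
}

#' Extract a measured time series from a simulation
#'
#' Converts simulator output into the \code{\link{transport_series}} input
#' consumed by the transport reduction functions, for either the parent or
#' the metabolite analyte.
#'
#' @param sim a \code{\link{sim_transport}} result.
#' @param analyte \code{"parent"} or \code{"metabolite"}.
#' @return a \code{\link{transport_series}}.
#' @export
as_transport_series <- function(sim, analyte = c("parent", "metabolite")) {
  stopifnot(inherits(sim, "transport_sim"))
  analyte <- match.arg(analyte)
  conc <- if (analyte == "parent") sim$samples_parent
          else sim$samples_metabolite
  transport_series(
    analyte_id = analyte, direction = sim$direction,
    donor_c0 = sim$donor_c0, V_donor = sim$V_donor,
    V_receiver = sim$V_receiver, v_sample = sim$v_sample,
    t = sim$timepoints, c_receiver = conc, replicate = sim$replicate)
}
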