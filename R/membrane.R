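#' Instrument correction (G) factor
#'
#' Grating correction factor for polarized fluorescence measurements,
#' computed with horizontally polarized excitation as
#' \eqn{G = I_{HV} / I_{HH}}. Some instrument manuals print the ratio with
#' transposed subscripts; \code{\link{anisotropy}} accepts either convention
#' via its \code{g_convention} argument.
#'
#' @param I_HV intensity, horizontal excitation / vertical emission.
#' @param I_HH intensity, horizontal excitation / horizontal emission
#'   (> 0).
#' @return the G factor.
#' @export
g_factor <- function(I_HV, I_HH) {
  if (any(I_HH <= 0))
    stop("'I_HH' must be > 0 (G undefined)", call. = FALSE)
  I_HV / I_HH
}

#' Construct a polarized-intensity reading
#'
#' One steady-state fluorescence anisotropy measurement: the four polarized
#' intensities (excitation/emission polarizer positions V or H) and,
#' optionally, a pre-measured instrument G factor.
#'
#' @param I_VV,I_VH,I_HV,I_HH intensities, arbitrary units, >= 0.
#' @param G optional instrument correction factor; derived from
#'   \code{I_HV}/\code{I_HH} when NULL.
#' @return a list of class \code{"anisotropy_reading"}.
#' @export
anisotropy_reading <- function(I_VV, I_VH, I_HV = NA_real_,
                               I_HH = NA_real_, G = NULL) {
  for (v in list(I_VV, I_VH))
    if (!is.finite(v) || v < 0)
      stop("intensities must be finite and >= 0", call. = FALSE)
  structure(list(I_VV = I_VV, I_VH = I_VH, I_HV = I_HV, I_HH = I_HH,
                 G = G), class = "anisotropy_reading")
}

#' Steady-state fluorescence anisotropy
#'
#' \deqn{r = (I_{VV} - G I_{VH}) / (I_{VV} + 2 G I_{VH})}
#' Lower anisotropy of a membrane probe such as DPH means higher membrane
#' fluidity. The default G convention is \code{"standard"}
#' (\eqn{G = I_{HV}/I_{HH}}, horizontal excitation); \code{"printed"}
#' uses \eqn{I_{VH}/I_{HH}} for exact agreement with sources that print the
#' transposed ratio.
#'
#' @param reading an \code{\link{anisotropy_reading}} (or a list with the
#'   required intensities).
#' @param g_convention \code{"standard"} or \code{"printed"}; ignored when
#'   the reading carries an explicit \code{G}.
#' @return the anisotropy r (dimensionless, within [-0.5, 1]).
#' @export
anisotropy <- function(reading, g_convention = c("standard", "printed")) {
  g_convention <- match.arg(g_convention)
  G <- reading$G
  if (is.null(G)) {
    G <- if (g_convention == "standard")
      g_factor(reading$I_HV, reading$I_HH)
    else g_factor(reading$I_VH, reading$I_HH)
  }
  denom <- reading$I_VV + 2 * G * reading$I_VH
  if (!is.finite(denom) || denom <= 0)
    stop("invalid reading: anisotropy denominator <= 0", call. = FALSE)
  r <- (reading$I_VV - G * reading$I_VH) / denom
  if (r < -0.5 - 1e-9 || r > 1 + 1e-9)
    stop("derived anisotropy outside the theoretical range [-0.5, 1]",
         call. = FALSE)
  r
}

#' Simulate polarized-intensity readings for a known anisotropy
#'
#' Constructs intensity quadruples whose reduction recovers \code{r_true}
#' exactly at zero noise: the polarized pair is built from the target
#' anisotropy via \eqn{I_{VV} = S (1 + 2r)/3},
#' \eqn{I_{VH} = S (1 - r)/(3G)} (total intensity \eqn{S}), and the
#' G-calibration pair as \eqn{I_{HV} = G I_{HH}}. Multiplicative lognormal
#' noise with coefficient of variation \code{noise_cv} is applied to every
#' intensity independently.
#'
#' @param r_true target anisotropy, within [-0.5, 1].
#' @param n number of readings.
#' @param intensity_scale total intensity \eqn{S} (arbitrary units).
#' @param G_true instrument correction factor.
#' @param noise_cv coefficient of variation of the intensity noise.
#' @param seed integer seed.
#' @return list of \code{\link{anisotropy_reading}} objects.
#' @export
sim_anisotropy <- function(r_true = 0.150, n = 1, intensity_scale = 3e4,
                           G_true = 1.1, noise_cv = 0, seed = 1) {
  check_scalar(r_true, "r_true", lower = -0.5, upper = 1)
  check_scalar(G_true, "G_true", lower = 0, strict_lower = TRUE)
  check_scalar(noise_cv, "noise_cv", lower = 0, upper = 1 - 1e-9)
  set.seed(fan_seed(seed, 1))
  I_VV <- intensity_scale * (1 + 2 * r_true) / 3
  I_VH <- intensity_scale * (1 - r_true) / (3 * G_true)
  I_HH <- intensity_scale / 3
  I_HV <- G_true * I_HH
  lapply(seq_len(n), function(k) {
    f <- lnorm_factor(4, noise_cv)
    anisotropy_reading(I_VV * f[1], I_VH * f[2], I_HV * f[3],
                       I_HH * f[4])
  })
}

# ---- ATPase ---------------------------------------------------------------

#' Construct an ATPase assay plate
#'
#' Well-level luminescence readings (RLU) of an ATP-depletion Pgp ATPase
#' assay, with control roles: sodium-orthovanadate wells (ATPase fully
#' inhibited, highest remaining ATP, the baseline), untreated wells (basal
#' activity), verapamil wells (substrate-stimulated activity) and test wells
#' with or without verapamil co-stimulation.
#'
#' @param wells data.frame with columns \code{condition} (one of
#'   \code{"NaVO4"}, \code{"untreated"}, \code{"verapamil"},
#'   \code{"test_verapamil"}, \code{"test_alone"}), \code{rlu} (>= 0) and
#'   optionally \code{test_article}, \code{conc}.
#' @return the validated data.frame with class \code{"atpase_plate"}.
#' @export
atpase_plate <- function(wells) {
  req <- c("condition", "rlu")
  if (!all(req %in% names(wells)))
    stop("wells need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  ok <- c("NaVO4", "untreated", "verapamil", "test_verapamil",
          "test_alone")
  bad <- setdiff(unique(wells$condition), ok)
  if (length(bad))
    stop("unknown condition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(wells$rlu)) || any(wells$rlu < 0))
    stop("'rlu' must be finite and >= 0", call. = FALSE)
  if (!"conc" %in% names(wells)) wells$conc <- NA_real_
  class(wells) <- unique(c("atpase_plate", class(wells)))
  wells
}

#' Delta-RLU activity contrasts from an ATPase plate
#'
#' Luminescence reports the ATP remaining after the reaction, so ATPase
#' activity is the drop relative to the sodium-orthovanadate baseline:
#' \eqn{\Delta RLU(cond) = \overline{RLU}(NaVO4) - \overline{RLU}(cond)}.
#' Basal activity is \eqn{\Delta RLU} of the untreated wells; stimulation by
#' a test article alone is reported as percent of basal; inhibition of the
#' verapamil-stimulated activity is reported, per test concentration, as the
#' ratio \eqn{\Delta RLU(test+verapamil) / \Delta RLU(verapamil)}.
#'
#' @param plate an \code{\link{atpase_plate}}.
#' @return a list of class \code{"atpase_result"}: \code{delta_rlu}
#'   (named per condition, test conditions split by concentration),
#'   \code{basal}, \code{verapamil}, \code{stimulation_pct} (test_alone vs
#'   basal, by concentration), \code{inhibition_ratio} (test_verapamil vs
#'   verapamil, by concentration).
#' @export
atpase_delta_rlu <- function(plate) {
  plate <- atpase_plate(plate)
  if (!any(plate$condition == "NaVO4"))
    stop("no NaVO4 wells: baseline undefined", call. = FALSE)
  base <- mean(plate$rlu[plate$condition == "NaVO4"])
  drlu_of <- function(sub) base - mean(sub$rlu)
  by_cond_conc <- function(cond) {
    sub <- plate[plate$condition == cond, , drop = FALSE]
    if (!nrow(sub)) return(numeric())
    sp <- split(sub, format(sub$conc))
    vapply(sp, drlu_of, 0)
  }
  basal <- if (any(plate$condition == "untreated"))
    drlu_of(plate[plate$condition == "untreated", ]) else NA_real_
  ver <- if (any(plate$condition == "verapamil"))
    drlu_of(plate[plate$condition == "verapamil", ]) else NA_real_
  test_alone <- by_cond_conc("test_alone")
  test_ver <- by_cond_conc("test_verapamil")
  structure(list(
    baseline_rlu = base, basal = basal, verapamil = ver,
    delta_rlu = c(untreated = basal, verapamil = ver,
                  test_alone, test_ver),
    stimulation_pct = if (length(test_alone) && is.finite(basal))
      100 * test_alone / basal else numeric(),
    inhibition_ratio = if (length(test_ver) && is.finite(ver))
      test_ver / ver else numeric()),
    class = "atpase_result")
}

#' @export
print.atpase_result <- function(x, ...) {
  cat(sprintf("ATPase activity: basal dRLU = %.4g, verapamil dRLU = %.4g\n",
              x$basal, x$verapamil))
  if (length(x$inhibition_ratio)) {
    cat("verapamil-stimulated activity remaining (test/verapamil):\n")
    print(signif(x$inhibition_ratio, 4))
  }
  invisible(x)
}

#' Simulate a Pgp ATPase luminescence plate
#'
#' Generates well RLU values for the standard plate layout. Expected RLU is
#' the orthovanadate baseline minus the programmed activity in RLU units:
#' untreated wells consume \code{basal_activity}; verapamil wells consume
#' \code{basal_activity * stimulation_factor}; test wells co-incubated with
#' verapamil consume the stimulated activity scaled by the remaining
#' fraction \eqn{1 - c^h / (IC50^h + c^h)} at test concentration \eqn{c}
#' (Hill inhibition; \code{IC50 = Inf} disables inhibition). Multiplicative
#' lognormal noise (\code{noise_cv}) is applied per well.
#'
#' @param basal_activity basal ATPase activity in RLU units (> 0).
#' @param stimulation_factor fold stimulation by verapamil (>= 0).
#' @param IC50 half-maximal inhibitory concentration of the test article,
#'   mg/L (may be \code{Inf}).
#' @param hill Hill coefficient (> 0).
#' @param concentrations test-article concentrations, mg/L.
#' @param baseline_rlu expected RLU of the orthovanadate wells (> 0).
#' @param n_rep wells per condition.
#' @param noise_cv per-well noise coefficient of variation.
#' @param seed integer seed.
#' @return an \code{\link{atpase_plate}}.
#' @export
sim_atpase_plate <- function(basal_activity = 2e4,
                             stimulation_factor = 3, IC50 = 10,
                             hill = 1, concentrations = c(5, 20, 80),
                             baseline_rlu = 1e5, n_rep = 4,
                             noise_cv = 0, seed = 1) {
  check_scalar(basal_activity, "basal_activity", lower = 0,
               strict_lower = TRUE)
  check_scalar(stimulation_factor, "stimulation_factor", lower = 0)
  check_scalar(baseline_rlu, "baseline_rlu", lower = 0,
               strict_lower = TRUE)
  check_scalar(hill, "hill", lower = 0, strict_lower = TRUE)
  if (!(is.numeric(IC50) && length(IC50) == 1L &&
        (is.infinite(IC50) || IC50 > 0)))
    stop("'IC50' must be a positive number or Inf", call. = FALSE)
  set.seed(fan_seed(seed, 2)[2])
  inhib <- function(conc) {
    if (is.infinite(IC50)) return(rep(0, length(conc)))
    conc^hill / (IC50^hill + conc^hill)
  }
  stim <- basal_activity * stimulation_factor
  rows <- list(
    data.frame(condition = "NaVO4", conc = NA_real_,
               mu = baseline_rlu),
    data.frame(condition = "untreated", conc = NA_real_,
               mu = baseline_rlu - basal_activity),
    data.frame(condition = "verapamil", conc = NA_real_,
               mu = baseline_rlu - stim),
    data.frame(condition = "test_verapamil", conc = concentrations,
               mu = baseline_rlu - stim * (1 - inhib(concentrations))))
  layout <- do.call(rbind, rows)
  layout <- layout[rep(seq_len(nrow(layout)), each = n_rep), ]
  layout$rlu <- layout$mu * lnorm_factor(nrow(layout), noise_cv)
  layout$mu <- NULL
  atpase_plate(layout)
}
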