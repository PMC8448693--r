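# Independent oracles used across tests. These deliberately take the
# slow/brute-force route so they cannot share a defect with the
# implementation they check.

# Equivalent reference dose of a mixture by numeric root finding: for each
# component at dose rho_i * x, find the reference dose giving the same
# response on the fitted curves, then sum.
oracle_equivalent_dose <- function(fit, mixture, x) {
  ref <- mixtk::exp_model_params(fit$shared$a, fit$b[[fit$reference_id]],
                                 fit$shared$c, fit$shared$d)
  rp <- mixtk::rpf(fit)
  vapply(x, function(xx) {
    sum(vapply(names(mixture$ratios), function(id) {
      dose_i <- mixture$ratios[[id]] * xx
      if (dose_i == 0) return(0)
      if (rp$rpf[[id]] == 0) return(0)   # non-cytotoxic: contributes nothing
      p_i <- mixtk::exp_model_params(fit$shared$a, fit$b[[id]],
                                     fit$shared$c, fit$shared$d)
      target <- mixtk::exp_model(dose_i, p_i)
      stats::uniroot(function(z) mixtk::exp_model(z, ref) - target,
                     lower = 0, upper = 1e9, tol = 1e-12)$root
    }, 0))
  }, 0)
}

# Event-by-event receiver ledger: replays the sampling protocol amount by
# amount to reconstruct the cumulative transported mass from measured
# concentrations, without the closed-form correction.
oracle_cumulative <- function(series) {
  conc <- series$samples$c_receiver
  removed <- 0
  Q <- numeric(length(conc))
  for (k in seq_along(conc)) {
    in_receiver <- conc[k] * series$V_receiver      # ng
    Q[k] <- (in_receiver + removed) / 1000          # ug
    removed <- removed + conc[k] * series$v_sample
  }
  Q
}

# Endpoint dataset with the plate design used in the inferential layer:
# k treatments + control, n_bio biological x n_tech technical replicates,
# common biological-replicate intercepts, optional mean shift in one arm.
make_endpoint_data <- function(seed, k = 7, n_bio = 3, n_tech = 6,
                               bio_sd = 3, sd = 5, shift_arm = NULL,
                               shift = 0) {
  set.seed(seed)
  trts <- c("control", paste0("t", seq_len(k)))
  g <- expand.grid(tech_rep = seq_len(n_tech),
                   bio_rep = paste0("b", seq_len(n_bio)),
                   treatment = trts, stringsAsFactors = FALSE)
  icept <- stats::rnorm(n_bio, 0, bio_sd)
  names(icept) <- paste0("b", seq_len(n_bio))
  g$response <- 100 + icept[g$bio_rep] + stats::rnorm(nrow(g), 0, sd)
  if (!is.null(shift_arm))
    g$response[g$treatment == shift_arm] <-
      g$response[g$treatment == shift_arm] + shift
  g
}

# Remove all between-biological-replicate variation so the REML variance
# component sits exactly at its 0 boundary (the "zero replicate variance"
# regime where the mixed model coincides with ordinary least squares).
center_bio_reps <- function(d) {
  d$response <- d$response - stats::ave(d$response, d$bio_rep) +
    mean(d$response)
  d
}

# Bidirectional transport percentages at the final timepoint for a config.
final_pct <- function(cfg, inhibitor = 0, analyte = "parent", seed = 1,
                      donor_c0 = 1) {
  out <- vapply(c("AP_to_BL", "BL_to_AP"), function(dir) {
    s <- mixtk::sim_transport(cfg, dir, donor_c0 = donor_c0,
                              inhibitor_conc = inhibitor, seed = seed)
    ser <- mixtk::as_transport_series(s, analyte)
    Q <- mixtk::cumulative_amount(ser)
    utils::tail(mixtk::relative_percent(Q, ser$donor_c0, ser$V_donor), 1)
  }, 0)
  list(absorptive = out[["AP_to_BL"]], secretory = out[["BL_to_AP"]])
}
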