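#' Simulate a replicated cytotoxicity dose-response dataset
#'
#' Generates viability observations from the four-parameter exponential
#' model with the replicate structure of a plate-based cytotoxicity study:
#' an additive normal intercept per biological replicate (day-to-day level
#' shift) plus independent normal residual noise at the technical-replicate
#' level. Defaults mirror the standard design of 3 biological x 6 technical
#' replicates over 8 concentrations including the solvent control.
#'
#' @param params true model parameters (\code{\link{exp_model_params}} or a
#'   named list/vector).
#' @param conc concentration grid, mg/L; must have at least 4 points and
#'   include 0 (the solvent control).
#' @param n_bio,n_tech numbers of biological and technical replicates.
#' @param sd residual (technical) standard deviation, viability percent.
#' @param bio_sd standard deviation of the biological-replicate intercept,
#'   viability percent.
#' @param compound compound id stamped on the rows.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return a \code{\link{dr_data}} table.
#' @export
sim_dose_response <- function(params, conc = c(0, 7.5, 15, 30, 60, 120,
                                               240, 480),
                              n_bio = 3, n_tech = 6, sd = 5, bio_sd = 2,
                              compound = "compound", seed = 1) {
  params <- exp_model_params(params)
  if (length(conc) < 4L || !0 %in% conc)
    stop("'conc' needs >= 4 points including 0", call. = FALSE)
  check_scalar(sd, "sd", lower = 0)
  check_scalar(bio_sd, "bio_sd", lower = 0)
  set.seed(fan_seed(seed, 1))
  mu <- exp_model(conc, params)
  grid <- expand.grid(tech_rep = paste0("t", seq_len(n_tech)),
                      bio_rep = paste0("b", seq_len(n_bio)),
                      conc = conc, stringsAsFactors = FALSE)
  intercept <- stats::rnorm(n_bio, 0, bio_sd)
  names(intercept) <- paste0("b", seq_len(n_bio))
  grid$viability <- mu[match(grid$conc, conc)] +
    intercept[grid$bio_rep] +
    stats::rnorm(nrow(grid), 0, sd)
  grid$compound <- compound
  dr_data(grid[, c("compound", "conc", "viability", "bio_rep",
                   "tech_rep")])
}
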