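# parallel fit constructed from noise-free data with known b ratios
make_fit <- function(bs, d = 1, reference = names(bs)[1]) {
  dat <- do.call(rbind, lapply(names(bs), function(id)
    sim_dose_response(exp_model_params(100, bs[[id]], 0.2, d),
                      compound = id, conc = c(0, 10, 25, 50, 100, 200,
                                              400, 800),
                      sd = 0, bio_sd = 0, seed = 1)))
  fit_drc_parallel(dat, reference_id = reference)
}

test_that("RPF follows the dose-scaling convention (b_i/b_ref)^(1/d)", {
  fit <- make_fit(c(R = 0.01, S = 0.01, T = 0.02), d = 1)
  rp <- rpf(fit)
  expect_equal(rp$rpf[["R"]], 1)
  expect_equal(rp$rpf[["S"]], 1, tolerance = 1e-4)
  expect_equal(rp$rpf[["T"]], 2, tolerance = 1e-4)
  # d = 2, b_i = 4 b_ref -> RPF 2; dose scaling maps curves onto each other
  fit2 <- make_fit(c(R = 1e-4, Q = 4e-4), d = 2)
  rp2 <- rpf(fit2)
  expect_equal(rp2$rpf[["Q"]], 2, tolerance = 1e-3)
  grid <- seq(0, 100, length.out = 41)
  ref_pars <- exp_model_params(fit2$shared$a, fit2$b[["R"]],
                               fit2$shared$c, fit2$shared$d)
  q_pars <- exp_model_params(fit2$shared$a, fit2$b[["Q"]],
                             fit2$shared$c, fit2$shared$d)
  expect_equal(exp_model(grid, q_pars),
               exp_model(rp2$rpf[["Q"]] * grid, ref_pars),
               tolerance = 1e-6)
})

test_that("RPFs rescale consistently when the reference is relabelled", {
  bs <- c(A = 0.01, B = 0.02, C = 0.05)
  rp_a <- rpf(make_fit(bs, reference = "A"))
  rp_b <- rpf(make_fit(bs, reference = "B"))
  expect_equal(unname(rp_b$rpf[c("A", "B", "C")]),
               unname(rp_a$rpf[c("A", "B", "C")] / rp_a$rpf[["B"]]),
               tolerance = 1e-4)
})

test_that("concentration-addition prediction matches trivial identities", {
  fit <- make_fit(c(R = 0.01, S = 0.02))
  ref_pars <- exp_model_params(fit$shared$a, fit$b[["R"]],
                               fit$shared$c, fit$shared$d)
  grid <- c(0, 5, 20, 80, 300)
  # reference-only mixture reproduces the reference curve
  pred <- predict_ca(fit, mixture_spec("R"), grid)
  expect_equal(pred$viability, exp_model(grid, ref_pars),
               tolerance = 1e-12)
  # inert co-formulants (RPF 0) leave the active-axis curve unchanged
  flat <- sim_dose_response(exp_model_params(100, 1e-9, 0.999, 1),
                            compound = "inert", sd = 0, bio_sd = 0,
                            seed = 2)
  fit_i <- fit_drc_parallel(rbind(fit$data, flat), reference_id = "R")
  pred_i <- predict_ca(fit_i, mixture_spec("R", c(inert = 50)), grid)
  ref_i <- exp_model_params(fit_i$shared$a, fit_i$b[["R"]],
                            fit_i$shared$c, fit_i$shared$d)
  expect_equal(pred_i$viability, exp_model(grid, ref_i),
               tolerance = 1e-12)
  # missing component is an explicit, named error
  expect_error(predict_ca(fit, mixture_spec("R", c(ghost = 1)), grid),
               "ghost")
})

test_that("CA prediction equals the brute-force equivalent-dose oracle", {
  fit <- make_fit(c(R = 0.01, S = 0.02, T = 0.005))
  mix <- mixture_spec("R", c(S = 1, T = 2))
  grid <- c(0.5, 2, 10, 40)
  x_eq_oracle <- oracle_equivalent_dose(fit, mix, grid)
  pred <- predict_ca(fit, mix, grid)
  expect_equal(pred$conc_eq, x_eq_oracle, tolerance = 1e-8)
  # two components at ratio 1:1 with RPF 2 -> x_eq = 3x
  mix2 <- mixture_spec("R", c(S = 1))
  rp <- rpf(fit)
  expect_equal(predict_ca(fit, mix2, grid)$conc_eq,
               (1 + rp$rpf[["S"]]) * grid, tolerance = 1e-10)
})

test_that("CA prediction is invariant to splitting a component in half", {
  fit <- make_fit(c(R = 0.01, S = 0.02))
  grid <- c(1, 10, 100)
  whole <- predict_ca(fit, mixture_spec("R", c(S = 2)), grid)
  # same compound entered twice at half the ratio via a manual rpf set
  rp <- rpf(fit)
  rp_split <- rp
  rp_split$rpf <- c(rp$rpf, S2 = unname(rp$rpf[["S"]]))
  fit_split <- fit
  fit_split$b <- c(fit$b, S2 = unname(fit$b[["S"]]))
  split <- predict_ca(fit_split, mixture_spec("R", c(S = 1, S2 = 1)),
                      grid, rpf_set = rp_split)
  expect_equal(split$viability, whole$viability, tolerance = 1e-12)
})
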