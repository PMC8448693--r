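test_that("G factor and anisotropy follow their defining ratios", {
  expect_equal(g_factor(3, 3), 1)
  expect_equal(g_factor(2, 4), 0.5)
  expect_error(g_factor(1, 0), "undefined")
  # fully depolarized, fully polarized, and a hand-evaluated case
  expect_equal(anisotropy(anisotropy_reading(5, 5, G = 1)), 0)
  expect_equal(anisotropy(anisotropy_reading(5, 0, G = 1)), 1)
  expect_equal(anisotropy(anisotropy_reading(2, 1, G = 1)), 0.25)
  expect_error(anisotropy(anisotropy_reading(0, 0, G = 1)),
               "denominator")
})

test_that("anisotropy is invariant under uniform intensity rescaling", {
  rd <- anisotropy_reading(4, 1.5, 2.2, 2)
  for (s in c(0.1, 3, 1000)) {
    rs <- anisotropy_reading(4 * s, 1.5 * s, 2.2 * s, 2 * s)
    expect_equal(anisotropy(rs), anisotropy(rd), tolerance = 1e-12)
  }
})

test_that("generated readings round-trip the target anisotropy", {
  # exact at zero noise, including the case-study calibration r = 0.150
  for (r_true in c(0, 0.150, 0.35)) {
    rd <- sim_anisotropy(r_true, n = 1, G_true = 1.1, noise_cv = 0)[[1]]
    expect_equal(anisotropy(rd), r_true, tolerance = 1e-12)
  }
  # r = 0 at zero noise implies I_VV = G * I_VH
  rd0 <- sim_anisotropy(0, G_true = 1.3, noise_cv = 0)[[1]]
  expect_equal(rd0$I_VV, g_factor(rd0$I_HV, rd0$I_HH) * rd0$I_VH,
               tolerance = 1e-12)
  # G recovery and convention switch
  expect_equal(g_factor(rd0$I_HV, rd0$I_HH), 1.3, tolerance = 1e-12)
  expect_equal(anisotropy(rd0, g_convention = "printed"),
               anisotropy(anisotropy_reading(rd0$I_VV, rd0$I_VH,
                                             G = rd0$I_VH / rd0$I_HH)))
  expect_error(sim_anisotropy(1.2), "'r_true'")
})

test_that("noisy anisotropy readings recover r_true within 2 SE", {
  rds <- sim_anisotropy(0.150, n = 100, noise_cv = 0.02, seed = 5)
  rs <- vapply(rds, anisotropy, 0)
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs) - 0.150), 2 * se + 1e-4)
})

test_that("delta-RLU contrasts reduce the plate against the NaVO4 baseline", {
  plate <- atpase_plate(data.frame(
    condition = rep(c("NaVO4", "untreated", "verapamil"), each = 2),
    rlu = c(100000, 100000, 80000, 80000, 40000, 40000)))
  res <- atpase_delta_rlu(plate)
  expect_equal(res$basal, 20000)
  expect_equal(res$verapamil, 60000)
  # wells identical to the baseline have zero activity
  same <- atpase_plate(data.frame(condition = c("NaVO4", "untreated"),
                                  rlu = c(1e5, 1e5)))
  expect_equal(atpase_delta_rlu(same)$basal, 0)
  expect_error(atpase_delta_rlu(
    atpase_plate(data.frame(condition = "untreated", rlu = 1))),
    "NaVO4")
})

test_that("plate generator encodes the programmed inhibition", {
  # no-inhibition limit: test wells match verapamil wells in expectation
  pl_inf <- sim_atpase_plate(IC50 = Inf, noise_cv = 0, seed = 1)
  res_inf <- atpase_delta_rlu(pl_inf)
  expect_equal(unname(res_inf$inhibition_ratio), rep(1, 3))
  # full inhibition: delta-RLU of test wells goes to 0
  pl_hi <- sim_atpase_plate(IC50 = 1e-6, concentrations = 100,
                            noise_cv = 0, seed = 1)
  expect_equal(unname(atpase_delta_rlu(pl_hi)$inhibition_ratio), 0,
               tolerance = 1e-4)
  # round trip at the half-inhibition point
  pl <- sim_atpase_plate(IC50 = 10, concentrations = 10, noise_cv = 0)
  expect_equal(unname(atpase_delta_rlu(pl)$inhibition_ratio), 0.5,
               tolerance = 1e-12)
  # NaVO4 wells carry the highest expected RLU on the plate
  expect_true(all(pl_inf$rlu[pl_inf$condition == "NaVO4"] >=
                  pl_inf$rlu[pl_inf$condition != "NaVO4"]))
  expect_error(sim_atpase_plate(stimulation_factor = -1),
               "'stimulation_factor'")
})

test_that("noisy plates recover the inhibition fraction within 10%", {
  err <- vapply(1:20, function(i) {
    pl <- sim_atpase_plate(IC50 = 10, concentrations = 10,
                           noise_cv = 0.05, seed = 100 + i)
    unname(atpase_delta_rlu(pl)$inhibition_ratio) - 0.5
  }, 0)
  expect_gte(mean(abs(err) / 0.5 < 0.10), 0.8)
})
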