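# Virtual pharmacology: OCR conversion, stress test, inhibitor fold-changes.

test_that("OCR unit conversion is exact and linear", {
  expect_identical(ocr_from_flux(0), 0)
  # 1 mol/s/l * 4e-14 l * 3e5 neurons * 60 s/min / 45 ug
  expect_equal(ocr_from_flux(1), 1.6e-8, tolerance = 1e-15)
  expect_equal(ocr_from_flux(2), 2 * ocr_from_flux(1), tolerance = 1e-15)
  expect_error(ocr_from_flux(-1), "unphysical")
})

test_that("physiological stress test orders the OCR phases correctly", {
  res <- mito_stress_test(ox_params(), n = 6, seed = 21)
  m <- res$median
  expect_gt(m[["max_ocr"]], m[["basal_ocr"]])
  expect_gt(m[["basal_ocr"]], m[["leak_ocr"]])
  expect_gt(m[["leak_ocr"]], 0)
})

test_that("a pre-inhibited CIII abolishes respiration in all phases", {
  p <- ox_params(x_CIII = 6.78e-4 * 1e-6)
  res <- mito_stress_test(p, n = 3, seed = 2)
  pc <- mito_stress_test(ox_params(), n = 3, seed = 2)
  for (ph in c("basal_ocr", "leak_ocr", "max_ocr"))
    expect_lt(res$median[[ph]], 0.05 * pc$median[["basal_ocr"]])
})

test_that("raised proton leak elevates basal OCR", {
  cal <- calibrate_activity("Hle", 200)
  hle <- mito_stress_test(cal$params, n = 8, seed = 13)
  pc <- mito_stress_test(ox_params(), n = 8, seed = 13)
  expect_gt(hle$median[["basal_ocr"]], pc$median[["basal_ocr"]])
})

test_that("inhibitor directions at the physiological condition match known pharmacology", {
  p <- ox_params()
  met <- ox_condition_metrics(p, c("stress_test", "oligo", "rot", "antia"),
                              n = 6, seed = 31)
  m <- met$median
  # oligomycin: OCR below basal is the leak phase (already ordered above);
  # dpsi slightly hyperpolarized, NADH up, ATP_m collapses
  expect_gt(m[["fc_dpsi_oligo"]], 1)
  expect_gt(m[["fc_nadh_oligo"]], 1)
  expect_lt(m[["fc_atp_m_oligo"]], 0.5)
  # rotenone / antimycin A: depolarization and NADH rise
  expect_lt(m[["fc_dpsi_rot"]], 0.9)
  expect_lt(m[["fc_dpsi_antia"]], 0.9)
  expect_gt(m[["fc_nadh_rot"]], 1)
})

test_that("rotenone and antimycin A drive OCR toward zero", {
  p <- ox_params()
  ss <- ox_steady_state(p)
  for (d in c("rotenone", "antimycin_a")) {
    tr <- ox_simulate(p, drug_preset(d, t_drug = 600), duration = 1800,
                      init = ss$state)
    ocr <- tr$fluxes[, "J_CIV"]
    expect_lt(ocr[which.min(abs(tr$times - 1800))],
              0.1 * ocr[which.min(abs(tr$times - 590))])
  }
})

test_that("FCCP raises OCR above basal", {
  p <- ox_params()
  ss <- ox_steady_state(p)
  tr <- ox_simulate(p, drug_preset("fccp", t_drug = 600), duration = 1800,
                    init = ss$state)
  ocr <- tr$fluxes[, "J_CIV"]
  expect_gt(ocr[which.min(abs(tr$times - 1800))],
            1.5 * ocr[which.min(abs(tr$times - 590))])
})

test_that("identity-magnitude drug event gives unit fold-changes", {
  p <- ox_params()
  ss <- ox_steady_state(p)
  tr <- ox_simulate(p, drug_protocol(drug_event(1200, "x_F1", "multiply", 1)),
                    duration = 2400, init = ss$state)
  pre <- tr$times >= 720 & tr$times <= 1200
  ipost <- which.min(abs(tr$times - 2400))
  for (v in c("dpsi", "nadh_m", "atp_m", "h2o2_c")) {
    fc <- unname(tr$state[ipost, v] / mean(tr$state[pre, v]))
    expect_equal(fc, 1, tolerance = 1e-5)
  }
})

test_that("severe CI impairment reverses the ATP synthase under oligomycin", {
  # oligomycin then depolarizes (FC < 1) and raises matrix ATP (FC > 1)
  cal <- calibrate_activity("CI", 6)
  met <- ox_condition_metrics(cal$params, "oligo", n = 6, seed = 8,
                              nudge_param = "x_CI")
  expect_lt(met$median[["fc_dpsi_oligo"]], 1)
  expect_gt(met$median[["fc_atp_m_oligo"]], 1)
})

test_that("inhibitor_response returns member-level fold-changes with a median", {
  r <- inhibitor_response(ox_params(), "oligomycin", "dpsi", n = 5, seed = 3)
  expect_length(r$fc, 5)
  expect_equal(r$median, stats::median(r$fc))
  expect_gt(r$median, 1)
  expect_error(inhibitor_response(ox_params(), "nosuchdrug"), "unknown drug")
})
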