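# Core model: fluxes, derivatives, steady states, conservation, populations.

test_that("designed physiological state is a fixed point of the model", {
  p <- ox_params()
  st <- ox_pc_state(p)
  d <- ox_derivatives(st, p)
  expect_lt(max(abs(d) / pmax(abs(st), 1e-12)), 1e-8)
  ss <- ox_steady_state(p)
  expect_equal(ss$status, "ok")
  # already at steady state: returned unchanged within tolerance
  expect_equal(ss$state, st, tolerance = 1e-6)
})

test_that("compiled and R derivatives agree along a trajectory", {
  p <- ox_params()
  st <- ox_pc_state(p)
  set.seed(4)
  init <- st * exp(stats::rnorm(22, 0, 0.05))
  names(init) <- ox_state_names()
  # compiled route
  tr <- ox_simulate(p, drug_protocol(), duration = 200, init = init, dt = 50)
  expect_equal(tr$status, "ok")
  # independent R-function route through the same stiff solver
  rhs <- function(t, y, parms) {
    names(y) <- ox_state_names()
    list(ox_derivatives(y, p))
  }
  out <- deSolve::vode(unname(init), seq(0, 200, 50), rhs, parms = NULL,
                       rtol = 1e-8, atol = 1e-12)
  final_r <- out[nrow(out), 1 + seq_len(22)]
  final_c <- tr$state[nrow(tr$state), ]
  expect_equal(unname(final_c), unname(final_r), tolerance = 1e-6)
})

test_that("every flux is zero when its multiplier is zero, and scales linearly", {
  st <- ox_pc_state(ox_params())
  zero_cases <- list(c("x_CI", "J_CI"), c("x_CIII", "J_CIII"),
                     c("x_CIV", "J_CIV"), c("x_F1", "J_F1"),
                     c("x_Hle", "J_Hle"), c("x_DH", "J_DH"),
                     c("K_ADTP_dyn", "J_KDyn"), c("K_ADTP_cons", "J_KCons"))
  for (cs in zero_cases) {
    args <- stats::setNames(list(0), cs[1])
    p0 <- do.call(ox_params, args)
    expect_identical(ox_fluxes(st, p0)[[cs[2]]], 0,
                     info = paste("zero", cs[1]))
    # linearity in the multiplier at fixed state
    p1 <- ox_params()
    args2 <- stats::setNames(list(2 * p1$x[[cs[1]]]), cs[1])
    p2 <- do.call(ox_params, args2)
    expect_equal(ox_fluxes(st, p2)[[cs[2]]],
                 2 * ox_fluxes(st, p1)[[cs[2]]], tolerance = 1e-12,
                 info = paste("linear", cs[1]))
  }
})

test_that("zeroed multiplier removes its component from the state derivative", {
  p0 <- ox_params(x_CI = 0)
  st <- ox_pc_state(p0)
  d <- ox_derivatives(st, p0)
  J <- ox_fluxes(st, p0)
  # with J_CI = 0 the NADH derivative is set by the DH flux alone
  expect_equal(d[["nadh_m"]], J[["J_DH"]] / p0$consts$W_m, tolerance = 1e-12)
})

test_that("derivatives reject non-finite state and name the offender", {
  st <- ox_pc_state(ox_params())
  st[["nadh_m"]] <- NaN
  expect_error(ox_fluxes(st, ox_params()), "nadh_m")
})

test_that("moieties are conserved along a stress-test trajectory", {
  p <- ox_params()
  tr <- ox_simulate(p, drug_preset("stress_test"), duration = 4800,
                    init = ox_pc_state(p))
  expect_equal(tr$status, "ok")
  pools <- list(c("nadh_m", "nad_m"), c("q", "qh2"), c("cred", "cox"),
                c("atp_m", "adp_m"), c("atp_c", "adp_c"))
  for (pr in pools) {
    tot <- rowSums(tr$state[, pr, drop = FALSE])
    expect_lt(diff(range(tot)) / mean(tot), 1e-6)
  }
  # derivative-level check: d/dt(NADH + NAD) identically zero
  d <- ox_derivatives(ox_pc_state(p) * 1.05, p)
  expect_equal(d[["nadh_m"]] + d[["nad_m"]], 0)
})

test_that("steady state is independent of the init within the basin", {
  p <- ox_params()
  st <- ox_pc_state(p)
  # redistribute within conserved pools and displace dpsi, keeping totals
  alt <- st
  alt[["dpsi"]] <- 120
  alt[["nadh_m"]] <- 0.7 * (st[["nadh_m"]] + st[["nad_m"]])
  alt[["nad_m"]] <- 0.3 * (st[["nadh_m"]] + st[["nad_m"]])
  atot <- st[["atp_m"]] + st[["adp_m"]]
  alt[["atp_m"]] <- 0.2 * atot
  alt[["adp_m"]] <- 0.8 * atot
  # keep the exchangeable-phosphate moiety unchanged as well
  alt[["pi_m"]] <- st[["pi_m"]] + (st[["atp_m"]] - alt[["atp_m"]])
  s1 <- ox_steady_state(p, st)
  s2 <- ox_steady_state(p, alt)
  expect_equal(s2$status, "ok")
  # the steady-state tolerance admits tiny offsets along the slowest
  # (potassium-cycle) mode, so agreement is to ~1%, not machine precision
  expect_equal(s1$state, s2$state, tolerance = 0.01)
})

test_that("steady-state component fluxes respond monotonically to their multiplier", {
  p <- ox_params()
  for (cs in list(c("x_CI", "J_CI"), c("x_Hle", "J_Hle"))) {
    fac <- exp(seq(log(0.2), log(2), length.out = 10))
    J <- vapply(fac, function(f) {
      pp <- p
      pp$x[[cs[1]]] <- p$x[[cs[1]]] * f
      ox_steady_state(pp)$fluxes[[cs[2]]]
    }, 0)
    expect_true(all(diff(J) > -1e-12), info = cs[1])
  }
})

test_that("empty protocol from steady state gives a constant trajectory", {
  p <- ox_params()
  ss <- ox_steady_state(p)
  tr <- ox_simulate(p, drug_protocol(), duration = 1200, init = ss$state)
  rel <- apply(tr$state, 2, function(x) diff(range(x)) / max(abs(x), 1e-300))
  expect_lt(max(rel), 1e-5)
})

test_that("identity event is indistinguishable from no event", {
  p <- ox_params()
  ss <- ox_steady_state(p)
  tr0 <- ox_simulate(p, drug_protocol(), duration = 1200, init = ss$state)
  tr1 <- ox_simulate(p, drug_protocol(drug_event(600, "x_F1", "multiply", 1)),
                     duration = 1200, init = ss$state)
  i0 <- which.min(abs(tr0$times - 1200))
  i1 <- which.min(abs(tr1$times - 1200))
  expect_equal(tr0$state[i0, ], tr1$state[i1, ], tolerance = 1e-7)
})

test_that("oligomycin event cuts the synthase flux immediately", {
  p <- ox_params()
  ss <- ox_steady_state(p)
  tr <- ox_simulate(p, drug_preset("oligomycin", t_drug = 600),
                    duration = 900, init = ss$state, dt = 10)
  pre <- tr$fluxes[which.min(abs(tr$times - 590)), "J_F1"]
  post <- tr$fluxes[which(tr$times > 600)[1], "J_F1"]
  expect_lt(abs(post), abs(pre) * 0.05)
})

test_that("populations are reproducible under a seed and collapse at zero variation", {
  p <- ox_params()
  m1 <- ox_condition_metrics(p, "basal", n = 6, seed = 9)
  m2 <- ox_condition_metrics(p, "basal", n = 6, seed = 9)
  expect_identical(m1$median, m2$median)
  m3 <- ox_condition_metrics(p, "basal", n = 6, seed = 10)
  expect_false(identical(m3$median, m1$median))
  m0 <- ox_condition_metrics(p, "basal", n = 3, variation = 0, seed = 1)
  expect_true(all(apply(m0$values, 2, function(x) diff(range(x)) == 0)))
})

test_that("population trajectories carry the retry-rule interface", {
  p <- ox_params()
  pop <- ox_population(p, protocol = NULL, n = 4, variation = 0.2, seed = 3,
                       nudge_param = "x_CI")
  expect_length(pop$members, 4)
  expect_equal(pop$nudged, 0)
  expect_true(all(vapply(pop$members,
                         function(m) m$steady$status == "ok", TRUE)))
  # the 4th-decimal nudge matches the printed convention
  expect_equal(oxphosim:::.ox_nudge(0.009), 0.009001)
})

test_that("trajectory tidy export round-trips through CSV", {
  p <- ox_params()
  tr <- ox_simulate(p, drug_protocol(), duration = 120, init = ox_pc_state(p),
                    dt = 60)
  path <- tempfile(fileext = ".csv")
  df <- ox_trajectory_tidy(tr, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(df))
  expect_equal(back$value, df$value, tolerance = 1e-12)
})

test_that("parameter config round-trips through YAML", {
  p <- ox_params(x_CI = 3e-5)
  path <- tempfile(fileext = ".yaml")
  ox_write_config(p, path, state = ox_pc_state(p))
  cfg <- ox_read_config(path)
  expect_equal(cfg$params$x, p$x, tolerance = 1e-6)
  expect_equal(cfg$init, ox_pc_state(p), tolerance = 1e-6)
})
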