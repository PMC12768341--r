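# Flux and derivative definitions (reference R implementation).
#
# The compiled C version in src/oxphos.c is the one handed to the solver;
# this R version defines the model for inspection and is tested for exact
# agreement with the compiled code.

#' Compute all model fluxes at a given state
#'
#' Evaluates every modelled flux (mol/s per litre of mitochondria) at a fixed
#' state.  Each flux is a thermokinetic mass-action rate: a rate multiplier
#' times a calibration scale times a net thermodynamic driving term, so every
#' flux is linear in its own multiplier at fixed state and vanishes when the
#' multiplier is zero.
#'
#' @param state Named numeric vector of the 22 state variables
#'   (see [ox_state_names()]).
#' @param params An [ox_params()] object.
#' @return Named numeric vector of fluxes (see [ox_flux_names()]).
#' @export
ox_fluxes <- function(state, params) {
  stopifnot(inherits(params, "ox_params"))
  if (any(!is.finite(state))) {
    bad <- ox_state_names()[!is.finite(state)]
    stop("non-finite state variable(s): ", paste(bad, collapse = ", "))
  }
  s <- as.list(state[ox_state_names()])
  k <- params$kin
  cn <- params$consts
  x <- params$x

  A <- s$dpsi / cn$rt_f
  g <- A + log(s$h_i / s$h_m)

  # proton pumps use the symmetric thermokinetic (Marcelin-de Donder) form
  # J = x c (S_f exp(D/2) - S_r exp(-D/2)), D = standard affinity - pumped
  # charge work in RT units: same equilibrium as one-sided mass action but
  # with the voltage sensitivity shared between the two directions.
  D1 <- cn$k_CI - 4 * g
  D3 <- cn$k_CIII - 2 * g
  D4 <- cn$k_CIV - 2 * g - 2 * A
  DF <- cn$n_F1 * g + log(cn$keq_F1)

  J_DH <- x[["x_DH"]] * k$c_DH * (cn$r_DH * s$nad_m - s$nadh_m)
  J_CI <- x[["x_CI"]] * k$c_CI *
    (s$nadh_m * s$q * exp(D1 / 2) - s$nad_m * s$qh2 * exp(-D1 / 2))
  J_CIII <- x[["x_CIII"]] * k$c_CIII *
    (s$qh2 * s$cox^2 * exp(D3 / 2) - s$q * s$cred^2 * exp(-D3 / 2))
  J_CIV <- x[["x_CIV"]] * k$c_CIV * (s$o2 / (s$o2 + cn$K_O2)) *
    (s$cred^2 * exp(D4 / 2) - s$cox^2 * exp(-D4 / 2))
  J_F1 <- x[["x_F1"]] * k$c_F1 *
    (s$adp_m * s$pi_m * exp(DF / 2) - s$atp_m * exp(-DF / 2))
  J_ANT <- k$a_ANT * (s$atp_m * s$adp_c - s$atp_c * s$adp_m * exp(-A))
  J_Hle <- x[["x_Hle"]] * k$c_Hle *
    (s$h_i * exp(A / 2) - s$h_m * exp(-A / 2))
  J_PiC <- k$a_PiC * (s$pi_c * s$h_i - s$pi_m * s$h_m)
  J_Kuni <- k$a_Kuni * (s$k_i * exp(A / 2) - s$k_m * exp(-A / 2))
  J_KHE <- k$a_KHE * (s$k_m * s$h_i - s$k_i * s$h_m)
  J_KDyn <- x[["K_ADTP_dyn"]] * k$c_dyn * s$adp_c
  J_KCons <- x[["K_ADTP_cons"]] * k$c_cons * s$atp_c
  J_exH <- cn$a_exH * (s$h_c - s$h_i)
  J_exK <- cn$a_exK * (s$k_c - s$k_i)
  J_ros <- k$rho_nadh * s$nadh_m + k$rho_qh2 * s$qh2
  J_clear_m <- k$k_clear_m * s$h2o2_m
  J_diff <- k$k_diff * (s$h2o2_m - s$h2o2_c)
  J_clear_c <- k$k_clear_c * s$h2o2_c

  c(J_DH = J_DH, J_CI = J_CI, J_CIII = J_CIII, J_CIV = J_CIV, J_F1 = J_F1,
    J_ANT = J_ANT, J_Hle = J_Hle, J_PiC = J_PiC, J_Kuni = J_Kuni,
    J_KHE = J_KHE, J_KDyn = J_KDyn, J_KCons = J_KCons, J_exH = J_exH,
    J_exK = J_exK, J_ros = J_ros, J_clear_m = J_clear_m, J_diff = J_diff,
    J_clear_c = J_clear_c)
}

#' Time derivative of the state vector
#'
#' Assembles d(state)/dt from the model fluxes with the membrane/compartment
#' stoichiometry: complexes I/III/IV translocate 4/2/4 charges per electron
#' pair, the ATP synthase consumes `n_F1` protons per ATP, the adenine
#' nucleotide transporter carries one charge, and proton fluxes are attenuated
#' by compartment buffering.  Clamped states (`o2`, `h_c`, `k_c`) have zero
#' derivative.
#'
#' @inheritParams ox_fluxes
#' @return Named numeric vector of d(state)/dt (per second).
#' @export
ox_derivatives <- function(state, params) {
  J <- ox_fluxes(state, params)
  s <- as.list(state[ox_state_names()])
  cn <- params$consts
  n_F1 <- cn$n_F1

  bm <- log(10) * s$h_m / cn$beta_pH
  bi <- log(10) * s$h_i / cn$beta_pH

  d <- c(
    dpsi = (4 * J[["J_CI"]] + 2 * J[["J_CIII"]] + 4 * J[["J_CIV"]] -
              n_F1 * J[["J_F1"]] - J[["J_ANT"]] - J[["J_Hle"]] -
              J[["J_Kuni"]]) / cn$c_mem,
    nadh_m = (J[["J_DH"]] - J[["J_CI"]]) / cn$W_m,
    nad_m = -(J[["J_DH"]] - J[["J_CI"]]) / cn$W_m,
    q = (J[["J_CIII"]] - J[["J_CI"]]) / cn$W_m,
    qh2 = -(J[["J_CIII"]] - J[["J_CI"]]) / cn$W_m,
    cred = 2 * (J[["J_CIII"]] - J[["J_CIV"]]) / cn$W_i,
    cox = -2 * (J[["J_CIII"]] - J[["J_CIV"]]) / cn$W_i,
    o2 = 0,
    atp_m = (J[["J_F1"]] - J[["J_ANT"]]) / cn$W_m,
    adp_m = -(J[["J_F1"]] - J[["J_ANT"]]) / cn$W_m,
    pi_m = (J[["J_PiC"]] - J[["J_F1"]]) / cn$W_m,
    h_m = bm * (-4 * J[["J_CI"]] - 2 * J[["J_CIII"]] - 4 * J[["J_CIV"]] +
                  n_F1 * J[["J_F1"]] + J[["J_Hle"]] + J[["J_PiC"]] +
                  J[["J_KHE"]]) / cn$W_m,
    k_m = (J[["J_Kuni"]] - J[["J_KHE"]]) / cn$W_m,
    h_i = bi * (4 * J[["J_CI"]] + 2 * J[["J_CIII"]] + 2 * J[["J_CIV"]] -
                  n_F1 * J[["J_F1"]] - J[["J_Hle"]] - J[["J_PiC"]] -
                  J[["J_KHE"]] + J[["J_exH"]]) / cn$W_i,
    k_i = (J[["J_KHE"]] - J[["J_Kuni"]] + J[["J_exK"]]) / cn$W_i,
    atp_c = (J[["J_ANT"]] + J[["J_KDyn"]] - J[["J_KCons"]]) / cn$V_c,
    adp_c = -(J[["J_ANT"]] + J[["J_KDyn"]] - J[["J_KCons"]]) / cn$V_c,
    pi_c = (J[["J_KCons"]] - J[["J_KDyn"]] - J[["J_PiC"]]) / cn$V_c,
    h_c = 0,
    k_c = 0,
    h2o2_m = (J[["J_ros"]] - J[["J_clear_m"]] - J[["J_diff"]]) / cn$W_m,
    h2o2_c = (J[["J_diff"]] - J[["J_clear_c"]]) / cn$V_c
  )
  d
}
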