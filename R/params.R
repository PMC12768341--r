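# Model parameterization.
#
# The eight user-facing activity multipliers (x_CI, x_CIII, x_CIV, x_F1,
# x_Hle, x_DH, K_ADTP_dyn, K_ADTP_cons) are the knobs every other stage of
# the pipeline turns.  All remaining kinetic scale constants are derived
# analytically in .ox_scales() from a designed physiological-condition (PC)
# steady state, so that the PC state is an exact fixed point of the ODE
# system by construction.

#' State variable names of the oxidative phosphorylation model
#'
#' The 22 state variables, in the order used by the solver: mitochondrial
#' membrane potential `dpsi` (mV); matrix NADH/NAD+, ubiquinol/ubiquinone,
#' adenine nucleotides, phosphate, protons and potassium; inter-membrane-space
#' (IMS) cytochrome c (reduced/oxidised), protons and potassium; cytosolic
#' adenine nucleotides, phosphate, protons and potassium; oxygen; and hydrogen
#' peroxide in matrix and cytosol.  All concentrations are mol/l of their
#' compartment.  `o2`, `h_c` and `k_c` are clamped (oxygen non-limiting;
#' cytosolic pH/K+ stat).
#'
#' @return Character vector of length 22.
#' @export
ox_state_names <- function() {
  c("dpsi",
    "nadh_m", "nad_m", "q", "qh2", "cred", "cox", "o2",
    "atp_m", "adp_m", "pi_m", "h_m", "k_m",
    "h_i", "k_i",
    "atp_c", "adp_c", "pi_c", "h_c", "k_c",
    "h2o2_m", "h2o2_c")
}

#' Flux names of the oxidative phosphorylation model
#'
#' All fluxes are expressed in mol/s per litre of mitochondria.  Electron
#' fluxes (`J_CI`, `J_CIII`, `J_CIV`) are in units of 2-electron pairs; the
#' oxygen consumption implied by `J_CIV` is `J_CIV / 2` mol O2/s/l.
#'
#' @return Character vector of flux names.
#' @export
ox_flux_names <- function() {
  c("J_DH", "J_CI", "J_CIII", "J_CIV", "J_F1", "J_ANT", "J_Hle", "J_PiC",
    "J_Kuni", "J_KHE", "J_KDyn", "J_KCons", "J_exH", "J_exK",
    "J_ros", "J_clear_m", "J_diff", "J_clear_c")
}

# indices of clamped states (o2, h_c, k_c)
.ox_clamped <- function() match(c("o2", "h_c", "k_c"), ox_state_names())

# Designed PC steady state (mol/l; dpsi in mV).  Values are physiologically
# motivated for primary cortical neurons: dpsi ~150 mV, matrix pH 7.7,
# cytosolic pH 7.2, NADH/NAD poise 0.5, Q-pool ~20% reduced, cytochrome c
# ~20% reduced, matrix ATP/ADP < 1, cytosolic ATP/ADP >> 1.
.ox_pc_state_design <- function(consts) {
  h_c <- 10^-7.2
  # IMS protons sit marginally below cytosolic: at the designed steady state
  # the IMS proton balance requires a small net influx from the cytosol.
  st <- c(
    dpsi  = 150,
    nadh_m = 1.25e-3, nad_m = 1.25e-3,
    q = 1.08e-3, qh2 = 2.7e-4,
    cred = 5.4e-5, cox = 2.16e-4,
    o2 = 2e-5,
    atp_m = 3e-3, adp_m = 7e-3, pi_m = 3e-3,
    h_m = 10^-7.7, k_m = 0.12,
    h_i = NA_real_, k_i = 0.14,
    atp_c = 2.5e-3, adp_c = 5e-5, pi_c = 2e-3,
    h_c = h_c, k_c = 0.14,
    h2o2_m = 2e-8, h2o2_c = 1e-8
  )
  # IMS proton deficit at PC: pumps deposit 8*J_e, while F1 + leak + PiC + KHE
  # withdraw 10*J_e; the difference (2*J_e) is supplied from the cytosol
  # through the exchange term a_exH * (h_c - h_i).
  st[["h_i"]] <- h_c - 2 * consts$J_e / consts$a_exH
  st
}

# Fixed physical and design constants (not varied by impairments).
.ox_consts <- function() {
  list(
    rt_f  = 26.73,     # RT/F at 310 K, mV
    c_mem = 6.75e-6,   # inner-membrane capacitance, M charge per mV per l mito
    W_m   = 0.65,      # matrix water volume, l per l mito
    W_i   = 0.1,       # IMS volume, l per l mito
    V_c   = 20,        # cytosol volume, l per l mito
    beta_pH = 0.022,   # proton buffer capacity, M per pH unit
    K_O2  = 1e-6,      # CIV oxygen affinity, M
    n_F1  = 3,         # protons translocated per ATP by the synthase
    r_DH  = 20,        # DH redox poise constant (NADH/NAD at DH equilibrium)
    k_CI  = 28.4,      # CI standard redox span, units of RT
    k_CIII = 15,       # CIII standard redox span net of pumped protons' share
    k_CIV = 41,        # CIV standard redox span
    keq_F1 = 4.5e-6,   # ATP synthesis equilibrium constant (1/M)
    a_exH = 5e5,       # IMS<->cytosol proton exchange rate
    a_exK = 5e5,       # IMS<->cytosol potassium exchange rate
    # PC design fluxes (mol/s/l mito)
    J_e   = 2.5e-4,    # electron-pair flux through the chain at PC
    leak_frac = 0.30,  # fraction of the basal proton current carried by Hle
    J_Kuni = 1e-5,     # basal electrophoretic K+ influx
    glyco_frac = 0.20, # fraction of cytosolic ATP supplied by KDyn at PC
    ros_frac  = 0.005, # H2O2 production as a fraction of electron flux
    ros_nadh_share = 0.8,  # share of PC H2O2 production from the NADH site
    # OCR unit conversion
    mito_volume = 4e-14,     # l mitochondria per neuron
    protein_per_well = 45,   # ug
    neurons_per_well = 3e5
  )
}

# Derive all kinetic scale constants from the designed PC state so that the
# PC state is an exact steady state given the Table-style PC multipliers.
.ox_scales <- function(x, consts) {
  cn <- consts
  st <- .ox_pc_state_design(cn)
  A <- st[["dpsi"]] / cn$rt_f
  g <- A + log(st[["h_i"]] / st[["h_m"]])

  J_e <- cn$J_e
  J_Hle <- cn$leak_frac * 10 * J_e
  J_Kuni <- cn$J_Kuni
  # charge balance: 10 J_e = n_F1 J_F1 + J_ANT + J_Hle + J_Kuni, J_ANT = J_F1
  J_F1 <- (10 * J_e - J_Hle - J_Kuni) / (cn$n_F1 + 1)
  J_ANT <- J_F1
  J_PiC <- J_F1
  J_KHE <- J_Kuni
  J_KDyn <- J_ANT * cn$glyco_frac / (1 - cn$glyco_frac)
  J_KCons <- J_ANT + J_KDyn
  p_ros <- cn$ros_frac * J_e

  D1 <- cn$k_CI - 4 * g
  D3 <- cn$k_CIII - 2 * g
  D4 <- cn$k_CIV - 2 * g - 2 * A
  DF <- cn$n_F1 * g + log(cn$keq_F1)
  drive_CI <- st[["nadh_m"]] * st[["q"]] * exp(D1 / 2) -
    st[["nad_m"]] * st[["qh2"]] * exp(-D1 / 2)
  drive_CIII <- st[["qh2"]] * st[["cox"]]^2 * exp(D3 / 2) -
    st[["q"]] * st[["cred"]]^2 * exp(-D3 / 2)
  fO2 <- st[["o2"]] / (st[["o2"]] + cn$K_O2)
  drive_CIV <- fO2 * (st[["cred"]]^2 * exp(D4 / 2) -
                        st[["cox"]]^2 * exp(-D4 / 2))
  drive_F1 <- st[["adp_m"]] * st[["pi_m"]] * exp(DF / 2) -
    st[["atp_m"]] * exp(-DF / 2)
  drive_ANT <- st[["atp_m"]] * st[["adp_c"]] -
    st[["atp_c"]] * st[["adp_m"]] * exp(-A)
  drive_Hle <- st[["h_i"]] * exp(A / 2) - st[["h_m"]] * exp(-A / 2)
  drive_PiC <- st[["pi_c"]] * st[["h_i"]] - st[["pi_m"]] * st[["h_m"]]
  drive_Kuni <- st[["k_i"]] * exp(A / 2) - st[["k_m"]] * exp(-A / 2)
  drive_KHE <- st[["k_m"]] * st[["h_i"]] - st[["k_i"]] * st[["h_m"]]
  drive_DH <- cn$r_DH * st[["nad_m"]] - st[["nadh_m"]]

  list(
    c_CI   = J_e / (x[["x_CI"]] * drive_CI),
    c_CIII = J_e / (x[["x_CIII"]] * drive_CIII),
    c_CIV  = J_e / (x[["x_CIV"]] * drive_CIV),
    c_F1   = J_F1 / (x[["x_F1"]] * drive_F1),
    c_Hle  = J_Hle / (x[["x_Hle"]] * drive_Hle),
    c_DH   = J_e / (x[["x_DH"]] * drive_DH),
    c_dyn  = J_KDyn / (x[["K_ADTP_dyn"]] * st[["adp_c"]]),
    c_cons = J_KCons / (x[["K_ADTP_cons"]] * st[["atp_c"]]),
    a_ANT  = J_ANT / drive_ANT,
    a_PiC  = J_PiC / drive_PiC,
    a_Kuni = J_Kuni / drive_Kuni,
    a_KHE  = J_KHE / drive_KHE,
    rho_nadh  = cn$ros_nadh_share * p_ros / st[["nadh_m"]],
    rho_qh2   = (1 - cn$ros_nadh_share) * p_ros / st[["qh2"]],
    k_clear_m = 0.6 * p_ros / st[["h2o2_m"]],
    k_diff    = 0.4 * p_ros / (st[["h2o2_m"]] - st[["h2o2_c"]]),
    k_clear_c = 0.4 * p_ros / st[["h2o2_c"]]
  )
}

#' Construct a model parameter set
#'
#' Returns the full parameterization of the oxidative phosphorylation model.
#' The defaults are the physiological condition (PC): the activity rate
#' multipliers of the eight tunable components at their 100%-activity values,
#' plus all derived kinetic, thermodynamic and compartment constants.
#'
#' @param x_CI,x_CIII,x_CIV,x_F1,x_Hle,x_DH Dimensionless activity rate
#'   multipliers for complexes I/III/IV, the F1Fo ATP synthase, the
#'   inner-membrane proton leak and the input dehydrogenase flux.
#' @param K_ADTP_dyn,K_ADTP_cons Cytosolic ATP production and consumption rate
#'   constants.
#' @param ... Overrides for derived kinetic constants (advanced use; names must
#'   match entries of the internal kinetics list).
#' @return An object of class `ox_params`: a list with elements `x` (the eight
#'   multipliers), `kin` (derived kinetic constants), `consts` (physical
#'   constants) and `conv` (OCR unit-conversion constants).
#' @examples
#' p <- ox_params()
#' p$x[["x_CI"]]
#' @export
ox_params <- function(x_CI = 5.75e-5, x_CIII = 6.78e-4, x_CIV = 2.44e-5,
                      x_F1 = 3.86e-7, x_Hle = 1.95e-2, x_DH = 7.55e-3,
                      K_ADTP_dyn = 9.63e-3, K_ADTP_cons = 1.78e-2, ...) {
  x <- c(x_CI = x_CI, x_CIII = x_CIII, x_CIV = x_CIV, x_F1 = x_F1,
         x_Hle = x_Hle, x_DH = x_DH,
         K_ADTP_dyn = K_ADTP_dyn, K_ADTP_cons = K_ADTP_cons)
  if (any(!is.finite(x)) || any(x < 0))
    stop("all rate multipliers must be finite and non-negative")
  consts <- .ox_consts()
  # scales are always derived at the PC multipliers so that impairments act
  # purely through the x multipliers
  x_pc <- c(x_CI = 5.75e-5, x_CIII = 6.78e-4, x_CIV = 2.44e-5, x_F1 = 3.86e-7,
            x_Hle = 1.95e-2, x_DH = 7.55e-3,
            K_ADTP_dyn = 9.63e-3, K_ADTP_cons = 1.78e-2)
  kin <- .ox_scales(x_pc, consts)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(kin))
    if (length(bad)) stop("unknown kinetic constants: ", paste(bad, collapse = ", "))
    kin[names(dots)] <- dots
  }
  structure(list(
    x = x, kin = kin, consts = consts,
    conv = list(mito_volume = consts$mito_volume,
                protein_per_well = consts$protein_per_well,
                neurons_per_well = consts$neurons_per_well)
  ), class = "ox_params")
}

#' @export
print.ox_params <- function(x, ...) {
  cat("<ox_params> oxidative phosphorylation model parameters\n")
  cat("multipliers:\n")
  print(x$x)
  invisible(x)
}

#' Physiological-condition initial state
#'
#' The designed physiological steady state of the model, used as the default
#' initial condition.  For the default [ox_params()] this state is an exact
#' fixed point of the ODE system.
#'
#' @param params An [ox_params()] object (only compartment constants are used).
#' @return Named numeric vector of the 22 state variables.
#' @export
ox_pc_state <- function(params = ox_params()) {
  stopifnot(inherits(params, "ox_params"))
  .ox_pc_state_design(params$consts)
}

# Flatten to the numeric vector handed to the compiled derivative function.
# Order must match src/oxphos.c.
.ox_parvec <- function(params) {
  cn <- params$consts
  k <- params$kin
  x <- params$x
  c(x[["x_CI"]], x[["x_CIII"]], x[["x_CIV"]], x[["x_F1"]], x[["x_Hle"]],
    x[["x_DH"]], x[["K_ADTP_dyn"]], x[["K_ADTP_cons"]],
    k$c_CI, k$c_CIII, k$c_CIV, k$c_F1, k$c_Hle, k$c_DH, k$c_dyn, k$c_cons,
    k$a_ANT, k$a_PiC, k$a_Kuni, k$a_KHE, cn$a_exH, cn$a_exK,
    cn$k_CI, cn$k_CIII, cn$k_CIV, cn$keq_F1, cn$n_F1, cn$r_DH,
    k$rho_nadh, k$rho_qh2, k$k_clear_m, k$k_diff, k$k_clear_c,
    cn$K_O2, cn$rt_f, cn$c_mem, cn$W_m, cn$W_i, cn$V_c, cn$beta_pH)
}

#' Read or write a parameter set as a flat YAML config
#'
#' Serializes the eight activity multipliers (and optionally an initial state)
#' as a flat key/value YAML mapping, and reads such a file back into an
#' [ox_params()] object.
#'
#' @param params An `ox_params` object.
#' @param path File path.
#' @param state Optional named state vector to include under `init`.
#' @return `ox_write_config` returns `path` invisibly; `ox_read_config`
#'   returns a list with elements `params` and (if present) `init`.
#' @export
ox_write_config <- function(params, path, state = NULL) {
  stopifnot(inherits(params, "ox_params"))
  out <- list(parameters = as.list(params$x))
  if (!is.null(state)) out$init <- as.list(state)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname ox_write_config
#' @export
ox_read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- do.call(ox_params, cfg$parameters)
  init <- NULL
  if (!is.null(cfg$init)) {
    init <- unlist(cfg$init)
    init <- init[ox_state_names()]
  }
  list(params = params, init = init)
}
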