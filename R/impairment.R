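# Impairment library: component activity, calibration, graded sweeps and
# resource export.
#
# "Activity" of a component is its steady-state baseline flux as a percentage
# of the physiological-condition (PC) flux.  Because the system redistributes
# flux control when a parameter changes, activity varies non-linearly with
# the parameter value; calibration therefore uses exponential bracketing
# followed by bisection in log-parameter space.

.ox_components <- c("CI", "CIII", "CIV", "F1", "Hle", "DH", "KDyn", "KCons")

.ox_component_param <- c(CI = "x_CI", CIII = "x_CIII", CIV = "x_CIV",
                         F1 = "x_F1", Hle = "x_Hle", DH = "x_DH",
                         KDyn = "K_ADTP_dyn", KCons = "K_ADTP_cons")

.ox_component_flux <- c(CI = "J_CI", CIII = "J_CIII", CIV = "J_CIV",
                        F1 = "J_F1", Hle = "J_Hle", DH = "J_DH",
                        KDyn = "J_KDyn", KCons = "J_KCons")

# analytic PC design fluxes (mol/s/l mito), exact for the default parameters
.ox_pc_fluxes <- function(consts) {
  J_e <- consts$J_e
  J_Hle <- consts$leak_frac * 10 * J_e
  J_F1 <- (10 * J_e - J_Hle - consts$J_Kuni) / (consts$n_F1 + 1)
  J_KDyn <- J_F1 * consts$glyco_frac / (1 - consts$glyco_frac)
  c(J_CI = J_e, J_CIII = J_e, J_CIV = J_e, J_DH = J_e,
    J_F1 = J_F1, J_Hle = J_Hle, J_KDyn = J_KDyn, J_KCons = J_F1 + J_KDyn)
}

#' Component activity as a percentage of the physiological condition
#'
#' Computes the steady-state baseline flux through a component and expresses
#' it relative to the PC steady-state flux of the same component.
#'
#' @param component One of `"CI"`, `"CIII"`, `"CIV"`, `"F1"`, `"Hle"`,
#'   `"DH"`, `"KDyn"`, `"KCons"`.
#' @param params An [ox_params()] object.
#' @return Activity in percent (100 at PC).
#' @export
activity_of <- function(component, params) {
  component <- match.arg(component, .ox_components)
  ss <- ox_steady_state(params)
  if (ss$status != "ok")
    stop("baseline numerically unstable; cannot measure activity of ", component)
  J <- ss$fluxes[[.ox_component_flux[[component]]]]
  J_pc <- .ox_pc_fluxes(params$consts)[[.ox_component_flux[[component]]]]
  100 * J / J_pc
}

#' Calibrate a parameter value to a target component activity
#'
#' Finds the parameter value at which the component's steady-state flux equals
#' `target` percent of its PC flux, by exponential bracketing and bisection in
#' log-parameter space.  Activity 100 returns the PC parameter value exactly.
#'
#' @param component Component name (see [activity_of()]).
#' @param target Target activity, percent.  Allowed range is \[2, 100\] for
#'   all components, extended to (100, 1000\] for `Hle`.
#' @param params Base parameter set (defaults to PC).
#' @param tol Tolerance in percentage points (default 0.5).
#' @param max_iter Maximum bisection iterations.
#' @return List with `value` (the resolved parameter), `params` (parameter set
#'   with the value applied), `activity` (achieved activity) and `component`.
#' @export
calibrate_activity <- function(component, target, params = ox_params(),
                               tol = 0.5, max_iter = 60) {
  component <- match.arg(component, .ox_components)
  hi_ok <- if (component == "Hle") 1000 else 100
  if (target < 2 || target > hi_ok)
    stop("target activity for ", component, " must be in [2, ", hi_ok, "]")
  pname <- .ox_component_param[[component]]
  p_pc <- ox_params()$x[[pname]]
  set_p <- function(v) { params$x[[pname]] <- v; params }
  if (target == 100)
    return(list(value = p_pc, params = set_p(p_pc),
                activity = 100, component = component))
  act <- function(v) tryCatch(activity_of(component, set_p(v)),
                              error = function(e) NA_real_)
  # exponential bracketing from the proportional first guess
  v0 <- p_pc * target / 100
  a0 <- act(v0)
  if (is.na(a0)) { v0 <- p_pc; a0 <- 100 }
  lo <- hi <- v0; a_lo <- a_hi <- a0
  iter <- 0
  while (a_hi < target && iter < 40) {
    hi <- hi * 2; a_hi <- act(hi); iter <- iter + 1
    if (is.na(a_hi)) stop("activity evaluation unstable near parameter ", hi)
    if (hi > p_pc * 1e6)
      stop("activity ", target, "% not reachable; achievable <= ", a_hi, "%")
  }
  iter <- 0
  while (a_lo > target && iter < 60) {
    lo <- lo / 2; a_lo <- act(lo); iter <- iter + 1
    if (is.na(a_lo)) stop("activity evaluation unstable near parameter ", lo)
    if (lo < p_pc * 1e-9)
      stop("activity ", target, "% not reachable; achievable >= ", a_lo, "%")
  }
  # bisection in log space
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    a_mid <- act(mid)
    if (is.na(a_mid)) a_mid <- target  # accept midpoint; instability logged upstream
    if (abs(a_mid - target) <= tol)
      return(list(value = mid, params = set_p(mid), activity = a_mid,
                  component = component))
    if (a_mid < target) { lo <- mid; a_lo <- a_mid } else { hi <- mid; a_hi <- a_mid }
  }
  mid <- sqrt(lo * hi)
  list(value = mid, params = set_p(mid), activity = act(mid),
       component = component)
}

#' Sweep graded impairments across components
#'
#' Crosses the requested components with an activity grid and runs the metric
#' battery for every cell, returning a long-format table of population
#' medians and quartiles.  Per-cell numerical instability is recorded in the
#' `status` column, not fatal.
#'
#' @param components Character vector of component names.
#' @param grid Numeric vector of activity levels (percent of PC), or a named
#'   list mapping component name to its own grid (e.g. an extended grid for
#'   `Hle`).
#' @param experiments Experiments to run per cell (see [ox_experiments()]).
#' @param n Population size per cell.
#' @param seed Integer seed (each cell derives its own sub-seed).
#' @param variation Population variability sd.
#' @return A `data.frame` with columns `component`, `activity`, `param_value`,
#'   `experiment`, `readout`, `n`, `median`, `q1`, `q3`, `status`.
#' @export
ox_sweep <- function(components = .ox_components,
                     grid = seq(2, 100, by = 2),
                     experiments = c("basal", "stress_test"),
                     n = 50, seed = 1, variation = 0.2) {
  components <- match.arg(components, .ox_components, several.ok = TRUE)
  read_exp <- function(r) {
    for (e in ox_experiments()) if (r %in% ox_readouts(e)) return(e)
    NA_character_
  }
  rows <- list()
  cell <- 0
  for (comp in components) {
    cgrid <- if (is.list(grid)) grid[[comp]] else grid
    for (lev in cgrid) {
      cell <- cell + 1
      cell_seed <- (seed * 10007 + cell * 131) %% 2147483647
      rec <- tryCatch({
        cal <- calibrate_activity(comp, lev)
        met <- ox_condition_metrics(cal$params, experiments = experiments,
                                    n = n, variation = variation,
                                    seed = cell_seed,
                                    nudge_param = .ox_component_param[[comp]])
        reads <- names(met$median)
        data.frame(component = comp, activity = lev, param_value = cal$value,
                   experiment = vapply(reads, read_exp, ""),
                   readout = reads, n = n,
                   median = unname(met$median), q1 = unname(met$q1),
                   q3 = unname(met$q3),
                   status = if (length(met$unstable)) "partial" else "ok",
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(component = comp, activity = lev, param_value = NA_real_,
                   experiment = NA_character_, readout = NA_character_,
                   n = n, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                   status = paste0("unstable: ", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a sweep as a resource workbook (directory of CSV sheets)
#'
#' Writes one CSV "sheet" per experiment (rows: component and activity level;
#' columns: readout medians), a mirrored category sheet per experiment when the
#' sweep has been categorized (a `category` column is present), and a
#' provenance sheet listing settings and any partial/unstable cells.
#'
#' @param sweep A sweep table from [ox_sweep()] (optionally with a `category`
#'   column from [categorize_sweep()]).
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
export_resource <- function(sweep, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ok <- !is.na(sweep$experiment)
  sheets <- unique(sweep$experiment[ok])
  for (e in sheets) {
    sub <- sweep[ok & sweep$experiment == e, ]
    wide <- stats::reshape(
      sub[, c("component", "activity", "readout", "median")],
      idvar = c("component", "activity"), timevar = "readout",
      direction = "wide")
    names(wide) <- sub("^median\\.", "", names(wide))
    utils::write.csv(wide, file.path(path, paste0(e, ".csv")),
                     row.names = FALSE)
    if ("category" %in% names(sweep)) {
      widec <- stats::reshape(
        sub[, c("component", "activity", "readout", "category")],
        idvar = c("component", "activity"), timevar = "readout",
        direction = "wide")
      names(widec) <- sub("^category\\.", "", names(widec))
      utils::write.csv(widec, file.path(path, paste0(e, "_categories.csv")),
                       row.names = FALSE)
    }
  }
  prov <- data.frame(
    key = c("sheets", "cells", "flagged_cells"),
    value = c(paste(sheets, collapse = ";"),
              nrow(unique(sweep[, c("component", "activity")])),
              sum(sweep$status != "ok", na.rm = TRUE)))
  flagged <- unique(sweep[sweep$status != "ok",
                          c("component", "activity", "status")])
  utils::write.csv(prov, file.path(path, "provenance.csv"), row.names = FALSE)
  if (nrow(flagged))
    utils::write.csv(flagged, file.path(path, "provenance_flagged.csv"),
                     row.names = FALSE)
  invisible(path)
}
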