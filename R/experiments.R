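# Virtual experiments: the mitochondrial stress test, inhibitor fold-change
# responses, and the per-condition metric battery used by sweeps and
# phenotype matching.
#
# Timing conventions (emulating the wet protocols): single-drug experiments
# run 20 min of baseline, drug at t = 1200 s, post-drug readout 20 min after
# the event; the baseline value is the mean over the final 8 min before the
# drug.  The stress test injects oligomycin / FCCP / antimycin A at 20/40/60
# min and each phase OCR is the median over the final 5 min of the phase.

.ox_drug_keys <- c(oligo = "oligomycin", rot = "rotenone",
                   antia = "antimycin_a", fccp = "fccp")

#' Experiment names understood by the metric battery
#' @return Character vector: `"basal"` (steady-state readouts),
#'   `"basal_flux"` (steady-state OCR, no drug protocol), `"stress_test"` and
#'   the four single-drug fold-change experiments (`"oligo"`, `"rot"`,
#'   `"antia"`, `"fccp"`).
#' @export
ox_experiments <- function() c("basal", "basal_flux", "stress_test",
                               names(.ox_drug_keys))

#' Readout names produced by each experiment
#' @param experiments Subset of [ox_experiments()].
#' @return Character vector of readout (feature) names.
#' @export
ox_readouts <- function(experiments = ox_experiments()) {
  out <- character()
  for (e in experiments) {
    out <- c(out, switch(e,
      basal = c("dpsi", "atp_m", "atp_c", "nadh", "h2o2"),
      basal_flux = "basal_ocr_ss",
      stress_test = c("basal_ocr", "leak_ocr", "max_ocr"),
      paste0(c("fc_dpsi_", "fc_nadh_", "fc_atp_m_", "fc_h2o2_", "resp_dpsi_"), e)
    ))
  }
  out
}

# OCR (experimental units) from a trajectory's CIV flux
.ox_traj_ocr <- function(traj, conv) {
  ocr_from_flux(pmax(traj$fluxes[, "J_CIV"], 0) / 2, conv)
}

# metrics for one member; returns named vector (NA on instability)
.ox_member_metrics <- function(params, steady, experiments, conv) {
  out <- stats::setNames(rep(NA_real_, length(ox_readouts(experiments))),
                         ox_readouts(experiments))
  st <- steady$state
  if ("basal" %in% experiments) {
    out[c("dpsi", "atp_m", "atp_c", "nadh", "h2o2")] <-
      st[c("dpsi", "atp_m", "atp_c", "nadh_m", "h2o2_c")]
  }
  if ("basal_flux" %in% experiments) {
    out["basal_ocr_ss"] <- ocr_from_flux(max(steady$fluxes[["J_CIV"]], 0) / 2,
                                         conv)
  }
  if ("stress_test" %in% experiments) {
    tr <- ox_simulate(params, drug_preset("stress_test"), duration = 4800,
                      init = st, dt = 30)
    if (tr$status != "ok") return(list(metrics = out, ok = FALSE))
    ocr <- .ox_traj_ocr(tr, conv)
    phase <- function(a, b) stats::median(ocr[tr$times >= a & tr$times <= b])
    out["basal_ocr"] <- phase(900, 1200)
    out["leak_ocr"] <- phase(2100, 2400)
    out["max_ocr"] <- phase(3300, 3600)
  }
  for (e in intersect(names(.ox_drug_keys), experiments)) {
    tr <- ox_simulate(params, drug_preset(.ox_drug_keys[[e]], t_drug = 1200),
                      duration = 2400, init = st, dt = 30)
    if (tr$status != "ok") return(list(metrics = out, ok = FALSE))
    pre <- tr$times >= 720 & tr$times <= 1200
    ipost <- which.min(abs(tr$times - 2400))
    for (v in c("dpsi", "nadh_m", "atp_m", "h2o2_c")) {
      base <- mean(tr$state[pre, v])
      if (abs(base) < .Machine$double.eps * 100)
        stop("baseline ~ 0 for readout ", v, "; foldchange undefined")
      key <- c(dpsi = "fc_dpsi_", nadh_m = "fc_nadh_", atp_m = "fc_atp_m_",
               h2o2_c = "fc_h2o2_")[[v]]
      out[paste0(key, e)] <- tr$state[ipost, v] / base
    }
    out[paste0("resp_dpsi_", e)] <- abs(1 - out[paste0("fc_dpsi_", e)])
  }
  list(metrics = out, ok = all(is.finite(out[ox_readouts(experiments)])))
}

#' Population metric battery for one condition
#'
#' Draws a seeded population (parameter and initial-concentration variability),
#' finds each member's basal steady state, runs the requested experiments for
#' each member, and summarises every readout by its population median and
#' quartiles.  The numerical-stability retry rule is applied when
#' `nudge_param` is given: with three or more unstable members, the named
#' parameter is varied in its 4th significant decimal and the condition rerun.
#'
#' @param params Condition parameter set ([ox_params()]).
#' @param experiments Subset of [ox_experiments()].
#' @param n Population size.
#' @param variation Variability sd (fraction, default 0.2).
#' @param seed Integer seed.
#' @param nudge_param Optional parameter name for the stability retry rule.
#' @param max_retries Retry budget.
#' @return List with `values` (n x readouts matrix), `median`, `q1`, `q3`
#'   (named vectors), `unstable` (member indices), `nudged` (retries used).
#' @export
ox_condition_metrics <- function(params, experiments = ox_experiments(),
                                 n = 50, variation = 0.2, seed = 1,
                                 nudge_param = NULL, max_retries = 20) {
  reads <- ox_readouts(experiments)
  base_init <- ox_pc_state(params)
  for (attempt in 0:max_retries) {
    set.seed(seed)
    vals <- matrix(NA_real_, n, length(reads), dimnames = list(NULL, reads))
    unstable <- integer()
    for (i in seq_len(n)) {
      pert <- .ox_perturb(params, base_init, variation)
      ss <- tryCatch(ox_steady_state(pert$params, pert$init),
                     error = function(e) list(status = "numerically-unstable"))
      if (ss$status != "ok") { unstable <- c(unstable, i); next }
      mm <- tryCatch(.ox_member_metrics(pert$params, ss, experiments, params$conv),
                     error = function(e) list(metrics = vals[i, ], ok = FALSE))
      vals[i, ] <- mm$metrics[reads]
      if (!mm$ok) unstable <- c(unstable, i)
    }
    if (length(unstable) < 3 || is.null(nudge_param)) {
      keep <- setdiff(seq_len(n), unstable)
      if (!length(keep))
        return(list(values = vals, median = stats::setNames(rep(NA_real_, length(reads)), reads),
                    q1 = NULL, q3 = NULL, unstable = unstable, nudged = attempt))
      med <- apply(vals[keep, , drop = FALSE], 2, stats::median)
      q1 <- apply(vals[keep, , drop = FALSE], 2, stats::quantile, 0.25, names = FALSE)
      q3 <- apply(vals[keep, , drop = FALSE], 2, stats::quantile, 0.75, names = FALSE)
      return(list(values = vals, median = med,
                  q1 = stats::setNames(q1, reads), q3 = stats::setNames(q3, reads),
                  unstable = unstable, nudged = attempt))
    }
    params$x[[nudge_param]] <- .ox_nudge(params$x[[nudge_param]])
  }
  stop("condition numerically unstable after ", max_retries,
       " retries; unstable members: ", paste(unstable, collapse = ", "))
}

#' Simulated mitochondrial stress test
#'
#' Runs the sequential oligomycin / FCCP / antimycin-A protocol on a seeded
#' population and reports the per-phase OCR metrics (basal, oligomycin-
#' insensitive "leak", and FCCP-induced maximal OCR) in experimental units
#' (mol O2/min/ug protein), together with basal-state summaries.
#'
#' @inheritParams ox_condition_metrics
#' @return A `bioenergetic_metrics` list: `median`, `q1`, `q3` over the
#'   population for `basal_ocr`, `leak_ocr`, `max_ocr` and the basal readouts,
#'   plus the raw per-member `values`.
#' @export
mito_stress_test <- function(params, n = 50, seed = 1, variation = 0.2,
                             nudge_param = NULL) {
  res <- ox_condition_metrics(params, experiments = c("basal", "stress_test"),
                              n = n, variation = variation, seed = seed,
                              nudge_param = nudge_param)
  structure(res, class = "bioenergetic_metrics")
}

#' @export
print.bioenergetic_metrics <- function(x, ...) {
  cat("<bioenergetic_metrics>\n")
  print(signif(x$median, 4))
  invisible(x)
}

#' Inhibitor fold-change response
#'
#' Simulates a single inhibitor addition on a seeded population and returns
#' the per-member fold-change (post-drug value / pre-drug baseline) of the
#' requested readout, plus its median.
#'
#' @param params Condition parameters.
#' @param drug One of `"oligomycin"`, `"rotenone"`, `"antimycin_a"`, `"fccp"`.
#' @param readout One of `"dpsi"`, `"nadh"`, `"atp_m"`, `"h2o2"`.
#' @param n,seed,variation Population settings.
#' @return List with `fc` (per-member fold-changes) and `median`.
#' @export
inhibitor_response <- function(params, drug = "oligomycin", readout = "dpsi",
                               n = 50, seed = 1, variation = 0.2) {
  key <- names(.ox_drug_keys)[match(drug, .ox_drug_keys)]
  if (is.na(key)) stop("unknown drug preset: ", drug)
  readout <- match.arg(readout, c("dpsi", "nadh", "atp_m", "h2o2"))
  res <- ox_condition_metrics(params, experiments = key, n = n,
                              variation = variation, seed = seed)
  col <- paste0("fc_", c(dpsi = "dpsi", nadh = "nadh", atp_m = "atp_m",
                         h2o2 = "h2o2")[[readout]], "_", key)
  fc <- res$values[, col]
  list(fc = fc, median = stats::median(fc, na.rm = TRUE))
}
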