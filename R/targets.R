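# Headline quantitative analyses: reactive-oxygen severity ordering,
# threshold-percentile correspondence, and the categorized response
# boundaries for oligomycin membrane-potential fold-change (vs Complex-I
# activity) and OCR suppression (vs proton-leak activity).
#
# These functions recompute each quantity from scratch by running the model;
# they back both the acceptance script and the test suite.

#' H2O2 increase ratio: CIII/CIV vs CI impairment
#'
#' Calibrates CI, CIII and CIV each to the given severe activity level, runs
#' seeded baseline populations for each condition plus the physiological
#' condition (identical seeds, so member variability is paired), and reports
#' the ratio of the median basal cytosolic H2O2 increase over PC under
#' CIII (and CIV) impairment to that under CI impairment.
#'
#' @param activity Severe activity level, percent of PC (default 20).
#' @param n Population size per condition (default 50).
#' @param seed Integer seed.
#' @return List with `ratio_ciii`, `ratio_civ`, `increase` (named vector of
#'   median H2O2 increases) and `pc_median`.
#' @export
h2o2_severity_ratio <- function(activity = 20, n = 50, seed = 1) {
  pc <- ox_condition_metrics(ox_params(), "basal", n = n, seed = seed)
  inc <- vapply(c("CI", "CIII", "CIV"), function(comp) {
    cal <- calibrate_activity(comp, activity)
    met <- ox_condition_metrics(cal$params, "basal", n = n, seed = seed,
                                nudge_param = .ox_component_param[[comp]])
    met$median[["h2o2"]] - pc$median[["h2o2"]]
  }, 0)
  list(ratio_ciii = inc[["CIII"]] / inc[["CI"]],
       ratio_civ = inc[["CIV"]] / inc[["CI"]],
       increase = inc, pc_median = pc$median[["h2o2"]])
}

#' Percentile rank of the -25% / +25% values in the PC basal-OCR population
#'
#' Simulates `n` physiological-condition baseline steady states with seeded
#' population variability, forms the basal OCR distribution, and locates the
#' values 25% below and above the population median as empirical percentile
#' ranks.
#'
#' @param n Population size (default 1000).
#' @param seed Integer seed.
#' @return List with `pct_lo` (percentile of median x 0.75), `pct_hi`
#'   (percentile of median x 1.25), `cv` and `n_ok`.
#' @export
ocr_percentile_spread <- function(n = 1000, seed = 1) {
  met <- ox_condition_metrics(ox_params(), "basal_flux", n = n, seed = seed)
  ocr <- met$values[, "basal_ocr_ss"]
  ocr <- ocr[is.finite(ocr)]
  m <- stats::median(ocr)
  list(pct_lo = 100 * mean(ocr <= 0.75 * m),
       pct_hi = 100 * mean(ocr <= 1.25 * m),
       cv = stats::sd(ocr) / mean(ocr), n_ok = length(ocr))
}

# shared scan-and-refine: largest activity level whose condition codes as a
# decrease, on a coarse grid refined at 2% steps near the boundary
.ox_boundary_scan <- function(component, levels, n, seed, is_decreased,
                              refine_step = 2) {
  dec <- vapply(levels, function(lev) is_decreased(lev, n, seed), TRUE)
  if (!any(dec)) return(NA_real_)
  largest <- max(levels[dec])
  above <- levels[levels > largest]
  if (length(above)) {
    nxt <- min(above)
    fine <- seq(largest + refine_step, nxt - refine_step, by = refine_step)
    for (lev in fine) {
      if (is_decreased(lev, n, seed)) largest <- lev else break
    }
  }
  largest
}

#' Largest CI activity with a categorized-decreased oligomycin response
#'
#' Sweeps Complex-I activity on a coarse 10%-grid refined to 2% near the
#' boundary.  At each level the oligomycin membrane-potential fold-change is
#' computed on a seeded population and its median categorized against the PC
#' fold-change reference; the largest level in any decrease grade is
#' returned.  This locates the onset of the blunted/reversed oligomycin
#' response caused by ATP-synthase reversal under severe CI impairment.
#'
#' @param n Population size per level (default 25).
#' @param seed Integer seed.
#' @param ref_n PC reference population size (default 200).
#' @param levels Coarse activity grid (default 10 to 100 by 10).
#' @return List with `largest_decreased` (activity percent) and `pc_fc`
#'   (PC reference fold-change median).
#' @export
oligo_dpsi_crossover <- function(n = 25, seed = 1, ref_n = 200,
                                 levels = seq(10, 100, by = 10)) {
  pc <- ox_condition_metrics(ox_params(), "oligo", n = ref_n, seed = seed)
  pc_fc <- pc$median[["fc_dpsi_oligo"]]
  is_dec <- function(lev, n, seed) {
    cal <- calibrate_activity("CI", lev)
    met <- ox_condition_metrics(cal$params, "oligo", n = n, seed = seed,
                                nudge_param = "x_CI")
    encode_category(categorize_value(met$median[["fc_dpsi_oligo"]], pc_fc)) <= -1L
  }
  list(largest_decreased = .ox_boundary_scan("CI", levels, n, seed, is_dec),
       pc_fc = pc_fc)
}

#' Largest proton-leak activity with all OCR metrics categorized decreased
#'
#' Sweeps proton-leak activity below 100% on a coarse grid refined to 2% near
#' the boundary, runs the simulated mitochondrial stress test at each level,
#' and categorizes the basal, leak (oligomycin-insensitive) and maximal OCR
#' medians against the PC reference.  Returns the largest level at which all
#' three are in a decrease category.
#'
#' @param n Population size per level (default 25).
#' @param seed Integer seed.
#' @param ref_n PC reference population size (default 200).
#' @param levels Coarse activity grid (default 10 to 90 by 10).
#' @return List with `largest_decreased` (activity percent) and `pc_median`
#'   (PC OCR medians).
#' @export
leak_ocr_suppression <- function(n = 25, seed = 1, ref_n = 200,
                                 levels = seq(10, 90, by = 10)) {
  pc <- ox_condition_metrics(ox_params(), "stress_test", n = ref_n, seed = seed)
  mets <- c("basal_ocr", "leak_ocr", "max_ocr")
  is_dec <- function(lev, n, seed) {
    cal <- calibrate_activity("Hle", lev)
    met <- ox_condition_metrics(cal$params, "stress_test", n = n, seed = seed,
                                nudge_param = "x_Hle")
    all(vapply(mets, function(r)
      encode_category(categorize_value(met$median[[r]], pc$median[[r]])) <= -1L,
      TRUE))
  }
  list(largest_decreased = .ox_boundary_scan("Hle", levels, n, seed, is_dec),
       pc_median = pc$median[mets])
}
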