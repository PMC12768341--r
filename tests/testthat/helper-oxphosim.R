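# Shared fixtures for the test suite.  Built once per session and cached;
# sizes are kept small (populations of 8-12) so the suite stays fast while
# preserving the qualitative behaviour under test.

.fixture_env <- new.env(parent = emptyenv())

fixture_ref <- function() {
  if (is.null(.fixture_env$ref)) {
    .fixture_env$ref <- build_pc_reference(
      n = 150, seed = 101,
      experiments = c("basal", "stress_test", "oligo", "rot", "antia"))
  }
  .fixture_env$ref
}

# small defect library across all 8 components (coarse grids), categorized
fixture_library <- function() {
  if (is.null(.fixture_env$lib)) {
    grids <- list(CI = c(20, 40, 60, 80), CIII = c(20, 60), CIV = c(20, 60),
                  F1 = c(20, 50, 80), DH = c(20, 50, 80, 90, 96),
                  Hle = c(20, 50, 80, 150, 250, 350, 500),
                  KDyn = c(10, 20, 50, 80), KCons = c(20, 40, 60, 80))
    sw <- ox_sweep(components = names(grids), grid = grids,
                   experiments = c("basal", "stress_test", "antia", "rot"),
                   n = 20, seed = 202)
    .fixture_env$lib <- categorize_sweep(sw, fixture_ref())
  }
  .fixture_env$lib
}

# seed-paired median ratios: the impaired and PC populations share the same
# seed, hence identical member variability factors, so per-member ratios
# cancel most sampling noise (essential for high-CV readouts such as ATP_m)
paired_ratios <- function(params, experiments = c("basal", "stress_test"),
                          n = 12, seed = 71, nudge_param = NULL) {
  key <- paste(c(experiments, n, seed), collapse = "|")
  if (is.null(.fixture_env$pc)) .fixture_env$pc <- list()
  if (is.null(.fixture_env$pc[[key]]))
    .fixture_env$pc[[key]] <- ox_condition_metrics(ox_params(), experiments,
                                                   n = n, seed = seed)
  pc <- .fixture_env$pc[[key]]
  met <- ox_condition_metrics(params, experiments, n = n, seed = seed,
                              nudge_param = nudge_param)
  apply(met$values / pc$values, 2, stats::median, na.rm = TRUE)
}

fixture_matrix <- function(features = c("basal_ocr", "leak_ocr", "max_ocr",
                                        "dpsi", "nadh", "atp_m", "h2o2")) {
  phenotype_matrix(fixture_library(), features = features)
}

# suppress solver chatter written by the Fortran core to stdout
quiet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) invokeRestart("muffleWarning"))
}
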