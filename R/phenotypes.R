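# Experimental phenotype fixtures and the synthetic-phenotype generator.
#
# Coding convention for experimental data: statistically significant,
# visually large changes are coded +/-2 (the minimal experimentally
# detectable grade); non-significant changes are coded 0.  Inhibitor
# "sensitivity" features are coded on the response magnitude |1 - FC| of the
# membrane-potential fold-change, so a blunted depolarization codes as a
# decrease.  Codes are overridable by editing the YAML fixture.

#' Built-in experimental phenotypes
#'
#' The three case-study phenotypes shipped with the package, read from the
#' YAML fixture in `inst/extdata/phenotypes.yaml`:
#' \describe{
#'   \item{tgad}{Transgenic Alzheimer's cortical neurons: unchanged basal and
#'     leak OCR, decreased maximal OCR.}
#'   \item{park}{Parkin-knockout dopaminergic neurons: increased basal OCR,
#'     unchanged maximal OCR, reduced mitochondrial ATP.}
#'   \item{pink1}{Pink1-knockout cortical neurons: decreased basal and maximal
#'     OCR, unchanged leak OCR, reduced membrane-potential response to
#'     antimycin A, unchanged response to rotenone.}
#' }
#'
#' @param names Optional subset of phenotype names.
#' @return Named list of `named_phenotype` objects (name, codes, provenance).
#' @export
builtin_phenotypes <- function(names = NULL) {
  path <- system.file("extdata", "phenotypes.yaml", package = "oxphosim")
  phen <- read_phenotypes(path)
  if (!is.null(names)) {
    if (!length(names)) stop("empty phenotype request")
    missing <- setdiff(names, base::names(phen))
    if (length(missing)) stop("unknown phenotype(s): ", paste(missing, collapse = ", "))
    phen <- phen[names]
  }
  phen
}

#' Read / write phenotypes as YAML
#'
#' @param path YAML file path.
#' @param phenotypes Named list of `named_phenotype` objects.
#' @return `read_phenotypes` returns a named list of `named_phenotype`;
#'   `write_phenotypes` returns `path` invisibly.
#' @export
read_phenotypes <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(base::names(raw), function(nm) {
    ph <- raw[[nm]]
    codes <- unlist(ph$codes)
    storage.mode(codes) <- "integer"
    if (any(codes < -3 | codes > 3)) stop("codes must lie in -3..3: ", nm)
    structure(list(name = nm, codes = codes,
                   provenance = ph$provenance %||% ""),
              class = "named_phenotype")
  })
  stats::setNames(out, base::names(raw))
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(phenotypes, path) {
  raw <- lapply(phenotypes, function(ph)
    list(codes = as.list(ph$codes), provenance = ph$provenance))
  yaml::write_yaml(raw, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.named_phenotype <- function(x, ...) {
  cat("<named_phenotype> ", x$name, "\n", sep = "")
  print(x$codes)
  invisible(x)
}

#' Generate a synthetic experimental phenotype from known defects
#'
#' Simulates the generating defect(s), categorizes and encodes the requested
#' features against the PC reference, then flips each code by +/-1 with
#' probability `noise` (clamped to -3..3).  Used to test end-to-end defect
#' recovery.
#'
#' @param defects Named numeric vector: component name -> activity (% of PC),
#'   e.g. `c(DH = 20)` or `c(DH = 84, KCons = 40)`.
#' @param features Feature (readout) names to include.
#' @param reference A `pc_reference` covering the features.
#' @param noise Per-feature probability of a +/-1 code flip, in \[0, 1\].
#' @param seed Integer seed.
#' @param n Population size for the generating simulation.
#' @param variation Population variability sd.
#' @return A `named_phenotype` with attribute `"true_codes"` (pre-noise).
#' @export
make_synthetic_phenotype <- function(defects, features, reference,
                                     noise = 0, seed = 1, n = 25,
                                     variation = 0.2) {
  stopifnot(noise >= 0, noise <= 1)
  p <- ox_params()
  for (comp in names(defects)) {
    cal <- calibrate_activity(comp, defects[[comp]])
    p$x[[.ox_component_param[[comp]]]] <- cal$value
  }
  need_exp <- unique(reference$experiment[match(features, reference$readout)])
  if (anyNA(need_exp)) stop("features missing from the reference")
  met <- ox_condition_metrics(p, experiments = need_exp, n = n,
                              variation = variation, seed = seed,
                              nudge_param = .ox_component_param[[names(defects)[1]]])
  med <- met$median[features]
  refm <- reference$median[match(features, reference$readout)]
  codes <- encode_category(categorize_value(med, refm))
  names(codes) <- features
  true_codes <- codes
  set.seed(seed)
  flip <- stats::runif(length(codes)) < noise
  sign_flip <- sample(c(-1L, 1L), length(codes), replace = TRUE)
  codes[flip] <- pmin(3L, pmax(-3L, codes[flip] + sign_flip[flip]))
  nm <- paste0("synthetic_", paste(names(defects), defects, sep = "",
                                   collapse = "_"))
  structure(list(name = nm, codes = codes,
                 provenance = sprintf("synthetic (noise %.2f, seed %d)",
                                      noise, seed)),
            class = "named_phenotype", true_codes = true_codes)
}
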