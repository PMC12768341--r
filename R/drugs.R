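# Virtual pharmacology: drug events, protocols and presets.
#
# Inhibitor doses common in primary-neuron work (oligomycin 2 ug/ml,
# rotenone 2 uM, antimycin A 1 uM) are mapped to near-complete inhibition of
# their targets (multiplier 0.005); FCCP multiplies the current proton-leak
# multiplier by 10.  The FCCP action is multiplicative on the *current*
# (possibly impaired) x_Hle, which is what produces the reduced maximal OCR
# under low proton leak.

.ox_drug_presets <- list(
  oligomycin  = list(target = "x_F1",   action = "multiply", magnitude = 5e-4),
  rotenone    = list(target = "x_CI",   action = "multiply", magnitude = 5e-4),
  antimycin_a = list(target = "x_CIII", action = "multiply", magnitude = 5e-4),
  fccp        = list(target = "x_Hle",  action = "multiply", magnitude = 10)
)

#' Create a drug event
#'
#' @param time Event time, s.
#' @param target Name of the targeted parameter (a field of the multiplier
#'   vector, e.g. `"x_F1"`).
#' @param action `"multiply"` (scale the current value) or `"set"`.
#' @param magnitude Positive scaling factor or new value.
#' @return A `drug_event` list.
#' @export
drug_event <- function(time, target, action = c("multiply", "set"), magnitude) {
  action <- match.arg(action)
  if (!is.numeric(magnitude) || magnitude <= 0)
    stop("event magnitude must be > 0")
  valid <- c("x_CI", "x_CIII", "x_CIV", "x_F1", "x_Hle", "x_DH",
             "K_ADTP_dyn", "K_ADTP_cons")
  if (!target %in% valid)
    stop("unknown target parameter: ", target)
  structure(list(time = time, target = target, action = action,
                 magnitude = magnitude), class = "drug_event")
}

#' Create a drug protocol
#'
#' A time-ordered list of [drug_event()]s.  Named presets are available via
#' [drug_preset()].
#'
#' @param ... `drug_event` objects.
#' @return A `drug_protocol` list.
#' @export
drug_protocol <- function(...) {
  events <- list(...)
  ok <- vapply(events, inherits, TRUE, "drug_event")
  if (length(events) && !all(ok)) stop("all arguments must be drug_event objects")
  structure(list(events = events), class = "drug_protocol")
}

#' Named drug protocols
#'
#' `"oligomycin"`, `"rotenone"`, `"antimycin_a"` and `"fccp"` apply the single
#' corresponding event at `t_drug`.  `"stress_test"` is the simulated
#' mitochondrial stress test: sequential oligomycin, FCCP and antimycin A at
#' 20/40/60 minutes.
#'
#' @param name Preset name.
#' @param t_drug Event time for single-drug presets, s.
#' @return A `drug_protocol`.
#' @export
drug_preset <- function(name = c("oligomycin", "rotenone", "antimycin_a",
                                 "fccp", "stress_test"), t_drug = 1200) {
  name <- match.arg(name)
  if (name == "stress_test") {
    ev <- function(nm, tt) {
      d <- .ox_drug_presets[[nm]]
      drug_event(tt, d$target, d$action, d$magnitude)
    }
    return(drug_protocol(ev("oligomycin", 1200), ev("fccp", 2400),
                         ev("antimycin_a", 3600)))
  }
  d <- .ox_drug_presets[[name]]
  drug_protocol(drug_event(t_drug, d$target, d$action, d$magnitude))
}

#' Apply a drug event to a parameter set
#'
#' @param params An [ox_params()] object.
#' @param event A [drug_event()].
#' @return Modified `ox_params`.
#' @export
apply_event <- function(params, event) {
  stopifnot(inherits(params, "ox_params"), inherits(event, "drug_event"))
  cur <- params$x[[event$target]]
  params$x[[event$target]] <- switch(event$action,
                                     multiply = cur * event$magnitude,
                                     set = event$magnitude)
  params
}

#' Convert a Complex-IV flux to an experimental-units OCR
#'
#' OCR (mol O2/min/ug protein) = J (mol O2/s/l mito) x mitochondrial volume
#' (4e-14 l/neuron) x neurons/well (300,000) x 60 / protein per well (45 ug).
#'
#' @param J_O2 Oxygen-consuming flux, mol O2/s per litre of mitochondria.
#' @param conv Conversion constants (defaults from [ox_params()]).
#' @return OCR in mol O2/min/ug protein.
#' @export
ocr_from_flux <- function(J_O2, conv = ox_params()$conv) {
  if (any(J_O2 < 0)) stop("negative oxygen flux is unphysical")
  J_O2 * conv$mito_volume * conv$neurons_per_well * 60 / conv$protein_per_well
}
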