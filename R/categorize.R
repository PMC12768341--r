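# Qualitative categorization of simulated outputs against the physiological
# reference distribution.
#
# Thresholds are analytic: +/-10%, +/-25% and +/-40% of the PC median of each
# (experiment, readout).  Seven categories result; outputs deviating >= 25%
# (codes +/-2, +/-3) are considered experimentally detectable.  Boundary ties
# go to the more extreme bin.

.ox_categories <- c("decrease---", "decrease--", "decrease-", "no change",
                    "increase+", "increase++", "increase+++")
.ox_codes <- stats::setNames(-3:3, .ox_categories)

#' Build the physiological-condition reference
#'
#' Simulates the requested experiments in the physiological condition (no
#' defect) on a seeded population and records, for every readout, the
#' population median and the six categorization thresholds at -40/-25/-10/
#' +10/+25/+40% of that median.
#'
#' @param n Population size (default 1000).
#' @param seed Integer seed.
#' @param experiments Experiments to include (see [ox_experiments()]).
#' @param variation Population variability sd.
#' @param params PC parameters (defaults to [ox_params()]).
#' @return An object of class `pc_reference`: data frame with columns
#'   `experiment`, `readout`, `median`, `lo40`, `lo25`, `lo10`, `hi10`,
#'   `hi25`, `hi40`, `n`, `seed`; the population values matrix is attached as
#'   attribute `"values"`.
#' @export
build_pc_reference <- function(n = 1000, seed = 1,
                               experiments = ox_experiments(),
                               variation = 0.2, params = ox_params()) {
  if (n < 100) stop("PC reference requires n >= 100")
  met <- ox_condition_metrics(params, experiments = experiments, n = n,
                              variation = variation, seed = seed)
  if (length(met$unstable) > 0.05 * n)
    stop("instability in more than 5% of PC members (",
         length(met$unstable), "/", n, ")")
  reads <- names(met$median)
  read_exp <- function(r) {
    for (e in ox_experiments()) if (r %in% ox_readouts(e)) return(e)
    NA_character_
  }
  m <- met$median
  ref <- data.frame(
    experiment = vapply(reads, read_exp, ""), readout = reads,
    median = unname(m),
    lo40 = unname(0.6 * m), lo25 = unname(0.75 * m), lo10 = unname(0.9 * m),
    hi10 = unname(1.1 * m), hi25 = unname(1.25 * m), hi40 = unname(1.4 * m),
    n = n, seed = seed, stringsAsFactors = FALSE)
  rownames(ref) <- NULL
  structure(ref, values = met$values, class = c("pc_reference", "data.frame"))
}

#' Write / read a PC reference as CSV
#' @param ref A `pc_reference`.
#' @param path CSV path.
#' @return `path` (write) or the `pc_reference` (read).
#' @export
write_pc_reference <- function(ref, path) {
  utils::write.csv(as.data.frame(ref), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pc_reference
#' @export
read_pc_reference <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(ref, class = c("pc_reference", "data.frame"))
}

#' Categorize a value against the PC reference
#'
#' Maps a quantitative output to one of the seven qualitative categories by
#' its deviation from the PC median of the same readout.  Bin boundaries
#' belong to the more extreme category (exactly +25% is `increase++`).
#'
#' @param value Numeric value (same units as the readout).
#' @param reference A `pc_reference` from [build_pc_reference()].
#' @param readout Readout name present in the reference.
#' @return Category label (character).
#' @export
categorize <- function(value, reference, readout) {
  if (!readout %in% reference$readout)
    stop("readout not in reference: ", readout)
  if (any(!is.finite(value))) stop("cannot categorize non-finite value")
  m <- reference$median[match(readout, reference$readout)]
  categorize_value(value, m)
}

#' Categorize by deviation from a reference median
#'
#' Vectorized backend of [categorize()]: thresholds are -40/-25/-10/+10/+25/
#' +40% of `median`, boundaries belonging to the more extreme bin.
#'
#' @param value Numeric vector.
#' @param median Reference median (scalar, same sign convention).
#' @return Character vector of category labels.
#' @export
categorize_value <- function(value, median) {
  if (any(!is.finite(value))) stop("cannot categorize non-finite value")
  r <- value / median
  cut_codes <- function(x) {
    ifelse(x <= 0.6, -3L,
    ifelse(x <= 0.75, -2L,
    ifelse(x <= 0.9, -1L,
    ifelse(x < 1.1, 0L,
    ifelse(x < 1.25, 1L,
    ifelse(x < 1.4, 2L, 3L))))))
  }
  code <- cut_codes(r)
  names(.ox_codes)[match(code, .ox_codes)]
}

#' Integer code of a category
#'
#' Order-preserving map `decrease---` ... `increase+++` to -3 ... +3.
#'
#' @param category Character vector of category labels.
#' @return Integer vector in -3..3.
#' @export
encode_category <- function(category) {
  bad <- !category %in% names(.ox_codes)
  if (any(bad)) stop("unknown category: ", paste(category[bad], collapse = ", "))
  unname(.ox_codes[category])
}

#' Category label of an integer code
#' @param code Integer vector in -3..3.
#' @return Character vector of category labels.
#' @export
decode_category <- function(code) {
  bad <- !code %in% -3:3
  if (any(bad)) stop("codes must be integers in -3..3")
  names(.ox_codes)[match(code, .ox_codes)]
}

#' Is a category experimentally detectable?
#'
#' Deviations of at least 25% from PC (codes with absolute value >= 2) are
#' considered detectable in experiments; smaller changes may not be.
#'
#' @param category Character vector of category labels (or integer codes).
#' @return Logical vector.
#' @export
detectable <- function(category) {
  code <- if (is.numeric(category)) as.integer(category)
          else encode_category(category)
  abs(code) >= 2L
}

#' Attach categories to a sweep table
#'
#' Categorizes every `(experiment, readout)` median of a sweep against the PC
#' reference (fold-change readouts are categorized against the PC fold-change
#' distribution of the same drug and readout, never against raw baselines).
#'
#' @param sweep A sweep table from [ox_sweep()].
#' @param reference A `pc_reference` covering the sweep's readouts.
#' @return The sweep with `category` and `code` columns added.
#' @export
categorize_sweep <- function(sweep, reference) {
  idx <- match(sweep$readout, reference$readout)
  if (all(is.na(idx))) stop("no sweep readout is covered by the reference")
  cat_col <- rep(NA_character_, nrow(sweep))
  ok <- !is.na(idx) & is.finite(sweep$median)
  cat_col[ok] <- categorize_value(sweep$median[ok], reference$median[idx[ok]])
  sweep$category <- cat_col
  sweep$code <- ifelse(is.na(cat_col), NA_integer_, encode_category(cat_col))
  sweep
}
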