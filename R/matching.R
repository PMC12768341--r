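# Phenotype matching: hierarchical clustering of coded phenotypes, cluster
# quality scores, defect matching, and combination search.

#' Build a phenotype matrix from a categorized sweep
#'
#' Rows are defect instances (component + activity level), columns are coded
#' features (integer codes -3..+3).
#'
#' @param sweep A categorized sweep ([categorize_sweep()]).
#' @param features Feature (readout) names to keep; default: all categorized.
#' @return A `phenotype_matrix`: integer matrix with row annotation attributes
#'   `component` and `activity`.
#' @export
phenotype_matrix <- function(sweep, features = NULL) {
  ok <- !is.na(sweep$code)
  sub <- sweep[ok, c("component", "activity", "readout", "code")]
  if (!is.null(features)) sub <- sub[sub$readout %in% features, ]
  if (!nrow(sub)) stop("no categorized records to build a phenotype matrix from")
  wide <- stats::reshape(sub, idvar = c("component", "activity"),
                         timevar = "readout", direction = "wide")
  names(wide) <- sub("^code\\.", "", names(wide))
  feats <- setdiff(names(wide), c("component", "activity"))
  m <- as.matrix(wide[, feats, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- paste0(wide$component, "_", wide$activity)
  structure(m, component = wide$component, activity = wide$activity,
            class = c("phenotype_matrix", "matrix", "array"))
}

# entropy of a label vector (natural log)
.ox_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(ifelse(p > 0, p * log(p), 0))
}

#' V-measure of a clustering against ground-truth labels
#'
#' Harmonic mean of homogeneity (1 - H(truth | cluster)/H(truth)) and
#' completeness (1 - H(cluster | truth)/H(cluster)).
#'
#' @param truth Ground-truth labels.
#' @param cluster Cluster assignments.
#' @return V-measure in \[0, 1\].
#' @export
v_measure <- function(truth, cluster) {
  stopifnot(length(truth) == length(cluster))
  ct <- table(truth, cluster)
  n <- sum(ct)
  h_t <- .ox_entropy(truth)
  h_c <- .ox_entropy(cluster)
  p <- ct / n
  pc <- colSums(ct) / n
  pt <- rowSums(ct) / n
  h_t_given_c <- -sum(p * log(sweep(p, 2, pc, "/")), na.rm = TRUE)
  h_c_given_t <- -sum(p * log(sweep(p, 1, pt, "/")), na.rm = TRUE)
  hom <- if (h_t == 0) 1 else 1 - h_t_given_c / h_t
  com <- if (h_c == 0) 1 else 1 - h_c_given_t / h_c
  if (hom + com == 0) return(0)
  2 * hom * com / (hom + com)
}

#' Hierarchical clustering of coded phenotypes
#'
#' Agglomerative clustering (Euclidean distance on integer codes) with flat
#' clusters at `k`, silhouette score, and, when component ground-truth
#' annotations are available, the V-measure of component separation.
#'
#' @param mat A `phenotype_matrix` (or plain integer matrix) with >= 3 rows.
#' @param k Number of flat clusters (default: number of distinct components,
#'   or silhouette-best over 2..20 when annotations are absent).
#' @param linkage Agglomeration method (default `"average"`).
#' @return List with `hclust`, `labels` (flat cluster ids), `k`, `silhouette`
#'   (mean silhouette width), `v_measure` (or NA), `silhouette_scan` (mean
#'   silhouette by k over 2..20).
#' @export
cluster_phenotypes <- function(mat, k = NULL, linkage = "average") {
  if (nrow(mat) < 3) stop("clustering requires at least 3 rows")
  if (stats::var(as.vector(mat)) == 0)
    stop("constant phenotype matrix: silhouette undefined")
  d <- stats::dist(mat, method = "euclidean")
  hc <- stats::hclust(d, method = linkage)
  kmax <- min(20, nrow(mat) - 1)
  scan <- vapply(2:kmax, function(kk) {
    lab <- stats::cutree(hc, k = kk)
    if (length(unique(lab)) < 2) return(NA_real_)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, 0)
  names(scan) <- 2:kmax
  comp <- attr(mat, "component")
  if (is.null(k)) {
    k <- if (!is.null(comp)) max(2, length(unique(comp)))
         else as.integer(names(scan)[which.max(scan)])
    k <- min(k, kmax)
  }
  labels <- stats::cutree(hc, k = k)
  sil <- mean(cluster::silhouette(labels, d)[, "sil_width"])
  vm <- if (!is.null(comp)) v_measure(comp, labels) else NA_real_
  list(hclust = hc, labels = labels, k = k, silhouette = sil,
       v_measure = vm, silhouette_scan = scan)
}

#' Match an experimental phenotype against a simulated defect library
#'
#' Restricts the library to the experimentally measured features, appends the
#' experimental row, clusters everything identically to the simulated-only
#' analysis, and ranks library rows by Euclidean distance to the experimental
#' phenotype.  "Clustered with" is reported as: same flat cluster AND within
#' the top-5 distance ranking.
#'
#' @param experimental Named integer vector of codes (-3..3); names must be
#'   library features.
#' @param library A `phenotype_matrix`.
#' @param k Flat cluster count (default as in [cluster_phenotypes()]).
#' @param linkage Agglomeration method.
#' @return A `match_report`: data frame of ranked candidates (`component`,
#'   `activity`, `distance`, `same_cluster`, `clustered_with`), with
#'   attributes `silhouette`, `v_measure`, `k`, `cluster_labels`.
#' @export
match_phenotype <- function(experimental, library, k = NULL,
                            linkage = "average") {
  feats <- intersect(names(experimental), colnames(library))
  if (!length(feats)) stop("no overlapping features between phenotype and library")
  lib <- library[, feats, drop = FALSE]
  exp_row <- matrix(as.integer(experimental[feats]), 1,
                    dimnames = list("experimental", feats))
  all_m <- rbind(lib, exp_row)
  comp <- c(attr(library, "component"), "experimental")
  attr(all_m, "component") <- comp
  cl <- cluster_phenotypes(all_m, k = k, linkage = linkage)
  n <- nrow(lib)
  dists <- sqrt(colSums((t(lib) - as.numeric(exp_row))^2))
  ord <- order(dists, rownames(lib))  # deterministic tie-break by row name
  exp_cluster <- cl$labels[n + 1]
  same <- cl$labels[seq_len(n)] == exp_cluster
  rep <- data.frame(
    component = attr(library, "component")[ord],
    activity = attr(library, "activity")[ord],
    distance = unname(dists[ord]),
    same_cluster = unname(same[ord]),
    rank = seq_len(n), stringsAsFactors = FALSE)
  rep$clustered_with <- rep$same_cluster & rep$rank <= 5
  structure(rep, silhouette = cl$silhouette, v_measure = cl$v_measure,
            k = cl$k, cluster_labels = cl$labels,
            class = c("match_report", "data.frame"))
}

#' Export a match report
#' @param report A `match_report`.
#' @param csv,json Optional output paths.
#' @return The report, invisibly.
#' @export
write_match_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(as.data.frame(report), csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(
      silhouette = attr(report, "silhouette"),
      v_measure = attr(report, "v_measure"),
      k = attr(report, "k"),
      candidates = as.data.frame(report)), json, auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Search pairwise defect combinations against an experimental phenotype
#'
#' Simulates every pair of component defects on the level grids (each level
#' resolved via [calibrate_activity()] independently, then applied jointly),
#' categorizes the measured features against the PC reference, and scores the
#' number of exact category-code matches with the experimental phenotype.
#'
#' @param experimental Named integer vector of codes (features as in the
#'   sweep readouts).
#' @param pairs List of 2-element character vectors of component names.
#' @param grids Named list mapping component to its activity levels.
#' @param reference A `pc_reference` covering the features.
#' @param n Population size per combination.
#' @param seed Integer seed.
#' @param variation Population variability sd.
#' @return A `data.frame` ranked by decreasing `match_count`: one row per
#'   combination with the per-feature codes, `match_count` and `exact_match`.
#' @export
combination_search <- function(experimental, pairs, grids, reference,
                               n = 25, seed = 1, variation = 0.2) {
  feats <- names(experimental)
  need_exp <- unique(reference$experiment[match(feats, reference$readout)])
  if (anyNA(need_exp)) stop("experimental features missing from the reference")
  rows <- list()
  combo_i <- 0
  for (pr in pairs) {
    gA <- grids[[pr[1]]]; gB <- grids[[pr[2]]]
    for (a in gA) for (b in gB) {
      combo_i <- combo_i + 1
      rec <- tryCatch({
        calA <- calibrate_activity(pr[1], a)
        calB <- calibrate_activity(pr[2], b)
        p <- ox_params()
        p$x[[.ox_component_param[[pr[1]]]]] <- calA$value
        p$x[[.ox_component_param[[pr[2]]]]] <- calB$value
        met <- ox_condition_metrics(p, experiments = need_exp, n = n,
                                    variation = variation,
                                    seed = (seed * 7919 + combo_i) %% 2147483647,
                                    nudge_param = .ox_component_param[[pr[1]]])
        med <- met$median[feats]
        refm <- reference$median[match(feats, reference$readout)]
        codes <- encode_category(categorize_value(med, refm))
        names(codes) <- feats
        mc <- sum(codes == experimental[feats])
        out <- data.frame(componentA = pr[1], levelA = a,
                          componentB = pr[2], levelB = b,
                          match_count = mc,
                          exact_match = mc == length(feats),
                          stringsAsFactors = FALSE)
        for (f in feats) out[[paste0("code_", f)]] <- codes[[f]]
        out
      }, error = function(e) NULL)  # unstable combinations recorded as skipped
      if (is.null(rec)) {
        rec <- data.frame(componentA = pr[1], levelA = a, componentB = pr[2],
                          levelB = b, match_count = NA_integer_,
                          exact_match = NA, stringsAsFactors = FALSE)
        for (f in feats) rec[[paste0("code_", f)]] <- NA_integer_
      }
      rows[[length(rows) + 1]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$match_count), -1, out$match_count),
                   out$componentA, out$levelA, out$componentB, out$levelB), ]
  rownames(out) <- NULL
  out
}
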