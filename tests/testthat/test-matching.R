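# Phenotype matching: clustering, V-measure, matching, combination search.

test_that("v_measure matches an explicit entropy-formula oracle", {
  # independent oracle: direct conditional-entropy computation on the
  # contingency table
  oracle <- function(truth, cluster) {
    ct <- table(truth, cluster)
    n <- sum(ct)
    H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    h_t <- H(rowSums(ct) / n); h_c <- H(colSums(ct) / n)
    htc <- 0; hct <- 0
    for (j in seq_len(ncol(ct))) {
      nj <- sum(ct[, j])
      for (i in seq_len(nrow(ct))) if (ct[i, j] > 0)
        htc <- htc - ct[i, j] / n * log(ct[i, j] / nj)
    }
    for (i in seq_len(nrow(ct))) {
      ni <- sum(ct[i, ])
      for (j in seq_len(ncol(ct))) if (ct[i, j] > 0)
        hct <- hct - ct[i, j] / n * log(ct[i, j] / ni)
    }
    hom <- if (h_t == 0) 1 else 1 - htc / h_t
    com <- if (h_c == 0) 1 else 1 - hct / h_c
    if (hom + com == 0) 0 else 2 * hom * com / (hom + com)
  }
  set.seed(12)
  for (rep in 1:5) {
    truth <- sample(letters[1:3], 30, replace = TRUE)
    clus <- sample(1:4, 30, replace = TRUE)
    expect_equal(v_measure(truth, clus), oracle(truth, clus),
                 tolerance = 1e-12)
  }
  # perfect clustering scores 1
  expect_equal(v_measure(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
})

test_that("identical rows co-cluster away from a distant row", {
  m <- rbind(a = c(0L, 0L, 0L), b = c(0L, 0L, 0L), c = c(3L, -3L, 3L))
  colnames(m) <- c("f1", "f2", "f3")
  cl <- cluster_phenotypes(m, k = 2)
  expect_equal(cl$labels[["a"]], cl$labels[["b"]])
  expect_false(cl$labels[["a"]] == cl$labels[["c"]])
  expect_gt(cl$silhouette, 0)
})

test_that("clustering rejects degenerate inputs", {
  m <- matrix(1L, 4, 3)
  expect_error(cluster_phenotypes(m), "constant")
  expect_error(cluster_phenotypes(matrix(1:4, 2, 2)), "at least 3 rows")
})

test_that("component separation is high and linkage-insensitive on the library", {
  pm <- fixture_matrix()
  vms <- vapply(c("average", "complete", "single"), function(lk)
    cluster_phenotypes(pm, linkage = lk)$v_measure, 0)
  expect_true(all(vms > 0.5))
  expect_lt(max(vms) - min(vms), 0.25)
  # row-order invariance
  perm <- sample(nrow(pm))
  pm2 <- pm[perm, ]
  attr(pm2, "component") <- attr(pm, "component")[perm]
  attr(pm2, "activity") <- attr(pm, "activity")[perm]
  c1 <- cluster_phenotypes(pm)
  c2 <- cluster_phenotypes(pm2)
  expect_equal(c2$v_measure, c1$v_measure, tolerance = 1e-9)
  expect_equal(c2$silhouette, c1$silhouette, tolerance = 1e-9)
})

test_that("ETC complex defects intermix more than non-ETC components", {
  pm <- fixture_matrix()
  cl <- cluster_phenotypes(pm)
  comp <- attr(pm, "component")
  purity <- function(keep) {
    # fraction of rows whose cluster is dominated by their own component
    mean(vapply(which(keep), function(i) {
      mates <- comp[cl$labels == cl$labels[i]]
      mean(mates == comp[i]) > 0.5
    }, TRUE))
  }
  etc <- comp %in% c("CI", "CIII", "CIV")
  expect_gt(purity(!etc), purity(etc))
})

test_that("a phenotype copied from a library row matches it at distance zero", {
  pm <- fixture_matrix()
  row <- pm["DH_20", ]
  rep <- match_phenotype(row, pm)
  expect_equal(rep$distance[1], 0)
  expect_identical(rep$component[1], "DH")
  expect_equal(rep$activity[1], 20)
  expect_error(match_phenotype(c(zzz = 1L), pm), "no overlapping features")
})

test_that("the Parkin-KO phenotype matches raised proton leak and severe KDyn loss", {
  pm <- fixture_matrix(features = c("basal_ocr", "max_ocr", "atp_m"))
  park <- builtin_phenotypes("park")$park
  rep <- match_phenotype(park$codes, pm)
  top5 <- rep[rep$rank <= 5, ]
  expect_true(any(top5$component == "Hle" & top5$activity > 100))
  expect_true(any(top5$component == "KDyn" & top5$activity <= 20))
})

test_that("the Alzheimer-model phenotype matches a mild dehydrogenase defect top-1", {
  pm <- fixture_matrix(features = c("basal_ocr", "leak_ocr", "max_ocr"))
  tgad <- builtin_phenotypes("tgad")$tgad
  rep <- match_phenotype(tgad$codes, pm)
  expect_identical(rep$component[1], "DH")
  expect_gte(rep$activity[1], 80)
})

test_that("no single library defect reproduces all five Pink1 features", {
  lib <- fixture_library()
  pink1 <- builtin_phenotypes("pink1")$pink1
  pm <- phenotype_matrix(lib, features = names(pink1$codes))
  dists <- apply(pm, 1, function(r) sqrt(sum((r - pink1$codes[colnames(pm)])^2)))
  expect_gt(min(dists), 0)
})

test_that("null combination exactly matches the all-zero PC phenotype", {
  ref <- fixture_ref()
  pcvec <- stats::setNames(rep(0L, 3), c("basal_ocr", "leak_ocr", "max_ocr"))
  res <- combination_search(pcvec, pairs = list(c("CI", "DH")),
                            grids = list(CI = 100, DH = 100),
                            reference = ref, n = 30, seed = 4)
  expect_true(res$exact_match[1])
  expect_equal(res$match_count[1], 3)
})

test_that("single-defect combinations reproduce the library's coded phenotype", {
  ref <- fixture_ref()
  lib <- fixture_library()
  feats <- c("basal_ocr", "leak_ocr", "max_ocr")
  row <- phenotype_matrix(lib, features = feats)["DH_20", ]
  res <- combination_search(stats::setNames(as.integer(row), feats),
                            pairs = list(c("DH", "KCons")),
                            grids = list(DH = 20, KCons = 100),
                            reference = ref, n = 10, seed = 15)
  codes <- unlist(res[1, paste0("code_", feats)])
  # embedded single defect agrees with the library coding (small-n medians may
  # straddle a bin boundary by at most one grade)
  expect_true(all(abs(codes - as.integer(row)) <= 1))
  expect_gte(res$match_count[1], 2)
})
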