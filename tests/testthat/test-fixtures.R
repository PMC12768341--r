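# Built-in phenotype fixtures and the synthetic-phenotype generator.

test_that("the three case-study phenotypes ship with the documented codes", {
  phen <- builtin_phenotypes()
  expect_setequal(names(phen), c("tgad", "park", "pink1"))
  expect_identical(phen$tgad$codes,
                   c(basal_ocr = 0L, leak_ocr = 0L, max_ocr = -2L))
  expect_identical(phen$park$codes,
                   c(basal_ocr = 2L, max_ocr = 0L, atp_m = -2L))
  expect_identical(phen$pink1$codes,
                   c(basal_ocr = -2L, max_ocr = -2L, leak_ocr = 0L,
                     resp_dpsi_antia = -2L, resp_dpsi_rot = 0L))
  expect_error(builtin_phenotypes(character(0)), "empty")
  expect_error(builtin_phenotypes("nope"), "unknown phenotype")
})

test_that("phenotypes round-trip losslessly through YAML", {
  phen <- builtin_phenotypes()
  path <- tempfile(fileext = ".yaml")
  write_phenotypes(phen, path)
  back <- read_phenotypes(path)
  for (nm in names(phen)) {
    expect_identical(back[[nm]]$codes, phen[[nm]]$codes)
  }
})

test_that("noise-free synthetic phenotypes equal the library coding", {
  # generated with the same population (same seed and n) as the sweep cell,
  # the no-noise synthetic phenotype reproduces the library row exactly
  ref <- fixture_ref()
  feats <- c("basal_ocr", "leak_ocr", "max_ocr", "dpsi", "nadh", "atp_m",
             "h2o2")
  sweep_seed <- 77
  cell_seed <- (sweep_seed * 10007 + 131) %% 2147483647  # first-cell seed
  sw <- ox_sweep(components = "Hle", grid = 350,
                 experiments = c("basal", "stress_test"), n = 12,
                 seed = sweep_seed)
  row <- phenotype_matrix(categorize_sweep(sw, ref),
                          features = feats)["Hle_350", ]
  ph <- make_synthetic_phenotype(c(Hle = 350), features = feats,
                                 reference = ref, noise = 0,
                                 seed = cell_seed, n = 12)
  expect_identical(ph$codes, stats::setNames(as.integer(row[names(ph$codes)]),
                                             names(ph$codes)))
  expect_identical(ph$codes, attr(ph, "true_codes"))
})

test_that("severe substrate-supply loss codes NADH as a strong decrease", {
  ref <- fixture_ref()
  ph <- make_synthetic_phenotype(c(DH = 20), features = c("nadh", "basal_ocr"),
                                 reference = ref, noise = 0, seed = 9, n = 10)
  expect_lte(ph$codes[["nadh"]], -2L)
})

test_that("code noise is seeded and bounded", {
  ref <- fixture_ref()
  feats <- c("basal_ocr", "leak_ocr", "max_ocr")
  a <- make_synthetic_phenotype(c(Hle = 350), feats, ref, noise = 1,
                                seed = 77, n = 6)
  b <- make_synthetic_phenotype(c(Hle = 350), feats, ref, noise = 1,
                                seed = 77, n = 6)
  expect_identical(a$codes, b$codes)
  expect_true(all(abs(a$codes - attr(a, "true_codes")) <= 1))
  expect_true(all(a$codes >= -3L & a$codes <= 3L))
  expect_error(make_synthetic_phenotype(c(Hle = 350), feats, ref, noise = 2),
               "noise")
})

test_that("single-defect phenotypes are recovered by matching", {
  # end-to-end: simulate a known severe defect, code it, and recover the
  # generating component from the library
  ref <- fixture_ref()
  pm <- fixture_matrix()
  feats <- colnames(pm)
  for (d in list(c(F1 = 20), c(DH = 20), c(Hle = 350), c(KDyn = 20),
                 c(KCons = 20))) {
    ph <- make_synthetic_phenotype(d, features = feats, reference = ref,
                                   noise = 0, seed = 55, n = 12)
    rep <- match_phenotype(ph$codes, pm)
    expect_identical(rep$component[1], names(d),
                     info = paste("recover", names(d)))
  }
})

test_that("ETC-complex defects are recovered at the complex-group level", {
  ref <- fixture_ref()
  pm <- fixture_matrix()
  ph <- make_synthetic_phenotype(c(CIII = 20), features = colnames(pm),
                                 reference = ref, noise = 0, seed = 56, n = 12)
  rep <- match_phenotype(ph$codes, pm)
  expect_true(rep$component[1] %in% c("CI", "CIII", "CIV"))
})

test_that("recovery tolerates moderate code noise", {
  ref <- fixture_ref()
  pm <- fixture_matrix()
  hits <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    ph <- make_synthetic_phenotype(c(DH = 20), features = colnames(pm),
                                   reference = ref, noise = 0.2,
                                   seed = 400 + s, n = 6)
    rep <- match_phenotype(ph$codes, pm)
    if ("DH" %in% rep$component[1:3]) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.8)
})
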