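# synthetic-data generators, bundle/Molden/XYZ/cube IO and the CLI surface

test_that("the Gaussian excitation fixture carries correct closed forms", {
  expect_equal(gaussian_excitation_fixture(0)$expected$d, 0)
  fx <- gaussian_excitation_fixture(4, 0.5)
  expect_equal(fx$expected$d, 4)
  expect_equal(fx$expected$sigma_hole, rep(0.7071, 3), tolerance = 1e-4)
  expect_error(gaussian_excitation_fixture(-1), ">= 0")
})

test_that("synthetic tables regenerate byte-identically under a fixed seed", {
  t1 <- synthetic_qspr_table(136, seed = 8)
  t2 <- synthetic_qspr_table(136, seed = 8)
  expect_identical(t1, t2)
  expect_false(identical(t1$phi_delta,
                         synthetic_qspr_table(136, seed = 9)$phi_delta))
  expect_equal(dim(t1), c(136, 4 + 73))
  expect_true(all(t1$phi_delta > 0 & t1$phi_delta <= 1))
  expect_identical(descriptor_columns(t1),
                   c(qcd_column_names(), structure_column_names(),
                     "cn", "cp", "mc", "cf", "cd", "cs",
                     "eps", "epsinf", "wl"))
})

test_that("a noiseless synthetic target is recovered almost exactly", {
  tab <- synthetic_qspr_table(100, noise_sd = 0, seed = 44)
  m <- train_single_model(model_spec("krr", params = list(alpha = 1e-6,
                                                          gamma = 0.01)), tab)
  expect_gt(evaluate_predictions(predict(m, tab), tab$phi_delta)$r2, 0.99)
})

make_toy_bundle <- function(path, soc = 120) {
  fx <- gaussian_excitation_fixture(3, 0.6)
  bundle <- list(
    geometry = list(elements = c("Ru", "N"), coords_bohr = fx$centers),
    orbitals = fx$orbitals,
    states = list(
      S1 = list(label = "S1", energy_ev = 2.4, configs = fx$configs,
                tedm = c(0.5, 0, 0), tvdm = c(0.45, 0, 0),
                tmdm = c(0, 0, 0.1)),
      T1 = list(label = "T1", energy_ev = 1.9,
                configs = configuration_set(
                  data.frame(i = 1, a = 2, w = 0.9),
                  data.frame(i = 1, a = 2, w = 0.1)),
                tedm = c(0.1, 0, 0), tvdm = c(0.1, 0, 0),
                tmdm = c(0, 0, 0.05))),
    soc = soc, provenance = "synthetic toy system")
  write_excitation_bundle(bundle, path)
  bundle
}

test_that("excitation bundles round-trip through JSON", {
  tmp <- tempfile(fileext = ".json")
  bundle <- make_toy_bundle(tmp)
  back <- read_excitation_bundle(tmp)
  expect_equal(back$geometry$coords_bohr,
               unname(bundle$geometry$coords_bohr), tolerance = 1e-12)
  expect_identical(names(back$states), c("S1", "T1"))
  expect_equal(back$states$S1$configs$excitations,
               bundle$states$S1$configs$excitations, tolerance = 1e-12)
  expect_equal(back$states$T1$configs$deexcitations$w, 0.1,
               tolerance = 1e-12)
  expect_equal(back$soc, 120)
  # orbitals survive: same values on a probe grid
  probe <- quadrature_grid(matrix(runif(30, -2, 4), ncol = 3), rep(1, 10))
  expect_equal(evaluate_orbital(back$orbitals[[1]], probe),
               evaluate_orbital(bundle$orbitals[[1]], probe),
               tolerance = 1e-10)
})

test_that("bundle validation reports every violation and version mismatches", {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "phidelta-bundle/1",
                            geometry = list(elements = c("H")),
                            states = list(list(label = "S1",
                                               configurations = list(list(1, 2))))),
                       tmp, auto_unbox = TRUE)
  err <- tryCatch(read_excitation_bundle(tmp), error = conditionMessage)
  expect_match(err, "coords_angstrom")
  expect_match(err, "malformed configurations triple at index 1")
  expect_match(err, "energy_ev")
  jsonlite::write_json(list(schema = "phidelta-bundle/99"), tmp,
                       auto_unbox = TRUE)
  expect_error(read_excitation_bundle(tmp), "migrate")
  expect_error(read_excitation_bundle(tempfile()), "not found")
  # missing soc is parsed as absent, not zero
  tmp2 <- tempfile(fileext = ".json")
  b <- make_toy_bundle(tmp2)
  doc <- jsonlite::fromJSON(tmp2, simplifyDataFrame = FALSE)
  doc$soc_cm1 <- NULL
  jsonlite::write_json(doc, tmp2, auto_unbox = TRUE, digits = NA)
  expect_true(is.na(read_excitation_bundle(tmp2)$soc))
})

test_that("qcd_from_bundle produces a full 40-column record end to end", {
  tmp <- tempfile(fileext = ".json")
  make_toy_bundle(tmp)
  bundle <- read_excitation_bundle(tmp)
  rec <- qcd_from_bundle(bundle, fragments = c("metal", "ligand"),
                         metal_fragment = "metal", grid_level = 2)
  expect_length(rec, 40)
  expect_identical(names(rec), qcd_column_names())
  expect_equal(unname(rec["soc"]), 120)
  expect_equal(unname(rec["S-ee"]), 2.4)
  expect_equal(unname(rec["D-ee"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(rec["S-d"]), bohr2ang(3), tolerance = 1e-3)
  expect_true(rec["S-mlct"] > 0.9)
  # t = d - hct by construction, in every state block
  expect_equal(unname(rec["S-t"]), unname(rec["S-d"] - rec["S-hct"]),
               tolerance = 1e-12)
})

test_that("the Molden reader rebuilds normalized orbitals from s/p shells", {
  tmp <- tempfile(fileext = ".molden")
  writeLines(c(
    "[Molden Format]",
    "[Atoms] AU",
    "H 1 1 0.0 0.0 0.0",
    "H 2 1 0.0 0.0 1.4",
    "[GTO]",
    "  1 0",
    " s 2 1.00",
    "  1.309756377 0.430128498",
    "  0.233135974 0.678913531",
    "",
    "  2 0",
    " s 2 1.00",
    "  1.309756377 0.430128498",
    "  0.233135974 0.678913531",
    "",
    "[MO]",
    "Sym= A1",
    "Ene= -0.578",
    "Spin= Alpha",
    "Occup= 2.0",
    "  1 0.70710678",
    "  2 0.70710678",
    "Sym= A1",
    "Ene= 0.271",
    "Spin= Alpha",
    "Occup= 0.0",
    "  1 0.70710678",
    "  2 -0.70710678"), tmp)
  mol <- read_molden(tmp)
  expect_equal(nrow(mol$atoms), 2)
  expect_length(mol$orbitals, 2)
  # each contracted basis function is unit-normalized, so the bonding MO
  # integrates to 1 + S12 (overlap of the two basis functions)
  grid <- becke_grid(as.matrix(mol$atoms[c("x", "y", "z")]), level = 3)
  n1 <- integrate_field(evaluate_orbital(mol$orbitals[[1]], grid)^2, grid)
  n2 <- integrate_field(evaluate_orbital(mol$orbitals[[2]], grid)^2, grid)
  expect_equal(n1 + n2, 2, tolerance = 1e-3)   # S12 terms cancel in the sum
  expect_gt(n1, 1)                             # bonding: 1 + S12 > 1
  expect_lt(n2, 1)                             # antibonding: 1 - S12 < 1
  # spherical-harmonic files are rejected
  writeLines(c("[Molden Format]", "[5D]", "[Atoms] AU"), tmp)
  expect_error(read_molden(tmp), "5D")
})

test_that("XYZ files read into bohr coordinates", {
  tmp <- tempfile(fileext = ".xyz")
  writeLines(c("2", "toy", "Ru 0.0 0.0 0.0", "N 0.0 0.0 2.0"), tmp)
  geo <- read_xyz(tmp)
  expect_identical(geo$elements, c("Ru", "N"))
  expect_equal(geo$coords_bohr[2, 3], 2 * 1.8897259886, tolerance = 1e-12)
  writeLines(c("5", "toy", "H 0 0 0"), tmp)
  expect_error(read_xyz(tmp), "malformed")
})

test_that("cube export writes a standard, re-parseable header and field", {
  fx <- gaussian_excitation_fixture(2, 0.7)
  grid <- uniform_grid(rbind(c(-4, -4, -4), c(4, 4, 6)), n = c(8, 8, 10))
  f <- build_hole_electron(fx$configs, fx$orbitals, grid)
  tmp <- tempfile(fileext = ".cube")
  write_cube(f$rho_hole, grid, tmp, elements = c("Ru", "N"),
             coords_bohr = fx$centers)
  lines <- readLines(tmp)
  hdr <- as.numeric(strsplit(trimws(lines[3]), "\\s+")[[1]])
  expect_equal(hdr[1], 2)                      # natoms
  dims <- sapply(4:6, function(k)
    as.numeric(strsplit(trimws(lines[k]), "\\s+")[[1]])[1])
  expect_equal(dims, c(8, 8, 10))
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:8)]), "\\s+")))
  expect_length(vals, 8 * 8 * 10)
  expect_equal(sum(vals) * prod(grid$voxel),
               integrate_field(f$rho_hole, grid), tolerance = 1e-5)
  # grid-order contract: the value block is z-fastest
  arr <- array(f$rho_hole, dim = c(8, 8, 10))
  expect_equal(vals[1:10], arr[1, 1, ], tolerance = 1e-5)
  expect_error(write_cube(f$rho_hole, becke_grid(c(0, 0, 0), level = 1),
                          tmp), "rectilinear")
})

test_that("the CLI wires simulate, train, predict and explain together", {
  dir <- withr::local_tempdir()
  tab_csv <- file.path(dir, "table.csv")
  expect_equal(phidelta_cli(c("simulate", "--n", "40", "--seed", "7",
                              "--out", tab_csv)), 0L)
  expect_true(file.exists(tab_csv))
  model_rds <- file.path(dir, "model.rds")
  expect_equal(phidelta_cli(c("train", "--table", tab_csv, "--family", "knr",
                              "--budget", "4", "--seed", "7",
                              "--out", model_rds)), 0L)
  pred_csv <- file.path(dir, "pred.csv")
  expect_equal(phidelta_cli(c("predict", "--model", model_rds, "--table",
                              tab_csv, "--out", pred_csv)), 0L)
  pred <- utils::read.csv(pred_csv)
  expect_equal(nrow(pred), 40)
  expect_true(all(is.finite(pred$prediction)))
  shap_csv <- file.path(dir, "shap.csv")
  expect_equal(phidelta_cli(c("explain", "--model", model_rds, "--table",
                              tab_csv, "--seed", "7", "--out", shap_csv)), 0L)
  expect_equal(nrow(utils::read.csv(shap_csv, check.names = FALSE)), 73)
  # qcd subcommand on a bundle fixture
  bundle_json <- file.path(dir, "bundle.json")
  make_toy_bundle(bundle_json)
  qcd_csv <- file.path(dir, "qcd.csv")
  expect_equal(phidelta_cli(c("qcd", "--bundle", bundle_json, "--grid-level",
                              "1", "--out", qcd_csv)), 0L)
  expect_equal(ncol(utils::read.csv(qcd_csv, check.names = FALSE)), 40)
  # featurize: measurement CSV -> preprocessed feature table + exclusion log
  meas <- synthetic_qspr_table(12, seed = 3)
  meas <- meas[c("id", "metal", "phi_delta", qcd_column_names(),
                 structure_column_names())]
  meas$solvent <- "water"
  meas$wl <- 450
  meas$phi_delta[1] <- 0.004            # must be excluded
  meas_csv <- file.path(dir, "meas.csv")
  utils::write.csv(meas, meas_csv, row.names = FALSE)
  feat_csv <- file.path(dir, "features.csv")
  expect_equal(phidelta_cli(c("featurize", "--measurements", meas_csv,
                              "--out", feat_csv)), 0L)
  feat <- read_feature_table(feat_csv)
  expect_equal(nrow(feat), 11)
  expect_true(all(c("eps", "cp") %in% names(feat)))
  expect_true(file.exists(paste0(feat_csv, ".exclusions.tsv")))
  # failure paths: unknown command, missing flag, mismatched manifest
  expect_equal(phidelta_cli("frobnicate"), 1L)
  expect_equal(phidelta_cli(c("train", "--table", tab_csv)), 1L)
  bad_csv <- file.path(dir, "bad.csv")
  utils::write.csv(data.frame(id = "r1", phi_delta = 0.5), bad_csv,
                   row.names = FALSE)
  expect_equal(phidelta_cli(c("predict", "--model", model_rds, "--table",
                              bad_csv, "--out", pred_csv)), 1L)
})
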