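# metal / condition / structure descriptor blocks, preprocessing, assembly

test_that("metal descriptors come straight from the free-atom configuration table", {
  ru <- metal_descriptors("Ru", charge = 2)
  expect_equal(unname(ru[c("cp", "cs", "cd", "cf")]), c(5, 1, 7, 0))
  ir <- metal_descriptors("Ir", charge = 3, count = 1)
  expect_equal(unname(ir[c("cp", "cs", "cd", "cf")]), c(6, 2, 7, 14))
  re <- metal_descriptors("Re", count = 1)
  expect_equal(unname(re["cn"]), 1)
  expect_equal(unname(re[c("cp", "cs", "cd", "cf")]), c(6, 2, 5, 14))
  # anomalous ground states are table-driven, not Aufbau heuristics
  expect_equal(unname(metal_descriptors("Pt")[c("cs", "cd")]), c(1, 9))
  expect_equal(unname(metal_descriptors("Cr")[c("cs", "cd")]), c(1, 5))
  expect_error(metal_descriptors("Xx"), "supported")
})

test_that("condition descriptors look up the solvent table and validate inputs", {
  w <- condition_descriptors("water", 450)
  expect_equal(unname(w["eps"]), 78.36, tolerance = 1e-3)
  expect_equal(unname(w["epsinf"]), 1.78, tolerance = 1e-3)
  expect_equal(unname(w["wl"]), 450)
  # pure lookup: identical on repetition, synonym- and case-insensitive
  expect_identical(condition_descriptors("water", 450),
                   condition_descriptors("water", 450))
  expect_equal(unname(condition_descriptors("MeCN", 500)["eps"]),
               unname(condition_descriptors("acetonitrile", 500)["eps"]))
  expect_error(condition_descriptors("water", -5), "positive")
  expect_error(condition_descriptors("watr", 450), "did you mean")
  # physical ordering holds across the whole table
  tab <- condition_descriptors("dmso", 400)
  expect_true(tab["eps"] >= tab["epsinf"] && tab["epsinf"] >= 1)
})

benzene_ct <- function() {
  connection_table(
    data.frame(element = rep("C", 6), hydrogens = 1),
    data.frame(a = 1:6, b = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1)))
}

test_that("benzene is matched as one phenyl, one six-ring, three double bonds", {
  sd <- structure_descriptors(benzene_ct())
  expect_equal(unname(sd[c("n-ph", "n-r6", "n-db", "n-tb")]), c(1, 1, 3, 0))
  expect_equal(unname(sd["an"]), 12)
  expect_equal(unname(sd["mw"]), 78.114, tolerance = 1e-3)
})

test_that("charge annotations reproduce the worked complex-1 pattern", {
  # a 2+ complex, three neutral ligands, one anionic O donor among the six
  # metal-bound atoms
  atoms <- data.frame(
    element = c("Ru", "O", rep("N", 5)),
    charge = c(2, -1, rep(0, 5)),
    metal_donor = c(FALSE, rep(TRUE, 6)))
  ct <- connection_table(atoms, data.frame(a = 1, b = 2:7, order = 1),
                         nc = 2, lc = 0, mc = 2)
  sd <- structure_descriptors(ct)
  expect_equal(unname(sd[c("nc", "lc", "cc")]), c(2, 0, -1))
})

test_that("the containment hierarchy counts each carbonyl once, as its largest group", {
  # N-methylacetamide: CC(=O)NC -- one peptide bond, no free carbonyl
  amide <- connection_table(
    data.frame(element = c("C", "C", "O", "N", "C"),
               hydrogens = c(3, 0, 0, 1, 3)),
    data.frame(a = c(1, 2, 2, 4), b = c(2, 3, 4, 5),
               order = c(1, 2, 1, 1)))
  sa <- structure_descriptors(amide)
  expect_equal(unname(sa[c("n-CONH", "n-CO", "n-CHO", "n-COO")]),
               c(1, 0, 0, 0))
  # methyl acetate: ester counted, carbonyl not double-counted, and the
  # ester oxygens still count toward n-O
  ester <- connection_table(
    data.frame(element = c("C", "C", "O", "O", "C"),
               hydrogens = c(3, 0, 0, 0, 3)),
    data.frame(a = c(1, 2, 2, 4), b = c(2, 3, 4, 5),
               order = c(1, 2, 1, 1)))
  se <- structure_descriptors(ester)
  expect_equal(unname(se[c("n-COO", "n-CO", "n-O")]), c(1, 0, 2))
  # acetaldehyde: aldehyde, not plain carbonyl; acetone: plain carbonyl
  ald <- connection_table(
    data.frame(element = c("C", "C", "O"), hydrogens = c(3, 1, 0)),
    data.frame(a = c(1, 2), b = c(2, 3), order = c(1, 2)))
  expect_equal(unname(structure_descriptors(ald)[c("n-CHO", "n-CO")]),
               c(1, 0))
  ket <- connection_table(
    data.frame(element = c("C", "C", "O", "C"), hydrogens = c(3, 0, 0, 3)),
    data.frame(a = c(1, 2, 2), b = c(2, 3, 4), order = c(1, 2, 1)))
  expect_equal(unname(structure_descriptors(ket)[c("n-CO", "n-CHO")]),
               c(1, 0))
})

test_that("heteroaromatic rings and substituent groups are recognized", {
  # pyridine
  py <- connection_table(
    data.frame(element = c("N", rep("C", 5)), hydrogens = c(0, rep(1, 5))),
    data.frame(a = 1:6, b = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1)))
  sp <- structure_descriptors(py)
  expect_equal(unname(sp[c("n-py", "n-ph", "n-r6", "n-pyra")]), c(1, 0, 1, 0))
  # pyrazine (1,4-diazine)
  pz <- connection_table(
    data.frame(element = c("N", "C", "C", "N", "C", "C"),
               hydrogens = c(0, 1, 1, 0, 1, 1)),
    data.frame(a = 1:6, b = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1)))
  expect_equal(unname(structure_descriptors(pz)[c("n-pyra", "n-py")]),
               c(1, 0))
  # pyrrole
  pyr <- connection_table(
    data.frame(element = c("N", rep("C", 4)), hydrogens = c(1, 1, 1, 1, 1)),
    data.frame(a = 1:5, b = c(2:5, 1), order = c(1, 2, 1, 2, 1)))
  expect_equal(unname(structure_descriptors(pyr)[c("n-pyrr", "n-r5")]),
               c(1, 1))
  # phenol + aniline-like substituents and halogen/nitrile counting
  sub <- connection_table(
    data.frame(element = c(rep("C", 6), "O", "N", "Cl", "C", "N"),
               hydrogens = c(0, 0, 0, 0, 1, 0, 1, 2, 0, 0, 0)),
    data.frame(a = c(1:6, 1, 2, 3, 4, 10),
               b = c(2:6, 1, 7, 8, 9, 10, 11),
               order = c(2, 1, 2, 1, 2, 1, 1, 1, 1, 1, 3)))
  ss <- structure_descriptors(sub)
  expect_equal(unname(ss[c("n-OH", "n-NH2", "n-X", "n-CN", "n-tb")]),
               c(1, 1, 1, 1, 1))
})

test_that("fused rings are perceived as their smallest set", {
  # naphthalene: 10 carbons, 11 bonds -> two six-rings
  naph <- connection_table(
    data.frame(element = rep("C", 10),
               hydrogens = c(1, 1, 1, 1, 0, 1, 1, 1, 1, 0)),
    data.frame(a = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 5),
               b = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 1, 10),
               order = c(2, 1, 2, 1, 2, 1, 2, 1, 2, 1, 1)))
  sn <- structure_descriptors(naph)
  expect_equal(unname(sn["n-r6"]), 2)
  expect_equal(unname(sn["n-r5"]), 0)
})

test_that("missing bond orders mark unsaturation-dependent counts absent", {
  ct <- connection_table(data.frame(element = c("C", "C")),
                         data.frame(a = 1, b = 2))
  sd <- structure_descriptors(ct)
  expect_true(is.na(sd["n-db"]) && is.na(sd["n-CO"]))
  expect_false(is.na(sd["n-S"]))
  # missing charge annotations are rejected
  expect_error(connection_table(
    data.frame(element = "C", charge = NA_real_)), "charge")
})

test_that("preprocessing drops low yields and wavelength-inconsistent groups, order-independently", {
  tab <- data.frame(
    id = c("a", "b", "b", "c", "d", "d", paste0("x", 1:4)),
    phi_delta = c(0.005, 0.30, 0.28, 0.008, 0.60, 0.10,
                  0.2, 0.3, 0.4, 0.5),
    wl = c(450, 450, 500, 450, 450, 520, 450, 450, 450, 450))
  res <- preprocess_dataset(tab)
  # a and c below 0.01; d inconsistent across wavelengths (ratio 6)
  expect_equal(sort(unique(res$kept$id)), c("b", paste0("x", 1:4)))
  expect_equal(nrow(res$kept), 6)
  expect_setequal(res$log$rule[res$log$id %in% c("a", "c")],
                  "below-threshold")
  expect_true("wavelength-inconsistency" %in% res$log$rule[res$log$id == "d"])
  # b retained: ratio 0.30/0.28 under the default 2.0
  expect_true(all(c(0.30, 0.28) %in% res$kept$phi_delta))
  # order independence
  perm <- tab[sample(nrow(tab)), ]
  res2 <- preprocess_dataset(perm)
  expect_setequal(paste(res2$kept$id, res2$kept$phi_delta),
                  paste(res$kept$id, res$kept$phi_delta))
  # 10 records, 2 below threshold, 2 dropped by the wavelength rule
  expect_equal(nrow(res$log), 4)
})

test_that("feature tables assemble with the fixed column order and round-trip", {
  make_sample <- function(id, metal, phi) {
    list(id = id, metal = metal, source = "internal", phi_delta = phi,
         qcd = stats::setNames(seq_along(qcd_column_names()) * 0.1,
                               qcd_column_names()),
         structure = stats::setNames(rep(1, 24), structure_column_names()),
         metal_desc = metal_descriptors(metal, charge = 2),
         condition = condition_descriptors("water", 450))
  }
  tab <- assemble_feature_table(list(make_sample("s1", "Ru", 0.5),
                                     make_sample("s2", "Ir", 0.7),
                                     make_sample("s3", "Ru", 0.2)))
  expect_equal(nrow(tab), 3)
  expect_identical(descriptor_columns(tab),
                   c(qcd_column_names(), structure_column_names(),
                     c("cn", "cp", "mc", "cf", "cd", "cs"),
                     c("eps", "epsinf", "wl")))
  ru <- subset_by_metal(tab, "Ru")
  expect_equal(ru$id, c("s1", "s3"))
  # serialization fidelity
  tmp <- tempfile(fileext = ".csv")
  write_feature_table(tab, tmp)
  back <- read_feature_table(tmp)
  expect_equal(as.data.frame(back)[names(tab)], as.data.frame(tab),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(unname(unlist(attr(back, "manifest")$blocks)),
                   unname(unlist(attr(tab, "manifest")$blocks)))
  # invalid target rejected, missing block rejected
  bad <- make_sample("s4", "Ru", 1.5)
  expect_error(assemble_feature_table(list(bad)), "phi_delta")
  bad2 <- make_sample("s5", "Ru", 0.5)
  bad2$qcd <- bad2$qcd[-1]
  expect_error(assemble_feature_table(list(bad2)), "missing column")
})
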