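# Feature encoding: scales, positional frequency, globals, charge/pI,
# property provider, and the assembled feature vector.

test_that("scale lookups return transcribed values and X encodes as 0", {
  expect_equal(residue_scale_lookup("A", "kd_hydrophobicity"), 1.8)
  expect_equal(residue_scale_lookup("R", "kd_hydrophobicity"), -4.5)
  expect_equal(residue_scale_lookup("G", "vdw_volume"), 48)
  expect_equal(residue_scale_lookup("R", "atchley_5"), 2.897)
  expect_equal(residue_scale_lookup("X", "atchley_1"), 0)
  expect_error(residue_scale_lookup("J", "kd_hydrophobicity"), "unknown")
  for (nm in c(paste0("atchley_", 1:5), "kd_hydrophobicity", "vdw_volume",
               "asa_propensity", "disorder_propensity")) {
    s <- aa_scale(nm)
    expect_setequal(names(s), c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                                "L", "M", "N", "P", "Q", "R", "S", "T", "V",
                                "W", "Y"))
  }
})

test_that("positional frequency table counts, normalizes, and encodes", {
  w <- ws_from_peptides(c("ARA", "GRG"), "positive")
  tab <- fit_positional_frequency(w)
  expect_equal(dim(tab), c(21L, 3L))
  expect_equal(unname(colSums(tab)), rep(1, 3), tolerance = 1e-12)
  expect_equal(tab["R", "0"], 1.0)
  expect_equal(tab["A", "-1"], 0.5)
  expect_equal(tab["G", "-1"], 0.5)
  expect_equal(tab["X", "-1"], 0)

  # encoding: invariant position -> 1, unseen residue -> 0, X uses X row
  expect_equal(positional_frequency_feature("ARA", tab), c(0.5, 1, 0.5))
  expect_equal(positional_frequency_feature("SRS", tab), c(0, 1, 0))
  expect_equal(positional_frequency_feature("XRX", tab), c(0, 1, 0))
  expect_error(positional_frequency_feature("AARAA", tab), "length")
  expect_error(fit_positional_frequency(ws_from_peptides(character(0))))
})

test_that("global scale averages exclude X padding", {
  expect_equal(global_scale_features("AAA")[["gravy"]], 1.8)
  expect_equal(global_scale_features("AXA")[["gravy"]], 1.8)
  expect_equal(global_scale_features("AR")[["gravy"]], (1.8 - 4.5) / 2)
  expect_equal(global_scale_features("GXG")[["avg_vdwv"]], 48)
  expect_error(global_scale_features("XXX"), "all X")
})

test_that("net charge follows the Henderson-Hasselbalch sum", {
  pep <- "ACDEFGHIKLMNPQRSTVWY"
  # frozen value from an independent implementation of the same pKa set
  expect_equal(net_charge(pep, 7), -0.16070196664006822, tolerance = 1e-12)
  expect_gt(net_charge(pep, 0.1), 0)    # full protonation limit
  expect_lt(net_charge(pep, 13.9), 0)   # full deprotonation limit
  # X is ignored
  expect_equal(net_charge("AXG", 7), net_charge("AG", 7))
  # strictly decreasing in pH
  grid <- seq(0, 14, by = 0.25)
  charges <- vapply(grid, function(p) net_charge("KDRC", p), 0)
  expect_true(all(diff(charges) < 0))
  expect_error(net_charge("AJZ", 7), "unknown")
})

test_that("isoelectric point is the root of the charge curve", {
  # frozen values from an independent bisection over the same pKa set
  expect_equal(isoelectric_point("G"), 5.525, tolerance = 1e-6)
  expect_equal(isoelectric_point("ACDEFGHIKLMNPQRSTVWY"), 6.741981065191622,
               tolerance = 1e-6)
  for (pep in c("KKKK", "DDDD", "GRAG", "PEPTIDE")) {
    expect_lt(abs(net_charge(pep, isoelectric_point(pep))), 1e-6)
  }
  expect_gt(isoelectric_point("KKKK"), isoelectric_point("DDDD"))
})

test_that("default property provider honours its contract", {
  prov <- default_property_provider()
  # constant peptide -> constant vectors
  out <- prov$predict("GGGGGGG")
  expect_equal(length(out$asa), 7L)
  expect_equal(diff(range(out$asa)), 0)
  expect_equal(diff(range(out$disorder)), 0)
  # bounded in [0,1], any peptide
  set.seed(5)
  for (pep in random_windows(10, 11, alphabet = c("A", "G", "K", "W", "X"))) {
    o <- prov$predict(pep)
    expect_true(all(o$asa >= 0 & o$asa <= 1))
    expect_true(all(o$disorder >= 0 & o$disorder <= 1))
    # symmetric smoothing: reverse commutes
    rev_pep <- paste(rev(strsplit(pep, "")[[1]]), collapse = "")
    expect_equal(prov$predict(rev_pep)$disorder, rev(o$disorder))
  }
})

test_that("encode_windows produces the full named 10L+4 vector", {
  set.seed(6)
  w <- ws_from_peptides(random_windows(8, 19, c("A", "G", "K", "D", "X")),
                        "positive")
  tab <- fit_positional_frequency(w)
  X <- encode_windows(w, tab)
  expect_equal(dim(X), c(8L, 194L))
  expect_identical(colnames(X), feature_names(19))
  expect_false(anyNA(X))
  # determinism: identical windows encode identically
  X2 <- encode_windows(w, tab)
  expect_identical(X, X2)
  # spot-check individual entries against the standalone functions
  expect_equal(unname(X[1, "hydro_0"]), -4.5)             # central R
  expect_equal(unname(X[1, "aafreq_0"]), 1.0)
  expect_equal(unname(X[3, "gravy"]),
               unname(global_scale_features(w$peptide[3])[["gravy"]]))
  expect_equal(unname(X[5, "pI"]), isoelectric_point(w$peptide[5]))
  # name order is family-major, position-minor, globals last
  fn <- feature_names(19)
  expect_equal(fn[1], "atchley_1_-9")
  expect_equal(fn[20], "atchley_2_-9")
  expect_equal(utils::tail(fn, 4), c("avg_vdwv", "gravy", "net_charge", "pI"))
  expect_error(encode_windows(ws_from_peptides(random_windows(2, 11)), tab),
               "does not match")
})

test_that("feature vector length matches the printed sizes for all windows", {
  for (L in c(7, 11, 15, 19, 23, 27, 31, 35)) {
    expect_length(feature_names(L), 10 * L + 4)
  }
})
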