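test_that("formula parsing handles plain, grouped and case-sensitive input", {
  expect_equal(unclass(parse_formula("H2O"))[c("H", "O")], c(H = 2L, O = 1L))
  expect_equal(format_formula(parse_formula("C14H18N2O2")), "C14H18N2O2")
  # single-level group expansion: CH3(CH2)2OH = C3H8O
  expect_equal(format_formula(parse_formula("CH3(CH2)2OH")), "C3H8O")
  # Hill order normalization regardless of input order
  expect_equal(format_formula(c(O = 1, H = 2, C = 3)), "C3H2O")
  expect_equal(format_formula(parse_formula("NaClH")), "ClHNa") # no C: alphabetical
  # Co is cobalt, CO is carbon monoxide
  expect_equal(names(unclass(parse_formula("Co"))), "Co")
  expect_equal(sort(names(unclass(parse_formula("CO")))), c("C", "O"))

  expect_error(parse_formula("C0H2"), "zero count")
  expect_error(parse_formula("Xy3"), "unknown element")
  expect_error(parse_formula("C(H(O)2)3"), "nested")
  expect_error(parse_formula("C(H2"), "unclosed")
  expect_error(parse_formula(""), "non-empty")
})

test_that("formula parse/serialize round-trips", {
  set.seed(11)
  for (i in 1:50) {
    counts <- c(C = sample(1:40, 1), H = sample(1:60, 1))
    if (runif(1) < 0.7) counts["N"] <- sample(1:5, 1)
    if (runif(1) < 0.7) counts["O"] <- sample(1:9, 1)
    if (runif(1) < 0.3) counts["S"] <- 1L
    txt <- format_formula(counts)
    expect_identical(format_formula(parse_formula(txt)), txt)
  }
})

test_that("monoisotopic and average masses match reference values", {
  # L-tryptophan C11H12N2O2: NIST monoisotopic sum and atomic-weight sum
  expect_equal(monoisotopic_mass("C11H12N2O2"), 204.0899, tolerance = 1e-4 / 204)
  expect_equal(average_mass("C11H12N2O2"), 204.23, tolerance = 0.01 / 204)
  expect_equal(monoisotopic_mass("H2O"), 18.0106, tolerance = 1e-4 / 18)
  expect_equal(average_mass("H2O"), 18.015, tolerance = 1e-3 / 18)
  expect_identical(monoisotopic_mass(as_formula(NULL)), 0)
  expect_identical(average_mass(as_formula(NULL)), 0)
})

test_that("masses agree with an independent toolkit on random formulas", {
  # oracle values computed once with pyteomics.mass.calculate_mass
  vectors <- list(
    list(formula = "C10H12O6", mono = 228.063388, avg = 228.1991),
    list(formula = "C12H20N4O4", mono = 284.148455, avg = 284.3121),
    list(formula = "C28H42NO4", mono = 456.311384, avg = 456.6384),
    list(formula = "C15H25N3O3", mono = 295.189592, avg = 295.3779),
    list(formula = "C27H43O8", mono = 495.295793, avg = 495.6266),
    list(formula = "C28H46N3O5", mono = 504.343747, avg = 504.6830),
    list(formula = "C6H11O6", mono = 179.055563, avg = 179.1482),
    list(formula = "C23H39NO5", mono = 409.282823, avg = 409.5603),
    list(formula = "C19H32O4", mono = 324.230060, avg = 324.4557),
    list(formula = "C30H50", mono = 410.391252, avg = 410.7191),
    list(formula = "C9H16N4O8", mono = 308.096813, avg = 308.2457),
    list(formula = "C16H26N3O5S", mono = 372.159317, avg = 372.4602),
    list(formula = "C19H32NO4P", mono = 369.206895, avg = 369.4362),
    list(formula = "C18H29O7", mono = 357.191328, avg = 357.4194),
    list(formula = "C14H21N", mono = 203.167400, avg = 203.3238),
    list(formula = "C5H6N2O5", mono = 174.027671, avg = 174.1118),
    list(formula = "C29H48O7", mono = 508.340004, avg = 508.6883),
    list(formula = "C20H33", mono = 273.258226, avg = 273.4768),
    list(formula = "C4H7N2O5S2", mono = 226.979638, avg = 227.2385),
    list(formula = "C10H12N4O3", mono = 236.090940, avg = 236.2277),
    list(formula = "C23H36OP", mono = 359.250377, avg = 359.5060),
    list(formula = "C29H46N4O8S", mono = 610.303635, avg = 610.7635),
    list(formula = "C9H14NO", mono = 152.107539, avg = 152.2139),
    list(formula = "C9H18N4O6S", mono = 310.094705, avg = 310.3276)
  )
  for (v in vectors) {
    expect_lt(abs(monoisotopic_mass(v$formula) - v$mono), 1e-3)
    expect_lt(abs(average_mass(v$formula) - v$avg), 1e-3)
  }
})

test_that("InChIKey validation enforces the 14-10-1 uppercase layout", {
  good <- "QIVBCDIJIAJPQS-VIFPVBQESA-N"
  expect_identical(validate_inchikey(good), good)
  expect_true(is.na(inchikey_issue(good)))

  expect_identical(inchikey_issue(tolower(good)), "bad_charset")
  expect_identical(inchikey_issue("ABC-DEF"), "bad_length")
  expect_identical(inchikey_issue("QIVBCDIJIAJPQSX-IFPVBQESA-N"), "bad_hyphenation")
  expect_identical(inchikey_issue("QIVBCDIJ1AJPQS-VIFPVBQESA-N"), "bad_charset")

  err <- tryCatch(validate_inchikey("ABC-DEF"), pb_inchikey_error = function(e) e)
  expect_identical(err$reason, "bad_length")
})

test_that("ion annotation grammar parses and round-trips", {
  a <- parse_ion_annotation("[M+H]+")
  expect_equal(a$multimer, 1L)
  expect_equal(a$charge, 1L)
  expect_identical(a$polarity, "+")
  expect_identical(a$terms$species, "H")
  expect_identical(a$terms$sign, 1L)

  b <- parse_ion_annotation("[2M+Na]+")
  expect_equal(b$multimer, 2L)
  expect_identical(b$terms$species, "Na")

  c1 <- parse_ion_annotation("[M+H-H2O]+")
  expect_identical(c1$terms$sign, c(1L, -1L))
  expect_identical(c1$terms$species, c("H", "H2O"))

  d <- parse_ion_annotation("[M-2H]2-")
  expect_equal(d$charge, 2L)
  expect_identical(d$polarity, "-")
  expect_identical(d$terms$species, "H2") # -2H folded into one species

  for (txt in c("[M+H]+", "[2M+Na]+", "[M+H-H2O]+", "[M-H]-", "[3M+K]2+")) {
    expect_identical(format_ion_annotation(parse_ion_annotation(txt)), txt)
  }

  expect_error(parse_ion_annotation("M+H+"), "cannot parse")
  expect_error(parse_ion_annotation("[M+H]"), "cannot parse")
  expect_error(parse_ion_annotation("[M+Xx]+"), "unknown element")
})

test_that("theoretical m/z applies adducts, multimers, charge and electron mass", {
  expect_equal(round(theoretical_mz("C14H18N2O2", "[M+H]+"), 4), 247.1441)
  expect_equal(round(theoretical_mz("C11H12N2O2", "[M+H]+"), 4), 205.0972)
  expect_equal(round(theoretical_mz("C11H12N2O2", "[M-H]-"), 4), 203.0826)

  # [M+H]+ adds exactly one proton
  prot <- mass_constants()$proton_mass
  set.seed(5)
  for (i in 1:20) {
    f <- format_formula(c(C = sample(2:30, 1), H = sample(4:50, 1),
                          O = sample(1:8, 1)))
    expect_lt(abs(theoretical_mz(f, "[M+H]+") - monoisotopic_mass(f) - prot), 1e-6)
    # linearity in multimer count
    expect_lt(abs(theoretical_mz(f, "[2M+H]+") - theoretical_mz(f, "[M+H]+") -
                    monoisotopic_mass(f)), 1e-6)
  }

  # doubly charged: half the (mass + 2 protons)
  f <- "C20H30N4O6"
  expect_equal(theoretical_mz(f, "[M+2H]2+"),
               (monoisotopic_mass(f) + 2 * prot) / 2, tolerance = 1e-12)
})

test_that("ppm error is the signed relative deviation in 1e6 units", {
  expect_identical(ppm_error(247.1441, 247.1441), 0)
  expect_equal(ppm_error(247.1453, 247.1441), 4.8555, tolerance = 1e-4)
  expect_equal(ppm_error(247.1429, 247.1441), -4.8555, tolerance = 1e-4)
  expect_error(ppm_error(100, 0), "positive")
})

test_that("mass tolerance validates value and unit", {
  tol <- mass_tolerance(5, "ppm")
  expect_identical(tol$unit, "ppm")
  expect_error(mass_tolerance(0, "ppm"), "positive")
  expect_error(mass_tolerance(-1, "Da"), "positive")
  expect_error(mass_tolerance(5, "mDa"))
})
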