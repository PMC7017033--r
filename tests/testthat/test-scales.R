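test_that("built-in ionization tables are complete and validated", {
  for (set in c("expasy", "calculator")) {
    tab <- ionization_table(set)
    expect_s3_class(tab, "ionization_table")
    expect_equal(nrow(tab), 9)  # 7 side chains + 2 termini
    expect_setequal(tab$group,
                    c("D", "E", "C", "Y", "K", "R", "H", "Nterm", "Cterm"))
    expect_true(all(tab$pKa > 0 & tab$pKa < 14))
    expect_true(all(tab$charge %in% c(-1L, 1L)))
    expect_identical(attr(tab, "name"), set)
  }
  expect_error(ionization_table("nosuch"), "unknown built-in pKa set")
})

test_that("config files round-trip and incomplete tables are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- ionization_table()
  write_ionization_table(tab, f)
  back <- read_ionization_table(f)
  expect_equal(back$pKa, tab$pKa)
  expect_equal(back$group, tab$group)
  expect_identical(attr(back, "name"), attr(tab, "name"))

  # drop tyrosine -> load error names the missing group
  crippled <- as.data.frame(tab)[tab$group != "Y", ]
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# name: broken",
               "group\tpKa\tcharge",
               paste(crippled$group, crippled$pKa, crippled$charge,
                     sep = "\t")), f2)
  expect_error(read_ionization_table(f2), "Y")

  # non-numeric pKa -> parse error
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("group\tpKa\tcharge", "D\toops\t-1"), f3)
  expect_error(read_ionization_table(f3))

  g <- withr::local_tempfile(fileext = ".tsv")
  sc <- lipophilicity_scale()
  write_lipophilicity_scale(sc, g)
  back2 <- read_lipophilicity_scale(g)
  expect_equal(back2$neutral, sc$neutral)
  expect_equal(back2$charged, sc$charged)
})

test_that("lipophilicity scale invariants hold and violations are caught", {
  sc <- lipophilicity_scale()
  expect_setequal(sc$aa, AA_STD)
  ion <- sc$aa %in% c("D", "E", "C", "Y", "K", "R", "H")
  expect_true(all(sc$charged[ion] <= sc$neutral[ion]))
  expect_true(all(sc$charged[!ion] == sc$neutral[!ion]))

  bad <- as.data.frame(sc)
  bad$charged[bad$aa == "D"] <- bad$neutral[bad$aa == "D"] + 1
  expect_error(pHsol:::validate_lipophilicity_scale(bad, "bad"),
               "exceeds neutral")
})

test_that("residue lipophilicity follows Henderson-Hasselbalch mixing", {
  sc <- lipophilicity_scale()
  pka <- ionization_table()

  # non-ionizable residues do not titrate
  expect_identical(residue_lipophilicity("A", 2),
                   residue_lipophilicity("A", 12))

  # at pH = pKa the two species are equimolar
  pkd <- pka["D", "pKa"]
  expect_equal(residue_lipophilicity("D", pkd),
               (sc["D", "neutral"] + sc["D", "charged"]) / 2,
               tolerance = 1e-14)

  # three pH units past the pKa the neutral fraction is 10^-3
  ln <- sc["D", "neutral"]; lc <- sc["D", "charged"]
  expected <- (1 / 1001) * ln + (1000 / 1001) * lc
  got <- residue_lipophilicity("D", pkd + 3)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_lt(abs(got - lc), 1e-3 * abs(ln - lc) * 1.001)

  # matches the direct-arithmetic oracle across residues and pH
  for (ph in c(2.5, 5, 7.4, 10.5)) {
    expect_equal(residue_lipophilicity(AA_STD, ph),
                 unname(oracle_residue_lipo(AA_STD, ph)),
                 tolerance = 1e-13)
  }
})

test_that("titration curves are monotone with the two species as asymptotes", {
  sc <- lipophilicity_scale()
  grid <- seq(0.5, 13.5, by = 0.1)
  for (a in c("D", "E", "C", "Y", "K", "R", "H")) {
    v <- residue_lipophilicity(rep(a, length(grid)), grid)
    ln <- sc[a, "neutral"]; lc <- sc[a, "charged"]
    # acids fall with pH, bases rise (charged species less lipophilic)
    gap <- ln - lc
    # the residual minority-species fraction at the grid edge scales the
    # distance to the asymptote (pKa(R) sits only 1.5 units from pH 13.5)
    if (a %in% c("D", "E", "C", "Y")) {
      expect_true(all(diff(v) <= 0), info = a)
      expect_lt(abs(v[1] - ln), 0.05 * gap)
      expect_lt(abs(v[length(v)] - lc), 0.05 * gap)
    } else {
      expect_true(all(diff(v) >= 0), info = a)
      expect_lt(abs(v[1] - lc), 0.05 * gap)
      expect_lt(abs(v[length(v)] - ln), 0.05 * gap)
    }
    expect_true(all(v >= min(ln, lc) & v <= max(ln, lc)))
  }
})

test_that("a penalty-free scale makes the whole pipeline pH-independent", {
  fs <- flat_scale()
  s <- rand_seq(80, seed = 11)
  vals <- vapply(c(2, 5, 7.4, 11),
                 function(ph) global_lipophilicity(s, ph, scale = fs),
                 numeric(1))
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-13)
})

test_that("unknown residue codes are rejected unless X mapping is enabled", {
  expect_error(residue_lipophilicity("B", 7), "unknown residue")
  expect_error(residue_lipophilicity("X", 7), "unknown residue")
  sc <- lipophilicity_scale()
  expect_equal(residue_lipophilicity("X", 7, allow_x = TRUE),
               mean(sc$neutral) * 1 + 0,  # X is treated as non-ionizable
               tolerance = 1e-12)
  expect_error(residue_lipophilicity("D", 0), "pH")
})
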