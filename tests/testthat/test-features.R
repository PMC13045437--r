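test_that("functional-group counting follows the documented patterns and priorities", {
  skip_if_no_chemminer()
  cases <- list(
    # name, smiles, expected nonzero counts
    list("phenol", "Oc1ccccc1", c(CtPh = 1)),
    list("ethanol", "CCO", c(CtOH = 1, CtMe = 1)),
    list("benzamide", "NC(=O)c1ccccc1", c(CtAm = 1)),  # amide subsumes N-H and C=O
    list("acetic acid", "CC(=O)O", c(CtCO2H = 1, CtMe = 1)),
    list("ethyl acetate", "CCOC(C)=O", c(CtRCO2R = 1, CtMe = 2)),
    list("methyl carbamate", "NC(=O)OC", c(CtRCO2R = 1, CtMe = 1)),  # ester wins over amide
    list("acetone", "CC(C)=O", c(CtR2CO = 1, CtMe = 2)),
    list("benzaldehyde", "O=Cc1ccccc1", c(CtAl = 1)),
    list("diethyl ether", "CCOCC", c(CtROR = 1, CtMe = 2)),
    list("anisole", "COc1ccccc1", c(CtROR = 1, CtMe = 1)),
    list("aniline", "Nc1ccccc1", c(CtNH2 = 1)),
    list("nitrobenzene", "O=[N+]([O-])c1ccccc1", c(CtNO2 = 1)),
    list("benzonitrile", "N#Cc1ccccc1", c(CtCN = 1)),
    list("1-bromo-4-iodobenzene", "Brc1ccc(I)cc1", c(CtBr = 1, CtI = 1)),
    list("fluoro-chloro-methane", "FCCl", c(CtF = 1, CtCl = 1))
  )
  counts <- count_functional_groups(
    stats::setNames(vapply(cases, `[[`, "", 2), vapply(cases, `[[`, "", 1)))
  for (k in seq_along(cases)) {
    expected <- stats::setNames(integer(16), fg_count_names())
    expected[names(cases[[k]][[3]])] <- cases[[k]][[3]]
    expect_equal(counts[k, ], expected, label = cases[[k]][[1]],
                 ignore_attr = FALSE)
  }
})

test_that("FG counts are invariant to SMILES atom ordering", {
  skip_if_no_chemminer()
  pairs <- list(
    c("Oc1ccccc1", "c1ccc(O)cc1"),
    c("CCOC(C)=O", "O=C(C)OCC"),
    c("NC(=O)c1ccccc1", "c1ccccc1C(N)=O"),
    c("CC(=O)O", "OC(=O)C"))
  for (p in pairs) {
    expect_equal(count_functional_groups(p[1]), count_functional_groups(p[2]),
                 label = p[1])
  }
})

test_that("carbonyl priority is exclusive: one count per carbonyl carbon", {
  skip_if_no_chemminer()
  carbonyl <- c("CtCO2H", "CtRCO2R", "CtAm", "CtAl", "CtR2CO")
  smiles <- c("CC(=O)O", "CCOC(C)=O", "NC(=O)C", "NC(=O)OC", "CC=O", "CC(C)=O")
  counts <- count_functional_groups(smiles)
  expect_true(all(rowSums(counts[, carbonyl]) == 1))
})

test_that("benzene-ring counting is restricted to six-membered carbocyclic aromatics", {
  skip_if_no_chemminer()
  expect_equal(count_benzene_rings(c("c1ccccc1", "CCCCCC",
                                     "c1ccc(-c2ccccc2)cc1",
                                     "c1ccc2ccccc2c1", "c1ccncc1")),
               c(1L, 0L, 2L, 2L, 0L))
})

test_that("unparsable structures raise an error naming the input", {
  skip_if_no_chemminer()
  expect_error(count_functional_groups("C(1"), "C\\(1")
})

test_that("solvent compositions are validated and optionally normalized", {
  v <- solvent_composition(hex = 0.7, ea = 0.3)
  expect_equal(sum(v), 1)
  expect_error(solvent_composition(hex = 0.5, ea = 0.3), "sum to")
  expect_equal(solvent_composition(hex = 0.4, ea = 0.4, normalize = TRUE),
               c(Hex = 0.5, EA = 0.5, DCM = 0, MeOH = 0, Et2O = 0))
  expect_error(solvent_composition(hex = 1.5, ea = -0.5), "\\[0, 1\\]")
})

test_that("assemble_features produces the canonical 23-vector", {
  rec <- tlc_record(solvent_composition(hex = 1), fg_counts(), 0, 0)
  x <- assemble_features(rec)
  expect_length(x, 23)
  expect_equal(names(x), tlc_feature_names())
  expect_equal(unname(x), c(1, rep(0, 22)))

  zero <- tlc_record(solvent_composition(dcm = 1), fg_counts(), 0, 0)
  expect_equal(sum(assemble_features(zero)), 1)  # only the DCM slot

  # a record built from the observed feature means: solvent slots first
  mean_solv <- c(Hex = 0.36, EA = 0.15, DCM = 0.40, MeOH = 0.014,
                 Et2O = 0.071)
  df <- example_dataset(1)
  df[, names(mean_solv)] <- as.list(mean_solv / sum(mean_solv))
  m <- assemble_features(df)
  expect_equal(unname(m[1, 1:5] * sum(mean_solv)), unname(mean_solv),
               tolerance = 1e-12)
})

test_that("dataset CSV round-trips losslessly and rejects bad rows", {
  d <- example_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_tlc_dataset(d, path)
  d2 <- read_tlc_dataset(path)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12)
  expect_identical(assemble_features(d2), assemble_features(d))

  # unknown column
  bad <- cbind(as.data.frame(d), Extra = 1)
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_tlc_dataset(path2), "Extra")

  # solvent sum violation is rejected with its row number in strict mode,
  # rescaled with a warning in normalize mode
  bad2 <- as.data.frame(d)
  bad2$Hex[2] <- bad2$Hex[2] - 0.2
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad2, path3, row.names = FALSE)
  expect_error(read_tlc_dataset(path3), "row\\(s\\) 2")
  expect_warning(d3 <- read_tlc_dataset(path3, solvent_mode = "normalize"),
                 "renormalized")
  expect_equal(unname(rowSums(d3[, solvent_names()])), rep(1, nrow(d3)),
               tolerance = 1e-9)

  # out-of-range Rf
  bad4 <- as.data.frame(d)
  bad4$Rf[3] <- 1.2
  path4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad4, path4, row.names = FALSE)
  expect_error(read_tlc_dataset(path4), "Rf outside")
})

test_that("featurize_smiles assembles a valid dataset from structures", {
  skip_if_no_chemminer()
  d <- featurize_smiles(c(phenol = "Oc1ccccc1", anisole = "COc1ccccc1"),
                        dm = c(1.2, 1.3),
                        solvent = data.frame(Hex = 0.7, EA = 0.3, DCM = 0,
                                             MeOH = 0, Et2O = 0))
  expect_s3_class(d, "tlc_dataset")
  expect_equal(d$CtPh, c(1L, 0L))
  expect_equal(d$CtROR, c(0L, 1L))
  expect_equal(d$NBen, c(1L, 1L))
})
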