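test_that("reference equations transcribe every printed coefficient exactly", {
  # solvent equation: pure-component probes are the coefficients
  expect_identical(psi_reference(hex = 1), -1.37)
  expect_identical(psi_reference(ea = 1), -0.20)
  expect_identical(psi_reference(dcm = 1), -1.02)
  expect_identical(psi_reference(meoh = 1), 4.65)
  expect_identical(psi_reference(et2o = 1), -0.45)
  expect_identical(psi_reference(), 0)  # no intercept

  # solute equation: finite differences isolate each printed coefficient
  expect_equal(xi_reference(0, 0), 0.69)
  expect_equal(xi_reference(1, 0) - xi_reference(0, 0), 0.37)
  expect_equal(xi_reference(0, 1) - xi_reference(0, 0), -0.35)
  expect_equal(xi_reference(1, 1) - xi_reference(1, 0) -
                 xi_reference(0, 1) + xi_reference(0, 0), -1)
  expect_equal(xi_reference(1, 1), -0.29)

  # Rf governing equation on the logit scale
  expect_equal(logit(rf_governing(0, 0)), 1.55)
  expect_equal(logit(rf_governing(1, 0)) - logit(rf_governing(0, 0)), 5.15)
  expect_equal(logit(rf_governing(0, 1)) - logit(rf_governing(0, 0)), 5.15)
})

test_that("the Rf governing equation behaves like a logistic in both indices", {
  expect_equal(rf_governing(0, 0), 1 / (1 + exp(-1.55)))
  expect_equal(rf_governing(-1.55 / 5.15, 0), 0.5)
  expect_equal(rf_governing(-1e4, 0), 0)
  expect_equal(rf_governing(1e4, 0), 1)
  # strictly increasing in both arguments, range (0, 1)
  g <- seq(-3, 3, length.out = 41)
  expect_true(all(diff(rf_governing(g, 0.3)) > 0))
  expect_true(all(diff(rf_governing(-0.2, g)) > 0))
  expect_true(all(rf_governing(g, rev(g)) > 0 & rf_governing(g, rev(g)) < 1))
})

test_that("printed one-hot probe weights preserve the polarity ordering", {
  w <- fg_probe_weights()
  ordering <- c("CtAm", "CtCO2H", "CtNH2", "CtOH", "CtPh", "CtAl", "CtR2CO",
                "CtRCO2R", "CtNO2", "CtCN", "CtF", "CtCl", "CtROR", "CtMe",
                "CtBr", "CtI")
  expect_true(all(diff(w[ordering]) <= 0))
  expect_equal(unname(w["CtAm"]), 1.43)
  expect_equal(unname(w["CtI"]), -2.97)

  one_amide <- fg_counts(CtAm = 1)
  expect_equal(fg_probe_linear(one_amide), 1.43)
  expect_equal(fg_probe_linear(fg_counts(CtI = 1)), -2.97)
  expect_equal(fg_probe_linear(fg_counts()), 0)
  # linear: two amides double the contribution
  expect_equal(fg_probe_linear(fg_counts(CtAm = 2)), 2.86)
})

test_that("interpretive alpha/beta fixtures evaluate their documented reading", {
  # gamma baselines at zero counts, hand-evaluated from the documented forms
  zero <- fg_counts()
  b <- beta_reference(zero)
  g <- b$gamma[1, ]
  expect_equal(unname(g["gamma1"]), 5.16 * log(0.86))
  expect_equal(unname(g["gamma2"]), -0.73)
  expect_equal(unname(g["gamma3"]), 0 / (-0.14) - 0.29)
  expect_equal(unname(g["gamma4"]), -2.96 - 2.96 * 0.66 * (-1.20))
  expect_equal(unname(g["gamma5"]), 2.54 * 1.21 * (2.73 * (-0.52)) + 2)
  beta0 <- 0.07 * g[["gamma2"]] -
    (0.003 * g[["gamma5"]] * (2 * g[["gamma2"]] - g[["gamma3"]] - g[["gamma4"]]) - 0.27) *
      (g[["gamma1"]] - g[["gamma5"]] +
         (g[["gamma2"]] - g[["gamma4"]]) * (0.14 * g[["gamma5"]] + 0.35)) - 0.63
  expect_equal(b$beta, beta0)

  # one amide raises gamma1 by exactly its linear weight
  g1 <- beta_reference(fg_counts(CtAm = 1))$gamma[1, "gamma1"]
  expect_equal(unname(g1 - g["gamma1"]), 5.16)

  # alpha surrogate fixture at a hand-checked point
  expect_equal(alpha_reference(0, 0),
               (-0.29) * (2.28 + 1.66) - 0.74)
})

test_that("decomposing the governing equation yields the partial constants", {
  expect_equal(decompose_rf("xi", 0)$constant, 1.55)
  expect_equal(decompose_rf("xi", 1)$constant, 6.70)
  expect_equal(decompose_rf("psi", 0)$constant, 1.55)
  h <- decompose_rf("xi", 0.2)$curve
  g <- seq(-2, 2, length.out = 21)
  expect_true(all(diff(h(g)) > 0))
  # the partial curve agrees with the full equation at the fixed value
  expect_equal(h(g), rf_governing(g, 0.2))
})

test_that("value flow traces every index and matches direct evaluation", {
  chain <- reference_chain()
  d <- example_dataset(1)
  x <- assemble_features(d)[1, ]
  fl <- value_flow(chain, x)
  expect_s3_class(fl, "uhsr_flow")
  rf_direct <- predict(chain, d)
  expect_equal(fl$value[fl$node == "rf"], rf_direct, tolerance = 1e-9)
  # terminal equals the composed reference fixtures
  nodes <- fl$value[match(c("psi", "alpha", "beta"), fl$node)]
  expect_equal(fl$value[fl$node == "rf"],
               rf_governing(nodes[1], xi_reference(nodes[2], nodes[3])),
               tolerance = 1e-9)

  # setting CtI = 1 perturbs the solute branch only
  x2 <- x
  x2["CtI"] <- 1
  fl2 <- value_flow(chain, x2)
  changed <- fl2$node[abs(fl2$value - fl$value) > 1e-12]
  expect_true(all(c("CtI", "beta", "xi", "rf") %in% changed))
  expect_false("psi" %in% changed)
})

test_that("perturbation importance has the documented structure", {
  set.seed(1)
  d <- data.frame(x1 = rnorm(100), x2 = rnorm(100), x3 = rep(1, 100))
  # equation using only x1
  imp <- feature_importance(function(z) 3 * z$x1, d)
  expect_equal(imp$importance[imp$feature == "x1"], 1)
  expect_equal(sum(imp$importance), 1)
  expect_true(imp$zero_variance[imp$feature == "x3"])

  # symmetric equation with equal-variance inputs
  d2 <- data.frame(x1 = rnorm(200), x2 = rnorm(200))
  d2$x2 <- d2$x2 * sd(d2$x1) / sd(d2$x2)
  imp2 <- feature_importance(function(z) z$x1 + z$x2, d2)
  expect_equal(imp2$importance, c(0.5, 0.5), tolerance = 1e-9)

  # on synthetic compositions the importance of each solvent feature for
  # the linear solvent equation reduces to |coefficient| * sd, and MeOH
  # has by far the largest per-unit (per-sd) sensitivity
  syn <- gen_dataset(synth_config(n_samples = 400, seed = 11))
  comp <- as.data.frame(syn$data)[, solvent_names()]
  imp3 <- feature_importance(function(z) psi_reference(as.matrix(z)), comp)
  coefs <- c(Hex = -1.37, EA = -0.20, DCM = -1.02, MeOH = 4.65,
             Et2O = -0.45)
  expected <- abs(coefs) * vapply(comp, sd, numeric(1))
  expect_equal(imp3$importance[match(names(coefs), imp3$feature)],
               unname(expected / sum(expected)), tolerance = 1e-9)
  per_sd <- imp3$importance / vapply(comp, sd, numeric(1))[imp3$feature]
  expect_equal(imp3$feature[which.max(per_sd)], "MeOH")
})

test_that("reference equation strings round-trip through the SR evaluator", {
  eqs <- reference_equation_strings()
  set.seed(4)
  comp <- gen_solvents(20, synth_config(seed = 4))
  X <- comp[, solvent_names()]
  expect_equal(sr_evaluate(eqs[["psi"]], X), psi_reference(as.matrix(X)))
  ab <- data.frame(alpha = rnorm(20), beta = rnorm(20))
  expect_equal(sr_evaluate(eqs[["xi"]], ab), xi_reference(ab$alpha, ab$beta))
  lat <- data.frame(psi = rnorm(20), xi = rnorm(20))
  expect_equal(sr_evaluate(eqs[["rf"]], lat), rf_governing(lat$psi, lat$xi))
})
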