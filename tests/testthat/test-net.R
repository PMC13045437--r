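test_that("network construction mirrors the stage groupings", {
  g <- default_groupings()
  n1 <- build_network(g$stage1, tiny_hp())
  expect_length(g$stage1$groups, 2)
  expect_equal(g$stage1$latents, c("psi", "xi"))
  expect_length(g$stage3$groups, 7)
  expect_equal(g$stage3$latents, c("psi", "alpha", paste0("gamma", 1:5)))
  # every stage consumes all 23 features
  for (s in g) expect_setequal(unlist(s$groups), 1:23)
  # subgroup sizes of the functional-group split
  expect_equal(lengths(g$stage3$groups[paste0("FG", 1:5)]),
               c(FG1 = 2L, FG2 = 3L, FG3 = 2L, FG4 = 5L, FG5 = 4L))
  expect_length(n1$params, 2 * 6 + 4)  # two sub-models x 3 layers, head

  expect_error(feature_grouping(list(a = 1:5, b = 5:8)), "disjoint")
  expect_error(feature_grouping(list(a = c(1, 24))), "1..23")
})

test_that("training is seeded-reproducible and latents are standardized", {
  syn <- gen_dataset(synth_config(n_samples = 500, noise_sd = 0.05, seed = 5))
  hp <- tiny_hp(epochs = 40L)
  s1 <- train_network(build_network(default_groupings()$stage1, hp),
                      syn$data, hp = hp)
  s2 <- train_network(build_network(default_groupings()$stage1, hp),
                      syn$data, hp = hp)
  expect_identical(s1$loss_trace, s2$loss_trace)  # bit-identical traces
  expect_identical(s1$params, s2$params)

  z <- extract_latents(s1, syn$data)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-6)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-6)
})

test_that("latents are group-local by construction", {
  syn <- gen_dataset(synth_config(n_samples = 500, noise_sd = 0.05, seed = 5))
  hp <- tiny_hp(epochs = 30L)
  st <- train_network(build_network(default_groupings()$stage1, hp),
                      syn$data, hp = hp)
  X <- assemble_features(syn$data)

  # identical solvent block, different solute block: psi identical
  Xa <- X[1:10, , drop = FALSE]
  Xb <- Xa
  Xb[, 6:23] <- X[11:20, 6:23]
  za <- extract_latents(st, Xa)
  zb <- extract_latents(st, Xb)
  expect_identical(za[, "psi"], zb[, "psi"])
  expect_false(any(za[, "xi"] == zb[, "xi"]))

  # perturbing a solvent feature leaves xi untouched
  Xc <- Xa
  Xc[, "MeOH"] <- Xc[, "MeOH"] + 0.5
  expect_identical(extract_latents(st, Xc)[, "xi"], za[, "xi"])

  # head output is strictly inside (0, 1) on in-range inputs and cannot
  # escape [0, 1] even where the sigmoid saturates in floating point
  other <- gen_dataset(synth_config(n_samples = 200, noise_sd = 0.1,
                                    seed = 77))
  p <- predict(st, other$data)
  expect_true(all(p > 0 & p < 1))
  Xw <- matrix(rnorm(23 * 50, sd = 50), 50,
               dimnames = list(NULL, tlc_feature_names()))
  pw <- predict(st, Xw)
  expect_true(all(pw >= 0 & pw <= 1))
})

test_that("one-hot probes read per-feature latent contributions", {
  syn <- gen_dataset(synth_config(n_samples = 600, noise_sd = 0.02, seed = 6))
  hp <- tiny_hp(epochs = 120L)
  st <- train_network(build_network(default_groupings()$stage2, hp),
                      syn$data, hp = hp)
  st <- canonicalize_sign(st, syn$data)

  # zero probe is the sub-model's bias latent, identical across calls
  expect_identical(probe(st, "FG"), probe(st, "FG"))
  # one-hot probe by name and by in-group index agree
  expect_equal(probe(st, "FG", "CtPh"), probe(st, "FG", 1))
  expect_error(probe(st, "FG", "MeOH"), "not inside")
  expect_error(probe(st, "solvent", 9), "outside group")
  expect_error(probe(st, "nope", 1), "unknown group")

  # probes of the FG one-hots rank like the generator's weights
  w <- fg_probe_weights()
  probes <- vapply(names(w), function(g) probe(st, "FG", g), numeric(1))
  expect_gt(cor(probes, w, method = "spearman"), 0.9)
})

test_that("sign canonicalization is idempotent and fixes stated correlations", {
  syn <- gen_dataset(synth_config(n_samples = 500, noise_sd = 0.05, seed = 7))
  hp <- tiny_hp(epochs = 60L)
  st <- train_network(build_network(default_groupings()$stage1, hp),
                      syn$data, hp = hp)
  c1 <- canonicalize_sign(st, syn$data)
  z <- extract_latents(c1, syn$data)
  expect_gte(cor(z[, "psi"], syn$data$MeOH), 0)
  expect_gte(cor(z[, "xi"], syn$data$Rf), 0)
  c2 <- canonicalize_sign(c1, syn$data)
  expect_identical(c1$standardization, c2$standardization)

  # forcing a flip: demanding the opposite sign inverts the latent
  flipped <- canonicalize_sign(st, syn$data,
                               rules = list(list(latent = "xi",
                                                 against = ".target")))
  z2 <- extract_latents(flipped, syn$data)
  expect_gte(cor(z2[, "xi"], syn$data$Rf), 0)
})

test_that("the three-stage hierarchy produces the unified latent table", {
  syn <- gen_dataset(synth_config(n_samples = 400, noise_sd = 0.05, seed = 8))
  hier <- run_hierarchy(syn$data, hp = tiny_hp(epochs = 25L))
  expect_named(hier$latents,
               c("id", "psi", "xi", "alpha", "beta", paste0("gamma", 1:5)))
  expect_equal(nrow(hier$latents), 400)
  expect_true(all(is.finite(as.matrix(hier$latents[, -1]))))

  # dropping the FGdist group from stage 2 leaves features unconsumed
  bad <- default_groupings()
  bad$stage2 <- feature_grouping(list(solvent = 1:5, FG = 6:21),
                                 latents = c("psi", "beta"))
  expect_error(run_hierarchy(syn$data, hp = tiny_hp(epochs = 5L),
                             groupings = bad),
               "incomplete cover")
})

test_that("stage checkpoints round-trip through save/load with a JSON sidecar", {
  syn <- gen_dataset(synth_config(n_samples = 400, noise_sd = 0.05, seed = 9))
  hp <- tiny_hp(epochs = 10L)
  st <- train_network(build_network(default_groupings()$stage1, hp),
                      syn$data, hp = hp)
  path <- withr::local_tempfile(fileext = ".rds")
  save_stage(st, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(unlist(side$latents), c("psi", "xi"))
  st2 <- load_stage(path)
  expect_identical(extract_latents(st2, syn$data),
                   extract_latents(st, syn$data))
})

test_that("training preconditions are enforced", {
  syn <- gen_dataset(synth_config(n_samples = 120, noise_sd = 0, seed = 1))
  hp <- uhsr_hyperparams(batch_size = 2048L, epochs = 2L)
  net <- build_network(default_groupings()$stage1, hp)
  expect_error(train_network(net, syn$data, hp = hp), "two minibatches")
  d <- syn$data
  d$Rf[1] <- NA
  expect_error(train_network(net, d, hp = tiny_hp(epochs = 2L)),
               "observed Rf")
})
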