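#' Configuration of the synthetic TLC data generator
#'
#' The generator emulates the shape of a high-throughput TLC screen: binary
#' mobile phases drawn from the three systems n-hexane/ethyl acetate,
#' n-hexane/diethyl ether and methanol/dichloromethane over a 17-point
#' composition grid (methanol capped at 10 volume-percent), solute
#' functional-group counts with marginals matching the observed feature
#' statistics, and Rf values produced by the reference governing equations
#' plus logit-scale noise.
#'
#' @param n_samples number of records.
#' @param noise_sd standard deviation of Gaussian noise added on the logit
#'   scale (0.05 default; 0 gives noiseless Rf).
#' @param system_weights sampling weights of the three mobile-phase systems
#'   `HexEA`, `HexEt2O`, `MeOHDCM`.
#' @param composition_mode `"grid"` (deterministic largest-remainder
#'   allocation over the 17 compositions; n = 17 yields each exactly once)
#'   or `"sample"` (random draws).
#' @param fg_rates Poisson rates of the 16 counts (defaults: the observed
#'   feature means), truncated at `fg_cap`.
#' @param fg_cap maximum count per group.
#' @param nben_probs distribution of the benzene-ring count over 0..3.
#' @param dm_mean,dm_sd dipole-moment normal parameters (truncated at 0).
#' @param seed RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 3000L, noise_sd = 0.05,
                         system_weights = c(HexEA = 0.43, HexEt2O = 0.16,
                                            MeOHDCM = 0.41),
                         composition_mode = c("grid", "sample"),
                         fg_rates = NULL, fg_cap = 3L,
                         nben_probs = c(0.08, 0.74, 0.16, 0.02),
                         dm_mean = 1.34, dm_sd = 0.74, seed = 0L) {
  composition_mode <- match.arg(composition_mode)
  if (is.null(fg_rates)) {
    fg_rates <- c(CtPh = 0.15, CtOH = 0.04, CtAl = 0.19, CtCO2H = 0.03,
                  CtRCO2R = 0.10, CtR2CO = 0.35, CtROR = 0.17, CtCN = 0.06,
                  CtNH2 = 0.08, CtNO2 = 0.06, CtAm = 0.02, CtMe = 0.20,
                  CtF = 0.25, CtCl = 0.11, CtBr = 0.15, CtI = 0.12)
  }
  stopifnot(n_samples >= 1, noise_sd >= 0, all(fg_rates >= 0),
            abs(sum(nben_probs) - 1) < 1e-9)
  structure(list(n_samples = as.integer(n_samples), noise_sd = noise_sd,
                 system_weights = system_weights / sum(system_weights),
                 composition_mode = composition_mode,
                 fg_rates = fg_rates[fg_count_names()], fg_cap = as.integer(fg_cap),
                 nben_probs = nben_probs, dm_mean = dm_mean, dm_sd = dm_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# the 17-point composition grid: minor-component fractions per system
synth_composition_grid <- function() {
  ea <- c(0.09, 0.17, 0.33, 0.50, 0.67)
  et <- c(0.17, 0.33, 0.50, 0.55, 0.67)
  me <- c(0, 0.01, 0.02, 0.03, 0.04, 0.056, 0.08)
  grid <- rbind(
    data.frame(system = "HexEA", Hex = 1 - ea, EA = ea, DCM = 0, MeOH = 0,
               Et2O = 0),
    data.frame(system = "HexEt2O", Hex = 1 - et, EA = 0, DCM = 0, MeOH = 0,
               Et2O = et),
    data.frame(system = "MeOHDCM", Hex = 0, EA = 0, DCM = 1 - me, MeOH = me,
               Et2O = 0))
  grid
}

#' Generate mobile-phase compositions
#'
#' Binary mixtures from the three systems over the 17-point grid; in
#' `"grid"` mode records are allocated over the grid deterministically in
#' proportion to the system weights (largest-remainder rounding), in
#' `"sample"` mode they are drawn at random.  Rows are shuffled (seeded).
#'
#' @param n number of compositions.
#' @param config a [synth_config()].
#' @return data.frame with columns `system, Hex, EA, DCM, MeOH, Et2O`.
#' @export
gen_solvents <- function(n, config = synth_config()) {
  grid <- synth_composition_grid()
  w_sys <- config$system_weights[grid$system]
  sizes <- table(grid$system)[unique(grid$system)]
  w <- as.numeric(w_sys / sizes[grid$system])
  w <- w / sum(w)
  with_seed(config$seed, {
    rows <- if (config$composition_mode == "grid") {
      counts <- floor(n * w)
      rem <- n - sum(counts)
      if (rem > 0) {
        extra <- order(n * w - counts, decreasing = TRUE)[seq_len(rem)]
        counts[extra] <- counts[extra] + 1
      }
      rep(seq_len(nrow(grid)), counts)
    } else {
      sample.int(nrow(grid), n, replace = TRUE, prob = w)
    }
    out <- grid[sample(rows), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

rtrunc_pois <- function(n, lambda, cap) {
  pmin(stats::rpois(n, lambda), cap)
}

#' Generate solute descriptor vectors
#'
#' Functional-group counts are truncated-Poisson with the configured rates
#' (cap 3); the benzene-ring count is drawn over 0..3 with mean about 1.12;
#' the dipole moment is normal(1.34, 0.74) truncated at zero.
#'
#' @param n number of solutes.
#' @param config a [synth_config()].
#' @return data.frame with the 16 count columns plus `NBen` and `DM`.
#' @export
gen_solutes <- function(n, config = synth_config()) {
  with_seed(config$seed + 1L, {
    fg <- vapply(fg_count_names(), function(g) {
      rtrunc_pois(n, config$fg_rates[[g]], config$fg_cap)
    }, numeric(n))
    if (n == 1L) fg <- matrix(fg, 1, dimnames = list(NULL, fg_count_names()))
    nben <- sample(0:3, n, replace = TRUE, prob = config$nben_probs)
    dm <- abs(stats::rnorm(n, config$dm_mean, config$dm_sd))
    data.frame(fg, NBen = nben, DM = dm, check.names = FALSE)
  })
}

#' Generate a synthetic TLC dataset from the reference equations
#'
#' The mechanism is exactly the reference-equation chain: psi from the
#' composition via [psi_reference()]; beta as the standardized linear-probe
#' index [fg_probe_linear()]; alpha as the standardized affine surrogate
#' `0.5 DM + 0.5 NBen`; xi via [xi_reference()]; noiseless Rf via
#' [rf_governing()]; observed Rf as `sigma(logit(Rf_true) + eps)` with
#' `eps ~ N(0, noise_sd)`.  No second implementation of the mechanism
#' exists.  The full truth table is stored and exactly regenerable from the
#' config and seed.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_dataset` with elements `data` (a
#'   `tlc_dataset` with observed Rf), `truth` (data.frame
#'   `id, psi, xi, alpha, beta, rf_true`), `fg_weights` (the generator's
#'   per-group beta weights) and `config`.
#' @export
gen_dataset <- function(config = synth_config()) {
  n <- config$n_samples
  solv <- gen_solvents(n, config)
  solu <- gen_solutes(n, config)
  psi <- psi_reference(solv$Hex, solv$EA, solv$DCM, solv$MeOH, solv$Et2O)
  beta_raw <- fg_probe_linear(solu[, fg_count_names()])
  alpha_raw <- 0.5 * solu$DM + 0.5 * solu$NBen
  std <- function(v) {
    s <- stats::sd(v)
    if (s == 0) {
      warning("zero-variance latent in synthetic generator")
      s <- 1
    }
    (v - mean(v)) / s
  }
  alpha <- std(alpha_raw)
  beta <- std(beta_raw)
  xi <- xi_reference(alpha, beta)
  rf_true <- rf_governing(psi, xi)
  rf_obs <- with_seed(config$seed + 2L, {
    if (config$noise_sd > 0) {
      sigmoid(logit(rf_true) + stats::rnorm(n, 0, config$noise_sd))
    } else rf_true
  })
  id <- sprintf("s%d", seq_len(n))
  data <- tlc_dataset(solv[, solvent_names()], solu[, fg_count_names()],
                      n_ben = solu$NBen, dm = solu$DM, rf = rf_obs, id = id)
  truth <- data.frame(id = id, psi = psi, xi = xi, alpha = alpha,
                      beta = beta, rf_true = rf_true)
  structure(list(data = data, truth = truth,
                 fg_weights = fg_probe_weights(), config = config),
            class = "synth_dataset")
}
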