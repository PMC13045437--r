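#' Goodness-of-fit metrics
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` and
#' `RMSE = sqrt(mean((y - yhat)^2))`, plus Pearson and Spearman
#' correlations.  With a zero-variance response R2 is undefined and
#' reported as `NA` with `r2_undefined = TRUE`.
#'
#' @param y observed values.
#' @param y_hat predictions (same length, >= 2).
#' @return list of class `uhsr_metrics`: `r2`, `rmse`, `pearson_r`,
#'   `spearman_rs`, `n`, `r2_undefined`.
#' @export
compute_metrics <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  if (anyNA(y) || anyNA(y_hat)) stop("metrics need complete observations")
  ss_res <- sum((y - y_hat)^2)
  ss_tot <- sum((y - mean(y))^2)
  undefined <- ss_tot == 0
  r2 <- if (undefined) NA_real_ else 1 - ss_res / ss_tot
  rmse <- sqrt(mean((y - y_hat)^2))
  pr <- if (stats::sd(y) == 0 || stats::sd(y_hat) == 0) {
    NA_real_
  } else stats::cor(y, y_hat)
  rs <- if (stats::sd(y) == 0 || stats::sd(y_hat) == 0) {
    NA_real_
  } else stats::cor(y, y_hat, method = "spearman")
  structure(list(r2 = r2, rmse = rmse, pearson_r = pr, spearman_rs = rs,
                 n = length(y), r2_undefined = undefined),
            class = "uhsr_metrics")
}

#' @export
print.uhsr_metrics <- function(x, ...) {
  cat(sprintf("R2 = %.4f  RMSE = %.4f  r = %.3f  rs = %.3f  (n = %d)\n",
              x$r2, x$rmse, x$pearson_r, x$spearman_rs, x$n))
  invisible(x)
}

#' End-to-end pipeline configuration
#'
#' @param net [uhsr_hyperparams()] for the three network stages.
#' @param sr [sr_config()] for the symbolic-regression fits.  The pipeline
#'   default widens the parsimony tolerance to 0.10: on noisy data,
#'   candidates within ~10 percent of the best loss are statistically
#'   indistinguishable and the simpler equation is preferred.
#' @param test_fraction held-out fraction for the top-level report metrics.
#' @param rf_clip records with Rf outside `(rf_clip, 1 - rf_clip)` are
#'   treated as saturated at the plate bounds (censored) and excluded from
#'   the logit-scale equation fit; predictions and metrics still cover all
#'   records.
#' @param seed master seed for the train/test split.
#' @return list of class `uhsr_config`.
#' @export
uhsr_config <- function(net = uhsr_hyperparams(),
                        sr = sr_config(parsimony_delta = 0.10),
                        test_fraction = 0.1, rf_clip = 0.01, seed = 0L) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            rf_clip > 0, rf_clip < 0.5)
  structure(list(net = net, sr = sr, test_fraction = test_fraction,
                 rf_clip = rf_clip, seed = as.integer(seed)),
            class = "uhsr_config")
}

# fit the hierarchy + the four symbolic-regression targets on one dataset
uhsr_fit <- function(data, config = uhsr_config(), verbose = FALSE) {
  hier <- run_hierarchy(data, hp = config$net, verbose = verbose)
  lat <- hier$latents
  X <- as.data.frame(data)
  sr_with_seed <- function(offset) {
    cfg <- config$sr
    cfg$seed <- cfg$seed + offset
    cfg
  }
  unsat <- data$Rf > config$rf_clip & data$Rf < 1 - config$rf_clip
  if (sum(unsat) < 10) stop("fewer than 10 unsaturated Rf observations")
  y_logit <- logit(data$Rf[unsat])
  if (verbose) message("symbolic regression: Rf ~ (psi, xi)")
  front_rf <- sr_fit(lat[unsat, c("psi", "xi")], y_logit, sr_with_seed(0L))
  if (verbose) message("symbolic regression: psi ~ solvent")
  front_psi <- sr_fit(X[, solvent_names()], lat$psi, sr_with_seed(1L))
  if (verbose) message("symbolic regression: xi ~ (alpha, beta)")
  front_xi <- sr_fit(lat[, c("alpha", "beta")], lat$xi, sr_with_seed(2L))
  if (verbose) message("symbolic regression: beta ~ (gamma1..gamma5)")
  front_beta <- sr_fit(lat[, paste0("gamma", 1:5)], lat$beta, sr_with_seed(3L))
  fronts <- list(rf = front_rf, psi = front_psi, xi = front_xi,
                 beta = front_beta)
  selected <- lapply(fronts, sr_select)
  fg_probes <- vapply(fg_count_names(), function(g) {
    probe(hier$stages$stage2, "FG", g)
  }, numeric(1))
  structure(list(hierarchy = hier, fronts = fronts, selected = selected,
                 fg_probes = fg_probes, config = config),
            class = "uhsr_model")
}

# latents + equation-based Rf prediction for new records
uhsr_eval <- function(model, data) {
  X <- assemble_features(data)
  lat1 <- extract_latents(model$hierarchy$stages$stage1, X)
  rf_hat <- sigmoid(sr_evaluate(model$selected$rf,
                                as.data.frame(lat1[, c("psi", "xi"),
                                                   drop = FALSE])))
  list(latents = lat1, rf_hat = rf_hat)
}

#' Predict Rf for new records with a fitted model
#'
#' Runs the stage-1 sub-models to obtain (psi, xi) and evaluates the
#' sigmoid-linked top-level equation.  Predictions lie in (0, 1) and are
#' order-preserving in the input rows.
#'
#' @param object a `uhsr_model` (from [run_uhsr()]`$model`).
#' @param newdata dataset data.frame (Rf not required).
#' @param ... unused.
#' @return numeric vector of predicted Rf.
#' @export
predict.uhsr_model <- function(object, newdata, ...) {
  uhsr_eval(object, newdata)$rf_hat
}

equation_report <- function(model, data_metrics) {
  targets <- c(rf = "logit(Rf)", psi = "psi", xi = "xi", beta = "beta")
  vars <- list(rf = c("psi", "xi"), psi = solvent_names(),
               xi = c("alpha", "beta"), beta = paste0("gamma", 1:5))
  lapply(names(targets), function(nm) {
    tree <- model$selected[[nm]]
    expr <- to_canonical_string(expand_tree(tree))
    if (nm == "rf") expr <- paste0("sigma(", expr, ")")
    list(target = if (nm == "rf") "Rf" else targets[[nm]],
         variables = vars[[nm]],
         expression = expr,
         complexity = as.integer(attr(tree, "complexity")),
         train_loss = as.numeric(attr(tree, "loss")),
         r2 = if (nm == "rf") data_metrics$train$r2 else NA,
         rmse = if (nm == "rf") data_metrics$train$rmse else NA)
  })
}

#' Run the full discovery pipeline on a dataset
#'
#' Splits off a seeded held-out fraction, trains the three-stage modular
#' hierarchy on the training part, extracts and sign-canonicalizes the
#' latent retention indices, and runs symbolic regression for (i) Rf versus
#' (psi, xi) on the logit scale, (ii) psi versus the solvent features,
#' (iii) xi versus (alpha, beta) and (iv) beta versus (gamma1..gamma5).
#' Reported equations live in the standardized latent gauge; the affine
#' transforms are published alongside.
#'
#' @param data a `tlc_dataset` with observed Rf.
#' @param config a [uhsr_config()].
#' @param verbose print stage progress.
#' @return list of class `uhsr_report`: `model`, `equations`, `metrics`
#'   (train and test, equation-based and network-based), `fg_probes`,
#'   `standardization`, `test_idx`, `config`.
#' @export
run_uhsr <- function(data, config = uhsr_config(), verbose = FALSE) {
  stopifnot("Rf" %in% colnames(data))
  n <- nrow(data)
  test_idx <- with_seed(config$seed,
                        sort(sample.int(n, max(1L, round(config$test_fraction * n)))))
  train <- data[-test_idx, , drop = FALSE]
  test <- data[test_idx, , drop = FALSE]
  model <- uhsr_fit(train, config, verbose = verbose)
  ev_tr <- uhsr_eval(model, train)
  ev_te <- uhsr_eval(model, test)
  metrics <- list(
    train = compute_metrics(train$Rf, ev_tr$rf_hat),
    test = compute_metrics(test$Rf, ev_te$rf_hat),
    network_test = compute_metrics(
      test$Rf, predict(model$hierarchy$stages$stage1, test)))
  std <- lapply(model$hierarchy$stages, function(s) s$standardization)
  structure(list(model = model,
                 equations = equation_report(model, metrics),
                 metrics = metrics, fg_probes = model$fg_probes,
                 standardization = std, test_idx = test_idx,
                 config = config),
            class = "uhsr_report")
}

#' @export
print.uhsr_report <- function(x, ...) {
  cat("UHSR report\n")
  for (eq in x$equations) {
    cat(sprintf("  %-9s = %s\n", eq$target, eq$expression))
  }
  cat("held-out: "); print(x$metrics$test)
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' Serializes the selected equations (target, variables, expression,
#' complexity, train loss, R2, RMSE), the Pareto fronts, metrics, one-hot
#' probe values and standardization transforms.
#'
#' @param report a `uhsr_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_uhsr_report <- function(report, path) {
  out <- list(
    equations = report$equations,
    pareto_fronts = lapply(report$model$fronts,
                           function(f) as.data.frame(f)),
    metrics = lapply(report$metrics, unclass),
    fg_probes = as.list(report$fg_probes),
    standardization = report$standardization,
    seed = report$config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' k-fold cross-validation of the pipeline
#'
#' Seeded fold assignment (fold sizes differ by at most one, each record
#' tested exactly once); each fold trains the full pipeline on the
#' remaining folds and reports held-out metrics plus the selected equation
#' strings.  Per-fold equations are reported side by side, not averaged.
#'
#' @param data a `tlc_dataset` with observed Rf.
#' @param k number of folds (default 10).
#' @param config a [uhsr_config()].
#' @param verbose print fold progress.
#' @return list of class `uhsr_cv`: `folds` (assignment vector), per-fold
#'   `results` (metrics + equations), and pooled test metrics.
#' @export
crossvalidate <- function(data, k = 10L, config = uhsr_config(),
                          verbose = FALSE) {
  n <- nrow(data)
  if (k > n) stop("k must not exceed the number of records")
  folds <- with_seed(config$seed,
                     sample(rep_len(seq_len(k), n)))
  results <- vector("list", k)
  pooled_y <- numeric(0); pooled_hat <- numeric(0)
  for (f in seq_len(k)) {
    if (verbose) message("fold ", f, "/", k)
    train <- data[folds != f, , drop = FALSE]
    test <- data[folds == f, , drop = FALSE]
    model <- uhsr_fit(train, config)
    ev <- uhsr_eval(model, test)
    results[[f]] <- list(
      metrics = compute_metrics(test$Rf, ev$rf_hat),
      equations = vapply(model$selected,
                         function(tr) to_canonical_string(expand_tree(tr)),
                         character(1)),
      standardization = lapply(model$hierarchy$stages,
                               function(s) s$standardization))
    pooled_y <- c(pooled_y, test$Rf)
    pooled_hat <- c(pooled_hat, ev$rf_hat)
  }
  structure(list(folds = folds, results = results,
                 pooled = compute_metrics(pooled_y, pooled_hat),
                 config = config, k = k),
            class = "uhsr_cv")
}

#' Rank candidate mobile phases for a target solute
#'
#' Predicts Rf for the solute under each candidate composition and ranks
#' candidates by the distance of the prediction to the target band
#' (default \[0.2, 0.3\]; in-band distance is zero).  Ties are broken by
#' the lower methanol fraction — small methanol changes cause large
#' polarity shifts, so the gentler eluent is preferred.
#'
#' @param predictor a fitted `uhsr_model`, an `uhsr_chain`, or a function
#'   mapping a dataset data.frame to predicted Rf.
#' @param solute named list/vector with the 16 counts plus `NBen` and `DM`
#'   (missing entries default to 0).
#' @param candidates data.frame of candidate compositions (five solvent
#'   columns).
#' @param band target Rf band.
#' @return data.frame of candidates with `rf_pred`, `band_distance`,
#'   ordered best first.
#' @export
recommend_solvent <- function(predictor, solute, candidates,
                              band = c(0.2, 0.3)) {
  candidates <- as.data.frame(candidates)
  if (nrow(candidates) == 0) stop("empty candidate list")
  stopifnot(all(solvent_names() %in% colnames(candidates)))
  fn <- c(fg_count_names(), "NBen", "DM")
  sol <- stats::setNames(numeric(length(fn)), fn)
  sol[intersect(names(solute), fn)] <- unlist(solute)[intersect(names(solute), fn)]
  newdata <- data.frame(id = sprintf("cand%d", seq_len(nrow(candidates))),
                        candidates[, solvent_names(), drop = FALSE],
                        NBen = sol[["NBen"]], DM = sol[["DM"]],
                        as.data.frame(as.list(sol[fg_count_names()])),
                        check.names = FALSE)
  rf <- if (is.function(predictor)) {
    predictor(newdata)
  } else {
    predict(predictor, newdata)
  }
  dist <- pmax(band[1] - rf, rf - band[2], 0)
  out <- cbind(candidates, rf_pred = rf, band_distance = dist)
  out[order(dist, out$MeOH), , drop = FALSE]
}
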