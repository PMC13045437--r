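#' Chemist-guided feature grouping
#'
#' A named partition of model feature positions (see [tlc_feature_names()]).
#' Each group feeds one independent sub-model emitting a single scalar
#' latent, so the latent's receptive field is restricted to its group by
#' construction.
#'
#' @param groups named list of integer index vectors over the 23 feature
#'   positions; must be pairwise disjoint.
#' @param latents optional character vector naming the latent emitted by
#'   each group (defaults to the group names).
#' @return object of class `feature_grouping`.
#' @export
feature_grouping <- function(groups, latents = names(groups)) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  idx <- unlist(groups)
  if (any(idx < 1) || any(idx > 23) || any(idx != round(idx))) {
    stop("group indices must be integers in 1..23")
  }
  if (anyDuplicated(idx)) {
    stop("feature groups must be pairwise disjoint")
  }
  if (length(latents) != length(groups)) {
    stop("one latent name per group required")
  }
  structure(list(groups = lapply(groups, as.integer), latents = latents),
            class = "feature_grouping")
}

#' Default hierarchical groupings
#'
#' Stage 1 splits solvent (5 features -> psi) from solute (18 -> xi);
#' stage 2 splits the solute into distribution features NBen, DM (-> alpha)
#' and the 16 counts (-> beta); stage 3 splits the counts into five
#' chemist-defined subgroups (-> gamma1..gamma5): amide/acid; phenol/amine/
#' alcohol; nitro/ester; fluorine/ether/ketone/aldehyde/cyano; and
#' methyl/chlorine/bromine/iodine.  Every stage keeps the solvent branch as
#' one group and trains end-to-end on Rf.
#'
#' @return named list of three [feature_grouping()] objects.
#' @export
default_groupings <- function() {
  fn <- tlc_feature_names()
  ix <- function(nms) match(nms, fn)
  list(
    stage1 = feature_grouping(
      list(solvent = 1:5, solute = 6:23),
      latents = c("psi", "xi")),
    stage2 = feature_grouping(
      list(solvent = 1:5, FGdist = ix(c("NBen", "DM")), FG = 6:21),
      latents = c("psi", "alpha", "beta")),
    stage3 = feature_grouping(
      list(solvent = 1:5, FGdist = ix(c("NBen", "DM")),
           FG1 = ix(c("CtAm", "CtCO2H")),
           FG2 = ix(c("CtPh", "CtNH2", "CtOH")),
           FG3 = ix(c("CtNO2", "CtRCO2R")),
           FG4 = ix(c("CtF", "CtROR", "CtR2CO", "CtAl", "CtCN")),
           FG5 = ix(c("CtMe", "CtCl", "CtBr", "CtI"))),
      latents = c("psi", "alpha", paste0("gamma", 1:5)))
  )
}

#' Training hyper-parameters for a modular network stage
#'
#' Defaults follow the study conditions: sub-models with two hidden layers
#' of 50 LeakyReLU units, Adam at learning rate 0.01, batch size 2048,
#' 1000 epochs with the best validation checkpoint retained.
#'
#' @param hidden_width neurons per hidden layer.
#' @param hidden_depth hidden layers per sub-model.
#' @param leaky_slope negative-side slope of LeakyReLU.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param validation_fraction fraction held out for checkpoint selection.
#' @param seed RNG seed controlling initialization, split and shuffling.
#' @return list of class `uhsr_hyperparams`.
#' @export
uhsr_hyperparams <- function(hidden_width = 50L, hidden_depth = 2L,
                             leaky_slope = 0.01, batch_size = 2048L,
                             learning_rate = 0.01, epochs = 1000L,
                             validation_fraction = 0.1, seed = 1L) {
  stopifnot(hidden_width >= 1, hidden_depth >= 1, batch_size >= 1,
            learning_rate > 0, epochs >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(hidden_width = as.integer(hidden_width),
                 hidden_depth = as.integer(hidden_depth),
                 leaky_slope = leaky_slope,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "uhsr_hyperparams")
}

lrelu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}

lrelu_grad <- function(pre, slope) {
  g <- matrix(1, nrow(pre), ncol(pre))
  g[pre < 0] <- slope
  g
}

init_mat <- function(nin, nout) {
  # He-style initialization for LeakyReLU layers
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

#' Build an untrained modular network
#'
#' One sub-model per feature group (`hidden_depth` layers of `hidden_width`
#' LeakyReLU units, scalar latent output), plus a head combining the latents
#' through one hidden layer; the head ends in a sigmoid so predictions stay
#' in (0, 1) (the Rf range).
#'
#' @param grouping a [feature_grouping()].
#' @param hp a [uhsr_hyperparams()]; `hp$seed` fixes the initialization.
#' @param output `"sigmoid"` (default, for the bounded Rf target) or
#'   `"linear"`.
#' @return object of class `uhsr_network`.
#' @export
build_network <- function(grouping, hp = uhsr_hyperparams(),
                          output = c("sigmoid", "linear")) {
  stopifnot(inherits(grouping, "feature_grouping"))
  output <- match.arg(output)
  k <- length(grouping$groups)
  w <- hp$hidden_width
  params <- list()
  with_seed(hp$seed, {
    for (g in seq_len(k)) {
      d <- length(grouping$groups[[g]])
      dims <- c(d, rep(w, hp$hidden_depth), 1L)
      for (l in seq_len(length(dims) - 1L)) {
        params[[sprintf("g%d.W%d", g, l)]] <- init_mat(dims[l], dims[l + 1])
        params[[sprintf("g%d.b%d", g, l)]] <- matrix(0, 1, dims[l + 1])
      }
    }
    params[["head.W1"]] <- init_mat(k, w)
    params[["head.b1"]] <- matrix(0, 1, w)
    params[["head.W2"]] <- init_mat(w, 1)
    params[["head.b2"]] <- matrix(0, 1, 1)
  })
  structure(list(grouping = grouping, hp = hp, output = output,
                 params = params),
            class = "uhsr_network")
}

# forward pass; returns latents Z, prediction o and (optionally) caches
net_forward <- function(params, grouping, hp, X, output, caches = FALSE) {
  k <- length(grouping$groups)
  n <- nrow(X)
  depth <- hp$hidden_depth + 1L
  Z <- matrix(0, n, k)
  cache <- if (caches) vector("list", k) else NULL
  for (g in seq_len(k)) {
    A <- X[, grouping$groups[[g]], drop = FALSE]
    acts <- if (caches) vector("list", depth + 1L) else NULL
    pres <- if (caches) vector("list", depth) else NULL
    if (caches) acts[[1]] <- A
    for (l in seq_len(depth)) {
      pre <- A %*% params[[sprintf("g%d.W%d", g, l)]]
      pre <- sweep(pre, 2, params[[sprintf("g%d.b%d", g, l)]], "+")
      A <- if (l < depth) lrelu(pre, hp$leaky_slope) else pre
      if (caches) { pres[[l]] <- pre; acts[[l + 1L]] <- A }
    }
    Z[, g] <- A
    if (caches) cache[[g]] <- list(acts = acts, pres = pres)
  }
  hpre <- sweep(Z %*% params[["head.W1"]], 2, params[["head.b1"]], "+")
  H <- lrelu(hpre, hp$leaky_slope)
  olin <- drop(H %*% params[["head.W2"]]) + params[["head.b2"]][1, 1]
  o <- if (output == "sigmoid") sigmoid(olin) else olin
  list(Z = Z, o = o, H = H, hpre = hpre, cache = cache)
}

net_backward <- function(params, grouping, hp, X, y, output, fw) {
  n <- nrow(X)
  grads <- list()
  o <- fw$o
  d_olin <- 2 * (o - y) / n
  if (output == "sigmoid") d_olin <- d_olin * o * (1 - o)
  d_olin <- matrix(d_olin, n, 1)
  grads[["head.W2"]] <- crossprod(fw$H, d_olin)
  grads[["head.b2"]] <- matrix(sum(d_olin), 1, 1)
  dH <- d_olin %*% t(params[["head.W2"]])
  dhpre <- dH * lrelu_grad(fw$hpre, hp$leaky_slope)
  grads[["head.W1"]] <- crossprod(fw$Z, dhpre)
  grads[["head.b1"]] <- matrix(colSums(dhpre), 1)
  dZ <- dhpre %*% t(params[["head.W1"]])
  depth <- hp$hidden_depth + 1L
  for (g in seq_along(grouping$groups)) {
    cache <- fw$cache[[g]]
    dA <- matrix(dZ[, g], n, 1)
    for (l in rev(seq_len(depth))) {
      if (l < depth) dA <- dA * lrelu_grad(cache$pres[[l]], hp$leaky_slope)
      grads[[sprintf("g%d.W%d", g, l)]] <- crossprod(cache$acts[[l]], dA)
      grads[[sprintf("g%d.b%d", g, l)]] <- matrix(colSums(dA), 1)
      if (l > 1) dA <- dA %*% t(params[[sprintf("g%d.W%d", g, l)]])
    }
  }
  grads
}

#' Train a modular network stage on Rf
#'
#' Minimizes mean-squared error with Adam (default settings: lr 0.01,
#' batch 2048), holding out a seeded validation fraction used only to select
#' the best checkpoint over the epochs.  Fully reproducible under a fixed
#' `hp$seed`.  After training, each latent is given an affine
#' standardization (mean 0, variance 1 over the training records) and a
#' sign (+1 until [canonicalize_sign()] is applied).
#'
#' @param network an untrained [build_network()] result.
#' @param data a `tlc_dataset` (or data.frame with the canonical columns and
#'   `Rf`), or a feature matrix if `y` is given.
#' @param y optional numeric response overriding the `Rf` column.
#' @param hp hyper-parameters (default: those stored in `network`).
#' @param verbose print a progress line every 100 epochs.
#' @return object of class `uhsr_stage`: best-checkpoint parameters, loss
#'   traces, best epoch, and per-latent standardization transforms.
#' @export
train_network <- function(network, data, y = NULL, hp = network$hp,
                          verbose = FALSE) {
  stopifnot(inherits(network, "uhsr_network"))
  if (is.null(y)) {
    stopifnot("Rf" %in% colnames(data))
    y <- data$Rf
  }
  X <- if (is.matrix(data)) data else assemble_features(data)
  if (anyNA(y)) stop("training records must carry an observed Rf")
  if (anyNA(X)) stop("training features contain missing values")
  n <- nrow(X)
  grouping <- network$grouping
  params <- network$params
  n_val <- max(1L, round(hp$validation_fraction * n))
  if (ceiling((n - n_val) / hp$batch_size) < 2) {
    stop("need at least two minibatches after the validation split; ",
         "reduce batch_size or add data")
  }
  m_state <- lapply(params, function(p) p * 0)
  v_state <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  best <- list(loss = Inf, params = params, epoch = 0L)
  trace_train <- numeric(hp$epochs)
  trace_val <- numeric(hp$epochs)
  with_seed(hp$seed, {
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]
    ntr <- length(tr_idx)
    for (epoch in seq_len(hp$epochs)) {
      ord <- sample.int(ntr)
      starts <- seq(1L, ntr, by = hp$batch_size)
      ep_loss <- 0
      for (s in starts) {
        bi <- ord[s:min(s + hp$batch_size - 1L, ntr)]
        Xb <- Xtr[bi, , drop = FALSE]; yb <- ytr[bi]
        fw <- net_forward(params, grouping, hp, Xb, network$output,
                          caches = TRUE)
        loss <- mean((fw$o - yb)^2)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite training loss at epoch %d", epoch))
        }
        ep_loss <- ep_loss + loss * length(bi)
        grads <- net_backward(params, grouping, hp, Xb, yb, network$output, fw)
        t_step <- t_step + 1L
        corr1 <- 1 - beta1^t_step
        corr2 <- 1 - beta2^t_step
        for (nm in names(params)) {
          g <- grads[[nm]]
          m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * g
          v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * g * g
          params[[nm]] <- params[[nm]] - hp$learning_rate *
            (m_state[[nm]] / corr1) / (sqrt(v_state[[nm]] / corr2) + eps)
        }
      }
      trace_train[epoch] <- ep_loss / ntr
      fv <- net_forward(params, grouping, hp, Xval, network$output)
      vloss <- mean((fv$o - yval)^2)
      trace_val[epoch] <- vloss
      if (vloss < best$loss) {
        best <- list(loss = vloss, params = params, epoch = epoch)
      }
      if (verbose && epoch %% 100 == 0) {
        message(sprintf("epoch %d  train %.5f  val %.5f (best %.5f @%d)",
                        epoch, trace_train[epoch], vloss, best$loss,
                        best$epoch))
      }
    }
  })
  stage <- structure(
    list(grouping = grouping, hp = hp, output = network$output,
         params = best$params, best_epoch = best$epoch,
         loss_trace = list(train = trace_train, validation = trace_val),
         standardization = list(
           shift = stats::setNames(rep(0, length(grouping$latents)),
                                   grouping$latents),
           scale = stats::setNames(rep(1, length(grouping$latents)),
                                   grouping$latents),
           sign = stats::setNames(rep(1, length(grouping$latents)),
                                  grouping$latents)),
         flips = character(0)),
    class = "uhsr_stage")
  z <- raw_latents(stage, X)
  stage$calibration <- latent_calibration(best$params, hp, z)
  z <- apply_calibration(stage$calibration, z)
  stage$standardization$shift[] <- colMeans(z)
  stage$standardization$scale[] <- apply(z, 2, stats::sd)
  if (any(stage$standardization$scale == 0)) {
    warning("zero-variance latent; standardization scale clamped to 1")
    stage$standardization$scale[stage$standardization$scale == 0] <- 1
  }
  stage
}

raw_latents <- function(stage, X) {
  fw <- net_forward(stage$params, stage$grouping, stage$hp, X, stage$output)
  colnames(fw$Z) <- stage$grouping$latents
  fw$Z
}

# head's pre-link output as a function of the latent vector(s)
head_linear <- function(params, Z, slope) {
  H <- lrelu(sweep(Z %*% params[["head.W1"]], 2, params[["head.b1"]], "+"),
             slope)
  drop(H %*% params[["head.W2"]]) + params[["head.b2"]][1, 1]
}

# Gauge fix: each raw latent is recalibrated onto its partial-dependence
# curve through the trained head on the logit scale, i.e. the average
# pre-sigmoid head output as that latent varies with the others held at
# training values.  Sub-model latents are identified only up to invertible
# transforms; this picks the gauge in which a latent is measured by the
# additive logit-Rf contribution it induces, which is what the governing
# equations are written in.  The transform depends only on the latent's own
# value, so group locality is preserved exactly.
latent_calibration <- function(params, hp, Z, n_grid = 101L, n_ref = 256L) {
  k <- ncol(Z)
  n <- nrow(Z)
  refs <- unique(round(seq(1L, n, length.out = min(n_ref, n))))
  lapply(seq_len(k), function(i) {
    lo <- min(Z[, i]); hi <- max(Z[, i])
    if (!is.finite(lo) || !is.finite(hi) || hi - lo < 1e-12) return(NULL)
    grid <- seq(lo, hi, length.out = n_grid)
    pd <- numeric(n_grid)
    for (r in refs) {
      Zr <- matrix(Z[r, ], n_grid, k, byrow = TRUE)
      Zr[, i] <- grid
      pd <- pd + head_linear(params, Zr, hp$leaky_slope)
    }
    list(x = grid, y = pd / length(refs))
  })
}

apply_calibration <- function(calibration, Z) {
  for (i in seq_len(ncol(Z))) {
    cal <- calibration[[i]]
    if (!is.null(cal)) {
      Z[, i] <- stats::approx(cal$x, cal$y, xout = Z[, i], rule = 2)$y
    }
  }
  Z
}

#' Extract standardized latent retention indices
#'
#' Applies the stored gauge to each sub-model's latent: the
#' partial-dependence calibration (each latent measured by the average
#' logit-scale contribution it induces through the trained head), then the
#' affine standardization and sign.  The affine part inverts exactly:
#' `calibrated = standardized * sign * scale + shift`.
#'
#' @param stage a trained `uhsr_stage`.
#' @param data dataset data.frame or 23-column feature matrix.
#' @return matrix (n x k) with one column per latent.
#' @export
extract_latents <- function(stage, data) {
  stopifnot(inherits(stage, "uhsr_stage"))
  X <- if (is.matrix(data)) data else assemble_features(data)
  if (ncol(X) != 23) stop("feature matrix must have 23 columns")
  z <- apply_calibration(stage$calibration, raw_latents(stage, X))
  st <- stage$standardization
  sweep(sweep(z, 2, st$shift, "-"), 2, st$sign * st$scale, "/")
}

#' Predict Rf with a trained stage
#'
#' @param object a trained `uhsr_stage`.
#' @param newdata dataset data.frame or feature matrix.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.uhsr_stage <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else assemble_features(newdata)
  net_forward(object$params, object$grouping, object$hp, X, object$output)$o
}

#' Probe a sub-model with a basis input
#'
#' Evaluates one group's latent on a one-hot (or otherwise specified) input
#' with all other features at zero — the pure-component / single-group
#' reading used to rank solvents and functional groups.  Values are on the
#' standardized, sign-canonical scale.
#'
#' @param stage a trained `uhsr_stage`.
#' @param group group name.
#' @param at either a feature name / index *within the group* to set to 1
#'   (one-hot probe), a full vector of values for the group's features, or
#'   `NULL` for the zero probe.
#' @return scalar latent value.
#' @export
probe <- function(stage, group, at = NULL) {
  stopifnot(inherits(stage, "uhsr_stage"))
  groups <- stage$grouping$groups
  if (!group %in% names(groups)) {
    stop("unknown group '", group, "'; have: ",
         paste(names(groups), collapse = ", "))
  }
  idx <- groups[[group]]
  fn <- tlc_feature_names()
  x <- stats::setNames(numeric(23), fn)
  if (is.null(at)) {
    # zero probe: sub-model bias latent
  } else if (is.character(at) && length(at) == 1L) {
    if (!at %in% fn[idx]) {
      stop("feature '", at, "' is not inside group '", group, "'")
    }
    x[at] <- 1
  } else if (is.numeric(at) && length(at) == 1L) {
    if (at < 1 || at > length(idx)) {
      stop("index ", at, " outside group '", group, "'")
    }
    x[idx[at]] <- 1
  } else if (is.numeric(at) && length(at) == length(idx)) {
    x[idx] <- at
  } else {
    stop("'at' must be NULL, a feature name/index in the group, ",
         "or a vector of the group's length")
  }
  z <- extract_latents(stage, matrix(x, 1, dimnames = list(NULL, fn)))
  lat <- stage$grouping$latents[match(group, names(groups))]
  z[1, lat]
}

#' Fix latent signs against stated references
#'
#' Latent retention indices are identified only up to sign; this fixes the
#' gauge by flipping latents so stated correlations (or probe orderings)
#' are non-negative.  Defaults: psi correlates positively with the MeOH
#' fraction; xi with Rf; alpha with DM; beta probes amide above iodine; each
#' gamma probes its first functional group above the zero probe.  Idempotent.
#'
#' @param stage a trained `uhsr_stage`.
#' @param data dataset used to evaluate correlations (must carry `Rf` for
#'   target rules).
#' @param rules optional list of rules; each rule is a list with `latent`
#'   and either `against` (a feature column name or `".target"`) or
#'   `probe_high`/`probe_low` (feature names within the latent's group, or
#'   `".zero"`).
#' @return the stage with adjusted signs; flips recorded in `stage$flips`.
#' @export
canonicalize_sign <- function(stage, data, rules = NULL) {
  stopifnot(inherits(stage, "uhsr_stage"))
  if (is.null(rules)) rules <- default_sign_rules(stage)
  X <- assemble_features(data)
  z <- extract_latents(stage, X)
  lat <- stage$grouping$latents
  for (rule in rules) {
    li <- match(rule$latent, lat)
    if (is.na(li)) next
    if (!is.null(rule$against)) {
      ref <- if (identical(rule$against, ".target")) {
        if (!"Rf" %in% colnames(data)) stop("target rule needs an Rf column")
        data$Rf
      } else X[, rule$against]
      if (stats::sd(z[, li]) == 0) {
        stop("cannot canonicalize sign of zero-variance latent '",
             rule$latent, "'")
      }
      if (stats::sd(ref) == 0) next
      flip <- stats::cor(z[, li], ref) < 0
    } else {
      grp <- names(stage$grouping$groups)[li]
      hi <- if (identical(rule$probe_high, ".zero")) {
        probe(stage, grp)
      } else probe(stage, grp, rule$probe_high)
      lo <- if (identical(rule$probe_low, ".zero")) {
        probe(stage, grp)
      } else probe(stage, grp, rule$probe_low)
      flip <- hi < lo
    }
    if (flip) {
      stage$standardization$sign[li] <- -stage$standardization$sign[li]
      stage$flips <- c(stage$flips, rule$latent)
      z[, li] <- -z[, li]
    }
  }
  stage
}

default_sign_rules <- function(stage) {
  lat <- stage$grouping$latents
  rules <- list()
  if ("psi" %in% lat) rules <- c(rules, list(list(latent = "psi", against = "MeOH")))
  if ("xi" %in% lat) rules <- c(rules, list(list(latent = "xi", against = ".target")))
  if ("alpha" %in% lat) rules <- c(rules, list(list(latent = "alpha", against = "DM")))
  if ("beta" %in% lat) {
    rules <- c(rules, list(list(latent = "beta",
                                probe_high = "CtAm", probe_low = "CtI")))
  }
  fn <- tlc_feature_names()
  for (g in grep("^gamma", lat, value = TRUE)) {
    grp <- names(stage$grouping$groups)[match(g, lat)]
    first <- fn[stage$grouping$groups[[grp]][1]]
    rules <- c(rules, list(list(latent = g, probe_high = first,
                                probe_low = ".zero")))
  }
  rules
}

#' Train the full three-stage hierarchy
#'
#' Trains stage 1 (psi, xi), stage 2 (alpha, beta) and stage 3
#' (gamma1..gamma5), each as a full Rf-predicting modular network with its
#' own grouping, canonicalizes latent signs, and assembles the unified
#' per-sample latent table.
#'
#' @param data a `tlc_dataset` with observed Rf.
#' @param hp hyper-parameters shared across stages (or a list of three).
#' @param groupings list of three groupings (default [default_groupings()]).
#' @param verbose print training progress.
#' @return list of class `uhsr_hierarchy` with elements `stages` (list of
#'   three `uhsr_stage`) and `latents` (data.frame
#'   `id, psi, xi, alpha, beta, gamma1..gamma5`).
#' @export
run_hierarchy <- function(data, hp = uhsr_hyperparams(),
                          groupings = default_groupings(), verbose = FALSE) {
  stopifnot("Rf" %in% colnames(data))
  if (inherits(hp, "uhsr_hyperparams")) hp <- list(hp, hp, hp)
  stopifnot(length(groupings) == 3, length(hp) == 3)
  for (g in groupings) {
    if (!setequal(unlist(g$groups), 1:23)) {
      stop("incomplete cover: every stage grouping must partition all 23 ",
           "features")
    }
  }
  X <- assemble_features(data)
  stages <- vector("list", 3)
  for (s in 1:3) {
    if (verbose) message("training stage ", s)
    net <- build_network(groupings[[s]], hp[[s]])
    stage <- train_network(net, X, y = data$Rf, hp = hp[[s]])
    stages[[s]] <- canonicalize_sign(stage, data)
  }
  names(stages) <- names(groupings)
  lat1 <- extract_latents(stages[[1]], X)
  lat2 <- extract_latents(stages[[2]], X)
  lat3 <- extract_latents(stages[[3]], X)
  latents <- data.frame(
    id = if ("id" %in% colnames(data)) data$id else seq_len(nrow(X)),
    psi = lat1[, "psi"], xi = lat1[, "xi"],
    alpha = lat2[, "alpha"], beta = lat2[, "beta"],
    lat3[, paste0("gamma", 1:5), drop = FALSE])
  structure(list(stages = stages, latents = latents),
            class = "uhsr_hierarchy")
}

#' Save / load a trained stage
#'
#' The checkpoint is a single binary file accompanied by a JSON sidecar
#' recording grouping, hyper-parameters, standardization transforms and
#' recorded sign flips for audit.
#'
#' @param stage a trained `uhsr_stage`.
#' @param path checkpoint path (`.rds`); the sidecar is `path` + `.json`.
#' @return `path`, invisibly (`save_stage`); the stage (`load_stage`).
#' @export
save_stage <- function(stage, path) {
  stopifnot(inherits(stage, "uhsr_stage"))
  saveRDS(stage, path)
  sidecar <- list(
    groups = lapply(stage$grouping$groups, as.integer),
    latents = stage$grouping$latents,
    hyperparams = unclass(stage$hp),
    best_epoch = stage$best_epoch,
    standardization = lapply(stage$standardization, as.list),
    flips = stage$flips)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_stage
#' @export
load_stage <- function(path) {
  stage <- readRDS(path)
  stopifnot(inherits(stage, "uhsr_stage"))
  stage
}
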