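#' Reference governing equations for TLC retention
#'
#' Executable transcriptions of the discovered governing equations linking
#' the retardation factor Rf to the solvent retention index (psi) and the
#' solute retention index (xi), psi to the mobile-phase composition, and xi
#' to the functional-group indices alpha and beta.  These fixtures are the
#' ground-truth mechanism of the synthetic-data generator and the oracles of
#' the recovery tests.
#'
#' @name reference-equations
#' @keywords internal
NULL

#' Logistic function
#' @param x numeric vector.
#' @return 1 / (1 + exp(-x)), elementwise.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Logit function
#' @param p numeric vector in (0, 1).
#' @return log(p / (1 - p)), elementwise.
#' @export
logit <- function(p) log(p / (1 - p))

#' Rf governing equation
#'
#' `Rf = sigma(5.15 psi + 5.15 xi + 1.55)` with `sigma(x) = 1/(1+exp(-x))`.
#' Strictly increasing in both retention indices, range (0, 1): a more
#' strongly eluting solvent (larger psi) or a less polar solute (larger xi)
#' carries the spot further up the plate.
#'
#' @param psi solvent retention index (numeric vector).
#' @param xi solute retention index (numeric vector).
#' @return predicted Rf in (0, 1).
#' @examples
#' rf_governing(0, 0)        # sigma(1.55) ~ 0.825
#' rf_governing(-1.55 / 5.15, 0)  # 0.5
#' @export
rf_governing <- function(psi, xi) {
  stopifnot(is.numeric(psi), is.numeric(xi))
  sigmoid(5.15 * psi + 5.15 * xi + 1.55)
}

#' Solvent retention index reference equation
#'
#' `psi = -1.37 Hex - 0.20 EA - 1.02 DCM + 4.65 MeOH - 0.45 Et2O`, a linear
#' form in the five volume fractions with no intercept.  The large MeOH
#' coefficient encodes the outsized polarity shift caused by small methanol
#' additions to dichloromethane.
#'
#' Accepts either five numeric vectors or a single matrix/data.frame with
#' columns `Hex, EA, DCM, MeOH, Et2O`.  The composition-sum constraint is
#' deliberately not enforced here so that pure-component probing
#' (e.g. `psi_reference(meoh = 1)`) is possible.
#'
#' @param hex,ea,dcm,meoh,et2o volume fractions, or `hex` a matrix /
#'   data.frame carrying the five named columns.
#' @return psi (numeric vector).
#' @examples
#' psi_reference(meoh = 1)  # 4.65
#' psi_reference(hex = 1)   # -1.37
#' @export
psi_reference <- function(hex = 0, ea = 0, dcm = 0, meoh = 0, et2o = 0) {
  if (is.matrix(hex) || is.data.frame(hex)) {
    m <- hex
    stopifnot(all(c("Hex", "EA", "DCM", "MeOH", "Et2O") %in% colnames(m)))
    return(psi_reference(unname(m[, "Hex"]), unname(m[, "EA"]),
                         unname(m[, "DCM"]), unname(m[, "MeOH"]),
                         unname(m[, "Et2O"])))
  }
  -1.37 * hex - 0.20 * ea - 1.02 * dcm + 4.65 * meoh - 0.45 * et2o
}

#' Solute retention index reference equation
#'
#' `xi = 0.37 alpha - 0.35 beta - alpha * beta + 0.69`: the solute's
#' effective polarity decomposes into a distribution term, a functional-group
#' term, and their interaction.
#'
#' @param alpha functional-group distribution retention index.
#' @param beta functional-group retention index.
#' @return xi (numeric vector).
#' @examples
#' xi_reference(0, 0)  # 0.69
#' xi_reference(1, 1)  # -0.29
#' @export
xi_reference <- function(alpha, beta) {
  0.37 * alpha - 0.35 * beta - alpha * beta + 0.69
}

#' Printed one-hot probe weights of the 16 functional groups
#'
#' Per-group contributions to the functional-group retention index beta,
#' read off a trained sub-model by setting a single count to 1 and all
#' others to 0.  Ordered here by the canonical count-column order; the
#' polarity ranking runs amide (1.43) down to iodine (-2.97).
#'
#' @return named numeric vector of length 16.
#' @export
fg_probe_weights <- function() {
  c(CtPh    =  0.43,  # phenolic hydroxyl
    CtOH    =  0.75,  # alcoholic hydroxyl
    CtAl    = -0.20,  # aldehyde
    CtCO2H  =  0.88,  # carboxylic acid
    CtRCO2R = -0.48,  # ester
    CtR2CO  = -0.20,  # ketone
    CtROR   = -1.22,  # ether
    CtCN    = -1.03,  # cyano
    CtNH2   =  0.80,  # amine
    CtNO2   = -0.50,  # nitro
    CtAm    =  1.43,  # amide
    CtMe    = -1.28,  # methyl
    CtF     = -1.03,  # fluorine
    CtCl    = -1.15,  # chlorine
    CtBr    = -1.55,  # bromine
    CtI     = -2.97)  # iodine
}

#' Linear probe approximation of the functional-group retention index
#'
#' `beta ~ sum_i count_i * weight_i` with the printed one-hot probe weights.
#' This is the unambiguous solute-beta oracle used by the synthetic-data
#' generator and the recovery tests.
#'
#' @param fg numeric vector of 16 counts (canonical order), or a matrix /
#'   data.frame with the 16 count columns.
#' @return beta approximation (numeric vector).
#' @examples
#' w <- fg_probe_weights()
#' fg_probe_linear(setNames(c(rep(0, 10), 1, rep(0, 5)), names(w)))  # 1.43
#' @export
fg_probe_linear <- function(fg) {
  w <- fg_probe_weights()
  if (is.data.frame(fg)) fg <- as.matrix(fg)
  if (is.matrix(fg)) {
    stopifnot(all(names(w) %in% colnames(fg)))
    return(unname(drop(fg[, names(w), drop = FALSE] %*% w)))
  }
  stopifnot(length(fg) == 16L)
  if (!is.null(names(fg))) fg <- fg[names(w)]
  sum(fg * w)
}

#' Interpretive reference equation for the FG distribution index alpha
#'
#' `alpha = (DM + NBen - 0.29) * ((-NBen + 2.28) * exp(DM - NBen)
#'          - 0.64 NBen + 1.66) - 0.74`.
#'
#' The typeset source of this equation is ambiguous; this is one documented
#' reading (grouping the two exp(DM - NBen) terms), marked *interpretive*.
#' Recovery tests never use it as an oracle; the synthetic generator uses a
#' plain affine surrogate in (DM, NBen) instead.
#'
#' @param dm dipole moment (Debye).
#' @param n_ben benzene-ring count.
#' @return alpha (numeric vector).
#' @export
alpha_reference <- function(dm, n_ben) {
  (dm + n_ben - 0.29) *
    ((-n_ben + 2.28) * exp(dm - n_ben) - 0.64 * n_ben + 1.66) - 0.74
}

#' Interpretive reference equations for the fine-grained FG indices and beta
#'
#' Evaluates the five subgroup indices gamma1..gamma5 and the composite
#' functional-group retention index beta from the 16 counts, under one
#' documented *interpretive* reading of the ambiguously typeset source:
#'
#' * `gamma1 = 5.16 CtAm + 5.16 log(CtCO2H + 0.86)`
#' * `gamma2 = 3.83 CtPh + 8.70 (CtNH2 + CtOH) - 0.73`
#' * `gamma3 = (CtNO2 + CtRCO2R) / (0.44 CtRCO2R - 0.14) - 0.29`
#'   (the ester clause is read as a ratio)
#' * `gamma4 = CtF (CtROR + 1.44) - 2.96 CtR2CO - 2.96 exp(CtAl)
#'    - 2.96 (CtAl + 0.66)(CtR2CO + CtROR + CtCN - 1.20)`
#' * `gamma5 = CtMe + 2.54 CtCl + 2.54 (1.21 - CtBr)(CtBr + 2.73 (CtI - 0.52)) + 2`
#' * `beta = 0.07 gamma2 - (0.003 gamma5 (2 gamma2 - gamma3 - gamma4) - 0.27)
#'    * (gamma1 - gamma5 + (gamma2 - gamma4)(0.14 gamma5 + 0.35)) - 0.63`
#'
#' These are computational fixtures for value-flow tracing, not oracles.
#'
#' @param fg numeric vector of 16 counts (canonical order, named), or a
#'   matrix / data.frame of counts.
#' @return list with elements `gamma` (matrix n x 5) and `beta` (vector).
#' @export
beta_reference <- function(fg) {
  w <- names(fg_probe_weights())
  if (is.data.frame(fg)) fg <- as.matrix(fg)
  if (!is.matrix(fg)) {
    stopifnot(length(fg) == 16L)
    if (is.null(names(fg))) names(fg) <- w
    fg <- matrix(fg, nrow = 1, dimnames = list(NULL, names(fg)))
  }
  stopifnot(all(w %in% colnames(fg)))
  g <- function(nm) fg[, nm]
  log_arg <- g("CtCO2H") + 0.86
  if (any(log_arg <= 0)) {
    stop("beta_reference: log(CtCO2H + 0.86) has non-positive argument ",
         "(term gamma1)")
  }
  gamma1 <- 5.16 * g("CtAm") + 5.16 * log(log_arg)
  gamma2 <- 3.83 * g("CtPh") + 8.70 * (g("CtNH2") + g("CtOH")) - 0.73
  gamma3 <- (g("CtNO2") + g("CtRCO2R")) / (0.44 * g("CtRCO2R") - 0.14) - 0.29
  gamma4 <- g("CtF") * (g("CtROR") + 1.44) - 2.96 * g("CtR2CO") -
    2.96 * exp(g("CtAl")) -
    2.96 * (g("CtAl") + 0.66) * (g("CtR2CO") + g("CtROR") + g("CtCN") - 1.20)
  gamma5 <- g("CtMe") + 2.54 * g("CtCl") +
    2.54 * (1.21 - g("CtBr")) * (g("CtBr") + 2.73 * (g("CtI") - 0.52)) + 2
  beta <- 0.07 * gamma2 -
    (0.003 * gamma5 * (2 * gamma2 - gamma3 - gamma4) - 0.27) *
      (gamma1 - gamma5 + (gamma2 - gamma4) * (0.14 * gamma5 + 0.35)) - 0.63
  gamma <- cbind(gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
                 gamma4 = gamma4, gamma5 = gamma5)
  rownames(gamma) <- NULL
  list(gamma = gamma, beta = unname(beta))
}

#' Decompose the Rf governing equation into a one-variable partial curve
#'
#' Fixing one retention index in the sigmoid-affine governing equation
#' yields `Rf = h(psi) = sigma(5.15 psi + C1)` or
#' `Rf = g(xi) = sigma(5.15 xi + C2)`, where the constant absorbs the fixed
#' index and the intercept.
#'
#' @param fix which index to hold fixed: fixing `"xi"` returns the solvent
#'   curve `h(psi)` and `C1`; fixing `"psi"` returns `g(xi)` and `C2`.
#' @param value the value at which the index is fixed.
#' @param coef_psi,coef_xi,intercept coefficients of the sigmoid-affine
#'   governing equation (defaults: the reference equation).
#' @return list with `curve` (a function of the free index), `constant`
#'   (C1 or C2) and `slope`.
#' @examples
#' decompose_rf("xi", 0)$constant  # C1 = 1.55
#' decompose_rf("xi", 1)$constant  # 5.15 + 1.55 = 6.70
#' @export
decompose_rf <- function(fix = c("xi", "psi"), value = 0,
                         coef_psi = 5.15, coef_xi = 5.15, intercept = 1.55) {
  fix <- match.arg(fix)
  if (fix == "xi") {
    constant <- coef_xi * value + intercept
    slope <- coef_psi
  } else {
    constant <- coef_psi * value + intercept
    slope <- coef_xi
  }
  force(constant); force(slope)
  list(curve = function(z) sigmoid(slope * z + constant),
       constant = constant, slope = slope, fixed = fix, value = value)
}

#' The reference equation chain as an evaluable object
#'
#' Bundles the reference fixtures into the chain used by value-flow tracing
#' and feature importance: solvent composition -> psi; counts -> beta (via
#' the linear probe weights); (DM, NBen) -> alpha (affine surrogate,
#' optionally standardized); (alpha, beta) -> xi; (psi, xi) -> Rf.
#'
#' @param alpha_transform,beta_transform optional `list(shift=, scale=)`
#'   affine standardizations applied to the raw alpha surrogate
#'   `0.5 DM + 0.5 NBen` and to the raw linear-probe beta (the gauge in
#'   which the governing equations live).  Defaults: identity.
#' @return object of class `uhsr_chain`.
#' @export
reference_chain <- function(alpha_transform = list(shift = 0, scale = 1),
                            beta_transform = list(shift = 0, scale = 1)) {
  structure(list(alpha_transform = alpha_transform,
                 beta_transform = beta_transform),
            class = "uhsr_chain")
}

chain_nodes <- function(chain, x) {
  # x: named numeric vector (or 1-row data.frame) with the 23 features
  fn <- tlc_feature_names()
  if (is.data.frame(x)) {
    cols <- intersect(colnames(x), fn)
    x <- vapply(x[1, cols, drop = FALSE], as.numeric, numeric(1))
  }
  stopifnot(all(fn %in% names(x)))
  x <- x[fn]
  psi <- psi_reference(x[["Hex"]], x[["EA"]], x[["DCM"]],
                       x[["MeOH"]], x[["Et2O"]])
  beta_raw <- fg_probe_linear(x[fg_count_names()])
  at <- chain$alpha_transform; bt <- chain$beta_transform
  alpha_raw <- 0.5 * x[["DM"]] + 0.5 * x[["NBen"]]
  alpha <- (alpha_raw - at$shift) / at$scale
  beta <- (beta_raw - bt$shift) / bt$scale
  xi <- xi_reference(alpha, beta)
  rf <- rf_governing(psi, xi)
  list(psi = psi, alpha_raw = alpha_raw, alpha = alpha,
       beta_raw = beta_raw, beta = beta, xi = xi, rf = rf)
}

#' Evaluate the reference chain on a feature table
#'
#' @param object an `uhsr_chain` from [reference_chain()].
#' @param newdata data.frame with the 23 canonical feature columns.
#' @param ... unused.
#' @return numeric vector of predicted Rf.
#' @export
predict.uhsr_chain <- function(object, newdata, ...) {
  chain <- object
  X <- as.data.frame(newdata)
  vapply(seq_len(nrow(X)),
         function(i) chain_nodes(chain, X[i, , drop = FALSE])$rf,
         numeric(1))
}

#' Trace how feature values flow through the equation chain
#'
#' Records every intermediate index value (beta from the counts, alpha from
#' the distribution features, xi from (alpha, beta), psi from the solvent
#' composition, Rf from (psi, xi)) for a single sample.  The terminal node
#' equals the direct chain evaluation to within 1e-9 by construction.
#'
#' @param chain an `uhsr_chain`.
#' @param x named numeric vector (or 1-row data.frame) with the 23 features.
#' @return data.frame of class `uhsr_flow` with columns `node`, `value`,
#'   `parent`.
#' @export
value_flow <- function(chain, x) {
  nodes <- chain_nodes(chain, x)
  fn <- tlc_feature_names()
  if (is.data.frame(x)) {
    cols <- intersect(colnames(x), fn)
    x <- vapply(x[1, cols, drop = FALSE], as.numeric, numeric(1))
  }
  solvent <- intersect(fn[1:5], names(x))
  counts <- fg_count_names()
  out <- rbind(
    data.frame(node = solvent, value = unname(x[solvent]), parent = "psi"),
    data.frame(node = counts, value = unname(x[counts]), parent = "beta"),
    data.frame(node = c("NBen", "DM"),
               value = unname(x[c("NBen", "DM")]), parent = "alpha"),
    data.frame(node = c("alpha", "beta"),
               value = c(nodes$alpha, nodes$beta), parent = "xi"),
    data.frame(node = c("psi", "xi"),
               value = c(nodes$psi, nodes$xi), parent = "rf"),
    data.frame(node = "rf", value = nodes$rf, parent = NA_character_)
  )
  class(out) <- c("uhsr_flow", "data.frame")
  out
}

#' Perturbation-based feature importance over an equation chain
#'
#' Importance of input i = mean absolute change of the chain output under a
#' one-at-a-time perturbation of feature i by one sample standard deviation,
#' normalized to sum to one.  Zero-variance inputs get importance 0 and are
#' flagged.
#'
#' @param f a function mapping a feature data.frame to a numeric output
#'   (e.g. `function(d) predict(reference_chain(), d)`), or an `uhsr_chain`.
#' @param data data.frame of samples over which importance is measured.
#' @param features character vector of column names to perturb (default:
#'   all columns of `data`).
#' @return data.frame with columns `feature`, `importance`,
#'   `zero_variance`, sorted by decreasing importance.
#' @export
feature_importance <- function(f, data, features = colnames(data)) {
  if (inherits(f, "uhsr_chain")) {
    chain <- f
    f <- function(d) predict(chain, d)
  }
  stopifnot(is.function(f), nrow(data) >= 2)
  base <- f(data)
  raw <- vapply(features, function(nm) {
    s <- stats::sd(data[[nm]])
    if (!is.finite(s) || s == 0) return(NA_real_)
    d <- data
    d[[nm]] <- d[[nm]] + s
    mean(abs(f(d) - base))
  }, numeric(1))
  zero_var <- is.na(raw)
  raw[zero_var] <- 0
  tot <- sum(raw)
  imp <- if (tot > 0) raw / tot else raw
  out <- data.frame(feature = features, importance = unname(imp),
                    zero_variance = unname(zero_var))
  out[order(-out$importance), , drop = FALSE]
}

#' Reference equations as canonical expression strings
#'
#' The fixtures in the grammar accepted by [parse_expression()], suitable
#' for round-tripping through the symbolic-regression evaluator.
#'
#' @return named character vector.
#' @export
reference_equation_strings <- function() {
  c(rf  = "sigma(5.15*psi + 5.15*xi + 1.55)",
    psi = "-1.37*Hex - 0.20*EA - 1.02*DCM + 4.65*MeOH - 0.45*Et2O",
    xi  = "0.37*alpha - 0.35*beta - alpha*beta + 0.69")
}
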