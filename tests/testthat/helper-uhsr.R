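# shared fixtures and an independent expression-evaluation oracle

tiny_hp <- function(seed = 2L, epochs = 120L) {
  uhsr_hyperparams(hidden_width = 16L, epochs = epochs, batch_size = 128L,
                   seed = seed)
}

# compile a tree into an R expression string and evaluate it with base R --
# a code path independent of the package's recursive interpreter, sharing
# only the documented protection contract
oracle_compile <- function(node) {
  if (!is.null(node$const)) return(sprintf("%.17g", node$const))
  if (!is.null(node$var)) return(node$var)
  a <- oracle_compile(node$args[[1]])
  if (length(node$args) > 1) b <- oracle_compile(node$args[[2]])
  switch(node$op,
    "+" = sprintf("(%s + %s)", a, b),
    "-" = sprintf("(%s - %s)", a, b),
    "*" = sprintf("(%s * %s)", a, b),
    "pdiv" = sprintf("PDIV(%s, %s)", a, b),
    "^" = sprintf("(%s ^ %s)", a, b),
    "exp" = sprintf("exp(pmin(%s, 50))", a),
    "plog" = sprintf("log(pmax(%s, 1e-9))", a),
    "sigma" = sprintf("(1 / (1 + exp(-(%s))))", a),
    "neg" = sprintf("(-(%s))", a),
    stop("oracle: unknown op ", node$op))
}

oracle_eval <- function(tree, X) {
  env <- list2env(as.list(X), parent = baseenv())
  env$PDIV <- function(a, b) {
    b[abs(b) < 1e-9] <- 1e-10
    a / b
  }
  env$pmin <- pmin; env$pmax <- pmax
  v <- eval(parse(text = oracle_compile(tree)), envir = env)
  rep_len(v, nrow(X))
}

# a single valid composition + solute for record-level tests
example_dataset <- function(n = 5) {
  solv <- data.frame(Hex = c(0.5, 0.8, 0, 0, 0.6),
                     EA = c(0.5, 0.2, 0, 0, 0),
                     DCM = c(0, 0, 0.95, 1, 0),
                     MeOH = c(0, 0, 0.05, 0, 0),
                     Et2O = c(0, 0, 0, 0, 0.4))[seq_len(n), , drop = FALSE]
  fg <- matrix(0L, n, 16, dimnames = list(NULL, fg_count_names()))
  fg[1, "CtOH"] <- 1L
  if (n >= 2) fg[2, "CtAm"] <- 1L
  tlc_dataset(solv, fg, n_ben = rep(1L, n), dm = seq(0.5, by = 0.3,
                                                     length.out = n),
              rf = seq(0.1, 0.9, length.out = n))
}

skip_if_no_chemminer <- function() {
  testthat::skip_if_not_installed("ChemmineR")
  testthat::skip_if_not_installed("ChemmineOB")
}
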