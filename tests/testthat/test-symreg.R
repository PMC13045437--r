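test_that("the evaluator matches an independent recursive oracle on random trees", {
  vars <- c("a", "b", "c")
  cfg <- sr_config(primitives = c("+", "-", "*", "pdiv", "exp", "plog"),
                   seed = 0)
  set.seed(42)
  X <- data.frame(a = rnorm(50), b = runif(50, -3, 3),
                  c = c(0, rnorm(49)))  # include an exact zero
  for (k in 1:100) {
    tree <- uhsr:::random_tree(vars, cfg, depth = 4L,
                               method = if (k %% 2) "grow" else "full")
    expect_equal(sr_evaluate(tree, X), oracle_eval(tree, X),
                 tolerance = 1e-12,
                 label = paste("tree", k, to_canonical_string(tree)))
  }
})

test_that("protected operators keep evaluation finite and penalize fitness", {
  div0 <- parse_expression("x / 0")
  X <- data.frame(x = c(1, 2, 3))
  expect_true(all(is.finite(sr_evaluate(div0, X))))
  expect_identical(uhsr:::sr_fitness(div0, X, c(1, 2, 3)), Inf)

  log_neg <- parse_expression("log(x - 5)")
  expect_true(all(is.finite(sr_evaluate(log_neg, X))))
  expect_identical(uhsr:::sr_fitness(log_neg, X, c(1, 2, 3)), Inf)

  # a constant tree broadcasts over the table
  expect_equal(sr_evaluate(parse_expression("0.69"), X), rep(0.69, 3))
  # unbound variables are named in the error
  expect_error(sr_evaluate(parse_expression("q + 1"), X), "'q'")
})

test_that("an exactly representable linear target is recovered", {
  set.seed(1)
  X <- data.frame(x = runif(60, -2, 2))
  y <- 2 * X$x + 1
  front <- sr_fit(X, y, sr_config(population = 300, generations = 15,
                                  seed = 1))
  sel <- sr_select(front)
  expect_lt(attr(sel, "loss"), 1e-6)
  # read the slope and intercept off the recovered expression
  f0 <- sr_evaluate(sel, data.frame(x = 0))
  f1 <- sr_evaluate(sel, data.frame(x = 1))
  expect_equal(f1 - f0, 2, tolerance = 0.01)
  expect_equal(f0, 1, tolerance = 0.01)
})

test_that("fits are deterministic under a fixed seed", {
  set.seed(99)
  X <- data.frame(u = runif(40), v = runif(40))
  y <- X$u - 0.5 * X$v + 0.2
  cfg <- sr_config(population = 150, generations = 6, seed = 7)
  f1 <- sr_fit(X, y, cfg)
  f2 <- sr_fit(X, y, cfg)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
})

test_that("constant optimization is exact for linear structure and monotone in loss", {
  set.seed(3)
  X <- data.frame(x = runif(40, -1, 2))
  y <- 2 * X$x + 1
  tree <- parse_expression("0.0*x + 0.0")
  opt <- optimize_constants(tree, X, y)
  cs <- sort(uhsr:::collect_constants(opt))
  expect_equal(cs, c(1, 2), tolerance = 1e-6)

  # never increases the loss, for assorted structures
  for (txt in c("1.3*x + 0.1*x*x", "exp(0.2*x)", "x*(x - 0.7)")) {
    tr <- parse_expression(txt)
    before <- uhsr:::sr_fitness(tr, X, y)
    after <- uhsr:::sr_fitness(optimize_constants(tr, X, y), X, y)
    expect_lte(after, before)
  }

  # constant-free trees pass through unchanged
  cf <- parse_expression("x * x")
  expect_identical(optimize_constants(cf, X, y), cf)
})

test_that("parsimony selection picks the simplest near-best expression", {
  mk <- function(cx, loss) list(complexity = cx, loss = loss,
                                tree = uhsr:::const_node(loss))
  front <- list(mk(3, 0.100), mk(9, 0.095), mk(15, 0.094))
  expect_equal(attr(sr_select(front, delta = 0.10), "complexity"), 3L)
  expect_equal(attr(sr_select(front, delta = 0), "complexity"), 15L)
  expect_equal(attr(sr_select(front[2], delta = 0.1), "complexity"), 9L)
  expect_error(sr_select(list()), "empty")
})

test_that("fitted fronts contain no dominated member", {
  set.seed(5)
  X <- data.frame(x = runif(80, -2, 2), z = runif(80, -2, 2))
  y <- X$x * X$z + 0.3 * X$x + rnorm(80, sd = 0.05)
  front <- sr_fit(X, y, sr_config(population = 250, generations = 10,
                                  seed = 2))$front
  cx <- vapply(front, `[[`, integer(1), "complexity")
  loss <- vapply(front, `[[`, numeric(1), "loss")
  expect_true(all(diff(cx) > 0))
  expect_true(all(diff(loss) < 0))
})

test_that("a constant response yields the degenerate constant front", {
  X <- data.frame(x = runif(20))
  front <- sr_fit(X, rep(0.4, 20), sr_config(seed = 1))
  expect_length(front$front, 1)
  expect_equal(sr_evaluate(front$front[[1]]$tree, X), rep(0.4, 20))
})

test_that("canonical rendering is deterministic under commutative reordering", {
  eq <- parse_expression("sigma(5.15*psi + 5.15*xi + 1.55)")
  expect_equal(to_canonical_string(eq),
               "sigma(5.15*psi + 5.15*xi + 1.55)")
  reordered <- parse_expression("sigma(1.55 + xi*5.15 + 5.15*psi)")
  expect_identical(to_canonical_string(reordered), to_canonical_string(eq))
  expect_equal(to_canonical_string(parse_expression("0.69"), digits = 3),
               "0.690")
  expect_equal(to_canonical_string(parse_expression("0.69 + x"), digits = 2),
               "x + 0.69")
})

test_that("simplification folds constants without changing the function", {
  set.seed(8)
  X <- data.frame(x = rnorm(30), y = rnorm(30))
  for (txt in c("2*(3*x) + 0*y", "1*x - 0", "(2 + 3)*x*y", "-(-x)")) {
    tr <- parse_expression(txt)
    s <- simplify_tree(tr)
    expect_equal(sr_evaluate(s, X), sr_evaluate(tr, X), label = txt)
    expect_lte(tree_complexity(s), tree_complexity(tr))
  }
  expect_equal(tree_complexity(simplify_tree(parse_expression("2*(3*x)"))), 3L)
})

test_that("expansion distributes products over sums without changing the function", {
  set.seed(12)
  X <- data.frame(x = rnorm(25), y = rnorm(25))
  cases <- c("2*(x + y)", "(1 + x)*(2 - y)", "0.5*(x - y)*y",
             "3.39*(x + y) - 1.13*y")
  for (txt in cases) {
    tr <- parse_expression(txt)
    ex <- expand_tree(tr)
    expect_equal(sr_evaluate(ex, X), sr_evaluate(tr, X), tolerance = 1e-12,
                 label = txt)
  }
  expect_identical(to_canonical_string(expand_tree(parse_expression("2*(x + y)"))),
                   "2.00*x + 2.00*y")
  expect_identical(
    to_canonical_string(expand_tree(parse_expression("3.39*(x + y) - 1.13*y"))),
    "3.39*x + 2.26*y")
})

test_that("configuration invariants are enforced", {
  expect_error(sr_config(primitives = character(0)), "empty")
  expect_error(sr_config(primitives = "sin"), "unknown")
  expect_error(sr_fit(data.frame(x = 1:5), 1:5), "10 samples")
  expect_error(sr_fit(data.frame(x = c(1:9, NA)), 1:10), "missing")
})
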