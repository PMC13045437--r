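# Expression trees for symbolic regression.
#
# A tree node is one of:
#   list(op = <name>, args = list(...))   primitive application
#   list(var = <name>)                    named variable terminal
#   list(const = <value>)                 real constant terminal
# Complexity is the total node count (constants and variables count 1).

sr_primitives <- function() {
  c("+" = 2L, "-" = 2L, "*" = 2L, "pdiv" = 2L, "^" = 2L,
    "exp" = 1L, "plog" = 1L, "sigma" = 1L, "neg" = 1L)
}

op_node <- function(op, ...) list(op = op, args = list(...))
var_node <- function(name) list(var = name)
const_node <- function(value) list(const = value)

is_op <- function(node) !is.null(node$op)
is_const <- function(node) !is.null(node$const)
is_var <- function(node) !is.null(node$var)

#' Complexity of an expression tree
#'
#' Total node count; primitive applications, variables and constants each
#' count one.
#'
#' @param expr an expression tree.
#' @return integer.
#' @export
tree_complexity <- function(expr) {
  if (is_op(expr)) {
    1L + sum(vapply(expr$args, tree_complexity, integer(1)))
  } else 1L
}

# Sentinel magnitude used by protected operators.  When a protected
# operation is triggered the candidate is additionally marked for a
# worst-case fitness penalty (ctx$penalty).
.sr_sentinel <- 1e10

eval_tree <- function(node, data, ctx) {
  if (is_const(node)) return(node$const)
  if (is_var(node)) {
    v <- data[[node$var]]
    if (is.null(v)) stop("unbound variable '", node$var, "'")
    return(v)
  }
  a <- eval_tree(node$args[[1]], data, ctx)
  switch(node$op,
    "+" = a + eval_tree(node$args[[2]], data, ctx),
    "-" = a - eval_tree(node$args[[2]], data, ctx),
    "*" = a * eval_tree(node$args[[2]], data, ctx),
    "pdiv" = {
      b <- eval_tree(node$args[[2]], data, ctx)
      bad <- abs(b) < 1e-9
      if (any(bad)) {
        ctx$penalty <- TRUE
        b[bad] <- 1 / .sr_sentinel
      }
      a / b
    },
    "^" = {
      b <- eval_tree(node$args[[2]], data, ctx)
      r <- a^b
      bad <- !is.finite(r)
      if (any(bad)) {
        ctx$penalty <- TRUE
        r[bad] <- .sr_sentinel
      }
      r
    },
    "exp" = {
      r <- exp(pmin(a, 50))
      if (any(a > 50)) ctx$penalty <- TRUE
      r
    },
    "plog" = {
      bad <- a < 1e-9
      if (any(bad)) {
        ctx$penalty <- TRUE
        a[bad] <- 1e-9
      }
      log(a)
    },
    "sigma" = 1 / (1 + exp(-a)),
    "neg" = -a,
    stop("unknown primitive '", node$op, "'")
  )
}

#' Evaluate an expression tree on a variable table
#'
#' Vectorized recursive evaluation.  Protected operators (`pdiv`, `plog`,
#' overflow guards on `exp` / `^`) never emit non-finite values: offending
#' elements receive a large-magnitude sentinel contribution, and during
#' fitting the candidate is assigned worst-case fitness.
#'
#' @param expr an expression tree (or a string parsed with
#'   [parse_expression()]).
#' @param X data.frame / named list binding every variable in `expr`.
#' @return numeric vector of predictions.
#' @export
sr_evaluate <- function(expr, X) {
  if (is.character(expr)) expr <- parse_expression(expr)
  ctx <- new.env(parent = emptyenv())
  ctx$penalty <- FALSE
  n <- if (is.data.frame(X)) nrow(X) else length(X[[1]])
  v <- eval_tree(expr, X, ctx)
  rep_len(v, n)
}

sr_fitness <- function(expr, X, y) {
  ctx <- new.env(parent = emptyenv())
  ctx$penalty <- FALSE
  v <- tryCatch(eval_tree(expr, X, ctx), error = function(e) NULL)
  if (is.null(v) || ctx$penalty) return(Inf)
  v <- rep_len(v, length(y))
  if (any(!is.finite(v))) return(Inf)
  mean((v - y)^2)
}

# ---- tree surgery ---------------------------------------------------------

# all node paths in pre-order; a path is an integer vector of arg positions
tree_paths <- function(node, prefix = integer(0)) {
  out <- list(prefix)
  if (is_op(node)) {
    for (i in seq_along(node$args)) {
      out <- c(out, tree_paths(node$args[[i]], c(prefix, i)))
    }
  }
  out
}

subtree_at <- function(node, path) {
  for (i in path) node <- node$args[[i]]
  node
}

replace_at <- function(node, path, sub) {
  if (length(path) == 0) return(sub)
  node$args[[path[1]]] <- replace_at(node$args[[path[1]]], path[-1], sub)
  node
}

collect_constants <- function(node) {
  if (is_const(node)) return(node$const)
  if (is_var(node)) return(numeric(0))
  unlist(lapply(node$args, collect_constants))
}

set_constants <- function(node, values, pos = 1L) {
  # returns list(node, next_pos)
  if (is_const(node)) {
    node$const <- values[pos]
    return(list(node = node, pos = pos + 1L))
  }
  if (is_var(node)) return(list(node = node, pos = pos))
  for (i in seq_along(node$args)) {
    r <- set_constants(node$args[[i]], values, pos)
    node$args[[i]] <- r$node
    pos <- r$pos
  }
  list(node = node, pos = pos)
}

# ---- algebraic simplification --------------------------------------------

#' Simplify an expression tree
#'
#' Folds constant-only subtrees and removes arithmetic identities
#' (addition of 0, multiplication by 0 or 1, double negation).  The
#' simplified tree computes the same function; only its representation
#' (and hence node-count complexity) changes.
#'
#' @param expr an expression tree.
#' @return the simplified tree.
#' @export
simplify_tree <- function(expr) {
  if (!is_op(expr)) return(expr)
  expr$args <- lapply(expr$args, simplify_tree)
  a <- expr$args[[1]]
  b <- if (length(expr$args) > 1) expr$args[[2]]
  if (all(vapply(expr$args, is_const, logical(1)))) {
    ctx <- new.env(parent = emptyenv()); ctx$penalty <- FALSE
    v <- tryCatch(eval_tree(expr, list(), ctx), error = function(e) NULL)
    if (!is.null(v) && !ctx$penalty && is.finite(v)) return(const_node(v))
    return(expr)
  }
  is_zero <- function(x) is_const(x) && x$const == 0
  is_one <- function(x) is_const(x) && x$const == 1
  switch(expr$op,
    "+" = merge_sum(expr),
    "-" = merge_sum(expr),
    "*" = {
      if (is_zero(a) || is_zero(b)) return(const_node(0))
      if (is_one(a)) return(b)
      if (is_one(b)) return(a)
      # collapse nested constant factors: c1*(c2*t) -> (c1*c2)*t
      if (is_const(b) && !is_const(a)) { tmp <- a; a <- b; b <- tmp }
      if (is_const(a) && is_op(b) && b$op == "*") {
        if (is_const(b$args[[1]])) {
          return(simplify_tree(op_node("*",
            const_node(a$const * b$args[[1]]$const), b$args[[2]])))
        }
        if (is_const(b$args[[2]])) {
          return(simplify_tree(op_node("*",
            const_node(a$const * b$args[[2]]$const), b$args[[1]])))
        }
      }
      op_node("*", a, b)
    },
    "neg" = {
      if (is_op(a) && a$op == "neg") return(a$args[[1]])
      expr
    },
    expr)
}

#' Expand products over sums
#'
#' Distributes multiplication over addition/subtraction recursively and
#' merges like terms, yielding the flat polynomial-style form used when
#' reporting equations.  Expansion can increase the node count, so it is a
#' display transform: Pareto complexities are measured on the compact tree.
#'
#' @param expr an expression tree.
#' @return the expanded, simplified tree.
#' @export
expand_tree <- function(expr) {
  if (!is_op(expr)) return(expr)
  expr$args <- lapply(expr$args, expand_tree)
  if (expr$op == "*") {
    for (i in 1:2) {
      a <- expr$args[[i]]
      other <- expr$args[[3 - i]]
      if (is_op(a) && a$op %in% c("+", "-")) {
        out <- NULL
        for (t in flatten_sum(a)) {
          prod <- op_node("*", t$node, other)
          if (t$negate) prod <- op_node("neg", prod)
          out <- if (is.null(out)) prod else op_node("+", out, prod)
        }
        return(expand_tree(out))
      }
    }
  }
  simplify_tree(expr)
}

# split a (simplified) term into a numeric coefficient and a non-constant
# core (NULL for pure constants)
term_split <- function(t) {
  if (is_const(t)) return(list(coef = t$const, core = NULL))
  if (is_var(t)) return(list(coef = 1, core = t))
  if (is_op(t) && t$op == "neg") {
    r <- term_split(t$args[[1]])
    r$coef <- -r$coef
    return(r)
  }
  if (is_op(t) && t$op == "*") {
    factors <- flatten_chain(t, "*")
    is_c <- vapply(factors, is_const, logical(1))
    coef <- prod(vapply(factors[is_c], `[[`, numeric(1), "const"), 1)
    rest <- factors[!is_c]
    if (!length(rest)) return(list(coef = coef, core = NULL))
    core <- rest[[1]]
    for (f in rest[-1]) core <- op_node("*", core, f)
    return(list(coef = coef, core = core))
  }
  list(coef = 1, core = t)
}

# flatten a +/- chain, fold constant terms together, and merge like terms
# (same non-constant core) by summing their coefficients
merge_sum <- function(node) {
  terms <- flatten_sum(node)
  const_total <- 0
  cores <- list()
  coefs <- numeric(0)
  keys <- character(0)
  for (t in terms) {
    r <- term_split(t$node)
    coef <- if (t$negate) -r$coef else r$coef
    if (is.null(r$core)) {
      const_total <- const_total + coef
      next
    }
    key <- to_canonical_string(r$core, digits = 10)
    i <- match(key, keys)
    if (is.na(i)) {
      keys <- c(keys, key)
      cores[[length(cores) + 1L]] <- r$core
      coefs <- c(coefs, coef)
    } else {
      coefs[i] <- coefs[i] + coef
    }
  }
  keep <- abs(coefs) > 1e-12
  cores <- cores[keep]
  coefs <- coefs[keep]
  mk_term <- function(coef, core) {
    if (abs(coef - 1) < 1e-12) core else op_node("*", const_node(coef), core)
  }
  out <- NULL
  for (i in seq_along(cores)) {
    if (coefs[i] <= 0) next
    term <- mk_term(coefs[i], cores[[i]])
    out <- if (is.null(out)) term else op_node("+", out, term)
  }
  for (i in seq_along(cores)) {
    if (coefs[i] > 0) next
    term <- mk_term(-coefs[i], cores[[i]])
    out <- if (is.null(out)) op_node("neg", term) else op_node("-", out, term)
  }
  if (is.null(out)) return(const_node(const_total))
  if (const_total > 1e-12) {
    out <- op_node("+", out, const_node(const_total))
  } else if (const_total < -1e-12) {
    out <- op_node("-", out, const_node(-const_total))
  }
  out
}

# ---- parsing and rendering ------------------------------------------------

lang_to_tree <- function(e) {
  if (is.numeric(e)) return(const_node(as.numeric(e)))
  if (is.name(e)) return(var_node(as.character(e)))
  if (!is.call(e)) stop("unsupported expression element: ", deparse(e))
  f <- as.character(e[[1]])
  args <- lapply(as.list(e)[-1], lang_to_tree)
  if (f == "(") return(args[[1]])
  if (f == "-" && length(args) == 1) {
    if (is_const(args[[1]])) return(const_node(-args[[1]]$const))
    return(op_node("neg", args[[1]]))
  }
  if (f == "+" && length(args) == 1) return(args[[1]])
  op <- switch(f, "/" = "pdiv", "log" = "plog", f)
  if (!op %in% names(sr_primitives())) stop("unknown function '", f, "'")
  if (length(args) != sr_primitives()[[op]]) {
    stop("wrong arity for '", f, "'")
  }
  do.call(op_node, c(list(op), args))
}

#' Parse an infix equation string into an expression tree
#'
#' Accepts the canonical grammar: `+ - * / ^ exp log sigma`, named
#' variables, and real constants.  `/` parses to the protected division and
#' `log` to the protected logarithm.
#'
#' @param text equation string, e.g. `"0.37*alpha - 0.35*beta + 0.69"`.
#' @return an expression tree.
#' @export
parse_expression <- function(text) {
  lang_to_tree(str2lang(text))
}

render_node <- function(node, digits) {
  fmt <- function(v) {
    if (v != 0 && abs(v) < 10^(-digits) / 2) {
      # below fixed-decimal resolution: fall back to significant digits
      return(formatC(v, digits = digits + 1, format = "g"))
    }
    s <- formatC(v, digits = digits, format = "f")
    sub("^-0(\\.0+)?$", "0", s)
  }
  # returns list(str, prec, is_negated) where prec ranks binding strength
  if (is_const(node)) {
    v <- node$const
    return(list(str = fmt(abs(v)), prec = 3L, neg = v < 0,
                sort_key = paste0("~", fmt(abs(v)))))
  }
  if (is_var(node)) {
    return(list(str = node$var, prec = 3L, neg = FALSE, sort_key = node$var))
  }
  op <- node$op
  if (op %in% c("exp", "plog", "sigma")) {
    inner <- render_sum(node$args[[1]], digits)
    nm <- c(exp = "exp", plog = "log", sigma = "sigma")[[op]]
    s <- paste0(nm, "(", inner, ")")
    return(list(str = s, prec = 3L, neg = FALSE, sort_key = s))
  }
  if (op == "neg") {
    r <- render_node(node$args[[1]], digits)
    return(list(str = r$str, prec = r$prec, neg = !r$neg,
                sort_key = r$sort_key))
  }
  if (op %in% c("+", "-")) {
    return(list(str = render_sum(node, digits), prec = 1L, neg = FALSE,
                sort_key = render_sum(node, digits)))
  }
  if (op == "*") {
    factors <- flatten_chain(node, "*")
    rendered <- lapply(factors, render_node, digits = digits)
    neg <- sum(vapply(rendered, function(r) r$neg, logical(1))) %% 2 == 1
    # constants first, then variables/others sorted for a canonical order
    is_c <- vapply(factors, is_const, logical(1))
    keys <- vapply(rendered, function(r) r$sort_key, character(1))
    ord <- order(!is_c, keys)
    strs <- vapply(rendered[ord], function(r) {
      if (r$prec < 2L) paste0("(", r$str, ")") else r$str
    }, character(1))
    return(list(str = paste(strs, collapse = "*"), prec = 2L, neg = neg,
                sort_key = paste(sort(keys[!is_c]), collapse = "*")))
  }
  # non-commutative binaries: pdiv, ^
  lhs <- render_node(node$args[[1]], digits)
  rhs <- render_node(node$args[[2]], digits)
  wrap <- function(r) {
    s <- if (r$neg) paste0("-", r$str) else r$str
    if (r$prec < 3L || r$neg) paste0("(", s, ")") else s
  }
  sym <- if (op == "pdiv") "/" else "^"
  s <- paste0(wrap(lhs), sym, wrap(rhs))
  list(str = s, prec = 2L, neg = FALSE, sort_key = s)
}

flatten_chain <- function(node, op) {
  if (is_op(node) && node$op == op) {
    c(flatten_chain(node$args[[1]], op), flatten_chain(node$args[[2]], op))
  } else list(node)
}

flatten_sum <- function(node, negate = FALSE) {
  # returns list of list(node, negate)
  if (is_op(node) && node$op == "+") {
    c(flatten_sum(node$args[[1]], negate), flatten_sum(node$args[[2]], negate))
  } else if (is_op(node) && node$op == "-") {
    c(flatten_sum(node$args[[1]], negate), flatten_sum(node$args[[2]], !negate))
  } else if (is_op(node) && node$op == "neg") {
    flatten_sum(node$args[[1]], !negate)
  } else {
    list(list(node = node, negate = negate))
  }
}

render_sum <- function(node, digits) {
  terms <- flatten_sum(node)
  rendered <- lapply(terms, function(t) {
    r <- render_node(t$node, digits)
    r$neg <- xor(r$neg, t$negate)
    r$is_const_term <- is_const(t$node)
    r
  })
  # canonical term order: non-constant terms sorted by key, constants last
  keys <- vapply(rendered, function(r) {
    paste0(if (r$is_const_term) "~~" else "", r$sort_key)
  }, character(1))
  rendered <- rendered[order(keys)]
  out <- ""
  for (i in seq_along(rendered)) {
    r <- rendered[[i]]
    s <- if (r$prec < 1L) paste0("(", r$str, ")") else r$str
    if (i == 1) {
      out <- if (r$neg) paste0("-", s) else s
    } else {
      out <- paste0(out, if (r$neg) " - " else " + ", s)
    }
  }
  out
}

#' Render an expression tree as a canonical infix string
#'
#' Deterministic: commutative chains are flattened and reordered into a
#' canonical term order (within sums, constants are printed last), so two
#' trees differing only by commutative reordering render identically.
#'
#' @param expr an expression tree.
#' @param digits decimal places for constants.
#' @return character string in the canonical grammar.
#' @export
to_canonical_string <- function(expr, digits = 2) {
  r <- render_node(expr, digits)
  if (r$neg) paste0("-", r$str) else r$str
}
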