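#' Symbolic-regression configuration
#'
#' Defaults for the built-in genetic-programming engine: population 1000,
#' 40 generations, tournament size 10, a 0.3/0.7 crossover/mutation split
#' (mutation mass spread over subtree, point, constant-jitter, insert and
#' hoist operators), maximum complexity 30 nodes, and parsimony tolerance
#' 0.01 for equation selection.  Once a near-perfect fit (loss below
#' `early_stop_loss`) is on the front, evolution continues for
#' `patience` further generations (giving simplifying mutations a chance to
#' reach the minimal exact form) and then stops.
#'
#' @param primitives primitive set, a subset of
#'   `c("+", "-", "*", "pdiv", "exp", "plog")`.
#' @param population population size.
#' @param generations maximum generations.
#' @param tournament tournament size for parent selection.
#' @param p_crossover probability an offspring comes from crossover; the
#'   remainder is split over mutation operators by `mutation_weights`.
#' @param mutation_weights named weights for `subtree`, `point`, `jitter`,
#'   `insert`, `hoist`.
#' @param max_complexity maximum tree node count.
#' @param parsimony_delta relative loss tolerance for [sr_select()].
#' @param const_range range for freshly sampled constants.
#' @param early_stop_loss loss threshold triggering early stopping.
#' @param patience extra generations after the threshold is reached.
#' @param optimize_constants run local least-squares refinement of the
#'   constants of new front members each generation.
#' @param seed RNG seed; fits are deterministic under a fixed seed.
#' @return list of class `sr_config`.
#' @export
sr_config <- function(primitives = c("+", "-", "*"),
                      population = 1000L, generations = 40L,
                      tournament = 10L, p_crossover = 0.3,
                      mutation_weights = c(subtree = 0.25, point = 0.25,
                                           jitter = 0.15, insert = 0.25,
                                           hoist = 0.10),
                      max_complexity = 30L, parsimony_delta = 0.01,
                      const_range = c(-2, 2), early_stop_loss = 1e-12,
                      patience = 8L, optimize_constants = TRUE,
                      seed = 0L) {
  if (length(primitives) == 0) stop("empty primitive set")
  bad <- setdiff(primitives, names(sr_primitives()))
  if (length(bad)) stop("unknown primitive(s): ", paste(bad, collapse = ", "))
  stopifnot(p_crossover >= 0, p_crossover <= 1, max_complexity >= 3,
            parsimony_delta >= 0, population >= 10, generations >= 1)
  structure(list(primitives = primitives, population = as.integer(population),
                 generations = as.integer(generations),
                 tournament = as.integer(tournament),
                 p_crossover = p_crossover,
                 mutation_weights = mutation_weights / sum(mutation_weights),
                 max_complexity = as.integer(max_complexity),
                 parsimony_delta = parsimony_delta,
                 const_range = const_range,
                 early_stop_loss = early_stop_loss,
                 patience = as.integer(patience),
                 optimize_constants = isTRUE(optimize_constants),
                 seed = as.integer(seed)),
            class = "sr_config")
}

random_terminal <- function(vars, config, p_const = 0.3) {
  if (stats::runif(1) < p_const) {
    const_node(stats::runif(1, config$const_range[1], config$const_range[2]))
  } else {
    var_node(sample(vars, 1))
  }
}

random_tree <- function(vars, config, depth, method = "grow") {
  if (depth <= 0 || (method == "grow" && stats::runif(1) < 0.3)) {
    return(random_terminal(vars, config))
  }
  op <- sample(config$primitives, 1)
  ar <- sr_primitives()[[op]]
  args <- lapply(seq_len(ar), function(i) {
    random_tree(vars, config, depth - 1L, method)
  })
  do.call(op_node, c(list(op), args))
}

mutate_tree <- function(tree, vars, config) {
  kind <- sample(names(config$mutation_weights), 1,
                 prob = config$mutation_weights)
  paths <- tree_paths(tree)
  p <- paths[[sample.int(length(paths), 1)]]
  switch(kind,
    subtree = replace_at(tree, p, random_tree(vars, config, 2L)),
    point = {
      node <- subtree_at(tree, p)
      if (is_op(node)) {
        ar <- sr_primitives()[[node$op]]
        alts <- setdiff(config$primitives[sr_primitives()[config$primitives] == ar],
                        node$op)
        if (length(alts)) node$op <- sample(alts, 1)
      } else if (is_var(node)) {
        node <- var_node(sample(vars, 1))
      } else {
        node <- const_node(stats::runif(1, config$const_range[1],
                                        config$const_range[2]))
      }
      replace_at(tree, p, node)
    },
    jitter = {
      cpaths <- Filter(function(q) is_const(subtree_at(tree, q)), paths)
      if (!length(cpaths)) return(mutate_point_fallback(tree, vars, config))
      q <- cpaths[[sample.int(length(cpaths), 1)]]
      node <- subtree_at(tree, q)
      node$const <- node$const + stats::rnorm(1, sd = 0.3 * (abs(node$const) + 0.5))
      replace_at(tree, q, node)
    },
    insert = {
      # wrap a subtree (often the root, to grow additive structure) in a
      # fresh binary node with a terminal sibling
      if (stats::runif(1) < 0.5) p <- integer(0)
      bin <- config$primitives[sr_primitives()[config$primitives] == 2L]
      if (!length(bin)) return(tree)
      op <- sample(bin, 1)
      s <- subtree_at(tree, p)
      term <- if (stats::runif(1) < 0.5) {
        random_terminal(vars, config, p_const = 0.3)
      } else {
        op_node("*", const_node(stats::runif(1, config$const_range[1],
                                             config$const_range[2])),
                var_node(sample(vars, 1)))
      }
      new <- if (stats::runif(1) < 0.5) {
        do.call(op_node, list(op, s, term))
      } else {
        do.call(op_node, list(op, term, s))
      }
      replace_at(tree, p, new)
    },
    hoist = {
      opaths <- Filter(function(q) is_op(subtree_at(tree, q)), paths)
      if (!length(opaths)) return(tree)
      q <- opaths[[sample.int(length(opaths), 1)]]
      node <- subtree_at(tree, q)
      keep <- node$args[[sample.int(length(node$args), 1)]]
      replace_at(tree, q, keep)
    })
}

mutate_point_fallback <- function(tree, vars, config) {
  paths <- tree_paths(tree)
  p <- paths[[sample.int(length(paths), 1)]]
  replace_at(tree, p, random_terminal(vars, config))
}

crossover_trees <- function(a, b) {
  pa <- tree_paths(a); pb <- tree_paths(b)
  replace_at(a, pa[[sample.int(length(pa), 1)]],
             subtree_at(b, pb[[sample.int(length(pb), 1)]]))
}

#' Refine the constants of an expression by local least squares
#'
#' Runs a Levenberg-Marquardt refinement (via \pkg{minpack.lm}) of all
#' constant terminals against the targets.  The refined tree is kept only
#' if its loss does not increase; on optimizer divergence the original
#' constants are retained and the result carries attribute
#' `constants_flagged = TRUE`.
#'
#' @param expr expression tree with at least one constant (constant-free
#'   trees are returned unchanged).
#' @param X variable table.
#' @param y targets.
#' @param max_iter maximum optimizer iterations.
#' @return the (possibly refined) expression tree.
#' @export
optimize_constants <- function(expr, X, y, max_iter = 50L) {
  theta0 <- collect_constants(expr)
  if (!length(theta0)) return(expr)
  resid_fn <- function(theta) {
    tr <- set_constants(expr, theta)$node
    ctx <- new.env(parent = emptyenv()); ctx$penalty <- FALSE
    v <- tryCatch(eval_tree(tr, X, ctx), error = function(e) NULL)
    if (is.null(v) || ctx$penalty || any(!is.finite(v))) {
      return(rep(1e6, length(y)))
    }
    rep_len(v, length(y)) - y
  }
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = max_iter, ptol = 1e-12, ftol = 1e-12))),
    error = function(e) NULL)
  loss0 <- sr_fitness(expr, X, y)
  if (!is.null(fit)) {
    cand <- set_constants(expr, fit$par)$node
    loss1 <- sr_fitness(cand, X, y)
    if (is.finite(loss1) && loss1 <= loss0) return(cand)
  }
  attr(expr, "constants_flagged") <- TRUE
  expr
}

# Memetic expansion: greedily extend an expression with an optimized
# additive term (c*v, or c*v*w in the second tier) and keep whatever
# improves the front.  Linear terms form their own tier so the fast lane
# prefers the simplest additive structure.
expand_candidates <- function(tree, vars, tier = c("linear", "product")) {
  tier <- match.arg(tier)
  out <- list()
  if (tier == "linear") {
    for (v in vars) {
      out[[length(out) + 1L]] <-
        op_node("+", tree, op_node("*", const_node(0), var_node(v)))
    }
  } else if (length(vars) <= 8) {
    for (i in seq_along(vars)) {
      for (j in i:length(vars)) {
        out[[length(out) + 1L]] <-
          op_node("+", tree,
                  op_node("*", const_node(0),
                          op_node("*", var_node(vars[i]), var_node(vars[j]))))
      }
    }
  }
  out
}

hof_to_front <- function(hof) {
  # prune to a strict Pareto front: increasing complexity, decreasing loss
  cx <- sort(as.integer(names(hof)))
  front <- list()
  best <- Inf
  for (c in cx) {
    e <- hof[[as.character(c)]]
    if (e$loss < best) {
      front[[length(front) + 1L]] <- e
      best <- e$loss
    }
  }
  front
}

#' Fit a Pareto front of symbolic expressions by genetic programming
#'
#' Evolves a seeded population of expression trees against mean-squared
#' error, maintaining the best expression at every complexity; new
#' per-complexity bests get their constants refined by local least squares.
#' Returns the non-dominated (complexity, loss) front.  Deterministic under
#' a fixed `config$seed`.
#'
#' @param X data.frame of named predictor columns (no missing values).
#' @param y numeric targets (length >= 10).
#' @param config an [sr_config()].
#' @return object of class `sr_pareto`: a list with `front` (list of
#'   `list(complexity, loss, tree)`), `config`, and `variables`.
#' @export
sr_fit <- function(X, y, config = sr_config()) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y))
  if (length(y) < 10) stop("need at least 10 samples")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  vars <- colnames(X)
  if (stats::sd(y) == 0) {
    tree <- const_node(mean(y))
    front <- list(list(complexity = 1L, loss = 0, tree = tree))
    return(structure(list(front = front, config = config, variables = vars),
                     class = "sr_pareto"))
  }
  hof <- list()  # per-complexity best, keyed by complexity
  update_hof <- function(tree, loss) {
    if (!is.finite(loss)) return(FALSE)
    # simplification is only worth its cost for candidates that improve
    # their own complexity slot (it can only shrink the tree further)
    key <- as.character(tree_complexity(tree))
    cur <- hof[[key]]
    if (!is.null(cur) && loss >= cur$loss) return(FALSE)
    tree <- simplify_tree(tree)
    key <- as.character(tree_complexity(tree))
    cur <- hof[[key]]
    if (is.null(cur) || loss < cur$loss) {
      hof[[key]] <<- list(complexity = as.integer(key), loss = loss,
                          tree = tree)
      return(TRUE)
    }
    FALSE
  }
  with_seed(config$seed, {
    pop <- lapply(seq_len(config$population), function(i) {
      random_tree(vars, config, depth = 1L + (i %% 3L),
                  method = if (i %% 2L) "grow" else "full")
    })
    fitness <- vapply(pop, function(tr) sr_fitness(tr, X, y), numeric(1))
    for (i in seq_along(pop)) update_hof(pop[[i]], fitness[i])
    stop_at <- Inf
    for (gen in seq_len(config$generations)) {
      # refine constants of current front members
      if (config$optimize_constants) {
        for (key in names(hof)) {
          e <- hof[[key]]
          if (isTRUE(e$optimized)) next
          tr <- optimize_constants(e$tree, X, y)
          l <- sr_fitness(tr, X, y)
          if (l < e$loss) {
            hof[[key]] <- list(complexity = e$complexity, loss = l, tree = tr,
                               optimized = TRUE)
          } else {
            hof[[key]]$optimized <- TRUE
          }
        }
      }
      front <- hof_to_front(hof)
      losses <- vapply(front, function(e) e$loss, numeric(1))
      best_loss <- min(losses)
      if (config$optimize_constants && best_loss > config$early_stop_loss &&
          gen %% 3L == 1L &&
          all(c("+", "*") %in% config$primitives)) {
        # chained greedy expansion of the most promising members: keep
        # adding the best least-squares-refined additive term while it
        # strictly improves, feeding every candidate back into the front
        seeds <- list(front[[which.min(losses)]]$tree)
        if (gen == 1L) seeds <- c(seeds, list(const_node(mean(y))))
        for (base in seeds) {
          tree <- base
          loss <- sr_fitness(tree, X, y)
          repeat {
            step <- NULL
            for (tier in c("linear", "product")) {
              best_cand <- NULL
              best_cl <- loss
              for (cand in expand_candidates(tree, vars, tier)) {
                if (tree_complexity(cand) > config$max_complexity) next
                cand <- optimize_constants(cand, X, y, max_iter = 30L)
                cl <- sr_fitness(cand, X, y)
                update_hof(cand, cl)
                if (cl < best_cl) {
                  best_cand <- cand
                  best_cl <- cl
                }
              }
              if (!is.null(best_cand) && best_cl < loss * 0.99) {
                step <- list(tree = best_cand, loss = best_cl)
                break  # a simpler-tier term improved; skip the next tier
              }
            }
            if (is.null(step)) break
            tree <- step$tree
            loss <- step$loss
            if (loss <= config$early_stop_loss) break
          }
        }
        front <- hof_to_front(hof)
        best_loss <- min(vapply(front, function(e) e$loss, numeric(1)))
      }
      if (best_loss <= config$early_stop_loss && !is.finite(stop_at)) {
        stop_at <- gen + config$patience
      }
      if (gen >= stop_at) break
      elites <- lapply(front, function(e) e$tree)
      n_off <- config$population - length(elites)
      tourn <- function() {
        idx <- sample.int(length(pop), config$tournament, replace = TRUE)
        pop[[idx[which.min(fitness[idx])]]]
      }
      offspring <- vector("list", n_off)
      for (i in seq_len(n_off)) {
        child <- if (stats::runif(1) < config$p_crossover) {
          crossover_trees(tourn(), tourn())
        } else {
          mutate_tree(tourn(), vars, config)
        }
        if (tree_complexity(child) > config$max_complexity) child <- tourn()
        offspring[[i]] <- child
      }
      pop <- c(elites, offspring)
      fitness <- vapply(pop, function(tr) sr_fitness(tr, X, y), numeric(1))
      for (i in seq_along(pop)) update_hof(pop[[i]], fitness[i])
    }
    if (config$optimize_constants) {
      for (key in names(hof)) {
        e <- hof[[key]]
        if (isTRUE(e$optimized)) next
        tr <- optimize_constants(e$tree, X, y)
        l <- sr_fitness(tr, X, y)
        if (l < e$loss) {
          hof[[key]] <- list(complexity = e$complexity, loss = l, tree = tr)
        }
      }
    }
  })
  front <- hof_to_front(hof)
  front <- lapply(front, function(e) e[c("complexity", "loss", "tree")])
  structure(list(front = front, config = config, variables = vars),
            class = "sr_pareto")
}

#' @export
print.sr_pareto <- function(x, digits = 3, ...) {
  cat("Pareto front (", length(x$front), " expressions)\n", sep = "")
  for (e in x$front) {
    cat(sprintf("  complexity %2d  loss %.4g  %s\n", e$complexity, e$loss,
                to_canonical_string(e$tree, digits)))
  }
  invisible(x)
}

#' @export
as.data.frame.sr_pareto <- function(x, ...) {
  data.frame(
    complexity = vapply(x$front, function(e) e$complexity, integer(1)),
    loss = vapply(x$front, function(e) e$loss, numeric(1)),
    expression = vapply(x$front, function(e) to_canonical_string(e$tree),
                        character(1)))
}

#' Parsimony-based equation selection from a Pareto front
#'
#' Returns the minimum-complexity front member whose loss is within a
#' relative tolerance `delta` of the front's best loss (with a small
#' absolute floor so numerically-zero losses compare as equal); ties are
#' broken by lower loss.
#'
#' @param front an `sr_pareto` (or plain list of
#'   `list(complexity, loss, tree)`).
#' @param delta relative parsimony tolerance (default: the fitted
#'   config's, else 0.01).
#' @return the selected expression tree, with attributes `complexity` and
#'   `loss`.
#' @export
sr_select <- function(front, delta = NULL) {
  members <- if (inherits(front, "sr_pareto")) front$front else front
  if (!length(members)) stop("empty Pareto front")
  if (is.null(delta)) {
    delta <- if (inherits(front, "sr_pareto")) {
      front$config$parsimony_delta
    } else 0.01
  }
  loss <- vapply(members, function(e) e$loss, numeric(1))
  cx <- vapply(members, function(e) as.integer(e$complexity), integer(1))
  best <- min(loss)
  ok <- loss <= best * (1 + delta) + 1e-12
  cand <- which(ok)
  sel <- cand[order(cx[cand], loss[cand])][1]
  out <- members[[sel]]$tree
  attr(out, "complexity") <- cx[sel]
  attr(out, "loss") <- loss[sel]
  out
}
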