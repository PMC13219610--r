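## Genetic-programming symbolic regression over {+, -, *, protected /} with
## descriptor leaves and ephemeral constants.  Fitness = RMSE + lambda_c *
## node count; generational evolution with tournament selection, subtree
## crossover/mutation, strict depth/node caps and elitism; numeric constants
## of the final best expression are refit by least squares.

PDIV_EPS <- 1e-6   # protected division: x/y == 1 when |y| <= PDIV_EPS

sr_var <- function(index, name) list(type = "var", index = index, name = name)
sr_const <- function(value) list(type = "const", value = value)
sr_op <- function(op, left, right) list(type = "op", op = op, left = left,
                                        right = right)

#' Symbolic-regression configuration
#'
#' @param population population size.
#' @param generations number of generations.
#' @param tournament tournament size.
#' @param p_crossover,p_mutation genetic operator probabilities.
#' @param lambda_c parsimony weight on node count.
#' @param max_depth,max_nodes complexity caps on every individual.
#' @param const_range range for ephemeral random constants.
#' @param seed integer seed.
#' @return object of class `sr_config`.
#' @export
sr_config <- function(population = 500, generations = 40, tournament = 5,
                      p_crossover = 0.9, p_mutation = 0.15, lambda_c = 0.005,
                      max_depth = 6, max_nodes = 25, const_range = c(-2, 2),
                      seed = 1L) {
  stopifnot(population >= 2, generations >= 1,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1, lambda_c >= 0)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 tournament = as.integer(tournament),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 lambda_c = lambda_c, max_depth = as.integer(max_depth),
                 max_nodes = as.integer(max_nodes), const_range = const_range,
                 seed = as.integer(seed)),
            class = "sr_config")
}

#' Evaluate an expression tree on a descriptor matrix
#'
#' Vectorized recursive evaluation; division is protected (`x / y` is 1 when
#' `|y| <= 1e-6`), so output is finite for any finite input.
#'
#' @param expr an expression tree (as produced by [sr_evolve()]).
#' @param X numeric matrix with named columns.
#' @return numeric vector of length `nrow(X)`.
#' @export
sr_evaluate <- function(expr, X) {
  X <- if (inherits(X, "compound_table")) X$X else as.matrix(X)
  ev <- function(node) {
    switch(node$type,
      const = rep(node$value, nrow(X)),
      var = {
        if (node$index > ncol(X) ||
            !identical(colnames(X)[node$index], node$name))
          stop_tox("expression references unknown column '%s'", node$name)
        X[, node$index]
      },
      op = {
        l <- ev(node$left); r <- ev(node$right)
        switch(node$op,
               "+" = l + r, "-" = l - r, "*" = l * r,
               "/" = ifelse(abs(r) > PDIV_EPS, l / r, 1))
      })
  }
  ev(expr)
}

#' Node count and depth of an expression tree
#'
#' @param expr expression tree.
#' @return list with `nodes` and `depth` (a single leaf has nodes 1, depth 1).
#' @export
sr_complexity <- function(expr) {
  walk <- function(node) {
    if (node$type != "op") return(c(1L, 1L))
    l <- walk(node$left); r <- walk(node$right)
    c(1L + l[1] + r[1], 1L + max(l[2], r[2]))
  }
  w <- walk(expr)
  list(nodes = w[1], depth = w[2])
}

#' Pretty-print an expression tree as infix
#'
#' @param expr expression tree.
#' @param digits significant digits for constants.
#' @return character scalar.
#' @export
sr_format <- function(expr, digits = 4) {
  fmt <- function(node) {
    switch(node$type,
           const = sprintf("%.*g", digits, node$value),
           var = node$name,
           op = sprintf("(%s %s %s)", fmt(node$left), node$op,
                        fmt(node$right)))
  }
  fmt(expr)
}

## ---- internal GP machinery ------------------------------------------------

sr_random_tree <- function(depth_left, vars, const_range, full = FALSE) {
  if (depth_left <= 1 || (!full && runif(1) < 0.3)) {
    if (runif(1) < 0.75) {
      j <- sample.int(length(vars), 1)
      sr_var(j, vars[j])
    } else sr_const(runif(1, const_range[1], const_range[2]))
  } else {
    op <- sample(c("+", "-", "*", "/"), 1, prob = c(0.3, 0.3, 0.3, 0.1))
    sr_op(op, sr_random_tree(depth_left - 1, vars, const_range, full),
          sr_random_tree(depth_left - 1, vars, const_range, full))
  }
}

sr_paths <- function(expr) {
  out <- list(integer(0))
  if (expr$type == "op") {
    for (p in sr_paths(expr$left)) out <- c(out, list(c(1L, p)))
    for (p in sr_paths(expr$right)) out <- c(out, list(c(2L, p)))
  }
  out
}

sr_get <- function(expr, path) {
  for (s in path) expr <- if (s == 1L) expr$left else expr$right
  expr
}

sr_set <- function(expr, path, sub) {
  if (!length(path)) return(sub)
  slot <- if (path[1] == 1L) "left" else "right"
  expr[[slot]] <- sr_set(expr[[slot]], path[-1], sub)
  expr
}

sr_within_caps <- function(expr, config) {
  cx <- sr_complexity(expr)
  cx$nodes <= config$max_nodes && cx$depth <= config$max_depth
}

sr_rmse <- function(expr, X, y) {
  pred <- sr_evaluate(expr, X)
  sqrt(mean((y - pred)^2))
}

## least-squares linear scaling (a + b * pred): evaluates the *structure* of
## a candidate, leaving the affine calibration to closed-form regression
sr_scaling <- function(expr, X, y) {
  pred <- sr_evaluate(expr, X)
  vp <- var(pred)
  if (!is.finite(vp) || vp < 1e-12) return(list(a = mean(y), b = 0,
                                                rmse = sd(y) * sqrt((length(y) - 1) / length(y))))
  b <- cov(y, pred) / vp
  a <- mean(y) - b * mean(pred)
  list(a = a, b = b, rmse = sqrt(mean((y - a - b * pred)^2)))
}

sr_fitness <- function(expr, X, y, lambda_c) {
  sr_scaling(expr, X, y)$rmse + lambda_c * sr_complexity(expr)$nodes
}

## wrap an expression in its optimal affine scaling (skipped when immaterial,
## simplified when the scaling degenerates to a constant)
sr_apply_scaling <- function(expr, X, y) {
  sc <- sr_scaling(expr, X, y)
  if (abs(sc$b - 1) < 1e-9 && abs(sc$a) < 1e-9) return(expr)
  if (sc$b == 0) return(sr_const(sc$a))
  if (expr$type == "const") return(sr_const(sc$a + sc$b * expr$value))
  sr_op("+", sr_const(sc$a), sr_op("*", sr_const(sc$b), expr))
}

## least-squares refit of every numeric constant in a tree
sr_refit_constants <- function(expr, X, y, maxit = 200, scaled = FALSE) {
  paths <- Filter(function(p) sr_get(expr, p)$type == "const",
                  sr_paths(expr))
  if (!length(paths)) return(expr)
  pack <- function(e, vals) {
    for (i in seq_along(paths)) e <- sr_set(e, paths[[i]], sr_const(vals[i]))
    e
  }
  init <- vapply(paths, function(p) sr_get(expr, p)$value, 0)
  fn <- function(v) {
    e <- pack(expr, v)
    r <- if (scaled) sr_scaling(e, X, y)$rmse else sr_rmse(e, X, y)
    if (!is.finite(r)) 1e9 else r
  }
  fit <- tryCatch(optim(init, fn, method = "BFGS",
                        control = list(maxit = maxit)),
                  error = function(e) NULL)
  if (is.null(fit)) fit <- optim(init, fn, method = "Nelder-Mead",
                                 control = list(maxit = maxit * 4))
  pack(expr, fit$par)
}

#' Evolve a closed-form descriptor-to-response expression
#'
#' Generational genetic programming with elitism (the best individual is never
#' lost), tournament selection, subtree crossover and mutation under strict
#' depth/node caps, minimizing `RMSE + lambda_c * nodes`.  Fitness uses
#' least-squares linear scaling (each candidate is affinely calibrated in
#' closed form before scoring), so evolution concentrates on structure; a
#' linear-term insertion mutation biases the search toward the affine forms
#' expected of descriptor/response relationships.  After the final generation
#' the scaling is materialized into the expression and every numeric constant
#' (best individual and hall-of-fame members) is refit by least squares.
#' The returned expression can therefore carry up to 4 nodes beyond
#' `max_nodes` (the affine wrapper); population individuals always respect
#' the caps.
#'
#' @param X matrix or [compound_table()] (n >= 20).
#' @param y response (from the table when omitted).
#' @param config an [sr_config()].
#' @return list of class `sr_model`: `best` (expression), `best_rmse`,
#'   `best_fitness`, `hall_of_fame` (Pareto shortlist by nodes/RMSE),
#'   `fitness_trace`.
#' @export
sr_evolve <- function(X, y = NULL, config = sr_config()) {
  if (inherits(X, "compound_table")) { if (is.null(y)) y <- X$y; X <- X$X }
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) < 20) stop_tox("sr_evolve requires n >= 20")
  vars <- colnames(X)
  lam <- config$lambda_c

  with_seed(config$seed, {
    npop <- config$population
    pop <- vector("list", npop)
    depths <- rep(2:4, length.out = npop)
    for (i in seq_len(npop)) {
      repeat {
        cand <- sr_random_tree(depths[i], vars, config$const_range,
                               full = i %% 2 == 0)
        if (sr_within_caps(cand, config)) break
      }
      pop[[i]] <- cand
    }
    fit_all <- function(pp) vapply(pp, function(e) sr_fitness(e, X, y, lam), 0)
    fit <- fit_all(pop)

    tournament <- function() {
      cand <- sample.int(npop, config$tournament, replace = TRUE)
      cand[which.min(fit[cand])]
    }

    best_i <- which.min(fit)
    best <- pop[[best_i]]; best_fit <- fit[best_i]
    trace <- numeric(config$generations)

    for (g in seq_len(config$generations)) {
      newpop <- vector("list", npop)
      newpop[[1]] <- best                       # elitism
      for (i in 2:npop) {
        child <- pop[[tournament()]]
        if (runif(1) < config$p_crossover) {
          donor <- pop[[tournament()]]
          cand <- sr_set(child,
                         sr_paths(child)[[sample.int(length(sr_paths(child)), 1)]],
                         sr_get(donor,
                                sr_paths(donor)[[sample.int(length(sr_paths(donor)), 1)]]))
          if (sr_within_caps(cand, config)) child <- cand
        }
        if (runif(1) < config$p_mutation) {
          cand <- if (runif(1) < 0.6) {
            # subtree mutation
            sr_set(child,
                   sr_paths(child)[[sample.int(length(sr_paths(child)), 1)]],
                   sr_random_tree(3, vars, config$const_range))
          } else {
            # linear-term insertion: child + c * var, with c set by a
            # closed-form two-predictor regression (forward-selection step)
            j <- sample.int(length(vars), 1)
            cj <- tryCatch({
              Z <- cbind(1, sr_evaluate(child, X), X[, j])
              co <- solve(crossprod(Z), crossprod(Z, y))
              if (abs(co[2]) > 1e-8) co[3] / co[2] else NA_real_
            }, error = function(e) NA_real_)
            if (!is.finite(cj))
              cj <- runif(1, config$const_range[1], config$const_range[2])
            sr_op("+", child, sr_op("*", sr_const(cj), sr_var(j, vars[j])))
          }
          if (sr_within_caps(cand, config)) child <- cand
        }
        if (runif(1) < 0.1) {   # constant jitter
          cps <- Filter(function(p) sr_get(child, p)$type == "const",
                        sr_paths(child))
          for (p in cps)
            child <- sr_set(child, p,
                            sr_const(sr_get(child, p)$value + rnorm(1, 0, 0.1)))
        }
        newpop[[i]] <- child
      }
      pop <- newpop
      fit <- fit_all(pop)
      gi <- which.min(fit)
      if (fit[gi] < best_fit) { best <- pop[[gi]]; best_fit <- fit[gi] }
      # periodic light constant refit of the generation's elite (under the
      # same scaled-fitness criterion)
      if (g %% 5 == 0) {
        refit <- sr_refit_constants(best, X, y, maxit = 50, scaled = TRUE)
        rf <- sr_fitness(refit, X, y, lam)
        if (rf < best_fit) { best <- refit; best_fit <- rf }
      }
      trace[g] <- best_fit
      pop[[1]] <- best; fit[1] <- best_fit
    }

    # hall of fame: Pareto front over (nodes, rmse), from the final population
    cand <- c(list(best), pop)
    nodes <- vapply(cand, function(e) sr_complexity(e)$nodes, 0L)
    rmses <- vapply(cand, function(e) sr_scaling(e, X, y)$rmse, 0)
    hof <- list()
    for (nn in sort(unique(nodes))) {
      i <- which(nodes == nn)[which.min(rmses[nodes == nn])]
      if (!length(hof) || rmses[i] < min(vapply(hof, `[[`, 0, "rmse")))
        hof <- c(hof, list(list(expr = cand[[i]], nodes = nn,
                                rmse = rmses[i])))
    }

    # materialize the affine scaling, then least-squares refit of every
    # constant (best + hall of fame); the deliverable is a plain expression
    final_fit <- function(e) sr_rmse(e, X, y) +
      lam * sr_complexity(e)$nodes
    finals <- lapply(c(list(best), lapply(hof, `[[`, "expr")), function(e)
      sr_refit_constants(sr_apply_scaling(e, X, y), X, y))
    finals <- c(finals, list(sr_const(mean(y))))  # parsimony-limit guard
    ff <- vapply(finals, final_fit, 0)
    best <- finals[[which.min(ff)]]

    structure(list(best = best, best_rmse = sr_rmse(best, X, y),
                   best_fitness = min(ff), hall_of_fame = hof,
                   fitness_trace = trace, config = config,
                   feature_names = vars),
              class = "sr_model")
  })
}

#' @export
print.sr_model <- function(x, ...) {
  cat(sprintf("<sr_model> best (RMSE %.4f, fitness %.4f):\n  %s\n",
              x$best_rmse, x$best_fitness, sr_format(x$best)))
  invisible(x)
}

#' Predict from an evolved symbolic model
#'
#' @param object an `sr_model`.
#' @param newdata matrix or [compound_table()].
#' @param ... unused.
#' @export
predict.sr_model <- function(object, newdata, ...) {
  sr_evaluate(object$best, newdata)
}

#' Serialize an expression to prefix notation
#'
#' @param expr expression tree.
#' @return character scalar, e.g. `"(+ (* 0.42 LogP) C)"`.
#' @export
sr_prefix <- function(expr) {
  switch(expr$type,
         const = sprintf("%.12g", expr$value),
         var = expr$name,
         op = sprintf("(%s %s %s)", expr$op, sr_prefix(expr$left),
                      sr_prefix(expr$right)))
}
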