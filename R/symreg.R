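#' Operator set for symbolic regression
#'
#' @param unary unary operator names; default `{sin, cos, ln, exp}`.
#' @param binary binary operator names; default `{+, -, /, *}`.
#' @return A list of class `operator_set`.
#' @export
operator_set <- function(unary = c("sin", "cos", "ln", "exp"),
                         binary = c("+", "-", "/", "*")) {
  known_un <- c("sin", "cos", "ln", "exp")
  known_bin <- c("+", "-", "/", "*")
  if (!all(unary %in% known_un)) stop("unknown unary operator", call. = FALSE)
  if (!all(binary %in% known_bin)) stop("unknown binary operator", call. = FALSE)
  structure(list(unary = unary, binary = binary), class = "operator_set")
}

#' Search configuration for genetic-programming symbolic regression
#'
#' @param population individuals per generation (default 400).
#' @param generations evolutionary iterations (default 30).
#' @param max_size maximum expression size in nodes (default 30).
#' @param parsimony relative complexity penalty: selection fitness is
#'   `mse * (1 + parsimony * size)` (default 1e-3).
#' @param tournament_size tournament size for parent selection.
#' @param crossover_prob probability a child is produced by subtree
#'   crossover rather than mutation alone.
#' @param const_opt refine constants of leading individuals by local
#'   optimization each generation (default TRUE).
#' @param const_restarts random restarts per constant optimization; restarts
#'   draw fresh constants so oscillation frequencies can escape local
#'   minima of the least-squares surface.
#' @param seed integer seed; the search is deterministic given it.
#' @param selection_mse_factor model-selection rule: among front members
#'   with `mse <= factor * best_mse`, pick the lowest complexity (default
#'   1.5).
#' @return A list of class `sr_config`.
#' @export
sr_config <- function(population = 400, generations = 30, max_size = 30,
                      parsimony = 1e-3, tournament_size = 3,
                      crossover_prob = 0.7, const_opt = TRUE,
                      const_restarts = 3, seed = 1L,
                      selection_mse_factor = 1.5) {
  if (population <= 0 || generations <= 0 || max_size <= 0)
    stop("population, generations and max_size must be positive",
         call. = FALSE)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 max_size = as.integer(max_size), parsimony = parsimony,
                 tournament_size = as.integer(tournament_size),
                 crossover_prob = crossover_prob, const_opt = const_opt,
                 const_restarts = as.integer(const_restarts),
                 seed = as.integer(seed),
                 selection_mse_factor = selection_mse_factor),
            class = "sr_config")
}

## ---- expression trees -------------------------------------------------

sr_const <- function(value) list(type = "const", value = value)
sr_var <- function(name) list(type = "var", name = name)
sr_un <- function(op, a) list(type = "un", op = op, a = a)
sr_bin <- function(op, l, r) list(type = "bin", op = op, l = l, r = r)

#' Size (node count) of an expression tree
#' @param expr an expression tree.
#' @return Integer node count.
#' @export
expr_size <- function(expr) {
  switch(expr$type,
         const = 1L, var = 1L,
         un = 1L + expr_size(expr$a),
         bin = 1L + expr_size(expr$l) + expr_size(expr$r))
}

#' Evaluate an expression tree on an input matrix
#'
#' Numerical evaluation with protected operators: `ln` takes the log of the
#' absolute value floored at 1e-9, division floors the denominator
#' magnitude at 1e-9, and `exp` caps its argument at 50. With
#' `protected = FALSE` domain violations produce `NaN` instead (and can be
#' detected by the caller).
#'
#' @param expr an expression tree (or an infix string, parsed first).
#' @param X matrix or data frame whose column names cover the tree's
#'   variables.
#' @param protected use guarded operators (default TRUE).
#' @return Numeric vector, one value per row of `X`.
#' @export
evaluate_expression <- function(expr, X, protected = TRUE) {
  if (is.character(expr)) expr <- parse_expression(expr)
  X <- as.data.frame(X)
  n <- nrow(X)
  ev <- function(node) {
    switch(node$type,
      const = rep(node$value, n),
      var = {
        if (is.null(X[[node$name]]))
          stop("variable not in input: ", node$name, call. = FALSE)
        X[[node$name]]
      },
      un = {
        v <- ev(node$a)
        switch(node$op,
               sin = sin(v), cos = cos(v),
               ln = if (protected) log(pmax(abs(v), 1e-9)) else log(v),
               exp = if (protected) exp(pmin(v, 50)) else exp(v))
      },
      bin = {
        l <- ev(node$l); r <- ev(node$r)
        switch(node$op,
               `+` = l + r, `-` = l - r, `*` = l * r,
               `/` = if (protected) {
                 l / (sign(r + (r == 0)) * pmax(abs(r), 1e-9))
               } else l / r)
      })
  }
  ev(expr)
}

#' Render an expression tree as an infix string
#' @param expr an expression tree.
#' @param digits significant digits for constants.
#' @return A string that [parse_expression()] round-trips.
#' @export
expression_to_string <- function(expr, digits = 6) {
  switch(expr$type,
         const = format(expr$value, digits = digits),
         var = expr$name,
         un = paste0(expr$op, "(", expression_to_string(expr$a, digits), ")"),
         bin = paste0("(", expression_to_string(expr$l, digits), " ",
                      expr$op, " ", expression_to_string(expr$r, digits),
                      ")"))
}

#' Parse an infix string into an expression tree
#'
#' Accepts the operator vocabulary of [operator_set()] (with `ln` or `log`
#' for the natural logarithm) plus numeric literals and variable names;
#' unary minus is folded into constants or rewritten as `0 - x`.
#'
#' @param text an infix expression string.
#' @return An expression tree.
#' @export
parse_expression <- function(text) {
  lang_to_tree <- function(e) {
    if (is.numeric(e)) return(sr_const(as.numeric(e)))
    if (is.name(e)) return(sr_var(as.character(e)))
    if (!is.call(e)) stop("cannot parse expression element", call. = FALSE)
    op <- as.character(e[[1]])
    args <- as.list(e)[-1]
    if (op == "(") return(lang_to_tree(args[[1]]))
    if (op == "-" && length(args) == 1) {
      inner <- lang_to_tree(args[[1]])
      if (inner$type == "const") return(sr_const(-inner$value))
      return(sr_bin("-", sr_const(0), inner))
    }
    if (op == "+" && length(args) == 1) return(lang_to_tree(args[[1]]))
    if (op %in% c("+", "-", "*", "/"))
      return(sr_bin(op, lang_to_tree(args[[1]]), lang_to_tree(args[[2]])))
    if (op %in% c("sin", "cos", "exp"))
      return(sr_un(op, lang_to_tree(args[[1]])))
    if (op %in% c("ln", "log"))
      return(sr_un("ln", lang_to_tree(args[[1]])))
    stop("unsupported operator in expression: ", op, call. = FALSE)
  }
  lang_to_tree(str2lang(text))
}

## ---- random trees and genetic operators --------------------------------

random_tree <- function(depth, vars, ops, p_leaf_const = 0.4) {
  if (depth <= 0 || (depth < 2 && stats::runif(1) < 0.3)) {
    if (stats::runif(1) < p_leaf_const) {
      return(sr_const(round(stats::rnorm(1, 0, 2), 3)))
    }
    return(sr_var(sample(vars, 1)))
  }
  if (stats::runif(1) < 0.35 && length(ops$unary) > 0) {
    sr_un(sample(ops$unary, 1), random_tree(depth - 1, vars, ops))
  } else {
    sr_bin(sample(ops$binary, 1),
           random_tree(depth - 1, vars, ops),
           random_tree(depth - 1, vars, ops))
  }
}

# Flatten node positions for uniform random access; returns the subtree at
# 1-based index `k` in preorder, or replaces it.
get_subtree <- function(expr, k) {
  env <- new.env(); env$i <- 0L; env$found <- NULL
  walk <- function(node) {
    if (!is.null(env$found)) return()
    env$i <- env$i + 1L
    if (env$i == k) { env$found <- node; return() }
    if (node$type == "un") walk(node$a)
    else if (node$type == "bin") { walk(node$l); walk(node$r) }
  }
  walk(expr)
  env$found
}

set_subtree <- function(expr, k, replacement) {
  env <- new.env(); env$i <- 0L
  walk <- function(node) {
    env$i <- env$i + 1L
    if (env$i == k) return(replacement)
    if (node$type == "un") {
      node$a <- walk(node$a)
    } else if (node$type == "bin") {
      node$l <- walk(node$l)
      if (env$i < k) node$r <- walk(node$r)
    }
    node
  }
  walk(expr)
}

crossover_trees <- function(t1, t2) {
  k1 <- sample(expr_size(t1), 1)
  k2 <- sample(expr_size(t2), 1)
  set_subtree(t1, k1, get_subtree(t2, k2))
}

mutate_tree <- function(expr, vars, ops) {
  kind <- sample(c("point", "subtree", "hoist", "insert_un", "const"),
                 1, prob = c(0.3, 0.25, 0.15, 0.15, 0.15))
  n <- expr_size(expr)
  k <- sample(n, 1)
  node <- get_subtree(expr, k)
  repl <- switch(kind,
    point = {
      if (node$type == "bin") { node$op <- sample(ops$binary, 1); node }
      else if (node$type == "un") { node$op <- sample(ops$unary, 1); node }
      else if (node$type == "const") sr_const(node$value + stats::rnorm(1, 0, 0.5))
      else sr_var(sample(vars, 1))
    },
    subtree = random_tree(sample(1:3, 1), vars, ops),
    hoist = {
      if (node$type == "un") node$a
      else if (node$type == "bin") {
        if (stats::runif(1) < 0.5) node$l else node$r
      } else node
    },
    insert_un = sr_un(sample(ops$unary, 1), node),
    const = {
      if (node$type == "const") {
        sr_const(node$value * exp(stats::rnorm(1, 0, 0.3)) +
                   stats::rnorm(1, 0, 0.05))
      } else sr_bin(sample(c("*", "+"), 1), sr_const(round(
        stats::rnorm(1, 1, 1), 3)), node)
    })
  set_subtree(expr, k, repl)
}

## ---- constants refinement ----------------------------------------------

collect_constants <- function(expr) {
  switch(expr$type,
         const = expr$value,
         var = numeric(0),
         un = collect_constants(expr$a),
         bin = c(collect_constants(expr$l), collect_constants(expr$r)))
}

set_constants <- function(expr, values) {
  env <- new.env(); env$i <- 0L
  walk <- function(node) {
    switch(node$type,
           const = { env$i <- env$i + 1L; node$value <- values[env$i]; node },
           var = node,
           un = { node$a <- walk(node$a); node },
           bin = { node$l <- walk(node$l); node$r <- walk(node$r); node })
  }
  walk(expr)
}

expr_mse <- function(expr, X, y) {
  v <- evaluate_expression(expr, X)
  if (any(!is.finite(v))) return(Inf)
  mean((v - y)^2)
}

# Structure signature: the expression string with constant values masked,
# used to recognize when a structurally new candidate first appears.
expr_signature <- function(expr) {
  walk <- function(node) {
    switch(node$type,
           const = "C",
           var = node$name,
           un = paste0(node$op, "(", walk(node$a), ")"),
           bin = paste0("(", walk(node$l), node$op, walk(node$r), ")"))
  }
  walk(expr)
}

# Nelder-Mead refinement of the tree's constants, with random restarts so
# multimodal coordinates (e.g. oscillation frequencies) can reach the
# global basin. Restarts alternate between redrawing all constants and
# redrawing a single one (keeping the rest at their current values), the
# latter being far more effective when only one coordinate — typically a
# frequency — is in the wrong basin.
optimize_constants <- function(expr, X, y, restarts = 3, maxit = 200) {
  cs <- collect_constants(expr)
  if (length(cs) == 0) return(expr)
  obj <- function(v) {
    m <- expr_mse(set_constants(expr, v), X, y)
    if (!is.finite(m)) 1e10 else m
  }
  starts <- c(list(cs),
              lapply(seq_len(restarts), function(i) {
                if (i %% 2 == 1 && length(cs) > 1) {
                  v <- cs
                  v[sample(length(cs), 1)] <- stats::rnorm(1, 0, 5)
                  v
                } else {
                  stats::rnorm(length(cs), 0, 5)
                }
              }))
  best_v <- cs; best_m <- obj(cs)
  for (v0 in starts) {
    fit <- tryCatch(
      stats::optim(v0, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value < best_m) {
      best_m <- fit$value; best_v <- fit$par
    }
  }
  set_constants(expr, best_v)
}

# Systematic library of small seeded structures alpha * u1(c * u2(v)) +
# gamma over every variable and unary pair (u2 may be the identity).
# Seeding the population with all two-level compositions of the operator
# vocabulary gives the evolution cheap access to motifs (e.g. an
# oscillation in the logarithm of one input) that are rare under purely
# random tree growth. The outer scale and offset start at the target's SD
# and mean, so refinement only has to find the inner constant's basin.
template_population <- function(vars, ops, y = NULL) {
  amp <- if (is.null(y)) 1 else max(stats::sd(y), 1e-3)
  off <- if (is.null(y)) 0 else mean(y)
  out <- list()
  for (v in vars) {
    for (u1 in ops$unary) {
      for (u2 in c("id", ops$unary)) {
        inner_v <- if (u2 == "id") sr_var(v) else sr_un(u2, sr_var(v))
        arg <- sr_bin("*", sr_const(round(stats::rnorm(1, 0, 2), 3)), inner_v)
        tree <- sr_bin("+",
                       sr_bin("*", sr_const(sample(c(-1, 1), 1) * amp),
                              sr_un(u1, arg)),
                       sr_const(off))
        out[[length(out) + 1L]] <- tree
      }
    }
  }
  out
}

## ---- the search --------------------------------------------------------

#' Fit a symbolic expression to input/output pairs
#'
#' Genetic-programming search over the operator vocabulary: tournament
#' selection, subtree crossover, point/subtree/hoist/unary-insertion and
#' constant mutations, elitism, and per-generation constant refinement of
#' the leading individuals. A hall of fame keeps the best expression at
#' each complexity (a Pareto-style front over fit and size); the selected
#' model is the simplest front member whose MSE is within
#' `selection_mse_factor` of the best.
#'
#' @param io_pairs data frame of inputs plus a target column named
#'   `a4_hat` (as produced by [export_io_pairs()]), or a plain input matrix
#'   if `y` is given separately.
#' @param y optional target vector when `io_pairs` holds only inputs.
#' @param operators an [operator_set()].
#' @param config an [sr_config()].
#' @param warm_start optional previous `sr_fit`; its front seeds the
#'   initial population (used to continue a search with a larger budget).
#' @return A list of class `sr_fit` with `front` (data frame: complexity,
#'   mse, expression, selected), `trees` (front expression trees), `best`
#'   (the selected tree) and `config`.
#' @export
fit_symbolic <- function(io_pairs, y = NULL, operators = operator_set(),
                         config = sr_config(), warm_start = NULL) {
  io_pairs <- as.data.frame(io_pairs)
  if (is.null(y)) {
    if (is.null(io_pairs$a4_hat))
      stop("io_pairs must contain an a4_hat target column", call. = FALSE)
    y <- io_pairs$a4_hat
    X <- io_pairs[setdiff(names(io_pairs), "a4_hat")]
  } else {
    X <- io_pairs
  }
  if (nrow(X) < 10) stop("need at least 10 input/output pairs", call. = FALSE)
  vars <- names(X)
  set.seed(config$seed)

  pen <- function(mse, size) mse * (1 + config$parsimony * size)

  pop <- lapply(seq_len(config$population), function(i)
    random_tree(sample(2:4, 1), vars, operators))
  templates <- template_population(vars, operators, y)
  if (config$const_opt)
    templates <- lapply(templates, function(tree)
      optimize_constants(tree, X, y, restarts = 5, maxit = 120))
  slots <- seq_len(min(length(templates), length(pop)))
  pop[length(pop) - slots + 1L] <- templates[slots]
  if (!is.null(warm_start))
    pop[seq_along(warm_start$trees)] <- warm_start$trees

  hof <- list()  # complexity (as character) -> list(tree, mse)
  seen_sigs <- new.env(parent = emptyenv())
  update_hof <- function(tree, mse) {
    key <- as.character(expr_size(tree))
    cur <- hof[[key]]
    if (is.null(cur) || mse < cur$mse)
      hof[[key]] <<- list(tree = tree, mse = mse)
  }

  mses <- vapply(pop, function(e) expr_mse(e, X, y), numeric(1))
  sizes <- vapply(pop, expr_size, integer(1))
  for (i in seq_along(pop)) if (is.finite(mses[i])) update_hof(pop[[i]], mses[i])

  for (gen in seq_len(config$generations)) {
    fitness <- pen(mses, sizes)
    fitness[!is.finite(fitness)] <- 1e12

    # constant refinement. Leaders get a thorough polish; in addition,
    # every structurally new small expression (signature with constants
    # masked) receives one cheap refinement the first time it appears, so
    # motifs whose constants start in the wrong basin (e.g. an oscillation
    # at the wrong frequency) are still given a chance to surface.
    if (config$const_opt) {
      lead <- order(fitness)[seq_len(min(3, length(pop)))]
      for (i in lead) {
        refined <- optimize_constants(pop[[i]], X, y,
                                      restarts = config$const_restarts,
                                      maxit = 150)
        m <- expr_mse(refined, X, y)
        if (m < mses[i]) {
          pop[[i]] <- refined; mses[i] <- m
          if (is.finite(m)) update_hof(refined, m)
        }
      }
      novel <- 0L
      for (i in seq_along(pop)) {
        if (novel >= 25L) break
        if (sizes[i] > 12L) next
        sig <- expr_signature(pop[[i]])
        if (!is.null(seen_sigs[[sig]])) next
        seen_sigs[[sig]] <- TRUE
        if (length(collect_constants(pop[[i]])) == 0) next
        novel <- novel + 1L
        refined <- optimize_constants(pop[[i]], X, y, restarts = 2,
                                      maxit = 80)
        m <- expr_mse(refined, X, y)
        if (m < mses[i]) {
          pop[[i]] <- refined; mses[i] <- m
          if (is.finite(m)) update_hof(refined, m)
        }
      }
      fitness <- pen(mses, sizes)
      fitness[!is.finite(fitness)] <- 1e12
    }

    # re-inject a few freshly refined templates over the worst individuals:
    # repeated shots at multimodal constant basins across generations
    if (config$const_opt) {
      inject <- template_population(vars, operators, y)
      inject <- inject[sample(length(inject), min(10, length(inject)))]
      worst <- order(fitness, decreasing = TRUE)[seq_along(inject)]
      for (j in seq_along(inject)) {
        tree <- optimize_constants(inject[[j]], X, y, restarts = 3,
                                   maxit = 80)
        m <- expr_mse(tree, X, y)
        i <- worst[j]
        pop[[i]] <- tree; mses[i] <- m; sizes[i] <- expr_size(tree)
        if (is.finite(m)) update_hof(tree, m)
      }
      fitness <- pen(mses, sizes)
      fitness[!is.finite(fitness)] <- 1e12
    }

    tournament <- function() {
      idx <- sample(length(pop), config$tournament_size)
      idx[which.min(fitness[idx])]
    }
    elite <- order(fitness)[seq_len(min(4, length(pop)))]
    children <- vector("list", config$population)
    for (j in seq_along(elite)) children[[j]] <- pop[[elite[j]]]
    for (j in setdiff(seq_len(config$population), seq_along(elite))) {
      p1 <- pop[[tournament()]]
      child <- if (stats::runif(1) < config$crossover_prob) {
        crossover_trees(p1, pop[[tournament()]])
      } else p1
      child <- mutate_tree(child, vars, operators)
      if (expr_size(child) > config$max_size) child <- p1
      children[[j]] <- child
    }
    pop <- children
    mses <- vapply(pop, function(e) expr_mse(e, X, y), numeric(1))
    sizes <- vapply(pop, expr_size, integer(1))
    for (i in seq_along(pop)) if (is.finite(mses[i])) update_hof(pop[[i]], mses[i])
  }

  # final polish of the hall of fame
  if (config$const_opt) {
    for (key in names(hof)) {
      refined <- optimize_constants(hof[[key]]$tree, X, y,
                                    restarts = config$const_restarts + 4,
                                    maxit = 400)
      m <- expr_mse(refined, X, y)
      if (m < hof[[key]]$mse) hof[[key]] <- list(tree = refined, mse = m)
    }
  }

  comp <- as.integer(names(hof))
  ord <- order(comp)
  front_trees <- lapply(hof[ord], `[[`, "tree")
  front_mse <- vapply(hof[ord], `[[`, numeric(1), "mse")
  front_comp <- comp[ord]
  # drop dominated entries (larger and no better)
  keep <- rep(TRUE, length(front_mse))
  best_so_far <- Inf
  for (i in seq_along(front_mse)) {
    if (front_mse[i] < best_so_far) best_so_far <- front_mse[i]
    else keep[i] <- FALSE
  }
  front_trees <- front_trees[keep]
  front_mse <- front_mse[keep]
  front_comp <- front_comp[keep]

  best_mse <- min(front_mse)
  # small absolute slack keeps the rule meaningful when the best fit is
  # numerically exact (best_mse ~ 0)
  admissible <- front_mse <= config$selection_mse_factor * best_mse + 1e-12
  cand <- which(admissible)
  sel <- cand[order(front_comp[cand], front_mse[cand])][1]

  front <- data.frame(
    complexity = front_comp,
    mse = front_mse,
    expression = vapply(front_trees, expression_to_string, character(1),
                        digits = 15),
    selected = seq_along(front_comp) == sel,
    row.names = NULL)

  structure(list(front = front, trees = front_trees,
                 best = front_trees[[sel]], best_mse = front_mse[sel],
                 config = config, vars = vars),
            class = "sr_fit")
}

#' @export
print.sr_fit <- function(x, ...) {
  cat("<sr_fit> Pareto front (", nrow(x$front), " sizes):\n", sep = "")
  print(x$front, digits = 4)
  invisible(x)
}

#' Learned-model prediction of combined saturation
#'
#' The mechanistic model with a4 supplied by a symbolic expression — the
#' "learned model" obtained after distilling the grey-box network.
#'
#' @param expr an expression tree or infix string over the input columns.
#' @param X input matrix with columns `pH, PCO2, FMetHb, T_cel, p`.
#' @return Vector of combined saturations.
#' @export
learned_model_predict <- function(expr, X) {
  X <- as.matrix(X)
  a4 <- evaluate_expression(expr, as.data.frame(X))
  sa_predict(X[, "pH"], X[, "PCO2"], X[, "FMetHb"],
             T_cel = X[, "T_cel"], p = X[, "p"], a4_override = a4)
}

#' Match an expression against the cosine-of-log-pressure family
#'
#' Detects whether an expression is (exactly) of the form
#' `alpha * cos(beta * ln(p) + phi) + gamma` in the pressure input alone,
#' and extracts the normalized coefficients: `beta > 0`, phase folded into
#' (-pi, pi\] with a phase of pi absorbed into the sign of `alpha`. The
#' check walks the tree for trigonometric nodes and verifies, by exact
#' numerical probes on a pressure grid, that the trig argument is affine in
#' `ln p` and the whole expression affine in the cosine; structurally
#' different expressions (e.g. cosine of `p` itself) return no match.
#'
#' @param expr an expression tree or infix string.
#' @param var pressure variable name (default `"p"`).
#' @param reference named list of the remaining input values used in the
#'   probes.
#' @param tol absolute tolerance of the exactness probes.
#' @return `NULL` when the structure differs; otherwise a list with
#'   `alpha`, `beta`, `gamma`, `phase`.
#' @export
match_canonical_form <- function(expr, var = "p",
                                 reference = list(pH = 7.40, PCO2 = 5.33,
                                                  FMetHb = 0, T_cel = 37),
                                 tol = 1e-6) {
  if (is.character(expr)) expr <- parse_expression(expr)
  p_grid <- exp(seq(log(0.8), log(40), length.out = 61))
  probe_X <- function(ref_shift = 0) {
    X <- data.frame(p = p_grid)
    for (nm in names(reference)) X[[nm]] <- reference[[nm]] + ref_shift
    X
  }
  v0 <- evaluate_expression(expr, probe_X(0))
  v1 <- evaluate_expression(expr, probe_X(0.05))
  if (any(!is.finite(v0)) || max(abs(v0 - v1)) > tol) return(NULL)
  if (stats::sd(v0) < tol) return(NULL)

  t_grid <- log(p_grid)
  # collect trig nodes in preorder
  trig <- list()
  walk <- function(node) {
    if (node$type == "un" && node$op %in% c("sin", "cos"))
      trig[[length(trig) + 1L]] <<- node
    if (node$type == "un") walk(node$a)
    if (node$type == "bin") { walk(node$l); walk(node$r) }
  }
  walk(expr)
  if (length(trig) == 0) return(NULL)

  affine_fit <- function(yv, xv) {
    if (stats::sd(xv) < 1e-12) return(NULL)
    fit <- stats::lm.fit(cbind(1, xv), yv)
    if (max(abs(fit$residuals)) > tol * max(1, max(abs(yv)))) return(NULL)
    c(intercept = fit$coefficients[[1]], slope = fit$coefficients[[2]])
  }

  for (node in trig) {
    u <- evaluate_expression(node$a, probe_X(0))
    cf_arg <- affine_fit(u, t_grid)
    if (is.null(cf_arg) || abs(cf_arg["slope"]) < tol) next
    beta <- cf_arg[["slope"]]
    phi <- cf_arg[["intercept"]]
    if (node$op == "sin") phi <- phi - pi / 2
    cosu <- cos(beta * t_grid + phi)
    if (stats::sd(cosu) < 1e-8) next
    cf_out <- affine_fit(v0, cosu)
    if (is.null(cf_out)) next
    alpha <- cf_out[["slope"]]
    gamma <- cf_out[["intercept"]]
    if (abs(alpha) < tol) next
    # normalize: beta > 0; phase reduced to (-pi/2, pi/2] with half-turn
    # flips absorbed into the sign of alpha (cos(t + pi) = -cos(t))
    if (beta < 0) { beta <- -beta; phi <- -phi }
    phi <- ((phi + pi) %% (2 * pi)) - pi
    if (phi > pi / 2) { phi <- phi - pi; alpha <- -alpha }
    if (phi <= -pi / 2) { phi <- phi + pi; alpha <- -alpha }
    return(list(alpha = alpha, beta = beta, gamma = gamma, phase = phi))
  }
  NULL
}
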