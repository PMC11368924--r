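#' Search configuration
#'
#' @param c Exploration constant (> 0 allowed to be 0 for the pure
#'   exploitation limit); scales the prior-weighted exploration bonus.
#'   Default 1.
#' @param iterations Simulation budget per token decision (the `IT`
#'   parameter; default 150).
#' @param max_depth Maximum number of non-terminal tokens in a molecule
#'   (default 100).
#' @param seed RNG seed for the whole generation run.
#' @param d Number of objectives.
#' @return A `search_config` object.
#' @export
search_config <- function(c = 1, iterations = 150L, max_depth = 100L,
                          seed = 1L, d = 2L) {
  stopifnot(is.numeric(c), length(c) == 1L, c >= 0)
  iterations <- as.integer(iterations)
  max_depth <- as.integer(max_depth)
  stopifnot(iterations >= 1L, max_depth >= 0L)
  d <- as.integer(d)
  stopifnot(d >= 1L)
  structure(list(c = c, iterations = iterations, max_depth = max_depth,
                 seed = as.integer(seed), d = d),
            class = "search_config")
}

# Tree nodes are environments: the backup step mutates statistics in place
# along the selected path.
new_tree_node <- function(token, prior = 1, d = 1L, parent = NULL) {
  node <- new.env(parent = emptyenv())
  node$token <- token
  node$N <- 0L
  node$W <- rep(0, d)
  node$prior <- prior
  node$children <- list()
  node$expanded <- FALSE
  node$parent <- parent
  class(node) <- "tree_node"
  node
}

#' ParetoPUCT selection score of a child node
#'
#' The vectorial selection criterion
#' \deqn{U_p = \frac{W_a}{N_a} + c\,P(a|C)\,\frac{\sqrt{N}}{1 + N_a},}
#' where the exploitation term \eqn{W_a/N_a} is the zero vector for an
#' unvisited child (so the prior term alone ranks fresh children) and the
#' scalar exploration bonus is added to every component.
#'
#' @param child A tree node (fields `N`, `W`, `prior`).
#' @param n_parent Visit count of the parent.
#' @param c Exploration constant.
#' @return Numeric score vector, one entry per objective.
#' @export
paretopuct_score <- function(child, n_parent, c) {
  stopifnot(n_parent >= 0)
  exploit <- if (child$N == 0L) rep(0, length(child$W)) else child$W / child$N
  exploit + c * child$prior * sqrt(n_parent) / (1 + child$N)
}

#' Scalar UCB1 score (single-objective baseline)
#'
#' \deqn{U = W_a/N_a + \sqrt{2 \ln N / N_a}.} Used only as the comparison
#' baseline for the single-objective reduction; requires a visited child.
#'
#' @param child A tree node with scalar cumulative reward.
#' @param n_parent Total iteration count `N`.
#' @return Scalar score.
#' @export
ucb_score <- function(child, n_parent) {
  if (child$N == 0L) {
    stop("UCB baseline is undefined for an unvisited child", call. = FALSE)
  }
  stopifnot(length(child$W) == 1L)
  child$W / child$N + sqrt(2 * log(n_parent) / child$N)
}

#' Select a child by ParetoPUCT
#'
#' Computes the score vector of every child, extracts the Pareto front of
#' the score vectors, and returns one front member uniformly at random
#' (deterministically when the front is a singleton). Draws come from R's
#' RNG, so a seeded run is reproducible.
#'
#' @param node An expanded tree node.
#' @param n_parent Visit count to use as `N` in the score.
#' @param c Exploration constant.
#' @return The selected child node.
#' @export
select_child <- function(node, n_parent, c) {
  kids <- node$children
  if (length(kids) == 0L) {
    stop("cannot select from an unexpanded node", call. = FALSE)
  }
  s <- vapply(kids, paretopuct_score, numeric(length(node$W)),
              n_parent = n_parent, c = c)
  # vapply returns a d x n matrix for d > 1 but a plain vector for d = 1
  scores <- if (is.matrix(s)) t(s) else matrix(s, ncol = 1L)
  front <- pareto_front(scores)
  pick <- if (length(front) == 1L) front else front[sample.int(length(front), 1L)]
  kids[[pick]]
}

#' Expand a leaf node
#'
#' Queries the policy for the next-token distribution at the node's context
#' and creates one child per vocabulary token, each initialized to
#' `{N = 0, W = 0, prior = P(a|C)}`. Idempotent: expanding an already
#' expanded node is a no-op.
#'
#' @param node Leaf tree node.
#' @param context [state_context()] whose fragment corresponds to `node`.
#' @param policy [policy_model()].
#' @param legal Legal vocabulary under this context (default: the whole
#'   vocabulary). At the depth cap only the terminal symbol is legal; the
#'   policy's distribution is renormalized over the legal set (uniform over
#'   it if the policy puts zero mass there).
#' @return The node, invisibly.
#' @export
expand_node <- function(node, context, policy, legal = policy$vocabulary) {
  if (node$expanded) return(invisible(node))
  p <- predict_tokens(policy, context)
  if (!identical(sort(legal), sort(policy$vocabulary))) {
    stopifnot(all(legal %in% policy$vocabulary))
    p <- p[legal]
    p <- if (sum(p) > 0) p / sum(p) else
      stats::setNames(rep(1 / length(legal), length(legal)), legal)
  }
  d <- length(node$W)
  node$children <- lapply(seq_along(p), function(i) {
    new_tree_node(names(p)[i], prior = unname(p[i]), d = d, parent = node)
  })
  names(node$children) <- names(p)
  node$expanded <- TRUE
  invisible(node)
}

#' Greedy policy rollout to a terminal string
#'
#' Repeatedly appends the argmax-probability token until the terminal
#' symbol is emitted or the fragment reaches `max_depth` non-terminal
#' tokens. Depth-capped rollouts are flagged incomplete.
#'
#' @param context [state_context()] to complete.
#' @param policy [policy_model()].
#' @param max_depth Maximum number of non-terminal tokens.
#' @return List with `tokens` (the full token string) and `complete`
#'   (logical: ended with the terminal symbol).
#' @export
policy_rollout <- function(context, policy, max_depth) {
  frag <- context$fragment
  if (fragment_depth(frag) > max_depth) {
    stop("rollout context already exceeds max_depth", call. = FALSE)
  }
  while (!ends_terminal(frag)) {
    if (fragment_depth(frag) >= max_depth) {
      return(list(tokens = paste(frag, collapse = ""), complete = FALSE))
    }
    p <- predict_tokens(policy, state_context(context$protein, frag))
    frag <- c(frag, names(p)[which.max(p)])
  }
  list(tokens = paste(frag, collapse = ""), complete = TRUE)
}

ends_terminal <- function(fragment) {
  length(fragment) > 0L && utils::tail(fragment, 1) == terminal_token()
}

fragment_depth <- function(fragment) {
  sum(fragment != terminal_token())
}

#' Back up a reward vector along a path
#'
#' For every node from the evaluated leaf to the root:
#' \eqn{N_a \leftarrow N_a + 1}, \eqn{W_a \leftarrow W_a + r}.
#'
#' @param path List of tree nodes (any order; each is updated once).
#' @param r Reward vector.
#' @export
backup <- function(path, r) {
  for (node in path) {
    node$N <- node$N + 1L
    node$W <- node$W + r
  }
  invisible(NULL)
}

#' One token decision by Pareto MCTS
#'
#' Runs `config$iterations` simulations of
#' Selection (ParetoPUCT) → Expansion → Rollout → evaluation → Backup from
#' a fresh root at `context`, mutating the global pool along the way, and
#' returns the most-visited child's token. Ties on visit count are broken
#' by larger mean-reward sum, then lexicographic token order. Rollout
#' strings that fail scoring (invalid molecules) or are depth-capped
#' receive a zero reward, are backed up normally, and never enter the
#' pool.
#'
#' @param context [state_context()]; its fragment is the committed prefix.
#' @param policy [policy_model()].
#' @param objectives [objective_set()] (dimension must match `config$d`).
#' @param pool [pareto_pool()]; carried across token decisions.
#' @param config [search_config()].
#' @return List with `token` (chosen symbol), `pool` (updated pool),
#'   `root` (the search tree, for inspection), and `n_evaluated` (number
#'   of molecule evaluations attempted).
#' @export
search_token <- function(context, policy, objectives, pool, config) {
  stopifnot(inherits(config, "search_config"))
  stopifnot(inherits(objectives, "objective_set"))
  if (objectives$d != config$d || pool$d != config$d) {
    stop("objective set, pool and config disagree on the number of objectives",
         call. = FALSE)
  }
  if (ends_terminal(context$fragment)) {
    stop("context already ends with the terminal symbol", call. = FALSE)
  }
  d <- config$d
  root <- new_tree_node(NA_character_, prior = 1, d = d)
  n_eval <- 0L
  for (it in seq_len(config$iterations)) {
    node <- root
    frag <- context$fragment
    path <- list(root)
    # Selection: descend while expanded and non-terminal
    while (node$expanded && !ends_terminal(frag)) {
      node <- select_child(node, node$N, config$c)
      frag <- c(frag, node$token)
      path[[length(path) + 1L]] <- node
    }
    if (ends_terminal(frag)) {
      mol <- list(tokens = paste(frag, collapse = ""), complete = TRUE)
    } else {
      legal <- if (fragment_depth(frag) >= config$max_depth)
        terminal_token() else policy$vocabulary
      expand_node(node, state_context(context$protein, frag), policy, legal)
      mol <- policy_rollout(state_context(context$protein, frag), policy,
                            config$max_depth)
    }
    n_eval <- n_eval + 1L
    ev <- tryCatch({
      if (!mol$complete) invalid_molecule(mol$tokens, "depth-capped rollout")
      if (mol$tokens == terminal_token()) {
        invalid_molecule(mol$tokens, "empty molecule")
      }
      canon <- objectives$canonicalize(mol$tokens)
      h <- assemble_h(mol$tokens, objectives)
      r <- reward_vector(h, pool)
      upd <- pool_update(pool, canon, h, r, iteration = it)
      pool <- upd$pool
      r
    }, invalid_molecule = function(e) rep(0, d))
    backup(path, ev)
  }
  list(token = best_move(root), pool = pool, root = root,
       n_evaluated = n_eval)
}

# Move rule: most-visited child; ties by larger mean-reward sum, then by
# lexicographic token order.
best_move <- function(root) {
  kids <- root$children
  if (length(kids) == 0L) {
    stop("search produced no expanded root; nothing to choose", call. = FALSE)
  }
  visits <- vapply(kids, `[[`, numeric(1), "N")
  means <- vapply(kids, function(k) {
    if (k$N == 0L) 0 else sum(k$W / k$N)
  }, numeric(1))
  tokens <- vapply(kids, `[[`, character(1), "token")
  ord <- order(-visits, -means, tokens)
  tokens[ord[1]]
}

#' Generate one molecule by Pareto MCTS
#'
#' The outer autoregressive loop: starting from the empty fragment,
#' [search_token()] chooses one token per position (a fresh tree per
#' decision) until the terminal symbol is emitted or `max_depth` is
#' reached; the global Pareto pool persists across all decisions of the
#' run. The RNG is seeded from `config$seed` at entry, so equal seeds give
#' identical runs.
#'
#' @param protein Character vector of protein sequence(s); with several
#'   sequences supply a [fused_policy()] built for them.
#' @param policy [policy_model()].
#' @param objectives [objective_set()].
#' @param config [search_config()].
#' @param pool Optional existing [pareto_pool()] to continue filling
#'   (shared-pool multi-run collection); a fresh pool by default.
#' @return A `pareto_generation` object: list with `status` (`"ok"` or
#'   `"failed"`), `record` (one-row tibble for the generated molecule, or
#'   `NULL`), `pool`, `config`, `trace` (one row per token decision) and
#'   `protein`.
#' @seealso [collect_molecules()] for multi-candidate runs;
#'   [generics::tidy()] / [generics::glance()] methods.
#' @export
generate_molecule <- function(protein, policy, objectives, config,
                              pool = NULL) {
  stopifnot(inherits(config, "search_config"))
  set.seed(config$seed)
  if (is.null(pool)) pool <- pareto_pool(config$d, objectives$names)
  fragment <- character(0)
  trace <- list()
  complete <- FALSE
  while (config$max_depth > 0L && fragment_depth(fragment) <= config$max_depth) {
    st <- search_token(state_context(protein, fragment), policy, objectives,
                       pool, config)
    pool <- st$pool
    fragment <- c(fragment, st$token)
    trace[[length(trace) + 1L]] <- tibble::tibble(
      position = length(fragment), token = st$token,
      root_visits = st$root$N, pool_size = pool_size(pool)
    )
    if (st$token == terminal_token()) {
      complete <- TRUE
      break
    }
  }
  trace <- if (length(trace)) dplyr::bind_rows(trace) else
    tibble::tibble(position = integer(0), token = character(0),
                   root_visits = integer(0), pool_size = integer(0))
  result <- structure(
    list(status = "failed", record = NULL, pool = pool, config = config,
         trace = trace, protein = protein),
    class = "pareto_generation"
  )
  if (!complete) return(result)
  tokens <- paste(fragment, collapse = "")
  rec <- tryCatch({
    if (tokens == terminal_token()) invalid_molecule(tokens, "empty molecule")
    canon <- objectives$canonicalize(tokens)
    h <- assemble_h(tokens, objectives)
    r <- reward_vector(h, pool)
    upd <- pool_update(pool, canon, h, r, iteration = nrow(trace))
    pool <- upd$pool
    hm <- matrix(h, nrow = 1, dimnames = list(NULL, objectives$names))
    rm_ <- matrix(r, nrow = 1,
                  dimnames = list(NULL, paste0("r_", objectives$names)))
    dplyr::bind_cols(tibble::tibble(tokens = canon),
                     tibble::as_tibble(hm), tibble::as_tibble(rm_))
  }, invalid_molecule = function(e) NULL)
  if (is.null(rec)) return(result)
  result$status <- "ok"
  result$record <- rec
  result$pool <- pool
  result
}

#' Collect several molecules from repeated searches
#'
#' Runs [generate_molecule()] `n` times with seeds derived from
#' `config$seed`. By default the global Pareto pool is shared across runs
#' (the archive keeps every Pareto-optimal molecule found so far); with
#' `share_pool = FALSE` each run gets a private pool.
#'
#' @inheritParams generate_molecule
#' @param n Number of runs.
#' @param share_pool Share one global pool across runs (default `TRUE`).
#' @return List with `records` (tibble of per-run generated molecules),
#'   `pool` (shared pool, or the last run's pool when not shared) and
#'   `runs` (list of `pareto_generation` objects).
#' @export
collect_molecules <- function(protein, policy, objectives, config, n = 10L,
                              share_pool = TRUE) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  pool <- pareto_pool(config$d, objectives$names)
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    runs[[i]] <- generate_molecule(protein, policy, objectives, cfg_i,
                                   pool = if (share_pool) pool else NULL)
    if (share_pool) pool <- runs[[i]]$pool
  }
  records <- dplyr::bind_rows(purrr::map(runs, "record"))
  list(records = records,
       pool = if (share_pool) pool else runs[[n]]$pool,
       runs = runs)
}

#' @export
print.pareto_generation <- function(x, ...) {
  cat("<pareto_generation> status: ", x$status,
      " | pool size: ", pool_size(x$pool),
      " | c = ", x$config$c, ", IT = ", x$config$iterations,
      ", seed = ", x$config$seed, "\n", sep = "")
  if (!is.null(x$record)) print(x$record)
  invisible(x)
}

#' Tidy a generation result
#'
#' `tidy()` returns the global Pareto pool as a tibble (one row per
#' archived molecule); `glance()` returns a one-row run summary.
#'
#' @param x A `pareto_generation` object.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy
#' @export
tidy.pareto_generation <- function(x, ...) {
  tibble::as_tibble(x$pool)
}

#' @rdname tidy.pareto_generation
#' @importFrom generics glance
#' @export
glance.pareto_generation <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    tokens = if (is.null(x$record)) NA_character_ else x$record$tokens,
    n_tokens = nrow(x$trace),
    pool_size = pool_size(x$pool),
    exploration_c = x$config$c,
    iterations = x$config$iterations,
    seed = x$config$seed
  )
}

#' Plot the Pareto pool of a generation run
#'
#' Scatter of the first two raw metric dimensions of the pool, the
#' generated molecule highlighted. With one objective, a dot plot of the
#' pool values.
#'
#' @param object A `pareto_generation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.pareto_generation <- function(object, ...) {
  pool_tb <- tibble::as_tibble(object$pool)
  nms <- object$pool$objective_names
  if (nrow(pool_tb) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "Empty Pareto pool"))
  }
  if (length(nms) == 1L) {
    p <- ggplot2::ggplot(pool_tb,
                         ggplot2::aes(x = .data[[nms[1]]], y = 0)) +
      ggplot2::geom_point() +
      ggplot2::labs(y = NULL, title = "Pareto pool")
    return(p)
  }
  p <- ggplot2::ggplot(pool_tb,
                       ggplot2::aes(x = .data[[nms[1]]],
                                    y = .data[[nms[2]]])) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::labs(title = "Global Pareto pool",
                  subtitle = "oriented metrics, higher is better")
  if (!is.null(object$record) && all(nms[1:2] %in% names(object$record))) {
    p <- p + ggplot2::geom_point(data = object$record, colour = "red",
                                 size = 3, shape = 17)
  }
  p
}
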