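#' An enumerable toy sequence MDP
#'
#' A synthetic stand-in for chemical space: a small token vocabulary, a
#' bounded molecule length and conflicting count-based surrogate
#' objectives. The terminal space is small enough to enumerate, so every
#' search behaviour can be checked against brute force. Toy tokens are
#' plain letters and never collide with SMILES atom symbols in fixtures.
#'
#' @param vocabulary Non-terminal token symbols (the terminal `"$"` is
#'   appended automatically if absent).
#' @param max_len Maximum number of non-terminal tokens.
#' @param objectives An [objective_set()] over token strings; defaults to
#'   the conflicting pair (countA, countB).
#' @return A `toy_mdp` object.
#' @export
toy_mdp <- function(vocabulary = c("A", "B"), max_len = 3L,
                    objectives = NULL) {
  vocabulary <- setdiff(vocabulary, terminal_token())
  stopifnot(length(vocabulary) >= 1L)
  max_len <- as.integer(max_len)
  stopifnot(max_len >= 0L)
  n_terminals <- sum(length(vocabulary)^(0:max_len))
  if (n_terminals > 1e5) {
    stop("toy MDP terminal space too large to enumerate (",
         n_terminals, " > 1e5)", call. = FALSE)
  }
  if (is.null(objectives)) {
    counted <- unique(vocabulary[c(1L, min(2L, length(vocabulary)))])
    objectives <- objective_set(lapply(counted, token_count_objective))
  }
  structure(list(vocabulary = c(vocabulary, terminal_token()),
                 max_len = max_len, objectives = objectives),
            class = "toy_mdp")
}

#' Enumerate all terminal strings of a toy MDP
#'
#' Every string of 0 to `max_len` non-terminal tokens followed by the
#' terminal symbol, duplicate-free, in deterministic (length, then
#' lexicographic) order.
#'
#' @param mdp A [toy_mdp()].
#' @return Character vector of terminal token strings.
#' @examples
#' enumerate_terminals(toy_mdp(c("A", "B"), max_len = 2))
#' @export
enumerate_terminals <- function(mdp) {
  stopifnot(inherits(mdp, "toy_mdp"))
  vocab <- setdiff(mdp$vocabulary, terminal_token())
  out <- terminal_token()
  for (l in seq_len(mdp$max_len)) {
    grids <- expand.grid(rep(list(vocab), l), stringsAsFactors = FALSE)
    strs <- sort(apply(as.matrix(grids), 1, paste, collapse = ""))
    out <- c(out, paste0(strs, terminal_token()))
  }
  out
}

#' Brute-force Pareto front of a toy MDP
#'
#' Scores every terminal string with the MDP's surrogate objectives and
#' returns the non-dominated subset — the exact front the search is
#' expected to recover.
#'
#' @param mdp A [toy_mdp()].
#' @return Tibble with `tokens` and one oriented metric column per
#'   objective, restricted to the Pareto-optimal terminals.
#' @export
brute_force_front <- function(mdp) {
  stopifnot(inherits(mdp, "toy_mdp"))
  terminals <- enumerate_terminals(mdp)
  hm <- vapply(terminals, assemble_h, numeric(mdp$objectives$d),
               objectives = mdp$objectives)
  h <- if (is.matrix(hm)) t(hm) else matrix(hm, ncol = 1L)
  colnames(h) <- mdp$objectives$names
  idx <- pareto_front(h)
  dplyr::bind_cols(tibble::tibble(tokens = terminals[idx]),
                   tibble::as_tibble(h[idx, , drop = FALSE]))
}

#' Deceptive toy policy
#'
#' Puts high prior mass (0.9 by default) on one misleading token in every
#' context, spreading the rest uniformly — so greedy decoding walks away
#' from the true front and recovery requires tree exploration.
#'
#' @param mdp A [toy_mdp()].
#' @param misleading_token The over-weighted token (must be in the
#'   vocabulary).
#' @param mass Prior mass on the misleading token.
#' @return A [policy_model()].
#' @export
make_deceptive_policy <- function(mdp, misleading_token, mass = 0.9) {
  stopifnot(inherits(mdp, "toy_mdp"))
  vocab <- mdp$vocabulary
  if (!misleading_token %in% vocab) {
    stop("misleading token must be in the vocabulary", call. = FALSE)
  }
  stopifnot(mass > 0, mass < 1)
  rest <- (1 - mass) / (length(vocab) - 1L)
  p <- stats::setNames(rep(rest, length(vocab)), vocab)
  p[misleading_token] <- mass
  policy_model(vocab, function(context) p, name = "deceptive")
}
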