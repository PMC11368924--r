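#' Define a property objective
#'
#' An objective names a raw molecular metric, how to score it from a token
#' string, and its optimisation direction. Before vectors enter any
#' dominance comparison every objective is oriented "higher is better":
#' minimise-type metrics are negated, and range-type metrics become a 0/1
#' indicator of falling inside `[lo, hi]` (boundaries inclusive). Reported
#' outputs undo the orientation.
#'
#' @param name Unique metric name.
#' @param scorer Function `(tokens) -> numeric(1)` returning the raw metric
#'   for a terminal token string. Scorers signal an `invalid_molecule`
#'   condition (see [invalid_molecule()]) for unparsable molecules.
#' @param direction `"maximize"`, `"minimize"`, or `"range"`.
#' @param lo,hi Closed-interval bounds, required when
#'   `direction = "range"`.
#' @return An `objective` object.
#' @seealso [objective_set()], [assemble_h()]
#' @export
objective <- function(name, scorer,
                      direction = c("maximize", "minimize", "range"),
                      lo = NULL, hi = NULL) {
  direction <- match.arg(direction)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.function(scorer))
  if (direction == "range") {
    stopifnot(is.numeric(lo), is.numeric(hi), lo < hi)
  }
  structure(list(name = name, scorer = scorer, direction = direction,
                 lo = lo, hi = hi),
            class = "objective")
}

#' Ordered set of objectives
#'
#' Fixes the dimension `d` and the layout of the raw metric vector `h` for
#' a whole run. Objective names must be unique.
#'
#' @param ... [objective()]s.
#' @param canonicalize Function `(tokens) -> character(1)` mapping a
#'   terminal token string to its canonical form (identity by default; the
#'   chemistry set canonicalizes SMILES). Must signal `invalid_molecule`
#'   for unparsable input.
#' @return An `objective_set` object.
#' @export
objective_set <- function(..., canonicalize = identity) {
  objs <- list(...)
  if (length(objs) == 1L && is.list(objs[[1]]) &&
      !inherits(objs[[1]], "objective")) {
    objs <- objs[[1]]
  }
  stopifnot(length(objs) >= 1L)
  for (o in objs) stopifnot(inherits(o, "objective"))
  nms <- vapply(objs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("objective names must be unique", call. = FALSE)
  structure(list(objectives = objs, names = nms, d = length(objs),
                 canonicalize = canonicalize),
            class = "objective_set")
}

#' @export
print.objective_set <- function(x, ...) {
  dirs <- vapply(x$objectives, `[[`, character(1), "direction")
  cat("<objective_set> d = ", x$d, ": ",
      paste0(x$names, " (", dirs, ")", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Signal an invalid molecule
#'
#' Scorers and canonicalizers call this for token strings that fail
#' chemical parsing. The search consumes the condition: the rollout gets a
#' zero reward vector, is backed up normally, and never enters the pool.
#'
#' @param tokens The offending token string.
#' @param reason Optional detail.
#' @export
invalid_molecule <- function(tokens, reason = "failed to parse") {
  cond <- structure(
    class = c("invalid_molecule", "error", "condition"),
    list(message = paste0("invalid molecule '", tokens, "': ", reason),
         call = NULL, tokens = tokens)
  )
  stop(cond)
}

#' Druggable LogP range indicator
#'
#' Returns 1 when the LogP value falls inside the druggable window
#' `[-0.4, 5.6]` (the Ghose filter range), 0 otherwise. Both boundaries are
#' inclusive.
#'
#' @param logp Numeric vector of LogP values.
#' @return Integer vector of 0/1 indicators.
#' @examples
#' logp_range_metric(c(5.4, 5.7, -0.4)) # 1 0 1
#' @export
logp_range_metric <- function(logp) {
  stopifnot(is.numeric(logp), all(is.finite(logp)))
  as.integer(logp >= -0.4 & logp <= 5.6)
}

#' Surrogate token-count objectives
#'
#' Deterministic scorers over token strings, used as docking stand-ins so
#' the full search pipeline is testable with no chemistry or external
#' binaries. `token_count_objective()` counts occurrences of one token;
#' `token_length_objective()` scores the number of non-terminal tokens.
#'
#' @param token Token symbol to count.
#' @param name Metric name (defaults to `count<token>`).
#' @param direction Orientation, as in [objective()].
#' @return An [objective()].
#' @examples
#' obj <- token_count_objective("A")
#' obj$scorer("AAB$") # 2
#' @export
token_count_objective <- function(token, name = paste0("count", token),
                                  direction = "maximize") {
  stopifnot(is.character(token), nchar(token) == 1L)
  objective(name, function(tokens) {
    lengths(regmatches(tokens, gregexpr(token, tokens, fixed = TRUE)))
  }, direction = direction)
}

#' @rdname token_count_objective
#' @export
token_length_objective <- function(name = "length", direction = "maximize") {
  objective(name, function(tokens) {
    nchar(tokens) # token count, terminal included
  }, direction = direction)
}

#' Assemble the oriented metric vector of a molecule
#'
#' Scores every objective in order and applies the orientation transform:
#' minimise-type metrics are negated, range-type metrics become the 0/1
#' inside-interval indicator. Any scorer failure propagates as an
#' `invalid_molecule` condition.
#'
#' @param tokens Terminal token string.
#' @param objectives An [objective_set()].
#' @return Named numeric vector of length `d` (oriented, higher-is-better).
#' @seealso [deorient_h()] to recover raw reporting values.
#' @export
assemble_h <- function(tokens, objectives) {
  stopifnot(inherits(objectives, "objective_set"))
  stopifnot(is.character(tokens), length(tokens) == 1L)
  h <- vapply(objectives$objectives, function(o) {
    raw <- o$scorer(tokens)
    if (!is.numeric(raw) || length(raw) != 1L || !is.finite(raw)) {
      invalid_molecule(tokens, paste0("scorer '", o$name,
                                      "' returned a non-finite value"))
    }
    orient_value(raw, o)
  }, numeric(1))
  stats::setNames(h, objectives$names)
}

orient_value <- function(raw, o) {
  switch(o$direction,
         maximize = raw,
         minimize = -raw,
         range = as.numeric(raw >= o$lo & raw <= o$hi))
}

#' Undo objective orientation for reporting
#'
#' Maps oriented entries of `h` back to the raw metric scale: negated
#' minimise-type entries are re-negated; range indicators are left as 0/1.
#'
#' @param h Oriented numeric vector (or matrix, columns = objectives).
#' @param objectives The [objective_set()] that produced it.
#' @return Same shape as `h`, on the raw reporting scale.
#' @export
deorient_h <- function(h, objectives) {
  stopifnot(inherits(objectives, "objective_set"))
  signs <- vapply(objectives$objectives, function(o) {
    if (o$direction == "minimize") -1 else 1
  }, numeric(1))
  if (is.matrix(h)) sweep(h, 2, signs, `*`) else h * signs
}
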