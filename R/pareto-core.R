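#' Pareto dominance between two objective vectors
#'
#' All objectives are oriented "higher is better" before they enter a
#' comparison (minimise-type metrics are negated upstream, see
#' [objective()]). `x` weakly dominates `y` when `x >= y` in every
#' component, and strictly dominates when additionally `x > y` in at least
#' one. Every vector weakly dominates itself.
#'
#' @param x,y Numeric vectors of equal length with finite entries.
#' @return One of `"none"`, `"weak"`, `"strict"`.
#' @examples
#' dominates(c(1, 2), c(1, 2)) # "weak"
#' dominates(c(3, 1), c(2, 1)) # "strict"
#' dominates(c(3, 1), c(1, 3)) # "none"
#' @export
dominates <- function(x, y) {
  check_objective_vector(x)
  check_objective_vector(y)
  if (length(x) != length(y)) {
    stop("objective vectors have different dimensions: ",
         length(x), " vs ", length(y), call. = FALSE)
  }
  if (all(x >= y)) {
    if (any(x > y)) "strict" else "weak"
  } else {
    "none"
  }
}

check_objective_vector <- function(x) {
  if (!is.numeric(x) || length(x) < 1L || !all(is.finite(x))) {
    stop("an objective vector must be a non-empty finite numeric vector",
         call. = FALSE)
  }
  invisible(x)
}

#' Extract the Pareto front of a set of objective vectors
#'
#' Returns the indices of the rows not strictly dominated by any other row
#' (the non-dominated set). Duplicated front rows are all retained: equal
#' vectors do not strictly dominate one another.
#'
#' @param h A numeric matrix or data frame, one row per candidate, one
#'   column per objective (all oriented higher-is-better).
#' @return Integer vector of row indices on the front, in input order.
#' @examples
#' h <- rbind(c(1, 1), c(2, 0), c(0, 2), c(1, 0))
#' pareto_front(h) # 1 2 3
#' @export
pareto_front <- function(h) {
  h <- as_h_matrix(h)
  n <- nrow(h)
  if (n == 0L) stop("cannot take the Pareto front of an empty set", call. = FALSE)
  keep <- vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      j != i && strictly_dominates_row(h[j, ], h[i, ])
    }, logical(1)))
  }, logical(1))
  which(keep)
}

strictly_dominates_row <- function(x, y) {
  all(x >= y) && any(x > y)
}

as_h_matrix <- function(h) {
  if (is.data.frame(h)) h <- as.matrix(h)
  if (!is.matrix(h)) h <- matrix(h, ncol = length(h))
  storage.mode(h) <- "double"
  if (nrow(h) > 0L && !all(is.finite(h))) {
    stop("objective vectors must be finite", call. = FALSE)
  }
  h
}

#' Create an empty global Pareto pool
#'
#' The pool is the running archive of mutually non-dominated molecules found
#' during a search. Each member carries its canonical token string, raw
#' oriented metric vector `h`, pool-relative reward vector `r` (as computed
#' at insertion time, against the pool state before insertion), and the
#' iteration at which it was found.
#'
#' @param d Number of objectives (fixed for the life of the pool).
#' @param objective_names Optional character vector of length `d` used for
#'   column names in [tibble::as_tibble()] output.
#' @return A `pareto_pool` object.
#' @seealso [pool_update()], [reward_vector()], [select_best()]
#' @export
pareto_pool <- function(d, objective_names = NULL) {
  d <- as.integer(d)
  stopifnot(d >= 1L)
  if (is.null(objective_names)) objective_names <- paste0("h", seq_len(d))
  stopifnot(length(objective_names) == d)
  structure(
    list(
      tokens = character(0),
      h = matrix(numeric(0), ncol = d),
      r = matrix(numeric(0), ncol = d),
      iteration = integer(0),
      d = d,
      objective_names = objective_names
    ),
    class = "pareto_pool"
  )
}

#' @export
print.pareto_pool <- function(x, ...) {
  cat("<pareto_pool> ", pool_size(x), " member(s), d = ", x$d, "\n", sep = "")
  if (pool_size(x) > 0L) print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Number of molecules in a Pareto pool
#' @param pool A [pareto_pool()].
#' @return Integer pool size \eqn{N_P}.
#' @export
pool_size <- function(pool) {
  stopifnot(inherits(pool, "pareto_pool"))
  length(pool$tokens)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.pareto_pool <- function(x, ...) {
  h <- x$h
  r <- x$r
  colnames(h) <- x$objective_names
  colnames(r) <- paste0("r_", x$objective_names)
  dplyr::bind_cols(
    tibble::tibble(tokens = x$tokens),
    tibble::as_tibble(h),
    tibble::as_tibble(r),
    tibble::tibble(iteration = x$iteration)
  )
}

#' Pool-relative reward vector of a candidate molecule
#'
#' Each reward component is the fraction of current pool members whose
#' corresponding metric the candidate matches or beats:
#' \deqn{r_i = \frac{1}{N_P}\sum_{k=1}^{N_P} 1[h_i \ge h_i^k].}
#' Dimensions are compared independently, so no cross-objective weighting or
#' rescaling is needed. Against an empty pool every component is 1: the
#' first molecule vacuously beats the empty front.
#'
#' @param h Numeric vector of oriented raw metrics for the candidate.
#' @param pool A [pareto_pool()] of the same dimension.
#' @return Numeric reward vector with entries in `[0, 1]`.
#' @export
reward_vector <- function(h, pool) {
  check_objective_vector(h)
  stopifnot(inherits(pool, "pareto_pool"))
  if (length(h) != pool$d) {
    stop("candidate has dimension ", length(h), " but pool has ", pool$d,
         call. = FALSE)
  }
  np <- pool_size(pool)
  if (np == 0L) return(rep(1, pool$d))
  colSums(sweep(pool$h, 2, h, function(hk, hi) hi >= hk)) / np
}

#' Offer a molecule to the global Pareto pool
#'
#' If the candidate's metric vector is strictly dominated by any member, the
#' pool is unchanged. Otherwise the candidate is inserted and every member
#' it strictly dominates is removed. Molecules are deduplicated by canonical
#' token string: re-offering a member (or a duplicate string) changes
#' nothing. The reward `r` must have been computed against the pool state
#' *before* this call (reward measures improvement over the existing front).
#'
#' @param pool A [pareto_pool()].
#' @param tokens Canonical token string of the molecule.
#' @param h Oriented raw metric vector.
#' @param r Reward vector stored with the record (see [reward_vector()]).
#' @param iteration Provenance index (which search iteration found it).
#' @return A list with elements `pool` (updated pool) and `admitted`
#'   (logical).
#' @export
pool_update <- function(pool, tokens, h, r = reward_vector(h, pool),
                        iteration = 0L) {
  stopifnot(inherits(pool, "pareto_pool"))
  stopifnot(is.character(tokens), length(tokens) == 1L, nzchar(tokens))
  check_objective_vector(h)
  if (length(h) != pool$d) {
    stop("candidate has dimension ", length(h), " but pool has ", pool$d,
         call. = FALSE)
  }
  if (tokens %in% pool$tokens) {
    return(list(pool = pool, admitted = FALSE))
  }
  np <- pool_size(pool)
  if (np > 0L) {
    dominated_by_member <- vapply(seq_len(np), function(k) {
      strictly_dominates_row(pool$h[k, ], h)
    }, logical(1))
    if (any(dominated_by_member)) {
      return(list(pool = pool, admitted = FALSE))
    }
    beats <- vapply(seq_len(np), function(k) {
      strictly_dominates_row(h, pool$h[k, ])
    }, logical(1))
    keep <- !beats
    pool$tokens <- pool$tokens[keep]
    pool$h <- pool$h[keep, , drop = FALSE]
    pool$r <- pool$r[keep, , drop = FALSE]
    pool$iteration <- pool$iteration[keep]
  }
  pool$tokens <- c(pool$tokens, tokens)
  pool$h <- rbind(pool$h, h)
  pool$r <- rbind(pool$r, r)
  pool$iteration <- c(pool$iteration, as.integer(iteration))
  rownames(pool$h) <- NULL
  rownames(pool$r) <- NULL
  list(pool = pool, admitted = TRUE)
}

#' Write / read a Pareto pool as CSV
#'
#' One row per member: canonical token string, raw oriented metrics, reward
#' components and discovery iteration.
#'
#' @param pool A [pareto_pool()].
#' @param path File path.
#' @return `pool_write_csv()` returns `path` invisibly; `pool_read_csv()`
#'   returns a tibble.
#' @export
pool_write_csv <- function(pool, path) {
  utils::write.csv(as.data.frame(tibble::as_tibble(pool)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname pool_write_csv
#' @export
pool_read_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
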