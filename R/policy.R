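#' The terminal token
#'
#' The reserved end-of-sequence symbol. Adapters for external autoregressive
#' models map their own end token to this symbol.
#' @return The string `"$"`.
#' @export
terminal_token <- function() "$"

#' State context for an autoregressive policy
#'
#' A context pairs one or more target protein sequences with the molecule
#' fragment generated so far (an ordered token vector). Policies predict the
#' next-token distribution from this context.
#'
#' @param protein Character vector of one or more amino-acid sequences
#'   (20-letter alphabet plus `X`); toy policies ignore it but it must be
#'   non-empty.
#' @param fragment Character vector of tokens generated so far (possibly
#'   empty).
#' @return A `state_context` object.
#' @export
state_context <- function(protein, fragment = character(0)) {
  stopifnot(is.character(protein), length(protein) >= 1L, all(nzchar(protein)))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", toupper(protein))
  if (any(bad)) {
    stop("protein sequence contains characters outside the amino-acid alphabet",
         call. = FALSE)
  }
  stopifnot(is.character(fragment))
  structure(list(protein = protein, fragment = fragment),
            class = "state_context")
}

#' Construct a next-token policy
#'
#' A policy is the pluggable guidance component of the search: given a
#' [state_context()] it returns a probability distribution over a fixed
#' token vocabulary (terminal symbol included). The distribution is
#' validated on every call: non-negative, summing to 1 within `1e-6`, named
#' in vocabulary order.
#'
#' @param vocabulary Character vector of token symbols; must contain the
#'   terminal symbol `"$"`.
#' @param predict Function `(context) -> numeric` returning one probability
#'   per vocabulary entry (named or in vocabulary order).
#' @param name Label used in logs and metadata.
#' @return A `policy_model` object.
#' @seealso [tabular_policy()], [fused_policy()], [external_policy()]
#' @export
policy_model <- function(vocabulary, predict, name = "policy") {
  stopifnot(is.character(vocabulary), length(vocabulary) >= 1L)
  if (anyDuplicated(vocabulary)) {
    stop("vocabulary contains duplicated tokens", call. = FALSE)
  }
  if (!terminal_token() %in% vocabulary) {
    stop("vocabulary must contain the terminal symbol \"$\"", call. = FALSE)
  }
  stopifnot(is.function(predict))
  structure(list(vocabulary = vocabulary, predict = predict, name = name),
            class = "policy_model")
}

#' @export
print.policy_model <- function(x, ...) {
  cat("<policy_model> ", x$name, " | vocabulary: ",
      paste(x$vocabulary, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Predict the next-token distribution
#'
#' Calls the policy and enforces the contract: the returned vector must be
#' non-negative and sum to 1 within `1e-6`, with one entry per vocabulary
#' token.
#'
#' @param policy A [policy_model()].
#' @param context A [state_context()].
#' @return Named numeric probability vector in vocabulary order.
#' @export
predict_tokens <- function(policy, context) {
  stopifnot(inherits(policy, "policy_model"))
  stopifnot(inherits(context, "state_context"))
  p <- policy$predict(context)
  validate_distribution(p, policy$vocabulary,
                        what = paste0("policy '", policy$name, "' at fragment [",
                                      paste(context$fragment, collapse = ""), "]"))
}

validate_distribution <- function(p, vocabulary, what = "policy") {
  if (!is.numeric(p) || length(p) != length(vocabulary)) {
    stop(what, " returned ", length(p), " probabilities for a vocabulary of ",
         length(vocabulary), call. = FALSE)
  }
  if (!is.null(names(p))) {
    if (!setequal(names(p), vocabulary)) {
      stop(what, " returned probabilities for tokens outside the vocabulary",
           call. = FALSE)
    }
    p <- p[vocabulary]
  } else {
    names(p) <- vocabulary
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop(what, " returned a non-normalized or negative distribution (sum = ",
         format(sum(p)), ")", call. = FALSE)
  }
  p
}

#' Deterministic tabular policy
#'
#' A table-driven policy used as the shipped test stand-in for a pretrained
#' autoregressive model. The table maps a bounded-order fragment suffix to a
#' next-token distribution; contexts whose suffix has no row fall back to
#' the uniform distribution over the vocabulary.
#'
#' @param table A data frame with columns `suffix` (the last `order` tokens
#'   pasted together, `""` for the empty fragment), `token`, `prob`. Rows
#'   for one suffix must sum to 1 within `1e-6`; tokens missing from a
#'   suffix's rows get probability 0.
#' @param vocabulary Character vector of tokens including `"$"`.
#' @param order Suffix length consulted for the lookup (default 1 token).
#' @param name Label.
#' @return A [policy_model()].
#' @examples
#' vocab <- c("A", "B", "$")
#' chain <- tibble::tibble(
#'   suffix = c("", "A", "B"),
#'   token  = c("A", "B", "$"),
#'   prob   = c(1, 1, 1)
#' )
#' pol <- tabular_policy(chain, vocab)
#' predict_tokens(pol, state_context("MKV", c("A")))
#' @export
tabular_policy <- function(table, vocabulary, order = 1L, name = "tabular") {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("suffix", "token", "prob") %in% names(table)))
  if (!all(table$token %in% vocabulary)) {
    stop("policy table mentions tokens outside the vocabulary", call. = FALSE)
  }
  sums <- tapply(table$prob, table$suffix, sum)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("policy table rows for suffix(es) ",
         paste(names(sums)[abs(sums - 1) > 1e-6], collapse = ", "),
         " do not sum to 1", call. = FALSE)
  }
  order <- as.integer(order)
  uniform <- rep(1 / length(vocabulary), length(vocabulary))
  names(uniform) <- vocabulary
  predict <- function(context) {
    frag <- context$fragment
    k <- min(order, length(frag))
    suffix <- if (k == 0L) "" else paste(utils::tail(frag, k), collapse = "")
    rows <- table[table$suffix == suffix, ]
    if (nrow(rows) == 0L) return(uniform)
    p <- stats::setNames(rep(0, length(vocabulary)), vocabulary)
    p[rows$token] <- rows$prob
    p
  }
  policy_model(vocabulary, predict, name = name)
}

#' Uniform policy over a vocabulary
#' @param vocabulary Character vector of tokens including `"$"`.
#' @return A [policy_model()] assigning equal mass to every token in every
#'   context.
#' @export
uniform_policy <- function(vocabulary) {
  tabular_policy(
    tibble::tibble(suffix = character(0), token = character(0),
                   prob = numeric(0)),
    vocabulary, name = "uniform"
  )
}

#' Mean-pool several next-token distributions
#'
#' The multi-target fusion rule: the fused probability of each token is the
#' arithmetic mean of its probabilities under the per-target policies,
#' \deqn{f(P_1,\dots,P_m)(a) = \frac{1}{m}\sum_{i=1}^m P_i(a).}
#' The result is normalized by construction and keeps every target's
#' preferences while boosting tokens preferred by all.
#'
#' @param distributions A list of `m >= 1` numeric probability vectors of
#'   equal length, each normalized.
#' @return A numeric probability vector.
#' @export
fuse_distributions <- function(distributions) {
  stopifnot(is.list(distributions), length(distributions) >= 1L)
  len <- length(distributions[[1]])
  for (p in distributions) {
    if (!is.numeric(p) || length(p) != len) {
      stop("distributions to fuse have mismatched lengths", call. = FALSE)
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop("distributions to fuse must each be normalized and non-negative",
           call. = FALSE)
    }
  }
  Reduce(`+`, distributions) / length(distributions)
}

#' Multi-target fused policy
#'
#' Combines `m` target-conditioned policies sharing one vocabulary into a
#' single policy whose prediction is the mean-pooled distribution over the
#' per-target predictions, each member seeing its own protein sequence and
#' the shared fragment. Plugging the fused policy into the standard
#' ParetoPUCT score reproduces the multi-target selection criterion exactly:
#' the two differ only in the prior term.
#'
#' @param policies List of `m >= 1` [policy_model()]s with identical
#'   vocabularies.
#' @param proteins Character vector of `m` protein sequences, one per
#'   member.
#' @return A [policy_model()] whose context's protein entry is ignored in
#'   favour of the per-member proteins fixed here.
#' @export
fused_policy <- function(policies, proteins) {
  stopifnot(is.list(policies), length(policies) >= 1L)
  stopifnot(length(proteins) == length(policies))
  vocab <- policies[[1]]$vocabulary
  for (pol in policies) {
    stopifnot(inherits(pol, "policy_model"))
    if (!identical(pol$vocabulary, vocab)) {
      stop("fused policies must share one vocabulary", call. = FALSE)
    }
  }
  predict <- function(context) {
    dists <- purrr::imap(policies, function(pol, i) {
      ctx_i <- state_context(proteins[[i]], context$fragment)
      tryCatch(
        predict_tokens(pol, ctx_i),
        error = function(e) {
          stop("fused member ", i, " failed: ", conditionMessage(e),
               call. = FALSE)
        }
      )
    })
    fuse_distributions(dists)
  }
  policy_model(vocab, predict,
               name = paste0("fused(", length(policies), ")"))
}

#' Read / write a vocabulary file
#'
#' Plain text, one token per line, terminal symbol `"$"` last.
#'
#' @param path File path.
#' @return `read_vocabulary()` returns a character vector;
#'   `write_vocabulary()` returns `path` invisibly.
#' @export
read_vocabulary <- function(path) {
  vocab <- readLines(path, warn = FALSE)
  vocab <- vocab[nzchar(vocab)]
  if (length(vocab) == 0L || utils::tail(vocab, 1) != terminal_token()) {
    stop("vocabulary file ", path,
         " must end with the terminal symbol \"$\"", call. = FALSE)
  }
  vocab
}

#' @rdname read_vocabulary
#' @param vocabulary Character vector of tokens (terminal last).
#' @export
write_vocabulary <- function(vocabulary, path) {
  stopifnot(utils::tail(vocabulary, 1) == terminal_token())
  writeLines(vocabulary, path)
  invisible(path)
}

#' Read / write a tabular policy file
#'
#' Tab-separated text with columns `suffix`, `token`, `prob`.
#'
#' @param path File path.
#' @return `read_policy_table()` returns a tibble; `write_policy_table()`
#'   returns `path` invisibly.
#' @export
read_policy_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric"))
  tab$suffix[is.na(tab$suffix)] <- ""
  tibble::as_tibble(tab)
}

#' @rdname read_policy_table
#' @param table Data frame with columns `suffix`, `token`, `prob`.
#' @export
write_policy_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Adapter for an external autoregressive policy
#'
#' Wraps an external next-token predictor behind the [policy_model()]
#' contract. The descriptor names a prediction source plus a vocabulary
#' file; the vocabulary is validated at load time (terminal symbol present,
#' last in file) and the returned distribution is validated on every call.
#' An unavailable source is an explicit load-time error, never a silent
#' fallback.
#'
#' Two descriptor kinds are supported:
#' \describe{
#'   \item{`fn`}{An R function `(context) -> numeric` (e.g. a socket or
#'     subprocess client for a pretrained SMILES model).}
#'   \item{`table`}{Path to a tabular policy file (see
#'     [read_policy_table()]) — the self-hosting test fixture.}
#' }
#'
#' @param descriptor A list with `vocabulary_file` and exactly one of `fn`
#'   or `table`; optional `name` and `order` (for `table`).
#' @return A [policy_model()].
#' @export
external_policy <- function(descriptor) {
  stopifnot(is.list(descriptor))
  if (is.null(descriptor$vocabulary_file)) {
    stop("policy descriptor must name a vocabulary_file", call. = FALSE)
  }
  if (!file.exists(descriptor$vocabulary_file)) {
    stop("vocabulary file not found: ", descriptor$vocabulary_file,
         call. = FALSE)
  }
  vocab <- read_vocabulary(descriptor$vocabulary_file)
  name <- descriptor$name %||% "external"
  if (!is.null(descriptor$table)) {
    if (!file.exists(descriptor$table)) {
      stop("policy table not found: ", descriptor$table, call. = FALSE)
    }
    tab <- read_policy_table(descriptor$table)
    return(tabular_policy(tab, vocab, order = descriptor$order %||% 1L,
                          name = name))
  }
  if (!is.null(descriptor$fn)) {
    stopifnot(is.function(descriptor$fn))
    return(policy_model(vocab, descriptor$fn, name = name))
  }
  stop("policy descriptor must provide either 'fn' or 'table'", call. = FALSE)
}
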