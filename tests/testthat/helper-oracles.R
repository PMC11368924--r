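# Independent oracles: a naive O(n^2) non-dominated filter and a standalone
# scalar-PUCT searcher. Both deliberately avoid the package's internals so
# they can stand as cross-checks.

# Naive double-loop Pareto front: row i survives unless some row j is >= in
# every column and > in at least one.
naive_front <- function(h) {
  h <- as.matrix(h)
  n <- nrow(h)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ge <- TRUE
      gt <- FALSE
      for (k in seq_len(ncol(h))) {
        if (h[j, k] < h[i, k]) { ge <- FALSE; break }
        if (h[j, k] > h[i, k]) gt <- TRUE
      }
      if (ge && gt) { keep[i] <- FALSE; break }
    }
  }
  which(keep)
}

# Deterministic A -> B -> $ chain policy over the toy vocabulary.
chain_policy <- function() {
  tabular_policy(
    tibble::tibble(suffix = c("", "A", "B"),
                   token = c("A", "B", "$"),
                   prob = c(1, 1, 1)),
    c("A", "B", "$"), name = "chain"
  )
}

# Standalone single-objective PUCT molecule generator. Scalar statistics
# throughout: argmax selection (uniform draw on exact ties), a max-value
# pool, greedy rollout, most-visited move. Used as the d = 1 reference
# trajectory.
scalar_puct_generate <- function(scorer, vocab, config) {
  pool <- list(max = -Inf, tokens = character(0))
  pool_reward <- function(h) {
    if (length(pool$tokens) == 0L) return(1)
    as.numeric(h >= pool$max)
  }
  pool_offer <- function(h, tok) {
    if (tok %in% pool$tokens) return(invisible(NULL))
    if (h > pool$max) pool <<- list(max = h, tokens = tok)
    else if (h == pool$max) pool$tokens <<- c(pool$tokens, tok)
    invisible(NULL)
  }
  uniform <- rep(1 / length(vocab), length(vocab))
  names(uniform) <- vocab
  predict <- function(frag) uniform
  depth_of <- function(frag) sum(frag != "$")
  ends_term <- function(frag) length(frag) > 0 && frag[length(frag)] == "$"

  one_decision <- function(prefix) {
    root <- new.env()
    root$n <- 0L; root$w <- 0; root$kids <- NULL
    for (it in seq_len(config$iterations)) {
      node <- root
      frag <- prefix
      path <- list(root)
      while (!is.null(node$kids) && !ends_term(frag)) {
        u <- vapply(node$kids, function(k) {
          (if (k$n == 0L) 0 else k$w / k$n) +
            config$c * k$prior * sqrt(node$n) / (1 + k$n)
        }, numeric(1))
        cand <- which(u >= max(u))
        pick <- if (length(cand) == 1L) cand else
          cand[sample.int(length(cand), 1L)]
        node <- node$kids[[pick]]
        frag <- c(frag, node$token)
        path[[length(path) + 1L]] <- node
      }
      if (ends_term(frag)) {
        mol <- paste(frag, collapse = ""); complete <- TRUE
      } else {
        legal <- if (depth_of(frag) >= config$max_depth) "$" else vocab
        p <- predict(frag)
        if (length(legal) < length(vocab)) {
          p <- p[legal]
          p <- if (sum(p) > 0) p / sum(p) else
            stats::setNames(rep(1 / length(legal), length(legal)), legal)
        }
        node$kids <- lapply(seq_along(p), function(i) {
          e <- new.env(); e$token <- names(p)[i]; e$prior <- unname(p[i])
          e$n <- 0L; e$w <- 0; e$kids <- NULL; e
        })
        rfrag <- frag
        while (!ends_term(rfrag) && depth_of(rfrag) < config$max_depth) {
          q <- predict(rfrag)
          rfrag <- c(rfrag, names(q)[which.max(q)])
        }
        mol <- paste(rfrag, collapse = "")
        complete <- ends_term(rfrag)
      }
      r <- 0
      if (complete && mol != "$") {
        h <- scorer(mol)
        r <- pool_reward(h)
        pool_offer(h, mol)
      }
      for (nd in path) { nd$n <- nd$n + 1L; nd$w <- nd$w + r }
    }
    visits <- vapply(root$kids, function(k) k$n, integer(1))
    means <- vapply(root$kids, function(k) if (k$n == 0L) 0 else k$w / k$n,
                    numeric(1))
    toks <- vapply(root$kids, function(k) k$token, character(1))
    toks[order(-visits, -means, toks)[1]]
  }

  set.seed(config$seed)
  frag <- character(0)
  repeat {
    if (config$max_depth == 0L) return(list(tokens = NA, trajectory = frag))
    tok <- one_decision(frag)
    frag <- c(frag, tok)
    if (tok == "$") break
  }
  list(tokens = paste(frag, collapse = ""), trajectory = frag,
       pool = pool)
}
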