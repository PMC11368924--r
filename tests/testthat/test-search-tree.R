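toy <- toy_mdp(c("A", "B"), 3)
toy_objs <- toy$objectives
toy_pool <- function() pareto_pool(2, toy_objs$names)
cfg <- function(...) {
  args <- utils::modifyList(
    list(c = 1, iterations = 200L, max_depth = 3L, seed = 1L, d = 2L),
    list(...)
  )
  do.call(search_config, args)
}

fake_child <- function(N, W, prior) list(N = N, W = W, prior = prior)

test_that("ParetoPUCT score combines exploitation and prior-scaled exploration", {
  expect_equal(paretopuct_score(fake_child(0L, c(0, 0), 0.5), 1, 1),
               c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(paretopuct_score(fake_child(1L, c(0.5, 1.0), 0.5), 4, 1),
               c(1.0, 1.5), tolerance = 1e-12)
  expect_equal(paretopuct_score(fake_child(2L, c(1.0, 0.4), 0.9), 100, 0),
               c(0.5, 0.2), tolerance = 1e-12)
})

test_that("scalar UCB baseline follows the closed form", {
  expect_equal(ucb_score(fake_child(4L, 2, 1), 16), 0.5 + sqrt(2 * log(16) / 4),
               tolerance = 1e-12)
  expect_equal(ucb_score(fake_child(1L, 0, 1), 1), 0)
  for (n in c(2, 5, 17)) {
    expect_equal(ucb_score(fake_child(n, n, 1), n), 1 + sqrt(2 * log(n) / n))
  }
  expect_error(ucb_score(fake_child(0L, 0, 1), 4), "unvisited")
})

make_parent <- function(children) {
  parent <- new.env()
  parent$W <- children[[1]]$W
  parent$N <- sum(vapply(children, function(k) k$N, numeric(1)))
  parent$children <- lapply(children, function(k) {
    e <- new.env()
    e$N <- k$N; e$W <- k$W; e$prior <- k$prior; e$token <- k$token
    e
  })
  parent
}

test_that("selection draws uniformly from the Pareto front of score vectors", {
  # a strictly dominating child is always selected
  dom <- make_parent(list(
    list(N = 4L, W = c(4, 4), prior = 0.5, token = "A"),
    list(N = 4L, W = c(1, 1), prior = 0.5, token = "B")
  ))
  for (i in 1:20) {
    expect_identical(select_child(dom, dom$N, 0)$token, "A")
  }
  # single child: probability one
  single <- make_parent(list(list(N = 1L, W = c(1, 1), prior = 1, token = "A")))
  expect_identical(select_child(single, 1, 1)$token, "A")
  expect_error(select_child(paretomcts:::new_tree_node("A", d = 2L), 1, 1),
               "unexpanded")
  # two mutually non-dominated children split draws ~ binomially
  tied <- make_parent(list(
    list(N = 5L, W = c(5, 0), prior = 0.5, token = "A"),
    list(N = 5L, W = c(0, 5), prior = 0.5, token = "B")
  ))
  set.seed(99)
  picks <- vapply(1:10000, function(i) select_child(tied, tied$N, 1)$token,
                  character(1))
  expect_true(abs(sum(picks == "A") - 5000) < 200)
})

test_that("expansion initializes one child per legal token with normalized priors", {
  pol <- uniform_policy(toy$vocabulary)
  node <- paretomcts:::new_tree_node(NA_character_, d = 2L)
  expand_node(node, state_context("MKV"), pol)
  expect_length(node$children, 3L)
  priors <- vapply(node$children, `[[`, numeric(1), "prior")
  expect_equal(sum(priors), 1, tolerance = 1e-12)
  expect_true(all(vapply(node$children, `[[`, numeric(1), "N") == 0))
  # all-mass-on-one-token policy
  onehot <- policy_model(toy$vocabulary, function(ctx) c(0, 1, 0))
  n2 <- paretomcts:::new_tree_node(NA_character_, d = 2L)
  expand_node(n2, state_context("MKV"), onehot)
  expect_equal(vapply(n2$children, `[[`, numeric(1), "prior"),
               c(A = 0, B = 1, `$` = 0))
  # idempotent re-expansion
  before <- n2$children
  expand_node(n2, state_context("MKV"), onehot)
  expect_identical(n2$children, before)
  # depth-capped context: only the terminal symbol is legal, prior renormalized
  n3 <- paretomcts:::new_tree_node(NA_character_, d = 2L)
  expand_node(n3, state_context("MKV", c("A", "A", "A")), pol,
              legal = terminal_token())
  expect_length(n3$children, 1L)
  expect_equal(n3$children[["$"]]$prior, 1)
})

test_that("greedy rollout follows the argmax chain and flags depth caps", {
  out <- policy_rollout(state_context("MKV", "A"), chain_policy(), 10)
  expect_equal(out, list(tokens = "AB$", complete = TRUE))
  done <- policy_rollout(state_context("MKV", c("A", "$")), chain_policy(), 10)
  expect_equal(done, list(tokens = "A$", complete = TRUE))
  stuck <- policy_model(c("A", "B", "$"), function(ctx) c(1, 0, 0))
  capped <- policy_rollout(state_context("MKV"), stuck, 5)
  expect_equal(capped, list(tokens = "AAAAA", complete = FALSE))
})

test_that("backup increments every node on the path once and adds the reward", {
  fresh <- paretomcts:::new_tree_node("A", d = 2L)
  backup(list(fresh), c(0.2, 0.8))
  expect_equal(fresh$N, 1L)
  expect_equal(fresh$W, c(0.2, 0.8))
  node <- paretomcts:::new_tree_node("B", d = 2L)
  node$N <- 3L; node$W <- c(1, 1)
  backup(list(node), c(0, 1))
  expect_equal(node$N, 4L)
  expect_equal(node$W, c(1, 2))
  path <- replicate(4, paretomcts:::new_tree_node("A", d = 2L))
  backup(path, c(0.5, 0.5))
  expect_true(all(vapply(path, `[[`, integer(1), "N") == 1L))
})

test_that("search_token accounts iterations, is deterministic, and proposes a front token", {
  pol <- uniform_policy(toy$vocabulary)
  set.seed(1)
  st1 <- search_token(state_context("MKV"), pol, toy_objs, toy_pool(),
                      cfg(iterations = 1L))
  expect_equal(st1$root$N, 1L)
  expect_equal(st1$n_evaluated, 1L)
  set.seed(123)
  a <- search_token(state_context("MKV"), pol, toy_objs, toy_pool(),
                    cfg(iterations = 300L))
  set.seed(123)
  b <- search_token(state_context("MKV"), pol, toy_objs, toy_pool(),
                    cfg(iterations = 300L))
  expect_identical(a$token, b$token)
  expect_identical(a$pool$tokens, b$pool$tokens)
  # with a solid budget the move starts a Pareto-optimal molecule
  set.seed(7)
  st <- search_token(state_context("MKV"), pol, toy_objs, toy_pool(),
                     cfg(iterations = 500L))
  front_first <- unique(substr(brute_force_front(toy)$tokens, 1, 1))
  expect_true(st$token %in% front_first)
})

walk_tree <- function(node, fn) {
  fn(node)
  for (child in node$children) walk_tree(child, fn)
}

test_that("visit counts are conserved and rewards bounded at every node", {
  pol <- uniform_policy(toy$vocabulary)
  for (seed in 1:3) {
    set.seed(seed)
    st <- search_token(state_context("MKV"), pol, toy_objs, toy_pool(),
                       cfg(iterations = 400L))
    expect_equal(st$root$N, 400L)
    walk_tree(st$root, function(node) {
      kid_sum <- sum(vapply(node$children, `[[`, integer(1), "N"), 0L)
      expect_gte(node$N, kid_sum)
      expect_true(all(node$W >= -1e-12))
      expect_true(all(node$W <= node$N + 1e-12))
    })
  }
})

test_that("generation returns the chain molecule, fails on zero depth, and is reproducible", {
  res <- generate_molecule("MKV", chain_policy(), toy_objs, cfg(seed = 5L))
  expect_equal(res$status, "ok")
  expect_equal(res$record$tokens, "AB$")
  expect_true("AB$" %in% res$pool$tokens)
  res0 <- generate_molecule("MKV", chain_policy(), toy_objs,
                            cfg(max_depth = 0L))
  expect_equal(res0$status, "failed")
  expect_equal(pool_size(res0$pool), 0L)
  again <- generate_molecule("MKV", chain_policy(), toy_objs, cfg(seed = 5L))
  expect_identical(res$record, again$record)
  expect_identical(res$pool$tokens, again$pool$tokens)
})

test_that("tidy, glance and autoplot expose the run as tables and a figure", {
  res <- generate_molecule("MKV", uniform_policy(toy$vocabulary), toy_objs,
                           cfg(seed = 2L, iterations = 300L))
  tb <- tidy(res)
  expect_s3_class(tb, "tbl_df")
  expect_true(all(c("tokens", "countA", "countB") %in% names(tb)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$pool_size, pool_size(res$pool))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("single-objective search reproduces the scalar PUCT reference trajectory", {
  objs1 <- objective_set(token_count_objective("A"))
  pol <- uniform_policy(c("A", "B", "$"))
  for (seed in c(2L, 11L, 29L)) {
    config <- search_config(c = 1, iterations = 150L, max_depth = 3L,
                            seed = seed, d = 1L)
    mine <- generate_molecule("MKV", pol, objs1, config)
    ref <- scalar_puct_generate(function(tok) {
      lengths(regmatches(tok, gregexpr("A", tok, fixed = TRUE)))
    }, c("A", "B", "$"), config)
    expect_identical(mine$record$tokens, ref$tokens)
  }
})

test_that("exploration recovers more of the front than pure exploitation under a deceptive prior", {
  dec <- make_deceptive_policy(toy, "A")
  front <- brute_force_front(toy)$tokens
  coverage <- function(cc, seed) {
    set.seed(seed)
    st <- search_token(state_context("MKV"), dec, toy_objs, toy_pool(),
                       cfg(c = cc, iterations = 400L, seed = seed))
    length(intersect(st$pool$tokens, front)) / length(front)
  }
  seeds <- 1:20
  cov1 <- vapply(seeds, function(s) coverage(1, s), numeric(1))
  cov0 <- vapply(seeds, function(s) coverage(0, s), numeric(1))
  expect_gt(mean(cov1), mean(cov0))
})

test_that("a shared pool persists across collected runs and stays non-dominated", {
  pol <- uniform_policy(toy$vocabulary)
  res <- collect_molecules("MKV", pol, toy_objs, cfg(iterations = 150L),
                           n = 3L, share_pool = TRUE)
  expect_lte(nrow(res$records), 3L)
  n <- pool_size(res$pool)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a != b) {
        expect_false(dominates(res$pool$h[a, ], res$pool$h[b, ]) == "strict")
      }
    }
  }
})
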