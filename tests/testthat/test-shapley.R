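# Shapley machinery: exact subset-weighted computation, the
# permutation-sampling estimator, SPA, caching and the game axioms.

test_that("exact Shapley values recover the canonical closed forms", {
  games <- canonical_games()
  for (nm in names(games)) {
    gm <- games[[nm]]
    tbl <- exact_shapley(game_from_canonical(gm))
    expect_equal(stats::setNames(tbl$gamma[match(gm$elements, tbl$element)],
                                 gm$elements),
                 gm$closed_form_shapley, tolerance = 1e-12)
  }
})

test_that("marginal contributions follow v(S + i) - v(S)", {
  games <- canonical_games()
  add <- game_from_canonical(games$additive)
  for (S in list(character(0), "a", c("a", "c"))) {
    expect_equal(marginal_contribution(add, "b", S), 2)
  }
  expect_error(marginal_contribution(add, "a", c("a", "b")), "already in")
  un <- game_from_canonical(games$unanimity)
  expect_equal(marginal_contribution(un, "a", "b"), 1)
  expect_equal(marginal_contribution(un, "a", character(0)), 0)
  gl <- game_from_canonical(games$glove)
  expect_equal(marginal_contribution(gl, "L", "R1"), 1)
})

test_that("exact computation equals full ordering enumeration on random games", {
  set.seed(1)
  sizes <- sample(rep(2:8, times = c(8, 8, 8, 8, 4, 2, 2)))
  for (k in seq_along(sizes)) {
    n <- sizes[k]
    vv <- random_game_table(n, seed = 1000 + k)
    els <- paste0("e", seq_len(n))
    tbl <- exact_shapley(game_from_table(els, vv))
    expect_equal(tbl$gamma[match(els, tbl$element)], brute_shapley(vv, n),
                 tolerance = 1e-9)
  }
})

test_that("the sampled estimator is exact for additive games and telescopes", {
  add <- game_from_canonical(canonical_games()$additive)
  tbl <- sampled_shapley(add, n_permutations = 23, seed = 5, ci = FALSE)
  expect_equal(stats::setNames(tbl$gamma[match(c("a", "b", "c"), tbl$element)],
                               c("a", "b", "c")),
               c(a = 1, b = 2, c = 3))
  contrib <- attr(tbl, "contributions")
  v_span <- attr(tbl, "v_grand") - attr(tbl, "v_empty")
  expect_equal(unname(rowSums(contrib)), rep(v_span, nrow(contrib)))

  gl <- game_from_canonical(canonical_games()$glove)
  tbl_gl <- sampled_shapley(gl, n_permutations = 1000, seed = 7)
  expect_lt(abs(tbl_gl$gamma[tbl_gl$element == "L"] - 2 / 3), 0.05)
  expect_true(all(tbl_gl$ci_low <= tbl_gl$gamma & tbl_gl$gamma <= tbl_gl$ci_high))
  expect_equal(tbl_gl$gamma, unname(colMeans(attr(tbl_gl, "contributions"))[
    match(tbl_gl$element, colnames(attr(tbl_gl, "contributions")))]),
    tolerance = 1e-12)
})

test_that("null players get exactly zero in both estimators", {
  # element "d" never referenced by v
  els <- c("a", "b", "d")
  vfun <- function(S) as.numeric(all(c("a", "b") %in% S))
  g1 <- coalition_game(els, function(S, rep) vfun(S))
  expect_identical(exact_shapley(g1)$gamma[exact_shapley(g1)$element == "d"], 0)
  g2 <- coalition_game(els, function(S, rep) vfun(S))
  tbl <- sampled_shapley(g2, n_permutations = 200, seed = 3, ci = FALSE)
  expect_identical(tbl$gamma[tbl$element == "d"], 0)
})

test_that("symmetric elements get equal values", {
  gl <- game_from_canonical(canonical_games()$glove)
  tbl <- exact_shapley(gl)
  expect_equal(tbl$gamma[tbl$element == "R1"], tbl$gamma[tbl$element == "R2"])
  s <- sampled_shapley(gl, n_permutations = 1000, seed = 11, ci = FALSE)
  contrib <- attr(s, "contributions")
  se <- sqrt(stats::var(contrib[, "R1"] - contrib[, "R2"]) / nrow(contrib))
  expect_lt(abs(s$gamma[s$element == "R1"] - s$gamma[s$element == "R2"]),
            max(3 * se, 1e-12))
})

test_that("the sampled estimator is consistent with the exact value", {
  gm <- canonical_games()$glove
  vv <- value_table(gm$elements, gm$value_fn)
  exact <- brute_shapley(vv, 3)
  est <- sapply(1:50, function(s) {
    tbl <- sampled_shapley(game_from_canonical(gm), n_permutations = 60,
                           seed = s, ci = FALSE)
    tbl$gamma[match(gm$elements, tbl$element)]
  })
  # mean over 50 independent seeds within 0.01 * range(v) of the exact value
  expect_true(all(abs(rowMeans(est) - exact) <= 0.01 * diff(range(vv))))
})

test_that("Shapley values are linear over games", {
  g1 <- canonical_games()$unanimity
  g2 <- canonical_games()$additive
  sum_game <- coalition_game(g1$elements, function(S, rep) {
    g1$value_fn(S) + g2$value_fn(S)
  })
  t_sum <- exact_shapley(sum_game)
  t1 <- exact_shapley(game_from_canonical(g1))
  t2 <- exact_shapley(game_from_canonical(g2))
  m <- function(tbl) tbl$gamma[match(g1$elements, tbl$element)]
  expect_equal(m(t_sum), m(t1) + m(t2), tolerance = 1e-12)
})

test_that("coalition caching is sound and counts evaluations once", {
  g <- make_motif_genome()
  task <- task_spec(T = 40)
  game <- lesion_game(g, task, "connections", plays_per_eval = 2, seed = 9)
  v1 <- game_value(game, game$elements)
  n_eval <- game$env$eval_count
  v2 <- game_value(game, game$elements)
  expect_identical(v1, v2)
  expect_identical(game$env$eval_count, n_eval)

  nocache <- lesion_game(g, task, "connections", plays_per_eval = 2, seed = 9)
  nocache$use_cache <- FALSE
  tbl_c <- sampled_shapley(game, n_permutations = 8, seed = 2, ci = FALSE)
  tbl_n <- sampled_shapley(nocache, n_permutations = 8, seed = 2, ci = FALSE)
  expect_identical(tbl_c$gamma, tbl_n$gamma)
  expect_gt(nocache$env$eval_count, game$env$eval_count)
})

test_that("lesion-game values tie out against the protocol runner", {
  g <- make_motif_genome()
  task <- task_spec()
  game <- lesion_game(g, task, "connections", plays_per_eval = 3, seed = 31)
  # v(N) replicate r is definitionally the mean of trial r's plays
  pr <- protocol_spec(n_trials = 2, plays_per_trial = 3, seed = 31)
  expect_equal(game_value(game, game$elements, rep = 1),
               run_protocol(g, task, pr)[1])
  # v(N \ {0->0}) shows the single-lesion deficit of the self-loop
  expect_lte(game_value(game, setdiff(game$elements, "0->0")),
             0.3 * max_score(task))
})

test_that("SPA isolates single-element effects on the motif", {
  g <- make_motif_genome()
  task <- task_spec()
  mx <- max_score(task)
  game <- lesion_game(g, task, "connections", plays_per_eval = 2, seed = 13)
  res <- spa(game, n_trials = 8)
  eff <- stats::setNames(res$effect, res$element)
  expect_lte(eff[["0->0"]], -0.5 * mx)
  expect_lt(abs(eff[["-4->0"]]), 0.05 * mx)
  ng <- lesion_game(g, task, "nodes", plays_per_eval = 2, seed = 13)
  resn <- spa(ng, n_trials = 8)
  expect_lt(abs(resn$effect[resn$element == "0"]), 0.05 * mx)
  expect_length(attr(res, "distributions")[["0->0"]], 8)
})

test_that("shapley_fraction truncates the percentage share toward zero", {
  expect_identical(shapley_fraction(80, 337), 23L)
  expect_identical(shapley_fraction(-80, 337), -23L)
  expect_identical(shapley_fraction(0, 337), 0L)
  expect_identical(shapley_fraction(337, 337), 100L)
  expect_error(shapley_fraction(1, 0), "non-zero")
})

test_that("exact computation refuses oversized games", {
  els <- paste0("e", 1:13)
  g <- coalition_game(els, function(S, rep) length(S))
  expect_error(exact_shapley(g), "sampled_shapley")
})

test_that("game files round-trip canonical games through the same interface", {
  gm <- canonical_games()$glove
  path <- withr::local_tempfile(fileext = ".json")
  write_game_file(gm, path)
  game <- read_game_file(path)
  tbl <- exact_shapley(game)
  expect_equal(stats::setNames(tbl$gamma[match(gm$elements, tbl$element)],
                               gm$elements),
               gm$closed_form_shapley, tolerance = 1e-12)
  expect_error(read_game_file(file.path(tempdir(), "missing.json")), "not found")
})
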