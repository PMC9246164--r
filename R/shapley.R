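# Coalition games over network elements and Shapley value estimation.
#
# A coalition game maps a subset S of "intact" elements to the performance
# v(S) of the system with every element NOT in S lesioned. The grand
# coalition v(N) is the intact system; v(empty) is the fully lesioned
# baseline. Stochastic games draw their replicate stream deterministically
# from (game seed, frozen S, replicate index), so revisiting a coalition
# returns the identical value - this makes the per-permutation telescoping
# sum exact and makes caching sound.

#' Construct a coalition game
#'
#' @param elements Character vector of element ids (the player set N).
#' @param value_fn Function `(subset, rep)` returning the worth of the
#'   intact-subset `subset` (character vector); `rep` is an integer
#'   replicate index (ignored by deterministic games).
#' @param stochastic Logical; whether distinct replicate indices may return
#'   different values.
#' @param cache Logical; memoize evaluations by `(subset, rep)`.
#' @param label Optional game name.
#' @return A `coalition_game` object with evaluation counters
#'   (`eval_count`, `unique_coalitions`).
#' @seealso [lesion_game()], [game_value()], [exact_shapley()],
#'   [sampled_shapley()]
#' @export
coalition_game <- function(elements, value_fn, stochastic = FALSE,
                           cache = TRUE, label = "game") {
  elements <- as.character(elements)
  stopifnot(length(elements) >= 1, !anyDuplicated(elements), is.function(value_fn))
  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv())
  env$seen <- new.env(parent = emptyenv())
  env$eval_count <- 0L
  env$unique_coalitions <- 0L
  structure(
    list(elements = elements, value_fn = value_fn, stochastic = stochastic,
         use_cache = cache, label = label, env = env),
    class = "coalition_game"
  )
}

#' @export
print.coalition_game <- function(x, ...) {
  cat(sprintf("<coalition_game '%s': %d elements, %s, %d evaluations (%d unique coalitions)>\n",
              x$label, length(x$elements),
              if (x$stochastic) "stochastic" else "deterministic",
              x$env$eval_count, x$env$unique_coalitions))
  invisible(x)
}

coalition_key <- function(S) paste(sort(S), collapse = ",")

#' Evaluate the characteristic function
#'
#' Returns `v(S)`, the system's worth with every element outside `S`
#' lesioned. Results are memoized per `(S, rep)`; repeated evaluation of
#' the same coalition with the same replicate index is free and returns
#' the identical value.
#'
#' @param game A `coalition_game`.
#' @param S Character vector, subset of `game$elements` (the intact set).
#' @param rep Integer replicate index selecting the noise stream.
#' @return Scalar worth.
#' @export
game_value <- function(game, S, rep = 0L) {
  S <- as.character(S)
  if (length(bad <- setdiff(S, game$elements))) {
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  }
  skey <- paste0("S:", coalition_key(S))
  key <- paste0(skey, "#", rep)
  if (game$use_cache && !is.null(v <- game$env$cache[[key]])) return(v)
  v <- game$value_fn(S, rep)
  stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  game$env$eval_count <- game$env$eval_count + 1L
  if (is.null(game$env$seen[[skey]])) {
    game$env$seen[[skey]] <- TRUE
    game$env$unique_coalitions <- game$env$unique_coalitions + 1L
  }
  if (game$use_cache) game$env$cache[[key]] <- v
  v
}

#' Coalition game induced by lesioning a network on the surrogate task
#'
#' Elements are either all node ids or the enabled-connection keys of the
#' pruned genome. `v(S)` is the mean score of `plays_per_eval` episodes of
#' the network with all elements not in `S` lesioned (node elements expand
#' to [node_lesion_mask()]); `v(N)` is intact performance. Episode noise
#' streams derive from `(seed, S, rep)`, so the game is reproducible and
#' cache-consistent.
#'
#' @param genome A `lesion_genome` (pruned internally).
#' @param task A [task_spec()].
#' @param granularity `"connections"` or `"nodes"`.
#' @param plays_per_eval Episodes averaged per coalition evaluation
#'   (default 16, the per-trial play count of the study protocol).
#' @param seed Integer base seed for all episode noise.
#' @return A stochastic `coalition_game`.
#' @examples
#' game <- lesion_game(make_motif_genome(), task_spec(), "connections",
#'                     plays_per_eval = 2, seed = 1)
#' game_value(game, game$elements)            # intact performance
#' game_value(game, setdiff(game$elements, "0->0"))
#' @export
lesion_game <- function(genome, task, granularity = c("connections", "nodes"),
                        plays_per_eval = 16L, seed = 1L) {
  granularity <- match.arg(granularity)
  g <- prune_disabled(genome)
  factory <- make_plan_factory(g)
  if (granularity == "connections") {
    en <- g$connections
    elements <- conn_key(en$source, en$target)
    keys_of <- lapply(elements, function(e) e)
  } else {
    elements <- as.character(sort(g$nodes$id))
    keys_of <- lapply(elements, function(e) {
      node_lesion_mask(g, as.integer(e))$disabled_connections
    })
  }
  names(keys_of) <- elements
  value_fn <- function(S, rep) {
    lesioned <- setdiff(elements, S)
    mask_keys <- unique(unlist(keys_of[lesioned], use.names = FALSE))
    seeds <- episode_seeds_for(seed, mask_keys, rep, plays_per_eval)
    mean(score_batch(g, task, NULL, seeds, plan = factory(mask_keys)))
  }
  game <- coalition_game(elements, value_fn, stochastic = TRUE,
                         label = paste0("lesion:", granularity))
  game$genome <- g
  game$task <- task
  game$granularity <- granularity
  game$plays_per_eval <- as.integer(plays_per_eval)
  game$seed <- as.integer(seed)
  game
}

#' Marginal contribution of an element to a coalition
#'
#' @param game A `coalition_game`.
#' @param i Element id, not in `S`.
#' @param S Character vector of intact elements.
#' @param rep Replicate index.
#' @return `v(S + i) - v(S)`.
#' @export
marginal_contribution <- function(game, i, S, rep = 0L) {
  if (i %in% S) stop("element '", i, "' is already in the coalition")
  game_value(game, c(S, i), rep) - game_value(game, S, rep)
}

shapley_table <- function(element, gamma, ci_low, ci_high, n_permutations,
                          contributions, v_grand, v_empty, method) {
  df <- data.frame(element = element, gamma = gamma, ci_low = ci_low,
                   ci_high = ci_high, n_permutations = n_permutations,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$gamma), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df, class = c("shapley_table", "data.frame"),
            contributions = contributions, v_grand = v_grand,
            v_empty = v_empty, method = method)
}

#' Exact Shapley values by subset enumeration
#'
#' Computes `gamma_i = sum over S not containing i of
#' |S|! (n-|S|-1)! / n! * (v(S+i) - v(S))`, which is algebraically equal to
#' averaging marginal contributions over all `n!` element orderings. The
#' full subset lattice is evaluated once, so the cost is `2^n` coalition
#' evaluations.
#'
#' @param game A `coalition_game`; stochastic games are evaluated at
#'   replicate 0 (their frozen replicate-averaged value).
#' @param exact_limit Refuse games larger than this (default 12, i.e. 4096
#'   subsets); use [sampled_shapley()] beyond it.
#' @return A `shapley_table` data.frame (element, gamma, ci bounds, rank)
#'   with per-subset weighted marginals in `attr(, "contributions")`.
#' @examples
#' gl <- canonical_games()$glove
#' game <- coalition_game(gl$elements, function(S, rep) gl$value_fn(S))
#' exact_shapley(game) # 2/3, 1/6, 1/6
#' @export
exact_shapley <- function(game, exact_limit = 12L) {
  n <- length(game$elements)
  if (n > exact_limit) {
    stop("exact Shapley computation is capped at n = ", exact_limit,
         " elements (", 2^exact_limit, " subsets); use sampled_shapley()")
  }
  els <- game$elements
  # v over the full lattice, indexed by bitmask + 1
  v <- vapply(0:(2^n - 1), function(m) {
    game_value(game, els[bitwAnd(m, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  sizes <- vapply(0:(2^n - 1), function(m) sum(bitwAnd(m, 2^(seq_len(n) - 1)) > 0), integer(1))
  # |S|!(n-|S|-1)!/n! weight; the grand coalition never occurs as an S
  w <- numeric(2^n)
  w[sizes < n] <- factorial(sizes[sizes < n]) *
    factorial(n - sizes[sizes < n] - 1) / factorial(n)
  gamma <- numeric(n)
  contribs <- vector("list", n)
  for (i in seq_len(n)) {
    bit <- 2^(i - 1)
    without <- which(bitwAnd(0:(2^n - 1), bit) == 0)  # masks of S not containing i
    delta <- v[without + bit] - v[without]
    wi <- w[without]
    gamma[i] <- sum(wi * delta)
    contribs[[i]] <- structure(delta, weights = wi)
  }
  names(contribs) <- els
  shapley_table(els, gamma, ci_low = gamma, ci_high = gamma,
                n_permutations = NA_integer_, contributions = contribs,
                v_grand = v[2^n], v_empty = v[1], method = "exact")
}

#' Permutation-sampling Shapley estimator (MSA)
#'
#' Draws `n_permutations` uniform random orderings of the element set
#' (with replacement) and, for each ordering, walks the prefix chain
#' computing `Delta_i = v(S_i + i) - v(S_i)` where `S_i` is the set
#' preceding element `i`. Coalition values along the walk are cached, so
#' each ordering costs at most `n + 1` distinct evaluations, and the
#' per-ordering marginals telescope exactly to `v(N) - v(empty)`. The
#' Shapley estimate is the mean over orderings; confidence intervals are
#' percentile bootstrap intervals of that mean.
#'
#' @param game A `coalition_game`.
#' @param n_permutations Number of sampled orderings (study default 1000).
#' @param seed Integer seed for the ordering draw.
#' @param ci Logical; attach bootstrap CIs.
#' @param n_boot Bootstrap resamples for the CI (default 10000).
#' @param level CI level (default 0.95).
#' @return A `shapley_table` with the per-permutation contribution samples
#'   in `attr(, "contributions")` (a `n_permutations x n` matrix) and the
#'   number of unique coalitions evaluated in `attr(, "unique_coalitions")`.
#' @export
sampled_shapley <- function(game, n_permutations = 1000L, seed = 1L,
                            ci = TRUE, n_boot = 10000L, level = 0.95) {
  stopifnot(n_permutations >= 1)
  els <- game$elements
  n <- length(els)
  contrib <- matrix(NA_real_, nrow = n_permutations, ncol = n,
                    dimnames = list(NULL, els))
  perms <- with_seed(seed, {
    lapply(seq_len(n_permutations), function(p) sample.int(n))
  })
  for (p in seq_len(n_permutations)) {
    ord <- perms[[p]]
    prefix <- character(0)
    v_prev <- game_value(game, prefix)
    for (i in ord) {
      nxt <- c(prefix, els[i])
      v_nxt <- game_value(game, nxt)
      contrib[p, i] <- v_nxt - v_prev
      prefix <- nxt
      v_prev <- v_nxt
    }
  }
  gamma <- colMeans(contrib)
  if (ci) {
    cis <- vapply(seq_len(n), function(i) {
      percentile_ci(contrib[, i], level = level, n_boot = n_boot,
                    seed = derive_seed(seed, "ci", els[i]))
    }, numeric(2))
    lo <- cis[1, ]; hi <- cis[2, ]
  } else {
    lo <- hi <- rep(NA_real_, n)
  }
  tbl <- shapley_table(els, gamma, lo, hi, n_permutations = n_permutations,
                       contributions = contrib,
                       v_grand = game_value(game, els),
                       v_empty = game_value(game, character(0)),
                       method = "sampled")
  attr(tbl, "unique_coalitions") <- game$env$unique_coalitions
  tbl
}

#' Single-element perturbation analysis (SPA)
#'
#' Lesions one element at a time: for each element `i` the game is
#' evaluated at `N - {i}` over `n_trials` replicates and compared with the
#' intact distribution `v(N)`. The effect is
#' `mean(lesioned) - mean(intact)`, so a deficit is negative.
#'
#' @param game A `coalition_game`.
#' @param n_trials Replicates per condition (study default 512).
#' @return An `spa_result` data.frame (element, mean_intact, mean_lesioned,
#'   effect) carrying the per-element score distributions in
#'   `attr(, "distributions")` and the intact distribution in
#'   `attr(, "intact")`.
#' @export
spa <- function(game, n_trials = 512L) {
  els <- game$elements
  reps <- seq_len(n_trials)
  intact <- vapply(reps, function(r) game_value(game, els, rep = r), numeric(1))
  dists <- lapply(els, function(e) {
    vapply(reps, function(r) game_value(game, setdiff(els, e), rep = r), numeric(1))
  })
  names(dists) <- els
  df <- data.frame(
    element = els,
    mean_intact = mean(intact),
    mean_lesioned = vapply(dists, mean, numeric(1)),
    stringsAsFactors = FALSE
  )
  df$effect <- df$mean_lesioned - df$mean_intact
  rownames(df) <- NULL
  structure(df, class = c("spa_result", "data.frame"),
            distributions = dists, intact = intact, n_trials = n_trials)
}

#' Shapley value as an integer percentage of total performance
#'
#' Expresses an element's Shapley value as the integer part (truncation
#' toward zero) of its percentage share of the grand coalition's worth:
#' with a total performance of 337, a Shapley value of 80 accounts for 23%
#' of the performance, and a value of -80 for -23%.
#'
#' @param gamma Shapley value, in the units of `v`.
#' @param v_total Total (grand coalition) performance; non-zero.
#' @return Integer percent.
#' @examples
#' shapley_fraction(80, 337)  # 23
#' @export
shapley_fraction <- function(gamma, v_total) {
  if (v_total == 0) stop("total performance must be non-zero")
  as.integer(trunc(100 * gamma / v_total))
}

game_file_key <- function(S) if (length(S)) coalition_key(S) else "()"

#' Read a coalition game from a game-file
#'
#' A game-file is a JSON object with an `elements` array and a `values`
#' object mapping comma-separated sorted subsets (`"()"` for the empty
#' set) to worths. It lets the analysis commands run on canonical games
#' without a network.
#'
#' @param path JSON file path.
#' @return A deterministic `coalition_game`.
#' @export
read_game_file <- function(path) {
  if (!file.exists(path)) stop("game file not found: ", path)
  j <- jsonlite::fromJSON(path)
  values <- unlist(j$values)
  if (!"()" %in% names(values)) stop("game file must define the empty coalition \"()\"")
  value_fn <- function(S, rep) {
    idx <- match(game_file_key(S), names(values))
    if (is.na(idx)) {
      stop("game file defines no value for coalition {", coalition_key(S), "}")
    }
    as.numeric(values[[idx]])
  }
  coalition_game(as.character(j$elements), value_fn, stochastic = FALSE,
                 label = j$name %||% basename(path))
}

#' Rank comparison between SPA and MSA
#'
#' SPA ranks ascending by effect (rank 1 = most deleterious single lesion);
#' MSA ranks descending by Shapley value (rank 1 = largest contribution).
#'
#' @param spa_result An [spa()] result.
#' @param shapley_tbl A `shapley_table` over the same elements.
#' @return data.frame with element, spa_rank, msa_rank, rank_difference.
#' @export
rank_comparison <- function(spa_result, shapley_tbl) {
  stopifnot(setequal(spa_result$element, shapley_tbl$element))
  spa_rank <- rank(spa_result$effect, ties.method = "first")
  msa_rank <- rank(-shapley_tbl$gamma, ties.method = "first")
  df <- data.frame(
    element = spa_result$element,
    spa_rank = spa_rank,
    msa_rank = msa_rank[match(spa_result$element, shapley_tbl$element)]
  )
  df$rank_difference <- df$msa_rank - df$spa_rank
  df[order(df$msa_rank), ]
}
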