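# Synthetic ground-truth environment.
#
# The bundled task is a winner-take-all surrogate for an arcade-game score:
# at every timestep the network chooses the output node with the highest
# activation, and earns `reward_per_hit` points whenever the chosen action
# equals `target_action`. The stimulus contains a pair of anticorrelated
# channels (a slowly decaying oscillation and its complement plus noise),
# emulating the statistical structure that drives the paradoxical-lesion
# motif; the remaining channels are iid Uniform[0, 1] distractors.

#' Task specification for the surrogate game
#'
#' @param T Timesteps per episode (default 200).
#' @param reward_per_hit Points per timestep on which the target action is
#'   chosen (default 10), so the maximum episode score is `reward_per_hit * T`.
#' @param target_action Output id counted as a hit (default 4).
#' @param noise_sd Gaussian noise sd added to the anticorrelated channel
#'   (default 0.05), on the unit activity scale.
#' @param seed Integer RNG seed for stimulus generation.
#' @return A `task_spec` list.
#' @export
task_spec <- function(T = 200L, reward_per_hit = 10, target_action = 4L,
                      noise_sd = 0.05, seed = 42L) {
  stopifnot(T >= 1, reward_per_hit > 0, noise_sd >= 0)
  structure(
    list(T = as.integer(T), reward_per_hit = reward_per_hit,
         target_action = as.integer(target_action),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "task_spec"
  )
}

#' Lesion-experiment protocol
#'
#' The default protocol mirrors the study convention of 512 trials of 16
#' plays each: a trial's score is the mean of its plays, yielding a
#' distribution of `n_trials` scores per lesion experiment.
#'
#' @param n_trials Number of trials (default 512).
#' @param plays_per_trial Episodes averaged per trial (default 16).
#' @param seed Integer seed from which all per-play streams derive.
#' @return A `protocol_spec` list.
#' @export
protocol_spec <- function(n_trials = 512L, plays_per_trial = 16L, seed = 1L) {
  stopifnot(n_trials >= 1, plays_per_trial >= 1)
  structure(
    list(n_trials = as.integer(n_trials),
         plays_per_trial = as.integer(plays_per_trial),
         seed = as.integer(seed)),
    class = "protocol_spec"
  )
}

#' Construct an input series
#'
#' @param values Numeric matrix, one row per timestep, columns named by
#'   input node ids.
#' @return An `input_series` matrix.
#' @export
input_series <- function(values) {
  m <- as.matrix(values)
  if (is.null(colnames(m))) stop("input series columns must be named by input ids")
  if (any(!is.finite(m))) stop("input series must be finite")
  structure(m, class = c("input_series", "matrix"))
}

#' @export
as.matrix.input_series <- function(x, ...) {
  attr(x, "class") <- NULL
  x
}

# The decaying oscillation driving channel -1; 0-based timestep index.
# Time constants scale with T so the signal shape is episode-length
# invariant: the envelope decays over ~T/6 steps with a period of T/5.
decaying_oscillation <- function(T) {
  t0 <- seq_len(T) - 1
  exp(-t0 / (T / 6)) * (0.5 + 0.5 * sin(2 * pi * t0 / (T / 5)))
}

#' Generate the task stimulus
#'
#' Channel `-1` carries a slowly decaying oscillation `s(t)` in `[0, 1]`;
#' its anticorrelated partner (channel `-4` when at least four inputs are
#' present, otherwise the most negative id) carries `1 - s(t)` plus
#' Gaussian noise clipped to `[0, 1]`; all remaining channels are iid
#' Uniform[0, 1]. Deterministic given `spec$seed`.
#'
#' @param spec A [task_spec()].
#' @param n_inputs Number of input channels (ids `-1 ... -n_inputs`); at
#'   least 2.
#' @param seed Overrides `spec$seed` when given.
#' @return An [input_series()] of dimension `T x n_inputs`.
#' @examples
#' xs <- generate_inputs(task_spec(noise_sd = 0), n_inputs = 4)
#' cor(xs[, "-1"], xs[, "-4"]) # exactly -1
#' @export
generate_inputs <- function(spec, n_inputs, seed = spec$seed) {
  stopifnot(inherits(spec, "task_spec"), n_inputs >= 2)
  T <- spec$T
  partner <- if (n_inputs >= 4) 4L else as.integer(n_inputs)
  with_seed(seed, {
    m <- matrix(0, nrow = T, ncol = n_inputs,
                dimnames = list(NULL, as.character(-seq_len(n_inputs))))
    s <- decaying_oscillation(T)
    m[, "-1"] <- s
    m[, as.character(-partner)] <-
      pmin(pmax(1 - s + stats::rnorm(T, 0, spec$noise_sd), 0), 1)
    rest <- setdiff(seq_len(n_inputs), c(1L, partner))
    for (j in rest) m[, as.character(-j)] <- stats::runif(T)
    input_series(m)
  })
}

#' Noise-as-input control stimulus
#'
#' Control condition in which the network is fed iid Uniform[0, 1] values on
#' every channel instead of the structured stimulus, destroying the
#' anticorrelated drive while leaving the architecture untouched.
#'
#' @inheritParams generate_inputs
#' @return An [input_series()].
#' @export
noise_input_control <- function(spec, n_inputs, seed = spec$seed) {
  stopifnot(inherits(spec, "task_spec"), n_inputs >= 1)
  with_seed(seed, {
    m <- matrix(stats::runif(spec$T * n_inputs), nrow = spec$T,
                dimnames = list(NULL, as.character(-seq_len(n_inputs))))
    input_series(m)
  })
}

#' Weight-shuffled control network
#'
#' Permutes the weights of the enabled connections uniformly at random
#' among themselves. Topology, biases and enabled flags are unchanged and
#' the multiset of weights is preserved.
#'
#' @param genome A `lesion_genome` with at least 2 enabled connections.
#' @param seed Integer seed.
#' @return A new `lesion_genome`.
#' @export
weight_shuffle_control <- function(genome, seed) {
  validate_genome(genome)
  en <- which(genome$connections$enabled)
  if (length(en) < 2) stop("weight shuffling needs at least 2 enabled connections")
  g <- genome
  perm <- with_seed(seed, sample(length(en)))
  g$connections$weight[en] <- g$connections$weight[en][perm]
  g$metadata$control <- "weight_shuffled"
  g
}

genome_n_inputs <- function(genome) sum(genome$nodes$role == "input")

# Shared replicate-stream convention: episode seeds depend only on the base
# seed, the canonical (sorted) set of masked connection keys, and the
# replicate index. run_protocol() trials and lesion_game() evaluations of
# the corresponding coalition therefore use identical noise streams.
episode_seeds_for <- function(seed, mask_keys, rep, n_plays) {
  base <- derive_seed(seed, paste(sort(mask_keys), collapse = ","), rep)
  as.integer((as.numeric(base) * 69621 +
                seq_len(n_plays) * 1013904223) %% 2147483647)
}

# Score a batch of episodes. inputs_fn(i) must return the input_series of
# episode i; returns raw scores (reward_per_hit * hits).
score_batch <- function(genome, spec, mask, episode_seeds,
                        control = c("task", "noise"), plan = NULL) {
  control <- match.arg(control)
  if (is.null(plan)) plan <- compile_network(genome, mask)
  n_in <- length(plan$input_ids)
  k <- length(episode_seeds)
  arr <- array(0, dim = c(spec$T, n_in, k))
  for (i in seq_len(k)) {
    xs <- if (control == "noise") {
      noise_input_control(spec, n_in, seed = episode_seeds[i])
    } else {
      generate_inputs(spec, n_in, seed = episode_seeds[i])
    }
    arr[, , i] <- as.matrix(xs)[, as.character(plan$input_ids), drop = FALSE]
  }
  hits <- run_batch_hits(plan, arr, spec$target_action)
  spec$reward_per_hit * hits
}

#' Score one episode of the surrogate task
#'
#' Runs the (possibly lesioned) network on the stimulus generated from
#' `spec` and returns `reward_per_hit` times the number of timesteps on
#' which the chosen action equals the target action.
#'
#' @param genome A `lesion_genome`.
#' @param spec A [task_spec()].
#' @param mask A `lesion_mask`.
#' @param seed Stimulus seed (defaults to `spec$seed`).
#' @return Scalar score in `[0, reward_per_hit * T]`.
#' @export
score_episode <- function(genome, spec, mask = lesion_mask(), seed = spec$seed) {
  score_batch(genome, spec, mask, episode_seeds = seed)
}

#' Maximum attainable episode score
#'
#' @param spec A [task_spec()].
#' @return `reward_per_hit * T`.
#' @export
max_score <- function(spec) spec$reward_per_hit * spec$T

#' Run the full lesion-experiment protocol
#'
#' Plays `plays_per_trial` episodes per trial with fresh stimulus noise per
#' play (streams derived deterministically from `protocol$seed`), averaging
#' plays into a trial score.
#'
#' @param genome A `lesion_genome`.
#' @param spec A [task_spec()].
#' @param protocol A [protocol_spec()].
#' @param mask A `lesion_mask`.
#' @param control `"task"` for the structured stimulus, `"noise"` for the
#'   noise-as-input control.
#' @return Numeric vector of `n_trials` trial scores.
#' @examples
#' g <- make_motif_genome()
#' run_protocol(g, task_spec(), protocol_spec(n_trials = 4, plays_per_trial = 2))
#' @export
run_protocol <- function(genome, spec, protocol = protocol_spec(),
                         mask = lesion_mask(), control = c("task", "noise")) {
  control <- match.arg(control)
  seeds <- t(vapply(seq_len(protocol$n_trials), function(tr) {
    episode_seeds_for(protocol$seed, mask$disabled_connections, tr,
                      protocol$plays_per_trial)
  }, integer(protocol$plays_per_trial)))
  dim(seeds) <- c(protocol$n_trials, protocol$plays_per_trial)
  all_seeds <- as.integer(seeds)
  chunk <- 256L
  scores <- numeric(length(all_seeds))
  plan <- compile_network(genome, mask)
  i <- 1L
  while (i <= length(all_seeds)) {
    j <- min(i + chunk - 1L, length(all_seeds))
    scores[i:j] <- score_batch(genome, spec, mask, all_seeds[i:j],
                               control = control, plan = plan)
    i <- j + 1L
  }
  dim(scores) <- dim(seeds)
  rowMeans(scores)
}

#' The bundled paradoxical-lesion motif genome
#'
#' A fixed ground-truth network built around an inhibitory self-loop motif:
#' input `-4` (the complement of the decaying oscillation on `-1`) drives
#' output node 0 (the "no action" analogue, bias -0.9) through the
#' positive-weight connection `(-4 -> 0)`, while the negative-weight
#' self-loop `(0 -> 0)` holds node 0 below the winning threshold. Output
#' node 4 (the target action) is driven by `(-1 -> 4)` and competes with a
#' noise-driven distractor output 2. Two steep hidden units (6 and 7) read
#' node 0's activity level and support node 4 (unit 6 detects the
#' suppressed-but-driven regime, unit 7 the silenced regime), which gives
#' the network a graded dependence on the state of node 0 rather than a
#' pure winner-take-all cliff; node 4's bias is low enough that a released
#' node 0 outcompetes it even with this support. A further hidden unit (9)
#' detects coincident activity of the anticorrelated input channels and
#' suppresses node 4, which only matters under unstructured input. Two
#' disabled connection genes are included as pseudogenes.
#'
#' Lesioning `(0 -> 0)` alone releases node 0 from inhibition, node 0
#' hyper-activates and performance collapses; additionally lesioning
#' `(-4 -> 0)` removes the drive and restores performance - the
#' paradoxical-lesion (Sprague) motif. Lesioning node 0 entirely, or
#' `(-4 -> 0)` alone, leaves performance near intact.
#'
#' @return A `lesion_genome` with 13 nodes and 13 connection genes (11
#'   enabled). All weights are recorded in the genome metadata.
#' @export
make_motif_genome <- function() {
  nodes <- data.frame(
    id = c(-1L, -2L, -3L, -4L, 0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 9L),
    role = c(rep("input", 4), rep("output", 6), rep("hidden", 3)),
    activation = "sigmoid",
    aggregation = "sum",
    bias = c(0, 0, 0, 0,
             -0.9,  # node 0: "no action", Sprague motif centre
             -4.0, -3.2, -4.0, 0.3, -4.0,
             -19.8, # hidden 6: detects node 0 active-but-suppressed (a0 > 0.33)
             13.2,  # hidden 7: detects node 0 silenced (a0 < 0.22)
             -16.8),# hidden 9: coincidence detector, fires when channels
                    # -1 and -4 are high together (never under the
                    # anticorrelated stimulus, often under uniform noise)
    response = 1.0,
    stringsAsFactors = FALSE
  )
  connections <- data.frame(
    source  = c(-4L,  0L, -1L, -2L,  0L,  6L,  0L,  7L,  -1L,  -4L,   9L, -3L, -2L),
    target  = c( 0L,  0L,  4L,  2L,  6L,  4L,  7L,  4L,   9L,   9L,   4L,  3L,  5L),
    weight  = c(2.0, -4.0, 2.0, 4.0, 60.0, 0.40, -60.0, 0.20, 12.0, 12.0, -4.0, 0.1, -0.2),
    enabled = c(rep(TRUE, 11), FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  lesion_genome(nodes, connections, metadata = list(
    name = "sprague_motif",
    description = paste(
      "Synthetic ground-truth network with an inhibitory self-loop motif",
      "producing a paradoxical lesion effect between (0->0) and (-4->0)."
    ),
    sigmoid = "plain logistic 1/(1+exp(-z)), z clamped to [-60, 60]",
    target_action = 4L
  ))
}

#' Canonical coalition games with known Shapley values
#'
#' Small deterministic games used as oracles for the Shapley machinery:
#' an additive game (`v(S) = sum of weights in S`, Shapley value = own
#' weight), a unanimity game on a pair within three elements (1/2, 1/2, 0),
#' the glove game on `{L, R1, R2}` (2/3, 1/6, 1/6) and an OR-game on a pair
#' (`v(S) = 1` iff the pair is hit). All satisfy `v(empty) = 0`.
#'
#' @return Named list of `canonical_game` objects, each with `elements`,
#'   `value_fn(subset)` and (where closed forms exist) `closed_form_shapley`.
#' @export
canonical_games <- function() {
  cg <- function(name, elements, value_fn, closed = NULL) {
    structure(list(name = name, elements = elements, value_fn = value_fn,
                   closed_form_shapley = closed),
              class = "canonical_game")
  }
  list(
    additive = cg(
      "additive", c("a", "b", "c"),
      function(S) sum(c(a = 1, b = 2, c = 3)[S]),
      closed = c(a = 1, b = 2, c = 3)
    ),
    unanimity = cg(
      "unanimity", c("a", "b", "c"),
      function(S) as.numeric(all(c("a", "b") %in% S)),
      closed = c(a = 0.5, b = 0.5, c = 0)
    ),
    glove = cg(
      "glove", c("L", "R1", "R2"),
      function(S) as.numeric("L" %in% S && any(c("R1", "R2") %in% S)),
      closed = c(L = 2 / 3, R1 = 1 / 6, R2 = 1 / 6)
    ),
    or_pair = cg(
      "or_pair", c("a", "b"),
      function(S) as.numeric(any(c("a", "b") %in% S)),
      closed = c(a = 0.5, b = 0.5)
    )
  )
}
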