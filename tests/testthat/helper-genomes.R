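# Small genomes constructed in code for the network-model tests.

# A minimal genome: node 0 with configurable activation/aggregation/bias and
# explicit incoming connections from inputs -1, -2.
tiny_genome <- function(activation = "identity", aggregation = "sum",
                        bias = 0, weights = c(1, 1), self_loop = NA) {
  conns <- data.frame(source = c(-1L, -2L), target = 0L,
                      weight = weights, enabled = TRUE)
  if (!is.na(self_loop)) {
    conns <- rbind(conns, data.frame(source = 0L, target = 0L,
                                     weight = self_loop, enabled = TRUE))
  }
  lesion_genome(
    nodes = data.frame(
      id = c(-1L, -2L, 0L),
      role = c("input", "input", "output"),
      activation = activation, aggregation = aggregation,
      bias = c(0, 0, bias), response = 1
    ),
    connections = conns
  )
}

# Two structurally disconnected components: inputs -1/-2 drive chains
# 0 -> 1 and 2 -> 3 respectively.
two_component_genome <- function() {
  lesion_genome(
    nodes = data.frame(
      id = c(-1L, -2L, 0L, 1L, 2L, 3L),
      role = c("input", "input", "hidden", "output", "hidden", "output"),
      activation = "tanh", aggregation = "sum", bias = 0, response = 1
    ),
    connections = data.frame(
      source = c(-1L, 0L, -2L, 2L),
      target = c(0L, 1L, 2L, 3L),
      weight = c(1, 0.5, 1, 0.5), enabled = TRUE
    )
  )
}

# A genome with two inputs only (both carried by the anticorrelated pair),
# so that noise_sd = 0 makes the whole task deterministic.
two_input_genome <- function() {
  lesion_genome(
    nodes = data.frame(
      id = c(-1L, -2L, 0L, 1L),
      role = c("input", "input", "output", "output"),
      activation = "sigmoid", aggregation = "sum",
      bias = c(0, 0, -0.5, 0.5), response = 1
    ),
    connections = data.frame(
      source = c(-1L, -2L), target = c(0L, 1L),
      weight = c(2, 1), enabled = TRUE
    )
  )
}

# Random many-connection genome used for pruning counts: n_total connection
# genes of which n_disabled are disabled.
wide_genome <- function(n_total = 58L, n_disabled = 7L, seed = 1) {
  set.seed(seed)
  n_in <- 6L; n_out <- 10L
  ids_in <- -seq_len(n_in)
  ids_out <- seq_len(n_out) - 1L
  pairs <- expand.grid(source = c(ids_in, ids_out), target = ids_out)
  pick <- pairs[sample(nrow(pairs), n_total), ]
  enabled <- rep(TRUE, n_total)
  enabled[sample(n_total, n_disabled)] <- FALSE
  lesion_genome(
    nodes = data.frame(
      id = c(ids_in, ids_out),
      role = c(rep("input", n_in), rep("output", n_out)),
      activation = "sigmoid", aggregation = "sum", bias = 0, response = 1
    ),
    connections = data.frame(source = pick$source, target = pick$target,
                             weight = stats::rnorm(n_total), enabled = enabled)
  )
}
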