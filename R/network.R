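# Recurrent network evaluation with synchronous one-step-delay updates.
#
# At every timestep each non-input node n computes
#   a_n(t) = act_n( bias_n + response_n * agg_n({ w_{m->n} * x_m }) )
# where x_m is the current stimulus for input sources and the *previous*
# activation for non-input sources (so self-loops and cycles are well
# defined). Masked or disabled connections are excluded from the aggregated
# set; a node whose surviving incoming set is empty aggregates 0 and emits
# act(bias). All nodes update synchronously from the t-1 state.

# Compile a genome + mask into an evaluation plan. Connections that are
# disabled or masked are dropped here, so the inner loops never see them.
compile_network <- function(genome, mask = lesion_mask()) {
  validate_genome(genome)
  if (!inherits(mask, "lesion_mask")) stop("mask must be a lesion_mask")
  nodes <- genome$nodes
  ins <- input_ids(genome)
  nis <- non_input_ids(genome)
  outs <- output_ids(genome)

  en <- genome$connections[genome$connections$enabled, , drop = FALSE]
  if (nrow(en)) {
    keys <- conn_key(en$source, en$target)
    en <- en[!keys %in% mask$disabled_connections, , drop = FALSE]
  }

  per_node <- lapply(nis, function(id) {
    row <- nodes[nodes$id == id, ]
    inc <- en[en$target == id, , drop = FALSE]
    src_is_input <- inc$source %in% ins
    list(
      id = id,
      act = get_activation(row$activation),
      agg = row$aggregation,
      bias = row$bias,
      response = row$response,
      w_in = inc$weight[src_is_input],
      idx_in = match(inc$source[src_is_input], ins),
      w_st = inc$weight[!src_is_input],
      idx_st = match(inc$source[!src_is_input], nis)
    )
  })

  plan <- list(
    input_ids = ins, non_input_ids = nis, output_ids = outs,
    out_rows = match(outs, nis), per_node = per_node
  )

  # Fast path: when every non-input node aggregates by summation the whole
  # step is two matrix products plus activation calls grouped by function.
  if (all(vapply(per_node, function(nd) identical(nd$agg, "sum"), logical(1)))) {
    n <- length(nis)
    W_in <- matrix(0, n, length(ins))
    W_st <- matrix(0, n, n)
    for (r in seq_len(n)) {
      nd <- per_node[[r]]
      if (length(nd$w_in)) W_in[r, nd$idx_in] <- W_in[r, nd$idx_in] + nd$w_in
      if (length(nd$w_st)) W_st[r, nd$idx_st] <- W_st[r, nd$idx_st] + nd$w_st
    }
    resp <- vapply(per_node, `[[`, numeric(1), "response")
    bias <- vapply(per_node, `[[`, numeric(1), "bias")
    act_names <- vapply(seq_len(n), function(r) {
      nodes$activation[nodes$id == nis[r]]
    }, character(1))
    groups <- lapply(split(seq_len(n), act_names), function(rows) {
      list(rows = rows, fn = get_activation(act_names[rows[1]]))
    })
    plan$dense <- list(W_in = W_in, W_st = W_st, resp = resp, bias = bias,
                       groups = groups)
  }
  plan
}

# Precompile a genome once and return a factory mapping a set of masked
# connection keys to an evaluation plan. For dense (all-sum) genomes the
# mask application is just zeroing weight-matrix entries, which avoids
# re-validating and re-indexing the genome for every coalition.
make_plan_factory <- function(genome) {
  base <- compile_network(genome, lesion_mask())
  if (is.null(base$dense)) {
    return(function(mask_keys) compile_network(genome, lesion_mask(mask_keys)))
  }
  en <- genome$connections[genome$connections$enabled, , drop = FALSE]
  keys <- conn_key(en$source, en$target)
  loc <- lapply(seq_along(keys), function(i) {
    tgt_row <- match(en$target[i], base$non_input_ids)
    src_in <- match(en$source[i], base$input_ids)
    if (!is.na(src_in)) list(mat = "W_in", r = tgt_row, c = src_in)
    else list(mat = "W_st", r = tgt_row, c = match(en$source[i], base$non_input_ids))
  })
  names(loc) <- keys
  function(mask_keys) {
    if (!length(mask_keys)) return(base)
    plan <- base
    for (k in mask_keys) {
      l <- loc[[k]]
      if (is.null(l)) stop("mask refers to unknown connection: ", k)
      plan$dense[[l$mat]][l$r, l$c] <- 0
    }
    plan
  }
}

step_dense <- function(dense, state, inputs_now) {
  z <- dense$bias + dense$resp *
    (dense$W_in %*% inputs_now + dense$W_st %*% state)
  for (gr in dense$groups) z[gr$rows, ] <- gr$fn(z[gr$rows, , drop = FALSE])
  z
}

# One synchronous step on a state matrix (non-input nodes x episodes).
# inputs_now: matrix (input nodes x episodes), rows ordered as plan$input_ids.
step_compiled <- function(plan, state, inputs_now) {
  k <- ncol(state)
  new_state <- state
  for (nd in plan$per_node) {
    if (length(nd$w_in) || length(nd$w_st)) {
      if (nd$agg == "sum") {
        z <- numeric(k)
        if (length(nd$w_in)) {
          z <- z + if (length(nd$w_in) == 1L) nd$w_in * inputs_now[nd$idx_in, ]
                   else as.vector(nd$w_in %*% inputs_now[nd$idx_in, , drop = FALSE])
        }
        if (length(nd$w_st)) {
          z <- z + if (length(nd$w_st) == 1L) nd$w_st * state[nd$idx_st, ]
                   else as.vector(nd$w_st %*% state[nd$idx_st, , drop = FALSE])
        }
      } else if (nd$agg == "max") {
        z <- rep(-Inf, k)
        for (j in seq_along(nd$w_in)) z <- pmax(z, nd$w_in[j] * inputs_now[nd$idx_in[j], ])
        for (j in seq_along(nd$w_st)) z <- pmax(z, nd$w_st[j] * state[nd$idx_st[j], ])
      } else {
        # generic registered aggregation, column by column
        aggf <- get_aggregation(nd$agg)
        z <- vapply(seq_len(k), function(e) {
          aggf(c(nd$w_in * inputs_now[nd$idx_in, e], nd$w_st * state[nd$idx_st, e]))
        }, numeric(1))
      }
    } else {
      z <- numeric(k) # empty incoming set aggregates to 0
    }
    new_state[match(nd$id, plan$non_input_ids), ] <- nd$act(nd$bias + nd$response * z)
  }
  new_state
}

#' Advance a network state by one timestep
#'
#' Applies the synchronous update rule: every non-input node reads the
#' previous state (for recurrent sources) and the current stimulus (for
#' input sources), aggregates the surviving weighted incoming values,
#' adds its bias and passes the result through its activation function.
#'
#' @param genome A `lesion_genome`.
#' @param state Named numeric vector of current activations, one entry per
#'   non-input node id; use [network_state()] for the zero initial state.
#' @param inputs Named numeric vector covering all input node ids.
#' @param mask A `lesion_mask` (default: no lesion).
#' @return The next state, in the same named-vector layout.
#' @examples
#' g <- make_motif_genome()
#' s <- network_state(g)
#' step_network(g, s, setNames(rep(0, 4), c(-1, -2, -3, -4)))
#' @export
step_network <- function(genome, state, inputs, mask = lesion_mask()) {
  plan <- compile_network(genome, mask)
  if (!all(as.character(plan$input_ids) %in% names(inputs))) {
    stop("inputs must cover all input nodes")
  }
  if (!all(as.character(plan$non_input_ids) %in% names(state))) {
    stop("state must cover all non-input nodes")
  }
  iv <- as.numeric(inputs[as.character(plan$input_ids)])
  if (any(!is.finite(iv))) stop("non-finite input value")
  sv <- matrix(as.numeric(state[as.character(plan$non_input_ids)]), ncol = 1)
  out <- step_compiled(plan, sv, matrix(iv, ncol = 1))
  stats::setNames(as.numeric(out), as.character(plan$non_input_ids))
}

#' Zero initial network state
#'
#' @param genome A `lesion_genome`.
#' @return Named numeric vector (all 0) over the non-input node ids.
#' @export
network_state <- function(genome) {
  ids <- non_input_ids(genome)
  stats::setNames(numeric(length(ids)), as.character(ids))
}

#' Run a (possibly lesioned) network over an input series
#'
#' Iterates the synchronous update from the zero initial state, recording
#' the post-activation value of every non-input node at every timestep. The
#' chosen action at each timestep is the output node with maximal
#' activation, ties broken by the lowest output id.
#'
#' @param genome A `lesion_genome`.
#' @param input_series An [input_series()] object (or plain matrix whose
#'   columns are named by input ids), one row per timestep.
#' @param mask A `lesion_mask`.
#' @return A list with `trace` (an `activity_trace`: timesteps x non-input
#'   nodes matrix, column names are node ids, with a `chosen_action`
#'   attribute) and `actions` (integer vector of chosen output ids).
#' @examples
#' g <- make_motif_genome()
#' xs <- generate_inputs(task_spec(T = 50), n_inputs = 4)
#' res <- run_network(g, xs)
#' table(res$actions)
#' @export
run_network <- function(genome, input_series, mask = lesion_mask()) {
  plan <- compile_network(genome, mask)
  X <- as.matrix(input_series)
  if (nrow(X) < 1L) stop("input series must contain at least one timestep")
  cols <- as.character(plan$input_ids)
  if (!all(cols %in% colnames(X))) stop("input series must cover all input nodes")
  if (any(!is.finite(X))) stop("non-finite input value")
  X <- X[, cols, drop = FALSE]
  T_ <- nrow(X)
  n <- length(plan$non_input_ids)
  trace <- matrix(0, nrow = T_, ncol = n,
                  dimnames = list(NULL, as.character(plan$non_input_ids)))
  actions <- integer(T_)
  state <- matrix(0, nrow = n, ncol = 1)
  for (t in seq_len(T_)) {
    x_t <- matrix(X[t, ], ncol = 1)
    state <- if (is.null(plan$dense)) step_compiled(plan, state, x_t)
             else step_dense(plan$dense, state, x_t)
    trace[t, ] <- state[, 1]
    o <- state[plan$out_rows, 1]
    actions[t] <- plan$output_ids[which.max(o)] # which.max: first (lowest id) on ties
  }
  structure(
    list(trace = structure(trace, class = c("activity_trace", "matrix"),
                           chosen_action = actions),
         actions = actions),
    class = "network_run"
  )
}

# Batched episode scorer: runs k episodes simultaneously (state matrix with
# one column per episode) and returns the number of timesteps each episode
# chose `target_action`. inputs_array: T x n_inputs x k, input columns
# ordered as plan$input_ids.
run_batch_hits <- function(plan, inputs_array, target_action) {
  d <- dim(inputs_array)
  T_ <- d[1]; k <- d[3]
  state <- matrix(0, nrow = length(plan$non_input_ids), ncol = k)
  hits <- integer(k)
  tgt_row <- match(target_action, plan$output_ids)
  if (is.na(tgt_row)) stop("target action is not an output node")
  dense <- plan$dense
  if (!is.null(dense)) {
    # hoist the input drive W_in %*% x out of the time loop: one matmul for
    # the whole (timestep x episode) block
    n <- length(plan$non_input_ids)
    X_flat <- matrix(aperm(inputs_array, c(1, 3, 2)), nrow = T_ * k, ncol = d[2])
    driveT <- tcrossprod(dense$W_in, X_flat) # n x (T*k), episode-major cols
    offs <- (seq_len(k) - 1L) * T_
    # rows competing with the target output; the target wins a timestep iff
    # it strictly beats every lower-id output and at least ties every
    # higher-id one (lowest-id tie-break)
    tgt_state_row <- plan$out_rows[tgt_row]
    lower <- plan$out_rows[seq_len(tgt_row - 1L)]
    higher <- if (tgt_row < length(plan$out_rows)) {
      plan$out_rows[(tgt_row + 1L):length(plan$out_rows)]
    } else integer(0)
    for (t in seq_len(T_)) {
      z <- dense$bias + dense$resp * (driveT[, t + offs, drop = FALSE] +
                                        dense$W_st %*% state)
      for (gr in dense$groups) z[gr$rows, ] <- gr$fn(z[gr$rows, , drop = FALSE])
      state <- z
      tv <- state[tgt_state_row, ]
      won <- rep(TRUE, k)
      for (r in lower) won <- won & tv > state[r, ]
      for (r in higher) won <- won & tv >= state[r, ]
      hits <- hits + won
    }
    return(hits)
  }
  for (t in seq_len(T_)) {
    x_t <- matrix(inputs_array[t, , ], nrow = d[2], ncol = k)
    state <- step_compiled(plan, state, x_t)
    outs <- state[plan$out_rows, , drop = FALSE]
    won <- max.col(t(outs), ties.method = "first") == tgt_row
    hits <- hits + won
  }
  hits
}

#' Export an activity trace as a delimited table
#'
#' Writes one row per timestep, one column per non-input node (named by
#' node id) plus a `chosen_action` column.
#'
#' @param trace An `activity_trace` (from [run_network()]).
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, sep = "\t") {
  df <- as.data.frame(unclass(trace))
  names(df) <- colnames(trace)
  df$chosen_action <- attr(trace, "chosen_action")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
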