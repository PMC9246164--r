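# Independent oracles for the Shapley machinery: full enumeration of all
# n! element orderings over an explicit value table, kept deliberately
# separate from the package's subset-weighted computation.

# All permutations of 1..n as an (n! x n) matrix.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
  unname(out)
}

# v indexed by subset bitmask (mask + 1); elements are bit positions 1..n.
subset_mask <- function(idx, n) sum(2^(idx - 1L))

# Brute-force Shapley values by averaging marginal contributions over every
# ordering. vvec: numeric vector of length 2^n, vvec[mask + 1] = v(S).
brute_shapley <- function(vvec, n) {
  P <- all_permutations(n)
  bits <- matrix(2^(P - 1L), nrow(P), n)
  cum <- t(apply(bits, 1, cumsum))
  delta <- vvec[cum + 1] - vvec[cum - bits + 1]
  vapply(seq_len(n), function(i) mean(delta[P == i]), numeric(1))
}

# Value table of a coalition_game (or plain value function) over the full
# lattice, as a bitmask-indexed vector.
value_table <- function(els, vfun) {
  n <- length(els)
  vapply(0:(2^n - 1), function(m) vfun(els[bitwAnd(m, 2^(seq_len(n) - 1L)) > 0]), numeric(1))
}

# Random deterministic game: iid Uniform(0, 1) worths over the lattice.
random_game_table <- function(n, seed) {
  set.seed(seed)
  stats::runif(2^n)
}

game_from_table <- function(els, vvec) {
  coalition_game(els, function(S, rep) {
    vvec[subset_mask(match(S, els), length(els)) + 1]
  }, stochastic = FALSE, label = "table")
}

game_from_canonical <- function(cg) {
  coalition_game(cg$elements, function(S, rep) cg$value_fn(S),
                 stochastic = FALSE, label = cg$name)
}

# Independent PCIA oracle: derive the compound and conditioned value
# tables directly from the base table and brute-force the three Shapley
# values of the pair (i, j), returning the interaction decomposition.
brute_pair_interaction <- function(els, vvec, i, j) {
  n <- length(els)
  ij <- c(which(els == i), which(els == j))
  rest <- setdiff(seq_len(n), ij)
  # compound game over rest + fused
  els_c <- c(rest, 0L) # 0 marks the fused element
  vv_c <- value_table(seq_along(els_c), function(Sidx) {
    base <- rest[Sidx[Sidx <= length(rest)]]
    if (length(els_c) %in% Sidx) base <- c(base, ij)
    vvec[subset_mask(base, n) + 1]
  })
  g_joint <- brute_shapley(vv_c, length(els_c))[length(els_c)]
  cond_gamma <- function(target, lesioned) {
    pool <- setdiff(seq_len(n), lesioned)
    vv <- value_table(seq_along(pool), function(Sidx) {
      vvec[subset_mask(pool[Sidx], n) + 1]
    })
    brute_shapley(vv, length(pool))[match(target, pool)]
  }
  gi <- cond_gamma(ij[1], ij[2])
  gj <- cond_gamma(ij[2], ij[1])
  list(gamma_joint = g_joint, gamma_i = gi, gamma_j = gj,
       interaction = g_joint - gi - gj)
}
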