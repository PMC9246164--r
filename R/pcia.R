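# Pairwise Causal Interaction Analysis (PCIA).
#
# For a pair (i, j) three Shapley values are computed on games derived from
# the same base game: the joint value gamma_(ij) of the fused compound
# element, and the conditioned values gamma(i | j lesioned) and
# gamma(j | i lesioned). The interaction term
#   I_{i,j} = gamma_(ij) - gamma(i | j-bar) - gamma(j | i-bar)
# is positive for net-synergy and negative for net-redundancy. A
# paradoxical-lesion (Sprague) effect from i to j is the ordered condition
#   gamma(i | j-bar) < 0   and   I_{i,j} + gamma(i | j-bar) > 0,
# i.e. element i hinders performance while j is lesioned yet the pair's
# joint contribution exceeds j's own conditioned contribution.

compound_label <- function(i, j) paste0(i, "+", j)

#' Fuse two elements of a game into a compound element
#'
#' The returned game has element set `(N - {i, j}) + {"i+j"}`; the
#' compound is intact iff both `i` and `j` are intact. Values are
#' delegated to the base game (and share its cache).
#'
#' @param game A `coalition_game`.
#' @param pair Character vector `c(i, j)` of two distinct elements.
#' @return A `coalition_game` on `n - 1` elements.
#' @export
compound_game <- function(game, pair) {
  pair <- as.character(pair)
  stopifnot(length(pair) == 2L)
  if (pair[1] == pair[2]) stop("compound pair must be two distinct elements")
  if (length(setdiff(pair, game$elements))) stop("pair elements must belong to the game")
  fused <- compound_label(pair[1], pair[2])
  rest <- setdiff(game$elements, pair)
  value_fn <- function(S, rep) {
    base_S <- setdiff(S, fused)
    if (fused %in% S) base_S <- c(base_S, pair)
    game_value(game, base_S, rep)
  }
  coalition_game(c(rest, fused), value_fn, stochastic = game$stochastic,
                 cache = FALSE, # base game already caches
                 label = paste0(game$label, "[", fused, "]"))
}

#' Conditioned game: permute a pool while other elements are pinned
#'
#' Restricts the player set to `target_pool`; elements in `always_lesioned`
#' are never intact, and every other non-pool element is always intact.
#' The Shapley value of `i` in
#' `conditioned_game(game, setdiff(N, j), j)` is the conditioned value
#' `gamma(i | j lesioned)`.
#'
#' @param game A `coalition_game`.
#' @param target_pool Character vector of elements to permute over.
#' @param always_lesioned Character vector of permanently lesioned
#'   elements; disjoint from the pool.
#' @return A `coalition_game` over `target_pool`, delegating to `game`.
#' @export
conditioned_game <- function(game, target_pool, always_lesioned = character()) {
  target_pool <- as.character(target_pool)
  always_lesioned <- as.character(always_lesioned)
  if (length(intersect(target_pool, always_lesioned))) {
    stop("target pool and always-lesioned set must be disjoint")
  }
  if (length(setdiff(c(target_pool, always_lesioned), game$elements))) {
    stop("pool elements must belong to the game")
  }
  pinned_intact <- setdiff(game$elements, c(target_pool, always_lesioned))
  value_fn <- function(S, rep) game_value(game, c(S, pinned_intact), rep)
  coalition_game(target_pool, value_fn, stochastic = game$stochastic,
                 cache = FALSE, label = paste0(game$label, "|cond"))
}

#' Interaction term of a pair
#'
#' `I_{i,j} = gamma_(ij) - gamma(i | j-bar) - gamma(j | i-bar)`: positive
#' values indicate net-synergy, negative values net-redundancy.
#'
#' @param gamma_joint Shapley value of the fused compound element.
#' @param gamma_i_given_j_lesioned,gamma_j_given_i_lesioned Conditioned
#'   Shapley values computed on the same base game and budget.
#' @return Scalar interaction term.
#' @export
interaction_term <- function(gamma_joint, gamma_i_given_j_lesioned,
                             gamma_j_given_i_lesioned) {
  gamma_joint - gamma_i_given_j_lesioned - gamma_j_given_i_lesioned
}

shapley_of <- function(game, element, n_permutations, seed, exact) {
  tbl <- if (exact) {
    exact_shapley(game)
  } else {
    sampled_shapley(game, n_permutations = n_permutations, seed = seed, ci = FALSE)
  }
  tbl$gamma[match(element, tbl$element)]
}

#' Analyse one element pair
#'
#' Computes the joint, conditioned and interaction quantities for an
#' unordered pair on a shared base game.
#'
#' @param game A `coalition_game`.
#' @param pair Character vector `c(i, j)`.
#' @param n_permutations Permutation budget per Shapley estimate (study
#'   default for PCIA: 100); only used on the sampled path.
#' @param seed Integer seed.
#' @param exact Use exact enumeration instead of sampling. The default
#'   (`NULL`) enumerates whenever the derived pair games have at most 12
#'   elements, which costs no more than sampling (all pair games share the
#'   base game's coalition cache) and removes Monte-Carlo sign errors from
#'   the small conditioned quantities that the Sprague condition compares.
#' @return A `pair_analysis` list: `i`, `j`, `gamma_joint`,
#'   `gamma_i_given_j_lesioned`, `gamma_j_given_i_lesioned`, `interaction`.
#' @export
pair_analysis <- function(game, pair, n_permutations = 100L, seed = 1L,
                          exact = NULL) {
  if (is.null(exact)) exact <- length(game$elements) <= 13L
  pair <- as.character(pair)
  i <- pair[1]; j <- pair[2]
  gj <- shapley_of(compound_game(game, pair), compound_label(i, j),
                   n_permutations, derive_seed(seed, "joint", i, j), exact)
  gi_ <- shapley_of(conditioned_game(game, setdiff(game$elements, j), j), i,
                    n_permutations, derive_seed(seed, "cond", i, j), exact)
  gj_ <- shapley_of(conditioned_game(game, setdiff(game$elements, i), i), j,
                    n_permutations, derive_seed(seed, "cond", j, i), exact)
  structure(
    list(i = i, j = j, gamma_joint = gj,
         gamma_i_given_j_lesioned = gi_, gamma_j_given_i_lesioned = gj_,
         interaction = interaction_term(gj, gi_, gj_)),
    class = "pair_analysis"
  )
}

#' Pairwise interaction matrix
#'
#' Runs [pair_analysis()] for every unordered element pair and assembles
#' the symmetric interaction matrix. All pair games delegate to the base
#' game's coalition cache, so the network is only re-simulated for
#' coalitions not seen before.
#'
#' @param game A `coalition_game` with at least 2 elements.
#' @param n_permutations Permutation budget per Shapley estimate
#'   (default 100); only used on the sampled path.
#' @param seed Integer seed.
#' @param exact Use exact enumeration for every pair game; `NULL` (default)
#'   enumerates automatically for games of up to 13 elements (see
#'   [pair_analysis()]).
#' @return An `interaction_matrix`: square symmetric numeric matrix with
#'   `NA` diagonal, carrying the per-pair analyses in
#'   `attr(, "analyses")` and the mean and SD of the unique off-diagonal
#'   entries in `attr(, "mean")` / `attr(, "sd")`.
#' @export
interaction_matrix <- function(game, n_permutations = 100L, seed = 1L,
                               exact = NULL) {
  if (is.null(exact)) exact <- length(game$elements) <= 13L
  els <- game$elements
  n <- length(els)
  if (n < 2) stop("interaction analysis needs at least 2 elements")
  M <- matrix(NA_real_, n, n, dimnames = list(els, els))
  analyses <- list()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      pa <- pair_analysis(game, c(els[a], els[b]),
                          n_permutations = n_permutations,
                          seed = derive_seed(seed, "pair", els[a], els[b]),
                          exact = exact)
      M[a, b] <- M[b, a] <- pa$interaction
      analyses[[paste(els[a], els[b], sep = "~")]] <- pa
    }
  }
  vals <- M[upper.tri(M)]
  structure(M, class = c("interaction_matrix", "matrix"), analyses = analyses,
            mean = mean(vals), sd = sqrt(mean((vals - mean(vals))^2)),
            n_permutations = as.integer(n_permutations))
}

#' Threshold an interaction matrix
#'
#' Retains the pairs whose interaction deviates from the mean of the
#' unique off-diagonal entries by at least `k_sd` population standard
#' deviations (values inside the band are excluded as likely estimation
#' noise); entries exactly at the mean are never retained, and a
#' zero-variance matrix yields no pairs.
#'
#' @param matrix An `interaction_matrix`.
#' @param k_sd Band half-width in SD units (default 2).
#' @return Character vector of retained pair keys (`"i~j"`).
#' @export
threshold_pairs <- function(matrix, k_sd = 2) {
  stopifnot(inherits(matrix, "interaction_matrix"))
  m <- attr(matrix, "mean"); s <- attr(matrix, "sd")
  if (is.na(s) || s == 0) return(character(0))
  keep <- vapply(attr(matrix, "analyses"), function(pa) {
    dev <- abs(pa$interaction - m)
    dev >= k_sd * s && dev > 0
  }, logical(1))
  names(which(keep))
}

#' Detect paradoxical-lesion (Sprague) effects
#'
#' For each ordered direction `(i, j)` of every retained pair, emits an
#' edge `i -> j` iff `gamma(i | j-bar) < 0` and
#' `I_{i,j} + gamma(i | j-bar) > 0`: lesioning `i` on top of an existing
#' lesion of `j` would restore performance that `i` was hindering. Both
#' directions of a pair may fire independently.
#'
#' @param pairs Character vector of pair keys (from [threshold_pairs()]).
#' @param matrix The `interaction_matrix` carrying the pair analyses.
#' @return A `sprague_edges` data.frame: stem, head, interaction,
#'   gamma_stem_given_head_lesioned.
#' @export
detect_sprague <- function(pairs, matrix) {
  analyses <- attr(matrix, "analyses")
  if (length(bad <- setdiff(pairs, names(analyses)))) {
    stop("pairs not analysed: ", paste(bad, collapse = ", "))
  }
  rows <- list()
  for (key in pairs) {
    pa <- analyses[[key]]
    directions <- list(
      list(stem = pa$i, head = pa$j, g = pa$gamma_i_given_j_lesioned),
      list(stem = pa$j, head = pa$i, g = pa$gamma_j_given_i_lesioned)
    )
    for (d in directions) {
      if (d$g < 0 && pa$interaction + d$g > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          stem = d$stem, head = d$head, interaction = pa$interaction,
          gamma_stem_given_head_lesioned = d$g, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(stem = character(), head = character(),
               interaction = numeric(),
               gamma_stem_given_head_lesioned = numeric(),
               stringsAsFactors = FALSE)
  }
  structure(out, class = c("sprague_edges", "data.frame"))
}

#' Export the interaction network in GraphML format
#'
#' Writes the thresholded interaction network (nodes = analysed elements,
#' edges = retained interactions, directed attribute edges for Sprague
#' pairs) to GraphML via igraph, for inspection in standard graph tools.
#'
#' @param matrix An `interaction_matrix`.
#' @param pairs Retained pair keys.
#' @param edges A `sprague_edges` data.frame.
#' @param path Output path.
#' @return `path`, invisibly; errors if igraph is unavailable.
#' @export
export_interaction_graphml <- function(matrix, pairs, edges, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("GraphML export requires the igraph package")
  }
  analyses <- attr(matrix, "analyses")[pairs]
  el <- do.call(rbind, lapply(analyses, function(pa) {
    data.frame(from = pa$i, to = pa$j, interaction = pa$interaction,
               sprague = paste(pa$i, pa$j, sep = "~") %in%
                 paste(edges$stem, edges$head, sep = "~") |
                 paste(pa$j, pa$i, sep = "~") %in%
                 paste(edges$stem, edges$head, sep = "~"),
               stringsAsFactors = FALSE)
  }))
  g <- if (is.null(el)) {
    igraph::make_empty_graph() + igraph::vertices(rownames(matrix))
  } else {
    igraph::graph_from_data_frame(el, directed = FALSE,
                                  vertices = rownames(matrix))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
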