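# Functional connectivity of node time series and lesion impact on it.
#
# FC is the Pearson correlation matrix of the non-input nodes' activity
# time series from a single episode. The impact of a lesion on functional
# connectivity (IFC) is the absolute element-wise sum of the difference
# between the intact and lesioned FC matrices, computed on the *same*
# stimulus so that any difference is attributable to the lesion alone.
# Zero-variance (silenced) series get correlation 0 with a flag rather
# than NA, so lesioned and intact matrices stay comparable.

#' Functional connectivity matrix of an activity trace
#'
#' @param trace An `activity_trace` (timesteps x nodes matrix) with at
#'   least 2 timesteps.
#' @return An `fc_matrix`: symmetric Pearson correlation matrix with unit
#'   diagonal; rows/columns of constant (degenerate) series are filled
#'   with 0 and listed in `attr(, "degenerate")`.
#' @export
fc <- function(trace) {
  m <- as.matrix(trace)
  if (nrow(m) < 2) stop("functional connectivity needs at least 2 timesteps")
  if (any(!is.finite(m))) stop("trace must be finite")
  sds <- apply(m, 2, stats::sd)
  degenerate <- colnames(m)[sds == 0]
  r <- suppressWarnings(stats::cor(m))
  r[!is.finite(r)] <- 0
  if (length(degenerate)) {
    r[degenerate, ] <- 0
    r[, degenerate] <- 0
  }
  structure(r, class = c("fc_matrix", "matrix"), degenerate = degenerate)
}

#' Impact of a lesion on functional connectivity (IFC)
#'
#' The absolute sum over all matrix cells of the intact-minus-lesioned FC
#' difference; both symmetric triangles (and the zero diagonal difference)
#' are counted, so a single correlation changing by 0.1 contributes 0.2.
#'
#' @param fc_intact,fc_lesioned `fc_matrix` objects over the same node set.
#' @return Non-negative scalar; 0 for identical matrices.
#' @export
ifc <- function(fc_intact, fc_lesioned) {
  a <- as.matrix(fc_intact); b <- as.matrix(fc_lesioned)
  if (!identical(dim(a), dim(b)) || !identical(colnames(a), colnames(b))) {
    stop("FC matrices must share the same node index")
  }
  sum(abs(a - b))
}

#' IFC sweep: single-element lesions versus network dynamics
#'
#' For every element (node or enabled connection), runs the lesioned
#' network on the *same* stimulus as the intact reference, computes the
#' lesioned FC and its IFC relative to the intact FC, and records the
#' lesioned performance.
#'
#' @param genome A `lesion_genome` (pruned internally).
#' @param task A [task_spec()]; the stimulus derives from `task$seed`.
#' @param granularity `"nodes"` or `"connections"`.
#' @return An `ifc_table` data.frame: element, ifc, score, plus
#'   `attr(, "fc_intact")` and the intact score in `attr(, "intact_score")`.
#' @export
ifc_sweep <- function(genome, task, granularity = c("nodes", "connections")) {
  granularity <- match.arg(granularity)
  g <- prune_disabled(genome)
  xs <- generate_inputs(task, genome_n_inputs(g))
  intact <- run_network(g, xs)
  fc0 <- fc(intact$trace)
  score0 <- task$reward_per_hit * sum(intact$actions == task$target_action)
  if (granularity == "nodes") {
    elements <- as.character(sort(g$nodes$id))
    masks <- lapply(as.integer(elements), function(id) node_lesion_mask(g, id))
  } else {
    en <- g$connections
    elements <- conn_key(en$source, en$target)
    masks <- lapply(elements, function(k) lesion_mask(k, genome = g))
  }
  rows <- mapply(function(el, mk) {
    les <- run_network(g, xs, mk)
    data.frame(element = el,
               ifc = ifc(fc0, fc(les$trace)),
               score = task$reward_per_hit * sum(les$actions == task$target_action),
               stringsAsFactors = FALSE)
  }, elements, masks, SIMPLIFY = FALSE)
  structure(do.call(rbind, rows), class = c("ifc_table", "data.frame"),
            fc_intact = fc0, intact_score = score0,
            granularity = granularity)
}

#' Correlate IFC with a per-element quantity
#'
#' Pearson correlation (with a two-sided p-value) between the IFC values
#' of an [ifc_sweep()] and a supplied per-element quantity such as the
#' SPA performance or the Shapley value.
#'
#' @param table An `ifc_table`.
#' @param values Numeric vector; either named by element or in table
#'   order. At least 3 elements.
#' @return List with `r` and `p`.
#' @export
correlate_ifc <- function(table, values) {
  stopifnot(inherits(table, "ifc_table"))
  if (!is.null(names(values))) {
    if (!all(table$element %in% names(values))) {
      stop("values must cover every element of the IFC table")
    }
    values <- values[table$element]
  }
  if (length(values) != nrow(table) || nrow(table) < 3) {
    stop("correlation needs one value per element and at least 3 elements")
  }
  if (stats::sd(table$ifc) == 0 || stats::sd(values) == 0) {
    stop("degenerate correlation: one of the vectors is constant")
  }
  ct <- stats::cor.test(table$ifc, values, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
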