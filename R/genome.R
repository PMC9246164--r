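# Genome representation: node genes + connection genes, NEAT-style.
#
# Nodes carry a per-node bias, response multiplier, activation and
# aggregation function; connections carry a weight and an enabled flag.
# Disabled connections are "pseudogenes": they pass zero and are removed by
# prune_disabled() before any lesion experiment. By convention input nodes
# have negative ids and outputs/hidden non-negative ids; the convention is
# validated softly (a warning) but not required.

#' Construct a network genome
#'
#' A genome bundles node genes and connection genes into the lesionable
#' description of a recurrent network phenotype.
#'
#' @param nodes data.frame with columns `id` (integer, unique; inputs
#'   conventionally negative), `role` (`"input"`, `"hidden"` or `"output"`),
#'   `activation`, `aggregation` (registered function names; ignored for
#'   inputs), `bias` and `response` (numeric; `response` defaults to 1).
#' @param connections data.frame with columns `source`, `target` (node ids),
#'   `weight` (numeric) and `enabled` (logical). `(source, target)` pairs
#'   must be unique; self-loops are permitted.
#' @param metadata free-form named list (name, provenance, notes).
#' @return An object of class `lesion_genome`.
#' @seealso [read_genome()], [prune_disabled()], [make_motif_genome()]
#' @export
lesion_genome <- function(nodes, connections, metadata = list()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  connections <- as.data.frame(connections, stringsAsFactors = FALSE)
  if (!"response" %in% names(nodes)) nodes$response <- 1.0
  nodes$id <- as.integer(nodes$id)
  connections$source <- as.integer(connections$source)
  connections$target <- as.integer(connections$target)
  connections$enabled <- as.logical(connections$enabled)
  g <- structure(
    list(nodes = nodes, connections = connections, metadata = metadata),
    class = "lesion_genome"
  )
  validate_genome(g)
  g
}

#' Validate a genome's referential integrity
#'
#' Checks id uniqueness, connection endpoints, duplicate `(source, target)`
#' pairs, registered activation/aggregation names, and the presence of at
#' least one input and one output node. Called by all genome constructors.
#'
#' @param genome A `lesion_genome`.
#' @return `genome`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_genome <- function(genome) {
  stopifnot(inherits(genome, "lesion_genome"))
  nodes <- genome$nodes
  conns <- genome$connections
  need <- c("id", "role", "activation", "aggregation", "bias", "response")
  if (!all(need %in% names(nodes))) {
    stop("genome nodes need columns: ", paste(setdiff(need, names(nodes)), collapse = ", "))
  }
  if (anyDuplicated(nodes$id)) stop("genome node ids must be unique")
  if (!all(nodes$role %in% c("input", "hidden", "output"))) {
    stop("node roles must be input, hidden or output")
  }
  if (!any(nodes$role == "input") || !any(nodes$role == "output")) {
    stop("genome needs at least one input and one output node")
  }
  non_input <- nodes[nodes$role != "input", , drop = FALSE]
  for (nm in unique(non_input$activation)) get_activation(nm)
  for (nm in unique(non_input$aggregation)) get_aggregation(nm)
  if (nrow(conns)) {
    if (!all(conns$source %in% nodes$id) || !all(conns$target %in% nodes$id)) {
      stop("connection endpoints must reference existing node ids")
    }
    if (anyDuplicated(paste(conns$source, conns$target))) {
      stop("(source, target) pairs must be unique")
    }
    if (any(conns$target %in% nodes$id[nodes$role == "input"])) {
      stop("input nodes cannot be connection targets")
    }
  }
  if (any(nodes$id[nodes$role == "input"] >= 0L)) {
    warning("convention: input node ids are negative", call. = FALSE)
  }
  invisible(genome)
}

#' @export
print.lesion_genome <- function(x, ...) {
  n_en <- sum(x$connections$enabled)
  cat(sprintf(
    "<lesion_genome '%s': %d nodes (%d input / %d hidden / %d output), %d connections (%d enabled)>\n",
    x$metadata$name %||% "unnamed",
    nrow(x$nodes),
    sum(x$nodes$role == "input"), sum(x$nodes$role == "hidden"),
    sum(x$nodes$role == "output"),
    nrow(x$connections), n_en
  ))
  invisible(x)
}

conn_key <- function(source, target) {
  if (!length(source)) return(character(0))
  paste0(source, "->", target)
}

input_ids <- function(genome) sort(genome$nodes$id[genome$nodes$role == "input"], decreasing = TRUE)
output_ids <- function(genome) sort(genome$nodes$id[genome$nodes$role == "output"])
non_input_ids <- function(genome) sort(genome$nodes$id[genome$nodes$role != "input"])

#' Remove disabled connections from a genome
#'
#' Disabled connection genes pass zero and play no role in network
#' evaluation; pruning removes them so that every remaining connection is a
#' lesionable element. Nodes are left untouched and the input genome is not
#' modified.
#'
#' @param genome A `lesion_genome`.
#' @return A `lesion_genome` containing exactly the enabled connections.
#' @examples
#' g <- make_motif_genome()
#' prune_disabled(g)
#' @export
prune_disabled <- function(genome) {
  validate_genome(genome)
  keep <- genome$connections[genome$connections$enabled, , drop = FALSE]
  rownames(keep) <- NULL
  lesion_genome(genome$nodes, keep, genome$metadata)
}

#' Construct a lesion mask
#'
#' A lesion is represented by severed connections: a masked connection
#' passes zero exactly like a disabled connection gene. `disabled_nodes` is
#' bookkeeping only; node lesions are realised as connection lesions (see
#' [node_lesion_mask()]). Applying a mask is idempotent.
#'
#' @param connections Character vector of connection keys (`"src->tgt"`), or
#'   a 2-column matrix/data.frame of (source, target) pairs.
#' @param nodes Integer ids of nodes the mask stands for (bookkeeping).
#' @param genome Optional `lesion_genome`; when supplied, every masked key
#'   must exist and be enabled in it.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(connections = character(), nodes = integer(), genome = NULL) {
  if (is.matrix(connections) || is.data.frame(connections)) {
    connections <- conn_key(connections[[1]], connections[[2]])
  }
  connections <- unique(as.character(connections))
  m <- structure(
    list(disabled_connections = connections, disabled_nodes = as.integer(nodes)),
    class = "lesion_mask"
  )
  if (!is.null(genome)) {
    en <- genome$connections[genome$connections$enabled, , drop = FALSE]
    keys <- conn_key(en$source, en$target)
    bad <- setdiff(connections, keys)
    if (length(bad)) {
      stop("mask refers to connections absent or disabled in the genome: ",
           paste(bad, collapse = ", "))
    }
  }
  m
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf(
    "<lesion_mask: %d connection(s)%s>\n",
    length(x$disabled_connections),
    if (length(x$disabled_nodes)) {
      paste0(", standing for node(s) ", paste(x$disabled_nodes, collapse = ", "))
    } else ""
  ))
  invisible(x)
}

#' Merge lesion masks
#'
#' @param ... `lesion_mask` objects.
#' @return The union mask.
#' @export
combine_masks <- function(...) {
  ms <- list(...)
  lesion_mask(
    connections = unique(unlist(lapply(ms, `[[`, "disabled_connections"))),
    nodes = unique(unlist(lapply(ms, `[[`, "disabled_nodes")))
  )
}

#' Lesion mask silencing a whole node
#'
#' A node is lesioned by disabling every enabled connection in which it
#' participates, incoming or outgoing (a self-loop is counted once). A fully
#' input-silenced node keeps emitting `activation(bias)`.
#'
#' @param genome A `lesion_genome`.
#' @param node_id Id of an existing node.
#' @param scope `"both"` (default) disables incoming and outgoing
#'   connections; `"incoming"` or `"outgoing"` restrict the lesion.
#' @return A `lesion_mask` with `disabled_nodes = node_id`.
#' @export
node_lesion_mask <- function(genome, node_id, scope = c("both", "incoming", "outgoing")) {
  scope <- match.arg(scope)
  node_id <- as.integer(node_id)
  if (!node_id %in% genome$nodes$id) stop("unknown node id: ", node_id)
  en <- genome$connections[genome$connections$enabled, , drop = FALSE]
  hit <- switch(scope,
    both     = en$source == node_id | en$target == node_id,
    incoming = en$target == node_id,
    outgoing = en$source == node_id
  )
  lesion_mask(
    connections = conn_key(en$source[hit], en$target[hit]),
    nodes = node_id, genome = genome
  )
}

#' Read / write genome JSON
#'
#' The genome interchange format is a JSON object with `nodes`,
#' `connections` and `metadata` members mirroring [lesion_genome()] fields.
#' Round-trips are lossless.
#'
#' @param path File path.
#' @return `read_genome` returns a `lesion_genome`; `write_genome` returns
#'   `path` invisibly.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  meta <- j$metadata %||% list()
  if (is.data.frame(meta)) meta <- as.list(meta)
  conns <- j$connections
  if (is.null(conns) || !length(conns)) {
    conns <- data.frame(source = integer(), target = integer(),
                        weight = numeric(), enabled = logical())
  }
  lesion_genome(j$nodes, conns, meta)
}

#' @rdname read_genome
#' @param genome A `lesion_genome`.
#' @export
write_genome <- function(genome, path) {
  validate_genome(genome)
  jsonlite::write_json(
    list(nodes = genome$nodes, connections = genome$connections,
         metadata = genome$metadata),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
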