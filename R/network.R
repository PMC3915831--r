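#' MI-weighted regulatory networks
#'
#' An `mi_network` is a tibble of undirected edges `u`, `v`, `mi` (nats)
#' carrying the node set and transcription-factor flags as attributes.
#' Every edge must have at least one TF endpoint, positive weight, distinct
#' endpoints, and appears once with `u < v` lexicographically. Direction is
#' a view derived from the TF flags ([orient_edges()]), not state: the DPI
#' is symmetric, so pruning operates on the undirected graph.
#'
#' @param edges data frame with columns `u`, `v`, `mi`.
#' @param tfs character vector (or [gene_set()]) of transcription-factor
#'   identifiers.
#' @param nodes optional full node set (to keep isolated nodes); defaults
#'   to the identifiers present in `edges` plus `tfs` actually used.
#' @return An `mi_network` tibble.
#' @examples
#' net <- as_mi_network(
#'   data.frame(u = c("TF1", "TF1"), v = c("g1", "g2"), mi = c(0.5, 0.4)),
#'   tfs = "TF1"
#' )
#' network_nodes(net)
#' @export
as_mi_network <- function(edges, tfs, nodes = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("u", "v", "mi") %in% names(edges))) {
    abort("`edges` needs columns u, v, mi.")
  }
  edges$u <- as.character(edges$u)
  edges$v <- as.character(edges$v)
  edges$mi <- as.numeric(edges$mi)
  tfs <- unique(as.character(tfs))
  nodes <- unique(as.character(nodes %||% c(edges$u, edges$v, tfs)))
  if (!all(c(edges$u, edges$v) %in% nodes)) {
    abort("edge endpoints must belong to the node set.")
  }

  cp <- canonical_pair(edges$u, edges$v)
  edges$u <- cp$u
  edges$v <- cp$v
  edges <- arrange(edges[, c("u", "v", "mi")], .data$u, .data$v)

  if (any(edges$u == edges$v)) abort("self-edges are not allowed.")
  if (any(!is.finite(edges$mi) | edges$mi <= 0)) {
    abort("edge weights must be positive and finite.")
  }
  if (anyDuplicated(edge_key(edges$u, edges$v))) {
    abort("duplicate edges (same unordered pair) are not allowed.")
  }
  bad <- !(edges$u %in% tfs) & !(edges$v %in% tfs)
  if (any(bad)) {
    abort(sprintf(
      "%d edge(s) have no transcription-factor endpoint (first: %s-%s).",
      sum(bad), edges$u[which(bad)[1L]], edges$v[which(bad)[1L]]
    ))
  }

  structure(edges,
    class = c("mi_network", class(tibble())),
    nodes = nodes, tfs = intersect(nodes, tfs)
  )
}

#' @rdname as_mi_network
#' @param net an `mi_network`.
#' @export
network_nodes <- function(net) attr(net, "nodes")

#' @rdname as_mi_network
#' @export
network_tfs <- function(net) attr(net, "tfs")

#' @export
print.mi_network <- function(x, ...) {
  cat(sprintf(
    "<mi_network> %d nodes (%d TFs), %d edges\n",
    length(network_nodes(x)), length(network_tfs(x)), nrow(x)
  ))
  NextMethod()
}

# keep attributes across dplyr-style subsetting used internally
keep_edges <- function(net, keep) {
  structure(
    as_tibble(net)[keep, , drop = FALSE],
    class = class(net),
    nodes = network_nodes(net), tfs = network_tfs(net)
  )
}

#' Orient network edges using the TF directionality rule
#'
#' A transcription factor can regulate a non-TF but not the reverse, so
#' TF to non-TF edges are directed from the TF; edges between two TFs
#' cannot be disambiguated and are emitted in both directions flagged
#' `"ambiguous"`.
#'
#' @param net an `mi_network`.
#' @return Tibble with columns `from`, `to`, `mi`, `mode` (`"directed"` or
#'   `"ambiguous"`).
#' @export
orient_edges <- function(net) {
  stopifnot(inherits(net, "mi_network"))
  if (nrow(net) == 0L) {
    return(tibble(
      from = character(), to = character(),
      mi = numeric(), mode = character()
    ))
  }
  tfs <- network_tfs(net)
  u_tf <- net$u %in% tfs
  v_tf <- net$v %in% tfs
  both <- u_tf & v_tf
  single <- tibble(
    from = ifelse(u_tf[!both], net$u[!both], net$v[!both]),
    to = ifelse(u_tf[!both], net$v[!both], net$u[!both]),
    mi = net$mi[!both], mode = "directed"
  )
  dual <- bind_rows(
    tibble(from = net$u[both], to = net$v[both], mi = net$mi[both]),
    tibble(from = net$v[both], to = net$u[both], mi = net$mi[both])
  )
  dual$mode <- rep("ambiguous", nrow(dual))
  arrange(bind_rows(single, dual), .data$from, .data$to)
}

#' Extract the regulon of a transcription factor
#'
#' A TF's regulon is the set of all its network neighbours (TFs and
#' non-TFs alike) with their interaction strengths.
#'
#' @param net an `mi_network`.
#' @param tf a transcription-factor identifier present in the network.
#' @return A `regulon`: tibble of `target`, `mi`, with the TF stored in the
#'   `tf` attribute.
#' @export
extract_regulon <- function(net, tf) {
  stopifnot(inherits(net, "mi_network"))
  if (!tf %in% network_nodes(net)) {
    abort(sprintf("'%s' is not a node of the network.", tf))
  }
  if (!tf %in% network_tfs(net)) {
    abort(sprintf("'%s' is not flagged as a transcription factor.", tf))
  }
  hit_u <- net$u == tf
  hit_v <- net$v == tf
  out <- tibble(
    target = c(net$v[hit_u], net$u[hit_v]),
    mi = c(net$mi[hit_u], net$mi[hit_v])
  )
  out <- arrange(out, .data$target)
  structure(out, class = c("regulon", class(tibble())), tf = tf)
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("<regulon> %s: %d targets\n", attr(x, "tf"), nrow(x)))
  NextMethod()
}

#' Read and write networks in ADJ, SIF, and edge-list formats
#'
#' The ADJ dialect: comment lines start with `>`; the node set and TF flags
#' are stored in `>nodes` / `>tfs` header comments so the round trip is
#' lossless; each data line is a hub identifier followed by alternating
#' target / weight tokens, tab-separated, weights printed with 6
#' significant digits. Each undirected edge is written once, under its
#' lexicographically smaller endpoint.
#'
#' @param net an `mi_network`.
#' @param path output or input file path.
#' @return `read_adj()` returns an `mi_network`; the writers return `path`
#'   invisibly.
#' @export
write_adj <- function(net, path) {
  stopifnot(inherits(net, "mi_network"))
  header <- c(
    ">haracne adjacency v1",
    paste(c(">nodes", network_nodes(net)), collapse = "\t"),
    paste(c(">tfs", network_tfs(net)), collapse = "\t")
  )
  hubs <- split(seq_len(nrow(net)), net$u)
  body <- vapply(names(hubs), function(h) {
    i <- hubs[[h]]
    paste(
      c(h, rbind(net$v[i], sprintf("%.6g", net$mi[i]))),
      collapse = "\t"
    )
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_adj
#' @export
read_adj <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nodes <- character()
  tfs <- character()
  edges <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(line)) next
    tok <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (startsWith(line, ">")) {
      if (tok[1L] == ">nodes") nodes <- tok[-1L]
      if (tok[1L] == ">tfs") tfs <- tok[-1L]
      next
    }
    if (length(tok) < 3L || length(tok) %% 2L == 0L) {
      abort(sprintf(
        "malformed ADJ line %d: expected hub plus target/weight pairs.", ln
      ))
    }
    tgt <- tok[seq(2L, length(tok), by = 2L)]
    w <- suppressWarnings(as.numeric(tok[seq(3L, length(tok), by = 2L)]))
    if (anyNA(w)) abort(sprintf("malformed weight on ADJ line %d.", ln))
    edges[[length(edges) + 1L]] <- tibble(u = tok[1L], v = tgt, mi = w)
  }
  edges <- if (length(edges)) bind_rows(edges) else {
    tibble(u = character(), v = character(), mi = numeric())
  }
  as_mi_network(edges,
    tfs = tfs,
    nodes = if (length(nodes)) nodes else NULL
  )
}

#' @rdname write_adj
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "mi_network"))
  writeLines(sprintf("%s\tpp\t%s", net$u, net$v), path)
  invisible(path)
}

#' @rdname write_adj
#' @export
write_edge_list <- function(net, path) {
  oriented <- orient_edges(net)
  oriented <- oriented[!duplicated(edge_key(
    pmin(oriented$from, oriented$to), pmax(oriented$from, oriented$to)
  )), ]
  readr::write_tsv(
    tibble(
      id1 = oriented$from, id2 = oriented$to,
      mi = oriented$mi, direction_flag = oriented$mode
    ),
    path,
    progress = FALSE
  )
  invisible(path)
}

#' Edges present in one network but not another
#'
#' Bookkeeping for pruning comparisons: returns the edges of `a` missing
#' from `b` (unordered pair comparison). `b` is expected to be a pruned
#' subset of `a`; if not, a warning is emitted and the difference is still
#' computed.
#'
#' @param a,b `mi_network` objects.
#' @return Tibble of edges `u`, `v`, `mi` (weights from `a`).
#' @export
network_difference <- function(a, b) {
  stopifnot(inherits(a, "mi_network"), inherits(b, "mi_network"))
  ka <- edge_key(a$u, a$v)
  kb <- edge_key(b$u, b$v)
  if (!all(kb %in% ka)) {
    warn("`b` contains edges absent from `a`; difference computed anyway.")
  }
  as_tibble(a)[!(ka %in% kb), , drop = FALSE]
}
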