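# --- internal index structures -------------------------------------------

# dense symmetric MI matrix + TF flags for fast path search; networks at
# pruning time are hub-limited and comfortably fit a dense matrix
net_index <- function(net) {
  nodes <- network_nodes(net)
  g <- length(nodes)
  idx <- setNames(seq_len(g), nodes)
  M <- matrix(0, g, g)
  ui <- unname(idx[net$u])
  vi <- unname(idx[net$v])
  if (length(ui)) {
    M[cbind(ui, vi)] <- net$mi
    M[cbind(vi, ui)] <- net$mi
  }
  list(
    nodes = nodes, g = g, M = M, ui = ui, vi = vi,
    tf = nodes %in% network_tfs(net)
  )
}

# neighbours eligible as path interiors, sorted by decreasing edge MI so the
# bottleneck search can stop a scan as soon as weights fall below the bound
interior_adjacency <- function(ix, allow_nontf_bridge) {
  allowed <- if (allow_nontf_bridge) rep(TRUE, ix$g) else ix$tf
  lapply(seq_len(ix$g), function(i) {
    nb <- which(ix$M[i, ] > 0 & allowed)
    nb[order(ix$M[i, nb], decreasing = TRUE)]
  })
}

# widest (max-bottleneck) simple path u -> w1..wk -> v with exactly k
# interior nodes drawn from `adjI`; only paths whose bottleneck exceeds
# `init` are of interest, which prunes the depth-first walk aggressively
max_bottleneck_path <- function(M, adjI, u, v, k, init) {
  visited <- logical(nrow(M))
  visited[u] <- TRUE
  path <- integer(k)
  best <- init
  best_path <- NULL
  rec <- function(cur, depth, rmin) {
    if (depth == k) {
      w_last <- M[cur, v]
      if (w_last > 0) {
        bn <- if (w_last < rmin) w_last else rmin
        if (bn > best) {
          best <<- bn
          best_path <<- path
        }
      }
      return(NULL)
    }
    for (nb in adjI[[cur]]) {
      wnb <- M[cur, nb]
      if (wnb <= best) break  # neighbours sorted by MI: rest are weaker
      if (visited[nb] || nb == v) next
      nm <- if (wnb < rmin) wnb else rmin
      visited[nb] <<- TRUE
      path[depth + 1L] <<- nb
      rec(nb, depth + 1L, nm)
      visited[nb] <<- FALSE
    }
    NULL
  }
  rec(u, 0L, Inf)
  list(bottleneck = best, interior = best_path)
}

new_dpi_ledger <- function(records, per_order) {
  structure(list(records = records, per_order = per_order),
    class = "dpi_ledger"
  )
}

empty_records <- function() {
  tibble(
    u = character(), v = character(), mi = numeric(),
    order_removed = integer(), witness_path = character(),
    margin = numeric()
  )
}

#' @export
print.dpi_ledger <- function(x, ...) {
  cat(sprintf("<dpi_ledger> %d removal(s)\n", nrow(x$records)))
  print(x$per_order)
  invisible(x)
}

new_dpi_prune <- function(network, ledger, order, tolerance, input,
                          stages = NULL, class = "dpi_prune") {
  structure(
    list(
      network = network, ledger = ledger, order = order,
      tolerance = tolerance, input = input, stages = stages
    ),
    class = class
  )
}

#' @export
print.dpi_prune <- function(x, ...) {
  cat(sprintf(
    "<%s> tolerance %g\n",
    if (inherits(x, "haracne_prune")) "haracne_prune" else "dpi_prune",
    x$tolerance
  ))
  print(x$ledger$per_order)
  invisible(x)
}

# shared mark-and-sweep driver: `find_witness(edge_row)` must return NULL or
# list(bottleneck, nodes) against the *entering* network, making each pass a
# pure function of its input and therefore scan-order invariant
run_dpi_pass <- function(net, order, tolerance, find_witness) {
  n_edges <- nrow(net)
  flagged <- logical(n_edges)
  recs <- vector("list", n_edges)
  for (e in seq_len(n_edges)) {
    wit <- find_witness(e)
    if (!is.null(wit)) {
      flagged[e] <- TRUE
      recs[[e]] <- tibble(
        u = net$u[e], v = net$v[e], mi = net$mi[e],
        order_removed = order,
        witness_path = paste(wit$nodes, collapse = "|"),
        margin = wit$bottleneck - net$mi[e]
      )
    }
  }
  records <- if (any(flagged)) bind_rows(recs[flagged]) else empty_records()
  per_order <- tibble(
    order = order, entering = n_edges,
    removed = sum(flagged), leaving = n_edges - sum(flagged)
  )
  list(
    network = keep_edges(net, !flagged),
    ledger = new_dpi_ledger(records, per_order)
  )
}

# --- exported operations --------------------------------------------------

#' First-order DPI pruning of indirect interactions
#'
#' The data processing inequality states that information transmitted along
#' a Markov chain cannot increase: if gene m mediates the dependence of u
#' and v, then I(u; v) is strictly smaller than both I(u; m) and I(m; v).
#' For every edge, all eligible intermediaries connected to both endpoints
#' in the *entering* network are examined, and the edge is flagged when
#' `mi(u, v) < (1 - tolerance) * min(mi(u, m), mi(m, v))` for some m.
#' Flagged edges are removed together after the full scan (mark-and-sweep),
#' so the result does not depend on scan order.
#'
#' Interior nodes must be transcription factors: a non-TF cannot propagate
#' transcriptional information onward. Set `allow_nontf_bridge = TRUE` to
#' also accept non-TF intermediaries (e.g. a shared target bridging two
#' TFs), the permissive triplet behaviour of classic relevance-network
#' pruning.
#'
#' @param net an [as_mi_network()] object.
#' @param tolerance DPI tolerance in `[0, 1)`; 0 (default) applies the
#'   strict inequality, larger values are more conservative (fewer
#'   removals).
#' @param allow_nontf_bridge allow non-TF interior nodes (default `FALSE`).
#' @return A `dpi_prune` object: list with `network` (pruned), `ledger`
#'   (removal records with witness paths and margins), `order`,
#'   `tolerance`, and the `input` network.
#' @seealso [dpik_prune()], [haracne_prune()], [per_order_summary()]
#' @export
dpi1_prune <- function(net, tolerance = 0, allow_nontf_bridge = FALSE) {
  stopifnot(inherits(net, "mi_network"))
  check_tolerance(tolerance)
  ix <- net_index(net)
  allowed <- if (allow_nontf_bridge) rep(TRUE, ix$g) else ix$tf
  scale <- 1 - tolerance

  find_witness <- function(e) {
    u <- ix$ui[e]
    v <- ix$vi[e]
    w <- net$mi[e]
    cand <- which(ix$M[u, ] > 0 & ix$M[v, ] > 0 & allowed)
    if (!length(cand)) return(NULL)
    mins <- pmin(ix$M[u, cand], ix$M[v, cand])
    j <- which.max(mins)
    if (w < scale * mins[j]) {
      list(
        bottleneck = mins[j],
        nodes = ix$nodes[c(u, cand[j], v)]
      )
    } else {
      NULL
    }
  }

  pass <- run_dpi_pass(net, 1L, tolerance, find_witness)
  new_dpi_prune(pass$network, pass$ledger, 1L, tolerance, input = net)
}

#' Higher-order DPI pruning
#'
#' Order-k DPI generalizes the triplet rule to Markov chains with k
#' intermediaries: an edge u-v is indirect when a simple path
#' u, w1, ..., wk, v of k+1 surviving edges exists whose weakest edge still
#' carries more information than the direct edge, i.e.
#' `mi(u, v) < (1 - tolerance) * min(path edge MIs)`. All paths are
#' evaluated against the entering network (mark-and-sweep); removed edges
#' are recorded with the maximal-margin witness path. Interior nodes obey
#' the same TF rule as [dpi1_prune()]. The witness search is a depth-first
#' simple-path walk that abandons any branch whose running minimum cannot
#' beat the best bottleneck found so far.
#'
#' The caller is responsible for applying orders sequentially (pass the
#' output of order k-1); [haracne_prune()] does this.
#'
#' @inheritParams dpi1_prune
#' @param k DPI order, an integer `>= 2` (use [dpi1_prune()] for order 1).
#' @return A `dpi_prune` object (see [dpi1_prune()]).
#' @export
dpik_prune <- function(net, k, tolerance = 0, allow_nontf_bridge = FALSE) {
  stopifnot(inherits(net, "mi_network"))
  check_tolerance(tolerance)
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k)) {
    abort("`k` must be an integer >= 2; use dpi1_prune() for order 1.")
  }
  k <- as.integer(k)
  ix <- net_index(net)
  adjI <- interior_adjacency(ix, allow_nontf_bridge)
  scale <- 1 - tolerance

  find_witness <- function(e) {
    u <- ix$ui[e]
    v <- ix$vi[e]
    w <- net$mi[e]
    res <- max_bottleneck_path(ix$M, adjI, u, v, k, init = w / scale)
    if (is.null(res$interior)) return(NULL)
    list(
      bottleneck = res$bottleneck,
      nodes = ix$nodes[c(u, res$interior, v)]
    )
  }

  pass <- run_dpi_pass(net, k, tolerance, find_witness)
  new_dpi_prune(pass$network, pass$ledger, k, tolerance, input = net)
}

#' Sequential higher-order DPI pruning (the hARACNe schedule)
#'
#' Applies [dpi1_prune()] and then [dpik_prune()] for k = 2..`max_order`,
#' each pass consuming the previous pass's output. Pairwise MI is computed
#' once, before pruning; no pass re-estimates it. Edges removed at a lower
#' order are never reinstated and never serve as witness-path edges at a
#' higher order, so lower orders need not be revisited and the surviving
#' edge sets are nested across orders.
#'
#' @inheritParams dpi1_prune
#' @param max_order largest DPI order K to apply (`>= 1`). Default 3:
#'   orders 2 and 3 provide nearly all of the additional filtering, while
#'   order 4 and above saturate quickly at much higher search cost.
#' @return A `haracne_prune` object: `network` (final), `ledger`
#'   (concatenated records and per-order counts), `stages` (network after
#'   each order), `input`, `tolerance`.
#' @examples
#' net <- as_mi_network(
#'   data.frame(
#'     u = c("A", "B", "C", "A"), v = c("B", "C", "D", "D"),
#'     mi = c(0.9, 0.8, 0.7, 0.3)
#'   ),
#'   tfs = c("A", "B", "C", "D")
#' )
#' fit <- haracne_prune(net, max_order = 3)
#' per_order_summary(fit)
#' @export
haracne_prune <- function(net, max_order = 3L, tolerance = 0,
                          allow_nontf_bridge = FALSE) {
  stopifnot(inherits(net, "mi_network"))
  if (max_order < 1L) abort("`max_order` must be at least 1.")
  max_order <- as.integer(max_order)

  current <- net
  records <- list()
  per_order <- list()
  stages <- list()
  for (k in seq_len(max_order)) {
    pass <- if (k == 1L) {
      dpi1_prune(current, tolerance, allow_nontf_bridge)
    } else {
      dpik_prune(current, k, tolerance, allow_nontf_bridge)
    }
    current <- pass$network
    records[[k]] <- pass$ledger$records
    per_order[[k]] <- pass$ledger$per_order
    stages[[as.character(k)]] <- current
  }

  ledger <- new_dpi_ledger(
    bind_rows(records),
    bind_rows(per_order)
  )
  new_dpi_prune(current, ledger, max_order, tolerance,
    input = net, stages = stages,
    class = c("haracne_prune", "dpi_prune")
  )
}

#' Per-order pruning summary
#'
#' Entering / removed / leaving edge counts for each DPI order of a run;
#' rows chain: `leaving = entering - removed` and the next order enters
#' with the previous order's survivors.
#'
#' @param x a `dpi_prune`, `haracne_prune`, or `dpi_ledger`.
#' @return Tibble with columns `order`, `entering`, `removed`, `leaving`.
#' @export
per_order_summary <- function(x) {
  if (inherits(x, "dpi_prune")) x <- x$ledger
  stopifnot(inherits(x, "dpi_ledger"))
  x$per_order
}

check_tolerance <- function(tolerance) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L ||
    tolerance < 0 || tolerance >= 1) {
    abort("`tolerance` must lie in [0, 1).")
  }
}
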