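# Shared fixtures and independent brute-force oracles.
#
# The oracles deliberately avoid the package's search strategy: DPI passes
# are checked against exhaustive enumeration of ordered interior tuples,
# and the exact tests against direct summation over the hypergeometric
# support using log-binomials.

# --- random fixtures ------------------------------------------------------

# random TF-constrained MI network; weights are continuous so ties have
# probability zero
random_test_network <- function(seed, n_nodes = 9L, n_tfs = 5L,
                                density = 0.45) {
  withr::with_seed(seed, {
    nodes <- sprintf("N%02d", seq_len(n_nodes))
    tfs <- nodes[seq_len(n_tfs)]
    pairs <- t(utils::combn(nodes, 2L))
    eligible <- pairs[pairs[, 1L] %in% tfs | pairs[, 2L] %in% tfs, ,
      drop = FALSE
    ]
    keep <- stats::runif(nrow(eligible)) < density
    if (!any(keep)) keep[1L] <- TRUE
    edges <- tibble::tibble(
      u = eligible[keep, 1L], v = eligible[keep, 2L],
      mi = stats::runif(sum(keep), 0.05, 1)
    )
    haracne::as_mi_network(edges, tfs = tfs, nodes = nodes)
  })
}

random_expression_fixture <- function(seed, n_genes = 6L, n_samples = 4L) {
  withr::with_seed(seed, {
    haracne::expression_matrix(matrix(
      round(stats::rnorm(n_genes * n_samples), 4L),
      n_genes, n_samples,
      dimnames = list(
        sprintf("G%03d", seq_len(n_genes)),
        sprintf("S%02d", seq_len(n_samples))
      )
    ))
  })
}

# --- brute-force DPI oracle ----------------------------------------------

# all ordered k-tuples of distinct values from v, as a matrix (rows=tuples)
ordered_tuples <- function(v, k) {
  if (k == 0L || length(v) < k) {
    return(matrix(integer(), nrow = 0L, ncol = k))
  }
  grids <- do.call(expand.grid, rep(list(v), k))
  m <- as.matrix(grids)
  if (k > 1L) {
    distinct <- apply(m, 1L, function(r) !anyDuplicated(r))
    m <- m[distinct, , drop = FALSE]
  }
  unname(m)
}

# flags edges removable by one order-k DPI pass over `net`, by exhaustive
# enumeration of every ordered interior tuple
oracle_dpi_flags <- function(net, k, eps, allow_nontf_bridge = FALSE) {
  nodes <- haracne::network_nodes(net)
  g <- length(nodes)
  idx <- stats::setNames(seq_len(g), nodes)
  M <- matrix(0, g, g)
  ui <- unname(idx[net$u])
  vi <- unname(idx[net$v])
  M[cbind(ui, vi)] <- net$mi
  M[cbind(vi, ui)] <- net$mi
  tf <- nodes %in% haracne::network_tfs(net)
  interiors <- if (allow_nontf_bridge) seq_len(g) else which(tf)
  tup <- ordered_tuples(interiors, k)

  flagged <- logical(nrow(net))
  if (nrow(tup) == 0L) return(flagged)
  for (e in seq_len(nrow(net))) {
    u <- ui[e]
    v <- vi[e]
    keep <- rowSums(tup == u) == 0L & rowSums(tup == v) == 0L
    t2 <- tup[keep, , drop = FALSE]
    if (nrow(t2) == 0L) next
    pathnodes <- cbind(u, t2, v)
    mins <- rep(Inf, nrow(t2))
    for (j in seq_len(k + 1L)) {
      mins <- pmin(mins, M[cbind(pathnodes[, j], pathnodes[, j + 1L])])
    }
    bottleneck <- max(mins)  # absent edges give 0, never the max over valid
    if (net$mi[e] < (1 - eps) * bottleneck) flagged[e] <- TRUE
  }
  flagged
}

# sequential oracle: order-1..K passes, each on the survivors of the last
oracle_sequential_prune <- function(net, max_order, eps,
                                    allow_nontf_bridge = FALSE) {
  removed_per_order <- integer(max_order)
  for (k in seq_len(max_order)) {
    flags <- oracle_dpi_flags(net, k, eps, allow_nontf_bridge)
    removed_per_order[k] <- sum(flags)
    net <- haracne::as_mi_network(
      tibble::as_tibble(net)[!flags, , drop = FALSE],
      tfs = haracne::network_tfs(net), nodes = haracne::network_nodes(net)
    )
  }
  list(network = net, removed = removed_per_order)
}

edge_keys <- function(net) paste(net$u, net$v, sep = "~")

# --- exact-test oracles ---------------------------------------------------

# hypergeometric upper tail by direct summation of log-binomial terms
oracle_hyper_tail <- function(N, K, n, k) {
  js <- seq(max(k, 0L, n - (N - K)), min(n, K))
  if (length(js) == 0L || k > min(n, K)) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# two-sided Fisher p by enumerating all tables with the observed margins
# and summing point probabilities <= the observed one (with the standard
# relative tolerance guarding floating-point ties)
oracle_fisher_two_sided <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  support <- seq(max(0L, r1 + c1 - n), min(r1, c1))
  probs <- exp(
    lchoose(r1, support) + lchoose(n - r1, c1 - support) - lchoose(n, c1)
  )
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
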