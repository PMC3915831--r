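#' Bootstrap resampling of expression samples
#'
#' Draws samples (columns) with replacement to the original sample count;
#' genes are untouched. Resampled column labels are suffix-disambiguated to
#' keep sample identifiers unique.
#'
#' @param x an expression matrix.
#' @param seed integer seed; the resample is deterministic given the seed.
#' @return An [expression_matrix()] of identical dimensions.
#' @export
bootstrap_sample <- function(x, seed) {
  x <- as_expression_matrix(x)
  n <- ncol(x)
  if (n < 1L) abort("need at least one sample to resample.")
  cols <- with_seed(seed, sample.int(n, n, replace = TRUE))
  vals <- unclass(x)[, cols, drop = FALSE]
  colnames(vals) <- make.unique(colnames(x)[cols], sep = ".b")
  expression_matrix(vals)
}

#' Consensus network from repeated inference runs
#'
#' Edges are scored by their support count across runs. Under the null
#' that edge occurrences land by chance on any evaluable pair, each edge's
#' support is modelled as Poisson with mean equal to the total number of
#' edge occurrences divided by the number of potential edges (pairs with
#' at least one TF endpoint over the union node set); an edge is kept when
#' its upper-tail Poisson probability passes `alpha` Bonferroni-corrected
#' for the distinct edges actually tested. Unanimously supported edges are
#' therefore retained at any practical `alpha`, while edges appearing in a
#' single run are discarded. Kept edges are weighted by their mean MI
#' across supporting runs. A consensus network can contain edges absent
#' from any single un-resampled run; that is expected behaviour, not an
#' error.
#'
#' @param runs list of [as_mi_network()] objects from independent runs.
#' @param alpha significance level before Bonferroni correction
#'   (default 0.05).
#' @return An `mi_network` with a `support` attribute: tibble of every
#'   observed edge with `support`, `mean_mi`, `p_value`, `kept`.
#' @export
consensus_network <- function(runs, alpha = 0.05) {
  if (!is.list(runs) || length(runs) < 2L) {
    abort("`runs` must be a list of at least 2 networks.")
  }
  if (!all(vapply(runs, inherits, logical(1), "mi_network"))) {
    abort("every element of `runs` must be an mi_network.")
  }
  all_edges <- bind_rows(lapply(runs, as_tibble))
  if (nrow(all_edges) == 0L) {
    abort("no edges observed in any run; nothing to score.")
  }
  support <- all_edges |>
    group_by(.data$u, .data$v) |>
    summarise(
      support = dplyr::n(), mean_mi = mean(.data$mi), .groups = "drop"
    )
  nodes <- unique(unlist(lapply(runs, network_nodes)))
  tfs <- unique(unlist(lapply(runs, network_tfs)))
  n_nodes <- length(nodes)
  n_nontf <- n_nodes - length(tfs)
  n_potential <- choose(n_nodes, 2L) - choose(n_nontf, 2L)

  n_distinct_edges <- nrow(support)
  lambda <- nrow(all_edges) / n_potential
  support$p_value <- ppois(support$support - 1L, lambda, lower.tail = FALSE)
  support$kept <- support$p_value <= alpha / n_distinct_edges
  net <- as_mi_network(
    support |>
      filter(.data$kept) |>
      select(u = "u", v = "v", mi = "mean_mi"),
    tfs = tfs, nodes = nodes
  )
  attr(net, "support") <- support
  net
}

#' @rdname consensus_network
#' @param net a consensus network.
#' @export
edge_support <- function(net) attr(net, "support")

#' Bootstrap-consensus network inference pipeline
#'
#' For each of `B` bootstraps: resample the expression samples, recompute
#' the MI significance threshold on the resample (the null depends on the
#' unchanged sample count, but resampling-induced ties shift the estimator,
#' so each bootstrap is treated as an independent full run), build the
#' TF-constrained MI network, and prune it with the sequential higher-order
#' DPI schedule. The runs are then combined by [consensus_network()].
#'
#' @param x an expression matrix.
#' @param tfs transcription-factor identifiers.
#' @param B number of bootstraps (at least 2; the conventional production
#'   count is 100).
#' @param alpha consensus significance level (see [consensus_network()]).
#' @param p_value MI-threshold p-value per run (see [mi_threshold()]).
#' @param n_perm permutations per run's null model.
#' @param max_order,tolerance passed to [haracne_prune()].
#' @param seed master seed; `B` per-run sub-seeds are derived from it and
#'   the whole pipeline is reproducible given the seed.
#' @return A `bootstrap_run`: list with the consensus `network`, the
#'   `support` table, `B`, `seed`, and the per-run seeds.
#' @export
bootstrap_haracne <- function(x, tfs, B = 100L, alpha = 0.05,
                              p_value = 1e-4, n_perm = 2000L,
                              max_order = 3L, tolerance = 0, seed = 1L) {
  x <- as_expression_matrix(x)
  if (B < 2L) abort("`B` must be at least 2.")
  sub_seeds <- derive_seeds(seed, 2L * B)
  runs <- lapply(seq_len(B), function(b) {
    xb <- bootstrap_sample(x, seed = sub_seeds[b])
    thr <- mi_null_threshold(
      n = ncol(xb), n_perm = n_perm, p_value = p_value,
      seed = sub_seeds[B + b]
    )$threshold
    haracne_prune(
      mi_network(xb, tfs, threshold = thr),
      max_order = max_order, tolerance = tolerance
    )$network
  })
  net <- consensus_network(runs, alpha = alpha)
  structure(
    list(
      network = net, support = edge_support(net), B = as.integer(B),
      seed = as.integer(seed), run_seeds = sub_seeds[seq_len(B)]
    ),
    class = "bootstrap_run"
  )
}

#' @export
print.bootstrap_run <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_run> B = %d (seed %d): %d supported edge(s), %d kept\n",
    x$B, x$seed, nrow(x$support), sum(x$support$kept)
  ))
  invisible(x)
}
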