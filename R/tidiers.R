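#' Broom-style tidiers
#'
#' `tidy()` returns the per-record detail of a fitted object as a tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x a fitted object from this package.
#' @param ... unused.
#' @return A tibble.
#' @name haracne-tidiers
NULL

#' @rdname haracne-tidiers
#' @export
tidy.mi_network <- function(x, ...) as_tibble(x)

#' @rdname haracne-tidiers
#' @export
glance.mi_network <- function(x, ...) {
  tibble(
    nodes = length(network_nodes(x)),
    tfs = length(network_tfs(x)),
    edges = nrow(x),
    total_mi = sum(x$mi)
  )
}

#' @rdname haracne-tidiers
#' @export
tidy.dpi_prune <- function(x, ...) x$ledger$records

#' @rdname haracne-tidiers
#' @export
glance.dpi_prune <- function(x, ...) {
  po <- x$ledger$per_order
  tibble(
    max_order = max(po$order),
    tolerance = x$tolerance,
    entering = po$entering[1L],
    removed = sum(po$removed),
    leaving = po$leaving[nrow(po)]
  )
}

#' @rdname haracne-tidiers
#' @export
tidy.dpi_ledger <- function(x, ...) x$records

#' @rdname haracne-tidiers
#' @export
tidy.bootstrap_run <- function(x, ...) x$support

#' @rdname haracne-tidiers
#' @export
glance.bootstrap_run <- function(x, ...) {
  tibble(
    B = x$B, seed = x$seed,
    edges_observed = nrow(x$support),
    edges_kept = sum(x$support$kept),
    total_edge_occurrences = sum(x$support$support)
  )
}

#' @rdname haracne-tidiers
#' @export
tidy.validation_report <- function(x, ...) x$stages

#' @rdname haracne-tidiers
#' @export
glance.validation_report <- function(x, ...) as_tibble(x$gain)
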