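#' Pipeline configuration
#'
#' A flat, serializable run configuration with every tunable parameter of
#' the inference pipeline. Unknown keys are rejected so a reloaded config
#' reproduces the run that wrote it.
#'
#' @param ... named overrides of the defaults listed below.
#' @return A `haracne_config` list: `estimator` ("adaptive"), `p_value`
#'   (1e-4), `n_perm` (2000), `tolerance` (0), `max_order` (3),
#'   `allow_nontf_bridge` (FALSE), `bootstrap` (0 = no bootstrap; the
#'   conventional production count is 100), `alpha` (0.05), `seed` (1).
#' @export
haracne_config <- function(...) {
  defaults <- list(
    estimator = "adaptive", p_value = 1e-4, n_perm = 2000L,
    tolerance = 0, max_order = 3L, allow_nontf_bridge = FALSE,
    bootstrap = 0L, alpha = 0.05, seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  structure(modifyList(defaults, overrides), class = "haracne_config")
}

#' @rdname haracne_config
#' @param config a `haracne_config`.
#' @param path file path for the JSON-serialized config.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "haracne_config"))
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname haracne_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  do.call(haracne_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run the full inference pipeline
#'
#' Orchestrates one reproducible run: expression in, MI significance
#' threshold from the permutation null, TF-constrained MI network (computed
#' once; pruning never re-estimates MI), sequential higher-order DPI
#' pruning, and optionally bootstrap consensus. When `out_dir` is given,
#' the pruned network (ADJ), the removal ledger (TSV), the per-order
#' summary (TSV) and a run manifest (JSON, with a config fingerprint that
#' suffices to reproduce the run bit for bit) are written there.
#'
#' @param x expression matrix, or path to a TSV readable by
#'   [read_expression()].
#' @param tfs TF identifiers, or path to a list readable by
#'   [read_gene_list()].
#' @param config a [haracne_config()].
#' @param out_dir optional output directory.
#' @return A `haracne_pipeline` list: `network` (final), `relevance`
#'   (unpruned MI network), `fit` (the [haracne_prune()] object),
#'   `threshold`, `bootstrap` (a `bootstrap_run` or `NULL`), `config`,
#'   `manifest`, and output `paths` when written.
#' @export
run_pipeline <- function(x, tfs, config = haracne_config(), out_dir = NULL) {
  stopifnot(inherits(config, "haracne_config"))
  x_is_path <- is.character(x) && length(x) == 1L && file.exists(x)
  tfs_is_path <- is.character(tfs) && length(tfs) == 1L && file.exists(tfs)
  input_paths <- list(
    expression = if (x_is_path) x else NA_character_,
    tfs = if (tfs_is_path) tfs else NA_character_
  )
  if (x_is_path) x <- read_expression(x)
  x <- as_expression_matrix(x)
  if (tfs_is_path) tfs <- read_gene_list(tfs, label = "TF list")

  sub_seeds <- derive_seeds(config$seed, 2L)
  thr <- mi_null_threshold(
    n = ncol(x), n_perm = config$n_perm, p_value = config$p_value,
    seed = sub_seeds[1L]
  )$threshold
  relevance <- mi_network(x, tfs, thr, estimator = config$estimator)
  fit <- haracne_prune(relevance,
    max_order = config$max_order, tolerance = config$tolerance,
    allow_nontf_bridge = config$allow_nontf_bridge
  )

  boot <- NULL
  if (config$bootstrap >= 2L) {
    boot <- bootstrap_haracne(x, tfs,
      B = config$bootstrap, alpha = config$alpha,
      p_value = config$p_value, n_perm = config$n_perm,
      max_order = config$max_order, tolerance = config$tolerance,
      seed = sub_seeds[2L]
    )
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("haracne")),
    config = unclass(config),
    config_fingerprint = fnv1a_hash(as.character(cfg_json)),
    inputs = input_paths,
    n_genes = nrow(x), n_samples = ncol(x),
    n_tfs_used = length(intersect(as.character(tfs), rownames(x))),
    mi_threshold = thr,
    derived_seeds = as.list(sub_seeds)
  )

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      network = file.path(out_dir, "network.adj"),
      relevance = file.path(out_dir, "relevance.adj"),
      ledger = file.path(out_dir, "ledger.tsv"),
      summary = file.path(out_dir, "per_order_summary.tsv"),
      manifest = file.path(out_dir, "manifest.json")
    )
    write_adj(fit$network, paths$network)
    write_adj(relevance, paths$relevance)
    readr::write_tsv(fit$ledger$records, paths$ledger, progress = FALSE)
    readr::write_tsv(per_order_summary(fit), paths$summary, progress = FALSE)
    jsonlite::write_json(manifest, paths$manifest,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    if (!is.null(boot)) {
      paths$consensus <- file.path(out_dir, "consensus.adj")
      paths$support <- file.path(out_dir, "support.tsv")
      write_adj(boot$network, paths$consensus)
      readr::write_tsv(boot$support, paths$support, progress = FALSE)
    }
  }

  structure(
    list(
      network = fit$network, relevance = relevance, fit = fit,
      threshold = thr, bootstrap = boot, config = config,
      manifest = manifest, paths = paths
    ),
    class = "haracne_pipeline"
  )
}

#' @export
print.haracne_pipeline <- function(x, ...) {
  cat(sprintf(
    "<haracne_pipeline> threshold %.4g nats; %d -> %d edges (max order %d)\n",
    x$threshold, nrow(x$relevance), nrow(x$network), x$config$max_order
  ))
  invisible(x)
}
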