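#' Rank-transform a numeric vector to (0, 1)
#'
#' Mutual information is estimated on the copula scale: values are replaced
#' by mid-ranks scaled to the open unit interval, `(rank - 0.5) / n`, with
#' ties broken by average rank. MI is invariant under monotone transforms,
#' so this removes marginal effects without losing dependence structure.
#'
#' @param x numeric vector, length at least 2.
#' @return Numeric vector in (0, 1); a constant input maps to all 0.5 and
#'   carries a `degenerate` attribute.
#' @export
rank_transform <- function(x) {
  if (length(x) < 2L) abort("need at least 2 observations to rank.")
  if (anyNA(x)) abort("missing values are not allowed.")
  r <- (rank(x, ties.method = "average") - 0.5) / length(x)
  if (isTRUE(all(x == x[1L]))) attr(r, "degenerate") <- TRUE
  r
}

#' Pairwise mutual information between two expression profiles
#'
#' Estimates I(x; y) = S(x) + S(y) - S(x, y) in nats. The default
#' adaptive-partitioning estimator rank-transforms both vectors and
#' recursively subdivides the unit square into quadrants while a chi-square
#' test (df = 3, alpha = 0.05) rejects uniformity of the quadrant counts;
#' each terminal cell contributes its plug-in term. Because the chi-square
#' gate refuses to split under independence, independent data typically
#' yield exactly zero. A fixed-bin (equal-frequency) estimator is provided
#' as a cross-check.
#'
#' @param x,y numeric vectors of equal length (at least 8).
#' @param estimator `"adaptive"` (default) or `"fixed"`.
#' @param bins number of marginal bins for the fixed-bin estimator; default
#'   `floor(sqrt(n / 5))`, clamped to 2..20.
#' @return An `mi_estimate`: list with `value` (nats, >= 0), `n`,
#'   `estimator`, and `degenerate` flag. The estimate is exactly symmetric
#'   in its arguments.
#' @examples
#' set.seed(1)
#' x <- rnorm(500)
#' mutual_information(x, 0.8 * x + 0.6 * rnorm(500))$value
#' @export
mutual_information <- function(x, y, estimator = c("adaptive", "fixed"),
                               bins = NULL) {
  estimator <- match.arg(estimator)
  if (length(x) != length(y)) abort("x and y must have equal length.")
  if (length(x) < 8L) abort("need at least 8 paired observations.")
  if (anyNA(x) || anyNA(y)) abort("missing values are not allowed.")
  n <- length(x)
  degenerate <- all(x == x[1L]) || all(y == y[1L])
  # canonicalize argument order so the estimate is bit-identical under
  # swapping (summation order inside the estimators is not commutative at
  # floating-point precision)
  rx <- rank_transform(x)
  ry <- rank_transform(y)
  d <- which(rx != ry)
  if (length(d) && ry[d[1L]] < rx[d[1L]]) {
    tmp <- rx
    rx <- ry
    ry <- tmp
  }
  value <- if (degenerate) {
    0
  } else if (estimator == "adaptive") {
    .ap_mi_cpp(rx, ry)
  } else {
    fixed_bin_mi_ranks(rx, ry, bins)
  }
  structure(
    list(value = value, n = n, estimator = estimator, degenerate = degenerate),
    class = "mi_estimate"
  )
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf(
    "<mi_estimate> %.5f nats (%s, n = %d)%s\n",
    x$value, x$estimator, x$n, if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

# equal-frequency binning on pre-computed ranks, plug-in MI in nats
fixed_bin_mi_ranks <- function(rx, ry, bins = NULL) {
  n <- length(rx)
  b <- bins %||% max(2L, min(20L, floor(sqrt(n / 5))))
  cx <- ceiling(rx * b)
  cy <- ceiling(ry * b)
  tab <- table(cx, cy) / n
  px <- rowSums(tab)
  py <- colSums(tab)
  pos <- tab > 0
  max(0, sum(tab[pos] * log(tab[pos] / outer(px, py)[pos])))
}

#' Permutation null model and significance threshold for MI
#'
#' Estimator noise under independence is calibrated by computing MI between
#' independently permuted rank vectors of the matched sample size; the rank
#' transform makes the null depend on `n` only. Because the chi-square gate
#' of the adaptive estimator returns exactly zero for most null draws,
#' interesting p-values exceed the permutation resolution and are obtained
#' from an exponential fit to the positive upper tail: the empirical
#' survival probabilities of the top decile of draws are regressed as
#' log p = a + b * MI, and `mi_threshold()` inverts the fit.
#'
#' @param n sample count the null is matched to.
#' @param n_perm number of permutations (at least 100).
#' @param p_value significance level in (0, 1] at which the threshold is
#'   reported.
#' @param seed integer seed; the null is reproducible given the seed.
#' @param estimator passed to [mutual_information()].
#' @param tail_fit if `FALSE`, use the empirical quantile instead of the
#'   exponential tail fit (errors when `p_value` is below `1/n_perm`).
#' @return `mi_null()` returns an `mi_null_model` (draws, fitted tail
#'   coefficients, seed); `mi_null_threshold()` returns a list with the
#'   model and the `threshold` in nats. Thresholds are monotone: a smaller
#'   `p_value` gives a larger threshold.
#' @export
mi_null <- function(n, n_perm = 2000L, seed = 1L,
                    estimator = c("adaptive", "fixed")) {
  estimator <- match.arg(estimator)
  if (n_perm < 100L) abort("`n_perm` must be at least 100.")
  if (n < 8L) abort("`n` must be at least 8.")
  draws <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      mutual_information(sample.int(n), sample.int(n),
        estimator = estimator
      )$value
    }, numeric(1))
  })
  tail <- fit_exponential_tail(draws)
  structure(
    list(
      n = as.integer(n), n_perm = as.integer(n_perm), draws = draws,
      tail = tail, seed = as.integer(seed), estimator = estimator
    ),
    class = "mi_null_model"
  )
}

# least-squares fit of log empirical survival vs MI on the positive part of
# the upper decile; returns c(intercept, slope) or NULL when degenerate
fit_exponential_tail <- function(draws) {
  n_perm <- length(draws)
  pos <- sort(draws[draws > 0], decreasing = TRUE)
  pos <- pos[seq_len(min(length(pos), ceiling(n_perm / 10)))]
  if (length(pos) < 3L) return(NULL)
  surv <- seq_along(pos) / n_perm
  fit <- lm(log(surv) ~ pos)
  cf <- coef(fit)
  if (!is.finite(cf[2L]) || cf[2L] >= 0) return(NULL)
  c(intercept = unname(cf[1L]), slope = unname(cf[2L]))
}

#' @rdname mi_null
#' @param null an `mi_null_model`.
#' @export
mi_threshold <- function(null, p_value, tail_fit = TRUE) {
  stopifnot(inherits(null, "mi_null_model"))
  if (p_value <= 0 || p_value > 1) abort("`p_value` must be in (0, 1].")
  if (p_value == 1) return(0)
  if (!tail_fit) {
    if (p_value < 1 / null$n_perm) {
      abort(paste(
        "`p_value` below permutation resolution;",
        "increase `n_perm` or enable the tail fit."
      ))
    }
    return(unname(quantile(null$draws, 1 - p_value, type = 1)))
  }
  if (is.null(null$tail)) {
    # too few positive draws to fit a tail; fall back to the empirical
    # quantile when the p-value is within permutation resolution
    if (p_value >= 1 / null$n_perm) {
      return(unname(quantile(null$draws, 1 - p_value, type = 1)))
    }
    abort(paste(
      "the permutation null has too few positive draws to fit a tail",
      "and `p_value` is below permutation resolution; increase `n_perm`."
    ))
  }
  max(0, (log(p_value) - null$tail[["intercept"]]) / null$tail[["slope"]])
}

#' @rdname mi_null
#' @export
mi_null_threshold <- function(n, n_perm = 2000L, p_value = 1e-4, seed = 1L,
                              tail_fit = TRUE) {
  null <- mi_null(n, n_perm = n_perm, seed = seed)
  list(null = null, threshold = mi_threshold(null, p_value, tail_fit))
}

#' @export
print.mi_null_model <- function(x, ...) {
  cat(sprintf(
    "<mi_null_model> n = %d, %d permutations (seed %d), %.1f%% positive\n",
    x$n, x$n_perm, x$seed, 100 * mean(x$draws > 0)
  ))
  invisible(x)
}

#' Build a TF-constrained mutual-information relevance network
#'
#' Evaluates MI only for gene pairs with at least one transcription-factor
#' endpoint (a TF can regulate a non-TF but not vice versa, so pairs of
#' non-TFs cannot be regulatory edges) and keeps pairs whose MI reaches the
#' significance threshold.
#'
#' @param x an expression matrix (or coercible data frame / matrix).
#' @param tfs transcription-factor identifiers ([gene_set()] or character).
#' @param threshold MI threshold in nats, usually from [mi_threshold()].
#' @param estimator passed to [mutual_information()].
#' @return An [as_mi_network()] tibble of edges `u`, `v`, `mi`.
#' @export
mi_network <- function(x, tfs, threshold, estimator = c("adaptive", "fixed")) {
  x <- as_expression_matrix(x)
  estimator <- match.arg(estimator)
  ids <- rownames(x)
  tf_ids <- intersect(as.character(tfs), ids)
  if (length(tf_ids) == 0L) {
    abort("no transcription factor is present in the expression matrix.")
  }
  if (threshold < 0) abort("`threshold` must be non-negative.")

  g <- length(ids)
  is_tf <- ids %in% tf_ids
  tf_idx <- which(is_tf)

  # unordered pairs with >= 1 TF endpoint, each exactly once: a TF is paired
  # with every other gene except TFs of smaller index (those pairs were
  # already emitted when the smaller-index TF was processed)
  partner_sets <- lapply(tf_idx, function(i) {
    j <- seq_len(g)
    j[j != i & !(is_tf & j < i)]
  })
  pairs <- rbind(
    rep(tf_idx, lengths(partner_sets)),
    unlist(partner_sets, use.names = FALSE)
  )

  mis <- if (estimator == "adaptive") {
    ranks <- apply(unclass(x), 1L, rank_transform)  # samples x genes
    .ap_mi_pairs_cpp(ranks, pairs)
  } else {
    apply(pairs, 2L, function(p) {
      mutual_information(unclass(x)[p[1L], ], unclass(x)[p[2L], ],
        estimator = "fixed"
      )$value
    })
  }

  keep <- mis >= threshold & mis > 0
  edges <- tibble(
    u = ids[pairs[1L, keep]],
    v = ids[pairs[2L, keep]],
    mi = mis[keep]
  )
  as_mi_network(edges, tfs = tf_ids, nodes = ids)
}
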