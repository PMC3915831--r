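#' Classify a regulon against a gold-standard positive set
#'
#' Counts how many inferred targets of a TF are supported by orthogonal
#' evidence (e.g. promoter binding in ChIP experiments, or differential
#' expression after knocking the TF down): `tp` is the number of targets in
#' the positive set, `fp` the number outside it. A drop in true positives
#' caused by pruning is equivalently an increase in false negatives.
#'
#' @param regulon a [extract_regulon()] result, or a character vector of
#'   target identifiers.
#' @param positives gold-standard positive identifiers.
#' @param universe all identifiers under consideration (e.g. every probe on
#'   the platform); both the regulon and the positives must lie inside it.
#' @param tf TF identifier (taken from the regulon attribute when absent).
#' @return A `classified_regulon` tibble row: `tf`, `size`, `tp`, `fp`,
#'   `positive_set_size`, `universe_size`.
#' @export
classify_regulon <- function(regulon, positives, universe, tf = NULL) {
  targets <- if (inherits(regulon, "regulon")) regulon$target else
    as.character(regulon)
  tf <- tf %||% attr(regulon, "tf") %||% NA_character_
  positives <- unique(as.character(positives))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) abort("`universe` must not be empty.")
  if (!all(targets %in% universe)) {
    abort("regulon targets must be contained in the universe.")
  }
  if (!all(positives %in% universe)) {
    abort("positives must be contained in the universe.")
  }
  tp <- sum(targets %in% positives)
  out <- tibble(
    tf = tf, size = length(targets), tp = tp, fp = length(targets) - tp,
    positive_set_size = length(positives), universe_size = length(universe)
  )
  class(out) <- c("classified_regulon", class(out))
  out
}

#' Gain statistics between two pruning stages
#'
#' Compares a regulon before and after additional pruning:
#' `tp_gain = tp_before - tp_after`, `fp_gain = fp_before - fp_after`,
#' `removed_total = size_before - size_after`. When nothing is added,
#' `removed_total = |tp_gain| + fp_gain`; a negative `tp_gain` means true
#' targets were *added* (e.g. by bootstrap consensus scoring). The gain
#' p-value asks whether the membership changes are significantly drawn from
#' the false positives: a hypergeometric upper tail over the before-regulon
#' (population = before size, successes = before FP count, draws = number
#' of membership changes, observed = FP changes).
#'
#' @param before,after `classified_regulon` rows for the same TF and the
#'   same positive set.
#' @return A `gain_result` tibble row: `tf`, `tp_gain`, `fp_gain`,
#'   `removed_total`, `gain_p`.
#' @export
gain_statistics <- function(before, after) {
  stopifnot(
    inherits(before, "classified_regulon"),
    inherits(after, "classified_regulon")
  )
  if (!identical(before$tf, after$tf)) {
    abort("`before` and `after` must describe the same TF.")
  }
  if (before$positive_set_size != after$positive_set_size) {
    abort("`before` and `after` must use the same positive set.")
  }
  tp_gain <- before$tp - after$tp
  fp_gain <- before$fp - after$fp
  changes <- abs(tp_gain) + abs(fp_gain)
  gain_p <- if (changes == 0L) 1 else hypergeometric_tail(
    N = before$size, K = before$fp, n = changes, k = abs(fp_gain)
  )
  out <- tibble(
    tf = before$tf, tp_gain = tp_gain, fp_gain = fp_gain,
    removed_total = before$size - after$size, gain_p = gain_p
  )
  class(out) <- c("gain_result", class(out))
  out
}

#' Hypergeometric upper-tail probability
#'
#' Exact P(X >= k) when drawing `n` items without replacement from a
#' population of `N` containing `K` successes.
#'
#' @param N population size.
#' @param K number of successes in the population.
#' @param n number of draws.
#' @param k observed number of successes among the draws.
#' @return Probability in (0, 1].
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  ok <- k >= 0 && n >= k && N >= n && N >= K && K >= 0
  if (!ok) abort("inconsistent hypergeometric counts (need 0 <= k <= n <= N, K <= N).")
  if (k > K) return(0)  # impossible to observe more successes than exist
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact p-value by point-probability ordering (the standard two-sided
#' convention: sum over all tables with the observed margins whose
#' probability does not exceed the observed table's).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return The exact p-value.
#' @export
fisher_exact <- function(table, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) abort("`table` must be 2x2.")
  if (any(table < 0) || any(table != round(table))) {
    abort("`table` must contain non-negative integer counts.")
  }
  if (any(rowSums(table) == 0) && any(colSums(table) == 0)) {
    abort("a table with an all-zero margin carries no information.")
  }
  fisher.test(table, alternative = alternative)$p.value
}

#' Per-stage validation report across DPI orders
#'
#' For each pruning stage, classifies the TF's regulon against the positive
#' set and attaches a Fisher's exact enrichment p-value (regulon membership
#' vs positive-set membership over the universe); the overall gain between
#' the first and last stage is summarized with [gain_statistics()].
#'
#' @param stages a named list of regulons (or target-identifier vectors),
#'   ordered by DPI order, e.g. the per-order networks of
#'   [haracne_prune()]`$stages` passed through [extract_regulon()]; names
#'   are used as stage labels.
#' @param positives,universe see [classify_regulon()].
#' @param tf TF identifier.
#' @return A `validation_report`: list with `stages` (one classified row
#'   per stage, with `fisher_p`) and `gain` (a `gain_result` row).
#' @export
validation_report <- function(stages, positives, universe, tf = NULL) {
  if (length(stages) == 0L) abort("`stages` must not be empty.")
  labels <- names(stages) %||% as.character(seq_along(stages))
  universe <- unique(as.character(universe))
  positives <- unique(as.character(positives))
  K <- sum(positives %in% universe)

  rows <- purrr::imap(stages, function(reg, label) {
    cls <- classify_regulon(reg, positives, universe, tf = tf)
    mutate(cls,
      stage = label,
      fisher_p = fisher_exact(matrix(
        c(.data$tp, .data$fp, K - .data$tp,
          (.data$universe_size - K) - .data$fp), 2L, 2L
      ))
    )
  })
  stage_tbl <- bind_rows(rows) |>
    select(
      "stage", "tf", "size", "tp", "fp", "fisher_p",
      "positive_set_size", "universe_size"
    )

  first <- rows[[1L]]
  last <- rows[[length(rows)]]
  gain <- gain_statistics(
    first[, setdiff(names(first), c("stage", "fisher_p"))],
    last[, setdiff(names(last), c("stage", "fisher_p"))]
  )
  structure(list(stages = stage_tbl, gain = gain),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(x$stages)
  cat("overall gain:\n")
  print(x$gain)
  invisible(x)
}
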