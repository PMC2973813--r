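# Quantitative genetic-interaction tables: buffering calls, summaries and
# the two randomization null protocols.

#' Read a quantitative genetic-interaction table
#'
#' Expects a TSV with columns `gene_a`, `gene_b`, `score` (epistasis score
#' epsilon; negative = aggravating) and `p_value`. Rows with non-numeric
#' score/p or p outside \[0, 1\] are rejected with their line numbers;
#' duplicate unordered pairs are collapsed keeping the record with the
#' smaller p-value, with a logged count.
#'
#' @param path path to a TSV file or a character vector of lines.
#' @return an `interaction_table`: list with `records` (data.frame of
#'   gene_a, gene_b, score, p_value), `n_collapsed`, `n_rejected`. Lookup by
#'   pair is symmetric in gene order.
#' @export
read_interaction_table <- function(path) {
  df <- if (is.data.frame(path)) path else {
    con <- if (length(path) == 1L && file.exists(path)) path else textConnection(path)
    utils::read.delim(con, stringsAsFactors = FALSE)
  }
  need <- c("gene_a", "gene_b", "score", "p_value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    pb_stop("interaction_format_error",
            paste0("missing column(s): ", paste(miss, collapse = ", ")))
  score <- suppressWarnings(as.numeric(df$score))
  p <- suppressWarnings(as.numeric(df$p_value))
  bad <- !is.finite(score) | !is.finite(p) | p < 0 | p > 1
  if (any(bad))
    message(sprintf("read_interaction_table: rejected %d row(s) (lines %s)",
                    sum(bad), paste(utils::head(which(bad), 5), collapse = ", ")))
  df <- data.frame(gene_a = as.character(df$gene_a)[!bad],
                   gene_b = as.character(df$gene_b)[!bad],
                   score = score[!bad], p_value = p[!bad],
                   stringsAsFactors = FALSE)
  if (!nrow(df)) pb_stop("interaction_format_error", "interaction table is empty")
  key <- pair_key(df$gene_a, df$gene_b)
  ord <- order(key, df$p_value)            # keep most significant per pair
  df <- df[ord, ]; key <- key[ord]
  dup <- duplicated(key)
  n_collapsed <- sum(dup)
  if (n_collapsed)
    message(sprintf("read_interaction_table: collapsed %d duplicate pair(s)", n_collapsed))
  df <- df[!dup, ]; key <- key[!dup]
  rownames(df) <- NULL
  idx <- seq_len(nrow(df)); names(idx) <- key
  structure(list(records = df, index = idx,
                 n_collapsed = n_collapsed, n_rejected = sum(bad)),
            class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("<interaction_table> %d pairs (%d collapsed, %d rejected on read)\n",
              nrow(x$records), x$n_collapsed, x$n_rejected))
  invisible(x)
}

#' Look up the interaction record for an unordered gene pair
#' @param table an `interaction_table`.
#' @param gene_a,gene_b gene ids, in either order.
#' @return a one-row data.frame, or `NULL` when the pair was not assayed.
#' @export
interaction_lookup <- function(table, gene_a, gene_b) {
  i <- table$index[pair_key(gene_a, gene_b)]
  if (is.na(i)) NULL else table$records[i, ]
}

#' Classify a pair as buffering
#'
#' A pair buffers (has backup capacity) iff its interaction score is
#' negative (aggravating epistasis) and the per-pair p-value falls below
#' `alpha`. More negative scores indicate stronger backup capacity.
#'
#' @param score epistasis score(s).
#' @param p_value per-pair p-value(s).
#' @param alpha significance level, default 0.05.
#' @return logical vector.
#' @export
classify_buffering <- function(score, p_value, alpha = 0.05) {
  score < 0 & p_value < alpha
}

#' Buffering fraction and mean strength for a set of pairs
#'
#' @param pairs data.frame with columns `score` and `p_value`.
#' @param alpha significance level for [classify_buffering()].
#' @return list with `n_buffering`, `n_total`, `fraction` and
#'   `mean_strength` (mean score over buffering pairs only; `NA` when no
#'   pair buffers — explicitly undefined, never 0).
#' @export
buffering_summary <- function(pairs, alpha = 0.05) {
  if (!nrow(pairs)) pb_stop("empty_input_error", "no pairs supplied")
  buf <- classify_buffering(pairs$score, pairs$p_value, alpha)
  list(n_buffering = sum(buf), n_total = nrow(pairs),
       fraction = sum(buf) / nrow(pairs),
       mean_strength = if (any(buf)) mean(pairs$score[buf]) else NA_real_)
}

new_null_distribution <- function(pct, means, n_controls, pairs_per_control, seed) {
  structure(list(control_percentages = pct, control_mean_scores = means,
                 n_controls = n_controls, pairs_per_control = pairs_per_control,
                 seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d controls: %% negative %.2f +/- %.2f, mean negative score %.3f\n",
              x$n_controls, mean(x$control_percentages),
              stats::sd(x$control_percentages),
              mean(x$control_mean_scores, na.rm = TRUE)))
  invisible(x)
}

#' Randomized-pairs null (control protocol 1)
#'
#' For each of `n_controls` control groups, samples `pairs_per_control`
#' assayed gene pairs uniformly without replacement and records (a) the
#' percentage with a negative interaction score and (b) the mean score among
#' those negative pairs. The ensemble estimates the background rate of
#' aggravating interactions among arbitrary assayed pairs.
#'
#' @param table an `interaction_table`.
#' @param n_controls number of control groups (default 1000).
#' @param pairs_per_control pairs sampled per group (default 1000).
#' @param seed integer seed; results are reproducible given the seed.
#' @param replace sample with replacement (needed when the table is smaller
#'   than `pairs_per_control`).
#' @return a `null_distribution`.
#' @export
randomization_null <- function(table, n_controls = 1000L,
                               pairs_per_control = 1000L, seed,
                               replace = FALSE) {
  n <- nrow(table$records)
  if (!replace && n < pairs_per_control)
    pb_stop("table_too_small_error", sprintf(
      "table has %d pairs < pairs_per_control = %d; set replace = TRUE to sample with replacement",
      n, pairs_per_control))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  scores <- table$records$score
  pct <- numeric(n_controls); means <- rep(NA_real_, n_controls)
  for (k in seq_len(n_controls)) {
    s <- scores[sample.int(n, pairs_per_control, replace = replace)]
    neg <- s < 0
    pct[[k]] <- 100 * mean(neg)
    if (any(neg)) means[[k]] <- mean(s[neg])
  }
  new_null_distribution(pct, means, n_controls, pairs_per_control, seed)
}

#' Duplicate-shuffle null (control protocol 2)
#'
#' Takes the set of genes that belong to duplicate pairs and, per control,
#' randomly regroups them into disjoint pairs (no gene reused within a
#' control). Pairings present in the interaction table are scored exactly as
#' in [randomization_null()]; shuffles that happen to regenerate a true
#' duplicate pair are allowed and counted. This tests whether duplicate
#' genes per se — rather than duplicate *pairings* — carry excess
#' aggravating interactions.
#'
#' @param duplicate_genes character vector of genes appearing in duplicate
#'   pairs.
#' @param table an `interaction_table`.
#' @param n_controls number of shuffles (default 1000).
#' @param seed integer seed.
#' @return a `null_distribution`; `pairs_per_control` holds the mean number
#'   of assayed shuffled pairs per control. Controls in which no shuffled
#'   pairing was assayed are dropped with a warning; all dropped is an
#'   error.
#' @export
duplicate_shuffle_null <- function(duplicate_genes, table,
                                   n_controls = 1000L, seed) {
  genes <- unique(as.character(duplicate_genes))
  if (length(genes) < 4L)
    pb_stop("too_few_genes_error", "need >= 4 duplicate genes to shuffle")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  half <- length(genes) %/% 2L
  pct <- rep(NA_real_, n_controls); means <- rep(NA_real_, n_controls)
  n_assayed <- numeric(n_controls)
  for (k in seq_len(n_controls)) {
    perm <- sample(genes)
    a <- perm[seq_len(half)]; b <- perm[half + seq_len(half)]
    idx <- table$index[pair_key(a, b)]
    idx <- idx[!is.na(idx)]
    n_assayed[[k]] <- length(idx)
    if (!length(idx)) next
    s <- table$records$score[idx]
    neg <- s < 0
    pct[[k]] <- 100 * mean(neg)
    if (any(neg)) means[[k]] <- mean(s[neg])
  }
  dropped <- is.na(pct)
  if (all(dropped))
    pb_stop("no_assayed_shuffle_error",
            "no shuffled pairing was assayed in any control")
  if (any(dropped))
    warning(sprintf("duplicate_shuffle_null: dropped %d control(s) with no assayed pairing",
                    sum(dropped)))
  new_null_distribution(pct[!dropped], means[!dropped],
                        sum(!dropped), mean(n_assayed[!dropped]), seed)
}

#' Empirical p-value of an observed statistic against a null ensemble
#'
#' Uses the add-one rule `p = (#{null at least as extreme} + 1) /
#' (n_controls + 1)`, which never returns 0.
#'
#' @param observed observed statistic (e.g. a buffering percentage).
#' @param null a `null_distribution` or a numeric vector of null values.
#' @param side `"greater"` (observed unusually large) or `"less"`.
#' @param statistic which null ensemble to use when `null` is a
#'   `null_distribution`: `"percentage"` or `"mean_score"`.
#' @return p-value in (0, 1].
#' @export
empirical_p <- function(observed, null, side = c("greater", "less"),
                        statistic = c("percentage", "mean_score")) {
  side <- match.arg(side)
  statistic <- match.arg(statistic)
  vals <- if (inherits(null, "null_distribution")) {
    if (statistic == "percentage") null$control_percentages else null$control_mean_scores
  } else as.numeric(null)
  vals <- vals[is.finite(vals)]
  if (!length(vals)) pb_stop("empty_null_error", "null distribution is empty")
  extreme <- if (side == "greater") sum(vals >= observed) else sum(vals <= observed)
  (extreme + 1) / (length(vals) + 1)
}
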