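# End-to-end orchestration: from a fixture bundle (on disk or freshly
# synthesized) to a machine-readable report of every analysis stage.

#' Run the full paralog-buffering analysis pipeline
#'
#' Stages, in dependency order: (1) pair/interaction join with exclusion
#' accounting and optional gene-list (e.g. ribosomal) filtering;
#' (2) buffering summaries per duplication class plus the two randomization
#' nulls and empirical p-values; (3) GO-div per pair; (4) divergence
#' (precomputed Ka/Ks columns take precedence over NG86 re-estimation from
#' the codon alignments) and expression divergence; (5) strength vs
#' divergence correlations among buffering pairs, per class;
#' (6) cross-validated backup-capacity prediction; (7) the neutral-mode
#' report on buffering SSD pairs; (8) structure and network comparisons of
#' buffering vs non-buffering pairs.
#'
#' @param input_dir a bundle directory from [write_fixture_bundle()], or
#'   `NULL` to synthesize (requires `config`).
#' @param config a [synth_config()]; used when `input_dir` is `NULL`.
#' @param out_dir optional output directory for `report.json` and per-stage
#'   TSVs.
#' @param alpha buffering significance threshold (default 0.05).
#' @param ks_max Ks saturation threshold (default 2).
#' @param n_controls controls per null protocol (default 1000).
#' @param pairs_per_control pairs sampled per control (default 1000).
#' @param cv_repeats repeated CV fold draws (default 10).
#' @param exclude_genes genes whose pairs are dropped up front (e.g. a
#'   ribosomal list); default none.
#' @param seed integer seed driving the nulls and CV.
#' @return a `pipeline_report` list; see details in the package vignette.
#' @export
run_pipeline <- function(input_dir = NULL, config = NULL, out_dir = NULL,
                         alpha = 0.05, ks_max = 2,
                         n_controls = 1000L, pairs_per_control = 1000L,
                         cv_repeats = 10L, exclude_genes = character(),
                         seed = 1L) {
  if (is.null(input_dir) && is.null(config))
    pb_stop("config_error", "supply input_dir or a synth_config to synthesize")
  bundle <- if (!is.null(input_dir)) read_fixture_bundle(input_dir)
            else {
              b <- generate_pairs(config)
              b$interactions <- read_interaction_table(b$interactions)
              b
            }
  pairs <- bundle$pairs
  n_input <- nrow(pairs)

  ## stage 1: filtering and interaction join --------------------------------
  drop_listed <- pairs$gene_a %in% exclude_genes | pairs$gene_b %in% exclude_genes
  pairs <- pairs[!drop_listed, ]
  itab <- bundle$interactions
  hit <- itab$index[pair_key(pairs$gene_a, pairs$gene_b)]
  assayed <- !is.na(hit)
  pairs <- pairs[assayed, ]
  pairs$score <- itab$records$score[hit[assayed]]
  pairs$p_value <- itab$records$p_value[hit[assayed]]
  pairs$buffering <- classify_buffering(pairs$score, pairs$p_value, alpha)
  exclusions <- list(gene_list = sum(drop_listed),
                     not_assayed = sum(!assayed))

  ## stage 2: buffering summaries and nulls ---------------------------------
  by_class <- lapply(split(pairs, pairs$class), buffering_summary, alpha = alpha)
  null_random <- randomization_null(itab, n_controls = n_controls,
                                    pairs_per_control = min(pairs_per_control,
                                                            nrow(itab$records)),
                                    seed = seed)
  dup_genes <- unique(c(pairs$gene_a, pairs$gene_b))
  null_shuffle <- tryCatch(
    duplicate_shuffle_null(dup_genes, itab, n_controls = n_controls,
                           seed = seed + 1L),
    parabuffer_error = function(e) NULL)
  buffering_stage <- list(
    per_class = lapply(by_class, function(s) {
      s$p_vs_random_null <- empirical_p(100 * s$fraction, null_random, "greater")
      s
    }),
    null_random = list(mean_pct = mean(null_random$control_percentages),
                       sd_pct = stats::sd(null_random$control_percentages),
                       mean_negative_score =
                         mean(null_random$control_mean_scores, na.rm = TRUE)),
    null_shuffle = if (!is.null(null_shuffle))
      list(mean_pct = mean(null_shuffle$control_percentages),
           sd_pct = stats::sd(null_shuffle$control_percentages),
           n_controls = null_shuffle$n_controls) else NULL)

  ## stage 3: GO-div ---------------------------------------------------------
  godiv <- go_div_table(bundle$dag, bundle$corpus, pairs)
  pairs$go_div <- godiv$go_div

  ## stage 4: divergence -----------------------------------------------------
  if (is.null(pairs$ks) || all(!is.finite(pairs$ks))) {
    est <- lapply(seq_len(nrow(pairs)), function(i)
      ka_ks_ng86(bundle$cds[[pairs$gene_a[[i]]]],
                 bundle$cds[[pairs$gene_b[[i]]]]))
    pairs$ks <- vapply(est, `[[`, 1, "ks")
    pairs$ka <- vapply(est, `[[`, 1, "ka")
    divergence_source <- "ng86"
  } else divergence_source <- "precomputed"
  rn <- rownames(bundle$expression)
  ed <- vapply(seq_len(nrow(pairs)), function(i) {
    if (!pairs$gene_a[[i]] %in% rn || !pairs$gene_b[[i]] %in% rn)
      return(NA_real_)
    expression_divergence(bundle$expression[pairs$gene_a[[i]], ],
                          bundle$expression[pairs$gene_b[[i]], ])$value
  }, 1)
  pairs$expression_divergence <- ed

  ## stage 5: strength vs divergence correlations ----------------------------
  strength_cor <- lapply(split(pairs, pairs$class), function(df) {
    buf <- df[df$buffering, ]
    safe_cor <- function(x, y) tryCatch(
      { ct <- pearson_test(x, y); list(r = ct$r, p = ct$p, n = ct$n) },
      parabuffer_error = function(e) NULL)
    list(go_div = safe_cor(buf$go_div, buf$score),
         ka = safe_cor(buf$ka, buf$score),
         expression_divergence = safe_cor(buf$expression_divergence, buf$score),
         n_buffering = nrow(buf))
  })

  ## stage 6: prediction ------------------------------------------------------
  feats <- assemble_features(pairs)
  cv <- cross_validate(feats, folds = 3L, repeats = cv_repeats, seed = seed + 2L)
  cv_godiv <- cross_validate(feats, folds = 3L, repeats = cv_repeats,
                             seed = seed + 2L, feature_subset = "go_div")

  ## stage 7: neutral mode (buffering SSD pairs) ------------------------------
  ssd_buf <- pairs[pairs$class == "SSD" & pairs$buffering, ]
  neutral <- tryCatch(neutral_mode_report(ssd_buf, ks_max = ks_max),
                      parabuffer_error = function(e) list(error = conditionMessage(e)))

  ## stage 8: structure and network -------------------------------------------
  buf <- pairs[pairs$buffering, ]; non <- pairs[!pairs$buffering, ]
  ss_d <- function(df) {
    vapply(seq_len(nrow(df)), function(i) {
      if (!df$gene_a[[i]] %in% names(bundle$ss) ||
          !df$gene_b[[i]] %in% names(bundle$ss)) return(NA_real_)
      sa <- bundle$ss[[df$gene_a[[i]]]]; sb <- bundle$ss[[df$gene_b[[i]]]]
      as.numeric(structure_discrepancy(ss_transition_vector(sa),
                                       ss_transition_vector(sb)))
    }, 1)
  }
  structnet <- list(
    structure_discrepancy = list(
      mean_buffering = mean(ss_d(buf), na.rm = TRUE),
      mean_non_buffering = mean(ss_d(non), na.rm = TRUE)),
    shared_partners = tryCatch(
      shared_partner_comparison(buf, non, bundle$ppi),
      parabuffer_error = function(e) NULL),
    cocluster = list(
      buffering = complex_cocluster_fraction(buf, bundle$complexes),
      non_buffering = complex_cocluster_fraction(non, bundle$complexes)))

  report <- structure(list(
    provenance = list(seed = seed, alpha = alpha, ks_max = ks_max,
                      n_controls = n_controls,
                      divergence_source = divergence_source,
                      n_input = n_input,
                      n_used = nrow(pairs),
                      exclusions = exclusions,
                      go_div_unannotated = sum(godiv$status != "ok"),
                      version = as.character(utils::packageVersion("parabuffer"))),
    buffering = buffering_stage,
    strength_correlations = strength_cor,
    prediction = list(auc_mean = cv$auc_mean, auc_sd = cv$auc_sd,
                      auc_go_div_only = cv_godiv$auc_mean,
                      folds = cv$folds, repeats = cv$repeats,
                      n_examples = length(feats$y),
                      n_excluded = feats$n_excluded),
    neutral_mode = if (!is.null(neutral$error)) neutral else list(
      partial_ks_strength = unclass(neutral$partial_ks_strength),
      partial_ka_strength = unclass(neutral$partial_ka_strength),
      regression = unclass(neutral$regression),
      ks_modes = if (!is.null(neutral$ks_density)) neutral$ks_density$modes
                 else NULL,
      n = neutral$n),
    structnet = structnet
  ), class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass_report(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", force = TRUE)
    utils::write.table(pairs, file.path(out_dir, "pairs_annotated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cv$roc_points, file.path(out_dir, "roc_points.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

unclass_report <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_report) else x
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (cl in names(x$buffering$per_class)) {
    s <- x$buffering$per_class[[cl]]
    cat(sprintf("  %s: %d/%d buffering (%.1f%%), mean strength %.3f, p(null) %.3g\n",
                cl, s$n_buffering, s$n_total, 100 * s$fraction,
                s$mean_strength, s$p_vs_random_null))
  }
  cat(sprintf("  random-pair null: %.2f%% negative\n",
              x$buffering$null_random$mean_pct))
  if (!is.null(x$buffering$null_shuffle))
    cat(sprintf("  duplicate-shuffle null: %.2f%% negative\n",
                x$buffering$null_shuffle$mean_pct))
  cat(sprintf("  prediction: AUC %.3f +/- %.3f (GO-div alone %.3f)\n",
              x$prediction$auc_mean, x$prediction$auc_sd,
              x$prediction$auc_go_div_only))
  if (is.null(x$neutral_mode$error))
    cat(sprintf("  neutral mode: slope %.3f (n = %d), r(Ks,strength|Ka) = %.2f (p %.3g), r(Ka,strength|Ks) = %.2f (p %.3g)\n",
                x$neutral_mode$regression$slope, x$neutral_mode$regression$n,
                x$neutral_mode$partial_ks_strength$r,
                x$neutral_mode$partial_ks_strength$p,
                x$neutral_mode$partial_ka_strength$r,
                x$neutral_mode$partial_ka_strength$p))
  invisible(x)
}
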