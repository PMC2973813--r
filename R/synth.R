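# Synthetic-data generator: every input the pipeline consumes, with the
# statistical structure the analysis assumes planted at stated rates.

#' Configuration for the synthetic-data generator
#'
#' Defaults encode the world the analysis targets: 266 WGD and 228 SSD
#' assayed pairs; 39.5% / 18.4% buffering rates; a 7% background rate of
#' aggravating interactions among random assayed pairs and 6.6% among
#' re-paired duplicate genes; WGD mean buffering strength -0.42; SSD
#' buffering strength decaying along `strength = neutral_slope * Ks -
#' strength_intercept` with Gaussian noise below the Ks = 2 saturation
#' point; an SSD Ks mixture with a young peak at 0.18 and a broad ancient
#' peak at 3.0 (weights 10/42 vs 32/42); 549 expression conditions; and
#' Fig-4-style network rates (shared partner 0.62 buffering vs 0.40
#' non-buffering; complex co-clustering 0.18 vs 0.065).
#'
#' @param seed integer seed (mandatory; every generator draws from it).
#' @param n_ontology_terms,n_levels,n_branches DAG size and shape.
#' @param extra_parent_prob probability a term gets a second (part_of)
#'   parent.
#' @param n_background_genes background annotation corpus size.
#' @param n_wgd_pairs,n_ssd_pairs duplicate pair counts.
#' @param buffering_rate_wgd,buffering_rate_ssd planted buffering rates.
#' @param background_negative_rate,duplicate_negative_rate planted negative
#'   rates for the two null protocols.
#' @param n_background_pairs,n_duplicate_cross_pairs extra assayed pairs in
#'   the interaction table.
#' @param neutral_slope,strength_intercept,strength_noise_sd the SSD
#'   neutral-decay strength model.
#' @param wgd_strength_mean,wgd_strength_sd WGD buffering strength (no Ks
#'   dependence: WGD backup is selectively stabilized).
#' @param ssd_ks_left_mode,ssd_ks_left_sd,ssd_ks_right_mode,ssd_ks_right_sd,ssd_ks_left_weight
#'   the bimodal SSD Ks mixture for buffering pairs.
#' @param wgd_ks_mean,wgd_ks_sd saturated WGD Ks.
#' @param ka_ks_ratio,ka_noise_sd Ka given Ks.
#' @param n_conditions expression profile length.
#' @param n_codons fixture CDS length (codons).
#' @param shared_partner_rate_buffering,shared_partner_rate_non,cocluster_rate_buffering,cocluster_rate_non,n_complexes
#'   network/complex planting rates.
#' @param ss_length,ss_mut_rate_buffering,ss_mut_rate_non secondary
#'   structure string generation.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed,
                         n_ontology_terms = 120L, n_levels = 5L,
                         n_branches = 4L, extra_parent_prob = 0.15,
                         n_background_genes = 150L,
                         n_wgd_pairs = 266L, n_ssd_pairs = 228L,
                         buffering_rate_wgd = 0.395,
                         buffering_rate_ssd = 0.184,
                         background_negative_rate = 0.07,
                         duplicate_negative_rate = 0.066,
                         n_background_pairs = 20000L,
                         n_duplicate_cross_pairs = 20000L,
                         neutral_slope = 0.41,
                         strength_intercept = 0.8,
                         strength_noise_sd = 0.05,
                         wgd_strength_mean = -0.42, wgd_strength_sd = 0.15,
                         ssd_ks_left_mode = 0.18, ssd_ks_left_sd = 0.05,
                         ssd_ks_right_mode = 3.0, ssd_ks_right_sd = 0.5,
                         ssd_ks_left_weight = 10 / 42,
                         wgd_ks_mean = 3.5, wgd_ks_sd = 0.5,
                         ka_ks_ratio = 0.25, ka_noise_sd = 0.03,
                         n_conditions = 549L,
                         n_codons = 150L,
                         shared_partner_rate_buffering = 0.62,
                         shared_partner_rate_non = 0.40,
                         cocluster_rate_buffering = 0.18,
                         cocluster_rate_non = 0.065,
                         n_complexes = 60L,
                         ss_length = 120L,
                         ss_mut_rate_buffering = 0.05,
                         ss_mut_rate_non = 0.25) {
  if (missing(seed)) pb_stop("config_error", "seed is mandatory")
  cfg <- as.list(environment())
  rates <- c(buffering_rate_wgd, buffering_rate_ssd, background_negative_rate,
             duplicate_negative_rate, ssd_ks_left_weight,
             shared_partner_rate_buffering, shared_partner_rate_non,
             cocluster_rate_buffering, cocluster_rate_non)
  if (any(rates < 0 | rates > 1))
    pb_stop("config_error", "all rates must lie in [0, 1]")
  if (n_ontology_terms < 10L)
    pb_stop("config_error", "need at least 10 ontology terms")
  structure(cfg, class = "synth_config")
}

# Construct an ontology_dag from a parent map (shared with parse_obo output).
new_dag <- function(parents, root, names = NULL) {
  terms <- names(parents)
  dag <- structure(list(terms = terms, parents = parents, root = root,
                        alt_id = character(),
                        name = stats::setNames(names %||% terms, terms)),
                   class = "ontology_dag")
  dag$children <- invert_parent_map(dag)
  dag$ancestors <- ancestor_closures(dag)
  dag
}

#' Generate a random rooted BP-like DAG and annotation corpus
#'
#' Builds a layered DAG: the root, `n_branches` top-level branches, and
#' deeper levels of geometrically growing size. Every term below level 1
#' gets one primary parent on the previous level of the same branch, plus a
#' second (part_of) parent with probability `extra_parent_prob`. Background
#' genes are annotated to terms with depth-weighted sampling (deeper terms
#' preferred, mimicking specific curation).
#'
#' @param config a [synth_config()].
#' @return list with `dag` (an `ontology_dag`), `corpus` (an
#'   `annotation_corpus` over the background genes), `annotations`
#'   (data.frame gene/term), `level` (named integer vector), `branch`
#'   (named vector, NA for the root).
#' @export
generate_ontology <- function(config) {
  set.seed(config$seed)
  L <- config$n_levels
  n <- config$n_ontology_terms
  root <- "ST:0000000"
  w <- 1.6^(seq_len(L) - 1)
  sizes <- pmax(round((n - 1L) * w / sum(w)), 1L)
  sizes[1L] <- max(sizes[1L], config$n_branches)
  term_id <- function(i) sprintf("ST:%07d", i)
  parents <- list(); parents[[root]] <- character()
  level <- c(stats::setNames(0L, root))
  branch <- c(stats::setNames(NA_integer_, root))
  counter <- 0L
  by_level <- list(`0` = root)
  for (l in seq_len(L)) {
    ids <- character(sizes[[l]])
    for (j in seq_len(sizes[[l]])) {
      counter <- counter + 1L
      id <- term_id(counter); ids[[j]] <- id
      if (l == 1L) {
        parents[[id]] <- root
        branch[[id]] <- ((j - 1L) %% config$n_branches) + 1L
      } else {
        prev <- by_level[[as.character(l - 1L)]]
        br <- branch[[sample1(prev)]]
        cand <- prev[branch[prev] == br]
        p1 <- sample1(cand)
        ps <- p1
        if (stats::runif(1) < config$extra_parent_prob && length(cand) > 1L) {
          p2 <- sample1(setdiff(cand, p1))
          ps <- c(p1, p2)
        }
        parents[[id]] <- ps
        branch[[id]] <- br
      }
      level[[id]] <- l
    }
    by_level[[as.character(l)]] <- ids
  }
  dag <- new_dag(parents, root)
  non_root <- setdiff(dag$terms, root)
  wts <- (level[non_root])^1.5
  genes <- sprintf("BG%04d", seq_len(config$n_background_genes))
  ann_g <- character(); ann_t <- character()
  for (g in genes) {
    k <- sample(2:4, 1L)
    ts <- sample(non_root, k, prob = wts)
    ann_g <- c(ann_g, rep(g, k)); ann_t <- c(ann_t, ts)
  }
  dup <- duplicated(paste(ann_g, ann_t))
  ann_g <- ann_g[!dup]; ann_t <- ann_t[!dup]
  list(dag = dag,
       corpus = build_corpus(dag, ann_g, ann_t),
       annotations = data.frame(gene = ann_g, term = ann_t,
                                stringsAsFactors = FALSE),
       level = level, branch = branch)
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lower | x > upper
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lower | x > upper
  }
  x
}

#' Background interaction table with a planted negative-score rate
#'
#' @param n_pairs number of assayed gene pairs.
#' @param negative_rate fraction with a negative score.
#' @param seed integer seed.
#' @param gene_prefix prefix for generated gene names.
#' @return data.frame gene_a/gene_b/score/p_value (unordered-unique pairs).
#' @export
generate_background_interactions <- function(n_pairs, negative_rate, seed,
                                             gene_prefix = "RND") {
  set.seed(seed)
  n_genes <- max(20L, ceiling(sqrt(4 * n_pairs)))
  genes <- sprintf("%s%05d", gene_prefix, seq_len(n_genes))
  a <- integer(0); b <- integer(0)
  while (length(a) < n_pairs) {
    need <- n_pairs - length(a)
    ca <- sample.int(n_genes, 2 * need, replace = TRUE)
    cb <- sample.int(n_genes, 2 * need, replace = TRUE)
    ok <- ca != cb
    a <- c(a, ca[ok]); b <- c(b, cb[ok])
    dup <- duplicated(pair_key(a, b))
    a <- a[!dup]; b <- b[!dup]
  }
  a <- a[seq_len(n_pairs)]; b <- b[seq_len(n_pairs)]
  neg <- stats::runif(n_pairs) < negative_rate
  mag <- abs(stats::rnorm(n_pairs, 0, 0.09)) + 0.003
  score <- ifelse(neg, -mag, mag)
  p <- ifelse(neg, stats::runif(n_pairs, 0, 0.3), stats::runif(n_pairs))
  data.frame(gene_a = genes[a], gene_b = genes[b],
             score = score, p_value = p, stringsAsFactors = FALSE)
}

#' Buffering pairs under pure neutral decay
#'
#' Simulates `n` buffering pairs whose strength follows the linear neutral
#' decay `strength = slope * Ks - intercept + N(0, noise_sd)` with Ks
#' uniform below the saturation point and Ka tracking Ks
#' (`ka = ka_coef * ks + noise`) but carrying no independent effect on
#' strength. This is the positive-control world for the partial-correlation
#' analysis: Ks should correlate with strength given Ka; Ka should not,
#' given Ks.
#'
#' @param n number of pairs.
#' @param slope,intercept,noise_sd strength model (defaults 0.41, 0.8,
#'   0.05).
#' @param ks_range Ks sampling interval (default (0.05, 2]).
#' @param ka_coef,ka_noise_sd Ka model.
#' @param seed optional integer seed.
#' @return data.frame with `ks`, `ka`, `strength` (all strengths <= 0).
#' @export
simulate_buffering_decay <- function(n = 50L, slope = 0.41, intercept = 0.8,
                                     noise_sd = 0.05,
                                     ks_range = c(0.05, 2),
                                     ka_coef = 0.25, ka_noise_sd = 0.05,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ks <- stats::runif(n, ks_range[[1L]], ks_range[[2L]])
  ka <- pmax(ka_coef * ks + stats::rnorm(n, 0, ka_noise_sd), 0.001)
  strength <- pmin(slope * ks - intercept + stats::rnorm(n, 0, noise_sd), -0.01)
  data.frame(ks = ks, ka = ka, strength = strength)
}

# Pick two distinct descendant terms of `anc` for a gene pair's shared
# annotation (prefer deepest), or two deep terms from different branches
# when the pair shares only the root.
pick_pair_terms <- function(onto, shared_level) {
  lv <- onto$level; br <- onto$branch
  deep <- names(lv)[lv >= max(lv) - 1L]
  if (shared_level == 0L) {
    # branches that actually hold deep terms; fall back to any non-root term
    avail <- unique(br[deep])
    avail <- avail[!is.na(avail)]
    if (length(avail) < 2L) {
      deep <- names(lv)[lv >= 1L]
      avail <- unique(br[deep]); avail <- avail[!is.na(avail)]
    }
    bs <- sample(avail, 2L)
    t1 <- sample1(deep[br[deep] == bs[[1L]]])
    t2 <- sample1(deep[br[deep] == bs[[2L]]])
    return(c(t1, t2))
  }
  cand_anc <- names(lv)[lv == shared_level]
  for (anc in sample(cand_anc, length(cand_anc))) {
    desc <- names(onto$dag$ancestors)[vapply(onto$dag$ancestors,
                                             function(a) anc %in% a, TRUE)]
    desc <- setdiff(desc, anc)
    if (length(desc) >= 2L) {
      deepest <- desc[lv[desc] == max(lv[desc])]
      pool <- if (length(deepest) >= 2L) deepest else desc
      return(sample(pool, 2L))
    }
  }
  # fall back to annotating both genes with the ancestor's children
  c(anc, anc)
}

#' Generate duplicate pairs and every associated data layer
#'
#' Creates WGD and SSD pair tables with planted buffering flags, scores and
#' p-values, planted Ks/Ka/identity, GO annotations whose best-match depth
#' separates buffering from non-buffering pairs, correlated expression
#' profiles, codon alignments mutated to the planted divergence, a
#' genome-scale interaction table (pair records plus background and
#' cross-duplicate records at the planted negative rates), PPI edges with
#' planted shared partners, a complex catalog with planted co-clustering,
#' and secondary-structure strings.
#'
#' @param config a [synth_config()].
#' @param onto output of [generate_ontology()] (generated from `config` if
#'   omitted).
#' @return list with elements `pairs` (data.frame), `interactions`
#'   (data.frame), `annotations` (data.frame incl. background),
#'   `corpus`, `dag`, `expression` (matrix), `cds` (named character of
#'   aligned sequences), `ss` (named character), `ppi` (edge data.frame),
#'   `complexes` (data.frame), `duplicate_genes` (character), `config`.
#' @export
generate_pairs <- function(config, onto = NULL) {
  if (is.null(onto)) onto <- generate_ontology(config)
  set.seed(config$seed + 1L)
  L <- config$n_levels
  n_w <- config$n_wgd_pairs; n_s <- config$n_ssd_pairs
  n_pairs <- n_w + n_s
  pair_id <- sprintf("P%04d", seq_len(n_pairs))
  class <- c(rep("WGD", n_w), rep("SSD", n_s))
  gene_a <- sprintf("D%04dA", seq_len(n_pairs))
  gene_b <- sprintf("D%04dB", seq_len(n_pairs))
  buffering <- c(stats::runif(n_w) < config$buffering_rate_wgd,
                 stats::runif(n_s) < config$buffering_rate_ssd)

  ## -- Ks ------------------------------------------------------------
  ks <- numeric(n_pairs)
  is_w <- class == "WGD"; is_s <- !is_w
  ks[is_w] <- rtrunc_norm(sum(is_w), config$wgd_ks_mean, config$wgd_ks_sd,
                          lower = 2.05)
  sb <- is_s & buffering
  left <- stats::runif(sum(sb)) < config$ssd_ks_left_weight
  ks_sb <- numeric(sum(sb))
  # the unsaturated component peaks at the young mode but keeps a uniform
  # tail toward the saturation point, so the decay regression has leverage
  tail_draw <- stats::runif(sum(left)) < 0.3
  ks_young <- rtrunc_norm(sum(left), config$ssd_ks_left_mode,
                          config$ssd_ks_left_sd, lower = 0.01, upper = 2)
  ks_young[tail_draw] <- stats::runif(sum(tail_draw), 0.25, 2)
  ks_sb[left] <- ks_young
  ks_sb[!left] <- rtrunc_norm(sum(!left), config$ssd_ks_right_mode,
                              config$ssd_ks_right_sd, lower = 2.05)
  ks[sb] <- ks_sb
  sn <- is_s & !buffering
  old <- stats::runif(sum(sn)) < 0.88      # most non-buffering SSDs are ancient
  ks_sn <- numeric(sum(sn))
  ks_sn[old] <- rtrunc_norm(sum(old), 3.2, 0.6, lower = 2.05)
  ks_sn[!old] <- stats::runif(sum(!old), 0.3, 1)
  ks[sn] <- ks_sn

  ## -- Ka, identity ---------------------------------------------------
  ka <- pmax(config$ka_ks_ratio * pmin(ks, 2.5) / 2.5 * 0.6 +
               stats::rnorm(n_pairs, 0, config$ka_noise_sd), 0.005)
  identity <- pmin(pmax(0.92 - 0.9 * ka + stats::rnorm(n_pairs, 0, 0.04),
                        0.2), 0.99)

  ## -- scores and p-values ---------------------------------------------
  score <- numeric(n_pairs); p_value <- numeric(n_pairs)
  wb <- is_w & buffering
  score[wb] <- rtrunc_norm(sum(wb), config$wgd_strength_mean,
                           config$wgd_strength_sd, upper = -0.05)
  # young SSD pairs decay along the neutral line; ancient (saturated)
  # buffering SSD pairs are selectively stabilized and stay strong
  sb_young <- sb & ks <= 2
  sb_old <- sb & ks > 2
  score[sb_young] <- pmin(config$neutral_slope * ks[sb_young] -
                            config$strength_intercept +
                            stats::rnorm(sum(sb_young), 0,
                                         config$strength_noise_sd),
                          -0.02)
  score[sb_old] <- rtrunc_norm(sum(sb_old), -0.33, 0.2, upper = -0.05)
  p_value[buffering] <- stats::runif(sum(buffering), 0, 0.05)
  nb <- !buffering
  score[nb] <- stats::rnorm(sum(nb), 0.02, 0.08)
  p_value[nb] <- ifelse(score[nb] < 0,
                        stats::runif(sum(nb), 0.05, 1),
                        stats::runif(sum(nb)))

  ## -- GO annotations ---------------------------------------------------
  lv_opts <- seq_len(L - 1L)
  shared_level <- integer(n_pairs)
  shared_level[buffering] <- sample(lv_opts, sum(buffering), replace = TRUE,
                                    prob = lv_opts^3)
  root_only <- stats::runif(sum(nb)) < 0.5
  sl_nb <- integer(sum(nb))
  sl_nb[!root_only] <- sample(lv_opts, sum(!root_only), replace = TRUE,
                              prob = rev(lv_opts)^3)
  shared_level[nb] <- sl_nb
  ann_g <- onto$annotations$gene; ann_t <- onto$annotations$term
  non_root <- setdiff(onto$dag$terms, onto$dag$root)
  for (i in seq_len(n_pairs)) {
    tt <- pick_pair_terms(onto, shared_level[[i]])
    g <- c(gene_a[[i]], gene_b[[i]])
    ann_g <- c(ann_g, g); ann_t <- c(ann_t, tt)
    extra <- stats::runif(2) < 0.7
    if (any(extra)) {
      ann_g <- c(ann_g, g[extra])
      ann_t <- c(ann_t, sample(non_root, sum(extra), replace = TRUE))
    }
  }
  dup <- duplicated(paste(ann_g, ann_t))
  ann_g <- ann_g[!dup]; ann_t <- ann_t[!dup]
  corpus <- build_corpus(onto$dag, ann_g, ann_t)

  ## -- expression -------------------------------------------------------
  r_target <- pmin(pmax(0.85 - 0.22 * pmin(ks, 4) + 0.12 * buffering +
                          stats::rnorm(n_pairs, 0, 0.08), -0.6), 0.99)
  nc <- config$n_conditions
  expr <- matrix(0, 2L * n_pairs, nc,
                 dimnames = list(c(rbind(gene_a, gene_b)), NULL))
  for (i in seq_len(n_pairs)) {
    a <- stats::rnorm(nc)
    b <- r_target[[i]] * a + sqrt(1 - r_target[[i]]^2) * stats::rnorm(nc)
    expr[gene_a[[i]], ] <- a; expr[gene_b[[i]], ] <- b
  }
  colnames(expr) <- sprintf("cond_%03d", seq_len(nc))

  ## -- coding sequences -------------------------------------------------
  cds <- character(2L * n_pairs)
  names(cds) <- c(rbind(gene_a, gene_b))
  for (i in seq_len(n_pairs)) {
    sim <- simulate_codon_pair(config$n_codons, min(ks[[i]], 2.6), ka[[i]])
    cds[[gene_a[[i]]]] <- sim$seq_a
    cds[[gene_b[[i]]]] <- sim$seq_b
  }

  ## -- secondary structure ----------------------------------------------
  ss <- character(2L * n_pairs)
  names(ss) <- c(rbind(gene_a, gene_b))
  for (i in seq_len(n_pairs)) {
    base <- random_ss_string(config$ss_length)
    rate <- if (buffering[[i]]) config$ss_mut_rate_buffering else config$ss_mut_rate_non
    ss[[gene_a[[i]]]] <- base
    ss[[gene_b[[i]]]] <- mutate_ss_string(base, rate)
  }

  ## -- PPI and complexes ------------------------------------------------
  pool <- sprintf("X%05d", seq_len(3000L))
  ppi_a <- character(); ppi_b <- character()
  for (i in seq_len(n_pairs)) {
    rate <- if (buffering[[i]]) config$shared_partner_rate_buffering
            else config$shared_partner_rate_non
    partners_a <- sample(pool, sample(2:4, 1L))
    partners_b <- sample(pool, sample(2:4, 1L))
    if (stats::runif(1) < rate) {
      hub <- sample(pool, 1L)
      partners_a <- c(partners_a, hub); partners_b <- c(partners_b, hub)
    }
    ppi_a <- c(ppi_a, rep(gene_a[[i]], length(partners_a)),
               rep(gene_b[[i]], length(partners_b)))
    ppi_b <- c(ppi_b, partners_a, partners_b)
  }
  ppi <- data.frame(gene_a = ppi_a, gene_b = ppi_b, stringsAsFactors = FALSE)

  cx_pool <- sprintf("C%05d", seq_len(2000L))
  cx_id <- character(); cx_gene <- character()
  for (k in seq_len(config$n_complexes)) {
    m <- sample(3:8, 1L)
    cx_id <- c(cx_id, rep(sprintf("CPX%03d", k), m))
    cx_gene <- c(cx_gene, sample(cx_pool, m))
  }
  for (i in seq_len(n_pairs)) {
    rate <- if (buffering[[i]]) config$cocluster_rate_buffering
            else config$cocluster_rate_non
    if (stats::runif(1) < rate) {
      cx <- sample(sprintf("CPX%03d", seq_len(config$n_complexes)), 1L)
      cx_id <- c(cx_id, cx, cx)
      cx_gene <- c(cx_gene, gene_a[[i]], gene_b[[i]])
    } else if (stats::runif(1) < 0.3) {
      cxs <- sample(sprintf("CPX%03d", seq_len(config$n_complexes)), 2L)
      cx_id <- c(cx_id, cxs)
      cx_gene <- c(cx_gene, gene_a[[i]], gene_b[[i]])
    }
  }
  complexes <- data.frame(complex_id = cx_id, gene = cx_gene,
                          stringsAsFactors = FALSE)

  ## -- interaction table ------------------------------------------------
  bg <- generate_background_interactions(config$n_background_pairs,
                                         config$background_negative_rate,
                                         seed = config$seed + 2L)
  dup_genes <- c(gene_a, gene_b)
  set.seed(config$seed + 3L)
  n_cross <- config$n_duplicate_cross_pairs
  ia <- sample(dup_genes, 2L * n_cross, replace = TRUE)
  ib <- sample(dup_genes, 2L * n_cross, replace = TRUE)
  ok <- ia != ib
  ia <- ia[ok]; ib <- ib[ok]
  sister <- pair_key(ia, ib) %in% pair_key(gene_a, gene_b)
  ia <- ia[!sister]; ib <- ib[!sister]
  dupk <- duplicated(pair_key(ia, ib))
  ia <- ia[!dupk][seq_len(min(n_cross, sum(!dupk)))]
  ib <- ib[!dupk][seq_len(min(n_cross, sum(!dupk)))]
  negx <- stats::runif(length(ia)) < config$duplicate_negative_rate
  magx <- abs(stats::rnorm(length(ia), 0, 0.09)) + 0.003
  cross <- data.frame(gene_a = ia, gene_b = ib,
                      score = ifelse(negx, -magx, magx),
                      p_value = ifelse(negx, stats::runif(length(ia), 0, 0.3),
                                       stats::runif(length(ia))),
                      stringsAsFactors = FALSE)
  interactions <- rbind(
    data.frame(gene_a = gene_a, gene_b = gene_b, score = score,
               p_value = p_value, stringsAsFactors = FALSE),
    cross, bg)

  pairs <- data.frame(pair_id = pair_id, gene_a = gene_a, gene_b = gene_b,
                      class = class, score = score, p_value = p_value,
                      buffering = buffering, ks = ks, ka = ka,
                      identity = identity, stringsAsFactors = FALSE)
  list(pairs = pairs, interactions = interactions,
       annotations = data.frame(gene = ann_g, term = ann_t,
                                stringsAsFactors = FALSE),
       corpus = corpus, dag = onto$dag, level = onto$level,
       expression = expr, cds = cds, ss = ss, ppi = ppi,
       complexes = complexes, duplicate_genes = dup_genes,
       config = config)
}

random_ss_string <- function(len, stay = 0.85) {
  states <- .pb_ss_states
  s <- character(len)
  s[[1L]] <- sample(states, 1L)
  for (i in 2:len)
    s[[i]] <- if (stats::runif(1) < stay) s[[i - 1L]] else sample(setdiff(states, s[[i - 1L]]), 1L)
  paste(s, collapse = "")
}

mutate_ss_string <- function(ss, rate) {
  s <- strsplit(ss, "")[[1L]]
  hit <- stats::runif(length(s)) < rate
  s[hit] <- vapply(s[hit], function(x) sample(setdiff(.pb_ss_states, x), 1L), "")
  paste(s, collapse = "")
}
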