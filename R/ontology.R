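# Biological Process ontology: OBO/GAF parsing, information content and the
# best-match semantic divergence score (GO-div) between two genes.

#' Parse an OBO 1.2 flat file into a Biological Process DAG
#'
#' Reads `[Term]` stanzas, keeping `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of`, `alt_id` and `is_obsolete`. Only terms in the
#' `biological_process` namespace are retained; obsolete terms are dropped
#' and their edges ignored; `alt_id`s are recorded so annotation files using
#' superseded identifiers resolve to the canonical term. Both `is_a` and
#' `part_of` edges enter the parent map, as both denote subsumption for
#' information-content purposes.
#'
#' @param path path to an OBO file, or a character vector of OBO lines.
#' @return an object of class `ontology_dag` with elements `terms`
#'   (character vector), `parents` (named list of parent term ids),
#'   `children` (named list), `root` (the unique parentless BP term),
#'   `alt_id` (named character vector mapping alternate to canonical ids)
#'   and `name` (named character vector of term labels).
#' @details The graph is checked for cycles by topological sort; a cyclic
#'   edge set is a structural error naming the terms involved. A BP term set
#'   without a unique root is a format error.
#' @export
parse_obo <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  # split into stanzas
  starts <- grep("^\\[", lines)
  if (!length(starts)) pb_stop("obo_format_error", "no stanzas found in OBO input")
  ends <- c(starts[-1L] - 1L, length(lines))
  headers <- lines[starts]

  ids <- character(); nms <- character(); ns <- character()
  parents <- list(); alt <- character(); obsolete <- logical()
  for (k in seq_along(starts)) {
    if (headers[k] != "[Term]") next
    body <- lines[seq.int(starts[k] + 1L, ends[k])]
    body <- body[nzchar(body)]
    key <- sub(":.*$", "", body)
    val <- trimws(sub("^[^:]*:", "", body))
    val <- sub("!.*$", "", val)          # strip trailing comments
    val <- trimws(val)
    id <- val[key == "id"][1L]
    if (is.na(id)) next
    is_a <- val[key == "is_a"]
    rel <- val[key == "relationship"]
    part_of <- sub("^part_of\\s+", "", rel[grepl("^part_of\\s", rel)])
    ids <- c(ids, id)
    nms <- c(nms, if (any(key == "name")) val[key == "name"][1L] else id)
    ns <- c(ns, if (any(key == "namespace")) val[key == "namespace"][1L] else NA_character_)
    obsolete <- c(obsolete, any(key == "is_obsolete" & val == "true"))
    parents[[id]] <- unique(c(is_a, part_of))
    for (a in val[key == "alt_id"]) alt[[a]] <- id
  }
  if (!length(ids)) pb_stop("obo_format_error", "OBO input contains no [Term] stanzas")
  names(nms) <- ids; names(ns) <- ids; names(obsolete) <- ids

  keep <- !obsolete & (is.na(ns) | ns == "biological_process")
  # if namespaces are declared at all, require BP explicitly
  if (any(!is.na(ns))) keep <- !obsolete & !is.na(ns) & ns == "biological_process"
  ids <- ids[keep]
  if (!length(ids)) pb_stop("obo_format_error", "no biological_process terms in OBO input")
  parents <- lapply(parents[ids], function(p) intersect(p, ids))
  alt <- alt[alt %in% ids]

  roots <- ids[vapply(parents, length, 1L) == 0L]
  if (length(roots) != 1L)
    pb_stop("obo_format_error", sprintf(
      "expected a single Biological Process root, found %d (%s)",
      length(roots), paste(utils::head(roots, 5), collapse = ", ")))

  dag <- structure(list(
    terms = ids, parents = parents, root = roots,
    alt_id = alt, name = nms[ids]
  ), class = "ontology_dag")
  cyc <- dag_find_cycle(dag)
  if (!is.null(cyc))
    pb_stop("obo_structure_error",
            paste0("cycle in ontology graph: ", paste(cyc, collapse = " -> ")))
  dag$children <- invert_parent_map(dag)
  dag$ancestors <- ancestor_closures(dag)
  dag
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d BP terms, root %s\n", length(x$terms), x$root))
  invisible(x)
}

# Kahn topological sort; returns NULL if acyclic, else one cycle's members.
dag_find_cycle <- function(dag) {
  indeg <- vapply(dag$parents, length, 1L)  # edges child -> parent
  q <- names(indeg)[indeg == 0L]
  child_of <- invert_parent_map(dag)
  seen <- 0L
  while (length(q)) {
    t <- q[[1L]]; q <- q[-1L]; seen <- seen + 1L
    for (ch in child_of[[t]] %||% character()) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) q <- c(q, ch)
    }
  }
  if (seen == length(dag$terms)) NULL else names(indeg)[indeg > 0L]
}

invert_parent_map <- function(dag) {
  ch <- lapply(dag$terms, function(x) character())
  names(ch) <- dag$terms
  for (t in dag$terms) for (p in dag$parents[[t]]) ch[[p]] <- c(ch[[p]], t)
  ch
}

# Ancestor closure (self-inclusive) for every term, computed once in
# topological order from the root down.
ancestor_closures <- function(dag) {
  anc <- list()
  remaining <- dag$terms
  anc[[dag$root]] <- dag$root
  remaining <- setdiff(remaining, dag$root)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(t)
      all(dag$parents[[t]] %in% names(anc)), TRUE)]
    for (t in ready)
      anc[[t]] <- unique(c(t, unlist(anc[dag$parents[[t]]], use.names = FALSE)))
    remaining <- setdiff(remaining, ready)
  }
  anc
}

#' Term ancestors (self-inclusive)
#' @param dag an `ontology_dag`.
#' @param term a term id (alternate ids are resolved).
#' @return character vector of `term` and all its ancestors up to the root.
#' @export
term_ancestors <- function(dag, term) {
  term <- resolve_term(dag, term)
  dag$ancestors[[term]]
}

resolve_term <- function(dag, term) {
  if (term %in% dag$terms) return(term)
  if (term %in% names(dag$alt_id)) return(dag$alt_id[[term]])
  pb_stop("unknown_term_error", sprintf("term '%s' not in ontology", term))
}

#' Parse a GAF 2.x annotation file against a BP ontology
#'
#' Retains rows in aspect `P` (Biological Process) whose evidence code is not
#' `IEA` (electronic annotations are excluded as unreviewed). Direct
#' annotations are de-duplicated per (gene, term) and each is propagated to
#' every ancestor term, so a term's count covers the term and all its
#' descendants. Rows naming terms absent from the DAG are skipped and
#' counted.
#'
#' @param path path to a GAF file or a character vector of GAF lines.
#' @param dag an `ontology_dag` from [parse_obo()].
#' @param count_mode `"annotation"` (default) counts de-duplicated
#'   annotation rows; `"gene"` counts distinct genes per term.
#' @return an `annotation_corpus`: list with `gene_terms` (named list of
#'   direct term sets per gene), `term_count` (named integer vector over
#'   terms reachable by propagation), `total` (count at the root),
#'   `n_skipped` (rows whose term was not in the DAG) and `count_mode`.
#' @export
parse_gaf <- function(path, dag, count_mode = c("annotation", "gene")) {
  count_mode <- match.arg(count_mode)
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) pb_stop("empty_corpus_error", "GAF input has no annotation rows")
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(f, length, 1L) < 9L
  if (any(short))
    pb_stop("gaf_format_error",
            sprintf("GAF row %d has fewer than 9 columns", which(short)[1L]))
  gene <- vapply(f, `[[`, "", 3L)          # DB object symbol
  gene[!nzchar(gene)] <- vapply(f[!nzchar(gene)], `[[`, "", 2L)
  term <- vapply(f, `[[`, "", 5L)
  evid <- vapply(f, `[[`, "", 7L)
  aspect <- vapply(f, `[[`, "", 9L)

  keep <- aspect == "P" & evid != "IEA"
  gene <- gene[keep]; term <- term[keep]
  known <- term %in% dag$terms | term %in% names(dag$alt_id)
  n_skipped <- sum(!known)
  if (n_skipped > 0L)
    message(sprintf("parse_gaf: skipped %d row(s) with terms absent from the DAG", n_skipped))
  gene <- gene[known]; term <- term[known]
  if (!length(gene))
    pb_stop("empty_corpus_error",
            "no qualifying annotations (aspect P, evidence != IEA) in GAF input")
  term <- vapply(term, function(t) resolve_term(dag, t), "", USE.NAMES = FALSE)

  dup <- duplicated(paste(gene, term, sep = "\r"))
  gene <- gene[!dup]; term <- term[!dup]

  build_corpus(dag, gene, term, count_mode, n_skipped)
}

# Shared constructor: propagate direct (gene, term) annotations up the DAG.
build_corpus <- function(dag, gene, term, count_mode = "annotation",
                         n_skipped = 0L) {
  gene_terms <- lapply(split(term, gene), unique)
  counts <- integer(length(dag$terms)); names(counts) <- dag$terms
  if (count_mode == "annotation") {
    for (i in seq_along(gene)) {
      anc <- dag$ancestors[[term[[i]]]]
      counts[anc] <- counts[anc] + 1L
    }
  } else {
    gene_anc <- lapply(gene_terms, function(ts)
      unique(unlist(dag$ancestors[ts], use.names = FALSE)))
    for (anc in gene_anc) counts[anc] <- counts[anc] + 1L
  }
  structure(list(
    gene_terms = gene_terms,
    term_count = counts,
    total = counts[[dag$root]],
    n_skipped = n_skipped,
    count_mode = count_mode
  ), class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("<annotation_corpus> %d genes, %d annotations at the root (%s counting)\n",
              length(x$gene_terms), x$total, x$count_mode))
  invisible(x)
}

#' Probability of sampling a term or any of its descendants
#'
#' `p(x) = term_count(x) / total`, the probability of drawing term `x` or any
#' recursive child of `x` from the annotation corpus. `p(root) = 1` by
#' construction; the information content of `x` is `-ln p(x)`.
#'
#' @param corpus an `annotation_corpus`.
#' @param term a term id.
#' @return numeric probability in (0, 1].
#' @export
term_probability <- function(corpus, term) {
  if (!term %in% names(corpus$term_count))
    pb_stop("unknown_term_error", sprintf("term '%s' not in corpus", term))
  n <- corpus$term_count[[term]]
  if (n < 1L)
    pb_stop("undefined_probability_error",
            sprintf("term '%s' has zero annotations; p(x) undefined", term))
  n / corpus$total
}

#' Information-content similarity between two ontology terms
#'
#' The similarity of terms `m` and `n` is read off their most informative
#' common ancestor (MICA) `x*`, the shared ancestor with minimal sampling
#' probability. With the default Lin normalization,
#' `T(m, n) = 2 ln p(x*) / (ln p(m) + ln p(n))`, which is 1 when the terms
#' coincide (and are not the root) and 0 when their only shared ancestor is
#' the root (`p = 1`, zero information). A term subsuming the other is its
#' own shared ancestor. `normalization = "max_ic"` instead divides the MICA
#' information content by `max(IC(m), IC(n))`; both scales lie in \[0, 1\].
#'
#' @param dag an `ontology_dag`.
#' @param corpus an `annotation_corpus` over the same DAG.
#' @param m,n term ids (must carry at least one annotation).
#' @param normalization `"lin"` (default) or `"max_ic"`.
#' @return a `term_pair_score`: list with `term_a`, `term_b`, `similarity`
#'   in \[0, 1\], `mica` and `normalization`.
#' @export
term_similarity <- function(dag, corpus, m, n,
                            normalization = c("lin", "max_ic")) {
  normalization <- match.arg(normalization)
  m <- resolve_term(dag, m); n <- resolve_term(dag, n)
  pm <- term_probability(corpus, m)
  pn <- term_probability(corpus, n)
  shared <- intersect(dag$ancestors[[m]], dag$ancestors[[n]])
  ps <- corpus$term_count[shared] / corpus$total
  ps <- ps[ps > 0]
  mica <- names(ps)[which.min(ps)]
  px <- min(ps)
  sim <- if (px >= 1) {
    0  # only the root (or root-equivalent, p = 1) is shared: no information
  } else if (normalization == "lin") {
    2 * log(px) / (log(pm) + log(pn))
  } else {
    # IC(mica) / max(IC(m), IC(n)); logs are negative so max IC is min log
    log(px) / min(log(pm), log(pn))
  }
  if (!is.finite(sim)) sim <- 0
  sim <- min(max(sim, 0), 1)
  structure(list(term_a = m, term_b = n, similarity = sim, mica = mica,
                 normalization = normalization),
            class = "term_pair_score")
}

#' Best-match GO semantic divergence between two genes
#'
#' GO-div scores the functional overlap of a gene pair from their Biological
#' Process annotation sets: every cross pair of annotated terms is scored
#' with [term_similarity()] and `GO-div = 1 - max T(i, j)`, the divergence of
#' the best-matched term pair. Because only the maximum enters, shared very
#' specific functions drive the score to 0 regardless of how many other,
#' diverged functions the two genes carry; 1 means the annotation sets meet
#' only at the root. Lower GO-div therefore means higher functional overlap.
#'
#' @param dag an `ontology_dag`.
#' @param corpus an `annotation_corpus`.
#' @param gene_a,gene_b gene identifiers present in the corpus.
#' @param normalization passed to [term_similarity()].
#' @return a `go_div_score`: list with `go_div` in \[0, 1\], `best_match`
#'   (terms of the maximizing pair), `mica`, `status` ("ok") and
#'   `normalization`. A gene without qualifying annotation raises a
#'   condition of class `unannotated_gene_error` (the pair must be excluded,
#'   never silently scored 0 or 1).
#' @export
go_div <- function(dag, corpus, gene_a, gene_b,
                   normalization = c("lin", "max_ic")) {
  normalization <- match.arg(normalization)
  ta <- corpus$gene_terms[[gene_a]]
  tb <- corpus$gene_terms[[gene_b]]
  if (is.null(ta) || !length(ta))
    pb_stop("unannotated_gene_error",
            sprintf("gene '%s' has no qualifying BP annotation", gene_a),
            gene = gene_a)
  if (is.null(tb) || !length(tb))
    pb_stop("unannotated_gene_error",
            sprintf("gene '%s' has no qualifying BP annotation", gene_b),
            gene = gene_b)
  best <- -1; best_pair <- c(NA_character_, NA_character_); best_mica <- NA_character_
  for (i in ta) for (j in tb) {
    s <- term_similarity(dag, corpus, i, j, normalization)
    if (s$similarity > best) {
      best <- s$similarity
      best_pair <- c(s$term_a, s$term_b)
      best_mica <- s$mica
    }
  }
  structure(list(go_div = 1 - best,
                 best_match = best_pair, mica = best_mica,
                 status = "ok", normalization = normalization),
            class = "go_div_score")
}

#' GO-div for a table of gene pairs
#'
#' Vectorized driver for [go_div()]: unannotated genes yield status
#' `"unannotated"` and `NA` scores instead of an error, so a pair table can
#' be scored wholesale with explicit exclusion accounting.
#'
#' @param dag,corpus as in [go_div()].
#' @param pairs data.frame with columns `gene_a`, `gene_b` (and optionally
#'   `pair_id`).
#' @param normalization passed through.
#' @return data.frame with columns `pair_id`, `gene_a`, `gene_b`, `go_div`,
#'   `best_match_term_a`, `best_match_term_b`, `mica`, `status`.
#' @export
go_div_table <- function(dag, corpus, pairs,
                         normalization = c("lin", "max_ic")) {
  normalization <- match.arg(normalization)
  pair_id <- pairs$pair_id %||% paste(pairs$gene_a, pairs$gene_b, sep = "|")
  out <- data.frame(pair_id = pair_id,
                    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                    go_div = NA_real_,
                    best_match_term_a = NA_character_,
                    best_match_term_b = NA_character_,
                    mica = NA_character_, status = "unannotated",
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairs))) {
    res <- tryCatch(go_div(dag, corpus, pairs$gene_a[[k]], pairs$gene_b[[k]],
                           normalization),
                    unannotated_gene_error = function(e) NULL)
    if (!is.null(res)) {
      out$go_div[[k]] <- res$go_div
      out$best_match_term_a[[k]] <- res$best_match[[1L]]
      out$best_match_term_b[[k]] <- res$best_match[[2L]]
      out$mica[[k]] <- res$mica
      out$status[[k]] <- "ok"
    }
  }
  out
}
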