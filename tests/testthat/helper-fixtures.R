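# Shared fixtures and independent oracles.
# Oracles deliberately re-derive quantities by brute force (naive recursion,
# exhaustive enumeration) and never call the code paths they check.

# --- OBO fixture builders ---------------------------------------------------

obo_stanza <- function(id, name = id, is_a = character(),
                       part_of = character(), obsolete = FALSE,
                       alt_id = character(),
                       namespace = "biological_process") {
  c("[Term]", paste0("id: ", id), paste0("name: ", name),
    paste0("namespace: ", namespace),
    if (length(alt_id)) paste0("alt_id: ", alt_id),
    if (length(is_a)) paste0("is_a: ", is_a, " ! p"),
    if (length(part_of)) paste0("relationship: part_of ", part_of, " ! p"),
    if (obsolete) "is_obsolete: true",
    "")
}

# root <- mid <- leaf chain
chain_obo <- function() {
  c("format-version: 1.2", "",
    obo_stanza("GO:0000001", "root"),
    obo_stanza("GO:0000002", "mid", is_a = "GO:0000001"),
    obo_stanza("GO:0000003", "leaf", is_a = "GO:0000002"))
}

gaf_row <- function(gene, term, evidence = "IDA", aspect = "P") {
  paste("DB", gene, gene, "", term, "REF", evidence, "", aspect,
        "", "", "gene", "taxon:4932", "20090101", "DB", "", sep = "\t")
}

# --- ontology oracles -------------------------------------------------------

# naive recursive ancestor set (self-inclusive), independent of the package's
# precomputed closures
oracle_ancestors <- function(parents, term) {
  seen <- character()
  walk <- function(t) {
    if (t %in% seen) return()
    seen <<- c(seen, t)
    for (p in parents[[t]]) walk(p)
  }
  walk(term)
  seen
}

# descendant-enumeration count: annotations to term or any descendant
oracle_term_count <- function(parents, all_terms, ann_gene, ann_term, term) {
  desc <- all_terms[vapply(all_terms, function(t)
    term %in% oracle_ancestors(parents, t), TRUE)]
  sum(ann_term %in% desc)
}

# exhaustive best-match GO-div with its own probability computation
oracle_go_div <- function(parents, all_terms, ann_gene, ann_term, ga, gb) {
  total <- length(ann_term)
  p_of <- function(t) oracle_term_count(parents, all_terms, ann_gene,
                                        ann_term, t) / total
  tsim <- function(m, n) {
    shared <- intersect(oracle_ancestors(parents, m),
                        oracle_ancestors(parents, n))
    ps <- vapply(shared, p_of, 1)
    ps <- ps[ps > 0]
    px <- min(ps)
    if (px >= 1) return(0)
    val <- 2 * log(px) / (log(p_of(m)) + log(p_of(n)))
    min(max(val, 0), 1)
  }
  ta <- unique(ann_term[ann_gene == ga])
  tb <- unique(ann_term[ann_gene == gb])
  best <- max(vapply(ta, function(i)
    max(vapply(tb, function(j) tsim(i, j), 1)), 1))
  1 - best
}

# --- other oracles ----------------------------------------------------------

oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

oracle_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# small synth config keeping unit tests fast
small_config <- function(seed, ...) {
  args <- list(seed = seed,
               n_ontology_terms = 60L, n_background_genes = 60L,
               n_wgd_pairs = 60L, n_ssd_pairs = 60L,
               n_background_pairs = 3000L, n_duplicate_cross_pairs = 3000L,
               n_conditions = 40L, n_codons = 60L, n_complexes = 20L,
               ss_length = 60L)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}
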