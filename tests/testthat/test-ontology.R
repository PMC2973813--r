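# OBO/GAF parsing, information content, term similarity and GO-div.

test_that("parse_obo builds the chain DAG with full ancestor closure", {
  dag <- parse_obo(chain_obo())
  expect_s3_class(dag, "ontology_dag")
  expect_length(dag$terms, 3L)
  expect_equal(dag$root, "GO:0000001")
  expect_setequal(term_ancestors(dag, "GO:0000003"),
                  c("GO:0000003", "GO:0000002", "GO:0000001"))
})

test_that("parse_obo drops obsolete terms and maps alt_ids", {
  txt <- c("format-version: 1.2", "",
           obo_stanza("GO:0000001", "root", alt_id = "GO:0000099"),
           obo_stanza("GO:0000002", "mid", is_a = "GO:0000001"),
           obo_stanza("GO:0000004", "dead", is_a = "GO:0000001",
                      obsolete = TRUE))
  dag <- parse_obo(txt)
  expect_false("GO:0000004" %in% dag$terms)
  expect_equal(term_ancestors(dag, "GO:0000099"), "GO:0000001")
})

test_that("parse_obo records both is_a and part_of edges (5-term fixture)", {
  # root <- a, b;  c is_a a, part_of b  => closure(c) = {c, a, b, root}
  txt <- c(obo_stanza("R:1"),
           obo_stanza("A:1", is_a = "R:1"),
           obo_stanza("B:1", is_a = "R:1"),
           obo_stanza("C:1", is_a = "A:1", part_of = "B:1"),
           obo_stanza("D:1", is_a = "C:1"))
  dag <- parse_obo(txt)
  expect_setequal(dag$parents[["C:1"]], c("A:1", "B:1"))
  expect_setequal(term_ancestors(dag, "D:1"),
                  c("D:1", "C:1", "A:1", "B:1", "R:1"))
  # matches the naive recursion oracle on every term
  for (t in dag$terms)
    expect_setequal(term_ancestors(dag, t), oracle_ancestors(dag$parents, t))
})

test_that("parse_obo rejects cycles and rootless files", {
  cyc <- c(obo_stanza("R:1"),
           obo_stanza("A:1", is_a = c("R:1", "B:1")),
           obo_stanza("B:1", is_a = "A:1"))
  expect_error(parse_obo(cyc), class = "obo_structure_error")
  two_roots <- c(obo_stanza("R:1"), obo_stanza("R:2"))
  expect_error(parse_obo(two_roots), class = "obo_format_error")
})

test_that("parse_gaf propagates annotations up the chain and filters IEA", {
  dag <- parse_obo(chain_obo())
  corpus <- parse_gaf(gaf_row("g1", "GO:0000003"), dag)
  expect_equal(unname(corpus$term_count[c("GO:0000003", "GO:0000002",
                                          "GO:0000001")]),
               c(1L, 1L, 1L))
  expect_equal(corpus$total, 1L)
  expect_error(parse_gaf(gaf_row("g1", "GO:0000003", evidence = "IEA"), dag),
               class = "empty_corpus_error")
  # duplicate (gene, term) rows counted once; unknown terms skipped+counted
  rows <- c(gaf_row("g1", "GO:0000003"), gaf_row("g1", "GO:0000003"),
            gaf_row("g2", "GO:9999999"))
  expect_message(corpus2 <- parse_gaf(rows, dag), "skipped 1")
  expect_equal(corpus2$total, 1L)
  expect_equal(corpus2$n_skipped, 1L)
})

test_that("term_probability is count/total, 1 at the root, error at zero", {
  dag <- parse_obo(chain_obo())
  rows <- c(gaf_row("g1", "GO:0000003"),
            vapply(2:10, function(i) gaf_row(paste0("g", i), "GO:0000002"), ""))
  corpus <- parse_gaf(rows, dag)
  expect_equal(term_probability(corpus, "GO:0000001"), 1)
  expect_equal(term_probability(corpus, "GO:0000003"), 0.1)
  expect_equal(term_probability(corpus, "GO:0000002"), 1)  # all 10 propagate
  # a term annotated nowhere has undefined probability
  txt <- c(chain_obo(), obo_stanza("GO:0000005", is_a = "GO:0000001"))
  dag2 <- parse_obo(txt)
  corpus2 <- parse_gaf(gaf_row("g1", "GO:0000003"), dag2)
  expect_error(term_probability(corpus2, "GO:0000005"),
               class = "undefined_probability_error")
})

# Y-shaped fixture: root <- mid <- {leafA, leafB}, plus an off-branch leaf
y_obo <- function() {
  c(obo_stanza("GO:0000001", "root"),
    obo_stanza("GO:0000002", "mid", is_a = "GO:0000001"),
    obo_stanza("GO:0000003", "leafA", is_a = "GO:0000002"),
    obo_stanza("GO:0000004", "leafB", is_a = "GO:0000002"),
    obo_stanza("GO:0000005", "other", is_a = "GO:0000001"))
}

test_that("term_similarity: root-only overlap gives T = 0, self gives 1", {
  dag <- parse_obo(y_obo())
  rows <- c(gaf_row("g1", "GO:0000003"), gaf_row("g2", "GO:0000005"))
  corpus <- parse_gaf(rows, dag)
  s <- term_similarity(dag, corpus, "GO:0000003", "GO:0000005")
  expect_equal(s$similarity, 0)
  expect_equal(s$mica, "GO:0000001")
  self <- term_similarity(dag, corpus, "GO:0000003", "GO:0000003")
  expect_equal(self$similarity, 1)
})

test_that("term_similarity matches the hand-computed chain value", {
  # p(mid) = 0.5, p(leafA) = p(leafB) = 0.2 built from 10 annotations:
  # leafA 2, leafB 2, mid direct 1, other 5
  dag <- parse_obo(y_obo())
  rows <- c(gaf_row("a1", "GO:0000003"), gaf_row("a2", "GO:0000003"),
            gaf_row("b1", "GO:0000004"), gaf_row("b2", "GO:0000004"),
            gaf_row("m1", "GO:0000002"),
            vapply(1:5, function(i) gaf_row(paste0("o", i), "GO:0000005"), ""))
  corpus <- parse_gaf(rows, dag)
  expect_equal(term_probability(corpus, "GO:0000002"), 0.5)
  s <- term_similarity(dag, corpus, "GO:0000003", "GO:0000004")
  expect_equal(s$similarity, 2 * log(0.5) / (log(0.2) + log(0.2)),
               tolerance = 1e-12)  # ~0.4307
  expect_equal(s$mica, "GO:0000002")
  # symmetric
  s2 <- term_similarity(dag, corpus, "GO:0000004", "GO:0000003")
  expect_equal(s2$similarity, s$similarity)
})

test_that("go_div trivial limits and unannotated handling", {
  dag <- parse_obo(y_obo())
  rows <- c(gaf_row("g1", "GO:0000003"), gaf_row("g2", "GO:0000003"),
            gaf_row("g3", "GO:0000005"))
  corpus <- parse_gaf(rows, dag)
  expect_equal(go_div(dag, corpus, "g1", "g2")$go_div, 0)   # identical sets
  expect_equal(go_div(dag, corpus, "g1", "g3")$go_div, 1)   # root-only
  expect_error(go_div(dag, corpus, "g1", "nope"),
               class = "unannotated_gene_error")
  tab <- go_div_table(dag, corpus, data.frame(gene_a = c("g1", "g1"),
                                              gene_b = c("g2", "nope")))
  expect_equal(tab$status, c("ok", "unannotated"))
  expect_true(is.na(tab$go_div[[2L]]))
})

test_that("go_div equals the exhaustive oracle on random ontologies", {
  for (seed in 1:12) {
    cfg <- synth_config(seed = seed, n_ontology_terms = sample(15:50, 1),
                        n_levels = 4L, n_background_genes = 10L)
    onto <- generate_ontology(cfg)
    ann <- onto$annotations
    genes <- unique(ann$gene)
    gs <- sample(genes, 2L)
    got <- go_div(onto$dag, onto$corpus, gs[[1L]], gs[[2L]])$go_div
    want <- oracle_go_div(onto$dag$parents, onto$dag$terms,
                          ann$gene, ann$term, gs[[1L]], gs[[2L]])
    expect_equal(got, want, tolerance = 1e-12)
    # term_count vs descendant-enumeration oracle on a few terms
    for (t in sample(onto$dag$terms, 5L))
      expect_equal(unname(onto$corpus$term_count[[t]]),
                   oracle_term_count(onto$dag$parents, onto$dag$terms,
                                     ann$gene, ann$term, t))
  }
})

test_that("GO-div properties: bounds, symmetry, best-match monotonicity", {
  cfg <- synth_config(seed = 42, n_ontology_terms = 40L,
                      n_background_genes = 20L)
  onto <- generate_ontology(cfg)
  ann <- onto$annotations
  genes <- unique(ann$gene)
  set.seed(9)
  for (i in 1:10) {
    gs <- sample(genes, 2L)
    d1 <- go_div(onto$dag, onto$corpus, gs[[1L]], gs[[2L]])$go_div
    d2 <- go_div(onto$dag, onto$corpus, gs[[2L]], gs[[1L]])$go_div
    expect_gte(d1, 0); expect_lte(d1, 1)
    expect_equal(d1, d2)
  }
  # give both genes one identical deep annotation: divergence must not rise
  lv <- onto$level
  deep <- names(lv)[lv == max(lv)][1L]
  gs <- sample(genes, 2L)
  before <- go_div(onto$dag, onto$corpus, gs[[1L]], gs[[2L]])$go_div
  ann2 <- rbind(ann, data.frame(gene = gs, term = deep))
  corpus2 <- parse_gaf(vapply(seq_len(nrow(ann2)), function(i)
    gaf_row(ann2$gene[[i]], ann2$term[[i]]), ""), onto$dag)
  after <- go_div(onto$dag, corpus2, gs[[1L]], gs[[2L]])$go_div
  expect_lte(after, before)
})
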