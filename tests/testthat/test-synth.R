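# Synthetic-data generator: determinism, planted structure, round-trips.

test_that("generate_ontology is deterministic and satisfies corpus invariants", {
  cfg <- synth_config(seed = 1, n_ontology_terms = 40L,
                      n_background_genes = 25L)
  o1 <- generate_ontology(cfg)
  o2 <- generate_ontology(cfg)
  expect_identical(o1$dag$parents, o2$dag$parents)
  expect_identical(o1$annotations, o2$annotations)
  # p(root) = 1 and counts monotone parent >= child
  expect_equal(term_probability(o1$corpus, o1$dag$root), 1)
  for (t in setdiff(o1$dag$terms, o1$dag$root))
    for (p in o1$dag$parents[[t]])
      expect_gte(o1$corpus$term_count[[p]], o1$corpus$term_count[[t]])
  # every ancestor closure reaches the root
  for (t in o1$dag$terms)
    expect_true(o1$dag$root %in% term_ancestors(o1$dag, t))
})

test_that("generate_pairs plants buffering rates within binomial CI", {
  cfg <- small_config(seed = 5, n_wgd_pairs = 200L, n_ssd_pairs = 200L)
  b <- generate_pairs(cfg)
  for (cl in c("WGD", "SSD")) {
    sub <- b$pairs[b$pairs$class == cl, ]
    s <- buffering_summary(sub)
    rate <- if (cl == "WGD") cfg$buffering_rate_wgd else cfg$buffering_rate_ssd
    half <- 1.96 * sqrt(rate * (1 - rate) / nrow(sub))
    expect_lt(abs(s$fraction - rate), half + 1e-9)
    # planted flags agree with the score/p classification
    expect_equal(sub$buffering,
                 classify_buffering(sub$score, sub$p_value))
  }
})

test_that("planted GO-div separates buffering from non-buffering pairs", {
  cfg <- small_config(seed = 6)
  b <- generate_pairs(cfg)
  gd <- go_div_table(b$dag, b$corpus, b$pairs)
  m <- merge(gd, b$pairs[, c("pair_id", "buffering")], by = "pair_id")
  expect_true(all(m$status == "ok"))
  wt <- wilcox.test(go_div ~ buffering, data = m)
  expect_lt(wt$p.value, 0.01)
  expect_lt(mean(m$go_div[m$buffering]), mean(m$go_div[!m$buffering]))
})

test_that("a zero-slope world yields a near-zero fitted slope", {
  d <- simulate_buffering_decay(n = 80, slope = 0, seed = 9)
  fit <- strength_ks_regression(d)
  expect_lt(abs(fit$slope), 0.05)
})

test_that("fixture bundle round-trips through every parser cleanly", {
  cfg <- small_config(seed = 7, n_wgd_pairs = 20L, n_ssd_pairs = 20L,
                      n_background_pairs = 500L,
                      n_duplicate_cross_pairs = 500L)
  dir <- withr::local_tempdir()
  m1 <- write_fixture_bundle(dir, cfg)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # no warnings or messages from any reader
  expect_no_condition(bundle <- read_fixture_bundle(dir),
                      class = "warning")
  expect_equal(nrow(bundle$pairs), 40L)
  expect_equal(length(bundle$dag$terms), cfg$n_ontology_terms)
  expect_true(all(bundle$pairs$gene_a %in% names(bundle$cds)))
  expect_true(all(bundle$pairs$gene_a %in% rownames(bundle$expression)))
  # checksums are stable under the same seed
  dir2 <- withr::local_tempdir()
  m2 <- write_fixture_bundle(dir2, cfg)
  expect_identical(unname(unlist(m1$checksums)),
                   unname(unlist(m2$checksums)))
})

test_that("generated corpus round-trips GO-div through OBO/GAF files", {
  cfg <- synth_config(seed = 8, n_ontology_terms = 30L,
                      n_background_genes = 15L)
  onto <- generate_ontology(cfg)
  dir <- withr::local_tempdir()
  write_obo(onto$dag, file.path(dir, "o.obo"))
  write_gaf(onto$annotations, file.path(dir, "a.gaf"))
  dag2 <- parse_obo(file.path(dir, "o.obo"))
  corpus2 <- parse_gaf(file.path(dir, "a.gaf"), dag2)
  expect_setequal(dag2$terms, onto$dag$terms)
  expect_equal(corpus2$term_count[names(onto$corpus$term_count)],
               onto$corpus$term_count)
  genes <- unique(onto$annotations$gene)[1:2]
  expect_equal(go_div(dag2, corpus2, genes[[1]], genes[[2]])$go_div,
               go_div(onto$dag, onto$corpus, genes[[1]], genes[[2]])$go_div)
})

test_that("synth_config validates rates and requires a seed", {
  expect_error(synth_config(), class = "config_error")
  expect_error(synth_config(seed = 1, buffering_rate_wgd = 1.4),
               class = "config_error")
})
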