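# Secondary-structure transition vectors, discrepancy D, PPI sharing and
# complex co-clustering.

test_that("ss_transition_vector trivial cases and code mapping", {
  v <- ss_transition_vector("HHHH")
  expect_equal(unname(v$probs["H->H"]), 1)
  expect_equal(sum(v$probs), 1)
  expect_setequal(v$unvisited, c("E", "C"))

  cyc <- ss_transition_vector("HECHEC")
  expect_equal(unname(cyc$probs[c("H->E", "E->C", "C->H")]), c(1, 1, 1))

  # G/I map to H, B to E, T/S to C
  mapped <- ss_transition_vector("GIHB")     # -> HHHE
  expect_equal(unname(mapped$probs["H->H"]), 2 / 3)
  expect_equal(unname(mapped$probs["H->E"]), 1 / 3)
  expect_error(ss_transition_vector("H"), class = "ss_input_error")
})

test_that("ss_transition_vector matches brute-force bigram counts", {
  set.seed(12)
  s <- paste(sample(c("H", "E", "C"), 50, replace = TRUE), collapse = "")
  v <- ss_transition_vector(s)
  ch <- strsplit(s, "")[[1]]
  for (a in c("H", "E", "C")) {
    from_a <- sum(ch[-50] == a)
    for (b in c("H", "E", "C")) {
      n_ab <- sum(ch[-50] == a & ch[-1] == b)
      want <- if (from_a > 0) n_ab / from_a else 0
      expect_equal(unname(v$probs[paste0(a, "->", b)]), want)
    }
  }
  # visited rows are stochastic
  for (a in setdiff(c("H", "E", "C"), v$unvisited))
    expect_equal(sum(v$probs[paste0(a, "->", c("H", "E", "C"))]), 1)
})

test_that("structure_discrepancy is a symmetric divergence, 0 iff equal", {
  set.seed(13)
  a <- ss_transition_vector(paste(sample(c("H", "E", "C"), 60, TRUE),
                                  collapse = ""))
  b <- ss_transition_vector(paste(sample(c("H", "E", "C"), 60, TRUE),
                                  collapse = ""))
  expect_equal(as.numeric(structure_discrepancy(a, a)), 0, tolerance = 1e-9)
  expect_equal(as.numeric(structure_discrepancy(a, b)),
               as.numeric(structure_discrepancy(b, a)))
  expect_gt(as.numeric(structure_discrepancy(a, b)), 0)
  # hand-computed Jensen-Shannon value on 2-state vectors
  d <- as.numeric(structure_discrepancy(c(1, 0), c(0.5, 0.5)))
  m <- c(0.75, 0.25)
  want <- (1 * log(1 / 0.75) +
             (0.5 * log(0.5 / 0.75) + 0.5 * log(0.5 / 0.25))) / 2
  expect_equal(d, want, tolerance = 1e-3)
})

test_that("shared_partner_comparison fractions, exclusions and chi-square", {
  net <- ppi_network(data.frame(
    gene_a = c("a1", "b1", "a2", "a2", "b2", "a3", "b3"),
    gene_b = c("x",  "x",  "b2", "y",  "z",  "q",  "w")))
  g1 <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"))
  g2 <- data.frame(gene_a = c("a3", "nope"), gene_b = c("b3", "b1"))
  res <- shared_partner_comparison(g1, g2, net)
  expect_equal(res$frac1, 0.5)   # a1-b1 share x; a2-b2 only interact directly
  expect_equal(res$frac2, 0)
  expect_equal(res$excluded2, 1L)   # "nope" absent from the network
  # chi-square equals the textbook formula on reconstructed counts
  res2_tab <- matrix(c(65, 105 - 65, 64, 161 - 64), 2, byrow = TRUE)
  big1 <- data.frame(gene_a = character(), gene_b = character())
  expect_equal(
    unname(suppressWarnings(
      chisq.test(res2_tab, correct = FALSE))$statistic),
    oracle_chi2(res2_tab), tolerance = 1e-10)
  p2 <- pchisq(oracle_chi2(res2_tab), 1, lower.tail = FALSE)
  expect_lt(p2, 1e-3); expect_gt(p2, 1e-5)  # the reported order of magnitude
})

test_that("complex_cocluster_fraction counts common complexes exactly", {
  cat <- complex_catalog(data.frame(
    complex_id = c("c1", "c1", "c1", "c2", "c2", "c3"),
    gene = c("a", "b", "x", "a", "y", "z")))
  expect_length(cat, 2L)  # c3 has < 2 members
  pairs <- data.frame(gene_a = c("a", "a", "q"), gene_b = c("b", "y", "r"))
  res <- complex_cocluster_fraction(pairs, cat)
  expect_equal(res$n_cocluster, 2L)
  expect_equal(res$fraction, 2 / 3)
  # planted 18% fixture recovered exactly
  n <- 50
  cx <- data.frame(
    complex_id = c(sprintf("k%02d", 1:9), sprintf("k%02d", 1:9)),
    gene = c(sprintf("pa%02d", 1:9), sprintf("pb%02d", 1:9)))
  pr <- data.frame(gene_a = sprintf("pa%02d", 1:n),
                   gene_b = sprintf("pb%02d", 1:n))
  res2 <- complex_cocluster_fraction(pr, complex_catalog(cx))
  expect_equal(res2$fraction, 9 / 50)  # 0.18
})
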