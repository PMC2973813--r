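# Interaction tables, buffering calls and the randomization nulls.

itab_text <- function(rows) {
  c("gene_a\tgene_b\tscore\tp_value", rows)
}

test_that("read_interaction_table parses, collapses and rejects rows", {
  t1 <- read_interaction_table(itab_text(c("a\tb\t-0.5\t0.01",
                                           "a\tc\t0.2\t0.5",
                                           "b\tc\t-0.1\t0.2")))
  expect_equal(nrow(t1$records), 3L)
  # (A,B) and (B,A) collapse to the more significant record
  expect_message(
    t2 <- read_interaction_table(itab_text(c("a\tb\t-0.5\t0.10",
                                             "b\ta\t-0.7\t0.01"))),
    "collapsed 1")
  expect_equal(nrow(t2$records), 1L)
  expect_equal(t2$records$p_value, 0.01)
  expect_identical(interaction_lookup(t2, "b", "a")$score,
                   interaction_lookup(t2, "a", "b")$score)
  # out-of-range p rejected with a message
  expect_message(
    t3 <- read_interaction_table(itab_text(c("a\tb\t-0.5\t1.5",
                                             "a\tc\t0.1\t0.4"))),
    "rejected 1")
  expect_equal(nrow(t3$records), 1L)
  expect_error(read_interaction_table(itab_text("a\tb\tzzz\t2")),
               class = "interaction_format_error")
})

test_that("classify_buffering needs a negative score and p < alpha", {
  expect_true(classify_buffering(-0.5, 0.01))
  expect_false(classify_buffering(-0.5, 0.20))
  expect_false(classify_buffering(0.1, 0.001))
  expect_equal(classify_buffering(c(-1, -1, 1), c(0.04, 0.06, 0.01)),
               c(TRUE, FALSE, FALSE))
})

test_that("buffering_summary fractions and undefined mean", {
  # the headline arithmetic: 105 of 266 buffering
  pairs <- data.frame(score = c(rep(-0.4, 105), rep(0.1, 161)),
                      p_value = c(rep(0.01, 105), rep(0.5, 161)))
  s <- buffering_summary(pairs)
  expect_equal(s$fraction, 105 / 266)
  expect_equal(s$mean_strength, -0.4)
  s0 <- buffering_summary(data.frame(score = rep(1, 10),
                                     p_value = rep(0.5, 10)))
  expect_equal(s0$fraction, 0)
  expect_true(is.na(s0$mean_strength))
  expect_error(buffering_summary(data.frame(score = numeric(),
                                            p_value = numeric())),
               class = "empty_input_error")
})

test_that("buffering_summary recovers a planted rate within binomial CI", {
  set.seed(4)
  n <- 200L; rate <- 0.30
  buf <- runif(n) < rate
  pairs <- data.frame(score = ifelse(buf, -0.5, 0.2),
                      p_value = ifelse(buf, 0.01, 0.5))
  s <- buffering_summary(pairs)
  ci <- rate + c(-1, 1) * 1.96 * sqrt(rate * (1 - rate) / n)
  expect_gte(s$fraction, ci[[1L]]); expect_lte(s$fraction, ci[[2L]])
})

test_that("randomization_null degenerate, recovery and determinism", {
  allneg <- read_interaction_table(data.frame(
    gene_a = paste0("g", 1:50), gene_b = paste0("h", 1:50),
    score = -runif(50), p_value = runif(50)))
  n0 <- randomization_null(allneg, n_controls = 20, pairs_per_control = 10,
                           seed = 1)
  expect_true(all(n0$control_percentages == 100))

  bg <- read_interaction_table(
    generate_background_interactions(5000, 0.07, seed = 2))
  nn <- randomization_null(bg, n_controls = 200, pairs_per_control = 1000,
                           seed = 3)
  expect_lt(abs(mean(nn$control_percentages) - 7), 1)
  nn2 <- randomization_null(bg, n_controls = 200, pairs_per_control = 1000,
                            seed = 3)
  expect_identical(nn$control_percentages, nn2$control_percentages)
  expect_error(randomization_null(allneg, 10, 1000, seed = 1),
               class = "table_too_small_error")
})

test_that("duplicate_shuffle_null pairs disjointly and recovers the rate", {
  # 4 genes, complete table: every control scores exactly 2 disjoint pairs
  genes <- c("a", "b", "c", "d")
  cmb <- t(combn(genes, 2))
  full <- read_interaction_table(data.frame(
    gene_a = cmb[, 1], gene_b = cmb[, 2],
    score = c(-1, 1, 1, 1, 1, -1), p_value = 0.01))
  ns <- duplicate_shuffle_null(genes, full, n_controls = 50, seed = 1)
  expect_equal(ns$pairs_per_control, 2)
  expect_true(all(ns$control_percentages %in% c(0, 50, 100)))

  # planted 6.6% negative among all pairings of 120 genes
  genes2 <- sprintf("dup%03d", 1:120)
  cmb2 <- t(combn(genes2, 2))
  set.seed(8)
  neg <- runif(nrow(cmb2)) < 0.066
  tab2 <- read_interaction_table(data.frame(
    gene_a = cmb2[, 1], gene_b = cmb2[, 2],
    score = ifelse(neg, -0.3, 0.3), p_value = 0.2))
  ns2 <- duplicate_shuffle_null(genes2, tab2, n_controls = 300, seed = 2)
  expect_lt(abs(mean(ns2$control_percentages) - 6.6), 1.2)
  expect_error(duplicate_shuffle_null(genes[1:3], full, 10, seed = 1),
               class = "too_few_genes_error")
})

test_that("empirical_p follows the add-one rule and is monotone", {
  null_vals <- 1:1000
  expect_equal(empirical_p(2000, null_vals, "greater"), 1 / 1001)
  p_med <- empirical_p(500, null_vals, "greater")
  expect_lt(abs(p_med - 0.5), 0.01)
  # direct-count check: observed 39.5 against N(7, 1) nulls
  set.seed(5)
  nd <- rnorm(1000, 7, 1)
  expect_equal(empirical_p(39.5, nd, "greater"), 1 / 1001)
  expect_lt(empirical_p(9, nd, "greater"), empirical_p(5, nd, "greater"))
  expect_error(empirical_p(1, numeric(), "greater"),
               class = "empty_null_error")
})
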