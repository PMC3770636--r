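test_that("spearman_rho matches hand-checked values and flags degeneracy", {
  expect_equal(spearman_rho(c(1, 2, 3), c(10, 20, 30)), 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(30, 20, 10)), -1)
  # mid-ranks 1, 2.5, 2.5, 4 vs 1, 2, 3, 4
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(1, 2, 3, 4)), 0.9487,
               tolerance = 1e-4)
  expect_warning(r <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r))
  expect_warning(r2 <- spearman_rho(c(1, 2), c(1, 2)), "n < 3")
  expect_true(is.na(r2))
})

test_that("spearman_rho equals the independent mid-rank Pearson oracle", {
  set.seed(91)
  for (rep in 1:100) {
    n <- sample(4:30, 1L)
    x <- sample(1:6, n, replace = TRUE)   # heavy ties
    y <- rnorm(n)
    if (length(unique(x)) < 2L) next
    expect_equal(spearman_rho(x, y), midrank_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("exact permutation p enumerates all n! relabelings", {
  expect_equal(two_tailed_p(1:3, 1:3, method = "exact"), 2 / 6)
  # n = 4, perfect concordance: rho = +-1 for the identity and the reversal
  expect_equal(two_tailed_p(1:4, 1:4, method = "exact"), 2 / 24)
  expect_error(two_tailed_p(1:10, 1:10, method = "exact"), "refused for n > 9")
})

test_that("Monte-Carlo p is seeded, bounded below, and near exact", {
  x <- c(3, 1, 4, 1, 5, 9, 2)
  y <- c(2, 7, 1, 8, 2, 8, 1)
  p1 <- two_tailed_p(x, y, method = "monte_carlo", n_perm = 2000, seed = 5)
  p2 <- two_tailed_p(x, y, method = "monte_carlo", n_perm = 2000, seed = 5)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 2001)
  p_exact <- two_tailed_p(x, y, method = "exact")
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(p1 - p_exact), 3 * se + 1e-9)
})

test_that("correlate_steps_vs_rank pairs, excludes, and signs correctly", {
  steps <- data.frame(char_id = 1:5, steps = c(10, 8, 6, 4, 2), k = 2L)
  ranks <- data.frame(char_id = 1:5, rank = 1:5, usable = TRUE)
  out <- correlate_steps_vs_rank(steps, ranks)
  expect_equal(out$rho, -1)   # more steps -> better (smaller) rank
  expect_equal(out$n, 5L)

  ranks2 <- ranks; ranks2$usable[3] <- FALSE; ranks2$rank[3] <- NA
  out2 <- correlate_steps_vs_rank(steps, ranks2)
  expect_equal(out2$n, 4L)
  expect_equal(out2$n_excluded, 1L)

  # permutation invariance of the pairing
  shuf <- sample(5)
  out3 <- correlate_steps_vs_rank(steps[shuf, ], ranks)
  expect_equal(out3$rho, out$rho)

  # negating the rank convention flips the sign exactly
  ranks_neg <- ranks; ranks_neg$rank <- 6L - ranks$rank
  expect_equal(correlate_steps_vs_rank(steps, ranks_neg)$rho, 1)

  steps_const <- steps; steps_const$steps <- 3
  expect_warning(out4 <- correlate_steps_vs_rank(steps_const, ranks),
                 "zero variance")
  expect_true(is.na(out4$rho))
  expect_error(correlate_steps_vs_rank(steps[1:2, ], ranks[1:2, ]),
               "fewer than 3")
})

test_that("stratification partitions characters and respects min_n", {
  steps <- data.frame(char_id = 1:13, steps = c(13:1),
                      k = c(rep(2L, 6), rep(3L, 4), rep(4L, 3)))
  ranks <- data.frame(char_id = 1:13, rank = 1:13, usable = TRUE)
  st <- stratify_by_state_count(steps, ranks, min_n = 4L)
  expect_equal(sum(st$n), correlate_steps_vs_rank(steps, ranks)$n)
  expect_false(st$tested[st$k == 4])       # only 3 members
  expect_true(all(st$tested[st$k %in% c(2, 3)]))

  # single stratum equals the overall result
  steps1 <- steps; steps1$k <- 2L
  st1 <- stratify_by_state_count(steps1, ranks, min_n = 4L)
  expect_equal(nrow(st1), 1L)
  expect_equal(st1$rho, correlate_steps_vs_rank(steps, ranks)$rho)
})

test_that("run_study wires simulation, counting, ranking and reporting", {
  cfg <- sim_config(n_taxa = 40, state_counts = c(rep(2L, 8), rep(3L, 8)),
                    rate_low = 0.05, rate_high = 5, missing_fraction = 0.02,
                    seed = 101)
  rep1 <- run_study(cfg, n_perm = 500)
  expect_s3_class(rep1, "study_report")
  expect_equal(rep1$n_characters, 16L)
  expect_equal(nrow(rep1$per_character), 16L)
  expect_lte(rep1$n_homoplastic + rep1$n_invariant, rep1$n_characters)
  expect_true(rep1$rho_overall >= -1 && rep1$rho_overall <= 1)
  expect_gt(rep1$p_overall, 0)
  expect_lte(rep1$p_overall, 1)
  expect_equal(sum(rep1$strata$n) + rep1$n_excluded, rep1$n_characters)
})

test_that("two runs with the same config produce byte-identical reports", {
  cfg <- sim_config(n_taxa = 25, state_counts = c(2L, 2L, 3L, 3L, 4L),
                    seed = 103)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  write_study_report(run_study(cfg, n_perm = 300), d1)
  write_study_report(run_study(cfg, n_perm = 300), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("a flat rate profile yields no rate-utility signal", {
  cfg <- sim_config(n_taxa = 60, state_counts = rep(3L, 20),
                    rate_low = 1, rate_high = 1, missing_fraction = 0,
                    seed = 104)
  rep_null <- run_study(cfg, n_perm = 500)
  # all characters share one rate: any correlation is sampling noise
  expect_gt(rep_null$p_overall, 0.01)
})

test_that("run_study on explicit inputs checks taxon consistency", {
  tr <- simulate_yule_tree(10, seed = 105)
  m <- simulate_matrix(tr, sim_config(n_taxa = 10, state_counts = rep(3L, 8),
                                      rate_low = 1, rate_high = 5,
                                      seed = 106))$matrix
  sub <- char_matrix(m$taxa[1:8], m$characters, m$cells[1:8, , drop = FALSE])
  expect_error(run_study(tree = tr, matrix = sub, n_perm = 200),
               "taxa on tree but not in matrix: t009, t010")

  # matrix may hold more taxa than the tree (key vs phylogeny subsample)
  bigger <- char_matrix(c(m$taxa, "extra"), m$characters,
                        rbind(m$cells, m$cells[1, , drop = FALSE]))
  rep2 <- run_study(tree = tr, matrix = bigger, n_perm = 200, seed = 2)
  expect_true(rep2$populations_differ)
})

test_that("run_study attaches per-class molecular step averages", {
  tr <- simulate_yule_tree(15, seed = 107)
  m <- simulate_matrix(tr, sim_config(n_taxa = 15, state_counts = rep(c(2L, 3L), 4),
                                      seed = 108))$matrix
  aln <- simulate_alignment(tr, c(mt3 = 40L, n1 = 40L),
                            c(mt3 = 1.5, n1 = 0.1), seed = 109)
  rep3 <- run_study(tree = tr, matrix = m, alignment = aln, n_perm = 200,
                    seed = 3)
  expect_true(all(c("mt3", "n1") %in% rep3$class_average_steps$class))
  expect_true(all(c("color", "morphometric", "sculpture") %in%
                    rep3$class_average_steps$class))
})
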