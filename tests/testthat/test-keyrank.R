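four_taxa <- function() {
  # X splits 2/2, Y splits 3/1
  matrix_from_strings(c("A", "B", "C", "D"),
                      list(c("0", "0"), c("0", "0"), c("1", "0"), c("1", "1")),
                      k_per_char = c(2L, 2L))
}

test_that("best_score implements the expected-retained-fraction formula", {
  m <- four_taxa()
  expect_equal(as.numeric(best_score(m, 1)), 0.5)       # 2/2 split
  expect_equal(as.numeric(best_score(m, 2)), 0.625)     # 3/1 split
  m2 <- matrix_from_strings(c("A", "B", "C"), list("0", "1", "?"),
                            k_per_char = 2L)
  expect_equal(as.numeric(best_score(m2, 1)), 2 / 3)    # missing always kept
  m3 <- matrix_from_strings(c("A", "B"), list("0", "0"), k_per_char = 2L)
  b <- best_score(m3, 1)
  expect_equal(as.numeric(b), 1)                        # cannot eliminate
  expect_false(attr(b, "usable"))
})

test_that("rank_best orders by score with deterministic tie-breaks", {
  m <- four_taxa()
  rb <- rank_best(m)
  expect_equal(rb$char_id, c(1L, 2L))
  expect_equal(rb$rank, c(1L, 2L))
  # tie -> lower id first
  m_tie <- matrix_from_strings(c("A", "B"), list(c("0", "1"), c("1", "0")),
                               k_per_char = c(2L, 2L))
  expect_equal(rank_best(m_tie)$char_id, c(1L, 2L))
  # constant character (2) flagged unusable and appended after usable (1)
  m_const <- matrix_from_strings(c("A", "B"), list(c("0", "0"), c("1", "0")),
                                 k_per_char = c(2L, 2L))
  rb2 <- rank_best(m_const)
  expect_equal(rb2$char_id, c(1L, 2L))
  expect_false(rb2$usable[2])
  expect_true(is.na(rb2$rank[2]))
})

test_that("select_state eliminates by containment with wildcard missing", {
  m <- matrix_from_strings(c("A", "B", "C", "D"),
                           list("0", "1", "0/1", "?"), k_per_char = 2L)
  s <- key_session(m)
  s1 <- select_state(s, 1, 1L)                 # state index 1 = label "0"
  expect_setequal(s1$active, c("A", "C", "D"))
  s2 <- select_state(s1, 1, 2L)
  expect_setequal(s2$active, c("C", "D"))
  expect_equal(nrow(s2$history), 2L)
  # a selection that empties the set errors without mutating the session
  m2 <- matrix_from_strings(c("A", "B"), list("0", "0"), k_per_char = 2L)
  s3 <- key_session(m2)
  expect_error(select_state(s3, 1, 2L), "no matching taxa")
  expect_setequal(s3$active, c("A", "B"))
})

test_that("elimination semantics compose in any order", {
  set.seed(51)
  tr <- simulate_yule_tree(15, seed = 52)
  m <- simulate_matrix(tr, sim_config(n_taxa = 15, state_counts = rep(2:4, 2),
                                      missing_fraction = 0.1, seed = 53))$matrix
  # select states held by taxon 1, so no order can empty the active set
  sels <- lapply(c(1L, 3L, 5L), function(id) {
    cell <- m$cells[[1L, id]]
    c(id, if (is.null(cell)) 1L else cell[1L])
  })
  final_sets <- lapply(list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1)), function(ord) {
    s <- key_session(m)
    for (i in ord) s <- select_state(s, sels[[i]][1], sels[[i]][2])
    sort(s$active)
  })
  expect_equal(final_sets[[1]], final_sets[[2]])
  expect_equal(final_sets[[1]], final_sets[[3]])
})

test_that("greedy_key_path identifies targets or reports non-uniqueness", {
  m <- matrix_from_strings(c("A", "B"), list("0", "1"), k_per_char = 2L)
  p <- greedy_key_path(m, "A")
  expect_equal(nrow(p$path), 1L)
  expect_true(p$unique)

  dup <- matrix_from_strings(c("A", "B"), list(c("0", "1"), c("0", "1")),
                             k_per_char = c(2L, 2L))
  p2 <- greedy_key_path(dup, "A")
  expect_false(p2$unique)
  expect_setequal(p2$final_active, c("A", "B"))

  # 4 taxa = all combinations of 2 binary characters: depth 2 for any target
  combos <- matrix_from_strings(c("T00", "T01", "T10", "T11"),
                                list(c("0", "0"), c("0", "1"),
                                     c("1", "0"), c("1", "1")),
                                k_per_char = c(2L, 2L))
  for (tx in combos$taxa) {
    p3 <- greedy_key_path(combos, tx)
    expect_true(p3$unique)
    expect_equal(nrow(p3$path), 2L)
  }
})

test_that("mean_key_depth aggregates and is order-invariant", {
  m <- matrix_from_strings(c("A", "B"), list("0", "1"), k_per_char = 2L)
  d <- mean_key_depth(m)
  expect_equal(d$mean, 1)
  expect_equal(d$frac_unique, 1)

  dup <- matrix_from_strings(c("A", "B", "C"), list("0", "1", "1"),
                             k_per_char = 2L)
  expect_lt(mean_key_depth(dup)$frac_unique, 1)

  tr <- simulate_yule_tree(10, seed = 61)
  m2 <- simulate_matrix(tr, sim_config(n_taxa = 10, state_counts = rep(3L, 6),
                                       missing_fraction = 0, seed = 62))$matrix
  d1 <- mean_key_depth(m2)
  perm <- rev(seq_along(m2$taxa))
  m2r <- char_matrix(m2$taxa[perm], m2$characters,
                     m2$cells[perm, , drop = FALSE])
  d2 <- mean_key_depth(m2r)
  expect_equal(d1[c("mean", "median", "max", "frac_unique")],
               d2[c("mean", "median", "max", "frac_unique")])
})

test_that("binary best_score is minimized at the most balanced split", {
  for (N in 4:12) {
    taxa <- sprintf("t%02d", 1:N)
    score_of_split <- function(a) {
      rows <- lapply(seq_len(N), function(i) if (i <= a) "0" else "1")
      as.numeric(best_score(matrix_from_strings(taxa, rows, k_per_char = 2L), 1))
    }
    scores <- vapply(1:(N - 1), score_of_split, 0)
    expect_equal(which.min(scores), floor(N / 2))
    expect_equal(min(scores), score_of_split(floor(N / 2)))
  }
})

test_that("adding an unscored taxon never decreases the best score", {
  set.seed(54)
  for (rep in 1:20) {
    N <- sample(3:8, 1L)
    taxa <- sprintf("t%d", 1:N)
    rows <- lapply(seq_len(N), function(i) as.character(sample(0:2, 1)))
    m <- matrix_from_strings(taxa, rows, k_per_char = 3L)
    b0 <- as.numeric(best_score(m, 1))
    m2 <- matrix_from_strings(c(taxa, "extra"), c(rows, list("?")),
                              k_per_char = 3L)
    expect_gte(as.numeric(best_score(m2, 1)), b0 - 1e-12)
  }
})

test_that("ranking is stable under duplicating every taxon", {
  tr <- simulate_yule_tree(12, seed = 55)
  m <- simulate_matrix(tr, sim_config(n_taxa = 12, state_counts = c(2L, 3L, 4L, 2L),
                                      missing_fraction = 0.1, seed = 56))$matrix
  doubled <- char_matrix(
    c(m$taxa, paste0(m$taxa, "_dup")), m$characters,
    rbind(m$cells, m$cells))
  r1 <- rank_best(m); r2 <- rank_best(doubled)
  expect_equal(r1$char_id, r2$char_id)
  expect_equal(r1$rank, r2$rank)
  expect_equal(r1$best_score, r2$best_score, tolerance = 1e-12)
})
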