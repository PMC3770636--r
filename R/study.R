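#' Spearman rank correlation (mid-ranks)
#'
#' Pearson correlation of mid-ranks; ties get average ranks. Returns exactly
#' -1 or 1 for perfectly monotone tie-free inputs. A zero-variance rank
#' vector (or n < 3) has no defined correlation: the result is `NA` with a
#' warning, never silently 0.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`.
#' @return numeric rho in `[-1, 1]`, or `NA` when undefined.
#' @examples
#' spearman_rho(c(1, 2, 3), c(10, 20, 30))   #  1
#' spearman_rho(c(1, 2, 2, 4), c(1, 2, 3, 4))
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) {
    warning("spearman_rho undefined for n < 3")
    return(NA_real_)
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("spearman_rho undefined: zero variance in ranks")
    return(NA_real_)
  }
  cor(rx, ry)
}

#' Two-tailed permutation p-value for the Spearman correlation
#'
#' `method = "exact"` enumerates all `n!` permutations of `y` (refused for
#' `n > 9`); the p-value is the share of permutations with `|rho|` at least
#' the observed `|rho|`. `method = "monte_carlo"` uses `n_perm` seeded
#' resamples and the add-one estimator `(b + 1) / (n_perm + 1)`, which is
#' never smaller than `1 / (n_perm + 1)`.
#'
#' @param x,y equal-length numeric vectors.
#' @param method `"exact"` or `"monte_carlo"`.
#' @param n_perm number of Monte-Carlo resamples.
#' @param seed integer seed for the Monte-Carlo method.
#' @return p-value in `(0, 1]`.
#' @export
two_tailed_p <- function(x, y, method = c("monte_carlo", "exact"),
                         n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  n <- length(x)
  obs <- spearman_rho(x, y)
  if (is.na(obs)) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  eps <- 1e-12
  if (method == "exact") {
    if (n > 9L) stop("exact enumeration refused for n > 9 (", n,
                     "); use method = 'monte_carlo'")
    pm <- permutations(n)
    # Pearson of fixed rx with each permutation of ry, via cross-products
    sx <- (rx - mean(rx)) / sqrt(sum((rx - mean(rx))^2))
    sy <- (ry - mean(ry)) / sqrt(sum((ry - mean(ry))^2))
    rhos <- as.numeric(matrix(sy[pm], nrow(pm), n) %*% sx)
    mean(abs(rhos) >= abs(obs) - eps)
  } else {
    withr::with_seed(seed, {
      b <- 0L
      for (i in seq_len(n_perm)) {
        r <- cor(rx, ry[sample.int(n)])
        if (abs(r) >= abs(obs) - eps) b <- b + 1L
      }
      (b + 1) / (n_perm + 1)
    })
  }
}

# All permutations of 1..n as a (n! x n) integer matrix.
permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (pos in seq_len(n)) {
    block <- seq_len(nrow(sub)) + row
    out[block, pos] <- n
    out[block, -pos] <- sub
    row <- row + nrow(sub)
  }
  out
}

#' Correlate parsimony steps with Best rank
#'
#' Pairs characters by id; characters unusable for ranking (`rank = NA`) or
#' without a defined step count are excluded and counted. Rank 1 = most
#' useful, so the expectation that fast characters are the most useful
#' appears as a negative rho.
#'
#' @param steps data frame from [step_table] (`char_id`, `steps`).
#' @param ranks data frame from [rank_best] (`char_id`, `rank`, `usable`).
#' @param method,n_perm,seed passed to [two_tailed_p]; the default method
#'   enumerates exactly when `n <= 9` and resamples otherwise.
#' @return list: `rho`, `p`, `n`, `n_excluded`.
#' @export
correlate_steps_vs_rank <- function(steps, ranks, method = NULL,
                                    n_perm = 10000L, seed = 1L) {
  merged <- merge(steps[, c("char_id", "steps")],
                  ranks[, c("char_id", "rank", "usable")], by = "char_id")
  ok <- merged$usable & !is.na(merged$rank) & !is.na(merged$steps)
  n <- sum(ok)
  if (n < 3L) stop("fewer than 3 usable character pairs (", n, ")")
  x <- merged$steps[ok]; y <- merged$rank[ok]
  rho <- spearman_rho(x, y)
  if (is.null(method)) method <- if (n <= 9L) "exact" else "monte_carlo"
  p <- if (is.na(rho)) NA_real_
       else two_tailed_p(x, y, method = method, n_perm = n_perm, seed = seed)
  list(rho = rho, p = p, n = n, n_excluded = sum(!ok))
}

#' Steps-versus-rank correlation stratified by state count
#'
#' @inheritParams correlate_steps_vs_rank
#' @param k data frame column source: `steps` must carry a `k` column.
#' @param min_n strata with fewer usable characters than this are reported
#'   but not tested (`tested = FALSE`, rho/p `NA`); default 5.
#' @return data frame: `k`, `n`, `rho`, `p`, `tested`.
#' @export
stratify_by_state_count <- function(steps, ranks, min_n = 5L,
                                    n_perm = 10000L, seed = 1L) {
  merged <- merge(steps[, c("char_id", "steps", "k")],
                  ranks[, c("char_id", "rank", "usable")], by = "char_id")
  merged <- merged[merged$usable & !is.na(merged$rank) & !is.na(merged$steps), ]
  out <- lapply(sort(unique(merged$k)), function(kk) {
    sub <- merged[merged$k == kk, ]
    n <- nrow(sub)
    if (n < max(min_n, 3L)) {
      return(data.frame(k = kk, n = n, rho = NA_real_, p = NA_real_,
                        tested = FALSE))
    }
    rho <- suppressWarnings(spearman_rho(sub$steps, sub$rank))
    p <- if (is.na(rho)) NA_real_ else two_tailed_p(
      sub$steps, sub$rank,
      method = if (n <= 9L) "exact" else "monte_carlo",
      n_perm = n_perm, seed = seed)
    data.frame(k = kk, n = n, rho = rho, p = p, tested = TRUE)
  })
  do.call(rbind, out)
}

#' Run the full rate-versus-utility study
#'
#' Either simulates a tree and matrix from a [sim_config] or takes them as
#' given, then: counts parsimony steps per character, ranks all characters
#' on the full matrix with the Best score, correlates steps with rank
#' (overall and stratified by state count), censuses homoplasy, and, when an
#' alignment is supplied, appends per-class average steps for the molecular
#' partitions. Deterministic given `seed`.
#'
#' @param config a [sim_config], or `NULL` when `tree` and `matrix` are
#'   supplied directly.
#' @param tree,matrix empirical inputs (ignored when `config` is given).
#' @param alignment optional `dna_alignment` with a partition, for per-class
#'   molecular step averages.
#' @param n_perm Monte-Carlo permutations for p-values.
#' @param stratum_min minimum stratum size to test (default 5).
#' @param seed integer seed driving simulation sub-seeds and permutation
#'   resampling; defaults to `config$seed`.
#' @return an object of class `study_report`.
#' @export
run_study <- function(config = NULL, tree = NULL, matrix = NULL,
                      alignment = NULL, n_perm = 10000L, stratum_min = 5L,
                      seed = NULL) {
  records <- NULL
  if (!is.null(config)) {
    if (is.null(seed)) seed <- config$seed
    tree <- simulate_yule_tree(config$n_taxa, config$birth_rate, seed = seed)
    cfg <- config; cfg$seed <- seed + 1L
    sim <- simulate_matrix(tree, cfg)
    matrix <- sim$matrix
    records <- sim$records
  } else {
    if (is.null(tree) || is.null(matrix))
      stop("supply either a config or both tree and matrix")
    if (is.null(seed)) seed <- 1L
    missing_in_matrix <- setdiff(tree$tip.label, matrix$taxa)
    missing_in_tree <- setdiff(matrix$taxa, tree$tip.label)
    if (length(missing_in_matrix))
      stop("taxa on tree but not in matrix: ",
           paste(missing_in_matrix, collapse = ", "),
           if (length(missing_in_tree))
             paste0("; in matrix but not on tree: ",
                    paste(missing_in_tree, collapse = ", ")) else "")
  }
  perm_seed <- seed + 2L

  steps <- step_table(tree, matrix)
  ranks <- rank_best(matrix)  # full matrix: all taxa active
  overall <- correlate_steps_vs_rank(steps, ranks, n_perm = n_perm,
                                     seed = perm_seed)
  strata <- stratify_by_state_count(steps, ranks, min_n = stratum_min,
                                    n_perm = n_perm, seed = perm_seed)

  per_char <- merge(steps, ranks[, c("char_id", "best_score", "rank", "usable")],
                    by = "char_id")
  per_char <- per_char[order(per_char$char_id), ]
  rownames(per_char) <- NULL
  if (!is.null(records))
    per_char <- merge(per_char,
                      records[, c("char_id", "true_rate", "true_change_count")],
                      by = "char_id")

  class_avg <- class_average_steps(steps$steps, steps$class,
                                   scored = steps$n_scored)
  if (!is.null(alignment) && !is.null(alignment$partition)) {
    colsteps <- column_steps(tree, alignment)
    mol <- class_average_steps(colsteps$steps, colsteps$class,
                               scored = colsteps$scored)
    class_avg <- rbind(class_avg, mol)
  }

  # Ranking and step-counting use the same taxon set unless the matrix holds
  # taxa absent from the tree (the empirical design: full key, tree subsample).
  ranked_off_tree <- length(setdiff(matrix$taxa, tree$tip.label))

  structure(list(
    n_characters = n_characters(matrix),
    n_taxa_matrix = n_taxa(matrix),
    n_taxa_tree = length(tree$tip.label),
    per_character = per_char,
    mean_steps = mean(steps$steps),
    n_homoplastic = sum(steps$homoplastic),
    n_invariant = sum(steps$steps == 0L),
    rho_overall = overall$rho, p_overall = overall$p,
    n_correlated = overall$n, n_excluded = overall$n_excluded,
    strata = strata,
    class_average_steps = class_avg,
    populations_differ = ranked_off_tree > 0L,
    config = list(seed = seed, n_perm = n_perm, stratum_min = stratum_min,
                  sign_convention = "rank 1 = most useful; negative rho means fast characters are most useful",
                  sim = if (!is.null(config)) unclass(config) else NULL)
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report\n")
  cat(sprintf("  characters: %d (matrix %d taxa, tree %d leaves)\n",
              x$n_characters, x$n_taxa_matrix, x$n_taxa_tree))
  cat(sprintf("  mean steps: %.2f; homoplastic: %d; invariant: %d\n",
              x$mean_steps, x$n_homoplastic, x$n_invariant))
  cat(sprintf("  steps vs Best rank: rho = %.3f, p = %.4g, n = %d (%d excluded)\n",
              x$rho_overall, x$p_overall, x$n_correlated, x$n_excluded))
  cat("  by state count:\n")
  for (i in seq_len(nrow(x$strata))) {
    s <- x$strata[i, ]
    cat(sprintf("    k = %d: n = %d, %s\n", s$k, s$n,
                if (s$tested) sprintf("rho = %.3f, p = %.4g", s$rho, s$p)
                else "not tested"))
  }
  invisible(x)
}

#' Write a study report as JSON plus TSV tables
#'
#' Emits `report.json`, `per_character.tsv`, `ranking.tsv`, `steps.tsv` and
#' `class_average_steps.tsv` into `dir`.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scalar <- report[c("n_characters", "n_taxa_matrix", "n_taxa_tree",
                     "mean_steps", "n_homoplastic", "n_invariant",
                     "rho_overall", "p_overall", "n_correlated",
                     "n_excluded", "populations_differ")]
  jsonlite::write_json(
    c(scalar, list(strata = report$strata,
                   class_average_steps = report$class_average_steps,
                   config = report$config)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null")
  tsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tsv(report$per_character, "per_character.tsv")
  rk <- report$per_character[, c("char_id", "class", "k", "best_score",
                                 "rank", "usable")]
  tsv(rk[order(rk$rank, na.last = TRUE), ], "ranking.tsv")
  tsv(report$per_character[, c("char_id", "class", "k", "k_obs", "steps",
                               "min_steps", "max_steps", "ci", "ri",
                               "homoplastic")], "steps.tsv")
  tsv(report$class_average_steps, "class_average_steps.tsv")
  invisible(dir)
}
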