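#' Minimum parsimony steps for an unordered character on a rooted tree
#'
#' Computes the minimum number of state changes over all assignments of
#' single states to internal nodes (and resolutions of polymorphic leaves),
#' using unit-cost dynamic programming over the tree. On binary trees this
#' equals the Fitch count; the same recursion handles polytomies exactly, as
#' Hartigan's generalization does. Missing leaves carry the full state set
#' and can never force a change; polymorphic leaves carry their observed
#' state set.
#'
#' @param tree a rooted `phylo` tree (polytomies allowed; branch lengths
#'   ignored).
#' @param states named list over the tree's leaf labels: each element an
#'   integer vector of 1-based state indices (length > 1 = polymorphic), or
#'   `NULL`/`NA` for missing. Every leaf must be present.
#' @param k number of states; default `max` observed index.
#' @return integer step count. Attribute `n_scored` gives the number of
#'   non-missing leaves; a character with zero scored leaves returns 0 steps
#'   with a warning.
#' @examples
#' tr <- read_newick("((A,B),(C,D));")
#' count_steps(tr, list(A = 1, B = 2, C = 1, D = 2))  # 2
#' @export
count_steps <- function(tree, states, k = NULL) {
  labs <- tree$tip.label
  missing_leaves <- setdiff(labs, names(states))
  if (length(missing_leaves))
    stop("leaf absent from matrix: ", paste(missing_leaves, collapse = ", "))
  sets <- lapply(states[labs], function(s) {
    if (is.null(s) || all(is.na(s))) NULL else as.integer(s)
  })
  if (is.null(k)) k <- max(c(1L, unlist(sets)))
  n_scored <- sum(!vapply(sets, is.null, TRUE))
  if (n_scored == 0L) {
    warning("character has zero scored leaves; steps = 0")
    return(structure(0L, n_scored = 0L))
  }
  steps <- sankoff_unit_cost(tree, sets, k)
  structure(as.integer(steps), n_scored = n_scored)
}

# Unit-cost Sankoff DP. cost[v, s] = min changes in subtree of v given v has
# state s; for an edge (v, c): contribution to cost[v, s] is
# min(cost[c, s], min_t cost[c, t] + 1). Leaves cost 0 on their own states,
# "infinity" elsewhere; missing leaves cost 0 everywhere.
sankoff_unit_cost <- function(tree, sets, k) {
  BIG <- 1e9
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  cost <- matrix(0, nnode, k)
  for (i in seq_len(ntip)) {
    s <- sets[[i]]
    if (!is.null(s)) {
      cost[i, ] <- BIG
      cost[i, s] <- 0
    }
  }
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]
    child <- po$edge[e, 2L]
    cc <- cost[child, ]
    cost[parent, ] <- cost[parent, ] + pmin(cc, min(cc) + 1)
  }
  root <- ntip + 1L
  min(cost[root, ])
}

#' Per-character parsimony and homoplasy summary
#'
#' Combines the minimum step count `s` with its theoretical bounds and the
#' usual homoplasy indices: `m` = minimum conceivable steps on any tree
#' (number of states needed to cover every scored cell, minus one; equals
#' observed states minus one when no cell is polymorphic); `g` = maximum
#' steps (scored leaves minus the count of the most frequent state, a
#' polymorphic leaf counting toward that state when it contains it);
#' consistency index `ci = m/s` (`NA` when `s = 0`); retention index
#' `ri = (g - s)/(g - m)` (`NA` when `g = m`). A character is flagged
#' homoplastic when `s > m`, i.e. when some state must arise more than once
#' or revert on the tree.
#'
#' @param tree a rooted `phylo` tree.
#' @param matrix a [char_matrix] covering all tree leaves.
#' @param char_id character id.
#' @return a list of class `step_count` with fields `char_id`, `class_tag`,
#'   `k`, `k_obs`, `n_scored`, `steps`, `min_steps`, `max_steps`, `ci`,
#'   `ri`, `homoplastic`.
#' @export
summarize_character <- function(tree, matrix, char_id) {
  j <- char_index(matrix, char_id)
  def <- matrix$characters[[j]]
  k <- length(def$state_labels)
  column <- matrix_column(matrix, char_id)
  scored <- column[!vapply(column, is.null, TRUE)]
  on_tree <- scored[intersect(names(scored), tree$tip.label)]
  s <- suppressWarnings(count_steps(tree, column, k = k))
  n_scored <- attr(s, "n_scored")
  observed <- sort(unique(unlist(on_tree)))
  k_obs <- length(observed)
  m <- if (n_scored == 0L) 0L else min_cover_states(on_tree, observed) - 1L
  g <- if (n_scored == 0L) 0L else {
    counts <- vapply(observed, function(st)
      sum(vapply(on_tree, function(cell) st %in% cell, TRUE)), 0L)
    n_scored - max(counts)
  }
  s <- as.integer(s)
  structure(list(
    char_id = def$id, class_tag = def$class_tag, k = k, k_obs = k_obs,
    n_scored = n_scored, steps = s, min_steps = as.integer(m),
    max_steps = as.integer(g),
    ci = if (s > 0L) m / s else NA_real_,
    ri = if (g > m) (g - s) / (g - m) else NA_real_,
    homoplastic = s > m
  ), class = "step_count")
}

#' @export
print.step_count <- function(x, ...) {
  cat(sprintf("character %d: steps %d (min %d, max %d), ci %s, ri %s%s\n",
              x$char_id, x$steps, x$min_steps, x$max_steps,
              fmt_or_na(x$ci), fmt_or_na(x$ri),
              if (x$homoplastic) ", homoplastic" else ""))
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)

# Smallest number of states whose union hits every scored cell (k <= 6, so
# subset enumeration is cheap). Equals the number of distinct observed states
# when no cell is polymorphic.
min_cover_states <- function(cells, observed) {
  if (!length(cells)) return(1L)
  for (size in seq_along(observed)) {
    combos <- utils::combn(observed, size, simplify = FALSE)
    for (sub in combos) {
      if (all(vapply(cells, function(cell) any(cell %in% sub), TRUE)))
        return(size)
    }
  }
  length(observed)
}

#' Step summaries for every character in a matrix
#'
#' @inheritParams summarize_character
#' @return a data frame, one row per character: `char_id`, `class`, `k`,
#'   `k_obs`, `n_scored`, `steps`, `min_steps`, `max_steps`, `ci`, `ri`,
#'   `homoplastic`.
#' @export
step_table <- function(tree, matrix) {
  rows <- lapply(matrix$characters, function(def)
    summarize_character(tree, matrix, def$id))
  data.frame(
    char_id = vapply(rows, `[[`, 1L, "char_id"),
    class = vapply(rows, `[[`, "", "class_tag"),
    k = vapply(rows, `[[`, 1L, "k"),
    k_obs = vapply(rows, `[[`, 1L, "k_obs"),
    n_scored = vapply(rows, `[[`, 1L, "n_scored"),
    steps = vapply(rows, `[[`, 1L, "steps"),
    min_steps = vapply(rows, `[[`, 1L, "min_steps"),
    max_steps = vapply(rows, `[[`, 1L, "max_steps"),
    ci = vapply(rows, `[[`, 1, "ci"),
    ri = vapply(rows, `[[`, 1, "ri"),
    homoplastic = vapply(rows, `[[`, TRUE, "homoplastic")
  )
}

#' Parsimony steps per alignment column
#'
#' Each column is treated as an unordered 4-state character (A, C, G, T);
#' gaps and N are missing. Columns are grouped by partition class when a
#' partition is available; unassigned columns get class `NA`.
#'
#' @param tree a rooted `phylo` tree whose leaves all appear in the alignment.
#' @param alignment a `dna_alignment` (taxa may be a superset of the leaves).
#' @param partition optional named list of column indices; defaults to
#'   `alignment$partition`.
#' @return data frame: `site`, `class`, `steps`, `scored` (number of
#'   non-missing leaves; 0 = unscored column).
#' @export
column_steps <- function(tree, alignment, partition = alignment$partition) {
  labs <- tree$tip.label
  absent <- setdiff(labs, rownames(alignment$seqs))
  if (length(absent))
    stop("tree leaf absent from alignment: ", paste(absent, collapse = ", "))
  seqs <- alignment$seqs[labs, , drop = FALSE]
  nsite <- ncol(seqs)
  cls <- rep(NA_character_, nsite)
  if (!is.null(partition))
    for (nm in names(partition)) cls[partition[[nm]]] <- nm
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  # deduplicate identical column patterns before running the DP
  pattern <- apply(seqs, 2L, paste, collapse = "")
  uniq <- !duplicated(pattern)
  usteps <- integer(sum(uniq)); uscored <- integer(sum(uniq))
  ui <- 0L
  for (site in which(uniq)) {
    ui <- ui + 1L
    col <- code[seqs[, site]]
    sets <- lapply(unname(col), function(v) if (is.na(v)) NULL else v)
    names(sets) <- labs
    st <- suppressWarnings(count_steps(tree, sets, k = 4L))
    usteps[ui] <- as.integer(st)
    uscored[ui] <- attr(st, "n_scored")
  }
  idx <- match(pattern, pattern[uniq])
  data.frame(site = seq_len(nsite), class = cls,
             steps = usteps[idx], scored = uscored[idx])
}

#' Mean parsimony steps per character class
#'
#' @param steps integer/numeric vector of per-character (or per-column) step
#'   counts.
#' @param class character vector of class labels, same length as `steps`;
#'   `NA` entries are dropped.
#' @param scored optional logical (or count) vector; entries with
#'   `scored == 0`/`FALSE` are excluded as unscored.
#' @return data frame `class`, `n`, `mean_steps`; classes with no scored
#'   members are omitted with a warning.
#' @examples
#' class_average_steps(c(0, 2, 4, 15), c("a", "a", "a", "b"))
#' @export
class_average_steps <- function(steps, class, scored = NULL) {
  stopifnot(length(steps) == length(class))
  keep <- !is.na(class)
  if (!is.null(scored)) keep <- keep & (as.numeric(scored) > 0)
  all_classes <- unique(class[!is.na(class)])
  steps <- steps[keep]; class <- class[keep]
  dropped <- setdiff(all_classes, unique(class))
  if (length(dropped))
    warning("class(es) with no scored members omitted: ",
            paste(dropped, collapse = ", "))
  if (!length(steps))
    return(data.frame(class = character(0), n = integer(0),
                      mean_steps = numeric(0)))
  agg <- tapply(steps, class, mean)
  cnt <- tapply(steps, class, length)
  ord <- order(names(agg))
  data.frame(class = names(agg)[ord], n = as.integer(cnt[ord]),
             mean_steps = as.numeric(agg[ord]), row.names = NULL)
}
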