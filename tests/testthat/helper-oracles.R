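# Independent oracles and small random-instance generators shared by the
# unit and acceptance tests. Everything here is deliberately brute-force and
# separate from the package's own code paths.

# Minimum number of changes by exhaustive enumeration over all single-state
# assignments to internal nodes (leaf resolutions are optimized per leaf,
# which is exact because leaves are independent given their parent's state).
enum_steps <- function(tree, sets, k) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  total <- numeric(nrow(grid))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    ps <- grid[, p - ntip]
    if (ch > ntip) {
      total <- total + (ps != grid[, ch - ntip])
    } else {
      s <- sets[[tree$tip.label[ch]]]
      if (is.null(s) || all(is.na(s))) next
      total <- total + !(ps %in% s)
    }
  }
  min(total)
}

# Direct mid-rank Pearson, not using rank() or cor(): the independent
# Spearman oracle.
midrank_pearson <- function(x, y) {
  midrank <- function(v)
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, 0)
  rx <- midrank(x); ry <- midrank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Random rooted tree with optional polytomies (collapse zero-length
# internal edges).
random_tree <- function(n, p_poly = 0.3) {
  tr <- ape::rtree(n)
  tips <- length(tr$tip.label)
  internal <- tr$edge[, 2L] > tips
  if (any(internal) && p_poly > 0) {
    collapse <- internal & (runif(nrow(tr$edge)) < p_poly)
    tr$edge.length[collapse] <- 0
    tr <- ape::di2multi(tr, tol = 1e-9)
  }
  tr$edge.length <- abs(tr$edge.length) + 0.1
  tr
}

# Random character on a tree's leaves: each cell missing, polymorphic, or a
# single state.
random_character <- function(tree, k, p_missing = 0.15, p_poly = 0.15) {
  labs <- tree$tip.label
  sets <- lapply(labs, function(l) {
    u <- runif(1)
    if (u < p_missing) NULL
    else if (u < p_missing + p_poly && k >= 2)
      sort(sample.int(k, 2L))
    else sample.int(k, 1L)
  })
  setNames(sets, labs)
}

# Build a char_matrix from a plain character matrix of label strings
# ("0", "0/1", "?"), the shorthand used throughout the tests.
matrix_from_strings <- function(taxa, rows, k_per_char = NULL,
                                classes = NULL) {
  nc <- length(rows[[1L]])
  if (is.null(k_per_char)) {
    k_per_char <- vapply(seq_len(nc), function(j) {
      labs <- unlist(strsplit(vapply(rows, `[`, "", j), "/"))
      max(as.integer(setdiff(labs, "?"))) + 1L
    }, 1L)
  }
  chars <- lapply(seq_len(nc), function(j)
    character_def(j, state_labels = as.character(seq_len(k_per_char[j]) - 1L),
                  class_tag = if (is.null(classes)) NA_character_ else classes[j]))
  cells <- matrix(vector("list", length(taxa) * nc), length(taxa), nc)
  for (i in seq_along(taxa)) for (j in seq_len(nc)) {
    tok <- rows[[i]][j]
    if (tok != "?")
      cells[[i, j]] <- as.integer(strsplit(tok, "/", fixed = TRUE)[[1L]]) + 1L
  }
  char_matrix(taxa, chars, cells)
}
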