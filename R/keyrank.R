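#' "Best"-style diagnostic score of a character
#'
#' Scores how evenly a character's states are distributed across the active
#' taxa, as the expected fraction of active taxa retained after selecting one
#' state. With `N` active taxa, `n_s` = number of active taxa whose cell
#' contains state `s` (polymorphic taxa count for every state they carry),
#' `u` = number of active unscored (missing) taxa, and selection probability
#' `p_s = n_s / sum_t(n_t)`:
#'
#'   `b = sum_s p_s * (n_s + u) / N`
#'
#' Missing taxa are never eliminated, so they always count toward the
#' retained set. Lower is better; `b = 1` exactly when no selection can
#' eliminate any active taxon. With complete data the score reduces to the
#' Simpson concentration of the state frequencies, so it is minimized by the
#' most even split. When no state is observed among the active taxa the
#' character is unusable and `b = 1`.
#'
#' @param matrix a [char_matrix].
#' @param char_id character id.
#' @param active character vector of active taxon labels (default: all).
#' @return numeric score in `(0, 1]`, with attribute `usable` (`TRUE` when
#'   at least two states are observed among active taxa).
#' @export
best_score <- function(matrix, char_id, active = matrix$taxa) {
  stopifnot(length(active) > 0L)
  memb <- state_membership(matrix, char_id)[active, , drop = FALSE]
  j <- char_index(matrix, char_id)
  is_missing <- vapply(match(active, matrix$taxa), function(i)
    is.null(matrix$cells[[i, j]]), TRUE)
  n_s <- colSums(memb)
  u <- sum(is_missing)
  N <- length(active)
  tot <- sum(n_s)
  usable <- sum(n_s > 0) >= 2L
  if (tot == 0)
    return(structure(1, usable = FALSE))
  b <- sum((n_s / tot) * (n_s + u) / N)
  structure(b, usable = usable)
}

#' Rank all characters by diagnostic utility
#'
#' Usable characters (at least two states observed among the active taxa)
#' are sorted by ascending [best_score], ties broken by ascending character
#' id; rank 1 is the most useful. Unusable characters are appended with
#' `rank = NA` and `usable = FALSE`.
#'
#' @inheritParams best_score
#' @return data frame: `char_id`, `class`, `k`, `best_score`, `rank`,
#'   `usable`, ordered best-first.
#' @export
rank_best <- function(matrix, active = matrix$taxa) {
  ids <- vapply(matrix$characters, `[[`, 1L, "id")
  scores <- numeric(length(ids)); usable <- logical(length(ids))
  for (i in seq_along(ids)) {
    b <- best_score(matrix, ids[i], active)
    scores[i] <- as.numeric(b)
    usable[i] <- attr(b, "usable")
  }
  df <- data.frame(
    char_id = ids,
    class = vapply(matrix$characters, `[[`, "", "class_tag"),
    k = vapply(matrix$characters, function(d) length(d$state_labels), 1L),
    best_score = scores, rank = NA_integer_, usable = usable
  )
  ord_u <- order(df$best_score[usable], df$char_id[usable])
  df_u <- df[usable, , drop = FALSE][ord_u, , drop = FALSE]
  if (nrow(df_u)) df_u$rank <- seq_len(nrow(df_u))
  df_n <- df[!usable, , drop = FALSE]
  df_n <- df_n[order(df_n$char_id), , drop = FALSE]
  out <- rbind(df_u, df_n)
  rownames(out) <- NULL
  out
}

#' Start an interactive-key session
#'
#' A session tracks the set of taxa still compatible with the character
#' states selected so far. Selecting a state eliminates every active taxon
#' whose cell for that character is scored and does not contain the state;
#' unscored (missing) taxa are never eliminated.
#'
#' @param matrix a [char_matrix].
#' @return an object of class `key_session` with fields `matrix`, `active`,
#'   `history` (data frame of selections).
#' @export
key_session <- function(matrix) {
  stopifnot(inherits(matrix, "char_matrix"))
  structure(list(matrix = matrix, active = matrix$taxa,
                 history = data.frame(char_id = integer(0), state = integer(0))),
            class = "key_session")
}

#' @export
print.key_session <- function(x, ...) {
  cat("key_session: ", length(x$active), "/", length(x$matrix$taxa),
      " taxa active after ", nrow(x$history), " selection(s)\n", sep = "")
  invisible(x)
}

#' Select a character state in a key session
#'
#' @param session a [key_session].
#' @param char_id character id.
#' @param state 1-based state index of that character.
#' @return the updated session. A selection that would empty the active set
#'   raises an error and leaves the session unchanged.
#' @export
select_state <- function(session, char_id, state) {
  stopifnot(inherits(session, "key_session"))
  m <- session$matrix
  j <- char_index(m, char_id)
  k <- length(m$characters[[j]]$state_labels)
  state <- as.integer(state)
  if (is.na(state) || state < 1L || state > k)
    stop("invalid state ", state, " for character ", char_id)
  keep <- vapply(session$active, function(tx) {
    cell <- m$cells[[match(tx, m$taxa), j]]
    is.null(cell) || state %in% cell
  }, TRUE)
  if (!any(keep)) stop("no matching taxa for character ", char_id,
                       ", state ", state)
  session$active <- session$active[keep]
  session$history <- rbind(session$history,
                           data.frame(char_id = as.integer(char_id),
                                      state = state))
  session
}

#' Greedy identification path for a known specimen
#'
#' Simulates identifying `target` with the key: at each step the top-ranked
#' usable character (by [rank_best] over the currently active taxa) among
#' those scored in the target and not yet used is selected with the target's
#' own state. For a polymorphic target cell the selectable state with the
#' fewest active carriers is used (ties to the lowest state index). The walk
#' stops when the target is the only active taxon or no usable scored
#' character remains.
#'
#' @param matrix a [char_matrix].
#' @param target taxon label present in the matrix.
#' @return list with `path` (data frame `char_id`, `state`), `final_active`
#'   (character vector) and `unique` (`TRUE` when the target was singled
#'   out). A non-unique endpoint is reported, not an error.
#' @export
greedy_key_path <- function(matrix, target) {
  if (!target %in% matrix$taxa) stop("unknown taxon: ", target)
  session <- key_session(matrix)
  used <- integer(0)
  ti <- match(target, matrix$taxa)
  repeat {
    if (identical(session$active, target)) break
    rb <- rank_best(matrix, session$active)
    rb <- rb[rb$usable & !(rb$char_id %in% used), , drop = FALSE]
    scored <- vapply(rb$char_id, function(id)
      !is.null(matrix$cells[[ti, char_index(matrix, id)]]), TRUE)
    rb <- rb[scored, , drop = FALSE]
    if (!nrow(rb)) break
    id <- rb$char_id[1L]
    cell <- matrix$cells[[ti, char_index(matrix, id)]]
    state <- if (length(cell) == 1L) cell else {
      n_s <- colSums(state_membership(matrix, id)[session$active, , drop = FALSE])
      cell[order(n_s[cell], cell)][1L]
    }
    session <- select_state(session, id, state)
    used <- c(used, id)
  }
  list(path = session$history, final_active = session$active,
       unique = length(session$active) == 1L &&
         session$active[1L] == target)
}

#' Summary of greedy identification depth over taxa
#'
#' @param matrix a [char_matrix].
#' @param sample_size optional number of taxa to sample (without
#'   replacement); default uses every taxon.
#' @param seed integer seed for the sampling step (ignored when all taxa are
#'   used); results are deterministic given the seed.
#' @return list: `mean`, `median`, `max` path length, `frac_unique`
#'   (fraction of sampled taxa uniquely identified), `n`.
#' @export
mean_key_depth <- function(matrix, sample_size = NULL, seed = NULL) {
  taxa <- matrix$taxa
  if (!is.null(sample_size) && sample_size < length(taxa)) {
    taxa <- withr::with_seed(
      if (is.null(seed)) 1L else seed,
      sample(sort(taxa), sample_size))
  }
  paths <- lapply(taxa, function(tx) greedy_key_path(matrix, tx))
  depth <- vapply(paths, function(p) nrow(p$path), 1L)
  uniq <- vapply(paths, `[[`, TRUE, "unique")
  list(mean = mean(depth), median = median(depth), max = max(depth),
       frac_unique = mean(uniq), n = length(taxa))
}
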