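#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic study: a Yule tree
#' rescaled to unit height, characters evolved under the Mk model with
#' per-character rates drawn log-uniformly, and missing cells placed
#' completely at random. The defaults emulate the structure of the empirical
#' study the package is built around: ~350 taxa scored for 47 discrete
#' characters with 2-6 states, a matrix over 95% complete, and character
#' rates spanning two orders of magnitude (0.05-5 expected changes per unit
#' tree height).
#'
#' @param n_taxa number of leaves (>= 3).
#' @param birth_rate Yule speciation rate per unit time (the tree is rescaled
#'   to unit height, so this affects shape only).
#' @param state_counts integer vector of states-per-character, each in 2..6;
#'   its length is the number of characters. Default: 19 two-state, 17
#'   three-state, 8 four-state and 3 six-state characters (47 total).
#' @param rate_low,rate_high log-uniform bounds for the per-character change
#'   rate, in expected changes per unit tree height.
#' @param missing_fraction per-cell probability of a missing entry
#'   (default 0.02, keeping completeness above 95%).
#' @param seed integer seed; mandatory for reproducibility.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 350L, birth_rate = 1,
                       state_counts = c(rep(2L, 19), rep(3L, 17),
                                        rep(4L, 8), rep(6L, 3)),
                       rate_low = 0.05, rate_high = 5,
                       missing_fraction = 0.02, seed) {
  if (missing(seed)) stop("seed is required")
  n_taxa <- as.integer(n_taxa)
  state_counts <- as.integer(state_counts)
  stopifnot(n_taxa >= 3L, birth_rate > 0,
            length(state_counts) >= 1L,
            all(state_counts >= 2L), all(state_counts <= 6L),
            rate_low > 0, rate_low <= rate_high,
            missing_fraction >= 0, missing_fraction < 1)
  structure(list(n_taxa = n_taxa, birth_rate = birth_rate,
                 state_counts = state_counts,
                 rate_low = rate_low, rate_high = rate_high,
                 missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation config from a flat key=value or JSON file
#' @param path file with either JSON or `key = value` lines matching the
#'   [sim_config] arguments (`state_counts` comma-separated).
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  vals <- if (grepl("^\\s*\\{", txt)) {
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else {
    lines <- grep("=", readLines(path, warn = FALSE), fixed = TRUE, value = TRUE)
    kv <- lapply(strsplit(lines, "=", fixed = TRUE), trimws)
    setNames(lapply(kv, function(p)
      as.numeric(strsplit(p[[2L]], ",", fixed = TRUE)[[1L]])),
      vapply(kv, `[`, "", 1L))
  }
  do.call(sim_config, vals)
}

#' Simulate an ultrametric Yule tree rescaled to unit height
#'
#' A pure-birth tree conditioned on the number of tips, rescaled so every
#' root-to-leaf path length is exactly 1 and relabelled `t001, t002, ...`.
#' Per-character rates are therefore interpretable as expected changes per
#' unit tree height.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param birth_rate speciation rate.
#' @param seed integer seed; the same seed always yields the same Newick
#'   string.
#' @return an ultrametric `phylo` tree of height 1.
#' @export
simulate_yule_tree <- function(n_taxa, birth_rate = 1, seed) {
  stopifnot(n_taxa >= 2L)
  tree <- withr::with_seed(seed,
    ape::rphylo(n_taxa, birth = birth_rate, death = 0))
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  tree$tip.label <- sprintf("t%03d", seq_len(n_taxa))
  tree
}

#' Simulate one Mk character on a tree, recording realized changes
#'
#' The k-state symmetric Markov (Mk) model simulated as its jump chain: the
#' root state is uniform on the k states; along a branch of length `t`
#' change events arrive as a Poisson process with mean `rate * t`, and each
#' event moves the state uniformly to one of the other `k - 1` states. The
#' realized event count is returned, so the hidden changes that parsimony
#' cannot see (parallelisms, reversals on internal branches) are known
#' exactly: parsimony steps are always <= `true_change_count`.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param k number of states (>= 2).
#' @param rate change rate per unit branch length (>= 0).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (so a caller can seed once for many characters).
#' @return list: `states` (named integer vector of leaf states, 1-based),
#'   `true_change_count`, `root_state`, `k`, `rate`.
#' @export
simulate_mk_character <- function(tree, k, rate, seed = NULL) {
  stopifnot(k >= 2L, rate >= 0)
  run <- function() {
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    state <- integer(nnode)
    root <- ntip + 1L
    state[root] <- sample.int(k, 1L)
    n_changes <- 0L
    pr <- ape::reorder.phylo(tree, "postorder")
    edges <- pr$edge[rev(seq_len(nrow(pr$edge))), , drop = FALSE]  # preorder
    lens <- pr$edge.length[rev(seq_len(nrow(pr$edge)))]
    for (e in seq_len(nrow(edges))) {
      s <- state[edges[e, 1L]]
      n_ev <- rpois(1L, rate * lens[e])
      if (n_ev > 0L) {
        for (i in seq_len(n_ev)) {
          j <- sample.int(k - 1L, 1L)  # uniform over the other k-1 states
          s <- j + (j >= s)
        }
        n_changes <- n_changes + n_ev
      }
      state[edges[e, 2L]] <- s
    }
    list(states = setNames(state[seq_len(ntip)], tree$tip.label),
         true_change_count = n_changes, root_state = state[root],
         k = as.integer(k), rate = rate)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a full character matrix with known per-character rates
#'
#' One character per entry of `config$state_counts`. All per-character rates
#' are drawn first (log-uniform on `[rate_low, rate_high]`), then each
#' character is evolved with [simulate_mk_character] and missing cells are
#' placed by independent Bernoulli draws. Class tags cycle round-robin over
#' color, morphometric, sculpture. Fully deterministic given `config$seed`.
#'
#' @param tree an ultrametric `phylo` tree (e.g. from [simulate_yule_tree]).
#' @param config a [sim_config].
#' @return list: `matrix` (a [char_matrix]) and `records` (data frame
#'   `char_id`, `class`, `k`, `true_rate`, `true_change_count`,
#'   `root_state`).
#' @export
simulate_matrix <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  ks <- config$state_counts
  nchar_ <- length(ks)
  taxa <- tree$tip.label
  classes <- rep(c("color", "morphometric", "sculpture"),
                 length.out = nchar_)
  withr::with_seed(config$seed, {
    rates <- exp(runif(nchar_, log(config$rate_low), log(config$rate_high)))
    sims <- lapply(seq_len(nchar_), function(i)
      simulate_mk_character(tree, ks[i], rates[i]))
    miss <- matrix(rbinom(length(taxa) * nchar_, 1L,
                          config$missing_fraction) == 1L,
                   length(taxa), nchar_)
  })
  characters <- lapply(seq_len(nchar_), function(i)
    character_def(i, state_labels = as.character(seq_len(ks[i]) - 1L),
                  class_tag = classes[i]))
  cells <- matrix(vector("list", length(taxa) * nchar_),
                  length(taxa), nchar_)
  for (j in seq_len(nchar_)) {
    st <- sims[[j]]$states[taxa]
    for (i in seq_along(taxa))
      if (!miss[i, j]) cells[[i, j]] <- st[[i]]
  }
  records <- data.frame(
    char_id = seq_len(nchar_), class = classes, k = ks, true_rate = rates,
    true_change_count = vapply(sims, `[[`, 1L, "true_change_count"),
    root_state = vapply(sims, `[[`, 1L, "root_state"))
  list(matrix = char_matrix(taxa, characters, cells), records = records)
}

#' Simulate an alignment with per-class site rates
#'
#' Sites are independent 4-state Mk (Jukes-Cantor-like) characters grouped
#' into named classes, each class with its own rate; useful for comparing
#' per-class parsimony step averages between molecular and morphological
#' characters.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param n_sites_per_class named integer vector: sites per class.
#' @param class_rates named numeric vector (same names): rate per class,
#'   changes per unit branch length.
#' @param seed integer seed.
#' @return a `dna_alignment` whose `partition` maps each class to its
#'   (contiguous) column block.
#' @export
simulate_alignment <- function(tree, n_sites_per_class, class_rates, seed) {
  stopifnot(length(n_sites_per_class) == length(class_rates),
            setequal(names(n_sites_per_class), names(class_rates)),
            all(class_rates >= 0))
  nms <- names(n_sites_per_class)
  total <- sum(n_sites_per_class)
  taxa <- tree$tip.label
  seqs <- matrix("N", length(taxa), total, dimnames = list(taxa, NULL))
  partition <- list()
  bases <- c("A", "C", "G", "T")
  col0 <- 0L
  withr::with_seed(seed, {
    for (nm in nms) {
      nsites <- n_sites_per_class[[nm]]
      rate <- class_rates[[nm]]
      for (s in seq_len(nsites)) {
        sim <- simulate_mk_character(tree, 4L, rate)
        seqs[, col0 + s] <- bases[sim$states[taxa]]
      }
      partition[[nm]] <- seq.int(col0 + 1L, col0 + nsites)
      col0 <- col0 + nsites
    }
  })
  new_dna_alignment(seqs, partition)
}
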