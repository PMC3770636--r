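#' Read an aligned FASTA and optional partition file
#'
#' Sequences must be equal length over the alphabet `A C G T - N`
#' (case-insensitive). The partition file uses RAxML-style lines
#' `DNA, name = start-end` or `DNA, name = start-end\3` (1-based inclusive
#' coordinates, optional stride 3 for codon positions). Internally columns
#' are addressed with R's 1-based indices, so `mt3 = 3-9\3` resolves to
#' columns 3, 6, 9.
#'
#' @param fasta_path aligned FASTA file.
#' @param partition_path optional partition file.
#' @return an object of class `dna_alignment`: list with `seqs` (character
#'   matrix, taxa x sites, upper case) and `partition` (named list of column
#'   index vectors, or `NULL`).
#' @export
read_alignment <- function(fasta_path, partition_path = NULL) {
  dna <- ape::read.FASTA(fasta_path)
  if (!length(dna)) stop("no sequences in ", fasta_path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop("length mismatch among sequences: ",
         paste(unique(lens), collapse = " vs "))
  seqs <- toupper(do.call(rbind, lapply(as.character(dna), as.vector)))
  rownames(seqs) <- names(dna)
  bad <- setdiff(unique(as.vector(seqs)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad))
    stop("unexpected alignment symbol(s): ", paste(bad, collapse = ", "))
  partition <- if (!is.null(partition_path))
    read_partition(partition_path, ncol(seqs)) else NULL
  new_dna_alignment(seqs, partition)
}

new_dna_alignment <- function(seqs, partition = NULL) {
  structure(list(seqs = seqs, partition = partition), class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("dna_alignment: ", nrow(x$seqs), " sequences x ", ncol(x$seqs),
      " sites", sep = "")
  if (!is.null(x$partition))
    cat("; partition classes: ", paste(names(x$partition), collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Read a RAxML-style partition file
#' @param path partition file; one `DNA, name = range[, range...]` line per
#'   class, ranges `start-end` or `start-end\3`, 1-based inclusive.
#' @param n_sites number of alignment columns (for bounds checking).
#' @return named list of integer column vectors (1-based).
#' @export
read_partition <- function(path, n_sites) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*\\S+\\s*,\\s*(\\S+)\\s*=\\s*(.+)$", ln))[[1L]]
    if (length(m) < 3L) stop("unparseable partition line: ", ln)
    name <- m[2L]
    cols <- integer(0)
    for (rng in trimws(strsplit(m[3L], ",", fixed = TRUE)[[1L]])) {
      rm_ <- regmatches(rng, regexec("^(\\d+)\\s*-\\s*(\\d+)(\\\\(\\d+))?$", rng))[[1L]]
      if (length(rm_) < 3L) stop("unparseable partition range: ", rng)
      from <- as.integer(rm_[2L]); to <- as.integer(rm_[3L])
      by <- if (nzchar(rm_[4L])) as.integer(rm_[5L]) else 1L
      if (from < 1L || to > n_sites || from > to)
        stop("partition range out of bounds: ", rng)
      cols <- c(cols, seq.int(from, to, by = by))
    }
    out[[name]] <- cols
  }
  all_cols <- unlist(out)
  if (anyDuplicated(all_cols)) {
    dup <- sort(unique(all_cols[duplicated(all_cols)]))
    stop("overlapping partitions at column(s): ",
         paste(head(dup, 5L), collapse = ", "))
  }
  out
}

#' Write an alignment as FASTA
#' @param x a `dna_alignment`
#' @param path output file; partition (if any) is written alongside when
#'   `partition_path` is given.
#' @param partition_path optional path for a RAxML-style partition file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path, partition_path = NULL) {
  stopifnot(inherits(x, "dna_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x$seqs))) {
    writeLines(paste0(">", rownames(x$seqs)[i]), con)
    writeLines(paste(x$seqs[i, ], collapse = ""), con)
  }
  if (!is.null(partition_path) && !is.null(x$partition)) {
    lines <- vapply(names(x$partition), function(nm) {
      cols <- x$partition[[nm]]
      d <- unique(diff(cols))
      rng <- if (length(cols) == 1L) paste0(cols, "-", cols)
      else if (length(d) == 1L && d == 1L) paste0(min(cols), "-", max(cols))
      else if (length(d) == 1L) paste0(min(cols), "-", max(cols), "\\", d)
      else paste(paste0(cols, "-", cols), collapse = ",")
      paste0("DNA, ", nm, " = ", rng)
    }, "")
    writeLines(lines, partition_path)
  }
  invisible(path)
}
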