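#' Define a discrete character
#'
#' A character has an integer id, a name, an optional class tag (used for
#' per-class step averages: typically `"color"`, `"morphometric"`,
#' `"sculpture"`, or `"molecular"`), and an ordered vector of state labels.
#' State indices used elsewhere in the package are 1-based positions into
#' `state_labels`.
#'
#' @param id integer index of the character (1-based).
#' @param state_labels character vector of unique state labels, length >= 2
#'   for any character entering ranking or correlation.
#' @param name character name; defaults to `"char<id>"`.
#' @param class_tag optional class label or `NA`.
#' @return a list of class `character_def`.
#' @export
character_def <- function(id, state_labels, name = paste0("char", id),
                          class_tag = NA_character_) {
  id <- as.integer(id)
  state_labels <- as.character(state_labels)
  stopifnot(length(id) == 1L, !is.na(id), length(state_labels) >= 1L)
  if (anyDuplicated(state_labels))
    stop("duplicate state labels in character ", id)
  structure(list(id = id, name = as.character(name),
                 class_tag = as.character(class_tag),
                 state_labels = state_labels),
            class = "character_def")
}

#' Taxon-by-character matrix of discrete states
#'
#' Cells are sets of state indices: a length-1 integer vector for a plain
#' observation, a longer vector for a polymorphic cell, and `NULL` for a
#' MISSING (unscored) cell. The matrix is rectangular: every taxon has a cell
#' for every character.
#'
#' @param taxa character vector of unique taxon labels.
#' @param characters list of [character_def] objects.
#' @param cells a `length(taxa) x length(characters)` list-matrix; each
#'   element an integer vector of 1-based state indices, or `NULL`.
#' @return an object of class `char_matrix`.
#' @export
char_matrix <- function(taxa, characters, cells) {
  taxa <- as.character(taxa)
  if (!length(taxa)) stop("no taxa")
  if (anyDuplicated(taxa)) stop("duplicate taxa: ",
                                paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  stopifnot(is.list(characters), all(vapply(characters, inherits, TRUE, "character_def")))
  if (!is.matrix(cells) || !is.list(cells) ||
      nrow(cells) != length(taxa) || ncol(cells) != length(characters))
    stop("cells must be a taxa x characters list-matrix")
  for (j in seq_along(characters)) {
    k <- length(characters[[j]]$state_labels)
    for (i in seq_along(taxa)) {
      cell <- cells[[i, j]]
      if (is.null(cell)) next
      cell <- as.integer(cell)
      if (!length(cell) || anyNA(cell) || any(cell < 1L) || any(cell > k))
        stop("invalid state index for taxon '", taxa[i], "', character ",
             characters[[j]]$id)
      cells[[i, j]] <- sort(unique(cell))
    }
  }
  dimnames(cells) <- list(taxa, vapply(characters, `[[`, "", "name"))
  structure(list(taxa = taxa, characters = characters, cells = cells),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("char_matrix: ", length(x$taxa), " taxa x ", length(x$characters),
      " characters; completeness ",
      sprintf("%.3f", completeness(x)), "\n", sep = "")
  invisible(x)
}

#' Number of taxa / characters in a matrix
#' @param x a `char_matrix`
#' @export
n_taxa <- function(x) length(x$taxa)

#' @rdname n_taxa
#' @export
n_characters <- function(x) length(x$characters)

#' Fraction of scored (non-missing) cells
#' @param x a `char_matrix`
#' @return numeric in `[0, 1]`.
#' @export
completeness <- function(x) {
  stopifnot(inherits(x, "char_matrix"))
  1 - mean(vapply(x$cells, is.null, TRUE))
}

#' Extract one character's column as a named list of state sets
#' @param x a `char_matrix`
#' @param char_id character id (matching the `id` field of its definition).
#' @return named list over taxa; integer state-index vectors, `NULL` = missing.
#' @export
matrix_column <- function(x, char_id) {
  j <- char_index(x, char_id)
  setNames(x$cells[, j], x$taxa)
}

# Internal: map a character id to its column position.
char_index <- function(x, char_id) {
  ids <- vapply(x$characters, `[[`, 1L, "id")
  j <- match(as.integer(char_id), ids)
  if (is.na(j)) stop("unknown character id: ", char_id)
  j
}

# Internal: taxa x k logical membership matrix for one character
# (missing rows are all-FALSE; consumers handle missing separately).
state_membership <- function(x, char_id) {
  j <- char_index(x, char_id)
  k <- length(x$characters[[j]]$state_labels)
  m <- matrix(FALSE, length(x$taxa), k, dimnames = list(x$taxa, NULL))
  for (i in seq_along(x$taxa)) {
    cell <- x$cells[[i, j]]
    if (!is.null(cell)) m[i, cell] <- TRUE
  }
  m
}

# ---- delimited-text dialect ------------------------------------------------
# taxa as rows, characters as columns; cell = state label, "a/b" polymorphism,
# "?" missing.

#' Read a character matrix from CSV/TSV or simple NEXUS
#'
#' The delimited dialect has taxa as rows and characters as columns, with a
#' header row of character names and the taxon label in the first field. A
#' cell is a single state label, `a/b` for a polymorphic observation, or `?`
#' for missing. The NEXUS dialect is a plain `CHARACTERS` (or `DATA`) block
#' with single-character `SYMBOLS`, `?` for missing and `{ab}` polymorphism.
#'
#' @param path file to read.
#' @param format `"csv"`, `"tsv"`, or `"nexus"`; default guessed from the
#'   file extension (`.nex`/`.nexus` -> nexus, `.tsv`/`.txt` -> tsv).
#' @param characters optional list of [character_def]; when `NULL`, state
#'   labels are inferred per character as the sorted set of labels seen.
#' @return a [char_matrix].
#' @export
read_char_matrix <- function(path, format = NULL, characters = NULL) {
  if (is.null(format)) {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, nex = , nxs = , nexus = "nexus",
                     tsv = , txt = "tsv", "csv")
  }
  format <- match.arg(format, c("csv", "tsv", "nexus"))
  if (format == "nexus") return(read_nexus_matrix(path))
  sep <- if (format == "csv") "," else "\t"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("no taxa in ", path)
  rows <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(rows[[1L]])
  nc <- length(header) - 1L
  if (nc < 1L) stop("no characters in ", path)
  body <- rows[-1L]
  widths <- lengths(body)
  if (any(widths != nc + 1L))
    stop("ragged row(s): ", paste(trimws(vapply(body[widths != nc + 1L],
                                                `[`, "", 1L)), collapse = ", "))
  taxa <- trimws(vapply(body, `[`, "", 1L))
  if (anyDuplicated(taxa))
    stop("duplicate taxa: ", paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  raw <- matrix("", length(taxa), nc)
  for (i in seq_along(body)) raw[i, ] <- trimws(body[[i]][-1L])

  if (is.null(characters)) {
    characters <- lapply(seq_len(nc), function(j) {
      seen <- setdiff(unlist(strsplit(raw[, j], "/", fixed = TRUE)), "?")
      character_def(j, state_labels = sort(seen), name = header[j + 1L])
    })
  } else if (length(characters) != nc) {
    stop("matrix has ", nc, " characters but ", length(characters),
         " definitions were supplied")
  }

  cells <- matrix(vector("list", length(taxa) * nc), length(taxa), nc)
  for (j in seq_len(nc)) {
    labels <- characters[[j]]$state_labels
    for (i in seq_along(taxa)) {
      tok <- raw[i, j]
      if (tok == "?") next
      idx <- match(strsplit(tok, "/", fixed = TRUE)[[1L]], labels)
      if (anyNA(idx))
        stop("unknown state label '", tok, "' for taxon '", taxa[i],
             "', character '", characters[[j]]$name, "'")
      cells[[i, j]] <- sort(unique(as.integer(idx)))
    }
  }
  char_matrix(taxa, characters, cells)
}

#' Write a character matrix in the delimited dialect
#' @param x a `char_matrix`
#' @param path output file.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_char_matrix <- function(x, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  header <- c("taxon", vapply(x$characters, `[[`, "", "name"))
  lines <- paste(header, collapse = sep)
  for (i in seq_along(x$taxa)) {
    toks <- vapply(seq_along(x$characters), function(j) {
      cell <- x$cells[[i, j]]
      if (is.null(cell)) return("?")
      paste(x$characters[[j]]$state_labels[cell], collapse = "/")
    }, "")
    lines <- c(lines, paste(c(x$taxa[i], toks), collapse = sep))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- simple NEXUS CHARACTERS reader ---------------------------------------

read_nexus_matrix <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)  # strip comments
  sym <- regmatches(txt, regexpr('SYMBOLS\\s*=\\s*"[^"]*"', txt, ignore.case = TRUE))
  symbols <- if (length(sym)) {
    strsplit(gsub('.*"([^"]*)".*', "\\1", sym), "")[[1L]]
  } else as.character(0:9)
  symbols <- symbols[nzchar(trimws(symbols))]
  mat <- regmatches(txt, regexpr("MATRIX(.|\n)*?;", txt, ignore.case = TRUE))
  if (!length(mat)) stop("no MATRIX block in ", path)
  body <- sub(";$", "", sub("^MATRIX", "", mat, ignore.case = TRUE))
  rows <- trimws(strsplit(body, "\n")[[1L]])
  rows <- rows[nzchar(rows)]
  if (!length(rows)) stop("no taxa in ", path)
  taxa <- character(0); raws <- character(0)
  for (r in rows) {
    m <- regmatches(r, regexec("^('([^']+)'|\\S+)\\s+(\\S+)$", r))[[1L]]
    if (length(m) < 4L) stop("unparseable matrix row: ", r)
    taxa <- c(taxa, if (nzchar(m[3L])) m[3L] else m[2L])
    raws <- c(raws, m[4L])
  }
  if (anyDuplicated(taxa))
    stop("duplicate taxa: ", paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  # tokenize each row into single symbols or {..} groups
  cellify <- function(s, taxon) {
    toks <- regmatches(s, gregexpr("\\{[^}]*\\}|.", s))[[1L]]
    lapply(toks, function(tok) {
      if (tok == "?") return(NULL)
      chars <- strsplit(gsub("[{}]", "", tok), "")[[1L]]
      idx <- match(chars, symbols)
      if (anyNA(idx))
        stop("unknown state label '", tok, "' for taxon '", taxon, "'")
      sort(unique(as.integer(idx)))
    })
  }
  parsed <- mapply(cellify, raws, taxa, SIMPLIFY = FALSE)
  nc <- unique(lengths(parsed))
  if (length(nc) != 1L) stop("ragged row(s) in NEXUS matrix")
  characters <- lapply(seq_len(nc), function(j) {
    ks <- max(c(1L, unlist(lapply(parsed, function(p) p[[j]]))))
    character_def(j, state_labels = symbols[seq_len(ks)])
  })
  cells <- matrix(vector("list", length(taxa) * nc), length(taxa), nc)
  for (i in seq_along(taxa)) for (j in seq_len(nc))
    cells[i, j] <- list(parsed[[i]][[j]])
  char_matrix(taxa, characters, cells)
}
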