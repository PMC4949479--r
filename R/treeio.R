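#' Read a Newick tree
#'
#' Parses a Newick string (or the first tree of a file), resolves the leaf
#' labels through an optional registry, and records whether the topology is
#' to be treated as rooted. Branch lengths and support values are accepted
#' but discarded: the supertree method is purely topological.
#'
#' @param text a Newick string, or `NULL` when `file` is given.
#' @param rooted_hint logical; is the source tree rooted? Stored as the
#'   `rooted` attribute of the result.
#' @param registry optional [taxon_registry()] used to canonicalize leaf
#'   labels; unresolvable labels raise an error naming them.
#' @param file optional path to a Newick file.
#' @return An `ape` `phylo` object with attribute `rooted`.
#' @examples
#' tr <- read_newick("((A,B),C);")
#' attr(tr, "rooted")
#' @export
read_newick <- function(text = NULL, rooted_hint = TRUE, registry = NULL,
                        file = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse failure: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse failure: no tree in input")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  if (any(!nzchar(tr$tip.label))) stop("Newick parse failure: empty leaf label")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr$tip.label <- resolve_taxa(tr$tip.label, registry)
  tr$edge.length <- NULL
  tr$node.label <- NULL
  attr(tr, "rooted") <- isTRUE(rooted_hint)
  tr
}

## Cheap structural validation that reports a character offset, which
## ape::read.tree does not.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick parse failure: unbalanced ')' at offset %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("Newick parse failure: %d unclosed '(' at offset %d",
                 depth, length(chars)))
  if (!grepl(";", text, fixed = TRUE))
    stop(sprintf("Newick parse failure: missing ';' at offset %d",
                 nchar(text)))
  invisible(TRUE)
}

#' Write a tree as Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read an admixture Q-matrix
#'
#' Reads a population-by-cluster membership table as printed alongside
#' STRUCTURE/FRAPPE/ADMIXTURE bar plots: first column taxon labels, remaining
#' K numeric columns of ancestry proportions. Rows must sum to 1 within
#' `tol`; offending rows are rejected, not silently renormalized.
#'
#' @param path file path, or `NULL` when `text` is given.
#' @param text optional literal table text.
#' @param registry optional [taxon_registry()].
#' @param tol row-sum tolerance (default `1e-6`).
#' @return An object of class `qmatrix`: list with `taxa`, `K` and the
#'   numeric `memberships` matrix (rows = taxa).
#' @export
read_qmatrix <- function(path = NULL, text = NULL, registry = NULL,
                         tol = 1e-6) {
  if (is.null(text)) {
    stopifnot(!is.null(path))
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("Q-matrix validation error: no data rows")
  sep <- detect_delimiter(lines)
  fields <- lapply(lines, function(l) strsplit(l, sep, fixed = TRUE)[[1]])
  ncols <- unique(vapply(fields, length, 1L))
  if (length(ncols) != 1)
    stop("Q-matrix validation error: ragged rows")
  header <- suppressWarnings(any(is.na(as.numeric(fields[[1]][-1]))))
  if (header) fields <- fields[-1]
  if (length(fields) == 0) stop("Q-matrix validation error: no data rows")
  taxa <- vapply(fields, `[[`, "", 1L)
  mem <- t(vapply(fields, function(f) as.numeric(f[-1]),
                  numeric(ncols - 1L)))
  qmatrix(taxa = resolve_taxa(taxa, registry), memberships = mem, tol = tol)
}

detect_delimiter <- function(lines) {
  n_tab <- length(strsplit(lines[[1]], "\t", fixed = TRUE)[[1]])
  n_com <- length(strsplit(lines[[1]], ",", fixed = TRUE)[[1]])
  if (n_tab > 1 && n_com > 1)
    stop("ambiguous delimiter: both tabs and commas present")
  if (n_tab > 1) return("\t")
  if (n_com > 1) return(",")
  stop("cannot detect delimiter (expected tab- or comma-separated columns)")
}

#' Construct a Q-matrix object
#'
#' @param taxa character vector of canonical taxon ids.
#' @param memberships numeric matrix, one row per taxon, K >= 2 columns of
#'   cluster membership proportions in `[0, 1]`.
#' @param tol row-sum tolerance.
#' @return An object of class `qmatrix`.
#' @export
qmatrix <- function(taxa, memberships, tol = 1e-6) {
  memberships <- as.matrix(memberships)
  if (nrow(memberships) != length(taxa))
    stop("memberships must have one row per taxon")
  if (ncol(memberships) < 2) stop("a Q-matrix needs K >= 2 clusters")
  if (anyDuplicated(taxa)) stop("duplicate taxa in Q-matrix")
  if (any(is.na(memberships)))
    stop("Q-matrix validation error: missing proportions")
  neg <- which(memberships < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("Q-matrix validation error: negative proportion for taxon '%s'",
                 taxa[neg[1, 1]]))
  rs <- rowSums(memberships)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad) > 0)
    stop(sprintf("Q-matrix validation error: row sum %s for taxon '%s'",
                 format(rs[bad[1]], digits = 7), taxa[bad[1]]))
  rownames(memberships) <- taxa
  colnames(memberships) <- paste0("cluster", seq_len(ncol(memberships)))
  structure(list(taxa = as.character(taxa), K = ncol(memberships),
                 memberships = memberships),
            class = "qmatrix")
}

#' @export
print.qmatrix <- function(x, ...) {
  cat(sprintf("Q-matrix: %d taxa x %d clusters\n", length(x$taxa), x$K))
  invisible(x)
}

#' Write a Q-matrix as TSV
#' @param q a [qmatrix()].
#' @param file output path.
#' @export
write_qmatrix <- function(q, file) {
  df <- data.frame(taxon = q$taxa, q$memberships, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Serialize a binary character matrix
#'
#' Writes the matrix in either NEXUS (readable back by
#' [read_nexus_matrix()]) or TNT dialect. States are emitted as `0/1/?/-`;
#' nonunit character weights go into the dialect's weight statement
#' (`WTSET` for NEXUS, `ccode` for TNT). Columns are emitted in canonical
#' provenance order so output is deterministic.
#'
#' @param m a [binary_matrix()].
#' @param dialect `"nexus"` or `"tnt"`.
#' @param file optional output path; otherwise the text is returned.
#' @return The serialized text (invisibly when written to `file`).
#' @export
write_matrix <- function(m, dialect = c("nexus", "tnt"), file = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(m, "binary_matrix"))
  if (ncol(m$states) == 0) stop("cannot serialize an empty matrix")
  bad <- grepl("[][;,()'\"[:space:]]", m$taxa)
  if (any(bad))
    stop("taxon label(s) illegal in ", dialect, " dialect: ",
         paste(m$taxa[bad], collapse = ", "))
  m <- sort_columns(m)
  rows <- apply(m$states, 1, paste, collapse = "")
  nt <- length(m$taxa)
  nc <- ncol(m$states)
  pad <- formatC(m$taxa, width = max(nchar(m$taxa)) + 2, flag = "-")
  if (dialect == "nexus") {
    wlines <- character(0)
    if (any(m$weights != 1)) {
      grp <- split(seq_len(nc), m$weights)
      parts <- vapply(names(grp), function(w)
        paste0(format(as.numeric(w)), ": ", paste(grp[[w]], collapse = " ")),
        "")
      wlines <- c("BEGIN ASSUMPTIONS;",
                  paste0("  WTSET * mrpweights = ",
                         paste(parts, collapse = ", "), ";"),
                  "END;")
    }
    txt <- c("#NEXUS",
             "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nt, nc),
             "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
             "  MATRIX",
             paste0("    ", pad, rows),
             "  ;",
             "END;",
             wlines)
  } else {
    wlines <- character(0)
    if (any(m$weights != 1)) {
      grp <- split(seq_len(nc), m$weights)
      wlines <- vapply(names(grp), function(w)
        sprintf("ccode /%s %s;", format(as.numeric(w)),
                paste(grp[[w]] - 1L, collapse = " ")), "")
    }
    txt <- c("xread", sprintf("'%s'", "mrp matrix"),
             sprintf("%d %d", nc, nt),
             paste0(pad, rows), ";", wlines, "proc /;")
  }
  txt <- paste(txt, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a NEXUS binary matrix written by [write_matrix()]
#'
#' @param path file path, or `NULL` when `text` is given.
#' @param text optional literal NEXUS text.
#' @return A [binary_matrix()] (provenance is not round-tripped; weights and
#'   states are).
#' @export
read_nexus_matrix <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE),
                                   collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  i0 <- grep("^\\s*MATRIX\\s*$", lines)
  if (length(i0) != 1) stop("no MATRIX block found")
  rows <- character(0)
  taxa <- character(0)
  for (l in lines[(i0 + 1):length(lines)]) {
    l <- trimws(l)
    if (l == ";") break
    f <- strsplit(l, "\\s+")[[1]]
    taxa <- c(taxa, f[1])
    rows <- c(rows, f[2])
  }
  states <- do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]]))
  rownames(states) <- taxa
  nc <- ncol(states)
  weights <- rep(1, nc)
  iw <- grep("WTSET", lines)
  if (length(iw) == 1) {
    spec <- sub(".*=", "", lines[iw])
    spec <- sub(";\\s*$", "", spec)
    for (part in strsplit(spec, ",", fixed = TRUE)[[1]]) {
      kv <- strsplit(trimws(part), ":", fixed = TRUE)[[1]]
      w <- as.numeric(kv[1])
      cols <- as.integer(strsplit(trimws(kv[2]), "\\s+")[[1]])
      weights[cols] <- w
    }
  }
  binary_matrix(states, weights = weights)
}
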