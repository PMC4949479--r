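#' Taxon registry: canonical ids, display names and aliases
#'
#' Published population trees name the same people inconsistently (spelling
#' variants, diacritics, ethnonyms). A registry maps every alias to a single
#' canonical id so that sources can be combined. Resolution is
#' case-insensitive and diacritic-insensitive after normalization.
#'
#' @param canonical_id character vector of unique short ids.
#' @param display_name character vector of display names (defaults to the
#'   canonical ids).
#' @param aliases list of character vectors of aliases, one element per
#'   canonical id.
#' @return An object of class `taxon_registry`.
#' @examples
#' reg <- taxon_registry(c("san", "mbuti"),
#'                       aliases = list(c("San", "Bushmen"), "Mbuti Pygmy"))
#' resolve_taxa(c("bushmen", "MBUTI PYGMY"), reg)
#' @export
taxon_registry <- function(canonical_id, display_name = canonical_id,
                           aliases = vector("list", length(canonical_id))) {
  canonical_id <- as.character(canonical_id)
  if (anyDuplicated(canonical_id))
    stop("canonical ids must be unique")
  if (length(display_name) != length(canonical_id) ||
      length(aliases) != length(canonical_id))
    stop("display_name and aliases must match canonical_id in length")
  lut <- new.env(parent = emptyenv())
  add <- function(key, id) {
    k <- normalize_label(key)
    if (!nzchar(k)) return(invisible())
    prev <- lut[[k]]
    if (!is.null(prev) && prev != id)
      stop(sprintf("alias '%s' maps to both '%s' and '%s'", key, prev, id))
    assign(k, id, envir = lut)
  }
  for (i in seq_along(canonical_id)) {
    add(canonical_id[i], canonical_id[i])
    add(display_name[i], canonical_id[i])
    for (a in aliases[[i]]) add(a, canonical_id[i])
  }
  structure(list(canonical_id = canonical_id, display_name = display_name,
                 aliases = aliases, lut = lut),
            class = "taxon_registry")
}

## Lowercase, strip diacritics, collapse everything non-alphanumeric.
normalize_label <- function(x) {
  x <- tolower(as.character(x))
  y <- suppressWarnings(iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT"))
  y[is.na(y)] <- x[is.na(y)]
  gsub("[^a-z0-9]", "", y)
}

#' Resolve taxon labels to canonical ids
#'
#' @param x character vector of labels to resolve.
#' @param registry a [taxon_registry()], or `NULL` to pass labels through
#'   unchanged.
#' @return Character vector of canonical ids.
#' @export
resolve_taxa <- function(x, registry = NULL) {
  if (is.null(registry)) return(as.character(x))
  stopifnot(inherits(registry, "taxon_registry"))
  keys <- normalize_label(x)
  out <- character(length(x))
  for (i in seq_along(keys)) {
    hit <- registry$lut[[keys[i]]]
    if (is.null(hit)) {
      bad <- x[vapply(normalize_label(x), function(k)
        is.null(registry$lut[[k]]), TRUE)]
      stop(sprintf("cannot resolve taxon label(s): %s",
                   paste(unique(bad), collapse = ", ")))
    }
    out[i] <- hit
  }
  out
}

#' @export
print.taxon_registry <- function(x, ...) {
  cat(sprintf("Taxon registry: %d canonical ids, %d aliases\n",
              length(x$canonical_id),
              length(ls(envir = x$lut)) - length(x$canonical_id)))
  invisible(x)
}

#' Read an alias table into a taxon registry
#'
#' Expects a delimited text file with columns `canonical_id`, `display_name`
#' and `aliases` (aliases separated by `|`).
#'
#' @param path file path.
#' @return A [taxon_registry()].
#' @export
read_alias_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  need <- c("canonical_id", "display_name", "aliases")
  if (!all(need %in% names(df)))
    stop("alias table needs columns: ", paste(need, collapse = ", "))
  al <- lapply(df$aliases, function(a) {
    if (is.na(a) || !nzchar(a)) character(0)
    else strsplit(a, "|", fixed = TRUE)[[1]]
  })
  taxon_registry(df$canonical_id, df$display_name, al)
}
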