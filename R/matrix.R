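#' Binary character matrix (additive binary / Baum-Ragan coding)
#'
#' The central container of the package: taxa by characters over states
#' `0/1/?/-` with per-character weights and provenance. `1` means descended
#' from the coded node (or assigned to the coded cluster), `0` means present
#' in the source but not descended, `-` means the taxon was absent from the
#' source (inapplicable), and `?` means unknown/ambiguous. `?` and `-` are
#' distinguished in storage but identical in parsimony optimization.
#'
#' @param states character matrix with entries `"0" "1" "?" "-"`; row names
#'   are taxon ids.
#' @param weights numeric vector of nonnegative character weights, recycled;
#'   weight 0 deactivates a character (ignored by scoring).
#' @param provenance optional data frame with one row per character and
#'   columns `source_id`, `partition`, `node_id`.
#' @return An object of class `binary_matrix` with elements `taxa`, `states`,
#'   `weights`, `provenance`.
#' @examples
#' s <- rbind(A = c("1", "1"), B = c("1", "0"), C = c("0", "0"), D = c("0", "?"))
#' m <- binary_matrix(s)
#' is_informative(m)
#' @export
binary_matrix <- function(states, weights = 1, provenance = NULL) {
  states <- as.matrix(states)
  if (is.null(rownames(states))) stop("states needs taxon row names")
  if (!all(states %in% c("0", "1", "?", "-")))
    stop("states must be one of '0', '1', '?', '-'")
  nc <- ncol(states)
  weights <- rep_len(as.numeric(weights), nc)
  if (any(weights < 0) || any(is.na(weights)))
    stop("weights must be nonnegative numbers")
  if (nc > 0) {
    allmiss <- colSums(states == "0" | states == "1") == 0
    if (any(allmiss))
      stop("character(s) with no non-missing state: ",
           paste(which(allmiss), collapse = ", "))
  }
  if (is.null(provenance)) {
    provenance <- data.frame(source_id = rep("unknown", nc),
                             partition = rep("genomic_tree", nc),
                             node_id = if (nc) paste0("c", seq_len(nc)) else character(0),
                             stringsAsFactors = FALSE)
  }
  provenance <- as.data.frame(provenance, stringsAsFactors = FALSE)
  if (nrow(provenance) != nc)
    stop("provenance must have one row per character")
  need <- c("source_id", "partition", "node_id")
  if (!all(need %in% names(provenance)))
    stop("provenance needs columns: ", paste(need, collapse = ", "))
  if (!all(provenance$partition %in% ALL_PARTITIONS))
    stop("unknown partition label(s): ",
         paste(setdiff(provenance$partition, ALL_PARTITIONS), collapse = ", "))
  if (is.null(colnames(states)) && nc > 0)
    colnames(states) <- paste0(provenance$source_id, ".", provenance$node_id)
  structure(list(taxa = rownames(states), states = states,
                 weights = weights, provenance = provenance[need]),
            class = "binary_matrix")
}

#' @export
print.binary_matrix <- function(x, ...) {
  nc <- ncol(x$states)
  cat(sprintf("Binary character matrix: %d taxa x %d characters\n",
              length(x$taxa), nc))
  if (nc > 0) {
    cat(sprintf("  parsimony-informative: %d\n", sum(is_informative(x))))
    cat(sprintf("  weight classes: %s\n",
                paste(sort(unique(x$weights)), collapse = ", ")))
    cat(sprintf("  partitions: %s\n",
                paste(sort(unique(x$provenance$partition)), collapse = ", ")))
  }
  invisible(x)
}

#' Parsimony-informative flags
#'
#' A binary character is parsimony-informative iff at least two taxa are
#' scored 1 and at least two are scored 0 among non-missing states.
#'
#' @param m a [binary_matrix()].
#' @return Logical vector, one flag per character.
#' @export
is_informative <- function(m) {
  stopifnot(inherits(m, "binary_matrix"))
  if (ncol(m$states) == 0) return(logical(0))
  colSums(m$states == "1") >= 2 & colSums(m$states == "0") >= 2
}

#' Merge binary matrices over the union of their taxa
#'
#' Column-wise concatenation: taxa missing from a source matrix are coded
#' `-` (inapplicable) for that source's characters. States, weights and
#' provenance are preserved; up to column order the result does not depend
#' on the input order.
#'
#' @param matrices list of [binary_matrix()] objects.
#' @return A merged [binary_matrix()].
#' @export
merge_matrices <- function(matrices) {
  if (length(matrices) == 0) stop("empty input list")
  stopifnot(all(vapply(matrices, inherits, TRUE, "binary_matrix")))
  taxa <- unique(unlist(lapply(matrices, `[[`, "taxa")))
  blocks <- lapply(matrices, function(m) {
    out <- matrix("-", nrow = length(taxa), ncol = ncol(m$states),
                  dimnames = list(taxa, colnames(m$states)))
    out[m$taxa, ] <- m$states
    out
  })
  states <- do.call(cbind, blocks)
  binary_matrix(states,
                weights = unlist(lapply(matrices, `[[`, "weights")),
                provenance = do.call(rbind, lapply(matrices, `[[`, "provenance")))
}

#' Canonical column order (provenance-sorted)
#'
#' @param m a [binary_matrix()].
#' @return The matrix with columns ordered by `(source_id, node_id)`.
#' @export
sort_columns <- function(m) {
  stopifnot(inherits(m, "binary_matrix"))
  if (ncol(m$states) <= 1) return(m)
  ord <- order(m$provenance$source_id, m$provenance$node_id)
  binary_matrix(m$states[, ord, drop = FALSE], m$weights[ord],
                m$provenance[ord, , drop = FALSE])
}

## Integer state codes for the C++ engine: 1 = {0}, 2 = {1}, 3 = missing.
state_codes <- function(m, taxa = m$taxa) {
  s <- m$states[taxa, , drop = FALSE]
  codes <- matrix(3L, nrow = nrow(s), ncol = ncol(s))
  codes[s == "0"] <- 1L
  codes[s == "1"] <- 2L
  codes
}
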