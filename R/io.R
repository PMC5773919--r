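# Readers and writers for the on-disk formats: TSV edge lists, TSV
# association and annotation pair tables, and flat complex catalogs (one
# complex per line, tab-separated members).

# Reads a whitespace/tab-separated pair file, stripping '#' comments and
# blank lines; returns a 2-column character matrix plus original line
# numbers. Lines with a single field raise an error naming the line.
read_pairs <- function(path, what = "pair") {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  fields <- strsplit(trimws(lines[keep]), "[\t ]+")
  lineno <- which(keep)
  bad <- lengths(fields) < 2
  if (any(bad))
    stop("malformed ", what, " line ", lineno[which(bad)[1]], " in ", path,
         ": expected at least two fields")
  list(pairs = cbind(vapply(fields, `[`, "", 1),
                     vapply(fields, `[`, "", 2)),
       lineno = lineno)
}

#' Read an undirected network from a two-column edge list
#'
#' TSV (or whitespace-separated) file with one node pair per line; `#`
#' starts a comment. `(u, v)` and `(v, u)` collapse to one undirected edge,
#' duplicates are merged, and self-loops are dropped (their count is
#' reported); nodes keep first-appearance order.
#'
#' @param path file path.
#' @param layer `"protein"` or `"domain"`.
#' @return An [interaction_network].
#' @export
read_edgelist <- function(path, layer = c("protein", "domain")) {
  layer <- match.arg(layer)
  pr <- read_pairs(path, "edge")$pairs
  ids <- unique(as.vector(t(pr)))
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  self <- pr[, 1] == pr[, 2]
  if (any(self))
    message("dropped ", sum(self), " self-loop(s) in ", path)
  pr <- pr[!self, , drop = FALSE]
  A[pr] <- 1
  A[pr[, 2:1, drop = FALSE]] <- 1
  interaction_network(A, ids, layer)
}

#' Write a network as a two-column edge list
#'
#' @param net an [interaction_network].
#' @param path file path.
#' @export
write_edgelist <- function(net, path) {
  idx <- which(upper.tri(net$adjacency) & net$adjacency > 0, arr.ind = TRUE)
  writeLines(paste(net$node_ids[idx[, 1]], net$node_ids[idx[, 2]],
                   sep = "\t"), path)
  invisible(path)
}

#' Read a domain-protein association table
#'
#' TSV of `(domain_id, protein_id)` pairs. Pairs naming a node outside the
#' declared universes are dropped with a reported count; duplicate pairs
#' collapse to a single association. Proteins without any domain keep
#' all-zero columns.
#'
#' @param path file path.
#' @param proteins,domains character vectors declaring the two node
#'   universes (typically the `node_ids` of the two networks).
#' @return An [association_map].
#' @export
read_associations <- function(path, proteins, domains) {
  pr <- read_pairs(path, "association")$pairs
  if (nrow(pr) == 0) stop("association file ", path, " is empty")
  known <- pr[, 1] %in% domains & pr[, 2] %in% proteins
  if (any(!known))
    message("dropped ", sum(!known),
            " association(s) naming unknown nodes in ", path)
  pr <- pr[known, , drop = FALSE]
  Fm <- matrix(0, length(domains), length(proteins),
               dimnames = list(domains, proteins))
  Fm[pr] <- 1
  association_map(Fm, domains, proteins)
}

#' Write a domain-protein association table
#'
#' @param assoc an [association_map].
#' @param path file path.
#' @export
write_associations <- function(assoc, path) {
  idx <- which(assoc$matrix > 0, arr.ind = TRUE)
  writeLines(paste(assoc$domain_ids[idx[, 1]], assoc$protein_ids[idx[, 2]],
                   sep = "\t"), path)
  invisible(path)
}

#' Read a flat complex catalog
#'
#' One complex per line, members tab-separated (the flat format of the
#' classic yeast reference sets). Blank lines are skipped with a warning.
#'
#' @param path file path.
#' @return A [complex_catalog] with complexes named `C1`, `C2`, ... in file
#'   order.
#' @export
read_catalog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blank <- !grepl("\\S", lines)
  if (any(blank))
    warning("skipped ", sum(blank), " blank line(s) in ", path)
  complex_catalog(strsplit(trimws(lines[!blank]), "\t"))
}

#' Write a flat complex catalog
#'
#' @param catalog a [complex_catalog].
#' @param path file path.
#' @export
write_catalog <- function(catalog, path) {
  writeLines(vapply(catalog, paste, "", collapse = "\t"), path)
  invisible(path)
}

#' Read a term-protein annotation table
#'
#' TSV of `(term_id, protein_id)` pairs.
#'
#' @param path file path.
#' @return Named list: term id -> character vector of proteins.
#' @export
read_annotations <- function(path) {
  pr <- read_pairs(path, "annotation")$pairs
  if (nrow(pr) == 0) stop("annotation file ", path, " is empty")
  lapply(split(pr[, 2], pr[, 1]), unique)
}

#' Write a term-protein annotation table
#'
#' @param annotations named list: term id -> character vector of proteins.
#' @param path file path.
#' @export
write_annotations <- function(annotations, path) {
  writeLines(unlist(lapply(names(annotations), function(t)
    paste(t, annotations[[t]], sep = "\t"))), path)
  invisible(path)
}
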