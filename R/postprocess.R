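# Turning the continuous membership estimate into a discrete complex catalog.

#' Threshold a fitted membership matrix into complexes
#'
#' Protein `i` is assigned to complex `k` when `H[i, k] >= tau` (the
#' boundary value is included). Each column with at least one member becomes
#' one complex; a protein may pass the threshold in several columns, so
#' complexes can overlap.
#'
#' @param H_hat fitted nonnegative membership matrix, or a
#'   [membership_state], or an `mnc_fit`.
#' @param node_ids character labels for the rows of `H_hat`; taken from the
#'   matrix rownames when omitted.
#' @param tau membership threshold in (0, 1); default 0.3.
#' @return A [complex_catalog].
#' @examples
#' H <- rbind(c(0.35, 0.10), c(0.31, 0.29), c(0.05, 0.90))
#' threshold_memberships(H, c("n1", "n2", "n3"), tau = 0.3)
#' @export
threshold_memberships <- function(H_hat, node_ids = NULL, tau = 0.3) {
  if (inherits(H_hat, "mnc_fit")) H_hat <- H_hat$state
  if (inherits(H_hat, "membership_state")) H_hat <- H_hat$H
  H_hat <- as.matrix(H_hat)
  stopifnot(tau > 0, tau < 1)
  if (is.null(node_ids)) node_ids <- rownames(H_hat)
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(nrow(H_hat)))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != nrow(H_hat))
    stop("node_ids length must match the number of rows of H_hat")
  members <- lapply(seq_len(ncol(H_hat)),
                    function(k) node_ids[H_hat[, k] >= tau])
  members <- members[lengths(members) > 0]
  names(members) <- if (length(members))
    paste0("C", seq_along(members)) else NULL
  complex_catalog(members)
}

#' Filter small complexes and collapse exact duplicates
#'
#' Drops complexes with fewer than `min_size` members (reference complex
#' sets conventionally keep only complexes of three or more proteins), then
#' collapses exact duplicate member sets, keeping the first occurrence. The
#' relevance prior often leaves several columns that threshold to identical
#' sets, so deduplication is routinely needed.
#'
#' @param catalog a [complex_catalog].
#' @param min_size minimum number of members to keep (default 3).
#' @return A [complex_catalog], order preserved.
#' @export
filter_and_dedup <- function(catalog, min_size = 3) {
  stopifnot(min_size >= 1)
  kept <- catalog[lengths(catalog) >= min_size]
  keys <- vapply(kept, paste, "", collapse = "\r")
  structure(unclass(kept)[!duplicated(keys)], class = "complex_catalog")
}
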