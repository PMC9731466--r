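# A partition is an ordered collection of ordered, disjoint clusters of
# sequence identifiers, optionally carrying a per-cluster annotation.

#' Construct a clonal partition
#'
#' @param clusters List of character vectors of sequence ids (ordered,
#'   disjoint).
#' @param locus Optional chain/locus tag.
#' @param annotations Optional list of per-cluster annotations, parallel to
#'   `clusters`.
#' @param failed Ids excluded because annotation failed (side channel, not
#'   silently dropped).
#' @return An object of class `clonal_partition`.
#' @export
new_partition <- function(clusters, locus = NA_character_, annotations = NULL,
                          failed = character()) {
  ids <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(ids))
    stop("clusters are not disjoint")
  structure(list(clusters = clusters, locus = locus,
                 annotations = annotations, failed = failed),
            class = "clonal_partition")
}

#' @export
print.clonal_partition <- function(x, ...) {
  sz <- lengths(x$clusters)
  cat(sprintf("<clonal_partition> %s: %d clusters over %d sequences\n",
              x$locus, length(sz), sum(sz)))
  if (length(sz))
    cat("  sizes: ", paste(utils::head(sort(sz, decreasing = TRUE), 10L),
                           collapse = " "),
        if (length(sz) > 10L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.clonal_partition <- function(x) length(x$clusters)

#' Convert a partition to a data frame
#'
#' @param x A `clonal_partition`.
#' @param ... Unused.
#' @return Data frame with columns `sequence_id` and `clone_id`.
#' @export
as.data.frame.clonal_partition <- function(x, ...) {
  data.frame(
    sequence_id = unlist(x$clusters, use.names = FALSE),
    clone_id = rep(sprintf("c%d", seq_along(x$clusters)),
                   lengths(x$clusters)),
    stringsAsFactors = FALSE)
}

#' Build a partition from cluster membership
#'
#' @param ids Sequence identifiers.
#' @param group Cluster labels parallel to `ids`.
#' @param locus Optional locus tag.
#' @return A `clonal_partition` with clusters in order of first appearance.
#' @export
as_partition <- function(ids, group, locus = NA_character_) {
  cl <- split(ids, factor(group, levels = unique(group)))
  new_partition(unname(cl), locus = locus)
}

# id -> cluster index lookup
.cluster_index <- function(p) {
  idx <- rep(seq_along(p$clusters), lengths(p$clusters))
  setNames(idx, unlist(p$clusters, use.names = FALSE))
}
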