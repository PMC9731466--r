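# Refining single-chain partitions into one joint partition with pairing
# information.  The underlying objects are heavy/light *pairs*, represented
# by a shared pair identifier; discrepancies between the two single-chain
# partitions are resolved by splitting only, never merging: information
# from the other chain is a strong signal that a cluster should be split
# (different CDR3 lengths, or confidently different naive rearrangements),
# whereas similarity in the other chain is not a clear signal to merge.

#' Resolve one cluster against its overlapping opposite-chain clusters
#'
#' Given a cluster `c_l` (over pair identifiers) and the list of
#' opposite-chain clusters that share at least one identifier with it,
#' decides how the identifiers should be regrouped.  With fewer than two
#' overlapping clusters there is no discrepancy and `c_l` is returned
#' unchanged.  Otherwise the opposite-chain clusters are grouped by CDR3
#' length (inferred CDR3 length is essentially always right, so
#' differences always split); within each group, every pair of clusters
#' whose inferred naive sequences differ by more than `d_0` is put on each
#' other's "split list", and clusters are then greedily merged into the
#' first accumulated resolved cluster that contains nothing on their split
#' list.  This preserves all confident between-cluster boundaries while
#' merging everything else.
#'
#' @param c_l Character vector of pair identifiers.
#' @param ch_list List of opposite-chain clusters (pair identifier
#'   vectors), each sharing at least one id with `c_l`, mutually disjoint.
#' @param ch_meta List parallel to `ch_list`: each element has
#'   `cdr3_length`, `naive_sequence`, `cdr3_start` for that cluster.
#' @param d_0 Naive Hamming distance above which clusters must not merge.
#' @return List of resolved clusters covering the union of the inputs.
#' @export
resolve_clusters <- function(c_l, ch_list, ch_meta, d_0 = 0.05) {
  if (anyDuplicated(unlist(ch_list, use.names = FALSE)))
    stop("duplicate identifiers in the opposite-chain cluster list")
  if (length(ch_list) < 2L) return(list(c_l))
  lens <- vapply(ch_meta, function(m) m$cdr3_length, numeric(1))
  resolved <- list()
  for (len in unique(lens)) {
    grp <- which(lens == len)
    ng <- length(grp)
    split_mat <- matrix(FALSE, ng, ng)
    if (ng > 1L) {
      for (x in seq_len(ng - 1L)) {
        mx <- ch_meta[[grp[x]]]
        for (y in (x + 1L):ng) {
          my <- ch_meta[[grp[y]]]
          d <- anchored_naive_dist(mx$naive_sequence, mx$cdr3_start,
                                   my$naive_sequence, my$cdr3_start)
          if (d > d_0) split_mat[x, y] <- split_mat[y, x] <- TRUE
        }
      }
    }
    len_rclusts <- list() # resolved clusters for this CDR3-length group
    len_sources <- list() # which group members each one absorbed
    for (ci in seq_len(ng)) {
      placed <- FALSE
      for (ri in seq_along(len_rclusts)) {
        if (!any(split_mat[ci, len_sources[[ri]]])) {
          len_rclusts[[ri]] <- c(len_rclusts[[ri]], ch_list[[grp[ci]]])
          len_sources[[ri]] <- c(len_sources[[ri]], ci)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        len_rclusts[[length(len_rclusts) + 1L]] <- ch_list[[grp[ci]]]
        len_sources[[length(len_sources) + 1L]] <- ci
      }
    }
    resolved <- c(resolved, len_rclusts)
  }
  resolved
}

#' Incorporate resolved clusters into a growing final partition
#'
#' Resolved clusters from successive discrepancy resolutions can overlap
#' the clusters already in the final partition in complicated ways; since
#' new splits are based on new information, the more-highly-split
#' alternative is generally believed.  For each existing final cluster
#' that shares sequences with the resolved set: the first overlapping pair
#' has the common sequences removed from the *larger* of the two clusters
#' (ties remove from the incoming resolved cluster, keeping the
#' accumulated partition stable); each subsequent pair has the common
#' sequences removed from both and appended as their own new cluster, so
#' sequences from different resolved clusters are never merged.  All
#' (trimmed) resolved clusters are then appended.
#'
#' @param final_partition List of clusters (id vectors) accumulated so far.
#' @param resolved List of internally disjoint resolved clusters.
#' @return The updated final partition; no identifier is duplicated or
#'   lost.
#' @export
incorporate_resolved <- function(final_partition, resolved) {
  if (anyDuplicated(unlist(resolved, use.names = FALSE)))
    stop("resolved clusters must be disjoint")
  final <- final_partition
  fi <- 1L
  while (fi <= length(final)) {
    rf <- which(vapply(resolved, function(r) any(r %in% final[[fi]]),
                       logical(1)))
    first <- TRUE
    for (ri in rf) {
      ov <- intersect(resolved[[ri]], final[[fi]])
      if (!length(ov)) next
      if (first) {
        first <- FALSE
        if (length(resolved[[ri]]) >= length(final[[fi]])) {
          resolved[[ri]] <- setdiff(resolved[[ri]], ov)
        } else {
          final[[fi]] <- setdiff(final[[fi]], ov)
        }
      } else {
        resolved[[ri]] <- setdiff(resolved[[ri]], ov)
        final[[fi]] <- setdiff(final[[fi]], ov)
        resolved[[length(resolved) + 1L]] <- ov
      }
    }
    fi <- fi + 1L
  }
  out <- c(final, resolved)
  out[lengths(out) > 0L]
}

# Per-cluster metadata (CDR3 length + cluster naive) for resolution.
.cluster_meta <- function(p, ann_df, germ) {
  if (!is.null(p$annotations))
    return(lapply(p$annotations, function(a)
      list(cdr3_length = a$cdr3_length, naive_sequence = a$naive_sequence,
           cdr3_start = a$cdr3_start)))
  ann_by_id <- setNames(.ann_list(ann_df), ann_df$sequence_id)
  lapply(p$clusters, function(cl) {
    anns <- ann_by_id[cl]
    # resolved clusters can mix CDR3 lengths; annotate the modal class
    cls <- vapply(anns, function(a) a$cdr3_length, numeric(1))
    keep <- cls == as.numeric(mode_chr(cls))
    a <- annotate_cluster(germ = germ, anns = anns[keep])
    list(cdr3_length = a$cdr3_length, naive_sequence = a$naive_sequence,
         cdr3_start = a$cdr3_start)
  })
}

#' Joint (paired) partition from two single-chain partitions
#'
#' Iterates over every cluster of the light partition, resolving it
#' against the overlapping heavy clusters with [resolve_clusters()] and
#' incorporating the result into the growing final partition with
#' [incorporate_resolved()]; then does the same for every heavy cluster
#' against the light partition.  The result is a single partition applied
#' to both chains.  The net effect only ever splits single-chain clusters
#' (by avoiding specific merges); it never merges two clusters that both
#' chains agree are distinct.
#'
#' Only uniquely paired sequences participate; unpaired sequences must be
#' handled by [clean_pair_info()] / [attach_unpaired()] first.
#'
#' @param p_h,p_l Heavy and light `clonal_partition`s over sequence ids.
#' @param pairmap Data frame with `sequence_id`, `partner_id` (the cleaned
#'   pair map); rows with a non-missing partner define the pairs.
#' @param anns_h,anns_l Per-sequence annotation data frames (used to
#'   compute cluster-level naives when the partitions do not carry
#'   annotations).
#' @param germ Germline set for consensus tie-breaks (optional).
#' @param d_0 Naive Hamming split threshold.
#' @return A list of class `joint_partition` with elements `pairs` (the
#'   partition over pair identifiers = heavy sequence ids), `heavy` and
#'   `light` (the same partition expressed over each chain's sequence
#'   ids).
#' @export
joint_partition <- function(p_h, p_l, pairmap, anns_h = NULL, anns_l = NULL,
                            germ = NULL, d_0 = 0.05) {
  paired <- pairmap[!is.na(pairmap$partner_id), , drop = FALSE]
  h_ids <- unlist(p_h$clusters, use.names = FALSE)
  l_ids <- unlist(p_l$clusters, use.names = FALSE)
  h_paired <- paired$sequence_id[paired$sequence_id %in% h_ids]
  l2pid <- setNames(paired$partner_id, paired$sequence_id) # light -> heavy id
  pid2l <- setNames(paired$sequence_id, paired$partner_id)

  ph_pairs <- lapply(p_h$clusters, function(cl) cl[cl %in% h_paired])
  pl_pairs <- lapply(p_l$clusters, function(cl) {
    cl <- cl[cl %in% names(l2pid)]
    unname(l2pid[cl])
  })
  meta_h <- .cluster_meta(p_h, anns_h, germ)
  meta_l <- .cluster_meta(p_l, anns_l, germ)
  keep_h <- lengths(ph_pairs) > 0L
  keep_l <- lengths(pl_pairs) > 0L
  ph_pairs <- ph_pairs[keep_h]
  meta_h <- meta_h[keep_h]
  pl_pairs <- pl_pairs[keep_l]
  meta_l <- meta_l[keep_l]

  u_h <- sort(unlist(ph_pairs, use.names = FALSE))
  u_l <- sort(unlist(pl_pairs, use.names = FALSE))
  if (!identical(u_h, u_l))
    stop("heavy and light partitions cover different pair identifiers; ",
         "clean pair info first")

  ord <- function(cls) order(-lengths(cls),
                             vapply(cls, min, character(1)))
  idx_of <- function(cls) {
    ix <- rep(seq_along(cls), lengths(cls))
    setNames(ix, unlist(cls, use.names = FALSE))
  }
  final <- list()
  h_index <- idx_of(ph_pairs)
  for (ci in ord(pl_pairs)) {
    c_l <- pl_pairs[[ci]]
    ch_ix <- unique(h_index[c_l])
    rslvd <- resolve_clusters(c_l, ph_pairs[ch_ix], meta_h[ch_ix], d_0)
    final <- incorporate_resolved(final, rslvd)
  }
  l_index <- idx_of(pl_pairs)
  for (ci in ord(ph_pairs)) {
    c_h <- ph_pairs[[ci]]
    cl_ix <- unique(l_index[c_h])
    rslvd <- resolve_clusters(c_h, pl_pairs[cl_ix], meta_l[cl_ix], d_0)
    final <- incorporate_resolved(final, rslvd)
  }

  structure(list(
    pairs = new_partition(final, locus = "paired"),
    heavy = new_partition(final, locus = "IGH"),
    light = new_partition(lapply(final, function(cl) unname(pid2l[cl])),
                          locus = "IGK/IGL")), class = "joint_partition")
}

#' @export
print.joint_partition <- function(x, ...) {
  cat("<joint_partition>\n  ")
  print(x$pairs)
  invisible(x)
}
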