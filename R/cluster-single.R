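# Single-chain partitioning.

#' Clustering configuration
#'
#' @param d_0 Naive-Hamming merge threshold (normalized distance, default
#'   0.05: clusters closer than 5% merge).
#' @param n_t Key-translation subsample size: clusters larger than `n_t`
#'   are represented by `n_t` random members during agglomeration, with
#'   final annotations recomputed on the full clusters.
#' @param big_small_ratio Merge shortcut: when one cluster is at least this
#'   many times larger than the other, the merged cluster reuses the larger
#'   parent's annotation.
#' @param threshold_mode `"fixed"`, or `"shm_scaled"` to widen the
#'   threshold with the sample's mean SHM level:
#'   `d_0' = d_0 * (1 + 2 * mean_shm)`.
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(d_0 = 0.05, n_t = 15L, big_small_ratio = 4,
                           threshold_mode = c("fixed", "shm_scaled")) {
  if (d_0 <= 0 || d_0 >= 1) stop("d_0 must be in (0, 1)")
  if (n_t < 2L) stop("n_t must be >= 2")
  structure(list(d_0 = d_0, n_t = as.integer(n_t),
                 big_small_ratio = big_small_ratio,
                 threshold_mode = match.arg(threshold_mode)),
            class = "cluster_config")
}

#' VJ CDR3 0.8 baseline partition
#'
#' The widespread simple method: group sequences by V gene, J gene (allele
#' names truncated at "*") and CDR3 length, then single-linkage cluster the
#' observed CDR3 nucleotide sequences within each group at 0.8 identity
#' (normalized Hamming distance <= 0.2).
#'
#' @param anns Annotation data frame from [annotate_repertoire()].
#' @return A `clonal_partition`; sequences with failed annotation are
#'   listed in its `failed` field.
#' @export
vj_cdr3_partition <- function(anns) {
  ok <- anns$annot_ok
  failed <- anns$sequence_id[!ok]
  a <- anns[ok, , drop = FALSE]
  gene <- function(x) sub("\\*.*$", "", x)
  key <- paste(gene(a$v_call), gene(a$j_call), a$cdr3_length, sep = "|")
  cdr3 <- substr(a$sequence, a$cdr3_start + 1L, a$cdr3_start + a$cdr3_length)
  clusters <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) == 1L) {
      clusters[[length(clusters) + 1L]] <- a$sequence_id[idx]
      next
    }
    m <- int_mat_left(lapply(cdr3[idx], seq_to_int))
    d <- cpp_pairwise_dist(m)
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    grp <- stats::cutree(hc, h = 0.2 + 1e-9)
    for (gi in unique(grp))
      clusters[[length(clusters) + 1L]] <- a$sequence_id[idx[grp == gi]]
  }
  new_partition(clusters, locus = unique(a$locus)[1], failed = failed)
}

#' Key translation: subsample a large cluster
#'
#' During agglomeration, annotation is never computed on more than `n_t`
#' simultaneous sequences: clusters larger than `n_t` are represented by
#' `n_t` members chosen uniformly at random (relative order preserved).
#' The mapping back to the full cluster is kept in attribute `full`, and
#' final-partition annotations are recomputed on full clusters.
#'
#' @param cluster Character vector of member ids (ordered).
#' @param n_t Subsample size.
#' @return The proxy cluster (the input itself when not larger than `n_t`).
#' @export
key_translate <- function(cluster, n_t = 15L) {
  if (length(cluster) <= n_t) return(cluster)
  keep <- sort(sample.int(length(cluster), n_t))
  out <- cluster[keep]
  attr(out, "full") <- cluster
  out
}

#' Large/small merge shortcut
#'
#' Returns TRUE when `big` is at least `ratio` times larger than `small`,
#' in which case the merged cluster reuses the larger parent's annotation
#' without recalculation (merging a singleton into a large cluster barely
#' moves its consensus).
#'
#' @param big,small Clusters (id vectors) or their sizes.
#' @param ratio Size ratio threshold.
#' @return Logical.
#' @export
big_small_merge_shortcut <- function(big, small, ratio = 4) {
  nb <- if (is.numeric(big) && length(big) == 1L) big else length(big)
  ns <- if (is.numeric(small) && length(small) == 1L) small else length(small)
  nb >= ratio * ns
}

#' Naive-Hamming hierarchical agglomeration
#'
#' The main single-chain clustering method.  Sequences with identical
#' inferred naive sequences are first collapsed; clusters are then
#' agglomerated within CDR3-length classes by repeatedly merging the
#' closest pair of clusters whose cluster-level naive sequences are within
#' normalized Hamming distance `d_0`, re-annotating each newly formed
#' cluster with [subcluster_annotate()] (subject to [key_translate()] and
#' the [big_small_merge_shortcut()]).  Distance ties are broken toward the
#' lexicographically smallest pair of cluster leader ids (leader = smallest
#' member id), which makes the result independent of input row order.
#' Cluster order on merge is concatenation, preserving agglomeration order
#' for subcluster annotation.  Final annotations are recomputed on the full
#' clusters.
#'
#' @param anns Annotation data frame from [annotate_repertoire()], all one
#'   locus.
#' @param germ The germline set (for consensus tie-breaks).
#' @param cfg A [cluster_config()].
#' @return A `clonal_partition` with per-cluster annotations; ids whose
#'   annotation failed are in `$failed`.
#' @export
naive_hamming_partition <- function(anns, germ, cfg = cluster_config()) {
  stopifnot(length(unique(anns$locus)) <= 1L)
  ok <- anns$annot_ok
  failed <- anns$sequence_id[!ok]
  a <- anns[ok, , drop = FALSE]
  if (!nrow(a))
    return(new_partition(list(), locus = unique(anns$locus)[1], failed = failed))
  d0 <- cfg$d_0
  if (cfg$threshold_mode == "shm_scaled")
    d0 <- d0 * (1 + 2 * mean(a$shm_fraction))
  ann_by_id <- setNames(.ann_list(a), a$sequence_id)

  # collapse identical inferred naive sequences
  key <- paste(a$naive_sequence, a$cdr3_start)
  groups <- split(seq_len(nrow(a)), factor(key, levels = unique(key)))
  clusters <- lapply(groups, function(ix) a$sequence_id[ix])
  cl_ann <- lapply(groups, function(ix)
    annotate_cluster(anns = .ann_list(a[ix, , drop = FALSE])))
  names(clusters) <- NULL
  names(cl_ann) <- NULL

  cdr3_len <- vapply(cl_ann, function(x) x$cdr3_length, numeric(1))
  out_clusters <- list()
  out_anns <- list()
  for (len in unique(cdr3_len)) {
    cls_ix <- which(cdr3_len == len)
    res <- .agglomerate_class(clusters[cls_ix], cl_ann[cls_ix], ann_by_id,
                              germ, d0, cfg)
    out_clusters <- c(out_clusters, res$clusters)
    out_anns <- c(out_anns, res$annotations)
  }
  p <- new_partition(out_clusters, locus = unique(a$locus)[1],
                     annotations = out_anns, failed = failed)
  attr(p, "d0_used") <- d0
  p
}

# Agglomeration within one CDR3-length class.  Cluster naives are held in
# a shared CDR3-anchored integer matrix so distances are one C call.
.agglomerate_class <- function(clusters, cl_ann, ann_by_id, germ, d0, cfg) {
  k <- length(clusters)
  if (k == 1L)
    return(list(clusters = clusters, annotations = cl_ann))

  starts <- vapply(cl_ann, function(x) x$cdr3_start, numeric(1))
  naives <- vapply(cl_ann, function(x) x$naive_sequence, character(1))
  maxL <- max(starts)
  width <- as.integer(maxL + max(nchar(naives) - starts))
  row_of <- function(ann) {
    v <- seq_to_int(ann$naive_sequence)
    r <- integer(width)
    off <- as.integer(maxL - ann$cdr3_start)
    r[off + seq_along(v)] <- v
    r
  }
  mat <- do.call(rbind, lapply(cl_ann, row_of))
  dm <- cpp_pairwise_dist(mat)
  diag(dm) <- Inf
  active <- rep(TRUE, k)
  leader <- vapply(clusters, min, character(1))

  # nearest-neighbour bookkeeping so each merge costs O(k), not O(k^2)
  nn_dist <- numeric(k)
  nn_idx <- integer(k)
  for (r in seq_len(k)) {
    ix <- which.min(dm[r, ])
    nn_dist[r] <- dm[r, ix]
    nn_idx[r] <- ix
  }

  repeat {
    dmin <- min(nn_dist)
    if (!is.finite(dmin) || dmin >= d0) break
    rows <- which(nn_dist == dmin)
    hits <- do.call(rbind, lapply(rows, function(r)
      cbind(r, which(dm[r, ] == dmin))))
    hits <- unique(cbind(pmin(hits[, 1L], hits[, 2L]),
                         pmax(hits[, 1L], hits[, 2L])))
    if (nrow(hits) > 1L) { # tie-break: smallest lexicographic leader pair
      pl <- cbind(pmin(leader[hits[, 1L]], leader[hits[, 2L]]),
                  pmax(leader[hits[, 1L]], leader[hits[, 2L]]))
      hits <- hits[order(pl[, 1L], pl[, 2L])[1L], , drop = FALSE]
    }
    i <- hits[1L, 1L]
    j <- hits[1L, 2L]
    merged <- c(clusters[[i]], clusters[[j]])
    if (big_small_merge_shortcut(length(clusters[[i]]), length(clusters[[j]]),
                                 cfg$big_small_ratio) ||
        big_small_merge_shortcut(length(clusters[[j]]), length(clusters[[i]]),
                                 cfg$big_small_ratio)) {
      big <- if (length(clusters[[i]]) >= length(clusters[[j]])) i else j
      new_ann <- cl_ann[[big]]
    } else {
      proxy <- key_translate(merged, cfg$n_t)
      new_ann <- subcluster_annotate(germ = germ, anns = ann_by_id[proxy])
    }
    clusters[[i]] <- merged
    cl_ann[[i]] <- new_ann
    leader[i] <- min(merged)
    active[j] <- FALSE
    dm[j, ] <- Inf
    dm[, j] <- Inf
    nn_dist[j] <- Inf
    newrow <- row_of(new_ann)
    mat[i, ] <- newrow
    dvec <- cpp_row_dist(mat, newrow)
    dvec[!active] <- Inf
    dvec[i] <- Inf
    dm[i, ] <- dvec
    dm[, i] <- dvec
    ix <- which.min(dvec)
    nn_dist[i] <- dvec[ix]
    nn_idx[i] <- ix
    stale <- which(active & (nn_idx == i | nn_idx == j))
    for (r in setdiff(stale, i)) {
      rx <- which.min(dm[r, ])
      nn_dist[r] <- dm[r, rx]
      nn_idx[r] <- rx
    }
    better <- which(active & dvec < nn_dist)
    if (length(better)) {
      nn_dist[better] <- dvec[better]
      nn_idx[better] <- i
    }
  }
  keep <- which(active)
  # final annotations on the full clusters (no key translation)
  final_ann <- lapply(keep, function(ix) {
    if (length(clusters[[ix]]) == 1L) return(cl_ann[[ix]])
    subcluster_annotate(germ = germ, anns = ann_by_id[clusters[[ix]]])
  })
  list(clusters = clusters[keep], annotations = final_ann)
}
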