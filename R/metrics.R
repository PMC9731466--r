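# Scoring inferred partitions and pair fixes against simulation truth.

.clusters_of <- function(x) {
  if (inherits(x, "clonal_partition")) x$clusters else x
}

#' Per-sequence precision, sensitivity and F1 of a partition
#'
#' For each sequence with inferred cluster I and true family T, precision
#' is |I intersect T| / |I| (the fraction of its cluster that is truly
#' clonal) and sensitivity is |I intersect T| / |T| (the fraction of its
#' true family that ended up together).  Both are averaged over all
#' sequences, and F1 is the harmonic mean of the two averages.
#'
#' @param inferred,truth Partitions (`clonal_partition` or plain lists of
#'   id vectors) over the same sequence ids.
#' @return Named numeric vector `precision`, `sensitivity`, `f1`.
#' @export
partition_scores <- function(inferred, truth) {
  ci <- .clusters_of(inferred)
  ct <- .clusters_of(truth)
  ids_i <- unlist(ci, use.names = FALSE)
  ids_t <- unlist(ct, use.names = FALSE)
  if (!setequal(ids_i, ids_t))
    stop("inferred and true partitions cover different sequence ids")
  inf_idx <- rep(seq_along(ci), lengths(ci))
  names(inf_idx) <- ids_i
  true_idx <- rep(seq_along(ct), lengths(ct))
  names(true_idx) <- ids_t
  inf_of <- inf_idx[ids_t]         # aligned on the truth id order
  key <- paste(inf_of, true_idx)
  ov <- table(key)                 # |I intersect T| per (I, T) pair
  n_ov <- as.numeric(ov[key])
  prec <- mean(n_ov / lengths(ci)[inf_of])
  sens <- mean(n_ov / lengths(ct)[true_idx])
  c(precision = prec, sensitivity = sens,
    f1 = if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0)
}

#' Classify pair assignments against truth
#'
#' For every sequence, classifies its assigned partner as exactly correct,
#' correct-family (a clone-mate of the true partner), similar-family,
#' mispaired, or unpaired.  The heavy and light chains are both counted,
#' per sequence.
#'
#' A partner from the wrong family counts as *similar* when the two
#' rearrangement events are collided on the focal sequence's own chain:
#' the true naive sequences of the focal sequence's family and the
#' partner's family, on the focal chain, differ by at most `similar_max`
#' nucleotides.  Such partners arise when single-chain clusters merge
#' near-indistinguishable events, and the pairing is then likely still
#' functional because the focal sequence could stand in for a member of
#' the partner's own family.
#'
#' @param pairmap A `pair_map` (columns `sequence_id`, `partner_id`).
#' @param records Simulation records (for `clone_id`, `locus`,
#'   `true_partner`).
#' @param events Simulation events (for the true naive sequences).
#' @param similar_max Maximum absolute Hamming distance between true naive
#'   sequences for two families to count as similar (inclusive).
#' @return Data frame of class `pairing_scores`, one row per sequence:
#'   `sequence_id`, `family_size` (true, per chain), logicals `paired`,
#'   `correct_seq`, `correct_family`, `similar_family`.  Summarize with
#'   [pairing_summary()].
#' @export
pairing_scores <- function(pairmap, records, events, similar_max = 3L) {
  partner <- setNames(pairmap$partner_id, pairmap$sequence_id)
  clone_of <- setNames(records$clone_id, records$sequence_id)
  locus_of <- setNames(records$locus, records$sequence_id)
  fam_size <- table(paste(records$clone_id, records$locus))
  naive_of <- function(sid) { # true naive of a sequence's own chain+family
    ev <- match(clone_of[sid], events$clone_id)
    ifelse(locus_of[sid] == "IGH", events$heavy_naive[ev],
           events$light_naive[ev])
  }
  ids <- records$sequence_id
  p <- unname(partner[ids])
  paired <- !is.na(p)
  correct_seq <- paired & p == records$true_partner
  correct_family <- paired & unname(clone_of[p]) == records$clone_id &
    unname(locus_of[p]) != records$locus
  correct_family[is.na(correct_family)] <- FALSE
  similar <- correct_family
  todo <- which(paired & !correct_family)
  if (length(todo)) {
    # a partner on the same chain can never be similar-family
    opp <- unname(locus_of[p[todo]]) != records$locus[todo]
    # focal-chain naives of the focal sequence's event ...
    n1 <- naive_of(ids[todo])
    # ... and of the partner's event: close means the two events collided
    # on this chain
    pe <- match(unname(clone_of[p[todo]]), events$clone_id)
    n2 <- ifelse(records$locus[todo] == "IGH", events$heavy_naive[pe],
                 events$light_naive[pe])
    similar[todo] <- opp & nchar(n1) == nchar(n2) &
      mapply(function(a, b) cpp_hamming(seq_to_int(a), seq_to_int(b)),
             n1, n2) <= similar_max
  }
  out <- data.frame(
    sequence_id = ids,
    family_size = as.integer(fam_size[paste(records$clone_id, records$locus)]),
    paired = paired,
    correct_seq = unname(correct_seq),
    correct_family = unname(correct_family),
    similar_family = unname(similar),
    stringsAsFactors = FALSE)
  class(out) <- c("pairing_scores", "data.frame")
  out
}

#' Summarize pairing scores
#'
#' @param scores A [pairing_scores()] result.
#' @param min_family_size Restrict to sequences whose true family has at
#'   least this many members.
#' @return Named vector of fractions: `correct_seq`, `correct_family`,
#'   `similar_family`, `mispaired` (paired but not with the exact
#'   sequence), `unpaired`, and the number of sequences `n`.  By
#'   construction `correct_seq + mispaired + unpaired = 1` and
#'   `correct_seq <= correct_family <= similar_family`.
#' @export
pairing_summary <- function(scores, min_family_size = 1L) {
  s <- scores[scores$family_size >= min_family_size, , drop = FALSE]
  n <- nrow(s)
  c(correct_seq = mean(s$correct_seq),
    correct_family = mean(s$correct_family),
    similar_family = mean(s$similar_family),
    mispaired = mean(s$paired & !s$correct_seq),
    unpaired = mean(!s$paired),
    n = n)
}

#' Synthetic error partition: random singleton splitting
#'
#' Starting from the true partition, moves a random `fraction` of
#' sequences (exactly `round(fraction * N)`) into singleton clusters - a
#' baseline for how a simple known error affects the performance metrics.
#'
#' @param truth A partition.
#' @param fraction Fraction of sequences to split off.
#' @return A `clonal_partition`.
#' @export
synth_singleton <- function(truth, fraction = 0.2) {
  cl <- .clusters_of(truth)
  ids <- unlist(cl, use.names = FALSE)
  k <- round(fraction * length(ids))
  move <- sample(ids, k)
  kept <- lapply(cl, function(x) setdiff(x, move))
  out <- c(kept[lengths(kept) > 0L], as.list(move))
  new_partition(out, locus = if (inherits(truth, "clonal_partition"))
    truth$locus else NA_character_)
}

#' Synthetic error partition: merging naive-collision neighbours
#'
#' Starting from the true partition, single-linkage merges families whose
#' true naive sequences are closer than `threshold` in normalized
#' nucleotide Hamming distance (families with different naive lengths
#' never merge).  The precision of the result quantifies how often
#' distinct rearrangement events are practically indistinguishable from
#' single-chain information.
#'
#' @param truth A partition whose clusters are in the same order as
#'   `naives`.
#' @param naives Character vector of true naive sequences, one per true
#'   family.
#' @param threshold Normalized distance below which families merge
#'   (strict).
#' @return A `clonal_partition`.
#' @export
synth_neighbor <- function(truth, naives, threshold = 0.03) {
  cl <- .clusters_of(truth)
  stopifnot(length(cl) == length(naives))
  grp <- integer(length(cl))
  next_grp <- 0L
  for (len in unique(nchar(naives))) {
    ix <- which(nchar(naives) == len)
    if (length(ix) == 1L) {
      next_grp <- next_grp + 1L
      grp[ix] <- next_grp
      next
    }
    m <- do.call(rbind, lapply(naives[ix], seq_to_int))
    d <- cpp_pairwise_dist(m)
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    g <- stats::cutree(hc, h = threshold * (1 - 1e-9))
    grp[ix] <- next_grp + g
    next_grp <- next_grp + max(g)
  }
  merged <- lapply(split(seq_along(cl), grp), function(ii)
    unlist(cl[ii], use.names = FALSE))
  new_partition(unname(merged), locus = if (inherits(truth, "clonal_partition"))
    truth$locus else NA_character_)
}
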