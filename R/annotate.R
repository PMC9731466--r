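# Naive (unmutated ancestor) sequence inference.
#
# Single sequences are annotated by scored ungapped alignment against the
# germline set: the best V and J alleles over candidate 3'/5' deletion
# lengths (score = matches - mismatches), with the naive sequence taking
# germline bases where aligned and observed bases in the non-templated
# junction.  No indels are modelled: the simulator emits none, so
# annotation is a fixed-length comparison.  Clusters are annotated by
# per-position majority vote over the member-wise naive reconstructions
# (a star-tree consensus), with ties broken toward the germline base.

.germ_region <- function(germ, locus, region) {
  g <- germ[germ$locus == locus & germ$region == region, , drop = FALSE]
  g[order(g$name), , drop = FALSE]
}

# Vectorized best-allele search for one region over all sequences at once.
# tmat is a (width x n) integer matrix of the sequences, left-aligned for V
# (compare allele prefixes, eroding the 3' end) or right-aligned for J
# (compare allele suffixes, eroding the 5' end).
.score_region <- function(tmat, alleles, side, max_obs = NULL) {
  n <- ncol(tmat)
  W <- nrow(tmat)
  best <- rep(-Inf, n)
  b_allele <- integer(n)
  b_del <- integer(n)
  for (ai in seq_len(nrow(alleles))) {
    g <- seq_to_int(alleles$sequence[ai])
    La <- length(g)
    anchor <- alleles$anchor[ai]
    if (side == "V") {
      dmax <- La - (anchor + 3L) # keep the anchor codon intact
      eq <- tmat[seq_len(La), , drop = FALSE] == g
    } else {
      dmax <- anchor
      eq <- tmat[(W - La + 1L):W, , drop = FALSE] == g
    }
    # iterate deletions from largest to smallest with a strict update, so
    # ties go to the larger deletion: germline is only extended over the
    # junction when it strictly improves the match score
    if (side == "V") {
      cnt <- .colSums(eq[seq_len(La - dmax), , drop = FALSE], La - dmax, n)
    } else {
      cnt <- .colSums(eq[(dmax + 1L):La, , drop = FALSE], La - dmax, n)
    }
    for (d in dmax:0) {
      sc <- 2 * cnt - (La - d)
      upd <- sc > best # strict: earlier alleles also win ties
      if (!is.null(max_obs)) upd <- upd & (La - d) <= max_obs
      if (any(upd)) {
        best[upd] <- sc[upd]
        b_allele[upd] <- ai
        b_del[upd] <- d
      }
      if (d > 0L) {
        add_row <- if (side == "V") La - d + 1L else d
        cnt <- cnt + eq[add_row, ]
      }
    }
  }
  list(allele = b_allele, del = b_del, score = best)
}

# Best-effort D call: best ungapped overlap of each D allele within the
# observed junction insert; the aligned stretch is reverted to germline.
.call_d <- function(seq_int, mid_lo, mid_hi, dalleles, min_overlap = 5L) {
  nm <- mid_hi - mid_lo + 1L
  if (nm < min_overlap) return(NULL)
  mid <- seq_int[mid_lo:mid_hi]
  best <- -Inf
  out <- NULL
  for (ai in seq_len(nrow(dalleles))) {
    g <- seq_to_int(dalleles$sequence[ai])
    Ld <- length(g)
    for (s in (1L - Ld + min_overlap):(nm - min_overlap + 1L)) {
      lo <- max(1L, s)
      hi <- min(nm, s + Ld - 1L)
      if (hi - lo + 1L < min_overlap) next
      # end-trim the placement (5'/3' deletions): best-scoring contiguous
      # sub-segment of the match profile; mismatches cost double so chance
      # matches beyond the true segment rarely extend it
      gseg <- g[(lo - s + 1L):(hi - s + 1L)]
      v <- ifelse(mid[lo:hi] == gseg, 1L, -2L)
      nv <- length(v)
      cum <- c(0L, cumsum(v))
      seg <- NULL # best segment no shorter than min_overlap
      min_pref <- 0L
      min_at <- 0L
      for (k in min_overlap:nv) {
        j <- k - min_overlap # rightmost admissible segment start - 1
        if (cum[j + 1L] < min_pref) {
          min_pref <- cum[j + 1L]
          min_at <- j
        }
        sc_k <- cum[k + 1L] - min_pref
        if (is.null(seg) || sc_k > seg[1]) seg <- c(sc_k, min_at + 1L, k)
      }
      if (seg[1] > best) {
        best <- seg[1]
        idx <- seg[2]:seg[3]
        out <- list(d_call = dalleles$name[ai],
                    positions = (mid_lo + lo - 1L) + idx - 1L,
                    bases = gseg[idx])
      }
    }
  }
  out
}

#' Annotate a repertoire of sequences
#'
#' Infers for every sequence the best V and J alleles, deletion lengths,
#' naive sequence, and CDR3 bounds (0-based half-open, anchored at the
#' conserved V and J anchor codons).  Sequences whose best V or J match
#' fraction falls below `min_match_frac` are flagged `annot_ok = FALSE`
#' (excluded downstream, never silently dropped).
#'
#' @param records Data frame with columns `sequence_id`, `sequence`,
#'   `locus`, or a character vector of sequences (ids are generated).
#' @param germ A germline set.
#' @param locus Locus of the sequences when `records` is a bare character
#'   vector.
#' @param call_d Also call the D gene for heavy chains (best ungapped match
#'   within the junction; best-effort, not used by clustering).
#' @param min_match_frac Minimum fraction of matching germline positions.
#' @return Data frame with one row per input sequence: `sequence_id`,
#'   `locus`, `sequence`, `v_call`, `d_call`, `j_call`, `naive_sequence`,
#'   `cdr3_start`, `cdr3_length`, `shm_fraction`, `annot_ok`.
#' @export
annotate_repertoire <- function(records, germ, locus = NULL, call_d = FALSE,
                                min_match_frac = 0.55) {
  if (is.character(records)) {
    if (is.null(locus)) stop("locus is required for bare sequence input")
    records <- data.frame(sequence_id = sprintf("s%d", seq_along(records)),
                          sequence = records, locus = locus,
                          stringsAsFactors = FALSE)
  }
  out <- vector("list", length(unique(records$locus)))
  li <- 0L
  for (loc in unique(records$locus)) {
    li <- li + 1L
    idx <- which(records$locus == loc)
    out[[li]] <- .annotate_batch(records$sequence[idx],
                                 records$sequence_id[idx],
                                 germ, loc, call_d, min_match_frac)
  }
  res <- do.call(rbind, out)
  res <- res[match(records$sequence_id, res$sequence_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.annotate_batch <- function(seqs, ids, germ, locus, call_d, min_match_frac) {
  n <- length(seqs)
  ints <- lapply(seqs, seq_to_int)
  lens <- lengths(ints)
  valleles <- .germ_region(germ, locus, "V")
  jalleles <- .germ_region(germ, locus, "J")
  W <- max(lens, nchar(valleles$sequence), nchar(jalleles$sequence))
  tl <- t(int_mat_left(ints, W))
  tr <- t(int_mat_right(ints, W))
  v <- .score_region(tl, valleles, "V")
  # constrain the J to the suffix left over by the chosen V so the two
  # germline segments never overlap in the junction
  v_obs_len <- nchar(valleles$sequence)[v$allele] - v$del
  j <- .score_region(tr, jalleles, "J", max_obs = lens - v_obs_len)
  if (any(j$allele == 0L)) { # no J fits the leftover suffix: fail the row
    bad <- j$allele == 0L
    j$allele[bad] <- 1L
    j$score[bad] <- -Inf
  }
  dalleles <- if (call_d && locus == "IGH") .germ_region(germ, locus, "D") else NULL

  res <- data.frame(
    sequence_id = ids, locus = locus, sequence = seqs,
    v_call = valleles$name[v$allele], d_call = NA_character_,
    j_call = jalleles$name[j$allele],
    naive_sequence = NA_character_, cdr3_start = NA_integer_,
    cdr3_length = NA_integer_, shm_fraction = NA_real_,
    annot_ok = FALSE, stringsAsFactors = FALSE)

  lv <- nchar(valleles$sequence)[v$allele]
  lj <- nchar(jalleles$sequence)[j$allele]
  v_obs <- lv - v$del
  j_obs <- lj - j$del
  v_frac <- (v$score + v_obs) / (2 * v_obs)
  j_frac <- (j$score + j_obs) / (2 * j_obs)
  cdr3_start <- valleles$anchor[v$allele]
  cdr3_end <- lens - (lj - (jalleles$anchor[j$allele] + 3L))
  ok <- v_frac >= min_match_frac & j_frac >= min_match_frac &
    v_obs + j_obs <= lens & cdr3_end - cdr3_start >= 6L

  for (i in which(ok)) {
    naive <- paste0(
      substr(valleles$sequence[v$allele[i]], 1L, v_obs[i]),
      substr(seqs[i], v_obs[i] + 1L, lens[i] - j_obs[i]),
      substr(jalleles$sequence[j$allele[i]], j$del[i] + 1L, lj[i]))
    nv <- seq_to_int(naive)
    if (!is.null(dalleles)) {
      dc <- .call_d(nv, v_obs[i] + 1L, lens[i] - j_obs[i], dalleles)
      if (!is.null(dc)) {
        res$d_call[i] <- dc$d_call
        nv[dc$positions] <- dc$bases
        naive <- int_to_seq(nv)
      }
    }
    res$naive_sequence[i] <- naive
    res$shm_fraction[i] <- cpp_hamming(ints[[i]], nv) / lens[i]
  }
  res$cdr3_start[ok] <- cdr3_start[ok]
  res$cdr3_length[ok] <- (cdr3_end - cdr3_start)[ok]
  res$annot_ok <- ok & !is.na(res$naive_sequence)
  res
}

#' Annotate a single sequence
#'
#' Convenience wrapper around [annotate_repertoire()] for one sequence;
#' heavy chains also get a best-effort D call by default.
#'
#' @param seq Nucleotide sequence (string).
#' @param germ A germline set.
#' @param locus "IGH", "IGK" or "IGL".
#' @param call_d Call the D gene (heavy only).
#' @return A list of class `bcr_annotation` with fields `v_call`, `d_call`,
#'   `j_call`, `naive_sequence`, `cdr3_start`, `cdr3_length`,
#'   `shm_fraction`, `annot_ok`.
#' @export
annotate_single <- function(seq, germ, locus, call_d = TRUE) {
  df <- annotate_repertoire(seq, germ, locus = locus, call_d = call_d)
  ann <- as.list(df[1L, c("v_call", "d_call", "j_call", "naive_sequence",
                          "cdr3_start", "cdr3_length", "shm_fraction",
                          "annot_ok")])
  class(ann) <- "bcr_annotation"
  ann
}

# Normalize annotation input (data frame rows or list of lists/annotations)
# to a plain list of lists.
.ann_list <- function(anns) {
  if (is.data.frame(anns))
    return(lapply(seq_len(nrow(anns)), function(i) as.list(anns[i, ])))
  if (inherits(anns, "bcr_annotation")) return(list(anns))
  anns
}

#' Annotate a cluster by majority vote
#'
#' Computes a cluster-level annotation as the per-position majority vote
#' over the member-wise naive reconstructions, aligned at their CDR3 start
#' (the star-tree analogue of simultaneous multi-sequence inference).
#' Ties are broken toward the germline base of the cluster's consensus V/J
#' call where it covers the position; inside the non-templated junction
#' (which the germline does not cover) ties fall to the base backed by the
#' most underlying sequences (members that are themselves block consensus
#' naives carry their sequence count as a vote weight), then to the
#' alphabetically first base.
#'
#' All members must share one CDR3 length (enforced; the caller groups by
#' CDR3 length).
#'
#' @param seqs Character vector of observed sequences (annotated
#'   internally), or NULL when `anns` is given.
#' @param germ A germline set.
#' @param locus Locus, required with `seqs`.
#' @param anns Precomputed member annotations (data frame or list); when
#'   supplied, `seqs` is ignored and no alignment is recomputed.
#' @return A `bcr_annotation` for the cluster.
#' @export
annotate_cluster <- function(seqs = NULL, germ = NULL, locus = NULL,
                             anns = NULL) {
  if (is.null(anns)) {
    anns <- annotate_repertoire(seqs, germ, locus = locus)
    if (!all(anns$annot_ok)) stop("cluster contains unannotatable sequences")
  }
  anns <- .ann_list(anns)
  cl <- vapply(anns, function(a) a$cdr3_length, numeric(1))
  if (length(unique(cl)) != 1L) stop("mixed CDR3 lengths in cluster")
  cdr3_len <- as.integer(cl[1])
  starts <- vapply(anns, function(a) a$cdr3_start, numeric(1))
  naives <- vapply(anns, function(a) a$naive_sequence, character(1))
  maxL <- as.integer(max(starts))
  maxR <- as.integer(max(nchar(naives) - starts))
  width <- maxL + maxR

  # one vote per member; the number of underlying sequences each member
  # summarizes (> 1 for block naives in subcluster annotation) is kept as
  # a weight, used only to break voting ties
  wts <- vapply(anns, function(a) a$n_members %||% 1, numeric(1))
  counts <- matrix(0L, 4L, width)
  wcounts <- matrix(0, 4L, width)
  for (i in seq_along(anns)) {
    vv <- seq_to_int(naives[i])
    ix <- cbind(vv, (maxL - as.integer(starts[i])) + seq_along(vv))
    counts[ix] <- counts[ix] + 1L
    wcounts[ix] <- wcounts[ix] + wts[i]
  }

  v_call <- mode_chr(vapply(anns, function(a) a$v_call, character(1)))
  j_call <- mode_chr(vapply(anns, function(a) a$j_call, character(1)))

  # germline scaffold for tie-breaks: V through its anchor codon on the
  # left, J from its anchor codon on the right
  g <- integer(width)
  vrow <- if (is.null(germ)) data.frame() else germ[germ$name == v_call, ]
  jrow <- if (is.null(germ)) data.frame() else germ[germ$name == j_call, ]
  if (nrow(vrow)) {
    gv <- seq_to_int(vrow$sequence)
    p <- 0:min(maxL + 2L, width - 1L)
    vpos <- vrow$anchor + p - maxL
    keep <- vpos >= 0L & vpos < length(gv)
    g[p[keep] + 1L] <- gv[vpos[keep] + 1L]
  }
  if (nrow(jrow)) {
    gj <- seq_to_int(jrow$sequence)
    cdr3_end <- maxL + cdr3_len
    p <- max(0L, cdr3_end - 3L):(width - 1L)
    jpos <- (jrow$anchor + 3L) + p - cdr3_end
    keep <- jpos >= 0L & jpos < length(gj)
    g[p[keep] + 1L] <- gj[jpos[keep] + 1L]
  }

  colmax <- pmax(counts[1L, ], counts[2L, ], counts[3L, ], counts[4L, ])
  winner <- max.col(t(counts), ties.method = "first")
  n_tied <- .colSums(counts == rep(colmax, each = 4L), 4L, width)
  for (cc in which(n_tied > 1L)) { # tie: germline, then weight, then A<C<G<T
    tied <- which(counts[, cc] == colmax[cc])
    if (g[cc] %in% tied) {
      winner[cc] <- g[cc]
    } else {
      wm <- max(wcounts[tied, cc])
      winner[cc] <- tied[wcounts[tied, cc] == wm][1L]
    }
  }

  shm <- vapply(anns, function(a) a$shm_fraction %||% NA_real_, numeric(1))
  structure(list(
    v_call = v_call,
    d_call = NA_character_,
    j_call = j_call,
    naive_sequence = int_to_seq(winner),
    cdr3_start = maxL,
    cdr3_length = cdr3_len,
    shm_fraction = mean(shm, na.rm = TRUE),
    n_members = sum(wts),
    annot_ok = TRUE), class = "bcr_annotation")
}

#' Subcluster annotation configuration
#'
#' @param n_s Maximum subcluster size (>= 2).
#' @param max_iterations Safety bound on annotation rounds.
#' @return A list of class `subcluster_config`.
#' @export
subcluster_config <- function(n_s = 3L, max_iterations = 100L) {
  if (n_s < 2L) stop("n_s must be >= 2")
  structure(list(n_s = as.integer(n_s),
                 max_iterations = as.integer(max_iterations)),
            class = "subcluster_config")
}

#' Split a cluster size into subcluster sizes
#'
#' Splits `N` into `k = ceiling(N / n_s)` subcluster sizes that are as
#' equal as possible (all `floor(N/k)` or `ceiling(N/k)`, so no size
#' exceeds `n_s` and any two sizes differ by at most one), ordered
#' non-increasing.  A cluster of 10 at `n_s = 3` gives sizes 3, 3, 2, 2.
#'
#' @param N Cluster size (>= 1).
#' @param n_s Maximum subcluster size (>= 2).
#' @return Integer vector of subcluster sizes summing to `N`.
#' @export
subcluster_sizes <- function(N, n_s) {
  stopifnot(N >= 1, n_s >= 2)
  N <- as.integer(N)
  k <- as.integer(ceiling(N / n_s))
  base <- N %/% k
  r <- N %% k
  c(rep(base + 1L, r), rep(base, k - r))
}

#' Iterative subcluster annotation
#'
#' Annotates a cluster of arbitrary size while retaining the star-tree
#' consensus only locally: the ordered member list is split into contiguous
#' blocks per [subcluster_sizes()], each block is annotated with
#' [annotate_cluster()], the blocks are replaced by their inferred naive
#' sequences, and the procedure iterates until a single block remains.
#' Because cluster order is the agglomeration merge order, similar
#' sequences tend to share blocks, so the final naive sequence is
#' effectively weighted by the tree structure.
#'
#' @param seqs Ordered character vector of observed sequences (order
#'   preserved from agglomeration), or NULL when `anns` is given.
#' @param germ A germline set.
#' @param locus Locus, required with `seqs`.
#' @param cfg A [subcluster_config()].
#' @param anns Precomputed ordered member annotations.
#' @param trace Attach the per-iteration block counts as attribute
#'   `block_counts`.
#' @return A `bcr_annotation` for the full cluster.
#' @export
subcluster_annotate <- function(seqs = NULL, germ = NULL, locus = NULL,
                                cfg = subcluster_config(), anns = NULL,
                                trace = FALSE) {
  if (is.null(anns)) {
    df <- annotate_repertoire(seqs, germ, locus = locus)
    if (!all(df$annot_ok)) stop("cluster contains unannotatable sequences")
    anns <- .ann_list(df)
  } else {
    anns <- .ann_list(anns)
  }
  block_counts <- integer()
  current <- anns
  for (it in seq_len(cfg$max_iterations)) {
    sizes <- subcluster_sizes(length(current), cfg$n_s)
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    blocks <- Map(function(s, e) current[s:e], starts, ends)
    block_counts <- c(block_counts, length(blocks))
    current <- lapply(blocks, function(b) annotate_cluster(germ = germ, anns = b))
    if (length(current) == 1L) {
      out <- current[[1L]]
      if (trace) attr(out, "block_counts") <- block_counts
      return(out)
    }
  }
  stop("subcluster annotation did not converge")
}

#' @export
print.bcr_annotation <- function(x, ...) {
  cat(sprintf("<bcr_annotation> %s / %s / %s  CDR3 %d nt @ %d  SHM %.3f\n",
              x$v_call, x$d_call %||% NA, x$j_call,
              x$cdr3_length, x$cdr3_start, x$shm_fraction))
  invisible(x)
}
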