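# Fixing imperfect pairing information: disambiguating multiple candidate
# partners (overloaded droplets) by clonal-family voting, and approximate
# pairing of bulk sequences via a matched single cell sample.

.parse_paired_ids <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  out[is.na(x) | x == ""] <- list(character())
  out
}

# observed-sequence Hamming distance over the common aligned length
.obs_dist <- function(s1, s2) {
  L <- min(nchar(s1), nchar(s2))
  cpp_hamming(seq_to_int(substr(s1, 1L, L)), seq_to_int(substr(s2, 1L, L))) / L
}

#' Clean multiple pairing information by clonal-family voting
#'
#' Correct pair info is shared among members of a clonal family, while
#' spurious co-droplet partners are not.  For each cluster of the two
#' single-chain partitions (processed in decreasing size order, then by
#' smallest member id), the opposite-chain families of all members'
#' candidate partners are collected and ranked by "votes" (the number of
#' member-candidate links into each family).  Each member with multiple
#' candidates takes the candidate from the top-voted family; when tied
#' candidates belong to the same opposite-chain family one is chosen at
#' random (they likely stem from the same molecule), otherwise all pairing
#' information for the sequence is discarded.  Whenever a unique partner
#' is fixed, both sequences are removed from every other candidate list.
#' Every sequence ends with exactly zero or one partner.
#'
#' @param p_h,p_l Heavy and light single-chain `clonal_partition`s.
#' @param records Records data frame with `sequence_id`, `locus`,
#'   `paired_ids` (semicolon-separated co-droplet sequence ids, both
#'   chains).
#' @return Data frame of class `pair_map`: `sequence_id`, `partner_id`
#'   (NA when unpaired), `status` (`paired`, `unpaired`, or `stripped`).
#' @export
clean_pair_info <- function(p_h, p_l, records) {
  ids <- records$sequence_id
  cand <- .parse_paired_ids(records$paired_ids)
  names(cand) <- ids
  locus_of <- setNames(records$locus, ids)
  is_heavy <- locus_of == "IGH"
  unknown <- setdiff(unlist(cand, use.names = FALSE), ids)
  if (length(unknown))
    stop("unknown candidate id(s): ", paste(head(unknown, 3L), collapse = ", "))

  fam <- c(
    setNames(rep(paste0("H", seq_along(p_h$clusters)), lengths(p_h$clusters)),
             unlist(p_h$clusters, use.names = FALSE)),
    setNames(rep(paste0("L", seq_along(p_l$clusters)), lengths(p_l$clusters)),
             unlist(p_l$clusters, use.names = FALSE)))

  partner <- setNames(rep(NA_character_, length(ids)), ids)
  status <- setNames(rep(NA_character_, length(ids)), ids)
  resolved <- setNames(rep(FALSE, length(ids)), ids)

  # opposite-chain candidates only are potential partners
  opp <- function(id) {
    cs <- cand[[id]]
    cs[is_heavy[cs] != is_heavy[id]]
  }
  fix_pair <- function(a, b) {
    partner[a] <<- b
    partner[b] <<- a
    status[a] <<- status[b] <<- "paired"
    resolved[a] <<- resolved[b] <<- TRUE
    drop_from_lists(c(a, b))
  }
  drop_from_lists <- function(gone) {
    affected <- unique(unlist(cand[gone], use.names = FALSE))
    for (o in setdiff(affected, gone))
      cand[[o]] <<- setdiff(cand[[o]], gone)
    for (g in gone) cand[[g]] <<- character()
  }

  all_clusters <- c(p_h$clusters, p_l$clusters)
  all_clusters <- lapply(all_clusters, function(cl) cl[cl %in% ids])
  all_clusters <- all_clusters[lengths(all_clusters) > 0L]
  cl_ord <- order(-lengths(all_clusters),
                  vapply(all_clusters, min, character(1)))

  for (ci in cl_ord) {
    members <- all_clusters[[ci]]
    # votes against the current candidate lists, fixed for this cluster
    links <- unlist(lapply(members, opp), use.names = FALSE)
    votes <- table(fam[links])
    for (s in members) {
      if (resolved[s]) next
      cs <- opp(s)
      if (!length(cs)) {
        status[s] <- "unpaired"
        resolved[s] <- TRUE
        next
      }
      if (length(cs) == 1L) {
        fix_pair(s, cs)
        next
      }
      v <- as.numeric(votes[fam[cs]])
      v[is.na(v)] <- 0
      top <- cs[v == max(v)]
      if (length(top) == 1L) {
        fix_pair(s, top)
      } else if (length(unique(fam[top])) == 1L) {
        fix_pair(s, sample(top, 1L)) # same family: likely the same molecule
      } else {
        status[s] <- "stripped" # irresolvable tie across families
        resolved[s] <- TRUE
        drop_from_lists(s)
      }
    }
  }
  status[!resolved & !is.na(locus_of)] <- "unpaired"
  out <- data.frame(sequence_id = ids,
                    partner_id = unname(partner[ids]),
                    status = unname(status[ids]),
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_map", "data.frame")
  out
}

#' Attach unpaired sequences to the final joint partition
#'
#' Sequences without pair info (sequencing failure, stripped by cleaning,
#' or bulk) are ignored during paired clustering; afterwards each is added
#' to the final family of its nearest (by observed-sequence Hamming
#' distance) paired member of its own single-chain family.  Nearby
#' sequences share sublineages, so unpaired sequences piggy-back on the
#' clustering refinement of those with pair info.  A family with no paired
#' members is kept together as its own final cluster; unpaired singletons
#' remain singletons.
#'
#' @param joint A [joint_partition()].
#' @param p_h,p_l Single-chain partitions over all sequences.
#' @param pairmap The cleaned `pair_map`.
#' @param records Records data frame (for the observed sequences).
#' @return The `joint_partition` with `heavy` and `light` partitions
#'   extended to cover all sequences.
#' @export
attach_unpaired <- function(joint, p_h, p_l, pairmap, records) {
  seq_of <- setNames(records$sequence, records$sequence_id)
  paired_ids <- pairmap$sequence_id[!is.na(pairmap$partner_id)]
  for (chain in c("heavy", "light")) {
    p <- if (chain == "heavy") p_h else p_l
    fp <- joint[[chain]]$clusters
    fidx <- .cluster_index(joint[[chain]])
    extra <- list()
    for (cl in p$clusters) {
      pm <- cl[cl %in% paired_ids]
      um <- setdiff(cl, pm)
      if (!length(um)) next
      if (!length(pm)) { # no paired members: family stays together
        extra[[length(extra) + 1L]] <- cl
        next
      }
      for (u in um) {
        d <- vapply(pm, function(p2) .obs_dist(seq_of[[u]], seq_of[[p2]]),
                    numeric(1))
        best <- pm[d == min(d)]
        nb <- sort(best)[1L]
        fp[[fidx[[nb]]]] <- c(fp[[fidx[[nb]]]], u)
      }
    }
    joint[[chain]] <- new_partition(c(fp, extra), locus = joint[[chain]]$locus)
  }
  joint
}

#' Approximate pairing of bulk sequences
#'
#' Within each single-chain cluster that contains at least one paired
#' sequence, every unpaired (bulk) sequence is assigned the partner of its
#' nearest (by observed-sequence Hamming distance) paired cluster-mate;
#' clusters with no paired sequence are left unpaired.  This synchronizes
#' pair info among sublineages, pairing bulk sequences with the correct
#' (or at least a similar) opposite-chain family, though often not the
#' correct sequence.  Already-paired sequences are never modified.
#'
#' @param p_h,p_l Single-chain partitions over the merged bulk +
#'   single-cell sample.
#' @param pairmap `pair_map` of the single-cell subset.
#' @param records Records data frame.
#' @return The extended `pair_map`; bulk assignments get status
#'   `bulk_paired`.
#' @export
bulk_pair <- function(p_h, p_l, pairmap, records) {
  seq_of <- setNames(records$sequence, records$sequence_id)
  partner <- setNames(pairmap$partner_id, pairmap$sequence_id)
  status <- setNames(pairmap$status, pairmap$sequence_id)
  for (p in list(p_h, p_l)) {
    for (cl in p$clusters) {
      pm <- cl[!is.na(partner[cl])]
      um <- cl[is.na(partner[cl])]
      if (!length(pm) || !length(um)) next
      for (u in um) {
        d <- vapply(pm, function(p2) .obs_dist(seq_of[[u]], seq_of[[p2]]),
                    numeric(1))
        best <- pm[d == min(d)]
        nb <- sort(best)[1L]
        partner[u] <- partner[[nb]]
        status[u] <- "bulk_paired"
      }
    }
  }
  out <- data.frame(sequence_id = pairmap$sequence_id,
                    partner_id = unname(partner[pairmap$sequence_id]),
                    status = unname(status[pairmap$sequence_id]),
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_map", "data.frame")
  out
}
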