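# Paired repertoire simulation: events, droplets, bulk splits, truth.

.draw_family_sizes <- function(n, model) {
  switch(model$model,
    fixed = rep(as.integer(model$k), n),
    geometric = 1L + rgeom(n, 1 / model$mean),
    datalike = {
      # ~70% singletons plus a geometric tail on sizes 2, 3, ...; the
      # default tail success probability 0.3 gives an overall mean family
      # size of 2 (about 12,000 heavy+light sequences from 3,000 events).
      singleton <- model$singleton %||% 0.7
      tail_p <- model$tail_p %||% 0.3
      is_single <- runif(n) < singleton
      sizes <- rep(1L, n)
      ntail <- sum(!is_single)
      if (ntail) sizes[!is_single] <- 2L + rgeom(ntail, tail_p)
      sizes
    },
    stop("unknown family_size_model: ", model$model)
  )
}

.draw_droplet_sizes <- function(n_cells, model) {
  if (model$model == "fixed") {
    k <- as.integer(model$k)
    sizes <- rep(k, ceiling(n_cells / k))
  } else if (model$model == "poisson") {
    sizes <- integer()
    while (sum(sizes) < n_cells) {
      draw <- rpois(max(16L, ceiling(n_cells / model$mean)), model$mean)
      sizes <- c(sizes, draw[draw >= 1L]) # truncated at one cell
    }
  } else stop("unknown cells_per_droplet model: ", model$model)
  # trim to exactly n_cells
  cum <- cumsum(sizes)
  last <- which(cum >= n_cells)[1]
  sizes <- sizes[seq_len(last)]
  sizes[last] <- sizes[last] - (cum[last] - n_cells)
  sizes[sizes > 0L]
}

#' Simulate a paired heavy/light chain repertoire
#'
#' For each rearrangement event, draws a family size and a single tree, one
#' heavy and one light naive rearrangement (IgK with probability
#' `kappa_fraction`), and mutates both chains down the *same* tree - pairing
#' of heavy and light germline choices is uncorrelated.  Cells are then
#' assigned to droplets; each sequence's raw pair-info candidate list
#' contains every other sequence in its droplet (both chains).  A
#' `bulk_fraction` of cells is emitted with droplet and pair info stripped,
#' and each chain read is independently lost with `dropout_fraction`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `paired_sim` with elements `records` (data frame:
#'   `sequence_id`, `sequence`, `locus`, `cell_id`, `droplet_id`,
#'   `clone_id`, `true_partner`, `paired_ids` (semicolon-separated),
#'   `is_bulk`), `events` (per-event truth: naives, gene calls, trees as
#'   newick), `germline`, and `config`.
#' @export
simulate_paired_repertoire <- function(cfg = sim_config()) {
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  germ <- generate_germline_set(cfg)
  n <- cfg$n_events
  sizes <- .draw_family_sizes(n, cfg$family_size_model)
  light_locus <- ifelse(runif(n) < cfg$kappa_fraction, "IGK", "IGL")

  ev_rows <- vector("list", n)
  rec_rows <- vector("list", n)
  for (e in seq_len(n)) {
    clone <- sprintf("clone_%04d", e)
    tree <- generate_tree(cfg$tree_model, sizes[e])
    rh <- rearrange(germ, "IGH", cfg)
    rl <- rearrange(germ, light_locus[e], cfg)
    lh <- mutate_family(rh$naive, tree, cfg$shm_mean, cfg$gamma_shape)
    ll <- mutate_family(rl$naive, tree, cfg$shm_mean, cfg$gamma_shape)
    cells <- sprintf("%s_c%02d", clone, seq_len(sizes[e]))
    hid <- paste0(cells, "_igh")
    lid <- paste0(cells, "_", tolower(light_locus[e]))
    ev_rows[[e]] <- data.frame(
      clone_id = clone, n_cells = sizes[e],
      heavy_naive = rh$naive, light_naive = rl$naive,
      light_locus = light_locus[e],
      heavy_v = rh$v_call, heavy_d = rh$d_call, heavy_j = rh$j_call,
      light_v = rl$v_call, light_j = rl$j_call,
      heavy_cdr3_start = rh$cdr3_start, heavy_cdr3_length = rh$cdr3_length,
      light_cdr3_start = rl$cdr3_start, light_cdr3_length = rl$cdr3_length,
      newick = ape::write.tree(tree),
      stringsAsFactors = FALSE)
    rec_rows[[e]] <- data.frame(
      sequence_id = c(hid, lid),
      sequence = c(unname(lh), unname(ll)),
      locus = c(rep("IGH", sizes[e]), rep(light_locus[e], sizes[e])),
      cell_id = c(cells, cells),
      clone_id = clone,
      true_partner = c(lid, hid),
      stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev_rows)
  records <- do.call(rbind, rec_rows)
  rownames(records) <- NULL

  # bulk split and droplet assignment operate on cells
  cells <- unique(records$cell_id)
  is_bulk_cell <- setNames(runif(length(cells)) < cfg$bulk_fraction, cells)
  sc_cells <- cells[!is_bulk_cell[cells]]
  droplet_of <- setNames(rep(NA_character_, length(cells)), cells)
  if (length(sc_cells)) {
    shuffled <- sample(sc_cells)
    dsz <- .draw_droplet_sizes(length(shuffled), cfg$cells_per_droplet)
    droplet_of[shuffled] <- rep(sprintf("d%05d", seq_along(dsz)), dsz)
  }
  records$is_bulk <- unname(is_bulk_cell[records$cell_id])
  records$droplet_id <- unname(droplet_of[records$cell_id])

  if (cfg$dropout_fraction > 0) {
    keep <- runif(nrow(records)) >= cfg$dropout_fraction
    dropped <- records$sequence_id[!keep]
    records <- records[keep, , drop = FALSE]
    records$true_partner[records$true_partner %in% dropped] <- NA_character_
  }

  # raw pair info: all other sequences sharing the droplet, both chains
  records$paired_ids <- ""
  has_drop <- !is.na(records$droplet_id)
  if (any(has_drop)) {
    by_drop <- split(records$sequence_id[has_drop], records$droplet_id[has_drop])
    pid <- lapply(by_drop, function(ids) {
      vapply(seq_along(ids), function(i)
        paste(ids[-i], collapse = ";"), character(1))
    })
    records$paired_ids[has_drop][order(records$droplet_id[has_drop])] <-
      unlist(pid, use.names = FALSE)
  }
  rownames(records) <- NULL
  structure(list(records = records, events = events, germline = germ,
                 config = cfg), class = "paired_sim")
}

#' @export
print.paired_sim <- function(x, ...) {
  cat(sprintf("<paired_sim> %d events, %d sequences (%d bulk)\n",
              nrow(x$events), nrow(x$records), sum(x$records$is_bulk)))
  invisible(x)
}

#' True partition of simulated records
#'
#' Groups simulated sequences of one chain by their true clone id.
#'
#' @param records The `records` data frame of a [simulate_paired_repertoire()].
#' @param chain "heavy" (IGH) or "light" (IGK + IGL).
#' @return A `clonal_partition`.
#' @export
true_partition <- function(records, chain = c("heavy", "light")) {
  chain <- match.arg(chain)
  keep <- if (chain == "heavy") records$locus == "IGH" else records$locus != "IGH"
  r <- records[keep, , drop = FALSE]
  cl <- split(r$sequence_id, r$clone_id)
  new_partition(unname(cl[unique(r$clone_id)]),
                locus = if (chain == "heavy") "IGH" else "IGK/IGL")
}
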