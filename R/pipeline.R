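# End-to-end workflow: simulate -> annotate -> single-chain partition ->
# clean pairs -> paired partition -> attach unpaired -> bulk pair ->
# evaluate, with one shared seed and every stage's outputs on disk.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Combine single-chain partitions of several loci into one
#'
#' Light-chain partitioning runs per locus (IgK, IgL); the light partition
#' is their concatenation.
#'
#' @param ... `clonal_partition` objects.
#' @param locus Tag for the combined partition.
#' @return A `clonal_partition`.
#' @export
combine_partitions <- function(..., locus = NA_character_) {
  ps <- list(...)
  ps <- ps[!vapply(ps, is.null, logical(1))]
  new_partition(unlist(lapply(ps, function(p) p$clusters), recursive = FALSE),
                locus = locus,
                annotations = {
                  an <- lapply(ps, function(p) p$annotations)
                  if (any(vapply(an, is.null, logical(1)))) NULL
                  else unlist(an, recursive = FALSE)
                },
                failed = unlist(lapply(ps, function(p) p$failed)))
}

#' Run the full paired clustering workflow on a simulated sample
#'
#' Executes every stage in order with one shared seed: simulation,
#' per-sequence annotation, single-chain partitioning per locus, pair-info
#' cleaning, joint (paired) partitioning, attachment of unpaired
#' sequences, approximate bulk pairing (when the sample contains bulk
#' data), and evaluation against the simulation truth.
#'
#' @param cfg A [sim_config()].
#' @param ccfg A [cluster_config()].
#' @param outdir Optional directory; when given, every stage's inputs and
#'   outputs are written there (records, germline set, partitions, pair
#'   maps, evaluation, and a manifest with versions, seed and thresholds).
#' @param seed Seed applied to the whole run (overrides `cfg$rng_seed`).
#' @return List with elements `sim`, `annotations`, `partitions` (heavy,
#'   light and per-locus), `pairmap` (cleaned), `joint`, `bulk_pairmap`
#'   (when bulk data is present), and `evaluation`.
#' @export
run_pipeline <- function(cfg = sim_config(), ccfg = cluster_config(),
                         outdir = NULL, seed = NULL) {
  if (!is.null(seed)) cfg$rng_seed <- seed
  sim <- .stage("simulate", simulate_paired_repertoire(cfg))
  records <- sim$records

  anns <- .stage("annotate", annotate_repertoire(records, sim$germline))

  parts <- list()
  for (loc in c("IGH", "IGK", "IGL")) {
    sub <- anns[anns$locus == loc, , drop = FALSE]
    if (!nrow(sub)) next
    parts[[loc]] <- .stage(paste0("partition-", tolower(loc)),
                           naive_hamming_partition(sub, sim$germline, ccfg))
  }
  p_h <- parts$IGH
  p_l <- .stage("partition-light",
                combine_partitions(parts$IGK, parts$IGL, locus = "IGK/IGL"))

  pairmap <- .stage("clean-pairs", clean_pair_info(p_h, p_l, records))

  joint <- .stage("partition-paired", {
    jp <- joint_partition(p_h, p_l, pairmap,
                          anns_h = anns[anns$locus == "IGH", , drop = FALSE],
                          anns_l = anns[anns$locus != "IGH", , drop = FALSE],
                          germ = sim$germline, d_0 = ccfg$d_0)
    attach_unpaired(jp, p_h, p_l, pairmap, records)
  })

  bulk_pairmap <- NULL
  if (any(records$is_bulk))
    bulk_pairmap <- .stage("bulk-pair", bulk_pair(p_h, p_l, pairmap, records))

  evaluation <- .stage("evaluate", {
    t_h <- true_partition(records, "heavy")
    t_l <- true_partition(records, "light")
    pm <- bulk_pairmap %||% pairmap
    list(
      single_heavy = partition_scores(p_h, t_h),
      single_light = partition_scores(p_l, t_l),
      joint_heavy = partition_scores(joint$heavy, t_h),
      joint_light = partition_scores(joint$light, t_l),
      pairing = pairing_scores(pm, records, sim$events))
  })

  out <- list(sim = sim, annotations = anns, partitions = parts,
              heavy = p_h, light = p_l, pairmap = pairmap, joint = joint,
              bulk_pairmap = bulk_pairmap, evaluation = evaluation)

  if (!is.null(outdir)) .write_pipeline_outputs(out, cfg, ccfg, outdir)
  out
}

.write_pipeline_outputs <- function(out, cfg, ccfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  f <- function(...) file.path(outdir, ...)
  write_airr(out$sim$records, f("records.tsv"))
  write_germline_set(out$sim$germline, f("germline.fasta"))
  write_truth_trees(out$sim$events, f("truth_trees.nwk"))
  write_sim_config(cfg, f("sim_config.yaml"))
  write_airr(out$annotations, f("annotations.tsv"))
  for (chain in c("heavy", "light")) {
    write.table(as.data.frame(out[[chain]]), f(paste0(chain, "_partition.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(out$joint[[chain]]),
                f(paste0(chain, "_joint_partition.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(out$pairmap, f("pairmap.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(out$bulk_pairmap))
    write.table(out$bulk_pairmap, f("bulk_pairmap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  ev <- out$evaluation
  yaml::write_yaml(list(
    single_heavy = as.list(ev$single_heavy),
    single_light = as.list(ev$single_light),
    joint_heavy = as.list(ev$joint_heavy),
    joint_light = as.list(ev$joint_light),
    pairing = as.list(pairing_summary(ev$pairing))), f("evaluation.yaml"))
  yaml::write_yaml(list(
    package = "pairclone",
    version = as.character(packageVersion("pairclone")),
    r_version = as.character(getRversion()),
    seed = cfg$rng_seed,
    d_0 = ccfg$d_0, n_t = ccfg$n_t,
    big_small_ratio = ccfg$big_small_ratio,
    threshold_mode = ccfg$threshold_mode), f("manifest.yaml"))
  invisible(outdir)
}
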