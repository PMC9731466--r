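pairfix_records <- function(ids, locus, droplets, seqs = NULL) {
  by_drop <- split(ids, droplets)
  paired_ids <- unlist(lapply(by_drop, function(d)
    vapply(seq_along(d), function(i) paste(d[-i], collapse = ";"), character(1))))
  ord <- unlist(by_drop)
  data.frame(sequence_id = ids, locus = locus,
             sequence = seqs %||% vapply(ids, function(x) random_seq(30), character(1)),
             droplet_id = droplets,
             paired_ids = unname(paired_ids[match(ids, ord)]),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("family voting picks the partner backed by clone-mates", {
  set.seed(81)
  # heavy family {h1..h4}; light family F1 = {k1, ka, kb}, F2 = {k3}.
  # h1 shares a droplet with both k1 and k3; its clone-mates pair with
  # F1 members in their own droplets, so F1 outvotes F2 three to one.
  ids <- c("h1", "h2", "h3", "h4", "k1", "k3", "ka", "kb")
  locus <- c(rep("IGH", 4), rep("IGK", 4))
  droplets <- c("d1", "d2", "d3", "d4", "d1", "d1", "d2", "d3")
  rec <- pairfix_records(ids, locus, droplets)
  p_h <- new_partition(list(c("h1", "h2", "h3", "h4")), locus = "IGH")
  p_l <- new_partition(list(c("k1", "ka", "kb"), "k3"), locus = "IGK")
  pm <- clean_pair_info(p_h, p_l, rec)
  expect_equal(pm$partner_id[pm$sequence_id == "h1"], "k1")
  expect_equal(pm$partner_id[pm$sequence_id == "k1"], "h1")
  # k3 loses its only candidate once h1/k1 are fixed
  expect_equal(pm$status[pm$sequence_id == "k3"], "unpaired")
  expect_true(all(pm$status %in% c("paired", "unpaired", "stripped")))
})

test_that("singleton two-family ties are stripped", {
  set.seed(82)
  ids <- c("h1", "k1", "k2")
  rec <- pairfix_records(ids, c("IGH", "IGK", "IGK"), rep("d1", 3))
  p_h <- new_partition(list("h1"), locus = "IGH")
  p_l <- new_partition(list("k1", "k2"), locus = "IGK")
  pm <- clean_pair_info(p_h, p_l, rec)
  expect_equal(pm$status[pm$sequence_id == "h1"], "stripped")
  expect_true(is.na(pm$partner_id[pm$sequence_id == "h1"]))
})

test_that("tied candidates within one family resolve to one of them", {
  set.seed(83)
  ids <- c("h1", "k1", "k2")
  rec <- pairfix_records(ids, c("IGH", "IGK", "IGK"), rep("d1", 3))
  p_h <- new_partition(list("h1"), locus = "IGH")
  p_l <- new_partition(list(c("k1", "k2")), locus = "IGK")
  pm <- clean_pair_info(p_h, p_l, rec)
  expect_equal(pm$status[pm$sequence_id == "h1"], "paired")
  expect_true(pm$partner_id[pm$sequence_id == "h1"] %in% c("k1", "k2"))
})

test_that("with one cell per droplet cleaning is the identity", {
  cfg <- sim_config(n_events = 60, shm_mean = 0.08, rng_seed = 84,
                    family_size_model = list(model = "geometric", mean = 2))
  sim <- simulate_paired_repertoire(cfg)
  ann <- annotate_repertoire(sim$records, sim$germline)
  p_h <- naive_hamming_partition(ann[ann$locus == "IGH", ], sim$germline)
  p_l <- combine_partitions(
    naive_hamming_partition(ann[ann$locus == "IGK", ], sim$germline),
    naive_hamming_partition(ann[ann$locus == "IGL", ], sim$germline))
  pm <- clean_pair_info(p_h, p_l, sim$records)
  expect_true(all(pm$status == "paired"))
  expect_identical(pm$partner_id,
                   sim$records$true_partner[match(pm$sequence_id,
                                                  sim$records$sequence_id)])
})

test_that("cleaning output always has zero or one symmetric partner", {
  cfg <- sim_config(n_events = 120, shm_mean = 0.10, rng_seed = 85,
                    family_size_model = list(model = "datalike"),
                    cells_per_droplet = list(model = "poisson", mean = 3))
  sim <- simulate_paired_repertoire(cfg)
  ann <- annotate_repertoire(sim$records, sim$germline)
  p_h <- naive_hamming_partition(ann[ann$locus == "IGH", ], sim$germline)
  p_l <- combine_partitions(
    naive_hamming_partition(ann[ann$locus == "IGK", ], sim$germline),
    naive_hamming_partition(ann[ann$locus == "IGL", ], sim$germline))
  pm <- clean_pair_info(p_h, p_l, sim$records)
  paired <- pm[!is.na(pm$partner_id), ]
  back <- setNames(pm$partner_id, pm$sequence_id)
  expect_identical(unname(back[paired$partner_id]), paired$sequence_id)
  # partners are always opposite-chain
  loc <- setNames(sim$records$locus, sim$records$sequence_id)
  expect_true(all((loc[paired$sequence_id] == "IGH") !=
                    (loc[paired$partner_id] == "IGH")))
})

test_that("unpaired sequences are attached next to their nearest paired kin", {
  set.seed(86)
  base <- random_seq(60)
  s_h1 <- base
  s_h2 <- mutate_at(base, 3)
  s_h3 <- mutate_at(s_h2, 1) # h3 is nearest to h2
  rec <- data.frame(
    sequence_id = c("h1", "h2", "h3", "l1", "l2"),
    locus = c("IGH", "IGH", "IGH", "IGK", "IGK"),
    sequence = c(s_h1, s_h2, s_h3, random_seq(50), random_seq(50)),
    stringsAsFactors = FALSE)
  pairmap <- data.frame(sequence_id = c("h1", "h2", "h3", "l1", "l2"),
                        partner_id = c("l1", "l2", NA, "h1", "h2"),
                        status = c("paired", "paired", "unpaired", "paired", "paired"))
  p_h <- new_partition(list(c("h1", "h2", "h3")), locus = "IGH")
  p_l <- new_partition(list(c("l1", "l2")), locus = "IGK")
  # pretend the joint step split h1 from h2
  joint <- structure(list(
    pairs = new_partition(list("h1", "h2")),
    heavy = new_partition(list("h1", "h2"), locus = "IGH"),
    light = new_partition(list("l1", "l2"), locus = "IGK/IGL")),
    class = "joint_partition")
  out <- attach_unpaired(joint, p_h, p_l, pairmap, rec)
  expect_identical(canon_partition(out$heavy),
                   canon_partition(list("h1", c("h2", "h3"))))
  # a family with no paired members stays together ...
  p_h2 <- new_partition(list(c("h1", "h2"), "h3"), locus = "IGH")
  pairmap2 <- pairmap
  pairmap2$partner_id <- NA
  pairmap2$status <- "unpaired"
  joint2 <- structure(list(pairs = new_partition(list()),
                           heavy = new_partition(list(), locus = "IGH"),
                           light = new_partition(list(), locus = "IGK/IGL")),
                      class = "joint_partition")
  out2 <- attach_unpaired(joint2, p_h2, p_l, pairmap2, rec)
  expect_identical(canon_partition(out2$heavy),
                   canon_partition(list(c("h1", "h2"), "h3")))
  # ... and unpaired singletons remain singletons
  expect_true("h3" %in% unlist(out2$heavy$clusters))
})

test_that("bulk pairing fills clusters from their paired members", {
  set.seed(87)
  base <- random_seq(60)
  seqs <- c(base, vapply(1:4, function(i) mutate_at(base, 2), character(1)))
  rec <- data.frame(sequence_id = sprintf("h%d", 1:5), locus = "IGH",
                    sequence = seqs, stringsAsFactors = FALSE)
  pm <- data.frame(sequence_id = sprintf("h%d", 1:5),
                   partner_id = c("l9", NA, NA, NA, NA),
                   status = c("paired", rep("unpaired", 4)),
                   stringsAsFactors = FALSE)
  p_h <- new_partition(list(sprintf("h%d", 1:5)), locus = "IGH")
  p_l <- new_partition(list(), locus = "IGK")
  out <- bulk_pair(p_h, p_l, pm, rec)
  # the single paired member donates its partner to all bulk members
  expect_true(all(out$partner_id == "l9"))
  expect_equal(out$status, c("paired", rep("bulk_paired", 4)))
  # clusters without any paired sequence are left alone
  pm2 <- pm
  pm2$partner_id <- NA
  out2 <- bulk_pair(p_h, p_l, pm2, rec)
  expect_true(all(is.na(out2$partner_id)))
})

test_that("the exactly-correct bulk fraction equals the single-cell fraction", {
  cfg <- sim_config(n_events = 300, shm_mean = 0.10, rng_seed = 88,
                    family_size_model = list(model = "datalike"),
                    bulk_fraction = 0.8)
  sim <- simulate_paired_repertoire(cfg)
  ann <- annotate_repertoire(sim$records, sim$germline)
  p_h <- naive_hamming_partition(ann[ann$locus == "IGH", ], sim$germline)
  p_l <- combine_partitions(
    naive_hamming_partition(ann[ann$locus == "IGK", ], sim$germline),
    naive_hamming_partition(ann[ann$locus == "IGL", ], sim$germline))
  pm0 <- clean_pair_info(p_h, p_l, sim$records)
  out <- bulk_pair(p_h, p_l, pm0, sim$records)
  # never un-pairs
  was <- !is.na(pm0$partner_id)
  expect_true(all(!is.na(out$partner_id[was])))
  expect_identical(out$partner_id[was], pm0$partner_id[was])
  ps <- pairing_scores(out, sim$records, sim$events)
  expect_lt(abs(mean(ps$correct_seq) - (1 - 0.8)), 0.02)
})
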