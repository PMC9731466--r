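test_that("allele count probability converts mean alleles per gene", {
  expect_equal(allele_count_prob(1.0), 1.0)
  expect_equal(allele_count_prob(2.0), 0.0)
  expect_equal(allele_count_prob(1.33), 0.67) # p_1 solves p_1 + 2(1 - p_1) = n_a
  # algebraic identity p_1 = 2 - n_a across the domain
  for (na in seq(1, 2, by = 0.1))
    expect_equal(allele_count_prob(na), 2 - na, tolerance = 1e-12)
  expect_error(allele_count_prob(0.9), "1, 2")
  expect_error(allele_count_prob(2.1), "1, 2")
})

test_that("germline sets have the configured structure and prevalences", {
  set.seed(11)
  germ <- generate_germline_set(sim_config())
  gene_of <- sub("\\*.*$", "", germ$name)
  counts <- table(germ$locus, germ$region)
  # gene counts per region match the defaults
  expect_equal(length(unique(gene_of[germ$locus == "IGH" & germ$region == "V"])), 42L)
  expect_equal(length(unique(gene_of[germ$locus == "IGH" & germ$region == "D"])), 18L)
  expect_equal(length(unique(gene_of[germ$locus == "IGK" & germ$region == "J"])), 3L)
  expect_equal(length(unique(gene_of[germ$locus == "IGL" & germ$region == "J"])), 2L)
  # prevalences normalize and respect the minimum pairwise ratio
  for (loc in unique(germ$locus)) for (reg in unique(germ$region[germ$locus == loc])) {
    pv <- germ$prevalence[germ$locus == loc & germ$region == reg]
    expect_equal(sum(pv), 1, tolerance = 1e-9)
    expect_gte(min(pv) / max(pv), 0.1 * (1 - 1e-9))
  }
  # anchors conserved: Cys codon at V anchor, Trp/Phe at J anchor
  v <- germ[germ$region == "V", ]
  expect_true(all(substr(v$sequence, v$anchor + 1, v$anchor + 3) %in% c("TGT", "TGC")))
  j <- germ[germ$region == "J", ]
  expect_true(all(substr(j$sequence, j$anchor + 1, j$anchor + 3) %in% c("TGG", "TTT", "TTC")))
})

test_that("degenerate prevalence and allele-count settings behave as limits", {
  set.seed(3)
  cfg <- sim_config(min_prevalence_ratio = 1) # pseudo-counts all 1
  germ <- generate_germline_set(cfg)
  for (loc in unique(germ$locus)) for (reg in unique(germ$region[germ$locus == loc])) {
    pv <- germ$prevalence[germ$locus == loc & germ$region == reg]
    expect_true(all(abs(pv - pv[1]) < 1e-12))
  }
  # n_a = 1 forces exactly one allele per gene
  cfg1 <- sim_config(genes_per_region = list(IGK = c(V = 5L, J = 3L)),
                     alleles_per_gene = list(IGK = c(V = 1.0, J = 1.0)))
  g1 <- generate_germline_set(cfg1)
  expect_equal(sum(g1$locus == "IGK" & g1$region == "J"), 3L)
  expect_equal(sum(g1$locus == "IGK" & g1$region == "V"), 5L)
})

test_that("rearrangement draws genes by prevalence and assembles the naive", {
  set.seed(21)
  cfg <- no_junction_config()
  germ <- generate_germline_set(cfg)
  ev <- rearrange(germ, "IGH", cfg)
  vs <- germ$sequence[germ$name == ev$v_call]
  ds <- germ$sequence[germ$name == ev$d_call]
  js <- germ$sequence[germ$name == ev$j_call]
  expect_equal(ev$naive, paste0(vs, ds, js)) # zero deletions/insertions
  expect_equal(ev$cdr3_start, germ$anchor[germ$name == ev$v_call])
  expect_equal(ev$cdr3_start + ev$cdr3_length,
               nchar(ev$naive) - (nchar(js) - germ$anchor[germ$name == ev$j_call] - 3))
  # light chains have no D segment
  evl <- rearrange(germ, "IGK", sim_config())
  expect_true(is.na(evl$d_call))
  expect_null(evl$d_5p_del)

  # empirical V usage matches the prevalence vector (chi-square GoF)
  cfg2 <- sim_config(genes_per_region = list(IGK = c(V = 6L, J = 2L)),
                     alleles_per_gene = list(IGK = c(V = 1.0, J = 1.0)))
  g2 <- generate_germline_set(cfg2)
  draws <- replicate(10000, rearrange(g2, "IGK", cfg2)$v_call)
  vnames <- g2$name[g2$region == "V"]
  obs <- as.numeric(table(factor(draws, levels = vnames)))
  pv <- g2$prevalence[match(vnames, g2$name)]
  expect_gt(suppressWarnings(chisq.test(obs, p = pv)$p.value), 0.001)
})

test_that("tree models produce the advertised shapes", {
  set.seed(31)
  st <- generate_tree(list(model = "star"), 5)
  expect_equal(length(st$tip.label), 5L)
  expect_equal(st$Nnode, 1L) # every tip attached to one node
  expect_gt(st$root.edge, 0)

  for (i in 1:5) {
    bd <- generate_tree(list(model = "birth_death", lambda = 1, mu = 0.5), 50)
    expect_equal(length(bd$tip.label), 50L) # conditioned on tip count
    expect_true(all(bd$edge.length >= 0))
    expect_gt(bd$root.edge, 0)
  }

  # imbalance: sd of root-to-tip edge counts is 0 for star, > 0 for caterpillar
  edge_depth <- function(tr) {
    n <- length(tr$tip.label)
    d <- integer(n + tr$Nnode)
    tr <- ape::reorder.phylo(tr, "cladewise")
    for (e in seq_len(nrow(tr$edge)))
      d[tr$edge[e, 2]] <- d[tr$edge[e, 1]] + 1L
    d[seq_len(n)]
  }
  expect_equal(sd(edge_depth(generate_tree(list(model = "star"), 8))), 0)
  expect_gt(sd(edge_depth(generate_tree(list(model = "caterpillar"), 8))), 0)
  expect_error(generate_tree(list(model = "balanced"), 4), "unknown tree model")
})

test_that("mutation hits the target SHM fraction and shares ancestral mutations", {
  set.seed(41)
  naive <- random_seq(350)
  st <- generate_tree(list(model = "star"), 1000)
  leaves <- mutate_family(naive, st, 0.10)
  expect_equal(length(leaves), 1000L)
  frac <- vapply(leaves, function(s) hamming_chr(s, naive) / 350, numeric(1))
  expect_equal(mean(frac), 0.10, tolerance = 0.01)

  # zero SHM leaves everything untouched
  expect_true(all(mutate_family(naive, st, 0) == naive))

  # two leaves below a long shared branch share mutations; star leaves do not
  shared <- function(tree, reps = 20) {
    mean(replicate(reps, {
      lv <- mutate_family(naive, tree, 0.08)
      a <- strsplit(lv[["A"]], "")[[1]]
      b <- strsplit(lv[["B"]], "")[[1]]
      n0 <- strsplit(naive, "")[[1]]
      sum(a != n0 & a == b)
    }))
  }
  cherry <- generate_tree(list(model = "user_newick",
                               newick = "((A:0.05,B:0.05):2.0)root;"), 2)
  star2 <- generate_tree(list(model = "user_newick",
                              newick = "(A:1.0,B:1.0)root;"), 2)
  star2$root.edge <- 1e-6
  expect_gt(shared(cherry), shared(star2) + 1)
})

test_that("paired simulation wires droplets, candidates and truth together", {
  # one cell per droplet: exactly one candidate, the true partner
  cfg <- sim_config(n_events = 40, family_size_model = list(model = "geometric", mean = 2),
                    rng_seed = 5)
  sim <- simulate_paired_repertoire(cfg)
  r <- sim$records
  cands <- strsplit(r$paired_ids, ";")
  expect_true(all(lengths(cands) == 1L))
  expect_equal(unlist(cands), r$true_partner)
  # partner bijection and clone consistency across chains
  expect_equal(r$true_partner[match(r$true_partner, r$sequence_id)], r$sequence_id)
  expect_equal(r$clone_id, r$clone_id[match(r$true_partner, r$sequence_id)])
  # true heavy and light partitions group the same cells
  th <- true_partition(r, "heavy")
  tl <- true_partition(r, "light")
  cell_of <- setNames(r$cell_id, r$sequence_id)
  expect_identical(
    canon_partition(lapply(th$clusters, function(cl) unname(cell_of[cl]))),
    canon_partition(lapply(tl$clusters, function(cl) unname(cell_of[cl]))))

  # two cells per droplet (even cell count): every sequence lists all 3
  # co-droplet sequences, both chains
  cfg2 <- sim_config(n_events = 30, family_size_model = list(model = "fixed", k = 1),
                     cells_per_droplet = list(model = "fixed", k = 2),
                     rng_seed = 6)
  sim2 <- simulate_paired_repertoire(cfg2)
  expect_true(all(lengths(strsplit(sim2$records$paired_ids, ";")) == 3L))

  # fixed singleton families
  cfg3 <- sim_config(n_events = 100, family_size_model = list(model = "fixed", k = 1),
                     rng_seed = 7)
  sim3 <- simulate_paired_repertoire(cfg3)
  expect_equal(length(true_partition(sim3$records, "heavy")$clusters), 100L)
  expect_true(all(lengths(true_partition(sim3$records, "light")$clusters) == 1L))

  # byte-identical reruns under a fixed seed
  sim_a <- simulate_paired_repertoire(cfg)
  expect_identical(sim_a$records, sim$records)
  expect_identical(sim_a$events, sim$events)
})

test_that("bulk cells carry no droplet or pair info and dropout breaks partners", {
  cfg <- sim_config(n_events = 60, bulk_fraction = 0.5, dropout_fraction = 0.1,
                    rng_seed = 8)
  sim <- simulate_paired_repertoire(cfg)
  r <- sim$records
  expect_true(all(is.na(r$droplet_id[r$is_bulk])))
  expect_true(all(r$paired_ids[r$is_bulk] == ""))
  expect_gt(sum(r$is_bulk), 0)
  # dropped reads leave their partner with no true partner
  expect_true(any(is.na(r$true_partner)))
  expect_true(all(is.na(r$true_partner) | r$true_partner %in% r$sequence_id))
})
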