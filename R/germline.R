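# Synthetic germline sets and VDJ rearrangement.
#
# Germline alleles are synthesized rather than downloaded: each gene is a
# random nucleotide sequence of fixed region length (V 300 nt, D 20 nt heavy
# only, J 50 nt) with conserved CDR3 anchor codons (Cys near the V 3' end;
# Trp in heavy J, Phe in light J), and alleles of a gene differ from the base
# sequence by 1-3 point substitutions outside the anchors.  This preserves
# the gene/allele structure and CDR3 anchoring that the inference relies on.

V_LEN <- 300L
D_LEN <- 20L
J_LEN <- 50L
V_ANCHOR <- 288L # 0-based start of the conserved Cys codon (TGT/TGC)
J_ANCHOR <- 15L  # 0-based start of the conserved Trp/Phe codon

.default_genes_per_region <- list(
  IGH = c(V = 42L, D = 18L, J = 6L),
  IGK = c(V = 11L, J = 3L),
  IGL = c(V = 11L, J = 2L)
)

.default_alleles_per_gene <- list(
  IGH = c(V = 1.33, D = 1.2, J = 1.2),
  IGK = c(V = 1.1, J = 1.1),
  IGL = c(V = 1.1, J = 1.1)
)

# Geometric means for deletion/insertion lengths at each boundary; values
# are configurable and chosen to give the limited junctional diversity
# typical of each locus (light chains have much less than heavy).
.default_boundary_means <- list(
  IGH = c(v_3p_del = 3, d_5p_del = 4, d_3p_del = 4, j_5p_del = 4,
          vd_ins = 4, dj_ins = 4),
  IGK = c(v_3p_del = 2, j_5p_del = 2, vj_ins = 2),
  IGL = c(v_3p_del = 2, j_5p_del = 2, vj_ins = 2)
)

#' Simulation configuration
#'
#' Collects every parameter of the paired-repertoire simulator.  Defaults
#' reproduce the standard from-scratch study conditions: the germline set
#' sizes and mean alleles per gene of a diploid human-like repertoire, a
#' minimum pairwise allele prevalence ratio of 0.1, birth-death trees with
#' speciation rate 1 and extinction rate 0.5, JC69 mutation with four
#' discrete gamma rate categories, and a 2/3 kappa fraction for light chain
#' locus choice.
#'
#' @param n_events Number of rearrangement events (clonal families).
#' @param family_size_model List describing the family size distribution:
#'   `list(model = "fixed", k = )`, `list(model = "geometric", mean = )`
#'   (sizes on 1, 2, ... with the given mean), or `list(model = "datalike",
#'   singleton = 0.7, tail_p = 0.3)` - 70% singletons with a geometric tail
#'   on sizes 2, 3, ... (tail success probability `tail_p`, giving an
#'   overall mean family size of 2).
#' @param shm_mean Target mean fraction of nucleotides mutated per sequence.
#' @param tree_model List: `list(model = "birth_death", lambda = 1,
#'   mu = 0.5)`, `list(model = "star")`, `list(model = "caterpillar")`, or
#'   `list(model = "user_newick", newick = )`.
#' @param gamma_shape Shape of the discrete gamma distribution of per-site
#'   mutation rates (4 categories).
#' @param cells_per_droplet List: `list(model = "fixed", k = 1)` or
#'   `list(model = "poisson", mean = )` (truncated at 1).
#' @param dropout_fraction Probability that a chain read is lost.
#' @param bulk_fraction Fraction of cells emitted without pair info.
#' @param kappa_fraction Probability a light chain event uses IgK.
#' @param genes_per_region,alleles_per_gene Named lists (by locus) of named
#'   vectors (by region) giving gene counts and mean alleles per gene
#'   (each mean in \[1, 2\]).
#' @param min_prevalence_ratio Minimum desired pairwise allele prevalence
#'   ratio r_m in (0, 1].
#' @param boundary_means Named list (by locus) of geometric means for each
#'   deletion/insertion boundary.
#' @param rng_seed Integer seed; given an identical configuration including
#'   the seed, simulation output is byte-identical.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_events = 100L,
                       family_size_model = list(model = "geometric", mean = 3),
                       shm_mean = 0.10,
                       tree_model = list(model = "birth_death", lambda = 1, mu = 0.5),
                       gamma_shape = 0.35,
                       cells_per_droplet = list(model = "fixed", k = 1L),
                       dropout_fraction = 0,
                       bulk_fraction = 0,
                       kappa_fraction = 2 / 3,
                       genes_per_region = .default_genes_per_region,
                       alleles_per_gene = .default_alleles_per_gene,
                       min_prevalence_ratio = 0.1,
                       boundary_means = .default_boundary_means,
                       rng_seed = NULL) {
  stopifnot(n_events >= 1)
  if (shm_mean < 0 || shm_mean >= 0.7)
    stop("shm_mean must be in [0, 0.7): JC69 Hamming fractions saturate at 0.75")
  if (min_prevalence_ratio <= 0 || min_prevalence_ratio > 1)
    stop("min_prevalence_ratio must be in (0, 1]")
  if (bulk_fraction < 0 || bulk_fraction > 1)
    stop("bulk_fraction must be in [0, 1]")
  if (dropout_fraction < 0 || dropout_fraction >= 1)
    stop("dropout_fraction must be in [0, 1)")
  for (locus in names(alleles_per_gene)) {
    na <- alleles_per_gene[[locus]]
    if (any(na < 1 | na > 2))
      stop("alleles_per_gene means must be in [1, 2]")
    if (any(genes_per_region[[locus]] < 1))
      stop("genes_per_region counts must be >= 1")
  }
  structure(list(
    n_events = as.integer(n_events),
    family_size_model = family_size_model,
    shm_mean = shm_mean,
    tree_model = tree_model,
    gamma_shape = gamma_shape,
    cells_per_droplet = cells_per_droplet,
    dropout_fraction = dropout_fraction,
    bulk_fraction = bulk_fraction,
    kappa_fraction = kappa_fraction,
    genes_per_region = genes_per_region,
    alleles_per_gene = alleles_per_gene,
    min_prevalence_ratio = min_prevalence_ratio,
    boundary_means = boundary_means,
    rng_seed = rng_seed
  ), class = "sim_config")
}

#' Probability of a single allele from the mean alleles per gene
#'
#' Converts the mean number of alleles per gene `n_a` (between 1 and 2,
#' representing the prevalence of heterozygosity) to the probability `p_1`
#' of a gene carrying one allele, via `p_1 = f / (1 + f)` with
#' `f = (n_a - 2) / (1 - n_a)`; `p_2 = 1 - p_1`.  The endpoints are handled
#' as limits: `n_a = 1` gives `p_1 = 1` and `n_a = 2` gives `p_1 = 0`.
#'
#' @param n_a Mean alleles per gene, in \[1, 2\].
#' @return `p_1`, the probability of one allele.
#' @export
allele_count_prob <- function(n_a) {
  if (!is.numeric(n_a) || length(n_a) != 1L || is.na(n_a) || n_a < 1 || n_a > 2)
    stop("n_a must be a single number in [1, 2]")
  if (n_a == 1) return(1)
  if (n_a == 2) return(0)
  f <- (n_a - 2) / (1 - n_a)
  f / (1 + f)
}

.make_allele_name <- function(locus, region, gene_i, allele_i) {
  sprintf("%s%s%d*%02d", locus, region, gene_i, allele_i)
}

.synth_gene <- function(locus, region) {
  if (region == "V") {
    s <- strsplit(random_nt(V_LEN), "", fixed = TRUE)[[1]]
    anchor <- sample(c("TGT", "TGC"), 1L) # conserved Cys
    s[(V_ANCHOR + 1L):(V_ANCHOR + 3L)] <- strsplit(anchor, "", fixed = TRUE)[[1]]
    list(seq = paste(s, collapse = ""), anchor = V_ANCHOR)
  } else if (region == "J") {
    s <- strsplit(random_nt(J_LEN), "", fixed = TRUE)[[1]]
    anchor <- if (locus == "IGH") "TGG" else sample(c("TTT", "TTC"), 1L)
    s[(J_ANCHOR + 1L):(J_ANCHOR + 3L)] <- strsplit(anchor, "", fixed = TRUE)[[1]]
    list(seq = paste(s, collapse = ""), anchor = J_ANCHOR)
  } else {
    list(seq = random_nt(D_LEN), anchor = NA_integer_)
  }
}

.mutate_allele <- function(seq, anchor) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  avoid <- if (!is.na(anchor)) (anchor + 1L):(anchor + 3L) else integer()
  ok <- setdiff(seq_along(s), avoid)
  pos <- sample(ok, sample(1:3, 1L))
  for (p in pos) s[p] <- sample(setdiff(NT, s[p]), 1L)
  paste(s, collapse = "")
}

#' Generate a synthetic germline set
#'
#' For each locus and region, iteratively draws an allele count for each
#' gene via [allele_count_prob()], synthesizes the gene and its alleles,
#' then assigns allele prevalence frequencies by drawing integer pseudo
#' counts uniformly at random in the interval \[1, 1/r_m\] (rounded down)
#' and normalizing within the region, which bounds the pairwise prevalence
#' ratio below by roughly r_m.
#'
#' @param cfg A [sim_config()].
#' @return A data frame of class `germline_set` with one row per allele:
#'   `name`, `locus`, `region`, `sequence`, `anchor` (0-based start of the
#'   CDR3 anchor codon; NA for D), `prevalence`.
#' @export
generate_germline_set <- function(cfg = sim_config()) {
  rows <- list()
  for (locus in names(cfg$genes_per_region)) {
    counts <- cfg$genes_per_region[[locus]]
    for (region in names(counts)) {
      n_genes <- counts[[region]]
      p1 <- allele_count_prob(cfg$alleles_per_gene[[locus]][[region]])
      reg_rows <- list()
      for (g in seq_len(n_genes)) {
        n_alleles <- 1L + rbinom(1L, 1L, 1 - p1)
        base <- .synth_gene(locus, region)
        seqs <- base$seq
        if (n_alleles == 2L) seqs <- c(seqs, .mutate_allele(base$seq, base$anchor))
        for (a in seq_len(n_alleles)) {
          reg_rows[[length(reg_rows) + 1L]] <- data.frame(
            name = .make_allele_name(locus, region, g, a),
            locus = locus, region = region,
            sequence = seqs[a], anchor = base$anchor,
            stringsAsFactors = FALSE)
        }
      }
      reg <- do.call(rbind, reg_rows)
      pseudo <- floor(runif(nrow(reg), 1, 1 / cfg$min_prevalence_ratio))
      reg$prevalence <- pseudo / sum(pseudo)
      rows[[length(rows) + 1L]] <- reg
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("germline_set", "data.frame")
  out
}

#' @export
print.germline_set <- function(x, ...) {
  cat(sprintf("<germline_set> %d alleles over %d loci\n",
              nrow(x), length(unique(x$locus))))
  print(table(x$locus, x$region))
  invisible(x)
}

.sample_allele <- function(germ, locus, region) {
  g <- germ[germ$locus == locus & germ$region == region, , drop = FALSE]
  if (!nrow(g)) stop("germline set has no ", locus, " ", region, " alleles")
  g[sample.int(nrow(g), 1L, prob = g$prevalence), , drop = FALSE]
}

# Draw a geometric length, rejecting values above `cap` (bounded retries);
# caps keep the CDR3 anchor codons intact so the junction stays defined.
.draw_capped <- function(mean, cap) {
  for (i in 1:100) {
    x <- rgeom_mean(1L, mean)
    if (x <= cap) return(x)
  }
  stop("failed to draw a deletion length within the gene after 100 tries")
}

#' Simulate one naive rearrangement
#'
#' Draws V, (D,) and J alleles according to their prevalence frequencies,
#' deletion and insertion lengths from geometric distributions with the
#' configured boundary means, and uniform non-templated insertion bases;
#' light loci have no D segment.  CDR3 bounds run from the V anchor codon
#' to the end of the J anchor codon (0-based half-open).
#'
#' @param germ A [generate_germline_set()] result.
#' @param locus One of "IGH", "IGK", "IGL".
#' @param cfg A [sim_config()] (for the boundary means).
#' @return List with `naive`, `v_call`, `d_call` (NA for light), `j_call`,
#'   deletion/insertion lengths, `cdr3_start`, `cdr3_length`, `junction`.
#' @export
rearrange <- function(germ, locus, cfg = sim_config()) {
  if (!locus %in% germ$locus) stop("germline set does not cover locus ", locus)
  bm <- cfg$boundary_means[[locus]]
  v <- .sample_allele(germ, locus, "V")
  j <- .sample_allele(germ, locus, "J")
  lv <- nchar(v$sequence)
  lj <- nchar(j$sequence)
  v_del <- .draw_capped(bm[["v_3p_del"]], lv - (v$anchor + 3L))
  j_del <- .draw_capped(bm[["j_5p_del"]], j$anchor)
  v_part <- substr(v$sequence, 1L, lv - v_del)
  j_part <- substr(j$sequence, j_del + 1L, lj)
  if (locus == "IGH") {
    d <- .sample_allele(germ, locus, "D")
    ld <- nchar(d$sequence)
    repeat {
      d5 <- rgeom_mean(1L, bm[["d_5p_del"]])
      d3 <- rgeom_mean(1L, bm[["d_3p_del"]])
      if (d5 + d3 <= ld) break
    }
    d_part <- substr(d$sequence, d5 + 1L, ld - d3)
    vd <- random_nt(rgeom_mean(1L, bm[["vd_ins"]]))
    dj <- random_nt(rgeom_mean(1L, bm[["dj_ins"]]))
    naive <- paste0(v_part, vd, d_part, dj, j_part)
    calls <- list(d_call = d$name, d_5p_del = d5, d_3p_del = d3,
                  vd_ins = vd, dj_ins = dj)
  } else {
    vj <- random_nt(rgeom_mean(1L, bm[["vj_ins"]]))
    naive <- paste0(v_part, vj, j_part)
    calls <- list(d_call = NA_character_, vj_ins = vj)
  }
  cdr3_start <- v$anchor
  cdr3_end <- nchar(naive) - (lj - (j$anchor + 3L))
  c(list(naive = naive, locus = locus,
         v_call = v$name, j_call = j$name,
         v_3p_del = v_del, j_5p_del = j_del,
         cdr3_start = cdr3_start,
         cdr3_length = cdr3_end - cdr3_start,
         junction = substr(naive, cdr3_start + 1L, cdr3_end)),
    calls)
}
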