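# Phylogenies for clonal families and tree-based somatic hypermutation.

#' Generate a clonal family tree
#'
#' Returns a rooted tree with `n_leaves` tips, positive branch lengths and a
#' nonzero root branch above the MRCA (the naive ancestor sits below the
#' root branch, so shared mutations can occur before the first split).
#'
#' Models: `star` attaches every tip directly to one node (zero imbalance);
#' `birth_death` draws a constant-rate birth-death tree conditioned on the
#' tip count (speciation rate `lambda`, extinction rate `mu`, via
#' [ape::rphylo()]); `caterpillar` is the maximally imbalanced (pectinate)
#' topology with exponential(1) branch lengths; `user_newick` parses the
#' supplied string.  Branch length units are arbitrary: mutation scales
#' branches to the target SHM fraction (see [mutate_family()]).
#'
#' @param model A list, e.g. `list(model = "star")`; see [sim_config()].
#' @param n_leaves Number of tips (>= 1).
#' @return An [ape::phylo] object with a `root.edge`.
#' @export
generate_tree <- function(model, n_leaves) {
  stopifnot(n_leaves >= 1)
  name <- if (is.character(model)) model else model$model
  if (name == "user_newick") {
    tr <- ape::read.tree(text = model$newick)
    if (is.null(tr$root.edge)) tr$root.edge <- mean(tr$edge.length)
    return(tr)
  }
  if (n_leaves == 1L) {
    tr <- structure(list(
      edge = matrix(c(2L, 1L), 1L, 2L),
      edge.length = 1,
      tip.label = "t1",
      Nnode = 1L,
      root.edge = 0.5), class = "phylo")
    return(tr)
  }
  tr <- switch(name,
    star = {
      # a short root branch: star trees are the testbed for per-leaf
      # convergence, so the shared (perfectly correlated) mutation mass
      # above the MRCA is kept small relative to the tip branches
      n <- as.integer(n_leaves)
      structure(list(
        edge = cbind(rep(n + 1L, n), seq_len(n)),
        edge.length = rep(1, n),
        tip.label = paste0("t", seq_len(n)),
        Nnode = 1L,
        root.edge = 0.1), class = "phylo")
    },
    birth_death = {
      bt <- ape::rphylo(n_leaves, birth = model$lambda %||% 1,
                        death = model$mu %||% 0.5)
      bt$root.edge <- mean(bt$edge.length)
      bt
    },
    caterpillar = {
      n <- as.integer(n_leaves)
      # pectinate: internal node k subtends tip k and the next internal node
      edge <- matrix(0L, 2L * n - 2L, 2L)
      row <- 1L
      for (k in seq_len(n - 1L)) {
        node <- n + k
        edge[row, ] <- c(node, k); row <- row + 1L
        child <- if (k < n - 1L) n + k + 1L else n
        edge[row, ] <- c(node, child); row <- row + 1L
      }
      structure(list(
        edge = edge,
        edge.length = rexp(nrow(edge)),
        tip.label = paste0("t", seq_len(n)),
        Nnode = n - 1L,
        root.edge = rexp(1)), class = "phylo")
    },
    stop("unknown tree model: ", name)
  )
  tr
}

# Root-to-tip distances including the root branch.
.tip_depths <- function(tree) {
  n <- length(tree$tip.label)
  if (n == 1L) return(tree$root.edge + tree$edge.length[1])
  d <- ape::node.depth.edgelength(tree)[seq_len(n)]
  d + tree$root.edge
}

#' Mutate a naive sequence down a clonal family tree
#'
#' Simulates somatic hypermutation under the JC69 substitution model with
#' four discrete gamma rate categories.  Branch lengths are rescaled so
#' that the expected fraction of nucleotides differing between a leaf and
#' the naive sequence (the per-sequence SHM fraction, a p-distance, which
#' accounts for multiple hits) equals `shm_mean` on average over leaves.
#' Mutations are placed along branches, so leaves sharing ancestral
#' branches share mutations.
#'
#' @param naive Naive nucleotide sequence (string).
#' @param tree A tree from [generate_tree()].
#' @param shm_mean Target mean mutated fraction per leaf, in \[0, 0.7).
#' @param gamma_shape Shape of the discrete gamma site-rate distribution.
#' @param n_categories Number of rate categories.
#' @return Character vector of leaf sequences named by tip label.
#' @export
mutate_family <- function(naive, tree, shm_mean, gamma_shape = 0.35,
                          n_categories = 4L) {
  stopifnot(shm_mean >= 0, shm_mean < 0.7)
  L <- nchar(naive)
  v0 <- seq_to_int(naive)
  ntips <- length(tree$tip.label)
  if (shm_mean == 0) {
    out <- rep(naive, ntips)
    names(out) <- tree$tip.label
    return(out)
  }
  rates <- discrete_gamma_rates(gamma_shape, n_categories)
  depths <- .tip_depths(tree)
  z <- sample.int(n_categories, L, replace = TRUE) # site categories
  site_rate <- rates[z]
  # calibrate the branch scale against the realized site-rate composition
  # (categories are drawn once per family), so the expected p-distance
  # naive -> leaf, averaged over leaves and sites, equals shm_mean
  pdist <- function(s) {
    mean(vapply(depths, function(d)
      mean(0.75 * (1 - exp(-4 / 3 * s * site_rate * d))), numeric(1)))
  }
  upper <- 1
  while (pdist(upper) < shm_mean && upper < 1e8) upper <- upper * 2
  s <- uniroot(function(x) pdist(x) - shm_mean, c(0, upper), tol = 1e-10)$root
  evolve <- function(v, t) {
    p <- 0.75 * (1 - exp(-4 / 3 * s * site_rate * t))
    hit <- runif(L) < p
    nm <- sum(hit)
    if (nm) v[hit] <- (v[hit] - 1L + sample.int(3L, nm, replace = TRUE)) %% 4L + 1L
    v
  }
  if (ntips == 1L) {
    out <- int_to_seq(evolve(v0, tree$root.edge + tree$edge.length[1]))
    names(out) <- tree$tip.label
    return(out)
  }
  tree <- ape::reorder.phylo(tree, "cladewise")
  nnode <- tree$Nnode
  seqs <- vector("list", ntips + nnode)
  root <- ntips + 1L
  seqs[[root]] <- evolve(v0, tree$root.edge)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    seqs[[child]] <- evolve(seqs[[par]], tree$edge.length[e])
  }
  out <- vapply(seqs[seq_len(ntips)], int_to_seq, character(1))
  names(out) <- tree$tip.label
  out
}
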