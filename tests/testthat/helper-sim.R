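# Shared fixtures and independent oracles, built in code at test time.

# canonical form of a partition for order-insensitive comparison
canon_partition <- function(p) {
  cl <- if (inherits(p, "clonal_partition")) p$clusters else p
  sort(vapply(cl, function(x) paste(sort(x), collapse = ","), character(1)))
}

small_germline <- function(seed = 101) {
  set.seed(seed)
  generate_germline_set(sim_config())
}

# zero-junction configuration: naive = V + (D) + J verbatim
no_junction_config <- function(...) {
  bm <- list(
    IGH = c(v_3p_del = 0, d_5p_del = 0, d_3p_del = 0, j_5p_del = 0,
            vd_ins = 0, dj_ins = 0),
    IGK = c(v_3p_del = 0, j_5p_del = 0, vj_ins = 0),
    IGL = c(v_3p_del = 0, j_5p_del = 0, vj_ins = 0))
  sim_config(boundary_means = bm, ...)
}

# independent per-sequence precision/sensitivity oracle (plain loops)
oracle_partition_scores <- function(inferred, truth) {
  inf <- if (inherits(inferred, "clonal_partition")) inferred$clusters else inferred
  tru <- if (inherits(truth, "clonal_partition")) truth$clusters else truth
  ids <- unlist(tru)
  prec <- numeric(length(ids))
  sens <- numeric(length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    I <- inf[[which(vapply(inf, function(cl) id %in% cl, logical(1)))]]
    T_ <- tru[[which(vapply(tru, function(cl) id %in% cl, logical(1)))]]
    ov <- length(intersect(I, T_))
    prec[k] <- ov / length(I)
    sens[k] <- ov / length(T_)
  }
  p <- mean(prec)
  s <- mean(sens)
  c(precision = p, sensitivity = s, f1 = 2 * p * s / (p + s))
}

# every set partition of 1..n (restricted growth strings)
all_set_partitions <- function(n) {
  ids <- letters[seq_len(n)]
  res <- list()
  rec <- function(assign, k) {
    i <- length(assign) + 1L
    if (i > n) {
      res[[length(res) + 1L]] <<- unname(split(ids, assign))
      return()
    }
    for (g in seq_len(k + 1L)) rec(c(assign, g), max(k, g))
  }
  rec(integer(), 0L)
  res
}

# hand-built annotation rows for partition-level tests
fake_ann <- function(ids, naives, cdr3_start, cdr3_length,
                     v_call = "IGHV1*01", j_call = "IGHJ1*01",
                     seqs = naives, locus = "IGH") {
  data.frame(sequence_id = ids, locus = locus, sequence = seqs,
             v_call = v_call, d_call = NA_character_, j_call = j_call,
             naive_sequence = naives, cdr3_start = cdr3_start,
             cdr3_length = cdr3_length, shm_fraction = 0,
             annot_ok = TRUE, stringsAsFactors = FALSE)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

mutate_at <- function(seq, k) {
  s <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(s), k)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

hamming_chr <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
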