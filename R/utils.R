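# Internal sequence-coding helpers.  Nucleotides are coded A=1 C=2 G=3 T=4;
# 0 is padding in aligned matrices.

NT <- c("A", "C", "G", "T")

.nt_lookup <- local({
  x <- integer(128)
  x[utf8ToInt("A")] <- 1L
  x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L
  x[utf8ToInt("T")] <- 4L
  x
})

seq_to_int <- function(s) .nt_lookup[utf8ToInt(s)]

int_to_seq <- function(v) intToUtf8(c(65L, 67L, 71L, 84L)[v])

random_nt <- function(n) intToUtf8(sample(c(65L, 67L, 71L, 84L), n, replace = TRUE))

# Stack integer-coded sequences into a matrix, left-aligned, 0-padded.
int_mat_left <- function(ints, width = max(lengths(ints))) {
  m <- matrix(0L, length(ints), width)
  for (i in seq_along(ints)) {
    v <- ints[[i]]
    m[i, seq_along(v)] <- v
  }
  m
}

# Right-aligned variant (row ends at the final column).
int_mat_right <- function(ints, width = max(lengths(ints))) {
  m <- matrix(0L, length(ints), width)
  for (i in seq_along(ints)) {
    v <- ints[[i]]
    m[i, (width - length(v) + 1L):width] <- v
  }
  m
}

# Geometric draw with the given mean on {0, 1, 2, ...}.
rgeom_mean <- function(n, mean) {
  if (mean <= 0) return(rep(0L, n))
  rgeom(n, 1 / (1 + mean))
}

# Mean relative rates of k equal-probability discrete gamma categories with
# the given shape (mean rate 1), the standard discretization used for
# among-site rate variation.
discrete_gamma_rates <- function(shape, k = 4L) {
  b <- qgamma(seq(0, 1, length.out = k + 1), shape, rate = shape)
  k * (pgamma(b[-1], shape + 1, rate = shape) -
         pgamma(b[-(k + 1)], shape + 1, rate = shape))
}

# Normalized Hamming distance between two naive sequences aligned at their
# CDR3 start; flanks are compared over the overlapping length only.
anchored_naive_dist <- function(naive1, cdr3_start1, naive2, cdr3_start2) {
  v1 <- seq_to_int(naive1)
  v2 <- seq_to_int(naive2)
  off <- cdr3_start1 - cdr3_start2
  if (off >= 0) {
    a <- v1[(off + 1L):length(v1)]
    b <- v2
  } else {
    a <- v1
    b <- v2[(-off + 1L):length(v2)]
  }
  ov <- min(length(a), length(b))
  if (ov < 1L) return(1)
  cpp_hamming(a[seq_len(ov)], b[seq_len(ov)]) / ov
}

# Statistical mode with deterministic (lexicographic) tie-break.
mode_chr <- function(x) {
  tab <- table(x)
  names(tab)[which.max(tab)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
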