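# Naive reference implementations used as independent oracles. Written as
# plain loops over the definitions, deliberately sharing no code with the
# package internals.

naive_composition <- function(codes) {
  out <- numeric(7)
  for (g in 0:6) out[g + 1] <- 100 * sum(codes == g) / length(codes)
  out
}

naive_transition <- function(codes) {
  out <- numeric(21)
  n <- length(codes)
  if (n < 2) return(out)
  k <- 0
  for (g in 0:5) for (h in (g + 1):6) {
    k <- k + 1
    cnt <- 0
    for (i in 1:(n - 1)) {
      if ((codes[i] == g && codes[i + 1] == h) ||
          (codes[i] == h && codes[i + 1] == g)) cnt <- cnt + 1
    }
    out[k] <- 100 * cnt / (n - 1)
  }
  out
}

naive_distribution <- function(codes) {
  n <- length(codes)
  out <- numeric(35)
  for (g in 0:6) {
    pos <- which(codes == g)
    m <- length(pos)
    if (m == 0) next
    vals <- numeric(5)
    vals[1] <- 100 * pos[1] / n
    qs <- c(0.25, 0.5, 0.75, 1)
    for (j in 1:4) {
      r <- floor(qs[j] * m + 0.5)
      if (r < 1) r <- 1
      vals[j + 1] <- 100 * pos[r] / n
    }
    out[(5 * g + 1):(5 * g + 5)] <- vals
  }
  out
}

naive_triad_counts <- function(codes) {
  f <- integer(343)
  n <- length(codes)
  if (n >= 3) {
    for (i in 1:(n - 2)) {
      idx <- codes[i] + 7L * codes[i + 1] + 49L * codes[i + 2]
      f[idx + 1L] <- f[idx + 1L] + 1L
    }
  }
  f
}

naive_triad_norm <- function(codes) {
  f <- naive_triad_counts(codes)
  if (max(f) == 0) return(numeric(343))
  (f - min(f)) / max(f)
}

# brute-force AUC over all positive-negative score pairs, ties at 1/2
naive_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# random valid amino-acid sequence
random_protein_seq <- function(len) {
  paste(sample(names(lctdppi::aa_groups), len, replace = TRUE),
        collapse = "")
}

# the reference sequence worked through in the descriptor definitions
worked_seq <- "VCCPPVCVVCPPVCVPVPPCCV"
worked_codes <- as.integer(strsplit("0112201001220102022110", "")[[1]])

# small fast network configuration for model behaviour tests
tiny_mlp <- function(input_dim, ...) {
  lctdppi::mlp_config(input_dim, hidden = c(16L, 8L, 4L), dropout = 0,
                      batch_size = 64L, ...)
}
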