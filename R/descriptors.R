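# Descriptor blocks: composition (C), transition (T), distribution (D) and
# conjoint triad (CT) over the 7-group reduced alphabet, assembled into the
# CT / LD / LCTD feature vectors for proteins and pairs.

# transition pair -> index lookup, lexicographic (0,1),(0,2),...,(5,6)
.trans_index <- local({
  m <- matrix(NA_integer_, 7, 7)
  k <- 0L
  for (g in 0:5) for (h in (g + 1):6) {
    k <- k + 1L
    m[g + 1L, h + 1L] <- k
  }
  m
})

.dist_quantiles <- c(0.25, 0.5, 0.75, 1)

#' Composition of a region
#'
#' Percentage of the region's residues that belong to each of the seven
#' groups, ordered by group code 0..6. Sums to 100 for any non-empty
#' region.
#'
#' @param codes Integer vector of group codes (one region).
#' @return Numeric vector of 7 percentages.
#' @export
composition <- function(codes) {
  n <- length(codes)
  if (n == 0L) stop("empty region", call. = FALSE)
  100 * tabulate(codes + 1L, 7L) / n
}

#' Transitions of a region
#'
#' For each unordered group pair \{g, h\} with g < h, the percentage of
#' adjacent residue positions at which the code switches between g and h in
#' either direction, out of the region's `length - 1` adjacent positions.
#' Pairs are ordered lexicographically (0,1), (0,2), ..., (5,6). A
#' single-residue region has no adjacent positions and yields the zero
#' vector.
#'
#' @param codes Integer vector of group codes (one region).
#' @return Numeric vector of 21 percentages.
#' @export
transition <- function(codes) {
  n <- length(codes)
  if (n == 0L) stop("empty region", call. = FALSE)
  if (n == 1L) return(numeric(21))
  a <- codes[-n]
  b <- codes[-1L]
  changed <- a != b
  idx <- .trans_index[cbind(pmin(a, b) + 1L, pmax(a, b) + 1L)][changed]
  100 * tabulate(idx, 21L) / (n - 1L)
}

#' Distribution of a region
#'
#' For each group (order 0..6) the positions, as percentages of the region
#' length, at which the first, 25%, 50%, 75% and 100% occurrences of that
#' group are found. The ordinal of the q-quantile occurrence among the n
#' residues of the group is `max(1, floor(q*n + 0.5))` (round half up);
#' the "first" anchor is always ordinal 1. Groups absent from the region
#' contribute five zeros. Values are concatenated group-major.
#'
#' @param codes Integer vector of group codes (one region).
#' @return Numeric vector of 35 percentages in \[0, 100\].
#' @export
distribution <- function(codes) {
  n <- length(codes)
  if (n == 0L) stop("empty region", call. = FALSE)
  out <- numeric(35)
  for (g in 0:6) {
    pos <- which(codes == g)
    m <- length(pos)
    if (m == 0L) next
    r <- c(1L, pmax(1L, as.integer(floor(.dist_quantiles * m + 0.5))))
    out[(5L * g + 1L):(5L * g + 5L)] <- 100 * pos[r] / n
  }
  out
}

#' Conjoint-triad counts and normalized values of a region
#'
#' Every window of three consecutive group codes (c1, c2, c3) is a triad
#' with index `c1 + 7*c2 + 49*c3` in 0..342. Raw counts f are normalized to
#' `d_i = (f_i - min(f)) / max(f)`; when no window fits (region shorter
#' than 3) all values are zero. Setting `scale = "minmax"` divides by
#' `max(f) - min(f)` instead, a documented variant that is off by default.
#'
#' @param codes Integer vector of group codes (one region, any length).
#' @param scale Normalization: `"max"` (default) or `"minmax"`.
#' @return List with integer vector `f` (343 counts) and numeric vector
#'   `d` (343 normalized values in \[0, 1\]).
#' @examples
#' ct <- conjoint_triad(encode_sequence("VCCPPVCVVCPPVCVPVPPCCV"))
#' ct$f[113 + 1]  # triad (1,2,2) occurs twice
#' @export
conjoint_triad <- function(codes, scale = c("max", "minmax")) {
  scale <- match.arg(scale)
  n <- length(codes)
  if (n < 3L) {
    return(list(f = integer(343), d = numeric(343)))
  }
  idx <- codes[1:(n - 2L)] + 7L * codes[2:(n - 1L)] + 49L * codes[3:n]
  f <- tabulate(idx + 1L, 343L)
  hi <- max(f)
  lo <- min(f)
  d <- if (hi == 0L) {
    numeric(343)
  } else if (scale == "max") {
    (f - lo) / hi
  } else {
    if (hi == lo) numeric(343) else (f - lo) / (hi - lo)
  }
  list(f = f, d = d)
}

#' Triad index of a group triple
#'
#' @param c1,c2,c3 Group codes in 0..6 of three consecutive residues.
#' @return Index in 0..342: `c1 + 7*c2 + 49*c3`.
#' @examples
#' triad_index(1, 0, 0)  # 1
#' triad_index(0, 1, 0)  # 7
#' triad_index(3, 1, 0)  # 10
#' @export
triad_index <- function(c1, c2, c3) {
  stopifnot(all(c(c1, c2, c3) %in% 0:6))
  as.integer(c1 + 7L * c2 + 49L * c3)
}

# C(7) + T(21) + D(35) for one region
.ctd_block <- function(codes) {
  c(composition(codes), transition(codes), distribution(codes))
}

.as_codes <- function(x) {
  if (inherits(x, "EncodedSequence") || is.numeric(x)) as.integer(x)
  else as.integer(encode_sequence(x))
}

#' Whole-sequence conjoint-triad feature vector (CT)
#'
#' The 343 normalized triad values of the entire sequence, ordered by
#' ascending triad index.
#'
#' @param x An `EncodedSequence`, integer code vector, or sequence string.
#' @param scale Normalization passed to [conjoint_triad()].
#' @return Numeric feature vector of length 343.
#' @export
ct_vector <- function(x, scale = "max") {
  codes <- .as_codes(x)
  v <- conjoint_triad(codes, scale = scale)$d
  names(v) <- feature_names("CT")
  v
}

#' Local descriptor feature vector (LD)
#'
#' For each of the ten regions A..J in order, the concatenation
#' C(7), T(21), D(35); 630 values in total.
#'
#' @inheritParams ct_vector
#' @return Numeric feature vector of length 630.
#' @export
ld_vector <- function(x) {
  codes <- .as_codes(x)
  scheme <- split_regions(length(codes))
  v <- unlist(lapply(scheme, function(r) .ctd_block(region_codes(codes, r))),
              use.names = FALSE)
  names(v) <- feature_names("LD")
  v
}

#' Local conjoint triad descriptor feature vector (LCTD)
#'
#' For each of the ten regions A..J in order, the concatenation C(7),
#' T(21), D(35), CT(343); 10 x 406 = 4060 values in total. Triad windows
#' never span region boundaries: each region is treated as an independent
#' subsequence.
#'
#' @inheritParams ct_vector
#' @return Numeric feature vector of length 4060.
#' @export
lctd_vector <- function(x, scale = "max") {
  codes <- .as_codes(x)
  scheme <- split_regions(length(codes))
  v <- unlist(lapply(scheme, function(r) {
    rc <- region_codes(codes, r)
    c(.ctd_block(rc), conjoint_triad(rc, scale = scale)$d)
  }), use.names = FALSE)
  names(v) <- feature_names("LCTD")
  v
}

#' Per-protein feature vector by method
#'
#' @inheritParams ct_vector
#' @param method `"CT"`, `"LD"` or `"LCTD"` (case-insensitive).
#' @return Numeric feature vector of length 343, 630 or 4060.
#' @export
protein_features <- function(x, method = c("LCTD", "CT", "LD"), scale = "max") {
  method <- toupper(method)
  method <- match.arg(method)
  switch(method,
    CT = ct_vector(x, scale = scale),
    LD = ld_vector(x),
    LCTD = lctd_vector(x, scale = scale)
  )
}

#' Feature vector of a protein pair
#'
#' Concatenation of the first protein's vector then the second's, in the
#' order given; dimensions 686 (CT), 1260 (LD) or 8120 (LCTD).
#'
#' @param xA,xB Encoded sequences (or strings) of the two partners.
#' @param method Descriptor method, see [protein_features()].
#' @param scale Normalization passed to [conjoint_triad()].
#' @return Numeric feature vector for the pair.
#' @export
pair_features <- function(xA, xB, method = "LCTD", scale = "max") {
  vA <- protein_features(xA, method, scale = scale)
  vB <- protein_features(xB, method, scale = scale)
  names(vA) <- paste0("p1.", names(vA))
  names(vB) <- paste0("p2.", names(vB))
  c(vA, vB)
}

#' Column names of a per-protein feature vector
#'
#' @param method `"CT"`, `"LD"` or `"LCTD"`.
#' @return Character vector naming every feature, e.g. `"A.T.g0g1"` or
#'   `"J.CT.t310"`.
#' @export
feature_names <- function(method = c("LCTD", "CT", "LD")) {
  method <- match.arg(toupper(method), c("LCTD", "CT", "LD"))
  comp <- paste0("C.g", 0:6)
  tpair <- unlist(lapply(0:5, function(g)
    paste0("T.g", g, "g", (g + 1):6)))
  dist <- as.vector(t(outer(paste0("D.g", 0:6),
                            c("first", "q25", "q50", "q75", "q100"),
                            paste, sep = ".")))
  triads <- expand.grid(c1 = 0:6, c2 = 0:6, c3 = 0:6)  # index-major order
  ct <- paste0("CT.t", triads$c1, triads$c2, triads$c3)
  regions <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J")
  switch(method,
    CT = ct,
    LD = unlist(lapply(regions, function(r)
      paste0(r, ".", c(comp, tpair, dist)))),
    LCTD = unlist(lapply(regions, function(r)
      paste0(r, ".", c(comp, tpair, dist, ct))))
  )
}

#' Dimension of a feature vector
#'
#' @param method `"CT"`, `"LD"` or `"LCTD"`.
#' @param scope `"protein"` or `"pair"`.
#' @return Integer dimension (343/686, 630/1260 or 4060/8120).
#' @export
feature_dim <- function(method = c("LCTD", "CT", "LD"),
                        scope = c("pair", "protein")) {
  method <- match.arg(toupper(method), c("LCTD", "CT", "LD"))
  scope <- match.arg(scope)
  d <- switch(method, CT = 343L, LD = 630L, LCTD = 4060L)
  if (scope == "pair") 2L * d else d
}

#' Feature matrix for a list of interaction pairs
#'
#' Encodes every distinct protein once, then assembles one row per pair
#' (partner A's features followed by partner B's).
#'
#' @param proteome Named list of [protein_record()] objects (or named
#'   character vector of sequences).
#' @param pairs `data.frame` with columns `idA`, `idB` and optionally
#'   `label`.
#' @param method Descriptor method, see [protein_features()].
#' @param scale Normalization passed to [conjoint_triad()].
#' @param min_length Proteins shorter than this are rejected (the dataset
#'   construction rule; descriptor computation itself only needs 8).
#' @return List with `x` (numeric matrix, one row per pair, named
#'   columns), `label` (integer vector or NULL), and `pairs`.
#' @export
encode_pairs <- function(proteome, pairs, method = "LCTD", scale = "max",
                         min_length = 50L) {
  if (is.character(proteome)) {
    proteome <- mapply(protein_record, names(proteome), proteome,
                       SIMPLIFY = FALSE)
  }
  ids <- unique(c(pairs$idA, pairs$idB))
  missing <- setdiff(ids, names(proteome))
  if (length(missing) > 0L) {
    stop("pair list references unknown protein(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  lens <- vapply(proteome[ids], function(p) nchar(p$sequence), integer(1))
  if (any(lens < min_length)) {
    short <- ids[lens < min_length][1L]
    stop("protein '", short, "' has fewer than ", min_length,
         " residues", call. = FALSE)
  }
  feats <- lapply(proteome[ids], function(p)
    protein_features(encode_sequence(p), method, scale = scale))
  d <- feature_dim(method, "protein")
  x <- matrix(0, nrow = nrow(pairs), ncol = 2L * d)
  colnames(x) <- c(paste0("p1.", feature_names(method)),
                   paste0("p2.", feature_names(method)))
  for (i in seq_len(nrow(pairs))) {
    x[i, ] <- c(feats[[pairs$idA[i]]], feats[[pairs$idB[i]]])
  }
  rownames(x) <- paste(pairs$idA, pairs$idB, sep = "--")
  list(
    x = x,
    label = if ("label" %in% names(pairs)) as.integer(pairs$label) else NULL,
    pairs = pairs,
    method = toupper(method)
  )
}
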