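# Synthetic proteomes and labelled interaction datasets. Emulates the
# benchmark construction: proteins of >= 50 residues, per-protein
# subcellular-localization labels, positive pairs carrying a learnable
# sequence signal (an implanted compatible motif pair), and negative pairs
# drawn only between proteins with differing localization and never
# overlapping the positive set.

.aa_by_group <- local({
  g <- split(names(aa_groups), aa_groups)
  names(g) <- as.character(0:6)
  g
})

# compatible motif pair, fixed at the group level so every descriptor can
# see it: partner A alternates groups 1/5, partner B groups 1/6 -- both
# rare under a uniform residue background
.motif_groups <- function(motif_length, partner = c("A", "B")) {
  partner <- match.arg(partner)
  base <- if (partner == "A") c(1L, 5L) else c(1L, 6L)
  rep_len(base, motif_length)
}

#' Synthetic dataset configuration
#'
#' Defaults emulate a budding-yeast-scale proteome and a balanced
#' benchmark: 6000 proteins with uniform lengths 50--500, four
#' localization classes, 1000 positive and 1000 negative pairs, a
#' 6-residue compatible motif pair implanted into 90% of positives, and a
#' uniform residue background.
#'
#' @param n_proteins Number of proteins in the proteome.
#' @param length_range `c(min, max)` sequence lengths; `min` must be at
#'   least 50, mirroring the benchmark's short-protein exclusion.
#' @param length_dist `"uniform"` or `"lognormal"` (log-normal truncated
#'   to the range).
#' @param n_localizations Number of subcellular-localization classes.
#' @param n_pos,n_neg Number of positive / negative pairs.
#' @param motif_length Length in residues of the implanted motif.
#' @param motif_strength Probability in \[0, 1\] that a positive pair
#'   carries the compatible motif pair; 0 gives a null dataset with no
#'   learnable signal.
#' @param background Named numeric vector of residue probabilities over
#'   the 20 standard letters (default uniform); need not be normalized.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 6000L,
                             length_range = c(50L, 500L),
                             length_dist = c("uniform", "lognormal"),
                             n_localizations = 4L,
                             n_pos = 1000L,
                             n_neg = 1000L,
                             motif_length = 6L,
                             motif_strength = 0.9,
                             background = NULL,
                             seed = 1L) {
  length_dist <- match.arg(length_dist)
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), names(aa_groups))
  }
  stopifnot(n_proteins >= 2L, length(length_range) == 2L,
            length_range[1] <= length_range[2],
            n_localizations >= 1L, n_pos >= 0L, n_neg >= 0L,
            motif_length >= 3L, motif_strength >= 0, motif_strength <= 1,
            all(names(background) %in% names(aa_groups)),
            all(background >= 0), sum(background) > 0)
  if (length_range[1] < 50L) {
    stop("minimum sequence length must be at least 50", call. = FALSE)
  }
  if (length_range[1] < motif_length) {
    stop("motif longer than the shortest protein", call. = FALSE)
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    length_range = as.integer(length_range),
    length_dist = length_dist,
    n_localizations = as.integer(n_localizations),
    n_pos = as.integer(n_pos),
    n_neg = as.integer(n_neg),
    motif_length = as.integer(motif_length),
    motif_strength = motif_strength,
    background = background / sum(background),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

.draw_lengths <- function(n, cfg) {
  lo <- cfg$length_range[1]
  hi <- cfg$length_range[2]
  if (cfg$length_dist == "uniform" || lo == hi) {
    sample(lo:hi, n, replace = TRUE)
  } else {
    meanlog <- mean(log(c(lo, hi)))
    sdlog <- (log(hi) - log(lo)) / 4
    len <- round(stats::rlnorm(n, meanlog, sdlog))
    pmin(pmax(len, lo), hi)
  }
}

#' Generate a synthetic proteome
#'
#' Sequences are drawn residue-wise from the background distribution,
#' lengths from the configured distribution, and localization labels
#' uniformly at random; everything is reproducible from the seed.
#'
#' @param cfg A [synthetic_config()].
#' @return Named list of [protein_record()] objects with ids
#'   `P000001, ...` and localization labels `loc1, ...`.
#' @export
generate_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    lens <- .draw_lengths(cfg$n_proteins, cfg)
    letters20 <- names(cfg$background)
    locs <- sample(paste0("loc", seq_len(cfg$n_localizations)),
                   cfg$n_proteins, replace = TRUE)
    ids <- sprintf("P%06d", seq_len(cfg$n_proteins))
    recs <- vector("list", cfg$n_proteins)
    for (i in seq_len(cfg$n_proteins)) {
      seq_i <- paste(
        sample(letters20, lens[i], replace = TRUE, prob = cfg$background),
        collapse = ""
      )
      recs[[i]] <- protein_record(ids[i], seq_i, locs[i])
    }
    names(recs) <- ids
    recs
  })
}

# replace motif_length residues at a random position with letters drawn
# from the motif's group pattern
.implant_motif <- function(rec, groups) {
  L <- nchar(rec$sequence)
  start <- sample.int(L - length(groups) + 1L, 1L)
  letters_in <- vapply(groups, function(g) {
    members <- .aa_by_group[[as.character(g)]]
    members[sample.int(length(members), 1L)]
  }, character(1))
  s <- strsplit(rec$sequence, "", fixed = TRUE)[[1L]]
  s[start:(start + length(groups) - 1L)] <- letters_in
  rec$sequence <- paste(s, collapse = "")
  rec
}

#' Generate labelled interaction pairs
#'
#' Every protein appears in at most one pair, positive or negative — the
#' standard protein-identity control: without it, proteins shared between
#' training and held-out pairs let a classifier transfer memorized
#' per-protein features across folds and bias cross-validated estimates
#' in either direction. Positive pairs receive the compatible motif pair
#' (implanted into both partners' sequences at random positions) with
#' probability `motif_strength`. Negative pairs are drawn only between
#' proteins with differing localization labels and, by disjointness, can
#' never coincide with a positive pair or contain an implanted protein.
#'
#' @param proteome Named list from [generate_proteome()].
#' @param cfg The same [synthetic_config()].
#' @return List with `pairs` (`data.frame`: `idA`, `idB`, `label`) and
#'   `proteome` (the input proteome with motifs implanted).
#' @export
generate_pairs <- function(proteome, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- length(proteome)
  ids <- names(proteome)
  need <- 2L * (cfg$n_pos + cfg$n_neg)
  if (need > n) {
    stop("need at least ", need, " proteins for ", cfg$n_pos,
         " positive and ", cfg$n_neg, " negative protein-disjoint pairs",
         call. = FALSE)
  }
  locs <- vapply(proteome, `[[`, character(1), "localization")
  if (cfg$n_neg > 0L && length(unique(locs)) < 2L) {
    stop("negative pairs need at least two localization classes",
         call. = FALSE)
  }
  withr::with_seed(cfg$seed + 1L, {
    chosen <- sample(ids, 2L * cfg$n_pos)
    idA <- chosen[seq_len(cfg$n_pos)]
    idB <- chosen[cfg$n_pos + seq_len(cfg$n_pos)]
    implant <- stats::runif(cfg$n_pos) < cfg$motif_strength
    for (i in which(implant)) {
      proteome[[idA[i]]] <- .implant_motif(
        proteome[[idA[i]]], .motif_groups(cfg$motif_length, "A"))
      proteome[[idB[i]]] <- .implant_motif(
        proteome[[idB[i]]], .motif_groups(cfg$motif_length, "B"))
    }
    pool <- sample(setdiff(ids, chosen))
    # maximum number of differing-localization pairs in the pool:
    # min(floor(P/2), P - largest class)
    pool_cls <- table(locs[pool])
    capacity <- min(length(pool) %/% 2L,
                    length(pool) - max(pool_cls, 0L))
    if (cfg$n_neg > capacity) {
      stop("cannot satisfy ", cfg$n_neg, " cross-localization ",
           "protein-disjoint negative pairs: localization mix supports ",
           "at most ", capacity, call. = FALSE)
    }
    neg_a <- character(cfg$n_neg)
    neg_b <- character(cfg$n_neg)
    for (got in seq_len(cfg$n_neg)) {
      cls <- table(locs[pool])
      # when one class holds over half the remaining pool, it must supply
      # one partner of every further pair; otherwise draw freely
      if (max(cls) * 2L > length(pool)) {
        major <- names(cls)[which.max(cls)]
        xs <- pool[locs[pool] == major]
        ys <- pool[locs[pool] != major]
      } else {
        xs <- pool
        ys <- NULL  # chosen after x
      }
      x <- xs[sample.int(length(xs), 1L)]
      if (is.null(ys)) ys <- pool[locs[pool] != locs[x] & pool != x]
      y <- ys[sample.int(length(ys), 1L)]
      pool <- setdiff(pool, c(x, y))
      neg_a[got] <- x
      neg_b[got] <- y
    }
    pairs <- data.frame(
      idA = c(idA, neg_a),
      idB = c(idB, neg_b),
      label = rep(c(1L, 0L), c(cfg$n_pos, cfg$n_neg))
    )
  })
  list(pairs = pairs, proteome = proteome)
}

#' Simulate a complete labelled PPI dataset
#'
#' Convenience wrapper: [generate_proteome()] then [generate_pairs()].
#'
#' @param cfg A [synthetic_config()].
#' @return List with `proteome` (motifs implanted) and `pairs`.
#' @export
simulate_ppi_dataset <- function(cfg = synthetic_config()) {
  proteome <- generate_proteome(cfg)
  generate_pairs(proteome, cfg)
}
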