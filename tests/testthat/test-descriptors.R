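test_that("worked example: composition, transition, distribution", {
  expect_equal(composition(worked_codes),
               c(36.36, 31.82, 31.82, 0, 0, 0, 0), tolerance = 1e-4)
  tr <- transition(worked_codes)
  expect_equal(tr[[1]], 100 * 7 / 21, tolerance = 1e-9)  # 0<->1
  expect_equal(tr[[2]], 100 * 5 / 21, tolerance = 1e-9)  # 0<->2
  expect_equal(tr[[7]], 100 * 3 / 21, tolerance = 1e-9)  # 1<->2
  d <- distribution(worked_codes)
  expect_equal(d[6:10], c(9.09, 13.64, 45.45, 63.64, 95.45),
               tolerance = 1e-3)
  expect_equal(d[11:15], c(18.18, 22.73, 54.55, 72.73, 86.36),
               tolerance = 1e-3)
  expect_equal(d[1:5], c(4.55, 27.27, 40.91, 68.18, 100.00),
               tolerance = 1e-3)
})

test_that("descriptor blocks agree with naive recomputation", {
  set.seed(13)
  for (rep in 1:25) {
    codes <- sample(0:6, sample(1:80, 1), replace = TRUE)
    expect_equal(composition(codes), naive_composition(codes),
                 tolerance = 1e-12)
    expect_equal(transition(codes), naive_transition(codes),
                 tolerance = 1e-12)
    expect_equal(distribution(codes), naive_distribution(codes),
                 tolerance = 1e-12)
    ct <- conjoint_triad(codes)
    expect_identical(ct$f, naive_triad_counts(codes))
    expect_equal(ct$d, naive_triad_norm(codes), tolerance = 1e-12)
  }
})

test_that("descriptor edge cases and bounds", {
  expect_equal(composition(rep(5L, 4))[6], 100)
  expect_equal(sum(composition(rep(5L, 4))), 100)
  expect_equal(composition(0:6), rep(100 / 7, 7), tolerance = 1e-12)
  # one transition, denominator 1
  t05 <- transition(c(0L, 5L))
  expect_equal(t05[[5]], 100)
  expect_equal(sum(t05), 100)
  # single residue: no adjacent positions
  expect_equal(transition(3L), numeric(21))
  expect_error(composition(integer(0)), "empty")
  set.seed(5)
  for (rep in 1:10) {
    codes <- sample(0:6, 40, replace = TRUE)
    expect_equal(sum(composition(codes)), 100, tolerance = 1e-9)
    expect_lte(sum(transition(codes)), 100 + 1e-9)
    d <- distribution(codes)
    expect_true(all(d >= 0 & d <= 100))
    # the five anchors of each present group are non-decreasing
    for (g in 0:6) {
      vals <- d[(5 * g + 1):(5 * g + 5)]
      if (any(vals > 0)) expect_true(all(diff(vals) >= -1e-12))
    }
  }
})

test_that("triad indexing and counting", {
  expect_identical(triad_index(1, 0, 0), 1L)
  expect_identical(triad_index(0, 1, 0), 7L)
  expect_identical(triad_index(3, 1, 0), 10L)
  ct <- conjoint_triad(worked_codes)
  expect_identical(ct$f[113 + 1], 2L)      # triad (1,2,2)
  expect_identical(sum(ct$f), 20L)         # L - 2 windows
  expect_equal(ct$d[113 + 1], 1)           # (2 - 0) / 2
  # no window fits in a length-2 region
  short <- conjoint_triad(c(0L, 1L))
  expect_identical(sum(short$f), 0L)
  expect_identical(short$d, numeric(343))
  # "AAA" -> triad (0,0,0) once
  aaa <- conjoint_triad(as.integer(encode_sequence("AAA")))
  expect_identical(aaa$f[1], 1L)
  expect_equal(aaa$d[1], 1)
  expect_equal(sum(aaa$d), 1)
})

test_that("default max normalization vs the min-max variant", {
  codes <- c(0L, 0L, 0L, 0L, 1L, 2L, 0L)
  f <- conjoint_triad(codes)$f
  expect_equal(conjoint_triad(codes)$d, (f - min(f)) / max(f))
  expect_equal(conjoint_triad(codes, scale = "minmax")$d,
               (f - min(f)) / (max(f) - min(f)))
})

test_that("feature vectors have the advertised dimensions", {
  set.seed(3)
  s <- random_protein_seq(73)
  expect_length(ct_vector(s), 343)
  expect_length(ld_vector(s), 630)
  expect_length(lctd_vector(s), 4060)
  expect_length(pair_features(s, random_protein_seq(55), "CT"), 686)
  expect_length(pair_features(s, random_protein_seq(55), "LD"), 1260)
  expect_length(pair_features(s, random_protein_seq(55), "LCTD"), 8120)
  expect_identical(feature_dim("CT", "protein"), 343L)
  expect_identical(feature_dim("LD", "pair"), 1260L)
  expect_identical(feature_dim("LCTD", "pair"), 8120L)
  expect_length(feature_names("LCTD"), 4060)
  expect_error(ld_vector("ACDEFGH"), "too short")  # L = 7
})

test_that("region blocks equal naive recomputation on extracted substrings", {
  set.seed(101)
  regions <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J")
  for (rep in 1:20) {
    len <- sample(8:500, 1)
    codes <- as.integer(encode_sequence(random_protein_seq(len)))
    scheme <- split_regions(len)
    ld <- ld_vector(codes)
    lctd <- lctd_vector(codes)
    for (k in seq_along(regions)) {
      r <- scheme[[k]]
      sub <- codes[(r[1] + 1):r[2]]
      block <- c(naive_composition(sub), naive_transition(sub),
                 naive_distribution(sub))
      expect_equal(unname(ld[(63 * (k - 1) + 1):(63 * k)]), block,
                   tolerance = 1e-9)
      expect_equal(unname(lctd[(406 * (k - 1) + 1):(406 * (k - 1) + 63)]),
                   block, tolerance = 1e-9)
      expect_equal(
        unname(lctd[(406 * (k - 1) + 64):(406 * k)]),
        naive_triad_norm(sub), tolerance = 1e-9
      )
      # triad conservation within the region
      expect_identical(sum(naive_triad_counts(sub)),
                       max(0L, length(sub) - 2L))
    }
    expect_true(all(is.finite(lctd)))
    expect_true(all(lctd >= 0 & lctd <= 100))
  }
})

test_that("LD is embedded in LCTD: zeroing triad sub-blocks recovers LD", {
  set.seed(77)
  codes <- as.integer(encode_sequence(random_protein_seq(120)))
  lctd <- lctd_vector(codes)
  ctd_idx <- as.vector(vapply(0:9, function(k) 406L * k + 1:63,
                              integer(63)))
  expect_equal(unname(lctd[ctd_idx]), unname(ld_vector(codes)),
               tolerance = 1e-12)
})

test_that("pair vectors concatenate in input order", {
  set.seed(19)
  a <- random_protein_seq(60)
  b <- random_protein_seq(90)
  ab <- pair_features(a, b, "CT")
  ba <- pair_features(b, a, "CT")
  expect_equal(unname(ab[1:343]), unname(ba[344:686]))
  expect_equal(unname(ab[344:686]), unname(ba[1:343]))
  aa <- pair_features(a, a, "CT")
  expect_equal(unname(aa[1:343]), unname(aa[344:686]))
})

test_that("encode_pairs builds the matrix and enforces the length rule", {
  set.seed(23)
  prot <- list(
    p1 = protein_record("p1", random_protein_seq(60)),
    p2 = protein_record("p2", random_protein_seq(80)),
    p3 = protein_record("p3", random_protein_seq(49))
  )
  pairs <- data.frame(idA = c("p1", "p2"), idB = c("p2", "p1"),
                      label = c(1L, 0L))
  enc <- encode_pairs(prot, pairs, method = "LD")
  expect_identical(dim(enc$x), c(2L, 1260L))
  expect_identical(enc$label, c(1L, 0L))
  expect_equal(unname(enc$x[1, 1:630]), unname(enc$x[2, 631:1260]))
  short <- data.frame(idA = "p3", idB = "p1", label = 1L)
  expect_error(encode_pairs(prot, short), "fewer than 50")
  expect_silent(encode_pairs(prot, short, min_length = 8))
  unknown <- data.frame(idA = "p9", idB = "p1", label = 1L)
  expect_error(encode_pairs(prot, unknown), "unknown")
})
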