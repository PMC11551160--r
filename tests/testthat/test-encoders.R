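test_that("k-mer composition counts sliding windows", {
  v <- encode_kmer("AAAA", 2)
  expect_length(v, 16)
  expect_equal(unname(v["kmer:AA"]), 1)
  expect_equal(sum(v), 1, tolerance = 1e-12)

  v <- encode_kmer("ACGU", 2)
  expect_equal(unname(v[c("kmer:AC", "kmer:CG", "kmer:GU")]), rep(1 / 3, 3))
  expect_equal(sum(v != 0), 3)

  expect_length(encode_kmer(random_rna(41), 3), 64)
  expect_error(encode_kmer("AC", 3), "shorter")
})

test_that("reverse complement is the A<->U, C<->G involution", {
  expect_equal(reverse_complement("ACGU"), "ACGU")
  expect_equal(reverse_complement("AAAA"), "UUUU")
  set.seed(21)
  for (i in 1:20) {
    s <- random_rna(sample(5:30, 1))
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
  rs <- reverse_complement(rna_sequence("id1", "AACG"))
  expect_s3_class(rs, "rna_sequence")
  expect_equal(rs$residues, "CGUU")
})

test_that("canonical RC k-mer classes collapse to the expected counts", {
  expect_equal(canonical_rc_kmers(1), c("A", "C"))
  expect_length(canonical_rc_kmers(2), 10)
  # brute force: count equivalence classes {w, rc(w)} directly
  words3 <- apply(expand.grid(rep(list(c("A","C","G","U")), 3)), 1, paste0,
                  collapse = "")
  classes <- unique(vapply(words3, function(w) {
    paste(sort(c(w, reverse_complement(w))), collapse = "|")
  }, ""))
  expect_length(canonical_rc_kmers(3), length(classes))
  expect_length(canonical_rc_kmers(3), 32)
})

test_that("RC k-mer composition is strand-agnostic; plain k-mer is not", {
  v <- encode_rc_kmer("AAAA", 2)
  expect_length(v, 10)
  expect_equal(unname(v["rckmer:AA"]), 1)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  set.seed(31)
  for (i in 1:10) {
    s <- random_rna(25)
    expect_equal(encode_rc_kmer(s, 2),
                 encode_rc_kmer(reverse_complement(s), 2))
  }
  # counterexample: plain k-mer composition is orientation-sensitive
  s <- "AAAACGU"
  expect_false(isTRUE(all.equal(encode_kmer(s, 2),
                                encode_kmer(reverse_complement(s), 2))))
})

test_that("pseudo di/tri composition equals plain composition up to naming", {
  set.seed(41)
  for (i in 1:5) {
    s <- random_rna(41)
    expect_equal(unname(encode_pse_dnc(s)), unname(encode_kmer(s, 2)))
    expect_equal(unname(encode_pse_tnc(s)), unname(encode_kmer(s, 3)))
  }
  expect_length(encode_pse_dnc("ACGU"), 16)
  expect_length(encode_pse_tnc("ACGUA"), 64)
  expect_equal(unname(encode_pse_dnc("CCCC")["psednc:CC"]), 1)
  expect_equal(unname(encode_pse_tnc("GGGG")["psetnc:GGG"]), 1)
})

test_that("property tables are complete and standardized", {
  di <- default_di_properties()
  tri <- default_tri_properties()
  expect_equal(nrow(di$values), 16)
  expect_equal(ncol(di$values), 6)
  expect_equal(nrow(tri$values), 64)
  expect_equal(ncol(tri$values), 2)
  for (tab in list(di, tri)) {
    for (p in tab$property_names) {
      v <- tab$values[, p]
      expect_equal(mean(v), 0, tolerance = 1e-9)
      expect_equal(sqrt(mean((v - mean(v))^2)), 1, tolerance = 1e-9)
    }
  }
})

test_that("property profiles are positional lookups", {
  di <- default_di_properties()
  p <- property_profile("AAAA", di, "roll")
  expect_length(p, 3)
  expect_true(all(p == di$values["AA", "roll"]))
  expect_length(property_profile(random_rna(41), default_tri_properties(),
                                 "twist"), 39)
  expect_error(property_profile("ACGU", di, "bogus"), "unknown property")
})

test_that("covariance encoders have the published dimensions and vanish on homopolymers", {
  cfg <- encoder_config()
  homo <- strrep("A", 12)
  expect_length(encode_tac(homo, cfg), 4)
  expect_length(encode_tcc(homo, cfg), 4)
  expect_length(encode_dcc(homo, cfg), 60)
  expect_true(all(encode_tac(homo, cfg) == 0))
  expect_true(all(encode_tcc(homo, cfg) == 0))
  expect_true(all(encode_dcc(homo, cfg) == 0))
  expect_error(encode_tac("ACGU", cfg), "at least 5")
  expect_error(encode_dcc("ACG", cfg), "at least 4")
})

test_that("covariance encoders match the brute-force double-loop oracle", {
  cfg <- encoder_config()
  set.seed(51)
  for (i in 1:25) {
    s <- random_rna(sample(8:20, 1))
    tac <- encode_tac(s, cfg)
    for (u in cfg$tri_properties$property_names) {
      for (l in 1:2) {
        expect_equal(unname(tac[sprintf("tac:%s@lag%d", u, l)]),
                     oracle_lagged_cov(s, cfg$tri_properties, u, u, l),
                     tolerance = 1e-12)
      }
    }
    tcc <- encode_tcc(s, cfg)
    expect_equal(unname(tcc["tcc:roll~twist@lag1"]),
                 oracle_lagged_cov(s, cfg$tri_properties, "roll", "twist", 1),
                 tolerance = 1e-12)
    expect_equal(unname(tcc["tcc:twist~roll@lag2"]),
                 oracle_lagged_cov(s, cfg$tri_properties, "twist", "roll", 2),
                 tolerance = 1e-12)
    dcc <- encode_dcc(s, cfg)
    expect_equal(unname(dcc["dcc:rise~tilt@lag1"]),
                 oracle_lagged_cov(s, cfg$di_properties, "rise", "tilt", 1),
                 tolerance = 1e-12)
    expect_equal(unname(dcc["dcc:twist~shift@lag2"]),
                 oracle_lagged_cov(s, cfg$di_properties, "twist", "shift", 2),
                 tolerance = 1e-12)
  }
})

test_that("cross-covariance is generally asymmetric in the property pair", {
  cfg <- encoder_config()
  set.seed(61)
  diffs <- vapply(1:10, function(i) {
    s <- random_rna(15)
    v <- encode_tcc(s, cfg)
    abs(v["tcc:roll~twist@lag1"] - v["tcc:twist~roll@lag1"])
  }, numeric(1))
  expect_gt(max(diffs), 1e-6)
})

test_that("encoders are pure and the dimensional contract totals 174", {
  dims <- encoder_dimensions()
  expect_equal(unname(dims), c(16L, 10L, 16L, 64L, 4L, 4L, 60L))
  expect_equal(sum(dims), 174L)
  s <- random_rna(41)
  expect_identical(encode_hybrid_one(s), encode_hybrid_one(s))
})
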