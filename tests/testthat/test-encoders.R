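test_that("feature dimensionalities match the scheme definitions", {
  seq <- "ACDEFGHIKLMNPQRSTVWYA"  # L = 21
  dims <- c(
    AAC = length(encode_kmer(seq, 1)),
    DPC = length(encode_kmer(seq, 2)),
    TPC = length(encode_kmer(seq, 3)),
    PAAC = length(encode_paac(seq)),
    CKSAAP = length(suppressWarnings(encode_cksaap(seq))),
    GAAC = length(encode_gaac(seq, 1)),
    GDPC = length(encode_gaac(seq, 2)),
    GTPC = length(encode_gaac(seq, 3)),
    CTRIAD = length(encode_ctriad(seq)),
    CTDC = length(encode_ctd(seq, "C")),
    CTDT = length(encode_ctd(seq, "T")),
    CTDD = length(encode_ctd(seq, "D")),
    AAINDEX = length(encode_aaindex(seq))
  )
  expect_equal(dims, c(AAC = 20L, DPC = 400L, TPC = 8000L, PAAC = 25L,
                       CKSAAP = 2400L, GAAC = 5L, GDPC = 25L, GTPC = 125L,
                       CTRIAD = 343L, CTDC = 39L, CTDT = 39L, CTDD = 195L,
                       AAINDEX = 531L))
  expect_equal(length(encode_eaac("ACDEFG", 5, L_max = 10)), 120L)
  expect_equal(length(encode_binary("AC", 4)), 80L)
  expect_equal(length(encode_zscale(seq, L_max = 25)), 125L)
  expect_equal(length(encode_blosum62(seq, L_max = 25)), 500L)
})

test_that("k-mer composition follows count/(L-k+1) and normalizes", {
  v <- encode_kmer("AAA", 2)
  expect_equal(unname(v["AA"]), 1.0)
  expect_equal(sum(v), 1.0)

  v3 <- encode_kmer("ACDG", 3)
  expect_equal(unname(v3[c("ACD", "CDG")]), c(0.5, 0.5))
  expect_equal(sum(v3 != 0), 2L)

  expect_error(encode_kmer("AC", 3), "shorter")

  # order invariance of AAC
  expect_equal(encode_kmer("WYKAC", 1), encode_kmer("CAKYW", 1))
})

test_that("CKSAAP blocks count gapped pairs and the g0 block equals DPC", {
  v <- encode_cksaap("ACA", k_max = 1)
  expect_equal(unname(v[c("g0.AC", "g0.CA")]), c(0.5, 0.5))
  expect_equal(unname(v["g1.AA"]), 1.0)
  expect_equal(sum(v != 0), 3L)

  set.seed(42)
  for (i in 1:10) {
    s <- paste0(sample(aa_alphabet(), sample(9:25, 1), replace = TRUE),
                collapse = "")
    ck <- suppressWarnings(encode_cksaap(s, 5))
    expect_equal(unname(ck[paste0("g0.", names(encode_kmer(s, 2)))]),
                 unname(encode_kmer(s, 2)))
  }

  expect_warning(encode_cksaap("ACA", k_max = 2), "zero block")
})

test_that("grouped composition uses the five physicochemical classes", {
  expect_equal(unname(encode_gaac("GGGG", 1)["g1"]), 1.0)
  v <- encode_gaac("KD", 1)
  expect_equal(unname(v[c("g3", "g4")]), c(0.5, 0.5))
  v2 <- encode_gaac("KDKD", 2)
  expect_equal(unname(v2[c("g3g4", "g4g3")]), c(2 / 3, 1 / 3))
  expect_equal(sum(v2), 1.0)
  groups <- gaac_groups()
  expect_setequal(unlist(groups), aa_alphabet())
})

test_that("conjoint triads normalize over L-2 consecutive triples", {
  v <- encode_ctriad("AAA")
  expect_equal(sum(v), 1.0)
  expect_equal(sum(v != 0), 1L)
  # AVKD: A,V -> g1, K -> g5, D -> g6
  v2 <- encode_ctriad("AVKD")
  expect_equal(unname(v2[c("g1g1g5", "g1g5g6")]), c(0.5, 0.5))
  expect_error(encode_ctriad("AC"), "L >= 3")
  expect_setequal(unlist(ctriad_groups()), aa_alphabet())
})

test_that("CTD composition and transition behave on homopolymers and sum correctly", {
  cc <- encode_ctd("AAAAA", "C")
  # per property exactly one group has fraction 1
  expect_equal(sum(cc), 13)
  expect_true(all(cc %in% c(0, 1)))
  expect_equal(sum(encode_ctd("AAAAA", "T")), 0)
  expect_error(encode_ctd("A", "T"), "L >= 2")
  # groups partition the alphabet for every property
  for (p in ctd_groups())
    expect_setequal(unlist(strsplit(p, "")), aa_alphabet())
  # CTDC triple per property sums to one for arbitrary sequences
  cc2 <- encode_ctd("WYKACDMPQR", "C")
  expect_equal(sum(cc2), 13)
})

test_that("CTD distribution reports occurrence-position percentiles", {
  # ACACA under hydrophobicity_PRAM900101: A in group 2, C in group 3
  v <- encode_ctd("ACACA", "D")
  pre <- "hydrophobicity_PRAM900101."
  # independent enumeration: A at 1,3,5; C at 2,4; L = 5
  pos_a <- c(1, 3, 5); pos_c <- c(2, 4)
  expect_equal(unname(v[paste0(pre, "g2.p", c(0, 25, 50, 75, 100))]),
               100 * pos_a[c(1, ceiling(3 * c(.25, .5, .75)), 3)] / 5)
  expect_equal(unname(v[paste0(pre, "g3.p", c(0, 25, 50, 75, 100))]),
               100 * pos_c[c(1, ceiling(2 * c(.25, .5, .75)), 2)] / 5)
  expect_true(all(v[paste0(pre, "g1.p", c(0, 25, 50, 75, 100))] == 0))
})

test_that("PAAC reduces to residue frequencies at lam 0 and matches a brute-force correlation factor", {
  v0 <- encode_paac("ACDEFG", lam = 0)
  expect_equal(unname(v0), unname(encode_kmer("ACDEFG", 1)))

  v <- encode_paac("ACDEFG", lam = 1, w = 0.05)
  expect_equal(length(v), 21L)
  # brute force over the 5 adjacent pairs using the bundled properties
  props <- paac_properties()
  z <- t(apply(props, 1, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))))
  chars <- strsplit("ACDEFG", "")[[1]]
  theta1 <- mean(vapply(1:5, function(i)
    mean((z[, chars[i + 1]] - z[, chars[i]])^2), 0))
  denom <- 1 + 0.05 * theta1
  expect_equal(unname(v["theta1"]), 0.05 * theta1 / denom)
  expect_equal(unname(v["A"]), (1 / 6) / denom)
  expect_error(encode_paac("ACD", lam = 5), "L > lam")
})

test_that("binary encoding one-hots residues with zero padding", {
  expect_equal(unname(encode_binary("A", 1)), c(1, rep(0, 19)))
  expect_equal(unname(encode_binary("Y", 1)), c(rep(0, 19), 1))
  v <- encode_binary("AC", 4)
  expect_equal(sum(v[1:40]), 2)
  expect_true(all(v[41:80] == 0))
  expect_error(encode_binary("ACD", 2), "exceeds L_max")
  expect_equal(sum(encode_binary("ACD", 2, truncate = TRUE)), 2)
})

test_that("EAAC computes sliding-window compositions with padding", {
  v <- encode_eaac("AAAAA", window = 5, L_max = 5)
  expect_equal(unname(v["w1.A"]), 1.0)
  expect_equal(sum(v), 1.0)
  v2 <- encode_eaac("AAAAC", window = 5)
  expect_equal(unname(v2[c("w1.A", "w1.C")]), c(4 / 5, 1 / 5))
  v3 <- encode_eaac("AAAAAC", window = 5, L_max = 10)
  expect_equal(length(v3), 120L)
  expect_true(all(v3[grep("w[3-6]", names(v3))] == 0))
  expect_error(encode_eaac("AC", window = 5), "window")
})

test_that("AAindex encoding is the per-index mean over residues", {
  tab <- aaindex_table()[1:3, ]
  expect_equal(unname(encode_aaindex("AAAA", tab)), unname(tab[, "A"]))
  expect_equal(unname(encode_aaindex("AC", tab)),
               unname((tab[, "A"] + tab[, "C"]) / 2))
  expect_equal(length(encode_aaindex("ACD", tab)), 3L)
  expect_false(anyNA(aaindex_table()))
})

test_that("BLOSUM62 and z-scale encodings use the published tables with padding", {
  m <- blosum62_matrix()
  expect_equal(m["A", "A"], 4)
  expect_true(isSymmetric(unname(m)))
  v <- encode_blosum62("A", 1)
  expect_equal(unname(v), unname(m["A", ]))
  v2 <- encode_blosum62("AC", 3)
  expect_true(all(v2[41:60] == 0))

  z <- encode_zscale("W", 1)
  expect_equal(unname(z), c(-4.36, 3.94, 0.59, 3.44, -1.59))
  z2 <- encode_zscale("WA", 4)
  expect_true(all(z2[11:20] == 0))
})

test_that("encode_peptides builds clean aligned matrices", {
  ds <- generate_peptides(synthetic_spec(n_pos = 5, n_neg = 10, seed = 1))
  m <- encode_peptides(ds, "AAC")
  expect_equal(dim(m), c(15L, 20L))
  expect_false(any(!is.finite(m)))
  expect_equal(m[3, ], encode_kmer(ds$sequence[3], 1))
  # per-residue schemes default L_max to the longest sequence
  mb <- encode_peptides(ds, "BE")
  expect_equal(ncol(mb), 20L * max(nchar(ds$sequence)))
})
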