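test_that("FASTA round trip preserves sequences, labels, splits and folds", {
  ds <- generate_peptides(synthetic_spec(n_pos = 10, n_neg = 30, seed = 3))
  ds <- stratified_split(ds, 0.2, seed = 1)
  ds <- assign_folds(ds, 5, seed = 2)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ds, f)
  back <- read_fasta(f)
  expect_identical(back$sequence, ds$sequence)
  expect_identical(back$label, ds$label)
  expect_identical(back$split, ds$split)
  expect_identical(back$fold, ds$fold)
})

test_that("FASTA reading validates records and rejects empty files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACDE"), f)
  ds <- read_fasta(f)
  expect_equal(nrow(ds), 1L)
  expect_equal(nchar(ds$sequence), 4L)

  writeLines(c(">p1", "ACXE", ">p2", "ACDE"), f)
  expect_error(read_fasta(f), "p1")
  expect_equal(nrow(read_fasta(f, nonstandard = "drop")), 1L)

  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty|malformed")

  writeLines(c(">a", "ACDE", ">b", "MMMM", ">c", "WYKW"), f)
  expect_identical(read_fasta(f)$id, c("a", "b", "c"))
})

test_that("CSV datasets parse labels strictly and keep duplicates with a warning", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sequence,label", "AAAA,1", "CCCC,0"), f)
  ds <- read_csv_dataset(f)
  expect_equal(nrow(ds), 2L)
  expect_equal(sum(ds$label), 1L)

  writeLines(c("sequence,label", "AAAA,2"), f)
  expect_error(read_csv_dataset(f), "label")
  writeLines(c("sequence,label", "AAAA,1", "CCCC,"), f)
  expect_error(read_csv_dataset(f), "2")
  writeLines(c("sequence,label", "AAAA,1", "AAAA,1"), f)
  expect_warning(read_csv_dataset(f), "duplicate")
})

test_that("stratified split uses floor on the test side and preserves class counts", {
  ds <- generate_peptides(synthetic_spec(n_pos = 313, n_neg = 2908, seed = 5))
  sp <- stratified_split(ds, 0.2, seed = 9)
  expect_equal(sum(sp$split == "test" & sp$label == 1L), 62L)   # floor(313 * .2)
  expect_equal(sum(sp$split == "test" & sp$label == 0L), 581L)  # floor(2908 * .2)
  # no resampling: totals unchanged
  expect_equal(sum(sp$label == 1L), 313L)
  expect_equal(sum(sp$label == 0L), 2908L)
})

test_that("split membership is seed-reproducible and seed-sensitive", {
  ds <- generate_peptides(synthetic_spec(n_pos = 5, n_neg = 5, seed = 2))
  a <- stratified_split(ds, 0.2, seed = 1)
  b <- stratified_split(ds, 0.2, seed = 1)
  c <- stratified_split(ds, 0.4, seed = 2)
  d <- stratified_split(ds, 0.4, seed = 3)
  expect_identical(a$split, b$split)
  expect_equal(table(c$split), table(d$split))
  # with 2 test slots per class and different seeds, membership differs
  e <- stratified_split(generate_peptides(synthetic_spec(50, 50, seed = 4)),
                        0.2, seed = 10)
  f <- stratified_split(generate_peptides(synthetic_spec(50, 50, seed = 4)),
                        0.2, seed = 11)
  expect_false(identical(e$split, f$split))
})

test_that("fold assignment is stratified, balanced and partitions the training split", {
  ds <- generate_peptides(synthetic_spec(n_pos = 10, n_neg = 40, seed = 8))
  ds$split <- "train"
  ds <- assign_folds(ds, 5, seed = 3)
  tab <- table(ds$fold, ds$label)
  expect_true(all(tab[, "1"] == 2L))
  expect_true(all(tab[, "0"] == 8L))
  expect_setequal(which(!is.na(ds$fold)), which(ds$split == "train"))

  # 313 positives over 5 folds -> sizes 62 or 63
  big <- generate_peptides(synthetic_spec(n_pos = 313, n_neg = 320, seed = 8))
  big$split <- "train"
  big <- assign_folds(big, 5, seed = 4)
  sizes <- table(big$fold[big$label == 1L])
  expect_setequal(as.integer(sizes), c(62L, 63L))
  expect_equal(sum(sizes), 313L)
})

test_that("degenerate split and fold requests error", {
  ds <- generate_peptides(synthetic_spec(n_pos = 3, n_neg = 40, seed = 1))
  ds$split <- "train"
  expect_error(assign_folds(ds, 1, seed = 1), "at least 2")
  expect_error(assign_folds(ds, 5, seed = 1), "fewer members than folds")
  one <- peptide_set(sequence = c("AAAA", "CCCC", "DDDD"), label = c(1L, 0L, 0L))
  expect_error(stratified_split(one, 0.2, seed = 1), "at least 2")
})
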