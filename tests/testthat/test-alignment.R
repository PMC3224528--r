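test_that("FASTA parsing, normalization and round trips work", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">tax1", "MK-V", ">tax2", "mka?"), f)
  aln <- read_alignment(f, "fasta")
  expect_s3_class(aln, "aa_alignment")
  expect_equal(rownames(aln), c("tax1", "tax2"))
  expect_equal(ncol(aln), 4L)
  expect_equal(unname(unclass(aln)[2, ]), c("M", "K", "A", "X"))

  aln2 <- rand_alignment(6, 40, seed = 1, gap_frac = 0.1, amb_frac = 0.02)
  for (fmt in c("fasta", "phylip")) {
    p <- withr::local_tempfile()
    write_alignment(aln2, p, fmt)
    expect_equal(unclass(read_alignment(p, fmt)), unclass(aln2),
                 ignore_attr = FALSE)
  }
})

test_that("interleaved relaxed PHYLIP with long names is accepted", {
  f <- withr::local_tempfile()
  writeLines(c(" 2 8",
               "a_very_long_taxon_name MKVA",
               "second_taxon MK-A",
               "",
               "WYYV",
               "WY-V"), f)
  aln <- read_alignment(f, "phylip")
  expect_equal(rownames(aln), c("a_very_long_taxon_name", "second_taxon"))
  expect_equal(paste(unclass(aln)[2, ], collapse = ""), "MK-AWY-V")
})

test_that("malformed alignments raise informative errors", {
  f <- withr::local_tempfile()
  writeLines(c(">a", "MKVA", ">b", "MKVAA"), f)
  expect_error(read_alignment(f, "fasta"), "ragged.*b")
  writeLines(c(">a", "MKVA", ">a", "MKVA"), f)
  expect_error(read_alignment(f, "fasta"), "duplicate.*a")
  writeLines(c(">a", "MKJA", ">b", "MKVA"), f)
  expect_error(read_alignment(f, "fasta"), "illegal character 'J'.*'a'.*column 3")
})

test_that("mask_columns follows the gap/ambiguity rule and is idempotent", {
  m <- rbind(c("M", "-", "A"), c("K", "-", "X"), c("V", "-", "C"))
  rownames(m) <- c("a", "b", "c")
  aln <- aa_alignment(m)
  mk <- mask_columns(aln, max_gap_fraction = 0.5, drop_ambiguous = TRUE)
  expect_equal(mk$mask, 1L)
  expect_equal(ncol(mk$alignment), 1L)

  # identity at the permissive settings
  mk2 <- mask_columns(aln, 1.0, drop_ambiguous = FALSE)
  expect_equal(mk2$mask, 1:3)
  expect_equal(unclass(mk2$alignment), unclass(aln))

  # independent per-column recount on a random alignment
  aln3 <- rand_alignment(10, 50, seed = 2, gap_frac = 0.25, amb_frac = 0.05)
  mk3 <- mask_columns(aln3, 0.3, drop_ambiguous = TRUE)
  keep_oracle <- integer(0)
  for (j in 1:50) {
    col <- unclass(aln3)[, j]
    if (sum(col == "-") / 10 <= 0.3 && !any(col == "X"))
      keep_oracle <- c(keep_oracle, j)
  }
  expect_equal(mk3$mask, keep_oracle)

  # idempotence at the same threshold
  mk4 <- mask_columns(mk3$alignment, 0.3, drop_ambiguous = TRUE)
  expect_equal(unclass(mk4$alignment), unclass(mk3$alignment))
  expect_equal(mk4$mask, seq_along(mk3$mask))

  expect_error(mask_columns(aa_alignment(rbind(x = c("-", "-")))),
               "removed all")
})

test_that("map_to_reference reproduces reference numbering", {
  m <- rbind(ref = c("M", "-", "K", "V"), oth = c("M", "A", "K", "V"))
  aln <- aa_alignment(m)
  expect_equal(map_to_reference(aln, "ref"), c(1L, NA, 2L, 3L))
  expect_error(map_to_reference(aln, "nope"), "unknown")

  m2 <- rbind(ref = rep("-", 5), oth = c("A", "C", "D", "E", "F"))
  expect_true(all(is.na(map_to_reference(aa_alignment(m2), "ref"))))

  # cumulative-count oracle on a random gapped row
  aln3 <- rand_alignment(3, 80, seed = 5, gap_frac = 0.3)
  mp <- map_to_reference(aln3, "t01")
  ref <- unclass(aln3)["t01", ]
  cnt <- 0L
  for (j in seq_along(ref)) {
    if (ref[j] == "-") expect_true(is.na(mp[j]))
    else {
      cnt <- cnt + 1L
      expect_identical(mp[j], cnt)
    }
  }
  # exactly one distinct position per non-gap reference residue
  expect_equal(sort(unique(mp[!is.na(mp)])), seq_len(sum(ref != "-")))
})
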