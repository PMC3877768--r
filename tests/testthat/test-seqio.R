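test_that("normalize_alphabet maps RNA to DNA and is idempotent", {
  expect_equal(normalize_alphabet("ACGGCAACACCAGUCGAUGGGCUGU"),
               "ACGGCAACACCAGTCGATGGGCTGT")
  expect_equal(normalize_alphabet("acgt"), "ACGT")
  expect_equal(normalize_alphabet("ACGTN"), "ACGTN")
  set.seed(11)
  for (i in 1:25) {
    s <- random_seq(sample(5:40, 1), alphabet = c("a", "c", "g", "u", "T", "N"))
    out <- normalize_alphabet(s)
    expect_false(grepl("U", out))
    expect_identical(normalize_alphabet(out), out)
  }
})

test_that("normalize_alphabet rejects non-nucleotide characters by position", {
  expect_error(normalize_alphabet("ACGX"), "position 4")
  expect_error(normalize_alphabet(""), "non-empty")
  expect_error(normalize_alphabet("ACGTN", allow_n = FALSE), "position 5")
})

test_that("read_fastq parses well-formed files and preserves order", {
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1 extra", "ACGU", "+", "IIII",
               "@r2", "TTTTT", "+", "IIIII"), f)
  reads <- read_fastq(f)
  expect_equal(reads$read_id, c("r1", "r2"))
  expect_equal(reads$sequence, c("ACGT", "TTTTT"))
  expect_equal(reads$quality, c("IIII", "IIIII"))

  empty <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), empty)
  expect_equal(nrow(read_fastq(empty)), 0L)
})

test_that("read_fastq reports truncated and malformed records by index", {
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), f)
  expect_error(read_fastq(f), "record 1 \\(0-based\\)")
  g <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2", "ACGT", "+", "IIII"), g)
  expect_error(read_fastq(g), "record 1 \\(0-based\\)")
})

test_that("fastq round-trips through write_fastq", {
  reads <- data.frame(read_id = c("a", "b"), sequence = c("ACGT", "GGGTT"),
                      quality = c("IIII", "IIIII"))
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  expect_equal(read_fastq(f), reads)
})

test_that("adapter trimming cuts at the leftmost qualifying position", {
  insert <- "TAGCTTATCAGACTGATG"
  tr <- trim_adapter_3p(paste0(insert, "TGGAATTCTCGG"),
                        adapter = "TGGAATTCTCGG", min_overlap = 6,
                        max_mismatch_rate = 0)
  expect_equal(tr$sequence, insert)
  expect_true(tr$adapter_found)
  expect_equal(tr$trimmed_length, 12L)
  expect_true(tr$kept)

  # no adapter bases: unchanged, not found
  clean <- "TAGCTTATCAGACTGATGTTGA"
  tr2 <- trim_adapter_3p(clean, adapter = "CCCCCCCCCCCC",
                         max_mismatch_rate = 0)
  expect_false(tr2$adapter_found)
  expect_equal(tr2$trimmed_length, 0L)
  expect_equal(tr2$sequence, clean)

  # short insert is dropped, not an error
  tr3 <- trim_adapter_3p(paste0("ACGTACGTAC", "TGGAATTCTCGG"),
                         adapter = "TGGAATTCTCGG", min_insert_length = 16)
  expect_true(tr3$adapter_found)
  expect_false(tr3$kept)
})

test_that("trimming honors partial 3' overlaps and the mismatch budget", {
  # only the first 6 adapter bases fit at the read end
  tr <- trim_adapter_3p(paste0("TAGCTTATCAGACTGATG", "TGGAAT"),
                        adapter = "TGGAATTCTCGG", min_overlap = 6,
                        max_mismatch_rate = 0)
  expect_true(tr$adapter_found)
  expect_equal(tr$sequence, "TAGCTTATCAGACTGATG")
  # 5-base overlap is below min_overlap: not trimmed
  tr5 <- trim_adapter_3p(paste0("TAGCTTATCAGACTGATG", "TGGAA"),
                         adapter = "TGGAATTCTCGG", min_overlap = 6,
                         max_mismatch_rate = 0)
  expect_false(tr5$adapter_found)
  # one mismatch in a 12-base alignment is within rate 0.1
  adap_mm <- "TGGAATTCTCGA"
  tr_mm <- trim_adapter_3p(paste0("TAGCTTATCAGACTGATG", adap_mm),
                           adapter = "TGGAATTCTCGG", min_overlap = 6,
                           max_mismatch_rate = 0.1)
  expect_true(tr_mm$adapter_found)
  expect_equal(tr_mm$sequence, "TAGCTTATCAGACTGATG")
  expect_false(trim_adapter_3p(paste0("TAGCTTATCAGACTGATG", adap_mm),
                               adapter = "TGGAATTCTCGG",
                               max_mismatch_rate = 0)$adapter_found)
})

test_that("trimming at rate 0 is idempotent", {
  set.seed(21)
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  for (i in 1:20) {
    read <- paste0(random_seq(sample(16:30, 1)), adapter)
    once <- trim_adapter_3p(read, adapter = adapter, max_mismatch_rate = 0)
    twice <- trim_adapter_3p(once$sequence, adapter = adapter,
                             max_mismatch_rate = 0)
    expect_equal(twice$sequence, once$sequence)
    expect_false(twice$adapter_found)
  }
})

test_that("collapse_reads tallies, orders, and conserves mass", {
  out <- collapse_reads(c("ACGTACGTACGTACGTA", "ACGTACGTACGTACGTA",
                          "TTTTTTTTTTTTTTTTT"))
  expect_equal(out$sequence[1], "ACGTACGTACGTACGTA")
  expect_equal(out$occurrences, c(2L, 1L))
  expect_equal(nrow(collapse_reads(character(0))), 0L)

  set.seed(31)
  pool <- replicate(7, random_seq(20))
  reads <- sample(pool, 100, replace = TRUE)
  cc <- collapse_reads(reads)
  expect_equal(nrow(cc), length(unique(reads)))
  expect_equal(sum(cc$occurrences), 100L)
  expect_true(all(diff(cc$occurrences) <= 0))
  ties <- cc$occurrences == c(cc$occurrences[-1], NA)
  expect_true(all(cc$sequence[which(ties)] < cc$sequence[which(ties) + 1]))
})

test_that("reference sets validate ids, roles and alphabet", {
  refs <- reference_set(c("a", "b"), c("ACGUACGUACGUACGUA", "acgtacgtacgtacgta"))
  expect_equal(refs$sequence[1], "ACGTACGTACGTACGTA")
  expect_error(reference_set(c("a", "a"), c("ACGT", "ACGT")), "duplicate")
  expect_error(reference_set("a", "ACGTN"), "position")
  expect_error(reference_set("a", "ACGT", "hairpin"), "role")
})

test_that("reference FASTA reading picks up role tags", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">miR21 role=mature", "UAGCUUAUCAGACUGAUGUUGA",
               ">anti role=antagomir", "ACGGCAACACCAGUCGAUGGGCUGU"), f)
  refs <- read_reference_fasta(f)
  expect_equal(refs$role, c("mature", "antagomir"))
  expect_equal(refs$sequence[1], "TAGCTTATCAGACTGATGTTGA")
})
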