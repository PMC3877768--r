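test_that("seed enumeration yields L - k + 1 seeds in offset order", {
  sd <- enumerate_seeds(random_seq(23), k = 16)
  expect_equal(nrow(sd), 8L)
  expect_equal(sd$offset, 0:7)
  one <- enumerate_seeds("ACGTACGTACGTACGT", k = 16)
  expect_equal(nrow(one), 1L)
  expect_equal(one$offset, 0L)
  expect_equal(one$kmer, "ACGTACGTACGTACGT")
  expect_equal(nrow(enumerate_seeds(anti_mir21(), k = 16)), 10L)
  expect_error(enumerate_seeds("ACGT", k = 16, ref_id = "shorty"), "shorty")
  set.seed(41)
  for (L in sample(16:60, 10))
    expect_equal(nrow(enumerate_seeds(random_seq(L))), L - 15L)
})

test_that("the index covers every seed of every strand", {
  refs <- tiny_refs()
  idx <- build_index(refs, k = 16)
  expect_equal(length(idx$sequences), 2L)
  idx_rc <- build_index(refs[1, ], k = 16, add_reverse_complements = TRUE)
  expect_equal(names(idx_rc$sequences), c("refA", "refA|rc"))
  # a read equal to the reverse complement matches only the |rc sequence
  m <- match_read(oracle_revcomp(refs$sequence[1]), idx_rc)
  expect_equal(unique(m$ref_id), "refA|rc")
  expect_error(build_index(rbind(refs, refs[1, ])), "duplicate")
})

test_that("a shared 16-mer anchors a read onto both references", {
  core <- random_seq_fixed <- "TAGCTTATCAGACTGA"  # 16 nt
  refs <- reference_set(c("r1", "r2"),
                        c(paste0("GG", core, "ACAC"), paste0("TT", core, "GGGC")))
  idx <- build_index(refs, k = 16)
  m <- match_read(core, idx)
  expect_equal(sort(unique(m$ref_id)), c("r1", "r2"))
})

test_that("growth recovers the identity match and flanking mismatches", {
  refs <- tiny_refs()
  idx <- build_index(refs)
  r <- refs$sequence[1]
  m <- match_read(r, idx)
  expect_equal(nrow(m), 1L)
  expect_equal(m$ref_start, 1L)
  expect_equal(m$ref_end, 22L)
  expect_equal(m$flank5, "")
  expect_equal(m$flank3, "")
  expect_equal(m$matched_length, 22L)

  # "CC" disagreeing with reference bases 1..2 becomes a 5' flank
  inner <- substr(r, 3, 20)
  lead <- if (substr(r, 1, 2) == "CC") "GG" else "CC"
  m2 <- match_read(paste0(lead, inner), idx)
  expect_equal(m2$ref_start, 3L)
  expect_equal(m2$ref_end, 20L)
  expect_equal(m2$flank5, lead)
  expect_equal(m2$flank3, "")
  # and the brute-force oracle agrees
  o2 <- oracle_match_read(paste0(lead, inner),
                          setNames(refs$sequence, refs$ref_id))
  expect_equal(m2[names(o2)], o2)

  expect_equal(nrow(match_read(strrep("AC", 10), idx)), 0L)
})

test_that("distinct maximal spans on an internal repeat are all reported", {
  unit <- "TAGCTTATCAGACTGATG"                 # 18 nt
  ref <- reference_set("rep", paste0(unit, "CCCC", unit))
  idx <- build_index(ref)
  m <- match_read(unit, idx)
  expect_equal(nrow(m), 2L)
  expect_equal(m$ref_start, c(1L, 23L))
  expect_equal(m$ref_end, c(18L, 40L))
})

test_that("match_read equals the exhaustive all-anchor oracle on random pairs", {
  set.seed(51)
  refs_pool <- replicate(3, random_seq(sample(16:40, 1)))
  names(refs_pool) <- c("x", "y", "z")
  idx <- build_index(reference_set(names(refs_pool), refs_pool))
  for (i in 1:120) {
    kind <- sample(c("identical", "mutated", "shifted", "shuffled"), 1)
    base <- refs_pool[[sample(3, 1)]]
    read <- switch(kind,
      identical = base,
      mutated = mutate_seq(base, sample(nchar(base),
                                        sample(0:2, 1))),
      shifted = paste0(random_seq(sample(0:3, 1)),
                       substr(base, sample(1:3, 1), nchar(base)),
                       random_seq(sample(0:3, 1))),
      shuffled = random_seq(sample(16:40, 1)))
    if (nchar(read) < 16) next
    got <- match_read(read, idx)
    want <- oracle_match_read(read, refs_pool)
    expect_equal(got[names(want)], want, info = paste(kind, read))
  }
})

test_that("matches are maximal and decompose into flanks plus reference span", {
  set.seed(61)
  refs_pool <- replicate(2, random_seq(30))
  names(refs_pool) <- c("p", "q")
  idx <- build_index(reference_set(names(refs_pool), refs_pool))
  checked <- 0L
  for (i in 1:60) {
    read <- paste0(random_seq(sample(0:4, 1)),
                   substr(refs_pool[[sample(2, 1)]], 1, sample(16:30, 1)),
                   random_seq(sample(0:4, 1)))
    m <- match_read(read, idx)
    for (j in seq_len(nrow(m))) {
      span <- substr(refs_pool[[m$ref_id[j]]], m$ref_start[j], m$ref_end[j])
      expect_identical(m$sequence[j],
                       paste0(m$flank5[j], span, m$flank3[j]))
      expect_gte(m$matched_length[j], 16L)
      # maximality: one more base in either direction mismatches or exhausts
      rs <- m$ref_start[j]; re <- m$ref_end[j]
      f5 <- nchar(m$flank5[j]); f3 <- nchar(m$flank3[j])
      ref <- refs_pool[[m$ref_id[j]]]
      if (rs > 1 && f5 > 0)
        expect_false(substr(ref, rs - 1, rs - 1) ==
                       substr(m$flank5[j], f5, f5))
      if (re < nchar(ref) && f3 > 0)
        expect_false(substr(ref, re + 1, re + 1) ==
                       substr(m$flank3[j], 1, 1))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 50L)
})

test_that("appending a mismatching base grows exactly one flank", {
  set.seed(71)
  for (i in 1:20) {
    ref <- random_seq(25)
    idx <- build_index(reference_set("r", ref))
    read <- substr(ref, 2, 24)
    m0 <- match_read(read, idx)
    bad3 <- setdiff(c("A", "C", "G", "T"), substr(ref, 25, 25))[1]
    m3 <- match_read(paste0(read, bad3), idx)
    expect_equal(m3$ref_start, m0$ref_start)
    expect_equal(m3$ref_end, m0$ref_end)
    expect_equal(nchar(m3$flank3), nchar(m0$flank3) + 1L)
    expect_equal(m3$flank5, m0$flank5)
    bad5 <- setdiff(c("A", "C", "G", "T"), substr(ref, 1, 1))[1]
    m5 <- match_read(paste0(bad5, read), idx)
    expect_equal(m5$ref_start, m0$ref_start)
    expect_equal(m5$ref_end, m0$ref_end)
    expect_equal(nchar(m5$flank5), nchar(m0$flank5) + 1L)
  }
})

test_that("match_library carries occurrences and honors best/all modes", {
  shared <- "TAGCTTATCAGACTGATGAC"              # 20 nt
  refs <- reference_set(c("alpha", "beta"), c(shared, shared))
  idx <- build_index(refs)
  collapsed <- data.frame(sequence = shared, occurrences = 5L)
  all_m <- match_library(collapsed, idx, mode = "all")
  expect_equal(nrow(all_m), 2L)
  expect_equal(all_m$occurrences, c(5L, 5L))
  best <- match_library(collapsed, idx, mode = "best")
  expect_equal(nrow(best), 1L)
  expect_equal(best$ref_id, "alpha")   # tie broken by ref_id order
  expect_equal(best$occurrences, 5L)
  empty <- match_library(data.frame(sequence = character(0),
                                    occurrences = integer(0)), idx)
  expect_equal(nrow(empty), 0L)
})

test_that("export_stack draws a padded gapless pileup", {
  refs <- tiny_refs()
  idx <- build_index(refs)
  r <- refs$sequence[1]
  m <- match_read(r, idx)
  st <- export_stack(m, r, ref_id = "refA")
  expect_length(st, 2L)
  expect_equal(unname(nchar(st)), c(22L, 22L))
  expect_equal(unname(st[2]), r)

  inner <- substr(r, 3, 20)
  lead <- if (substr(r, 1, 2) == "CC") "GG" else "CC"
  m2 <- match_read(paste0(lead, inner), idx)
  st2 <- export_stack(m2, r, ref_id = "refA")
  expect_equal(substr(unname(st2[2]), 1, 2), tolower(lead))
  expect_equal(unname(nchar(st2)), rep(22L, 2))
  # matched bases sit directly under reference positions 3..20
  expect_equal(unname(substr(st2[2], 3, 20)),
               unname(substr(st2[1], 3, 20)))

  only_ref <- export_stack(m2[0, ], r, ref_id = "refA")
  expect_equal(unname(only_ref), r)

  m_bad <- m2
  m_bad$flank5 <- "AA"
  expect_error(export_stack(m_bad, r), "integrity")
})
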