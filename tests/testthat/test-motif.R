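test_that("planted operators round-trip at their TSS-relative offsets", {
  # offsets from the operator map: fnrN distal/proximal anaeroboxes,
  # fixK K-boxes, and the downstream fxkR operators
  cases <- list(list("anaerobox", -34), list("anaerobox", -2),
                list("kbox", -62), list("kbox", +6), list("anaerobox", +38))
  for (cs in cases) {
    fx <- promoter_fixture(cs[[1]], cs[[2]], seed = 10 + cs[[2]])
    hits <- scan_sequence(fx$sequence, fx$tss)
    expect_equal(nrow(hits), 1)
    expect_identical(hits$motif, cs[[1]])
    expect_identical(hits$offset, as.integer(cs[[2]]))
    expect_identical(hits$strand, "forward")
    expect_identical(hits$mismatches, 0L)
  }
})

test_that("motif-free sequences give no hits", {
  fx <- promoter_fixture("anaerobox", -34, seed = 3)
  bare <- paste0(substr(fx$sequence, 1, 50),
                 substr(fx$sequence, 300, 501))
  # construction check: oracle finds nothing either
  for (cons in c("TTGATNNNNATCAA", "GTTACANNNNGTTACA")) {
    expect_length(oracle_motif_starts(bare, cons), 0)
    expect_length(oracle_motif_starts(oracle_revcomp(bare), cons), 0)
  }
  expect_equal(nrow(scan_sequence(bare, 100)), 0)
})

test_that("reverse-strand K-boxes are reported with forward coordinates", {
  fx <- promoter_fixture("kbox", -80, strand = "reverse", seed = 21)
  hits <- scan_sequence(fx$sequence, fx$tss)
  expect_equal(nrow(hits), 1)
  expect_identical(hits$strand, "reverse")
  expect_identical(hits$offset, -80L)
  # brute force on the reverse complement finds the same site
  rc <- oracle_revcomp(fx$sequence)
  starts_rc <- oracle_motif_starts(rc, "GTTACANNNNGTTACA")
  expect_length(starts_rc, 1)
  # map the reverse-complement start back to a forward leftmost position
  fwd_start <- nchar(fx$sequence) - (starts_rc + 16 - 1) + 1
  expect_equal(fwd_start, fixcascade:::offset_to_pos(-80, fx$tss))
})

test_that("scanner equals the brute-force regex oracle on random fixtures", {
  withr::with_seed(99, {
    kinds <- sample(c("anaerobox", "kbox"), 12, replace = TRUE)
    offsets <- sample(c(-150:-1, 1:50), 12)
    strands <- sample(c("forward", "reverse"), 12, replace = TRUE)
    for (i in seq_along(kinds)) {
      fx <- promoter_fixture(kinds[i], offsets[i], strand = strands[i],
                             seed = 1000 + i)
      hits <- scan_sequence(fx$sequence, fx$tss, window = c(-260, 260))
      cons <- fixcascade:::motif_consensus(kinds[i])
      fwd <- oracle_motif_starts(fx$sequence, cons)
      rc <- oracle_motif_starts(oracle_revcomp(fx$sequence), cons)
      rc_fwd <- sort(nchar(fx$sequence) - (rc + nchar(cons) - 1) + 1)
      all_starts <- sort(unique(c(fwd, rc_fwd)))
      expect_identical(sort(unique(fixcascade:::offset_to_pos(hits$offset,
                                                              fx$tss))),
                       as.numeric(all_starts))
      expect_true(any(hits$offset == offsets[i]))
    }
  })
})

test_that("offset arithmetic honours the no-zero convention", {
  fx <- promoter_fixture("anaerobox", +1, seed = 5)
  hits <- scan_sequence(fx$sequence, fx$tss)
  expect_identical(hits$offset, 1L)  # motif starting on the TSS base is +1
  expect_error(promoter_fixture("anaerobox", 0), "offset 0")
  expect_identical(fixcascade:::pos_to_offset(100, 100), 1)
  expect_identical(fixcascade:::pos_to_offset(99, 100), -1)
})

test_that("palindromic anaeroboxes are reported once, K-boxes per strand", {
  fx <- promoter_fixture("anaerobox", -40, seed = 12)
  hits <- scan_sequence(fx$sequence, fx$tss)
  expect_equal(sum(hits$motif == "anaerobox"), 1)
  expect_identical(hits$strand, "forward")
  # planting a reverse anaerobox is indistinguishable from forward
  fxr <- promoter_fixture("anaerobox", -40, strand = "reverse", seed = 12)
  hr <- scan_sequence(fxr$sequence, fxr$tss)
  expect_equal(nrow(hr), 1)
  expect_identical(hr$strand, "forward")
})

test_that("scanner input validation catches malformed sequences", {
  expect_error(scan_sequence("ACGTX", 2), "characters")
  expect_error(scan_sequence("ACGTACGT", 20), "TSS")
  fx <- promoter_fixture("kbox", -30, seed = 2)
  expect_error(promoter_fixture("kbox", -500, flank = 100), "flank")
})

test_that("FASTA + TSS table scanning matches direct scanning", {
  skip_if_not_installed("Biostrings")
  fx1 <- promoter_fixture("anaerobox", -34, seed = 31)
  fx2 <- promoter_fixture("kbox", -62, seed = 32)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">pfnrN", fx1$sequence, ">pfixK", fx2$sequence), fa)
  tt <- data.frame(name = c("pfnrN", "pfixK"), tss = c(fx1$tss, fx2$tss))
  hits <- scan_fasta(fa, tt)
  expect_equal(nrow(hits), 2)
  expect_identical(hits$offset, c(-34L, -62L))
  expect_error(scan_fasta(fa, data.frame(name = "zzz", tss = 10)), "absent")
})
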