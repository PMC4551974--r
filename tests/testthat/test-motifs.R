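# Degenerate-motif compilation and exact word-matching semantics.

test_that("compile_iupac expands IUPAC codes positionwise", {
  m <- compile_iupac("N")
  expect_equal(m$length, 1L)
  expect_setequal(m$allowed[[1]], c("A", "C", "G", "T"))

  hox <- hoxb1()
  expect_equal(hox$length, 15L)
  expect_equal(hox$allowed[[8]], "A")
  expect_equal(hox$allowed[[9]], "T")
  expect_equal(hox$allowed[[10]], "G")
  expect_setequal(hox$allowed[[1]], c("A", "C", "T"))
  expect_setequal(hox$allowed[[5]], c("C", "G"))

  # compiling then re-emitting is the identity, case-insensitively
  expect_equal(as.character(compile_iupac("hwttSWnatgYWDWD")),
               "HWTTSWNATGYWDWD")
  for (pat in c("ACGT", "RYSWKMBDHVN")) {
    expect_equal(as.character(compile_iupac(pat)), pat)
  }
})

test_that("compile_iupac rejects non-IUPAC characters at the right position", {
  expect_error(compile_iupac("ATGX"), "position 4")
  expect_error(compile_iupac(""), "non-empty")
})

test_that("reverse_complement is the Watson-Crick involution", {
  expect_equal(reverse_complement("ATGC"), "GCAT")
  expect_equal(reverse_complement(""), "")
  expect_equal(reverse_complement("CTTTGTCATGCTAAT"), "ATTAGCATGACAAAG")
  set.seed(42)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(1:40, 1), TRUE),
               collapse = "")
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
  expect_error(reverse_complement("ACGN"), "A/C/G/T")
})

test_that("matches_at applies per-position set membership", {
  expect_true(matches_at(hoxb1(), "CTTTGTCATGCTAAT", 0L))
  # position 15 of the Utf1-like word requires G; the Hoxb1 core has A there
  expect_false(matches_at(utf1(), "CTTTGTCATGCTAAT", 0L))
  expect_error(matches_at(hoxb1(), "CTTTGTCATGCTAAT", 1L), "out of range")

  set.seed(7)
  for (m in list(hoxb1(), utf1(), fgf4())) {
    for (i in 1:10) {
      expect_true(matches_at(m, sample_expansions(m, 1L), 0L))
    }
  }
})

test_that("scan_sequence finds each published probe's own word exactly once", {
  cases <- list(
    list(motif = hoxb1(), probe = PROBE_HOXB1, offset = 11L,
         matched = "CTTTGTCATGCTAAT"),
    list(motif = utf1(), probe = PROBE_UTF1, offset = 18L,
         matched = "CATTGTTATGCTAGT"),
    list(motif = fgf4(), probe = PROBE_FGF4, offset = 13L,
         matched = "CTTTGTTTGGATGCTAAT")
  )
  for (cs in cases) {
    h <- scan_sequence(cs$motif, cs$probe, strands = "both")
    expect_equal(nrow(h), 1L)
    expect_equal(h$offset, cs$offset)
    expect_equal(h$strand, "+")
    expect_equal(h$matched_seq, cs$matched)
    # independent ambiguity-aware oracle agrees
    o <- oracle_scan(cs$motif$pattern, cs$probe)
    expect_equal(h$offset, o$offset)
    expect_equal(h$strand, o$strand)
  }
  # zero cross-class hits on both strands
  probes <- c(PROBE_HOXB1, PROBE_UTF1, PROBE_FGF4)
  motifs <- list(hoxb1(), utf1(), fgf4())
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    expect_equal(nrow(scan_sequence(motifs[[j]], probes[i])), 0L)
  }
})

test_that("scan_sequence handles edge cases and matches the oracle on random input", {
  hox <- hoxb1()
  expect_equal(nrow(scan_sequence(hox, "ACGT")), 0L)  # shorter than motif
  # non-ACGT positions never match
  probe_n <- sub("CTTTG", "CTNTG", PROBE_HOXB1)
  expect_equal(nrow(scan_sequence(hox, probe_n)), 0L)
  # lower-case input is normalized
  expect_equal(scan_sequence(hox, tolower(PROBE_HOXB1))$offset, 11L)

  set.seed(101)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    for (m in list(hox, fgf4())) {
      mine <- scan_sequence(m, s, strands = "both")
      o <- oracle_scan(m$pattern, s)
      expect_equal(mine$offset, o$offset)
      expect_equal(mine$strand, o$strand)
    }
  }
})

test_that("minus-strand scanning is equivalent to forward-scanning the reverse complement", {
  set.seed(11)
  for (m in list(hoxb1(), fgf4())) {
    L <- m$length
    for (i in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = "")
      both <- scan_sequence(m, s, strands = "both")
      minus <- both[both$strand == "-", ]
      fw_rc <- scan_sequence(m, reverse_complement(s), strands = "forward")
      expect_equal(sort(minus$offset), sort(nchar(s) - L - fw_rc$offset))
    }
  }
})

test_that("concrete patterns reduce to substring counting", {
  set.seed(3)
  for (i in 1:20) {
    s <- paste(sample(c("A", "T"), 200, TRUE), collapse = "")
    m <- compile_iupac("ATTA")
    fw <- scan_sequence(m, s, strands = "forward")
    naive <- sum(vapply(0:(nchar(s) - 4L), function(k)
      substr(s, k + 1L, k + 4L) == "ATTA", logical(1)))
    expect_equal(nrow(fw), naive)
  }
})

test_that("patterns_disjoint proves the Hoxb1/Utf1 separation", {
  expect_true(patterns_disjoint(hoxb1(), utf1()))
  expect_false(patterns_disjoint(hoxb1(), hoxb1()))
  expect_false(patterns_disjoint(compile_iupac("AN"), compile_iupac("NT")))
  expect_error(patterns_disjoint(hoxb1(), fgf4()), "equal-length")
  # the separating position is 14 (W vs G)
  expect_length(intersect(hoxb1()$allowed[[14]], utf1()$allowed[[14]]), 0L)
})

test_that("no sequence is reported as both Hoxb1-like and Utf1-like at one (offset, strand)", {
  set.seed(5)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    h1 <- scan_sequence(hoxb1(), s)
    h2 <- scan_sequence(utf1(), s)
    expect_length(intersect(paste(h1$offset, h1$strand),
                            paste(h2$offset, h2$strand)), 0L)
  }
})

test_that("expected_hit_rate is the product of allowed-base probabilities", {
  expect_equal(expected_hit_rate(compile_iupac("N")), 1.0)
  expect_equal(expected_hit_rate(compile_iupac("ATG")), 4^-3)
  expect_equal(expected_hit_rate(hoxb1()), 6912 / 4^15)

  # enumeration oracle on a short pattern, uniform and skewed base models
  pat <- compile_iupac("RYS")
  grid <- expand.grid(b1 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                      b3 = c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  seqs <- do.call(paste0, grid)
  hitmask <- vapply(seqs, function(s) matches_at(pat, s, 0L), logical(1))
  expect_equal(expected_hit_rate(pat), mean(hitmask))
  probs <- c(A = 0.1, C = 0.2, G = 0.3, T = 0.4)
  w <- apply(grid, 1, function(r) prod(probs[r]))
  expect_equal(expected_hit_rate(pat, probs), sum(w[hitmask]))

  expect_error(expected_hit_rate(hoxb1(), c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(expected_hit_rate(hoxb1(), c(1, -0.5, 0.25, 0.25)))
})

test_that("empirical forward hit frequency matches the analytic rate", {
  m <- compile_iupac("SWN")  # rate 1/8 per offset
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 1e5 + 2, TRUE), collapse = "")
  n_off <- nchar(s) - m$length + 1L
  obs <- nrow(scan_sequence(m, s, strands = "forward"))
  p <- expected_hit_rate(m)
  se <- sqrt(n_off * p * (1 - p))
  expect_lt(abs(obs - n_off * p), 3 * se)
})

test_that("motif TSV round-trips and the packaged defaults are the three composite words", {
  m <- default_motifs()
  expect_named(m, c("Hoxb1-like", "Utf1-like", "Fgf4-like"))
  expect_equal(as.character(m[["Hoxb1-like"]]), "HWTTSWNATGYWDWD")
  expect_equal(as.character(m[["Utf1-like"]]), "HWTTSWNATGYWDGD")
  expect_equal(as.character(m[["Fgf4-like"]]), "HWTTSWNNNNATGYWDWD")

  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tpattern", "probe\tHWTTSW"), tmp)
  m2 <- read_motifs(tmp)
  expect_equal(m2$probe$pattern, "HWTTSW")
})
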