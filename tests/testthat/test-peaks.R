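# Window extraction, per-class counting, positional distributions and
# GC-matched background selection.

make_peaks <- function(chrom, summits, width = 100L) {
  data.frame(chrom = chrom,
             start = summits - width %/% 2L,
             end = summits + width %/% 2L,
             peak_id = sprintf("p%03d", seq_along(summits)),
             summit = summits,
             stringsAsFactors = FALSE)
}

test_that("extract_windows centers windows on the summit", {
  set.seed(1)
  g <- generate_genome(2000, 0.5, seed = 1, chrom = "chr1")
  pk <- make_peaks("chr1", 500L)
  w <- extract_windows(g, pk, width = 100L)
  expect_equal(w$win_start, 450L)
  expect_equal(w$win_end, 550L)
  expect_equal(nchar(w$seq), 100L)
  expect_equal(w$seq, substr(as.character(g[[1]]), 451, 550))
})

test_that("boundary windows are skipped with a warning, unknown chromosomes error", {
  g <- generate_genome(2000, 0.5, seed = 2, chrom = "chr1")
  pk <- make_peaks("chr1", c(30L, 500L))
  pk$start[1] <- 0L  # keep the peak itself valid
  expect_warning(w <- extract_windows(g, pk), "boundary")
  expect_equal(w$peak_id, "p002")

  pk_bad <- make_peaks("chrZ", 500L)
  expect_error(extract_windows(g, pk_bad), "absent from genome")
})

test_that("a planted word in a toy genome is recovered through the window", {
  g <- toy_genome()  # 60 A's + 15-mer core + 60 A's
  pk <- make_peaks("chrT", 67L)  # summit at the planted word's center
  w <- extract_windows(g, pk)
  expect_equal(nchar(w$seq), 100L)
  expect_true(grepl("CTTTGTCATGCTAAT", w$seq, fixed = TRUE))
  sc <- scan_peaks(g, pk, list(hoxb1()))
  expect_equal(sc$counts$total_occurrences, 1L)
  expect_equal(sc$hits$matched_seq, "CTTTGTCATGCTAAT")
})

test_that("scan_peaks counts planted windows exactly and conserves totals", {
  cfg <- generator_config(
    n_peaks = 40L,
    plant_counts = c("Hoxb1-like" = 10L, "Utf1-like" = 3L, "Fgf4-like" = 2L),
    n_genes = 10L, seed = 21L)
  ds <- simulate_dataset(cfg)
  sc <- scan_peaks(ds$genome, ds$peaks, default_motifs())
  expect_equal(sc$counts$total_occurrences, c(10L, 3L, 2L))
  expect_equal(sc$counts$windows_with_hit, c(10L, 3L, 2L))
  expect_equal(sc$counts$n_windows, rep(40L, 3))
  # conservation: per-window hit counts sum to the per-class totals
  for (cl in sc$counts$motif) {
    per_window <- table(sc$hits$peak_id[sc$hits$motif == cl])
    expect_equal(sum(per_window),
                 sc$counts$total_occurrences[sc$counts$motif == cl])
  }
  # the hits land where the truth table planted them
  planted <- ds$peak_truth[!is.na(ds$peak_truth$class), ]
  key_truth <- paste(planted$peak_id, planted$class, planted$offset,
                     planted$strand)
  key_hits <- paste(sc$hits$peak_id, sc$hits$motif, sc$hits$offset,
                    sc$hits$strand)
  expect_setequal(key_hits, key_truth)
})

test_that("scan_peaks degenerate inputs behave per contract", {
  g <- toy_genome()
  pk <- make_peaks("chrT", 67L)
  empty <- scan_peaks(g, pk, list())
  expect_equal(nrow(empty$counts), 0L)
  expect_equal(nrow(empty$hits), 0L)
  expect_error(scan_peaks(g, pk[0, ], list(hoxb1())), "no peaks")
})

test_that("shifting summits shifts summit_offset by the opposite amount", {
  cfg <- generator_config(
    n_peaks = 30L, plant_counts = c("Hoxb1-like" = 12L, "Utf1-like" = 0L,
                                    "Fgf4-like" = 0L),
    n_genes = 10L, seed = 33L)
  ds <- simulate_dataset(cfg)
  sc0 <- scan_peaks(ds$genome, ds$peaks, default_motifs())
  pk_shift <- ds$peaks
  pk_shift$summit <- pk_shift$summit + 10L
  pk_shift$end <- pk_shift$end + 10L  # keep summit inside the peak
  sc1 <- scan_peaks(ds$genome, pk_shift, default_motifs())
  # hits within 10 bp of the left window edge leave the shifted window;
  # compare the hits present in both scans (one planted hit per window)
  h0 <- sc0$hits[sc0$hits$offset >= 10L, ]
  h1 <- sc1$hits[sc1$hits$peak_id %in% h0$peak_id, ]
  h0 <- h0[order(h0$peak_id), ]
  h1 <- h1[order(h1$peak_id), ]
  expect_gt(nrow(h0), 0L)
  expect_equal(h1$peak_id, h0$peak_id)
  expect_equal(h1$summit_offset, h0$summit_offset - 10L)
})

test_that("positional_distribution bins summit offsets correctly", {
  # one hit centered exactly at the summit
  h <- data.frame(peak_id = "p", motif = "m", offset = 43L,
                  summit_offset = 0L, strand = "+", matched_seq = "X")
  d <- positional_distribution(h, width = 100L, bin_width = 5L)
  expect_equal(sum(d$count), 1L)
  expect_equal(d$count[d$bin_lo == 0L], 1L)

  # empty hit list -> empty histogram; bad bin width rejected
  expect_equal(nrow(positional_distribution(h[0, ], 100L, 5L)), 0L)
  expect_error(positional_distribution(h, 100L, 7L), "divide")

  # conservation + uniform plantings consistent with a uniform multinomial
  # (chi-square goodness of fit across the 20 bins)
  set.seed(4)
  n <- 1000L
  offs <- sample(-50:49, n, replace = TRUE)
  hu <- data.frame(peak_id = "p", motif = "m", offset = 0L,
                   summit_offset = offs, strand = "+", matched_seq = "X")
  du <- positional_distribution(hu, 100L, 5L)
  expect_equal(sum(du$count), n)
  expect_gt(stats::chisq.test(du$count)$p.value, 1e-4)

  # boundary: an offset of exactly +width/2 falls in the (closed) last bin
  hb <- data.frame(peak_id = "p", motif = "m", offset = 0L,
                   summit_offset = 50L, strand = "+", matched_seq = "X")
  db <- positional_distribution(hb, 100L, 5L)
  expect_equal(db$count[db$bin_lo == 45L], 1L)
})

test_that("select_background matches GC, avoids peaks, and is reproducible", {
  cfg <- generator_config(
    n_peaks = 30L, plant_counts = c("Hoxb1-like" = 5L, "Utf1-like" = 0L,
                                    "Fgf4-like" = 0L),
    n_genes = 10L, seed = 55L)
  ds <- simulate_dataset(cfg)
  pw <- extract_windows(ds$genome, ds$peaks)
  target_gc <- sum(vapply(strsplit(pw$seq, ""), function(ch)
    sum(ch %in% c("G", "C")), integer(1))) / sum(nchar(pw$seq))

  bg1 <- select_background(ds$genome, ds$peaks, 25L, gc_tolerance = 0.02,
                           seed = 9L)
  bg2 <- select_background(ds$genome, ds$peaks, 25L, gc_tolerance = 0.02,
                           seed = 9L)
  expect_identical(bg1, bg2)
  expect_equal(nrow(bg1), 25L)
  expect_equal(nchar(bg1$seq), rep(100L, 25L))

  gc_each <- vapply(strsplit(bg1$seq, ""), function(ch)
    mean(ch %in% c("G", "C")), numeric(1))
  expect_true(all(abs(gc_each - target_gc) <= 0.02 + 1e-9))

  # no overlap with peak windows or among themselves
  spans <- function(s, e) unlist(Map(function(a, b) (a + 1L):b, s, e))
  occupied <- spans(pw$win_start, pw$win_end)
  bg_spans <- spans(bg1$win_start, bg1$win_end)
  expect_length(intersect(bg_spans, occupied), 0L)
  expect_equal(anyDuplicated(bg_spans), 0L)

  # strict motif-free genome: background windows carry zero hits
  bsc <- scan_peaks(NULL, NULL, default_motifs(), windows = bg1)
  expect_equal(sum(bsc$counts$total_occurrences), 0L)

  # impossible request errors with the shortfall reported
  expect_error(
    select_background(ds$genome, ds$peaks, 20L, gc_tolerance = 0,
                      seed = 1L, max_attempts = 50L),
    "placed only")
})
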