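# Summit-centered window extraction, per-class motif counting, positional
# distributions and GC-matched background selection.
#
# All genomic intervals use the BED convention: 0-based, half-open. The
# summit is an absolute 0-based position; the scanned window is
# [summit - width/2, summit + width/2).

#' Read a BED-like peak table
#'
#' Headerless TSV with columns chrom, start, end, peak_id, summit (summit as
#' an absolute 0-based position). When the 5th column is absent the summit
#' defaults to the interval midpoint `floor((start + end) / 2)`.
#'
#' @param path TSV file.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `peak_id`,
#'   `summit`, plus any further columns (e.g. a score usable as a
#'   confidence filter).
#' @export
read_peaks <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("peak file needs at least chrom/start/end: ", path)
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (ncol(tab) >= 4L) names(tab)[4] <- "peak_id"
  else tab$peak_id <- sprintf("peak_%05d", seq_len(nrow(tab)))
  if (ncol(tab) >= 5L && is.numeric(tab[[5]])) names(tab)[5] <- "summit"
  else tab$summit <- (tab$start + tab$end) %/% 2L
  validate_peaks(tab)
  tab
}

validate_peaks <- function(peaks) {
  req <- c("chrom", "start", "end", "peak_id", "summit")
  if (!all(req %in% names(peaks))) {
    stop("peak table must have columns ", paste(req, collapse = ", "))
  }
  bad <- peaks$start >= peaks$end |
    peaks$summit < peaks$start | peaks$summit >= peaks$end
  if (any(bad)) {
    stop("malformed peak(s) (need start < end, start <= summit < end): ",
         paste(utils::head(peaks$peak_id[bad], 5L), collapse = ", "))
  }
  if (anyDuplicated(peaks$peak_id)) stop("duplicate peak_id values")
  invisible(peaks)
}

#' Write a peak table as headerless BED-like TSV
#' @param peaks Peak `data.frame` (see [read_peaks()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.table(peaks[, c("chrom", "start", "end", "peak_id", "summit")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Accept a DNAStringSet or a FASTA path; return a named list of plain
# upper-case character sequences (fast substring access at desk scale).
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    # keep the first whitespace-delimited token as the sequence name
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- as.list(toupper(as.character(genome)))
  }
  if (!is.list(genome) || is.null(names(genome))) {
    stop("genome must be a FASTA path, a DNAStringSet, or a named list")
  }
  genome
}

#' Extract fixed-width summit-centered windows
#'
#' Each window is `[summit - width/2, summit + width/2)`. Peaks whose window
#' would extend past a chromosome boundary are skipped with a warning (never
#' silently truncated) so every window has identical length; an unknown
#' chromosome is an error.
#'
#' @param genome FASTA path, `DNAStringSet`, or named list of sequences.
#' @param peaks Peak `data.frame` (see [read_peaks()]).
#' @param width Window width in nt; even. Default 100.
#' @return `data.frame` with columns `peak_id`, `chrom`, `win_start`,
#'   `win_end`, `seq` (upper-cased, length `width`).
#' @export
extract_windows <- function(genome, peaks, width = 100L) {
  stopifnot(width > 0L, width %% 2L == 0L)
  validate_peaks(peaks)
  genome <- load_genome(genome)
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing)) {
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "))
  }
  half <- width %/% 2L
  win_start <- peaks$summit - half
  win_end <- peaks$summit + half
  chrom_len <- vapply(genome, nchar, integer(1))
  ok <- win_start >= 0L & win_end <= chrom_len[peaks$chrom]
  if (any(!ok)) {
    warning(sprintf("skipping %d peak(s) with windows past a chromosome boundary: %s",
                    sum(!ok),
                    paste(utils::head(peaks$peak_id[!ok], 5L), collapse = ", ")))
  }
  idx <- which(ok)
  seqs <- character(length(idx))
  for (ch in unique(peaks$chrom[idx])) {
    sel <- idx[peaks$chrom[idx] == ch]
    seqs[match(sel, idx)] <- substring(genome[[ch]],
                                       win_start[sel] + 1L, win_end[sel])
  }
  data.frame(
    peak_id = peaks$peak_id[idx],
    chrom = peaks$chrom[idx],
    win_start = win_start[idx],
    win_end = win_end[idx],
    seq = toupper(seqs),
    stringsAsFactors = FALSE
  )
}

# Scan many equal-width windows for one motif by concatenating them with a
# non-matching spacer and scanning once; returns per-window 0-based offsets.
scan_windows_one <- function(motif, seqs, width, strands) {
  L <- motif$length
  pad <- strrep("X", L)  # codes to 5 -> can never take part in a match
  slot <- width + L
  codes <- encode_seq(paste0(paste0(seqs, pad), collapse = ""))
  collect <- function(mask, strand) {
    off <- mask_hits(mask, codes)
    win <- off %/% slot
    local <- off %% slot
    keep <- local <= width - L & win < length(seqs)
    data.frame(window = win[keep] + 1L, offset = local[keep],
               strand = rep(strand, sum(keep)), stringsAsFactors = FALSE)
  }
  out <- collect(motif$mask, "+")
  if (strands == "both") out <- rbind(out, collect(rc_mask(motif$mask), "-"))
  out
}

#' Count composite motifs in peak windows
#'
#' Extracts `width`-nt summit-centered windows and scans each with every
#' motif on the requested strands. Both headline statistics are reported per
#' class: total occurrences (overlaps allowed, deduplicated by peak, motif,
#' offset, strand) and the number of windows with at least one hit.
#'
#' @param genome FASTA path, `DNAStringSet`, or named list of sequences.
#' @param peaks Peak `data.frame`, or `NULL` if `windows` is given.
#' @param motifs Named list of `degenerate_motif` objects.
#' @param width Window width (nt), even; default 100.
#' @param strands `"both"` (default) or `"forward"`.
#' @param windows Pre-extracted window `data.frame` (bypasses `genome` /
#'   `peaks`), e.g. background windows from [select_background()].
#' @return List of class `motif_count_table`:
#'   \describe{
#'     \item{counts}{`data.frame(motif, total_occurrences, windows_with_hit,
#'       n_windows)` in motif order.}
#'     \item{hits}{`data.frame(peak_id, motif, offset, summit_offset,
#'       strand, matched_seq)`; `summit_offset` is the signed distance from
#'       the window center to the hit's center nucleotide,
#'       `offset + floor(L/2) - width/2`.}
#'     \item{windows}{the scanned window table.}
#'   }
#' @export
scan_peaks <- function(genome, peaks, motifs, width = 100L,
                       strands = c("both", "forward"), windows = NULL) {
  strands <- match.arg(strands)
  if (is.null(windows)) {
    if (is.null(peaks) || nrow(peaks) == 0L) stop("no peaks to scan")
    windows <- extract_windows(genome, peaks, width)
  }
  if (nrow(windows) == 0L) stop("zero scannable windows")
  stopifnot(all(nchar(windows$seq) == width))
  half <- width %/% 2L
  hits_list <- lapply(motifs, function(m) {
    h <- scan_windows_one(m, windows$seq, width, strands)
    if (nrow(h) == 0L) {
      return(data.frame(peak_id = character(0), motif = character(0),
                        offset = integer(0), summit_offset = integer(0),
                        strand = character(0), matched_seq = character(0),
                        stringsAsFactors = FALSE))
    }
    data.frame(
      peak_id = windows$peak_id[h$window],
      motif = m$name,
      offset = h$offset,
      summit_offset = h$offset + m$length %/% 2L - half,
      strand = h$strand,
      matched_seq = substring(windows$seq[h$window],
                              h$offset + 1L, h$offset + m$length),
      stringsAsFactors = FALSE
    )
  })
  hit_proto <- data.frame(peak_id = character(0), motif = character(0),
                          offset = integer(0), summit_offset = integer(0),
                          strand = character(0), matched_seq = character(0),
                          stringsAsFactors = FALSE)
  hits <- rbind_all(hits_list, hit_proto)
  hits <- hits[!duplicated(hits[, c("peak_id", "motif", "offset", "strand")]), ]
  hits <- hits[order(match(hits$motif, vapply(motifs, `[[`, "", "name")),
                     match(hits$peak_id, windows$peak_id),
                     hits$offset, hits$strand), ]
  rownames(hits) <- NULL
  counts <- data.frame(
    motif = vapply(motifs, `[[`, "", "name"),
    total_occurrences = vapply(motifs, function(m)
      sum(hits$motif == m$name), integer(1)),
    windows_with_hit = vapply(motifs, function(m)
      length(unique(hits$peak_id[hits$motif == m$name])), integer(1)),
    n_windows = rep(nrow(windows), length(motifs)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(counts = counts, hits = hits, windows = windows),
            class = "motif_count_table")
}

#' @export
print.motif_count_table <- function(x, ...) {
  cat(sprintf("motif counts over %d windows:\n", x$counts$n_windows[1]))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Positional distribution of hits around the peak summit
#'
#' Histogram of each hit's center nucleotide position relative to the window
#' center (`summit_offset`). Bins are half-open `[lo, hi)`, the last bin
#' closed; `bin_width` must divide `width`.
#'
#' @param hits Hit table from [scan_peaks()].
#' @param width Window width the hits came from (nt).
#' @param bin_width Bin width (nt), default 5.
#' @return `data.frame(motif, bin_lo, bin_hi, count)`, one row per bin per
#'   motif present in `hits` (all-zero histograms for motifs with no hits
#'   are obtained by passing a `motif` factor; here absent motifs are
#'   simply absent).
#' @export
positional_distribution <- function(hits, width = 100L, bin_width = 5L) {
  if (width %% bin_width != 0L) {
    stop("bin_width must divide the window width")
  }
  half <- width %/% 2L
  if (nrow(hits) && any(abs(hits$summit_offset) > half)) {
    stop("summit_offset outside [-width/2, width/2]")
  }
  lo <- seq(-half, half - bin_width, by = bin_width)
  out <- lapply(unique(hits$motif), function(m) {
    x <- hits$summit_offset[hits$motif == m]
    bin <- pmin((x + half) %/% bin_width, length(lo) - 1L)  # close last bin
    data.frame(motif = m, bin_lo = lo, bin_hi = lo + bin_width,
               count = tabulate(bin + 1L, nbins = length(lo)),
               stringsAsFactors = FALSE)
  })
  rbind_all(out, data.frame(motif = character(0), bin_lo = integer(0),
                            bin_hi = integer(0), count = integer(0)))
}

gc_fraction <- function(seqs) {
  n_gc <- vapply(seqs, function(s)
    sum(encode_seq(s) %in% c(2L, 3L)), integer(1), USE.NAMES = FALSE)
  sum(n_gc) / sum(nchar(seqs))
}

#' Select GC- and length-matched background windows
#'
#' Seeded, reproducible rejection sampling of genomic windows that (i) do
#' not overlap any peak window or each other, (ii) match the pooled
#' peak-window GC fraction within `gc_tolerance`, and (iii) contain no
#' non-ACGT base. This plays the role of background control sequence
#' selection for the positional distributions.
#'
#' @param genome FASTA path, `DNAStringSet`, or named list of sequences.
#' @param peaks Peak `data.frame` whose windows define the pooled GC target
#'   and the excluded intervals.
#' @param n_regions Number of background windows.
#' @param width Window width (nt), default 100.
#' @param gc_tolerance Allowed absolute deviation from the pooled peak GC
#'   fraction; `1` makes the constraint vacuous. Default 0.02.
#' @param seed Integer seed (scoped to this call; the global RNG state is
#'   restored on exit).
#' @param max_attempts Attempt budget; default `500 * n_regions`.
#' @return Window `data.frame` as in [extract_windows()], with synthetic
#'   ids `bg_00001, ...`; the summit is taken as the window center.
#' @export
select_background <- function(genome, peaks, n_regions, width = 100L,
                              gc_tolerance = 0.02, seed = 1L,
                              max_attempts = 500L * n_regions) {
  stopifnot(n_regions >= 1L, width %% 2L == 0L, gc_tolerance >= 0)
  genome <- load_genome(genome)
  pw <- extract_windows(genome, peaks, width)
  target_gc <- gc_fraction(pw$seq)
  chrom_len <- vapply(genome, nchar, integer(1))
  usable <- names(chrom_len)[chrom_len >= width]
  if (!length(usable)) stop("genome too short to host background windows")
  taken <- lapply(genome, function(s) logical(0))  # occupied bp per chrom
  for (ch in names(genome)) taken[[ch]] <- logical(chrom_len[ch])
  for (i in seq_len(nrow(pw))) {
    taken[[pw$chrom[i]]][(pw$win_start[i] + 1L):pw$win_end[i]] <- TRUE
  }
  out <- vector("list", n_regions)
  with_seed(seed, {
    got <- 0L
    attempts <- 0L
    p_chrom <- chrom_len[usable] / sum(chrom_len[usable])
    while (got < n_regions && attempts < max_attempts) {
      attempts <- attempts + 1L
      ch <- if (length(usable) == 1L) usable else
        sample(usable, 1L, prob = p_chrom)
      start <- sample.int(chrom_len[ch] - width + 1L, 1L) - 1L
      span <- (start + 1L):(start + width)
      if (any(taken[[ch]][span])) next
      s <- substring(genome[[ch]], start + 1L, start + width)
      if (grepl("[^ACGT]", s)) next
      if (abs(gc_fraction(s) - target_gc) > gc_tolerance) next
      got <- got + 1L
      taken[[ch]][span] <- TRUE
      out[[got]] <- data.frame(
        peak_id = sprintf("bg_%05d", got), chrom = ch,
        win_start = start, win_end = start + width, seq = s,
        stringsAsFactors = FALSE
      )
    }
    if (got < n_regions) {
      stop(sprintf(
        "placed only %d of %d background windows within %d attempts",
        got, n_regions, max_attempts))
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}
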