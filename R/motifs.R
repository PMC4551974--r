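# Degenerate composite-motif model: IUPAC word compilation and exact
# set-membership matching on both strands. This is the matching semantics
# every other module relies on; no mismatches, no scoring.

IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

BASES <- c("A", "C", "G", "T")

#' Compile an IUPAC degenerate motif
#'
#' Turns an IUPAC string (15-letter DNA alphabet, case-insensitive) into a
#' `degenerate_motif`: an ordered list of per-position allowed-base sets plus
#' a lookup mask used by the scanner. Matching elsewhere is exact
#' set-membership per position -- a word search, not a scored model.
#'
#' @param pattern IUPAC string over A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N.
#' @param name Short label for the motif (e.g. `"Hoxb1-like"`).
#' @return An object of class `degenerate_motif` with fields `name`,
#'   `pattern` (upper-cased), `allowed` (list of character vectors),
#'   `length`, and `mask` (5 x length logical matrix; rows A,C,G,T plus a
#'   never-matching row for non-ACGT subject bases).
#' @examples
#' m <- compile_iupac("HWTTSWNATGYWDWD", "Hoxb1-like")
#' m$length
#' m$allowed[[8]]  # fixed A
#' @export
compile_iupac <- function(pattern, name = pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, !is.na(pattern))
  if (nchar(pattern) == 0L) stop("motif pattern must be non-empty")
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_DNA))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC symbol '%s' at position %d of pattern '%s'",
                 chars[bad[1]], bad[1], pattern))
  }
  allowed <- IUPAC_DNA[chars]
  names(allowed) <- NULL
  L <- length(chars)
  mask <- matrix(FALSE, nrow = 5L, ncol = L)
  for (i in seq_len(L)) mask[match(allowed[[i]], BASES), i] <- TRUE
  structure(
    list(name = name, pattern = pattern, allowed = allowed,
         length = L, mask = mask),
    class = "degenerate_motif"
  )
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cat(sprintf("degenerate_motif '%s': %s (%d nt, %s concrete expansions)\n",
              x$name, x$pattern, x$length,
              format(prod(lengths(x$allowed)), big.mark = ",")))
  invisible(x)
}

#' @export
as.character.degenerate_motif <- function(x, ...) x$pattern

#' The three packaged OCT4-SOX2 composite words
#'
#' Hoxb1-like and Utf1-like are canonical composites (SOX and OCT half-sites
#' juxtaposed) differing at a single position; Fgf4-like carries a
#' three-nucleotide spacer between the half-sites (four N positions in the
#' 18-nt word).
#'
#' @return Named list of `degenerate_motif` objects.
#' @export
default_motifs <- function() {
  read_motifs(system.file("extdata", "motifs.tsv", package = "composcan",
                          mustWork = TRUE))
}

#' Read motif definitions from a two-column TSV (name, IUPAC pattern)
#'
#' @param path TSV file with header columns `name` and `pattern`.
#' @return Named list of `degenerate_motif` objects, in file order.
#' @export
read_motifs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "pattern") %in% names(tab))) {
    stop("motif file must have columns 'name' and 'pattern': ", path)
  }
  motifs <- Map(compile_iupac, tab$pattern, tab$name)
  names(motifs) <- tab$name
  motifs
}

#' Reverse complement of a concrete DNA sequence
#'
#' Subject sequences only: ambiguity codes are rejected because scanned
#' subjects are concrete genomic sequence, never degenerate patterns.
#' Applying twice is the identity.
#'
#' @param seq Character vector of DNA strings over A,C,G,T
#'   (case-insensitive; returned upper-case).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ATGC")  # "GCAT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  seq <- toupper(seq)
  if (any(grepl("[^ACGT]", seq[nchar(seq) > 0L]))) {
    stop("reverse_complement accepts concrete A/C/G/T sequence only")
  }
  comp <- chartr("ACGT", "TGCA", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# rbind a list of data.frames, ignoring NULL/zero-row elements; `proto`
# supplies the zero-row result when nothing remains.
rbind_all <- function(lst, proto) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0L, lst)
  if (!length(lst)) return(proto)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

# Integer-encode a subject sequence: A,C,G,T -> 1..4, anything else -> 5
# (row 5 of every mask is FALSE, so non-ACGT positions can never match).
encode_seq <- function(seq) {
  codes <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], BASES)
  codes[is.na(codes)] <- 5L
  codes
}

# Forward-strand 0-based hit offsets of `mask` in integer-coded subject.
mask_hits <- function(mask, codes) {
  L <- ncol(mask)
  n <- length(codes)
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (i in seq_len(L)) {
    ok <- ok & mask[, i][codes[i:(n - L + i)]]
  }
  which(ok) - 1L
}

# Mask of the reverse-complemented pattern: reversed positions, complemented
# base sets (row order A,C,G,T -> T,G,C,A); the non-ACGT row stays last.
rc_mask <- function(mask) {
  mask[c(4L, 3L, 2L, 1L, 5L), rev(seq_len(ncol(mask))), drop = FALSE]
}

#' Does the motif match the subject at a given offset?
#'
#' @param motif A `degenerate_motif`.
#' @param seq Subject DNA string.
#' @param offset 0-based start position within `seq` (BED convention, used
#'   throughout the package).
#' @return `TRUE` iff every subject base at `offset + i` lies in the motif's
#'   allowed set at position `i`. Non-ACGT subject bases never match.
#' @export
matches_at <- function(motif, seq, offset) {
  stopifnot(inherits(motif, "degenerate_motif"), length(offset) == 1L)
  n <- nchar(seq)
  if (offset < 0L || offset + motif$length > n) {
    stop(sprintf("offset %d out of range for motif length %d on %d nt subject",
                 offset, motif$length, n))
  }
  codes <- encode_seq(substr(seq, offset + 1L, offset + motif$length))
  all(motif$mask[cbind(codes, seq_len(motif$length))])
}

#' Scan a subject sequence for a degenerate motif
#'
#' Every offset is tested; overlapping occurrences are all reported. A
#' minus-strand hit at offset `k` means the reverse complement of
#' `seq[k, k + L)` matches the motif; `matched_seq` is always the window
#' subsequence as read on the forward strand.
#'
#' @param motif A `degenerate_motif`.
#' @param seq Subject DNA string (case-insensitive; non-ACGT bases never
#'   match any position).
#' @param strands `"both"` (default) or `"forward"`.
#' @return `data.frame` with columns `offset` (0-based), `strand`
#'   (`"+"`/`"-"`), `matched_seq`; sorted by (offset, strand), deduplicated
#'   by (offset, strand). Sequences shorter than the motif yield zero rows.
#' @examples
#' hox <- compile_iupac("HWTTSWNATGYWDWD", "Hoxb1-like")
#' scan_sequence(hox, "GGAGGAAGTGTCTTTGTCATGCTAATGATTGGGGCTCC")
#' @export
scan_sequence <- function(motif, seq, strands = c("both", "forward")) {
  stopifnot(inherits(motif, "degenerate_motif"))
  strands <- match.arg(strands)
  codes <- encode_seq(seq)
  L <- motif$length
  fw <- mask_hits(motif$mask, codes)
  offset <- fw
  strand <- rep("+", length(fw))
  if (strands == "both") {
    rv <- mask_hits(rc_mask(motif$mask), codes)
    offset <- c(offset, rv)
    strand <- c(strand, rep("-", length(rv)))
  }
  ord <- order(offset, strand)
  offset <- as.integer(offset[ord])
  strand <- strand[ord]
  seq <- toupper(seq)
  data.frame(
    offset = offset,
    strand = strand,
    matched_seq = if (length(offset)) {
      substring(seq, offset + 1L, offset + L)
    } else character(0),
    stringsAsFactors = FALSE
  )
}

#' Are two same-length degenerate patterns provably disjoint?
#'
#' `TRUE` iff at some position the allowed-base sets do not intersect, in
#' which case no concrete sequence can match both patterns. Used to
#' guarantee the Hoxb1-like and Utf1-like classes (which differ at one
#' position, W vs G) never double-count a sequence.
#'
#' @param a,b `degenerate_motif` objects of equal length.
#' @return Logical scalar.
#' @export
patterns_disjoint <- function(a, b) {
  stopifnot(inherits(a, "degenerate_motif"), inherits(b, "degenerate_motif"))
  if (a$length != b$length) {
    stop("patterns_disjoint requires equal-length motifs; handle ",
         "length-heterogeneous classes separately")
  }
  for (i in seq_len(a$length)) {
    if (!any(a$allowed[[i]] %in% b$allowed[[i]])) return(TRUE)
  }
  FALSE
}

#' Analytic per-offset, per-strand chance hit rate
#'
#' Under an i.i.d. base model, the probability that a motif matches at one
#' fixed offset on one strand is the product over positions of the summed
#' probabilities of the allowed bases.
#'
#' @param motif A `degenerate_motif`.
#' @param base_probs Numeric probabilities for A, C, G, T (named or in that
#'   order); non-negative, summing to 1. Default uniform.
#' @return Probability in `[0, 1]`.
#' @examples
#' hox <- compile_iupac("HWTTSWNATGYWDWD", "Hoxb1-like")
#' expected_hit_rate(hox)  # 6912 / 4^15
#' @export
expected_hit_rate <- function(motif, base_probs = c(A = 0.25, C = 0.25,
                                                    G = 0.25, T = 0.25)) {
  stopifnot(inherits(motif, "degenerate_motif"))
  if (!is.numeric(base_probs) || length(base_probs) != 4L ||
      anyNA(base_probs) || any(base_probs < 0) ||
      abs(sum(base_probs) - 1) > 1e-8) {
    stop("base_probs must be 4 non-negative probabilities summing to 1")
  }
  if (!is.null(names(base_probs))) {
    if (!setequal(names(base_probs), BASES)) {
      stop("base_probs names must be A, C, G, T")
    }
    base_probs <- base_probs[BASES]
  }
  prod(vapply(motif$allowed,
              function(set) sum(base_probs[match(set, BASES)]),
              numeric(1)))
}

#' Sample one concrete expansion of a degenerate pattern
#'
#' Draws uniformly over the pattern's concrete expansions (each position
#' sampled uniformly from its allowed set, independently).
#'
#' @param motif A `degenerate_motif`.
#' @return A single DNA string of length `motif$length`.
#' @export
sample_expansion <- function(motif) {
  stopifnot(inherits(motif, "degenerate_motif"))
  paste(vapply(motif$allowed,
               function(set) set[sample.int(length(set), 1L)],
               character(1)),
        collapse = "")
}

#' Write motif hits as TSV
#'
#' @param hits Hit table as produced by [scan_peaks()] (columns `peak_id`,
#'   `motif`, `offset`, `summit_offset`, `strand`, `matched_seq`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  cols <- c("peak_id", "motif", "offset", "summit_offset", "strand",
            "matched_seq")
  stopifnot(all(cols %in% names(hits)))
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
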