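# Shared fixtures: the three published EMSA probe sequences (worked-example
# inputs for the scanner) and an independent scanning oracle built on
# Biostrings ambiguity-aware matching.

PROBE_HOXB1 <- "GGAGGAAGTGTCTTTGTCATGCTAATGATTGGGGCTCC"
PROBE_FGF4 <- "GGAGAAGAAAACTCTTTGTTTGGATGCTAATGGGATACTAAGCTCC"
PROBE_UTF1 <- "GGAGAAGATGAGAGCCCTCATTGTTATGCTAGTGAAGTGCCAAGCTCC"

hoxb1 <- function() compile_iupac("HWTTSWNATGYWDWD", "Hoxb1-like")
utf1 <- function() compile_iupac("HWTTSWNATGYWDGD", "Utf1-like")
fgf4 <- function() compile_iupac("HWTTSWNNNNATGYWDWD", "Fgf4-like")

# Independent double-strand oracle: Biostrings matchPattern with IUPAC
# ambiguity codes active on the pattern side. Returns a data.frame with the
# same (offset, strand) convention as scan_sequence.
oracle_scan <- function(pattern, seq) {
  subj <- Biostrings::DNAString(seq)
  fw <- Biostrings::matchPattern(pattern, subj, fixed = "subject")
  rv <- Biostrings::matchPattern(
    pattern, Biostrings::reverseComplement(subj), fixed = "subject")
  n <- nchar(seq)
  L <- nchar(pattern)
  out <- rbind(
    data.frame(offset = Biostrings::start(fw) - 1L,
               strand = rep("+", length(fw))),
    # map reverse-complement coordinates back to forward offsets
    data.frame(offset = n - (Biostrings::start(rv) - 1L) - L,
               strand = rep("-", length(rv)))
  )
  out[order(out$offset, out$strand), , drop = FALSE]
}

# Vectorized expansion sampler for property tests (independent of
# sample_expansion): one uniformly drawn concrete string per row.
sample_expansions <- function(motif, n) {
  cols <- lapply(motif$allowed, function(set)
    set[sample.int(length(set), n, replace = TRUE)])
  do.call(paste0, cols)
}

# Small deterministic toy genome with one planted Hoxb1-like word.
toy_genome <- function() {
  seq <- paste0(strrep("A", 60), "CTTTGTCATGCTAAT", strrep("A", 60))
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- "chrT"
  g
}
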