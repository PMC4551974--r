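# Seeded synthetic data: random genomes, peak sets with planted composite
# motifs (with a strict mode guaranteeing no chance occurrences), TSS
# tables, and expression matrices with planted fold effects. Every
# generator emits a ground-truth table for parameter-recovery tests.

#' Generator configuration
#'
#' Defaults mirror the scale of the ChIP-seq analysis this package
#' re-implements: 3,798 summit windows with 554 Hoxb1-like, 47 Utf1-like
#' and 26 Fgf4-like plantings. The genome carries a peak-free tail after
#' the peak zone so that unlinked genes can be placed farther than
#' `max_distance` from every motif-bearing summit.
#'
#' @param n_peaks Number of peaks (100-bp windows).
#' @param plant_counts Named integer vector: plantings per motif class;
#'   names must match `names(motifs)`. Sum must not exceed `n_peaks`.
#' @param motifs Named list of `degenerate_motif`s; default the three
#'   packaged composite words.
#' @param width Window width (nt), even.
#' @param gc Genome GC fraction in (0, 1); default 0.5 (uniform bases, the
#'   background model of the analytic chance-hit rate).
#' @param slot_gap Minimum gap between consecutive windows (bp).
#' @param peak_free_tail Motif-free genome tail length (bp); must exceed
#'   `max_distance` for unlinked TSS placement.
#' @param strict If `TRUE` (default), windows and flanks are
#'   rejection-sampled until the only motif occurrences in the genome are
#'   the planted ones.
#' @param n_genes,link_fraction TSS table size and the fraction of genes
#'   placed within `max_distance` of a motif-bearing summit.
#' @param max_distance Summit-to-TSS link distance (bp).
#' @param effect_fraction Fraction of motif-linked genes given a planted
#'   fold effect.
#' @param effect_fold_range Planted |fold| range; folds are drawn
#'   log-uniformly from it, with up/down direction equiprobable. The lower
#'   end sits strictly above the 2-fold classification threshold so that
#'   planted effects are recoverable in principle.
#' @param noise_sd Multiplicative log-normal noise (sd on the natural log
#'   scale) applied per sample.
#' @param group_sizes Named replicate counts per condition; first name is
#'   the reference. Default `c(SWT = 2, S113 = 2, S98_102 = 3)`.
#' @param attempt_budget Rejection-sampling attempts per window (and
#'   genome-cleaning sweeps) before giving up.
#' @param seed Master seed; sub-generators derive fixed offsets from it.
#' @return A validated config list of class `generator_config`.
#' @export
generator_config <- function(n_peaks = 3798L,
                             plant_counts = c("Hoxb1-like" = 554L,
                                              "Utf1-like" = 47L,
                                              "Fgf4-like" = 26L),
                             motifs = default_motifs(),
                             width = 100L,
                             gc = 0.5,
                             slot_gap = 30L,
                             peak_free_tail = 60000L,
                             strict = TRUE,
                             n_genes = 400L,
                             link_fraction = 0.6,
                             max_distance = 50000L,
                             effect_fraction = 0.4,
                             effect_fold_range = c(2.5, 6),
                             noise_sd = 0.1,
                             group_sizes = c(SWT = 2L, S113 = 2L,
                                             S98_102 = 3L),
                             attempt_budget = 200L,
                             seed = 1L) {
  stopifnot(n_peaks >= 1L, all(plant_counts >= 0L),
            sum(plant_counts) <= n_peaks,
            all(names(plant_counts) %in% names(motifs)),
            width %% 2L == 0L, gc > 0, gc < 1,
            slot_gap >= 2L, peak_free_tail > max_distance,
            n_genes >= 1L, link_fraction >= 0, link_fraction <= 1,
            effect_fraction >= 0, effect_fraction <= 1,
            length(effect_fold_range) == 2L, effect_fold_range[1] > 1,
            noise_sd >= 0, length(group_sizes) >= 2L,
            !is.null(names(group_sizes)))
  cfg <- as.list(environment())
  cfg$genome_length <- n_peaks * (width + slot_gap) + peak_free_tail
  class(cfg) <- "generator_config"
  cfg
}

random_dna <- function(n, gc) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a random genome
#'
#' I.i.d. bases with `P(G) + P(C) = gc`, split evenly within each pair;
#' seeded and reproducible.
#'
#' @param length Genome length (bp), at least 1000.
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed (scoped to this call).
#' @param chrom Sequence name; default `"chrS"`.
#' @return A `Biostrings::DNAStringSet` with one sequence.
#' @export
generate_genome <- function(length, gc = 0.5, seed = 1L, chrom = "chrS") {
  if (gc <= 0 || gc >= 1) stop("gc must lie strictly between 0 and 1")
  if (length < 1000L) stop("genome length must be at least 1000 bp")
  seq <- with_seed(seed, random_dna(length, gc))
  out <- Biostrings::DNAStringSet(seq)
  names(out) <- chrom
  out
}

# Scan one long sequence with every motif on both strands; returns
# data.frame(motif, offset, strand).
scan_all <- function(motifs, seq) {
  out <- lapply(motifs, function(m) {
    h <- scan_sequence(m, seq, strands = "both")
    if (nrow(h)) data.frame(motif = m$name, offset = h$offset,
                            strand = h$strand, stringsAsFactors = FALSE)
    else NULL
  })
  rbind_all(out, data.frame(motif = character(0), offset = integer(0),
                            strand = character(0), stringsAsFactors = FALSE))
}

# Draw one window: background bases plus (optionally) a planted expansion
# of `motif` at a random offset/strand. In strict mode the draw is rejected
# until the window's only motif occurrence (across all classes, both
# strands) is the planted one -- or none at all for unplanted windows.
draw_window <- function(class_motif, motifs, width, gc, strict, budget) {
  for (attempt in seq_len(budget)) {
    seq <- random_dna(width, gc)
    planted <- NULL
    if (!is.null(class_motif)) {
      L <- class_motif$length
      expansion <- sample_expansion(class_motif)
      offset <- sample.int(width - L + 1L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") expansion else reverse_complement(expansion)
      substr(seq, offset + 1L, offset + L) <- ins
      planted <- list(expansion = expansion, offset = offset,
                      strand = strand)
    }
    if (!strict) return(list(seq = seq, planted = planted))
    found <- scan_all(motifs, seq)
    ok <- if (is.null(planted)) {
      nrow(found) == 0L
    } else {
      nrow(found) == 1L && found$motif == class_motif$name &&
        found$offset == planted$offset && found$strand == planted$strand
    }
    if (ok) return(list(seq = seq, planted = planted))
  }
  stop(sprintf("window rejection sampling exceeded %d attempts", budget))
}

#' Plant composite motifs into peak windows of a synthetic genome
#'
#' Carves non-overlapping `width`-bp windows into the genome's peak zone
#' (everything before the peak-free tail), writes one uniformly sampled
#' concrete expansion of the assigned class at a random in-window offset
#' and strand, and emits the peak table plus a ground-truth table. In
#' strict mode every window is rejection-sampled until it contains no
#' chance occurrence of any class other than the planted one, and the
#' flanking sequence is then cleaned so that genome-wide the only motif
#' occurrences are the planted ones.
#'
#' @param genome `DNAStringSet` (single sequence) from [generate_genome()].
#' @param config A [generator_config()].
#' @return List with `genome` (modified `DNAStringSet`), `peaks` (peak
#'   `data.frame`; peak interval == window), and `truth`
#'   (`data.frame(peak_id, class, offset, strand, expansion, chrom,
#'   win_start, win_end, summit)`; `class` is `NA` for unplanted windows).
#' @export
plant_peaks <- function(genome, config) {
  stopifnot(inherits(config, "generator_config"),
            length(genome) == 1L)
  chrom <- names(genome)[1]
  gseq <- toupper(as.character(genome[[1]]))
  glen <- nchar(gseq)
  zone <- glen - config$peak_free_tail
  slot <- zone %/% config$n_peaks
  width <- config$width
  if (slot < width + config$slot_gap) {
    stop("genome peak zone too small for the requested number of windows")
  }
  motifs <- config$motifs
  with_seed(config$seed + 1L, {
    classes <- sample(rep(c(names(config$plant_counts), NA_character_),
                          c(config$plant_counts,
                            config$n_peaks - sum(config$plant_counts))))
    jitter_max <- slot - width - 1L
    win_start <- (seq_len(config$n_peaks) - 1L) * slot +
      sample.int(jitter_max, config$n_peaks, replace = TRUE)
    windows <- vector("list", config$n_peaks)
    for (i in seq_len(config$n_peaks)) {
      cm <- if (is.na(classes[i])) NULL else motifs[[classes[i]]]
      windows[[i]] <- draw_window(cm, motifs, width, config$gc,
                                  config$strict, config$attempt_budget)
    }
    # splice windows into the genome in one pass
    win_end <- win_start + width
    pieces <- character(2L * config$n_peaks + 1L)
    prev <- 0L
    for (i in seq_len(config$n_peaks)) {
      pieces[2L * i - 1L] <- substring(gseq, prev + 1L, win_start[i])
      pieces[2L * i] <- windows[[i]]$seq
      prev <- win_end[i]
    }
    pieces[2L * config$n_peaks + 1L] <- substring(gseq, prev + 1L, glen)
    gseq <- paste(pieces, collapse = "")
    planted <- lapply(windows, `[[`, "planted")
    truth <- data.frame(
      peak_id = sprintf("peak_%05d", seq_len(config$n_peaks)),
      class = classes,
      offset = vapply(planted, function(p)
        if (is.null(p)) NA_integer_ else p$offset, integer(1)),
      strand = vapply(planted, function(p)
        if (is.null(p)) NA_character_ else p$strand, character(1)),
      expansion = vapply(planted, function(p)
        if (is.null(p)) NA_character_ else p$expansion, character(1)),
      chrom = chrom,
      win_start = win_start,
      win_end = win_end,
      summit = win_start + width %/% 2L,
      stringsAsFactors = FALSE
    )
    if (config$strict) {
      gseq <- clean_flanks(gseq, truth, motifs, config)
    }
  })
  peaks <- data.frame(
    chrom = chrom, start = truth$win_start, end = truth$win_end,
    peak_id = truth$peak_id, summit = truth$summit,
    stringsAsFactors = FALSE
  )
  out <- Biostrings::DNAStringSet(gseq)
  names(out) <- chrom
  list(genome = out, peaks = peaks, truth = truth)
}

# Redraw any genome position involved in a non-planted motif occurrence
# (never touching planted expansion spans) until the genome-wide occurrence
# set equals the planted set. Windows are internally clean already, so
# offending hits live in flanks or straddle window boundaries.
clean_flanks <- function(gseq, truth, motifs, config) {
  pl <- truth[!is.na(truth$class), , drop = FALSE]
  expected <- character(0)
  protected <- logical(nchar(gseq))
  if (nrow(pl)) {
    g_off <- pl$win_start + pl$offset
    L <- vapply(pl$class, function(cl) motifs[[cl]]$length, integer(1))
    expected <- paste(pl$class, g_off, pl$strand)
    for (i in seq_len(nrow(pl))) {
      protected[(g_off[i] + 1L):(g_off[i] + L[i])] <- TRUE
    }
  }
  chars <- NULL
  for (sweep in seq_len(config$attempt_budget)) {
    found <- scan_all(motifs, gseq)
    keys <- paste(found$motif, found$offset, found$strand)
    bad <- found[!keys %in% expected, , drop = FALSE]
    if (nrow(bad) == 0L) return(gseq)
    if (is.null(chars)) chars <- strsplit(gseq, "", fixed = TRUE)[[1]]
    redraw <- logical(length(chars))
    for (i in seq_len(nrow(bad))) {
      L <- motifs[[bad$motif[i]]]$length
      redraw[(bad$offset[i] + 1L):(bad$offset[i] + L)] <- TRUE
    }
    redraw <- redraw & !protected
    gc <- config$gc
    chars[redraw] <- sample(BASES, sum(redraw), replace = TRUE,
                            prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                     (1 - gc) / 2))
    gseq <- paste(chars, collapse = "")
  }
  stop("genome cleaning exceeded the sweep budget")
}

#' Generate a TSS table tied to motif-bearing summits
#'
#' A configured fraction of genes is placed within `max_distance` of a
#' (randomly chosen) motif-bearing summit; the remaining genes are placed
#' in the peak-free tail, farther than `max_distance` from every
#' motif-bearing summit.
#'
#' @param truth Truth table from [plant_peaks()].
#' @param genome_length Genome length (bp).
#' @param n_genes Number of genes.
#' @param link_fraction Fraction of genes to link; default 0.6.
#' @param max_distance Link distance (bp); default 50000.
#' @param seed Integer seed (scoped to this call).
#' @return List with `tss` (`data.frame(gene_id, chrom, tss, strand)`) and
#'   `truth` (`data.frame(gene_id, linked, source_peak)`).
#' @export
generate_tss <- function(truth, genome_length, n_genes,
                         link_fraction = 0.6, max_distance = 50000L,
                         seed = 1L) {
  stopifnot(n_genes >= 1L)
  motif_peaks <- truth[!is.na(truth$class), , drop = FALSE]
  n_linked <- round(link_fraction * n_genes)
  if (n_linked > 0L && nrow(motif_peaks) == 0L) {
    stop("no motif-bearing peaks to link genes to")
  }
  tail_start <- if (nrow(motif_peaks))
    max(motif_peaks$summit) + max_distance + 1L else 0L
  if (n_linked < n_genes && tail_start > genome_length - 1L) {
    stop("genome too small to place unlinked genes beyond the link distance")
  }
  chrom <- truth$chrom[1]
  with_seed(seed, {
    linked_src <- if (n_linked > 0L)
      sample(motif_peaks$peak_id, n_linked, replace = TRUE) else character(0)
    pos_linked <- vapply(linked_src, function(p) {
      s <- motif_peaks$summit[motif_peaks$peak_id == p]
      as.integer(min(max(s + sample.int(2L * max_distance + 1L, 1L) -
                           max_distance - 1L, 0L), genome_length - 1L))
    }, integer(1), USE.NAMES = FALSE)
    n_un <- n_genes - n_linked
    pos_un <- if (n_un > 0L)
      sample(tail_start:(genome_length - 1L), n_un) else integer(0)
    tss <- data.frame(
      gene_id = sprintf("gene_%04d", seq_len(n_genes)),
      chrom = chrom,
      tss = c(pos_linked, pos_un),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  list(
    tss = tss,
    truth = data.frame(
      gene_id = tss$gene_id,
      linked = c(rep(TRUE, n_linked), rep(FALSE, n_genes - n_linked)),
      source_peak = c(linked_src, rep(NA_character_, n_genes - n_linked)),
      stringsAsFactors = FALSE
    )
  )
}

#' Generate an expression matrix with planted fold effects
#'
#' Baseline levels are drawn log-uniformly above the background floor;
#' affected genes are multiplied by their planted fold in the named
#' condition; multiplicative log-normal noise (sd on the natural log
#' scale) is applied independently per sample.
#'
#' @param genes Character vector of gene ids.
#' @param effects `data.frame(gene_id, condition, fold)`; genes/conditions
#'   not listed have fold 1. Folds must be positive.
#' @param group_sizes Named replicate counts per condition; the first name
#'   is the reference condition.
#' @param noise_sd Log-normal noise sd (natural log scale); 0 for
#'   noiseless data.
#' @param baseline_range Linear-scale baseline range; drawn log-uniformly.
#' @param seed Integer seed (scoped to this call).
#' @return List with `mat` (genes x samples matrix, columns
#'   `<condition>_<replicate>`), `sample_groups` (named list mapping
#'   condition to column names), and `truth` (`data.frame(gene_id,
#'   baseline)` plus one `fold_<condition>` column per non-reference
#'   condition).
#' @export
generate_expression <- function(genes, effects = NULL,
                                group_sizes = c(SWT = 2L, S113 = 2L,
                                                S98_102 = 3L),
                                noise_sd = 0.1,
                                baseline_range = c(20, 2000),
                                seed = 1L) {
  stopifnot(length(genes) >= 1L, !anyDuplicated(genes),
            noise_sd >= 0, all(baseline_range > 0))
  conds <- names(group_sizes)
  if (is.null(effects)) {
    effects <- data.frame(gene_id = character(0), condition = character(0),
                          fold = numeric(0))
  }
  stopifnot(all(effects$fold > 0), all(effects$gene_id %in% genes),
            all(effects$condition %in% conds[-1]))
  fold <- matrix(1, nrow = length(genes), ncol = length(conds),
                 dimnames = list(genes, conds))
  if (nrow(effects)) {
    fold[cbind(effects$gene_id, effects$condition)] <- effects$fold
  }
  with_seed(seed, {
    baseline <- exp(stats::runif(length(genes), log(baseline_range[1]),
                                 log(baseline_range[2])))
    cols <- unlist(lapply(conds, function(cn)
      paste0(cn, "_", seq_len(group_sizes[[cn]]))))
    mat <- matrix(0, nrow = length(genes), ncol = length(cols),
                  dimnames = list(genes, cols))
    for (cn in conds) {
      for (r in seq_len(group_sizes[[cn]])) {
        noise <- if (noise_sd > 0)
          exp(stats::rnorm(length(genes), 0, noise_sd)) else 1
        mat[, paste0(cn, "_", r)] <- baseline * fold[, cn] * noise
      }
    }
  })
  sample_groups <- lapply(conds, function(cn)
    paste0(cn, "_", seq_len(group_sizes[[cn]])))
  names(sample_groups) <- conds
  truth <- data.frame(gene_id = genes, baseline = baseline,
                      stringsAsFactors = FALSE)
  for (cn in conds[-1]) truth[[paste0("fold_", cn)]] <- fold[, cn]
  list(mat = mat, sample_groups = sample_groups, truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Orchestrates [generate_genome()], [plant_peaks()], [generate_tss()] and
#' [generate_expression()] from one config. Planted expression effects are
#' assigned to a random `effect_fraction` of the motif-linked genes, each
#' in one randomly chosen non-reference condition, with |fold| drawn
#' log-uniformly from `effect_fold_range` and direction (up/down)
#' equiprobable.
#'
#' @param config A [generator_config()].
#' @return List with `genome`, `peaks`, `peak_truth`, `tss`, `tss_truth`,
#'   `expression` (matrix), `sample_groups`, `expr_truth`, `effects`, and
#'   the `config`.
#' @export
simulate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  genome <- generate_genome(config$genome_length, config$gc,
                            seed = config$seed)
  pk <- plant_peaks(genome, config)
  ts <- generate_tss(pk$truth, config$genome_length, config$n_genes,
                     config$link_fraction, config$max_distance,
                     seed = config$seed + 2L)
  linked_genes <- ts$truth$gene_id[ts$truth$linked]
  conds <- names(config$group_sizes)
  effects <- with_seed(config$seed + 3L, {
    n_eff <- round(config$effect_fraction * length(linked_genes))
    if (n_eff > 0L) {
      g <- sample(linked_genes, n_eff)
      fr <- config$effect_fold_range
      mag <- exp(stats::runif(n_eff, log(fr[1]), log(fr[2])))
      dir <- sample(c(1, -1), n_eff, replace = TRUE)
      data.frame(gene_id = g,
                 condition = sample(conds[-1], n_eff, replace = TRUE),
                 fold = ifelse(dir > 0, mag, 1 / mag),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = character(0), condition = character(0),
                 fold = numeric(0))
    }
  })
  ex <- generate_expression(ts$tss$gene_id, effects, config$group_sizes,
                            config$noise_sd, seed = config$seed + 4L)
  list(genome = pk$genome, peaks = pk$peaks, peak_truth = pk$truth,
       tss = ts$tss, tss_truth = ts$truth,
       expression = ex$mat, sample_groups = ex$sample_groups,
       expr_truth = ex$truth, effects = effects, config = config)
}

#' Write a synthetic dataset to standard file formats
#'
#' FASTA genome, headerless BED-like peak TSV, TSS TSV, expression TSV,
#' sample-group TSV, and truth tables.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    peaks = file.path(dir, "peaks.tsv"),
    tss = file.path(dir, "tss.tsv"),
    expression = file.path(dir, "expression.tsv"),
    sample_groups = file.path(dir, "sample_groups.tsv"),
    peak_truth = file.path(dir, "truth_peaks.tsv"),
    tss_truth = file.path(dir, "truth_tss.tsv"),
    expr_truth = file.path(dir, "truth_expression.tsv")
  )
  Biostrings::writeXStringSet(dataset$genome, paths["genome"])
  write_peaks(dataset$peaks, paths["peaks"])
  utils::write.table(dataset$tss, paths["tss"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expr <- data.frame(gene_id = rownames(dataset$expression),
                     dataset$expression, check.names = FALSE)
  utils::write.table(expr, paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sg <- data.frame(
    sample = unlist(dataset$sample_groups, use.names = FALSE),
    condition = rep(names(dataset$sample_groups),
                    lengths(dataset$sample_groups))
  )
  utils::write.table(sg, paths["sample_groups"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$peak_truth, paths["peak_truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$tss_truth, paths["tss_truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$expr_truth, paths["expr_truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
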