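# One-config orchestration: scan -> background -> link -> compare, with
# stage-granular logging, a run manifest (parameters, seed, input
# checksums) and a plain-text report ranking motif classes by abundance.

#' Pipeline configuration
#'
#' Parameter defaults are the constants of the analysis this package
#' re-implements: 100-bp summit windows scanned on both strands, a 50-kb
#' summit-to-TSS link distance, an expression background floor of 5 and a
#' 2-fold classification threshold.
#'
#' @param genome,peaks,motifs,tss,expression,sample_groups Input paths
#'   (FASTA / TSV; see the reader functions). `motifs = NULL` uses the
#'   packaged composite words; `tss`/`expression`/`sample_groups = NULL`
#'   disable the corresponding stages.
#' @param outdir Output directory.
#' @param width Window width (nt), even.
#' @param strands `"both"` or `"forward"`.
#' @param max_distance Summit-to-TSS distance (bp).
#' @param floor Expression background floor (linear units).
#' @param threshold Fold-change threshold (> 1).
#' @param gc_tolerance Background GC matching tolerance.
#' @param n_background Background windows; `NULL` = one per peak window.
#' @param bin_width Positional-distribution bin width (nt).
#' @param reference Reference condition name; `NULL` = first condition in
#'   the sample-group file.
#' @param confidence_filter Optional predicate on the peak table (see
#'   [assign_peaks_to_genes()]).
#' @param seed Integer seed for background selection.
#' @return Config list of class `pipeline_config` (not yet validated; see
#'   [validate_config()]).
#' @export
pipeline_config <- function(genome = NULL, peaks = NULL, motifs = NULL,
                            tss = NULL, expression = NULL,
                            sample_groups = NULL, outdir = "composcan_out",
                            width = 100L, strands = "both",
                            max_distance = 50000L, floor = 5,
                            threshold = 2, gc_tolerance = 0.02,
                            n_background = NULL, bin_width = 5L,
                            reference = NULL, confidence_filter = NULL,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Injects defaults for absent optional fields and reports every violated
#' invariant at once rather than failing on the first.
#'
#' @param config A [pipeline_config()] (a bare list is coerced).
#' @return The validated config. If any invariant is violated, an error
#'   whose message lists all violations; the full character vector is also
#'   attached as the condition's `errors` field.
#' @export
validate_config <- function(config) {
  defaults <- pipeline_config()
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  class(config) <- "pipeline_config"
  errs <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  need(!is.null(config$genome), "genome path is required")
  need(!is.null(config$peaks), "peaks path is required")
  for (nm in c("genome", "peaks", "motifs", "tss", "expression",
               "sample_groups")) {
    p <- config[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      errs <- c(errs, sprintf("%s file not found: %s", nm, p))
    }
  }
  need(is.numeric(config$width) && config$width > 0 &&
         config$width %% 2 == 0, "width must be a positive even number")
  need(config$strands %in% c("both", "forward"),
       "strands must be 'both' or 'forward'")
  need(is.numeric(config$max_distance) && config$max_distance >= 0,
       "max_distance must be non-negative")
  need(is.numeric(config$floor) && config$floor > 0,
       "floor must be positive")
  need(is.numeric(config$threshold) && config$threshold > 1,
       "threshold must exceed 1")
  need(is.numeric(config$gc_tolerance) && config$gc_tolerance >= 0,
       "gc_tolerance must be non-negative")
  need(is.numeric(config$bin_width) && config$bin_width > 0 &&
         config$width %% config$bin_width == 0,
       "bin_width must be positive and divide width")
  if (!is.null(config$expression)) {
    need(!is.null(config$sample_groups),
         "sample_groups file is required when expression is given")
  }
  if (length(errs)) {
    stop(structure(
      class = c("composcan_config_error", "error", "condition"),
      list(message = paste0("invalid pipeline config:\n  - ",
                            paste(errs, collapse = "\n  - ")),
           call = sys.call(-1), errors = errs)))
  }
  config
}

stage_msg <- function(...) message(sprintf("[composcan] %s", sprintf(...)))

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline from a config
#'
#' Stages: window extraction + motif scan; GC-matched background selection
#' and positional distributions; peak-to-gene linking (if a TSS table is
#' configured); fold-change classification of the per-class gene sets (if
#' an expression matrix is configured). Writes counts, hits, distribution,
#' assignment, scatter and summary TSVs, a JSON run manifest with input
#' checksums, and a plain-text report ranking motif classes by abundance.
#'
#' @param config A [pipeline_config()]; validated internally.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the in-memory results (`scan`,
#'   `distribution`, `assignments`, `gene_sets`, `comparisons`,
#'   `summaries`, `manifest`, `outputs`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_config(config)
  log_ <- if (quiet) function(...) invisible() else stage_msg
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  out <- function(name) {
    p <- file.path(config$outdir, name)
    outputs <<- c(outputs, p)
    p
  }

  # --- scan stage ---------------------------------------------------------
  motifs <- if (is.null(config$motifs)) default_motifs()
            else read_motifs(config$motifs)
  peaks <- tryCatch(read_peaks(config$peaks),
                    error = function(e) stop("scan stage: ", conditionMessage(e)))
  genome <- load_genome(config$genome)
  scan <- scan_peaks(genome, peaks, motifs, config$width, config$strands)
  log_("scan: %d windows scanned (%d peaks read), %d hits",
       scan$counts$n_windows[1], nrow(peaks), nrow(scan$hits))
  write_tsv(scan$counts, out("counts.tsv"))
  write_hits(scan$hits, out("hits.tsv"))

  # --- background stage ---------------------------------------------------
  n_bg <- if (is.null(config$n_background)) scan$counts$n_windows[1]
          else config$n_background
  dist <- positional_distribution(scan$hits, config$width, config$bin_width)
  if (n_bg > 0) {
    bg <- select_background(genome, peaks, n_bg, config$width,
                            config$gc_tolerance, config$seed)
    bg_scan <- scan_peaks(NULL, NULL, motifs, config$width, config$strands,
                          windows = bg)
    bg_dist <- positional_distribution(bg_scan$hits, config$width,
                                       config$bin_width)
    log_("background: %d windows, %d hits", n_bg, nrow(bg_scan$hits))
    dist <- merge(dist, stats::setNames(
      bg_dist, c("motif", "bin_lo", "bin_hi", "background_count")),
      by = c("motif", "bin_lo", "bin_hi"), all.x = TRUE)
    dist$background_count[is.na(dist$background_count)] <- 0L
    dist <- dist[order(dist$motif, dist$bin_lo), ]
  } else {
    dist$background_count <- NA_integer_
  }
  write_tsv(dist, out("distribution.tsv"))

  # --- link stage ---------------------------------------------------------
  assignments <- NULL
  gene_sets <- NULL
  if (!is.null(config$tss)) {
    tss <- tryCatch(read_tss(config$tss),
                    error = function(e) stop("link stage: ", conditionMessage(e)))
    peaks_cls <- peak_motif_classes(peaks, scan$hits)
    assignments <- assign_peaks_to_genes(peaks_cls, tss,
                                         config$max_distance,
                                         config$confidence_filter)
    gene_sets <- class_gene_sets(assignments,
                                 classes = vapply(motifs, `[[`, "", "name"))
    log_("link: %d gene-peak assignments; class gene sets: %s",
         nrow(assignments),
         paste(sprintf("%s=%d", names(gene_sets), lengths(gene_sets)),
               collapse = ", "))
    write_tsv(assignments, out("assignments.tsv"))
  }

  # --- compare stage ------------------------------------------------------
  comparisons <- NULL
  summaries <- NULL
  if (!is.null(config$expression)) {
    if (is.null(assignments)) {
      stop("compare stage: expression given but no TSS table to link genes")
    }
    mat <- tryCatch(read_expression(config$expression),
                    error = function(e)
                      stop("compare stage: ", conditionMessage(e)))
    sg_tab <- utils::read.delim(config$sample_groups,
                                stringsAsFactors = FALSE)
    groups <- split(sg_tab$sample, sg_tab$condition)
    groups <- groups[unique(sg_tab$condition)]  # keep file order
    ref <- if (is.null(config$reference)) names(groups)[1]
           else config$reference
    if (!ref %in% names(groups)) {
      stop("compare stage: reference condition not in sample groups: ", ref)
    }
    means <- average_condition(mat, groups)
    comparisons <- list()
    summaries <- list()
    for (cond in setdiff(names(groups), ref)) {
      cmp <- compare_conditions(means[, cond], means[, ref],
                                config$floor, config$threshold)
      comparisons[[cond]] <- cmp
      for (cl in names(gene_sets)) {
        genes_here <- intersect(gene_sets[[cl]], cmp$gene_id)
        st <- scatter_table(genes_here, cmp)
        tag <- gsub("[^A-Za-z0-9]+", "_", paste(cl, cond, sep = "_"))
        write_tsv(st, out(sprintf("scatter_%s.tsv", tag)))
        summaries[[length(summaries) + 1L]] <- data.frame(
          motif = cl, condition = cond, reference = ref,
          n_genes = nrow(st), t(fc_summary(st)),
          stringsAsFactors = FALSE)
      }
    }
    summaries <- do.call(rbind, summaries); rownames(summaries) <- NULL
    log_("compare: %d condition(s) vs %s over %d class gene set(s)",
         length(comparisons), ref, length(gene_sets))
    write_tsv(summaries, out("summary.tsv"))
  }

  # --- manifest + report --------------------------------------------------
  input_paths <- Filter(Negate(is.null),
                        config[c("genome", "peaks", "motifs", "tss",
                                 "expression", "sample_groups")])
  input_paths <- Filter(is.character, input_paths)
  manifest <- list(
    parameters = config[c("width", "strands", "max_distance", "floor",
                          "threshold", "gc_tolerance", "bin_width",
                          "seed")],
    n_background = n_bg,
    inputs = lapply(input_paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    records = list(peaks_read = nrow(peaks),
                   windows_scanned = scan$counts$n_windows[1],
                   hits = nrow(scan$hits),
                   assignments = if (is.null(assignments)) 0L
                                 else nrow(assignments))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  rank <- scan$counts[order(-scan$counts$total_occurrences), ]
  report <- c(
    "composcan run report",
    "====================",
    sprintf("windows scanned: %d (width %d nt, strands: %s)",
            scan$counts$n_windows[1], config$width, config$strands),
    "",
    "motif classes ranked by total occurrences:",
    sprintf("  %d. %-12s %5d occurrences in %5d windows",
            seq_len(nrow(rank)), rank$motif, rank$total_occurrences,
            rank$windows_with_hit),
    if (!is.null(summaries)) c(
      "",
      "fold-change classification (up/down/unchanged) per class gene set:",
      sprintf("  %-12s %s vs %s: %d/%d/%d (n=%d)",
              summaries$motif, summaries$condition, summaries$reference,
              summaries$up, summaries$down, summaries$unchanged,
              summaries$n_genes))
  )
  writeLines(report, out("report.txt"))
  log_("done: %d output files in %s", length(outputs), config$outdir)

  invisible(list(scan = scan, distribution = dist,
                 assignments = assignments, gene_sets = gene_sets,
                 comparisons = comparisons, summaries = summaries,
                 manifest = manifest, outputs = outputs))
}

#' Generate a synthetic dataset and run the pipeline on it
#'
#' Single-command demonstration: simulates a dataset from a
#' [generator_config()], writes it to `file.path(outdir, "data")`, then
#' runs [run_pipeline()] on the written files.
#'
#' @param outdir Output directory.
#' @param config A [generator_config()]; the default full-scale preset
#'   takes tens of seconds, so a scaled-down config is handy for quick
#'   looks.
#' @param quiet Suppress stage messages.
#' @return Invisibly, `list(dataset, result)`.
#' @export
run_demo <- function(outdir, config = generator_config(), quiet = FALSE) {
  dataset <- simulate_dataset(config)
  paths <- write_dataset(dataset, file.path(outdir, "data"))
  pc <- pipeline_config(
    genome = paths[["genome"]], peaks = paths[["peaks"]],
    tss = paths[["tss"]], expression = paths[["expression"]],
    sample_groups = paths[["sample_groups"]],
    outdir = outdir, width = config$width,
    max_distance = config$max_distance, seed = config$seed
  )
  result <- run_pipeline(pc, quiet = quiet)
  invisible(list(dataset = dataset, result = result))
}
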