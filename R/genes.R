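# Peak-to-gene assignment by summit-to-TSS distance and fold-change
# classification of per-gene condition means. No differential-expression
# statistic is involved: classification is purely fold-change based, with a
# background floor applied to the linear-scale means first.

#' Read a TSS annotation table
#'
#' TSV with header columns `gene_id`, `chrom`, `tss` (0-based position),
#' `strand`.
#'
#' @param path TSV file.
#' @return `data.frame` with those columns.
#' @export
read_tss <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "tss", "strand")
  if (!all(req %in% names(tab))) {
    stop("TSS table must have columns ", paste(req, collapse = ", "))
  }
  if (any(tab$tss < 0)) stop("negative TSS position")
  tab
}

#' Annotate peaks with the motif classes found in their windows
#'
#' @param peaks Peak `data.frame`.
#' @param hits Hit table from [scan_peaks()].
#' @return `peaks` with an added `motif_classes` column: comma-joined motif
#'   names present in that peak's window (`""` when none).
#' @export
peak_motif_classes <- function(peaks, hits) {
  cls <- vapply(peaks$peak_id, function(p) {
    paste(sort(unique(hits$motif[hits$peak_id == p])), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  peaks$motif_classes <- cls
  peaks
}

#' Assign motif-bearing peaks to genes by summit-to-TSS distance
#'
#' Distance is `|summit - tss|`, strand-agnostic and boundary-inclusive at
#' `max_distance`. A peak near several TSSs serves all of them and a gene
#' aggregates over all its peaks (one-to-many both ways). High-confidence
#' peak selection is a pluggable predicate on the peak table; the default
#' passes everything.
#'
#' @param peaks Peak `data.frame` carrying a `motif_classes` column (see
#'   [peak_motif_classes()]).
#' @param tss TSS `data.frame` (see [read_tss()]).
#' @param max_distance Maximum summit-to-TSS distance in bp; default 50000.
#' @param confidence_filter Optional `function(peaks) -> logical` selecting
#'   high-confidence peaks (e.g. a score threshold); `NULL` keeps all.
#' @return `data.frame(gene_id, peak_id, distance, motif_classes)`, one row
#'   per qualifying (gene, peak) pair.
#' @export
assign_peaks_to_genes <- function(peaks, tss, max_distance = 50000L,
                                  confidence_filter = NULL) {
  if (is.null(tss) || nrow(tss) == 0L) stop("empty TSS table")
  if (!"motif_classes" %in% names(peaks)) {
    stop("peaks must carry motif_classes (see peak_motif_classes())")
  }
  if (!is.null(confidence_filter)) {
    keep <- confidence_filter(peaks)
    stopifnot(is.logical(keep), length(keep) == nrow(peaks))
    peaks <- peaks[keep, , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(tss)), function(i) {
    same <- peaks$chrom == tss$chrom[i]
    d <- abs(peaks$summit - tss$tss[i])
    sel <- same & d <= max_distance
    if (!any(sel)) return(NULL)
    data.frame(gene_id = tss$gene_id[i],
               peak_id = peaks$peak_id[sel],
               distance = d[sel],
               motif_classes = peaks$motif_classes[sel],
               stringsAsFactors = FALSE)
  })
  rbind_all(out, data.frame(gene_id = character(0), peak_id = character(0),
                            distance = integer(0),
                            motif_classes = character(0),
                            stringsAsFactors = FALSE))
}

#' Per-class gene sets from peak assignments
#'
#' A gene belongs to every motif class carried by at least one of its
#' assigned peaks; classes are not mutually exclusive.
#'
#' @param assignments Output of [assign_peaks_to_genes()].
#' @param classes Class names to report; default: every class observed.
#' @return Named list of character vectors of gene ids (sorted, unique).
#' @export
class_gene_sets <- function(assignments, classes = NULL) {
  split_cls <- strsplit(assignments$motif_classes, ",", fixed = TRUE)
  long <- data.frame(
    gene_id = rep(assignments$gene_id, lengths(split_cls)),
    class = unlist(split_cls),
    stringsAsFactors = FALSE
  )
  long <- long[nzchar(long$class), , drop = FALSE]
  if (is.null(classes)) classes <- sort(unique(long$class))
  sets <- lapply(classes, function(cl)
    sort(unique(long$gene_id[long$class == cl])))
  names(sets) <- classes
  sets
}

#' Per-gene condition means on the linear scale
#'
#' @param mat Numeric expression matrix, genes in rows (rownames = gene
#'   ids), samples in columns; linear scale, values >= 0.
#' @param sample_groups Named list mapping condition name -> character
#'   vector of column names.
#' @return Numeric matrix genes x conditions of arithmetic means.
#' @export
average_condition <- function(mat, sample_groups) {
  stopifnot(is.matrix(mat), is.numeric(mat), !is.null(rownames(mat)))
  if (any(mat < 0, na.rm = TRUE)) stop("negative expression value")
  missing <- setdiff(unlist(sample_groups), colnames(mat))
  if (length(missing)) {
    stop("sample(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  means <- vapply(sample_groups, function(cols)
    rowMeans(mat[, cols, drop = FALSE]), numeric(nrow(mat)))
  if (is.null(dim(means))) means <- matrix(means, nrow = nrow(mat),
                                           dimnames = list(rownames(mat),
                                                           names(sample_groups)))
  means
}

#' Classify fold changes between two conditions
#'
#' Each condition mean is first raised to `floor` if below it (values below
#' the floor are treated as non-expressed background), then the ratio
#' `mean_a / mean_b` determines the class: `up` iff ratio >= `threshold`,
#' `down` iff ratio <= 1/`threshold`, else `unchanged`. log2 values are
#' computed from the floored means (heatmap scale).
#'
#' @param means_a,means_b Named numeric vectors of linear-scale condition
#'   means over the same genes (names = gene ids).
#' @param floor Background floor in expression units; default 5.
#' @param threshold Fold-change threshold; must exceed 1. Default 2.
#' @return `data.frame(gene_id, mean_a, mean_b, ratio, fc_class, log2_a,
#'   log2_b)` with floored means and `fc_class` in
#'   `c("up", "down", "unchanged")`.
#' @export
compare_conditions <- function(means_a, means_b, floor = 5, threshold = 2) {
  stopifnot(floor > 0, threshold > 1)
  if (is.null(names(means_a)) || is.null(names(means_b))) {
    stop("condition means must be named by gene id")
  }
  if (!setequal(names(means_a), names(means_b))) {
    stop("conditions cover different gene sets")
  }
  means_b <- means_b[names(means_a)]
  if (any(means_a < 0) || any(means_b < 0)) stop("negative expression value")
  a <- pmax(means_a, floor)
  b <- pmax(means_b, floor)
  ratio <- a / b
  fc_class <- ifelse(ratio >= threshold, "up",
                     ifelse(ratio <= 1 / threshold, "down", "unchanged"))
  data.frame(
    gene_id = names(means_a),
    mean_a = unname(a), mean_b = unname(b),
    ratio = unname(ratio), fc_class = unname(fc_class),
    log2_a = unname(log2(a)), log2_b = unname(log2(b)),
    stringsAsFactors = FALSE
  )
}

#' Restrict comparisons to a gene set, with class counts
#'
#' The table behind a pairwise expression scatter plot: one row per gene of
#' the set with its two floored condition means and fold-change class, plus
#' up/down/unchanged summary counts (attached as attribute `fc_summary` and
#' available via [fc_summary()]). Plotting is left to the caller.
#'
#' @param gene_set Character vector of gene ids; must all be present in
#'   `comparisons`.
#' @param comparisons Output of [compare_conditions()].
#' @return `data.frame(gene_id, mean_b, mean_a, ratio, fc_class)` with
#'   attribute `fc_summary = c(up=, down=, unchanged=)`.
#' @export
scatter_table <- function(gene_set, comparisons) {
  missing <- setdiff(gene_set, comparisons$gene_id)
  if (length(missing)) {
    stop("gene(s) absent from comparisons: ", paste(missing, collapse = ", "))
  }
  rows <- comparisons[comparisons$gene_id %in% gene_set,
                      c("gene_id", "mean_b", "mean_a", "ratio", "fc_class")]
  rownames(rows) <- NULL
  counts <- c(up = sum(rows$fc_class == "up"),
              down = sum(rows$fc_class == "down"),
              unchanged = sum(rows$fc_class == "unchanged"))
  attr(rows, "fc_summary") <- counts
  rows
}

#' Up/down/unchanged counts of a scatter table
#' @param x Output of [scatter_table()].
#' @return Named integer vector `c(up=, down=, unchanged=)`.
#' @export
fc_summary <- function(x) attr(x, "fc_summary")

#' Read an expression matrix TSV
#'
#' Genes in rows, samples in columns, linear scale; first column `gene_id`.
#'
#' @param path TSV file.
#' @return Numeric matrix with gene-id rownames.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "gene_id") stop("first column must be gene_id")
  mat <- as.matrix(tab[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- tab$gene_id
  mat
}
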