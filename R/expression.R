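#' Build the expression container
#'
#' Wraps a gene x cell TPM matrix in a [SingleCellExperiment] with three
#' layers: `tpm` (raw), `logtpm` (log2(TPM+1) after zeroing TPM < 1 as
#' unreliable) and, after [mean_centre()], `centred`. Row metadata records
#' the genomic position of each gene, whether it is annotated, and whether
#' it is an RNA spike-in; column metadata records the tumour-group label.
#'
#' Unannotated genes are retained but flagged (`annotated = FALSE`) so that
#' downstream chromosomal smoothing can exclude them; spike-ins are flagged
#' so that gene filtering and CNV inference skip them.
#'
#' @param tpm Non-negative numeric gene x cell matrix with dimnames.
#' @param annotation Optional annotation `data.frame`
#'   (gene_id/chromosome/start/end); see [read_annotation()].
#' @param groups Optional named character vector or single label: tumour
#'   group per cell.
#' @param spike_ids Character vector of spike-in row ids.
#' @return A `SingleCellExperiment`.
#' @export
expression_matrix <- function(tpm, annotation = NULL, groups = NULL,
                              spike_ids = character()) {
  tpm <- as.matrix(tpm)
  if (is.null(rownames(tpm)) || is.null(colnames(tpm))) {
    stop("TPM matrix needs gene and cell dimnames")
  }
  if (anyDuplicated(rownames(tpm))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(tpm))) stop("duplicate cell ids")
  if (any(tpm < 0)) stop("negative TPM values")

  rd <- S4Vectors::DataFrame(row.names = rownames(tpm))
  rd$is_spike <- rownames(tpm) %in% spike_ids
  if (!is.null(annotation)) {
    validate_annotation(annotation)
    idx <- match(rownames(tpm), annotation$gene_id)
    rd$annotated <- !is.na(idx) & !rd$is_spike
    rd$chromosome <- annotation$chromosome[idx]
    rd$gene_start <- annotation$start[idx]
    rd$gene_end <- annotation$end[idx]
  } else {
    rd$annotated <- FALSE
    rd$chromosome <- NA_character_
    rd$gene_start <- NA_integer_
    rd$gene_end <- NA_integer_
  }

  if (is.null(groups)) {
    groups <- rep("all", ncol(tpm))
  } else if (length(groups) == 1 && is.null(names(groups))) {
    groups <- rep(groups, ncol(tpm))
  } else if (!is.null(names(groups))) {
    if (!all(colnames(tpm) %in% names(groups))) {
      stop("groups missing for some cells")
    }
    groups <- unname(groups[colnames(tpm)])
  }

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(tpm = tpm, logtpm = log_layer(tpm)),
    rowData = rd,
    colData = S4Vectors::DataFrame(group = groups,
                                   row.names = colnames(tpm))
  )
  sce
}

# TPM < 1 is treated as unreliable and zeroed before the log2(TPM + 1)
# transform, so logtpm is exactly 0 wherever TPM < 1.
log_layer <- function(tpm) {
  tpm[tpm < 1] <- 0
  log2(tpm + 1)
}

#' Load an expression matrix with annotation and group labels
#'
#' @param matrix_path TSV or MTX expression file ([read_expression_matrix()]).
#' @param annotation_path BED or GTF gene annotation.
#' @param groups_path Two-column TSV (cell id, tumour group), no header
#'   required.
#' @param spike_ids Spike-in row ids.
#' @param rows_path,cols_path Row/column id files for MTX input.
#' @return A `SingleCellExperiment`; see [expression_matrix()].
#' @export
load_expression <- function(matrix_path, annotation_path = NULL,
                            groups_path = NULL, spike_ids = character(),
                            rows_path = NULL, cols_path = NULL) {
  tpm <- read_expression_matrix(matrix_path, rows_path, cols_path)
  ann <- if (!is.null(annotation_path)) read_annotation(annotation_path)
  groups <- NULL
  if (!is.null(groups_path)) {
    g <- read.delim(groups_path, header = FALSE, stringsAsFactors = FALSE)
    if (tolower(g[1, 1]) %in% c("cell", "cell_id")) g <- g[-1, , drop = FALSE]
    groups <- setNames(as.character(g[[2]]), g[[1]])
  }
  expression_matrix(tpm, annotation = ann, groups = groups,
                    spike_ids = spike_ids)
}

#' Default cell- and gene-level QC thresholds
#'
#' The four per-cell criteria (total reads, mapping rate, detected genes,
#' intergenic fraction) are configurable rather than fixed constants;
#' `min_expressed_fraction_per_group` is the 10% group-expression rule used
#' by [filter_genes()].
#'
#' @param min_total_reads,min_mapping_rate,min_detected_genes,max_intergenic_fraction
#'   Per-cell cutoffs.
#' @param min_expressed_fraction_per_group Gene retention cutoff in (0, 1).
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(min_total_reads = 1e6, min_mapping_rate = 0.5,
                          min_detected_genes = 1000,
                          max_intergenic_fraction = 0.3,
                          min_expressed_fraction_per_group = 0.10) {
  th <- list(min_total_reads = min_total_reads,
             min_mapping_rate = min_mapping_rate,
             min_detected_genes = min_detected_genes,
             max_intergenic_fraction = max_intergenic_fraction,
             min_expressed_fraction_per_group =
               min_expressed_fraction_per_group)
  if (!all(vapply(th, is.finite, logical(1)))) stop("thresholds must be finite")
  if (th$min_expressed_fraction_per_group <= 0 ||
      th$min_expressed_fraction_per_group >= 1) {
    stop("min_expressed_fraction_per_group must be in (0, 1)")
  }
  th
}

#' Remove low-quality cells
#'
#' Applies the four sequencing-QC criteria: minimum total reads, minimum
#' mapping rate, minimum detected genes and maximum intergenic fraction.
#' A cell is retained only if it passes all four; column order is preserved.
#'
#' @param sce Expression container.
#' @param qc `data.frame` with one row per cell (rownames = cell ids or a
#'   `cell_id` column) and columns `total_reads`, `mapping_rate`,
#'   `detected_genes`, `intergenic_fraction`.
#' @param thresholds See [qc_thresholds()].
#' @return Filtered `SingleCellExperiment`.
#' @export
filter_cells <- function(sce, qc, thresholds = qc_thresholds()) {
  if ("cell_id" %in% names(qc)) {
    rownames(qc) <- qc$cell_id
  }
  cells <- colnames(sce)
  missing <- setdiff(cells, rownames(qc))
  if (length(missing)) {
    stop("no QC record for cell(s): ", paste(missing, collapse = ", "))
  }
  qc <- qc[cells, , drop = FALSE]
  bad_frac <- qc$mapping_rate < 0 | qc$mapping_rate > 1 |
    qc$intergenic_fraction < 0 | qc$intergenic_fraction > 1
  if (any(bad_frac)) stop("QC fractions must lie in [0, 1]")
  pass <- qc$total_reads >= thresholds$min_total_reads &
    qc$mapping_rate >= thresholds$min_mapping_rate &
    qc$detected_genes >= thresholds$min_detected_genes &
    qc$intergenic_fraction <= thresholds$max_intergenic_fraction
  sce[, pass]
}

#' Remove genes with low expression across tumour groups
#'
#' A gene counts as expressed in a cell when its `logtpm` value is > 0
#' (i.e. TPM >= 1). Under the default `"max"` reading, a gene is retained
#' iff in at least one tumour group the fraction of expressing cells
#' reaches `min_expressed_fraction_per_group`; under the `"groups"`
#' reading, iff the fraction of groups containing any expressing cell
#' reaches that cutoff. Spike-ins are exempt and always retained.
#'
#' @param sce Expression container with group labels.
#' @param thresholds See [qc_thresholds()].
#' @param rule `"max"` (fraction of cells within the best group) or
#'   `"groups"` (fraction of groups with any expression).
#' @return Filtered `SingleCellExperiment`.
#' @export
filter_genes <- function(sce, thresholds = qc_thresholds(),
                         rule = c("max", "groups")) {
  rule <- match.arg(rule)
  groups <- sce$group
  if (is.null(groups) || !length(groups)) stop("group labels required")
  tab <- table(groups)
  if (any(tab == 0)) stop("tumour group with zero cells")
  expressed <- SummarizedExperiment::assay(sce, "logtpm") > 0
  cutoff <- thresholds$min_expressed_fraction_per_group
  glev <- names(tab)
  frac_by_group <- vapply(glev, function(g) {
    rowMeans(expressed[, groups == g, drop = FALSE])
  }, numeric(nrow(sce)))
  frac_by_group <- matrix(frac_by_group, nrow = nrow(sce))
  keep <- if (rule == "max") {
    apply(frac_by_group, 1, max) >= cutoff
  } else {
    rowMeans(frac_by_group > 0) >= cutoff
  }
  keep <- keep | SummarizedExperiment::rowData(sce)$is_spike
  sce[keep, ]
}

#' Mean-centre the log layer per gene
#'
#' Adds (or refreshes) a `centred` assay: log2(TPM+1) minus each gene's mean
#' over retained cells. The `tpm` and `logtpm` layers are untouched, because
#' several analyses (spike-in checks, intratumoral correlations,
#' self-normalizing scores, centroid classification) read un-centred values.
#'
#' @param sce Expression container.
#' @return The container with a `centred` assay.
#' @export
mean_centre <- function(sce) {
  lg <- SummarizedExperiment::assay(sce, "logtpm")
  SummarizedExperiment::assay(sce, "centred") <- lg - rowMeans(lg)
  sce
}

#' Check spike-in consistency across cells
#'
#' For every pair of detected spike-ins, computes the per-cell difference of
#' log2(TPM+1) values (the spike log-ratio), its cohort mean and sd, and
#' flags cells whose ratio deviates more than `k` sd from the mean.
#' Spike-ins never observed (logtpm 0 in all cells) are reported as
#' undetected and excluded from ratios.
#'
#' @param sce Expression container.
#' @param spike_ids At least two spike-in row ids.
#' @param expected_copies Optional numeric vector of input copy numbers,
#'   parallel to `spike_ids` (reported alongside ratios).
#' @param k Flagging threshold in cohort standard deviations.
#' @return List with `detected` (named logical), `pairs` (data.frame:
#'   spike_a, spike_b, mean_ratio, sd_ratio, expected_log2_ratio) and
#'   `flagged` (named logical per cell: deviant on any pair).
#' @export
check_spikeins <- function(sce, spike_ids, expected_copies = NULL, k = 3) {
  if (length(spike_ids) < 2) stop("need at least two spike-in ids")
  absent <- setdiff(spike_ids, rownames(sce))
  if (length(absent)) {
    stop("spike id(s) absent from matrix: ", paste(absent, collapse = ", "))
  }
  lg <- SummarizedExperiment::assay(sce, "logtpm")[spike_ids, , drop = FALSE]
  detected <- rowSums(lg > 0) > 0
  det_ids <- spike_ids[detected]
  pairs <- if (length(det_ids) >= 2) {
    cmb <- utils::combn(det_ids, 2)
    do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- cmb[1, j]; b <- cmb[2, j]
      ratio <- lg[a, ] - lg[b, ]
      exp_r <- if (!is.null(expected_copies)) {
        log2(expected_copies[match(a, spike_ids)] /
               expected_copies[match(b, spike_ids)])
      } else NA_real_
      data.frame(spike_a = a, spike_b = b,
                 mean_ratio = mean(ratio), sd_ratio = sd(ratio),
                 expected_log2_ratio = exp_r,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(spike_a = character(), spike_b = character(),
               mean_ratio = numeric(), sd_ratio = numeric(),
               expected_log2_ratio = numeric())
  }
  flagged <- setNames(rep(FALSE, ncol(sce)), colnames(sce))
  if (nrow(pairs)) {
    for (j in seq_len(nrow(pairs))) {
      ratio <- lg[pairs$spike_a[j], ] - lg[pairs$spike_b[j], ]
      s <- pairs$sd_ratio[j]
      if (is.finite(s) && s > 0) {
        flagged <- flagged | abs(ratio - pairs$mean_ratio[j]) > k * s
      }
    }
  }
  list(detected = setNames(detected, spike_ids), pairs = pairs,
       flagged = flagged)
}
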