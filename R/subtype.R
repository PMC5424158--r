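#' Signed-weight module score per cell
#'
#' `score = sum(w_i * x_i) / sum(|w_i|)` over the module genes measured in
#' the matrix, computed on the mean-centred log layer, so that a cell at
#' the cohort average of every module gene scores 0. Used to scale ER and
#' HER2 signalling per cell.
#'
#' @param sce Expression container with a `centred` assay (see
#'   [mean_centre()]) or a plain centred matrix.
#' @param module `data.frame` with columns `gene_id` and `weight`
#'   (signs +/-1 or arbitrary finite weights).
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(sce, module) {
  m <- if (is(sce, "SummarizedExperiment")) {
    SummarizedExperiment::assay(sce, "centred")
  } else {
    as.matrix(sce)
  }
  stopifnot(all(c("gene_id", "weight") %in% names(module)))
  if (!all(is.finite(module$weight))) stop("module weights must be finite")
  keep <- module$gene_id %in% rownames(m)
  if (!any(keep)) stop("no module genes measured")
  module <- module[keep, , drop = FALSE]
  w <- module$weight
  colSums(m[module$gene_id, , drop = FALSE] * w) / sum(abs(w))
}

#' Fit ER/HER2 score thresholds on a labelled reference
#'
#' Grid-searches axis-aligned thresholds `(t_ER, t_HER2)` over the observed
#' score values, maximizing the accuracy of [classify_subtype()] against
#' the reference labels. Ties are broken toward the smallest thresholds
#' (lexicographically: smallest `t_HER2`, then smallest `t_ER`).
#'
#' @param reference_scores `data.frame` with columns `er` and `her2`.
#' @param reference_labels Character vector of `ER+`, `HER2+`, `TNBC`
#'   labels, parallel to the rows.
#' @return List `t_er`, `t_her2`, `accuracy`.
#' @export
fit_subtype_thresholds <- function(reference_scores, reference_labels) {
  stopifnot(all(c("er", "her2") %in% names(reference_scores)))
  if (!all(c("ER+", "HER2+", "TNBC") %in% reference_labels)) {
    stop("reference must contain all three subtype classes")
  }
  er <- reference_scores$er
  her2 <- reference_scores$her2
  cand_er <- sort(unique(c(-Inf, er)))
  cand_her2 <- sort(unique(c(-Inf, her2)))
  best <- list(t_er = NA, t_her2 = NA, accuracy = -1)
  for (th in cand_her2) {
    her2_pos <- her2 > th
    for (te in cand_er) {
      pred <- ifelse(her2_pos, "HER2+", ifelse(er > te, "ER+", "TNBC"))
      acc <- mean(pred == reference_labels)
      if (acc > best$accuracy) {
        best <- list(t_er = te, t_her2 = th, accuracy = acc)
      }
    }
  }
  best
}

#' Classify cells as ER+, HER2+ or TNBC from module scores
#'
#' HER2 takes precedence: a cell with `her2_score > t_her2` is HER2+
#' regardless of its ER score (dosage-driven HER2 positivity dominates
#' clinic-style calling); otherwise ER+ when `er_score > t_er`; otherwise
#' TNBC. Concomitant ER positivity of HER2+ cells is retained in the
#' `er_positive` evidence column.
#'
#' @param er_score,her2_score Numeric vectors (parallel).
#' @param t_er,t_her2 Thresholds, e.g. from [fit_subtype_thresholds()].
#' @param cell_ids Optional ids for the output.
#' @return `data.frame`: cell_id, er_score, her2_score, call,
#'   er_positive, her2_positive.
#' @export
classify_subtype <- function(er_score, her2_score, t_er, t_her2,
                             cell_ids = NULL) {
  if (is.null(cell_ids)) {
    cell_ids <- names(er_score)
    if (is.null(cell_ids)) cell_ids <- seq_along(er_score)
  }
  er_pos <- er_score > t_er
  her2_pos <- her2_score > t_her2
  call <- ifelse(her2_pos, "HER2+", ifelse(er_pos, "ER+", "TNBC"))
  data.frame(cell_id = as.character(cell_ids), er_score = er_score,
             her2_score = her2_score, call = call, er_positive = er_pos,
             her2_positive = her2_pos, stringsAsFactors = FALSE,
             row.names = NULL)
}

# Spearman rho and two-sided p. t-approximation at n >= 12; exact
# permutation distribution (via cor.test's AS89 algorithm) below that.
spearman_test <- function(x, y) {
  n <- length(x)
  rho <- suppressWarnings(cor(x, y, method = "spearman"))
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_))
  if (n < 12) {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = TRUE))
    return(list(rho = unname(ct$estimate), p = ct$p.value))
  }
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), n - 2))
}

#' Classify cells against subtype centroids by Spearman correlation
#'
#' Genes never expressed in any cell are removed first; the un-centred
#' log2(TPM+1) layer is used (centring would fabricate spurious
#' positivity for genes that are simply zero everywhere). Each cell is
#' correlated (Spearman) with every centroid over the intersecting genes;
#' it is assigned to every subtype with positive rho and p below `alpha`
#' — possibly several subtypes, possibly none.
#'
#' @param sce Expression container or plain log-scale matrix.
#' @param centroids Signature-gene x subtype numeric matrix.
#' @param alpha Significance cutoff (default 0.05).
#' @param min_genes Minimum intersecting genes per cell (default 10).
#' @return List of class `TnbcCalls`: `table` (long `data.frame`:
#'   cell_id, subtype, rho, p, assigned), `assigned` (named list of
#'   subtype sets per cell).
#' @export
centroid_classify <- function(sce, centroids, alpha = 0.05,
                              min_genes = 10) {
  m <- if (is(sce, "SummarizedExperiment")) {
    SummarizedExperiment::assay(sce, "logtpm")
  } else {
    as.matrix(sce)
  }
  m <- m[rowSums(m > 0) > 0, , drop = FALSE]
  shared <- intersect(rownames(m), rownames(centroids))
  if (length(shared) < min_genes) {
    stop("fewer than ", min_genes, " genes intersect the centroids")
  }
  m <- m[shared, , drop = FALSE]
  centroids <- centroids[shared, , drop = FALSE]
  rows <- lapply(colnames(m), function(cell) {
    x <- m[, cell]
    do.call(rbind, lapply(colnames(centroids), function(s) {
      st <- spearman_test(x, centroids[, s])
      data.frame(cell_id = cell, subtype = s, rho = st$rho, p = st$p,
                 assigned = !is.na(st$rho) && st$rho > 0 &&
                   !is.na(st$p) && st$p < alpha,
                 stringsAsFactors = FALSE)
    }))
  })
  tab <- do.call(rbind, rows)
  assigned <- lapply(split(tab, tab$cell_id), function(d) {
    d$subtype[d$assigned]
  })[colnames(m)]
  structure(list(table = tab, assigned = assigned, alpha = alpha),
            class = "TnbcCalls")
}

#' Aggressiveness signature scores, co-activation and rare-cell flags
#'
#' Scores each cell on every supplied gene set with the rank-based
#' single-sample scorer, reports pairwise Pearson correlations of the
#' scores across cells, and flags cells reaching the top `1 - q` fraction
#' (default top 5%) on both members of each set pair — candidate rare
#' co-activated cells.
#'
#' @param sce Expression container (or matrix on the log scale).
#' @param sets Named list of gene sets (e.g. EMT, stemness, angiogenesis,
#'   proliferation, recurrence), as from [read_gmt()].
#' @param q Quantile defining the cutoff (default 0.95: top 5%).
#' @param alpha Rank-weight exponent passed to [ssgsea_score()].
#' @return List: `scores` (cell x set matrix), `correlations` (set x set
#'   Pearson matrix), `cutoffs` (per-set score cutoff), `flags` (named
#'   list per set pair of doubly-extreme cell ids).
#' @export
aggressiveness_scores <- function(sce, sets, q = 0.95, alpha = 0.25) {
  if (!length(sets)) stop("no gene sets supplied")
  if (any(!lengths(sets))) stop("empty gene set")
  scores <- vapply(sets, function(s) ssgsea_score(sce, s, alpha = alpha),
                   numeric(ncol(sce)))
  rownames(scores) <- colnames(sce)
  n <- nrow(scores)
  # round before ceiling: (1 - 0.95) * 100 is 5 + 4e-15 in floating point
  k_top <- ceiling(round((1 - q) * n, 9))
  cutoffs <- apply(scores, 2, function(s) {
    sort(s, decreasing = TRUE)[k_top]
  })
  flags <- list()
  if (ncol(scores) >= 2) {
    cmb <- utils::combn(colnames(scores), 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      flags[[paste(a, b, sep = "|")]] <-
        rownames(scores)[scores[, a] >= cutoffs[a] &
                           scores[, b] >= cutoffs[b]]
    }
  }
  list(scores = scores, correlations = cor(scores), cutoffs = cutoffs,
       flags = flags)
}

#' Read a two-column module table (gene, weight)
#' @param path TSV path; header optional.
#' @return `data.frame` with `gene_id`, `weight`.
#' @export
read_module <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (suppressWarnings(is.na(as.numeric(df[1, 2])))) df <- df[-1, ]
  data.frame(gene_id = as.character(df[[1]]),
             weight = as.numeric(df[[2]]), stringsAsFactors = FALSE)
}

#' Read a centroid table (gene x subtype TSV with header)
#' @param path TSV path; first column gene ids.
#' @return Numeric matrix.
#' @export
read_centroids <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (ncol(m) < 2 || nrow(m) < 2) stop("centroid table too small")
  if (anyDuplicated(colnames(m))) stop("duplicate subtype names")
  m
}
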