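#' Hierarchically cluster per-cell CNV profiles
#'
#' Agglomerative clustering of the smoothed chromosomal profiles with Ward
#' linkage on Euclidean distance (the defaults used throughout the
#' package), cut at `n_clusters`.
#'
#' @param profiles A `CnvProfiles` object.
#' @param n_clusters Number of clusters to cut.
#' @param linkage `"ward"` (mapped to `hclust`'s `ward.D2`) or any other
#'   `hclust` method name.
#' @param distance Any `dist` method (default `"euclidean"`).
#' @return List of class `ClusterResult`: `assignment` (named integer),
#'   `tree` (`hclust`), `linkage`, `distance`, `n_clusters`.
#' @export
cluster_profiles <- function(profiles, n_clusters, linkage = "ward",
                             distance = "euclidean") {
  m <- t(profiles$smoothed)
  if (nrow(m) < 2) stop("need >= 2 cells")
  if (n_clusters > nrow(m)) stop("n_clusters exceeds number of cells")
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- hclust(dist(m, method = distance), method = method)
  structure(list(assignment = cutree(tree, k = n_clusters), tree = tree,
                 linkage = method, distance = distance,
                 n_clusters = n_clusters),
            class = "ClusterResult")
}

#' Choose the number of profile clusters by mean silhouette width
#'
#' Cuts the Ward dendrogram of the smoothed profiles at every k in
#' `k_range` and returns the cut maximizing the mean silhouette width.
#' An optional helper: the cluster count is normally chosen by the
#' analyst (e.g. number of patients plus one).
#'
#' @param profiles A `CnvProfiles` object.
#' @param k_range Candidate cluster counts.
#' @inheritParams cluster_profiles
#' @return The selected k (integer).
#' @export
choose_n_clusters <- function(profiles, k_range = 2:12, linkage = "ward",
                              distance = "euclidean") {
  m <- t(profiles$smoothed)
  k_range <- k_range[k_range < nrow(m)]
  d <- dist(m, method = distance)
  tree <- hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
  sil <- vapply(k_range, function(k) {
    mean(cluster::silhouette(cutree(tree, k), d)[, 3])
  }, numeric(1))
  k_range[which.max(sil)]
}

#' Export a clustering dendrogram as Newick
#' @param clusters A `ClusterResult`.
#' @param path Output path.
#' @export
write_dendrogram <- function(clusters, path) {
  ape::write.tree(ape::as.phylo(clusters$tree), file = path)
  invisible(path)
}

#' Copy-number signal strength of each cell
#'
#' The mean squared smoothed (centred) value over the genome — the energy
#' of the inferred CNV profile. Diploid cells with no coherent chromosomal
#' deviation score near zero; aneuploid carcinoma cells score high.
#'
#' @param profiles A `CnvProfiles` object (centred).
#' @return Named numeric vector, one non-negative score per cell.
#' @export
cnv_signal_score <- function(profiles) {
  colMeans(profiles$smoothed^2)
}

#' Single-sample rank-based gene-set enrichment score
#'
#' For each cell, genes are ranked by expression (descending, ties by
#' average rank). Walking down the ranking, an in-set cumulative
#' distribution weighted by rank magnitude to the power `alpha` is
#' compared against the unweighted out-of-set cumulative distribution;
#' the score is the mean difference over all positions, so it lies in
#' (-1, 1), is positive when set genes concentrate at the top of the
#' cell's ranking, and depends on the expression vector only through
#' ranks.
#'
#' @param sce Expression container or plain gene x cell matrix.
#' @param gene_set Character vector of gene ids (>= 1 measured).
#' @param alpha Rank-weight exponent (default 0.25).
#' @param layer Assay used when `sce` is a container (default `logtpm`).
#' @return Named numeric vector of per-cell scores.
#' @export
ssgsea_score <- function(sce, gene_set, alpha = 0.25, layer = "logtpm") {
  m <- if (is(sce, "SummarizedExperiment")) {
    SummarizedExperiment::assay(sce, layer)
  } else {
    as.matrix(sce)
  }
  if (length(gene_set) == 0) stop("empty gene set")
  in_set <- rownames(m) %in% gene_set
  if (!any(in_set)) stop("no gene-set member measured")
  n <- nrow(m)
  apply(m, 2, function(x) {
    rnk <- rank(-x, ties.method = "average")   # 1 = highest expression
    ord <- order(rnk)
    inside <- in_set[ord]
    w <- (n - rnk[ord] + 1)^alpha
    cdf_in <- cumsum(ifelse(inside, w, 0)) / sum(w[inside])
    cdf_out <- cumsum(!inside) / sum(!inside)
    mean(cdf_in - cdf_out)
  })
}

#' Default thresholds for marker-free cell-type assignment
#'
#' Signature-score cutoffs default to `NA`, meaning they are derived per
#' dataset by [bimodal_cutpoint()] on the cohort's score distribution
#' (the scores are bimodal in a mixed tumour: a population expressing the
#' signature and one that does not, with a dataset-dependent absolute
#' level). Fixed numeric cutoffs can be supplied instead.
#'
#' @param t_cnv Minimum median CNV signal for a carcinoma-like cluster.
#' @param f_dom Minimum fraction of a cluster's cells from one tumour
#'   group for the cluster to count as patient-specific.
#' @param t_imm,t_str,t_epi Signature-score cutoffs for immune, stromal
#'   and epithelial calls; `NA` = data-driven bimodal cut.
#' @param unclassified_as_stromal Count unclassified cells as stromal when
#'   their epithelial score is also below `t_epi`.
#' @return Named list.
#' @export
typing_thresholds <- function(t_cnv = 0.022, f_dom = 0.5, t_imm = NA,
                              t_str = NA, t_epi = NA,
                              unclassified_as_stromal = TRUE) {
  list(t_cnv = t_cnv, f_dom = f_dom, t_imm = t_imm, t_str = t_str,
       t_epi = t_epi, unclassified_as_stromal = unclassified_as_stromal)
}

#' Otsu-style cut separating a bimodal score distribution
#'
#' Returns the threshold (midpoint between adjacent observed values)
#' maximizing the between-class variance `w1 w2 (m1 - m2)^2` of the
#' induced two-group split. Deterministic; no distributional assumption
#' beyond bimodality.
#'
#' @param x Numeric vector (>= 2 distinct values).
#' @return Single cut value.
#' @export
bimodal_cutpoint <- function(x) {
  v <- sort(unique(x))
  if (length(v) < 2) stop("need >= 2 distinct values")
  cuts <- (v[-1] + v[-length(v)]) / 2
  crit <- vapply(cuts, function(tc) {
    lo <- x <= tc
    w1 <- mean(lo)
    w1 * (1 - w1) * (mean(x[lo]) - mean(x[!lo]))^2
  }, numeric(1))
  cuts[which.max(crit)]
}

#' Marker-free carcinoma / immune / stromal cell calls
#'
#' A cluster is carcinoma-like iff its median CNV signal exceeds `t_cnv`
#' AND it is dominated by a single tumour group (fraction >= `f_dom`) —
#' carcinoma clusters are patient-specific whereas the non-carcinoma
#' cluster mixes patients. Cells outside carcinoma-like clusters are
#' called immune when their immune signature score exceeds `t_imm`, else
#' stromal when the stromal score exceeds `t_str`; remaining cells are
#' flagged unclassified and, by default, counted as stromal when their
#' epithelial score is also low.
#'
#' @param clusters A `ClusterResult`.
#' @param profiles The clustered `CnvProfiles`.
#' @param scores `data.frame`/matrix of per-cell signature scores with
#'   columns `immune`, `stromal`, `epithelial` (cells as rownames).
#' @param groups Named tumour-group label per cell.
#' @param thresholds See [typing_thresholds()].
#' @return `data.frame` of per-cell labels: cell_id, call, cluster,
#'   cnv_signal, the three scores, unclassified flag.
#' @export
assign_cell_types <- function(clusters, profiles, scores, groups,
                              thresholds = typing_thresholds()) {
  req <- c("t_cnv", "f_dom", "t_imm", "t_str")
  if (!all(req %in% names(thresholds))) {
    stop("configuration error: thresholds must include ",
         paste(req, collapse = ", "))
  }
  scores <- as.data.frame(scores)
  if (!all(c("immune", "stromal", "epithelial") %in% names(scores))) {
    stop("scores must include immune, stromal and epithelial sets")
  }
  if (is.na(thresholds$t_imm)) {
    thresholds$t_imm <- bimodal_cutpoint(scores$immune)
  }
  if (is.na(thresholds$t_str)) {
    thresholds$t_str <- bimodal_cutpoint(scores$stromal)
  }
  if (is.na(thresholds$t_epi)) {
    thresholds$t_epi <- bimodal_cutpoint(scores$epithelial)
  }
  cells <- colnames(profiles$smoothed)
  signal <- cnv_signal_score(profiles)
  assignment <- clusters$assignment[cells]
  groups <- groups[cells]
  scores <- scores[cells, , drop = FALSE]

  carcinoma_cluster <- vapply(unique(assignment), function(k) {
    memb <- cells[assignment == k]
    dom <- max(table(groups[memb])) / length(memb)
    median(signal[memb]) > thresholds$t_cnv && dom >= thresholds$f_dom
  }, logical(1))
  names(carcinoma_cluster) <- unique(assignment)

  call <- character(length(cells))
  unclassified <- logical(length(cells))
  for (i in seq_along(cells)) {
    if (carcinoma_cluster[as.character(assignment[i])]) {
      call[i] <- "carcinoma"
    } else if (scores$immune[i] > thresholds$t_imm) {
      call[i] <- "immune"
    } else if (scores$stromal[i] > thresholds$t_str) {
      call[i] <- "stromal"
    } else {
      unclassified[i] <- TRUE
      call[i] <- if (isTRUE(thresholds$unclassified_as_stromal) &&
                     scores$epithelial[i] <= thresholds$t_epi) {
        "stromal"
      } else {
        "unclassified"
      }
    }
  }
  data.frame(cell_id = cells, call = call, cluster = unname(assignment),
             cnv_signal = unname(signal),
             immune_score = scores$immune, stromal_score = scores$stromal,
             epithelial_score = scores$epithelial,
             unclassified = unclassified,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Marker-free cell classification pipeline
#'
#' Runs the full separation scheme: Z-score against the normal reference,
#' chromosomal moving-average smoothing, hierarchical clustering of the
#' profiles, immune/stromal/epithelial signature scoring, and the
#' carcinoma / immune / stromal decision rule.
#'
#' @param sce Expression container (tumour cells).
#' @param reference Normal-tissue reference ([build_reference()]).
#' @param annotation Gene annotation.
#' @param signature_sets Named list with gene sets `immune`, `stromal`,
#'   `epithelial`.
#' @param n_clusters Clusters for the profile dendrogram cut.
#' @param window Moving-average window in genes.
#' @param thresholds See [typing_thresholds()].
#' @param groups Named tumour-group labels (defaults to the container's).
#' @return List: `labels` ([assign_cell_types()] output), `profiles`,
#'   `clusters`, `scores`.
#' @export
classify_cells <- function(sce, reference, annotation, signature_sets,
                           n_clusters, window = 150,
                           thresholds = typing_thresholds(),
                           groups = NULL) {
  if (is.null(groups)) groups <- setNames(sce$group, colnames(sce))
  z <- zscore(sce, reference)
  profiles <- smooth_chromosomal(z, annotation, window = window)
  clusters <- cluster_profiles(profiles, n_clusters = n_clusters)
  scores <- data.frame(
    immune = ssgsea_score(sce, signature_sets$immune),
    stromal = ssgsea_score(sce, signature_sets$stromal),
    epithelial = ssgsea_score(sce, signature_sets$epithelial),
    row.names = colnames(sce))
  labels <- assign_cell_types(clusters, profiles, scores, groups,
                              thresholds = thresholds)
  list(labels = labels, profiles = profiles, clusters = clusters,
       scores = scores)
}

#' Intratumoral correlation structure before and after carcinoma restriction
#'
#' Pairwise Pearson correlations between cells of the same tumour group on
#' the un-centred log2(TPM+1) layer, computed over all cells of the group
#' and again restricted to carcinoma-labelled cells. Groups contributing
#' fewer than two cells to a distribution are skipped with a message.
#'
#' @param sce Expression container.
#' @param labels Cell-type calls ([assign_cell_types()] output) or a named
#'   character vector of calls.
#' @param groups Named tumour-group label per cell (defaults to the
#'   container's `group` column).
#' @return List: `summary` `data.frame` (group, n_before/after,
#'   median/IQR/mean r before and after), `before`/`after` lists of
#'   per-group correlation vectors, `ranking` (groups by mean after-r,
#'   decreasing).
#' @export
correlation_structure <- function(sce, labels, groups = NULL) {
  if (is.data.frame(labels)) {
    labels <- setNames(labels$call, labels$cell_id)
  }
  if (is.null(groups)) groups <- setNames(sce$group, colnames(sce))
  lg <- SummarizedExperiment::assay(sce, "logtpm")
  pair_r <- function(cells) {
    if (length(cells) < 2) return(NULL)
    cm <- cor(lg[, cells, drop = FALSE])
    cm[upper.tri(cm)]
  }
  out <- lapply(sort(unique(groups)), function(g) {
    cells <- names(groups)[groups == g]
    carc <- cells[labels[cells] == "carcinoma"]
    rb <- pair_r(cells)
    ra <- pair_r(carc)
    if (is.null(rb)) message("group ", g, " has < 2 cells; skipped")
    list(group = g, before = rb, after = ra,
         n_before = length(cells), n_after = length(carc))
  })
  keep <- !vapply(out, function(o) is.null(o$before), logical(1))
  out <- out[keep]
  summ <- do.call(rbind, lapply(out, function(o) {
    data.frame(group = o$group, n_before = o$n_before, n_after = o$n_after,
               median_r_before = median(o$before),
               iqr_r_before = stats::IQR(o$before),
               mean_r_before = mean(o$before),
               median_r_after = if (length(o$after)) median(o$after) else NA,
               iqr_r_after = if (length(o$after)) stats::IQR(o$after) else NA,
               mean_r_after = if (length(o$after)) mean(o$after) else NA,
               stringsAsFactors = FALSE)
  }))
  list(summary = summ,
       before = setNames(lapply(out, `[[`, "before"),
                         vapply(out, `[[`, character(1), "group")),
       after = setNames(lapply(out, `[[`, "after"),
                        vapply(out, `[[`, character(1), "group")),
       ranking = summ$group[order(-summ$mean_r_after)])
}

#' Write cell labels as TSV
#' @param labels Output of [assign_cell_types()].
#' @param path Output path.
#' @export
write_cell_labels <- function(labels, path) {
  write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
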