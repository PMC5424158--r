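#' Non-negative matrix factorization clustering of immune cells
#'
#' Factorizes the non-negative log2(TPM+1) matrix restricted to an immune
#' signature gene list as `V ~ W H` (Frobenius loss, Lee-Seung
#' multiplicative updates), keeping the best of `n_restarts` seeded random
#' initializations; cells are assigned to the factor with the largest
#' coefficient in their `H` column.
#'
#' @param sce Expression container or non-negative matrix.
#' @param signature_genes Optional gene ids to restrict to (e.g. an
#'   immune cell-type signature list).
#' @param k Number of factors/clusters (default 3).
#' @param seed Integer seed.
#' @param n_restarts Random restarts (default 10).
#' @param max_iter,tol Update iterations and relative-error convergence
#'   tolerance.
#' @return List of class `NmfResult`: `W`, `H`, `assignment` (named
#'   integer), `k`, `seed`, `n_restarts`, `reconstruction_error`,
#'   `error_trace` (per-iteration error of the winning restart).
#' @export
nmf_cluster <- function(sce, signature_genes = NULL, k = 3, seed = 1L,
                        n_restarts = 10, max_iter = 300, tol = 1e-6) {
  v <- if (is(sce, "SummarizedExperiment")) {
    SummarizedExperiment::assay(sce, "logtpm")
  } else {
    as.matrix(sce)
  }
  if (!is.null(signature_genes)) {
    v <- v[intersect(rownames(v), signature_genes), , drop = FALSE]
  }
  if (any(v < 0)) stop("NMF input must be non-negative")
  if (all(v == 0)) stop("all-zero matrix")
  v <- v[rowSums(v) > 0, , drop = FALSE]
  if (k > min(dim(v))) stop("k exceeds matrix rank bound")
  eps <- .Machine$double.eps
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    w <- matrix(runif(nrow(v) * k, 0.1, 1), nrow(v), k)
    h <- matrix(runif(k * ncol(v), 0.1, 1), k, ncol(v))
    err <- numeric(0)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      h <- h * (crossprod(w, v) / (crossprod(w, w %*% h) + eps))
      w <- w * (tcrossprod(v, h) / (w %*% tcrossprod(h) + eps))
      e <- sqrt(sum((v - w %*% h)^2))
      err <- c(err, e)
      if (is.finite(prev) && (prev - e) < tol * max(prev, 1)) break
      prev <- e
    }
    if (is.null(best) || e < best$reconstruction_error) {
      best <- list(W = w, H = h, reconstruction_error = e,
                   error_trace = err, restart = r)
    }
  }
  dimnames(best$W) <- list(rownames(v), paste0("factor", seq_len(k)))
  dimnames(best$H) <- list(paste0("factor", seq_len(k)), colnames(v))
  assignment <- apply(best$H, 2, which.max)
  structure(c(best, list(assignment = assignment, k = k, seed = seed,
                         n_restarts = n_restarts)),
            class = "NmfResult")
}

# Log-likelihood of the zero-inflated log-normal model: a point mass at
# zero with probability 1 - pi, and Normal(mu, sigma) on the positive
# log-scale values. Groups with no positives contribute only the binomial
# part (pi-hat at the boundary).
zinf_loglik <- function(x, pi_hat, mu, sigma) {
  n0 <- sum(x == 0)
  pos <- x[x > 0]
  ll <- 0
  if (n0 > 0) ll <- ll + n0 * log(max(1 - pi_hat, .Machine$double.xmin))
  if (length(pos) > 0) {
    ll <- ll + length(pos) * log(max(pi_hat, .Machine$double.xmin)) +
      sum(dnorm(pos, mu, sigma, log = TRUE))
  }
  ll
}

#' Zero-inflated likelihood-ratio test for two expression groups
#'
#' Models each group's log-scale expression as a zero-inflated Normal:
#' detection with probability pi, positive values Normal(mu, sigma). The
#' alternative fits group-specific (pi, mu) with a standard deviation
#' pooled over all positive values; the null shares (pi, mu, sigma). The
#' statistic `2 (l_alt - l_null)` is referred to a chi-square with 2
#' degrees of freedom (detection rate + location). With
#' `pooled_sigma = FALSE` the alternative also frees sigma per group
#' (df 3).
#'
#' @param values_a,values_b Non-negative log-scale values, n >= 3 each.
#' @param pooled_sigma Pool sigma across groups under the alternative.
#' @return List of class `htest`-like: `statistic`, `df`, `p.value`.
#' @export
zero_inflated_lrt <- function(values_a, values_b, pooled_sigma = TRUE) {
  if (length(values_a) < 3 || length(values_b) < 3) {
    stop("each group needs n >= 3")
  }
  if (any(values_a < 0) || any(values_b < 0)) {
    stop("values must be >= 0 (log layer)")
  }
  x <- c(values_a, values_b)
  pos_a <- values_a[values_a > 0]
  pos_b <- values_b[values_b > 0]
  pos <- c(pos_a, pos_b)
  sd_floor <- 1e-6

  mu_a <- if (length(pos_a)) mean(pos_a) else 0
  mu_b <- if (length(pos_b)) mean(pos_b) else 0
  mu_0 <- if (length(pos)) mean(pos) else 0
  ss_alt_loc <- sum((pos_a - mu_a)^2) + sum((pos_b - mu_b)^2)
  ss_null <- sum((pos - mu_0)^2)
  sig_null <- max(sqrt(ss_null / max(length(pos), 1)), sd_floor)

  pi_a <- length(pos_a) / length(values_a)
  pi_b <- length(pos_b) / length(values_b)
  pi_0 <- length(pos) / length(x)

  if (pooled_sigma) {
    sig_alt <- max(sqrt(ss_alt_loc / max(length(pos), 1)), sd_floor)
    ll_alt <- zinf_loglik(values_a, pi_a, mu_a, sig_alt) +
      zinf_loglik(values_b, pi_b, mu_b, sig_alt)
    df <- 2
  } else {
    sig_a <- max(sqrt(sum((pos_a - mu_a)^2) / max(length(pos_a), 1)),
                 sd_floor)
    sig_b <- max(sqrt(sum((pos_b - mu_b)^2) / max(length(pos_b), 1)),
                 sd_floor)
    ll_alt <- zinf_loglik(values_a, pi_a, mu_a, sig_a) +
      zinf_loglik(values_b, pi_b, mu_b, sig_b)
    df <- 3
  }
  ll_null <- zinf_loglik(values_a, pi_0, mu_0, sig_null) +
    zinf_loglik(values_b, pi_0, mu_0, sig_null)
  stat <- max(0, 2 * (ll_alt - ll_null))
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Rank-based ROC area under the curve
#'
#' `AUC = U / (n_pos * n_neg)` where U is the Mann-Whitney statistic of
#' the positive class; tied values count one half.
#'
#' @param values Numeric scores.
#' @param labels Logical (or two-level) class labels, TRUE = positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(values, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(values, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Cluster-specific marker genes by fold change, AUC and zero-inflated LRT
#'
#' One-vs-rest per cluster on the log2(TPM+1) layer. A gene is a marker
#' when its log2 fold change (difference of group means) exceeds
#' `log2(fc)`, its AUC for separating the cluster from the rest exceeds
#' `auc`, and the zero-inflated LRT p-value is below `p`. The LRT is only
#' evaluated for genes already passing the fold-change and AUC screens
#' (the result set is identical, the screens are cheap). Clusters with
#' fewer than 3 cells are skipped with a warning.
#'
#' @param sce Expression container or log-scale matrix.
#' @param assignment Named cluster assignment per cell.
#' @param fc Fold-change cutoff on the natural scale (default 2).
#' @param auc AUC cutoff (default 0.7).
#' @param p LRT p cutoff (default 0.05).
#' @return `data.frame`: gene_id, cluster, log_fold_change, auc, p_lrt,
#'   sorted by cluster then AUC descending.
#' @export
select_markers <- function(sce, assignment, fc = 2, auc = 0.7, p = 0.05) {
  m <- if (is(sce, "SummarizedExperiment")) {
    SummarizedExperiment::assay(sce, "logtpm")
  } else {
    as.matrix(sce)
  }
  assignment <- assignment[colnames(m)]
  if (length(unique(assignment)) < 2) stop("need >= 2 clusters")
  lfc_cut <- log2(fc)
  out <- list()
  for (k in sort(unique(assignment))) {
    in_k <- assignment == k
    if (sum(in_k) < 3 || sum(!in_k) < 3) {
      warning("cluster ", k, " comparison has < 3 cells on a side; skipped")
      next
    }
    lfc <- rowMeans(m[, in_k, drop = FALSE]) -
      rowMeans(m[, !in_k, drop = FALSE])
    cand <- which(lfc > lfc_cut)
    if (!length(cand)) next
    aucs <- vapply(cand, function(gi) roc_auc(m[gi, ], in_k), numeric(1))
    cand <- cand[aucs > auc]
    aucs <- aucs[aucs > auc]
    if (!length(cand)) next
    ps <- vapply(cand, function(gi) {
      zero_inflated_lrt(m[gi, in_k], m[gi, !in_k])$p.value
    }, numeric(1))
    pass <- ps < p
    if (!any(pass)) next
    d <- data.frame(gene_id = rownames(m)[cand[pass]], cluster = k,
                    log_fold_change = unname(lfc[cand[pass]]),
                    auc = unname(aucs[pass]), p_lrt = unname(ps[pass]),
                    stringsAsFactors = FALSE)
    out[[as.character(k)]] <- d[order(-d$auc), ]
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(gene_id = character(), cluster = integer(),
               log_fold_change = numeric(), auc = numeric(),
               p_lrt = numeric())
  }
  rownames(res) <- NULL
  res
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a marker list and
#' each term's gene set within a finite gene universe. Terms with zero
#' overlap are reported with p = 1.
#'
#' @param marker_genes Character vector, subset of `universe`.
#' @param term_map Named list: term -> gene set.
#' @param universe Character vector of all testable genes.
#' @return `data.frame`: term, overlap, term_size, n_markers, p, sorted
#'   by p.
#' @export
hypergeometric_ora <- function(marker_genes, term_map, universe) {
  if (!length(universe)) stop("empty universe")
  if (!all(marker_genes %in% universe)) {
    stop("marker genes must be contained in the universe")
  }
  N <- length(unique(universe))
  k <- length(unique(marker_genes))
  res <- do.call(rbind, lapply(names(term_map), function(tn) {
    term <- intersect(term_map[[tn]], universe)
    q <- length(intersect(term, marker_genes))
    pv <- if (q == 0) 1 else {
      phyper(q - 1, length(term), N - length(term), k, lower.tail = FALSE)
    }
    data.frame(term = tn, overlap = q, term_size = length(term),
               n_markers = k, p = pv, stringsAsFactors = FALSE)
  }))
  res[order(res$p), ]
}

#' T-cell functional-state scores and state dendrogram
#'
#' Scores every cell on each functional gene set (naive, costimulatory,
#' regulatory, exhaustion, cytotoxicity — any named sets are accepted)
#' with the rank-based single-sample scorer, then hierarchically clusters
#' the cells on their score vectors (Ward linkage, Euclidean distance).
#'
#' @param sce Expression container (already restricted to the cells of
#'   interest, e.g. T cells).
#' @param sets Named list of gene sets (typically five).
#' @return List of class `TcellStateProfile`: `scores` (cell x set
#'   matrix), `tree` (`hclust`).
#' @export
tcell_state_scores <- function(sce, sets) {
  if (ncol(sce) == 0) stop("no cells supplied")
  scores <- vapply(sets, function(s) ssgsea_score(sce, s),
                   numeric(ncol(sce)))
  rownames(scores) <- colnames(sce)
  tree <- hclust(dist(scores), method = "ward.D2")
  structure(list(scores = scores, tree = tree),
            class = "TcellStateProfile")
}
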