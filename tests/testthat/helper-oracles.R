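# Independent oracles used by unit and acceptance tests.

# Brute-force windowed-mean: O(G * W) loop, chromosome by chromosome,
# shrinking the window at ends; independent of the cumsum implementation.
brute_smooth <- function(z, ann, window) {
  ann <- ann[match(rownames(z), ann$gene_id), ]
  out <- z * NA
  half_lo <- floor((window - 1) / 2)
  half_hi <- floor(window / 2)
  for (ch in unique(ann$chromosome)) {
    idx <- which(ann$chromosome == ch)
    for (j in seq_along(idx)) {
      lo <- max(1, j - half_lo)
      hi <- min(length(idx), j + half_hi)
      out[idx[j], ] <- colMeans(z[idx[lo:hi], , drop = FALSE])
    }
  }
  out
}

# Exhaustive pair enumeration for the ROC area (ties count one half).
brute_auc <- function(values, labels) {
  pos <- values[labels]; neg <- values[!labels]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# One full marker-free classification of a simulated experiment,
# returning per-class recall and carcinoma-vs-rest accuracy.
classification_metrics <- function(fix) {
  sim <- fix$sim
  res <- classify_cells(sim$sce, build_reference(sim$normals),
                        sim$annotation,
                        list(immune = sim$marker_sets$immune,
                             stromal = sim$marker_sets$stromal_sig,
                             epithelial = sim$marker_sets$epithelial),
                        n_clusters = fix$cfg$n_clones + 1)
  truth <- truth_classes(sim$truth)
  tab <- table(factor(truth, c("carcinoma", "immune", "stromal")),
               factor(res$labels$call,
                      c("carcinoma", "immune", "stromal", "unclassified")))
  list(recall = diag(prop.table(tab, 1))[1:3],
       accuracy = mean((res$labels$call == "carcinoma") ==
                         (truth == "carcinoma")),
       labels = res$labels)
}
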