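test_that("profile clustering separates obvious structure and respects k", {
  set.seed(3)
  ann <- NULL
  cloud <- cbind(matrix(rnorm(50 * 10, 0), 50, 10),
                 matrix(rnorm(50 * 10, 8), 50, 10))
  dimnames(cloud) <- list(paste0("g", 1:50), paste0("c", 1:20))
  prof <- manual_profiles(cloud, ann)
  cl <- cluster_profiles(prof, 2)
  expect_equal(length(unique(cl$assignment[1:10])), 1)
  expect_equal(length(unique(cl$assignment[11:20])), 1)
  expect_false(cl$assignment[1] == cl$assignment[11])

  singles <- cluster_profiles(prof, 20)
  expect_equal(length(unique(singles$assignment)), 20)
  expect_error(cluster_profiles(prof, 21), "exceeds")

  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(cl, nwk)
  expect_s3_class(ape::read.tree(nwk), "phylo")

  # silhouette selection finds the obvious two-cluster structure
  expect_equal(choose_n_clusters(prof, 2:6), 2)
})

test_that("clustering chromosomal profiles recovers clones and the diploid pool", {
  fix <- default_sim()
  sim <- fix$sim
  prof <- smooth_chromosomal(zscore(sim$sce, build_reference(sim$normals)),
                             sim$annotation)
  cl <- cluster_profiles(prof, n_clusters = 4)
  truth_cl <- ifelse(is.na(sim$truth$clone_id), "none", sim$truth$clone_id)
  expect_gte(adjusted_rand(cl$assignment[sim$truth$cell_id], truth_cl), 0.9)
})

test_that("CNV signal energy is exact on constructed profiles", {
  sm <- matrix(0, 10, 2, dimnames = list(paste0("g", 1:10), c("a", "b")))
  sm[1:5, "b"] <- 1
  sm[6:10, "b"] <- -1
  prof <- manual_profiles(sm)
  sig <- cnv_signal_score(prof)
  expect_equal(unname(sig), c(0, 1))   # zero profile; +/-1 over the genome
  sm2 <- sm; sm2[, "b"] <- c(rep(1, 5), rep(0, 5))
  expect_equal(unname(cnv_signal_score(manual_profiles(sm2))["b"]), 0.5)
})

test_that("aneuploid cells out-score diploid cells on CNV signal", {
  fix <- default_sim()
  sim <- fix$sim
  prof <- smooth_chromosomal(zscore(sim$sce, build_reference(sim$normals)),
                             sim$annotation)
  sig <- cnv_signal_score(prof)
  carc <- which(sim$truth$population == "carcinoma")[1:50]
  dipl <- which(sim$truth$population != "carcinoma")[1:50]
  expect_lt(wilcox.test(sig[carc], sig[dipl],
                        alternative = "greater")$p.value, 0.01)
})

test_that("rank-based set score matches the hand-computed running sum", {
  # 5 genes, one cell, set = {g1, g3}, alpha 0.25: weights (5,4,3,2,1)^.25
  x <- matrix(c(5, 4, 3, 2, 1), 5, 1,
              dimnames = list(paste0("g", 1:5), "c1"))
  w1 <- 5^0.25; w3 <- 3^0.25
  s <- w1 + w3
  cdf_in <- c(w1 / s, w1 / s, 1, 1, 1)
  cdf_out <- c(0, 1, 1, 2, 3) / 3
  expect_equal(unname(ssgsea_score(x, c("g1", "g3"))),
               mean(cdf_in - cdf_out), tolerance = 1e-12)

  # top-k set scores positive, bottom-k negative
  set.seed(4)
  m <- matrix(runif(200), 100, 2,
              dimnames = list(paste0("g", 1:100), c("a", "b")))
  top <- names(sort(m[, "a"], decreasing = TRUE))[1:10]
  bottom <- names(sort(m[, "a"]))[1:10]
  expect_gt(ssgsea_score(m, top)[["a"]], 0)
  expect_lt(ssgsea_score(m, bottom)[["a"]], 0)
  expect_error(ssgsea_score(m, character()), "empty")
})

test_that("set scores are invariant under monotone transforms", {
  set.seed(5)
  m <- matrix(rexp(300), 60, 5,
              dimnames = list(paste0("g", 1:60), paste0("c", 1:5)))
  set <- sample(rownames(m), 12)
  base <- ssgsea_score(m, set)
  expect_equal(ssgsea_score(log1p(m), set), base, tolerance = 1e-12)
  expect_equal(ssgsea_score(m^3, set), base, tolerance = 1e-12)
})

test_that("cell-type assignment follows the cluster and score rules", {
  # single high-signal cluster, all from one tumour: everything carcinoma
  sm <- matrix(rnorm(40 * 6, 0, 1), 40, 6,
               dimnames = list(paste0("g", 1:40), paste0("c", 1:6)))
  prof <- manual_profiles(sm)
  cl <- structure(list(assignment = setNames(rep(1L, 6), paste0("c", 1:6))),
                  class = "ClusterResult")
  scores <- data.frame(immune = rep(0, 6), stromal = rep(0, 6),
                       epithelial = rep(0.5, 6),
                       row.names = paste0("c", 1:6))
  groups <- setNames(rep("BC1", 6), paste0("c", 1:6))
  th <- typing_thresholds(t_imm = 0.2, t_str = 0.2, t_epi = 0.2)
  lab <- assign_cell_types(cl, prof, scores, groups, th)
  expect_true(all(lab$call == "carcinoma"))

  # flat profiles: the rule falls through to the signature scores
  flat <- manual_profiles(sm * 0.001)
  scores2 <- data.frame(immune = c(0.5, 0.5, 0.1, 0.1, 0.1, 0.1),
                        stromal = c(0, 0, 0.5, 0.5, 0.1, 0.1),
                        epithelial = c(0, 0, 0, 0, 0.1, 0.6),
                        row.names = paste0("c", 1:6))
  lab2 <- assign_cell_types(cl, flat, scores2, groups, th)
  expect_equal(lab2$call, c("immune", "immune", "stromal", "stromal",
                            "stromal", "unclassified"))
  expect_true(all(table(lab2$call) >= 0) && nrow(lab2) == 6)
  expect_error(assign_cell_types(cl, flat, scores2, groups,
                                 list(t_cnv = 1)), "configuration")
})

test_that("a purely diploid immune cohort yields zero carcinoma calls", {
  cfg <- sim_config(n_genes = 1200, n_chromosomes = 3,
                    cells_per_population = c(T = 40, B = 20,
                                             macrophage = 20),
                    n_clones = 0, seed = 8)
  sim <- simulate_experiment(cfg)
  res <- classify_cells(sim$sce, build_reference(sim$normals),
                        sim$annotation,
                        list(immune = sim$marker_sets$immune,
                             stromal = sim$marker_sets$stromal_sig,
                             epithelial = sim$marker_sets$epithelial),
                        n_clusters = 2)
  expect_equal(sum(res$labels$call == "carcinoma"), 0)
  expect_equal(nrow(res$labels), ncol(sim$sce))
})

test_that("classification partitions cells and is accurate over seeds", {
  accs <- vapply(1:5, function(s) {
    fix <- default_sim(s)
    sim <- fix$sim
    res <- classify_cells(sim$sce, build_reference(sim$normals),
                          sim$annotation,
                          list(immune = sim$marker_sets$immune,
                               stromal = sim$marker_sets$stromal_sig,
                               epithelial = sim$marker_sets$epithelial),
                          n_clusters = fix$cfg$n_clones + 1)
    expect_equal(nrow(res$labels), ncol(sim$sce))
    truth_carc <- sim$truth$population == "carcinoma"
    mean((res$labels$call == "carcinoma") == truth_carc)
  }, numeric(1))
  expect_true(all(accs >= 0.95))
})

test_that("correlation structure behaves on duplicates, noise and mixtures", {
  # duplicate cells correlate perfectly
  tpm <- matrix(runif(100, 1, 50), 50, 2,
                dimnames = list(paste0("g", 1:50), c("a", "b")))
  tpm[, 2] <- tpm[, 1]
  sce <- expression_matrix(tpm, groups = c(a = "G", b = "G"))
  cs <- correlation_structure(sce, setNames(c("carcinoma", "carcinoma"),
                                            c("a", "b")))
  expect_equal(cs$summary$median_r_before, 1)

  # independent noise cells decorrelate
  set.seed(11)
  tpm <- matrix(2^rnorm(2000 * 50, 3, 2), 2000, 50,
                dimnames = list(paste0("g", 1:2000), paste0("c", 1:50)))
  sce <- expression_matrix(tpm, groups = "G")
  labels <- setNames(rep("carcinoma", 50), colnames(tpm))
  cs <- correlation_structure(sce, labels)
  expect_lt(abs(cs$summary$mean_r_before), 0.05)

  # groups of one cell are skipped with a message
  sce1 <- expression_matrix(tpm[, 1:3],
                            groups = c(c1 = "A", c2 = "A", c3 = "B"))
  expect_message(correlation_structure(sce1,
                                       setNames(rep("carcinoma", 3),
                                                paste0("c", 1:3))),
                 "skipped")
})

test_that("removing non-carcinoma cells raises within-group correlation", {
  fix <- default_sim()
  sim <- fix$sim
  labels <- setNames(truth_classes(sim$truth), sim$truth$cell_id)
  cs <- correlation_structure(sim$sce, labels)
  expect_true(all(cs$summary$median_r_after >= cs$summary$median_r_before))
})
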