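test_that("NMF recovers block structure, is seeded, and descends", {
  set.seed(1)
  blocks <- matrix(0.01, 60, 30)
  for (b in 1:3) {
    blocks[(b - 1) * 20 + 1:20, (b - 1) * 10 + 1:10] <-
      matrix(runif(200, 2, 5), 20, 10)
  }
  dimnames(blocks) <- list(paste0("g", 1:60), paste0("c", 1:30))
  res <- nmf_cluster(blocks, k = 3, seed = 2, n_restarts = 5)
  truth <- rep(1:3, each = 10)
  expect_equal(adjusted_rand(res$assignment, truth), 1)
  expect_true(all(res$W >= 0) && all(res$H >= 0))
  # reconstruction error never increases along the update trace
  expect_true(all(diff(res$error_trace) <= 1e-8))

  res2 <- nmf_cluster(blocks, k = 3, seed = 2, n_restarts = 5)
  expect_identical(res$W, res2$W)
  expect_identical(res$H, res2$H)

  k1 <- nmf_cluster(blocks, k = 1, seed = 1, n_restarts = 2)
  expect_equal(length(unique(k1$assignment)), 1)
  expect_error(nmf_cluster(blocks, k = 40), "rank")
  expect_error(nmf_cluster(matrix(0, 5, 5,
                                  dimnames = list(paste0("g", 1:5),
                                                  paste0("c", 1:5))),
                           k = 2), "zero")
})

test_that("zero-inflated LRT is exact at the extremes and monotone in effect", {
  set.seed(2)
  x <- pmax(rnorm(30, 3, 1), 0.1)
  same <- zero_inflated_lrt(x, x)
  expect_equal(same$statistic, 0, tolerance = 1e-8)
  expect_equal(same$p.value, 1, tolerance = 1e-6)

  # all-zero vs all-positive at n = 20: the normal parts cancel and the
  # statistic reduces to the binomial component 2 * 40 * log 2
  a <- rep(0, 20)
  b <- pmax(rnorm(20, 3, 0.5), 0.1)
  res <- zero_inflated_lrt(a, b)
  expect_equal(res$statistic, 80 * log(2), tolerance = 1e-8)
  expect_lt(res$p.value, 1e-4)

  # statistic is never negative
  for (i in 1:50) {
    g1 <- ifelse(rbinom(15, 1, 0.6) == 1, pmax(rnorm(15, 2), 0.1), 0)
    g2 <- ifelse(rbinom(15, 1, 0.6) == 1, pmax(rnorm(15, 2), 0.1), 0)
    expect_gte(zero_inflated_lrt(g1, g2)$statistic, 0)
  }

  # median p decreases along a planted effect grid
  effect_p <- vapply(c(0, 0.5, 1, 1.5, 2), function(eff) {
    median(vapply(1:40, function(i) {
      set.seed(1000 + i)
      g1 <- ifelse(rbinom(25, 1, 0.7) == 1, pmax(rnorm(25, 2 + eff), 0.01), 0)
      g2 <- ifelse(rbinom(25, 1, 0.7) == 1, pmax(rnorm(25, 2), 0.01), 0)
      zero_inflated_lrt(g1, g2)$p.value
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(effect_p) < 0))

  expect_error(zero_inflated_lrt(c(0, 1), c(1, 2, 3)), "n >= 3")
})

test_that("AUC matches exhaustive pair enumeration", {
  # 4-point toy: pos (3, 2), neg (1, 2)
  expect_equal(roc_auc(c(3, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE)),
               brute_auc(c(3, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(roc_auc(c(3, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 0.875)

  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  set.seed(3)
  for (i in 1:20) {
    v <- sample(0:5, 30, replace = TRUE)   # heavy ties
    l <- rbinom(30, 1, 0.4) == 1
    if (any(l) && any(!l)) {
      expect_equal(roc_auc(v, l), brute_auc(v, l))
    }
  }
})

test_that("marker selection applies all three criteria jointly", {
  set.seed(4)
  n1 <- 20; n2 <- 30
  g <- 40
  m <- matrix(pmax(rnorm(g * (n1 + n2), 2, 1), 0), g, n1 + n2,
              dimnames = list(paste0("g", 1:g), paste0("c", 1:(n1 + n2))))
  assign <- setNames(rep(1:2, c(n1, n2)), colnames(m))

  # no differences: nothing selected
  expect_equal(nrow(select_markers(m, assign)), 0)

  # high AUC but sub-threshold fold change is excluded
  m2 <- m
  m2["g1", 1:n1] <- 3 + rnorm(n1, 0, 0.05)
  m2["g1", (n1 + 1):(n1 + n2)] <- 2.4 + rnorm(n2, 0, 0.05)
  res <- select_markers(m2, assign)
  expect_gt(roc_auc(m2["g1", ], assign == 1), 0.9)
  expect_false("g1" %in% res$gene_id)

  # a genuine marker passes and survives permuting cell and gene order
  m3 <- m
  m3["g2", 1:n1] <- m3["g2", 1:n1] + 3
  res3 <- select_markers(m3, assign)
  expect_true("g2" %in% res3$gene_id[res3$cluster == 1])
  perm_c <- sample(colnames(m3)); perm_g <- sample(rownames(m3))
  res3p <- select_markers(m3[perm_g, perm_c], assign[perm_c])
  expect_identical(res3[order(res3$gene_id), ],
                   res3p[order(res3p$gene_id), ])

  expect_warning(select_markers(m3, setNames(rep(c(1, 2, 3), c(2, 24, 24)),
                                             colnames(m3))), "skipped")
})

test_that("hypergeometric enrichment matches combinatorial arithmetic", {
  universe <- paste0("g", 1:10)
  markers <- paste0("g", 1:3)
  term_exact <- list(hit = paste0("g", 1:3))
  res <- hypergeometric_ora(markers, term_exact, universe)
  expect_equal(res$p, 1 / choose(10, 3), tolerance = 1e-12)

  res2 <- hypergeometric_ora(markers, list(miss = paste0("g", 8:10)),
                             universe)
  expect_equal(res2$p, 1)
  expect_equal(res2$overlap, 0)
  expect_error(hypergeometric_ora("x", list(a = "x"), character()),
               "universe")
  expect_error(hypergeometric_ora("zz", list(a = "g1"), universe),
               "contained")
})

test_that("null enrichment p-values are approximately uniform", {
  set.seed(6)
  universe <- paste0("g", 1:2000)
  ps <- vapply(1:400, function(i) {
    markers <- sample(universe, 200)
    term <- list(t = sample(universe, 300))
    hypergeometric_ora(markers, term, universe)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
  d <- suppressWarnings(ks.test(ps, "punif")$statistic)
  expect_lt(unname(d), 0.1)
})

test_that("T-cell state scores separate planted functional states", {
  set.seed(7)
  g <- 200; genes <- paste0("g", 1:g)
  sets <- list(naive = genes[1:15], costim = genes[16:30],
               regulatory = genes[31:45], exhaustion = genes[46:60],
               cytotoxicity = genes[61:75])
  base <- matrix(2^rnorm(g * 40, 2, 1), g, 40,
                 dimnames = list(genes, paste0("c", 1:40)))
  base[sets$regulatory, 1:20] <- base[sets$regulatory, 1:20] * 2^4
  base[sets$exhaustion, 21:40] <- base[sets$exhaustion, 21:40] * 2^4
  sce <- expression_matrix(base)
  prof <- tcell_state_scores(sce, sets)
  expect_equal(dim(prof$scores), c(40, 5))
  # exhaustion-high cells have exhaustion as their strict maximum
  expect_true(all(apply(prof$scores[21:40, ], 1, which.max) ==
                    which(names(sets) == "exhaustion")))
  cut2 <- cutree(prof$tree, 2)
  expect_gte(adjusted_rand(cut2, rep(1:2, each = 20)), 0.9)

  # shuffling gene labels collapses the between-state contrast
  planted_gap <- mean(prof$scores[1:20, "regulatory"]) -
    mean(prof$scores[21:40, "regulatory"])
  gaps <- vapply(1:5, function(s) {
    set.seed(100 + s)
    shuf <- base
    rownames(shuf) <- sample(rownames(base))
    ps <- tcell_state_scores(expression_matrix(shuf), sets)$scores
    abs(mean(ps[1:20, "regulatory"]) - mean(ps[21:40, "regulatory"]))
  }, numeric(1))
  expect_true(all(gaps < planted_gap))
  expect_error(tcell_state_scores(sce[, 0], sets), "no cells")
})
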