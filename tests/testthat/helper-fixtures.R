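# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

# Default synthetic mixed tumour (300 carcinoma / 3 clones, 150 immune,
# 30 stromal) plus matched normals.
default_sim <- function(seed = 1L) {
  key <- paste0("sim", seed)
  if (is.null(.fixtures[[key]])) {
    cfg <- sim_config(seed = seed)
    .fixtures[[key]] <- list(cfg = cfg, sim = simulate_experiment(cfg))
  }
  .fixtures[[key]]
}

# Small, quick tumour: one clone, fewer genes/cells.
small_sim <- function(seed = 1L, ...) {
  cfg <- sim_config(n_genes = 1200, n_chromosomes = 3,
                    cells_per_population = c(carcinoma = 60, T = 20,
                                             B = 10, macrophage = 10,
                                             stromal = 10),
                    n_clones = 1, seed = seed, ...)
  list(cfg = cfg, sim = simulate_experiment(cfg))
}

# Truth reduced to the three-way call the classifier makes.
truth_classes <- function(truth) {
  ifelse(truth$population == "carcinoma", "carcinoma",
         ifelse(truth$population == "stromal", "stromal", "immune"))
}

# CnvProfiles wrapper around an arbitrary smoothed matrix, for unit tests
# of downstream consumers.
manual_profiles <- function(smoothed, annotation = NULL, window = 1,
                            centred = "cell") {
  structure(list(smoothed = smoothed, annotation = annotation,
                 window = window, centred = centred),
            class = "CnvProfiles")
}

# Adjusted Rand index between two labelings (contingency-table form).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maximum - expected)
}
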