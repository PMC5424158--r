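#' Simulation configuration
#'
#' Bundles every knob of the synthetic tumour generator. The generator
#' emulates the statistical structure the downstream analysis assumes:
#' log-normal baseline expression shared by all cells; clone-specific
#' copy-number segments shifting carcinoma expression by
#' `cnv_attenuation * log2(CN / 2)` (homozygous deletions treated as 0.1
#' copies so the shift stays finite); population marker modules (T, B,
#' macrophage, stromal, epithelial) raised by `marker_effect` log2 units;
#' mean-dependent logistic dropout; TPM renormalization to a column sum of
#' 10^6 including fixed-copy spike-ins.
#'
#' @param n_genes,n_chromosomes,chromosome_length Genome layout.
#' @param cells_per_population Named integer vector over populations
#'   `carcinoma`, `T`, `B`, `macrophage`, `stromal`.
#' @param n_clones Number of carcinoma clones (carcinoma cells are split
#'   evenly across them; each clone defines one synthetic tumour/patient).
#' @param segments_per_clone Aneuploid segments drawn per clone.
#' @param baseline_log_mean_sd Length-2: mean and sd of per-gene baseline
#'   log2 expression.
#' @param noise_sd Cell-level log2 biological + technical noise sd.
#' @param cnv_attenuation Fraction in (0, 1] of the dosage effect
#'   `log2(CN/2)` realized in RNA.
#' @param dropout_midpoint Log2 mean expression at which dropout is 50%.
#' @param dropout_slope Steepness of the logistic dropout curve; dropout
#'   probability decreases with the gene's mean.
#' @param spikein_copies Input copy numbers of the RNA spike-ins.
#' @param marker_effect Log2 shift applied to a population's marker genes.
#' @param n_marker_genes Genes per marker module.
#' @param n_normal_samples Bulk normal-tissue reference samples.
#' @param seed Integer seed fixing all randomness.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 3000, n_chromosomes = 5,
                       chromosome_length = 1e8,
                       cells_per_population = c(carcinoma = 300, T = 75,
                                                B = 45, macrophage = 30,
                                                stromal = 30),
                       n_clones = 3, segments_per_clone = 3,
                       baseline_log_mean_sd = c(2.5, 2), noise_sd = 1,
                       cnv_attenuation = 0.5, dropout_midpoint = 1.5,
                       dropout_slope = 1,
                       spikein_copies = c(12200, 912, 62),
                       marker_effect = 4, n_marker_genes = 25,
                       n_normal_samples = 20, seed = 1L) {
  cfg <- list(n_genes = n_genes, n_chromosomes = n_chromosomes,
              chromosome_length = chromosome_length,
              cells_per_population = cells_per_population,
              n_clones = n_clones, segments_per_clone = segments_per_clone,
              baseline_log_mean_sd = baseline_log_mean_sd,
              noise_sd = noise_sd, cnv_attenuation = cnv_attenuation,
              dropout_midpoint = dropout_midpoint,
              dropout_slope = dropout_slope,
              spikein_copies = spikein_copies,
              marker_effect = marker_effect,
              n_marker_genes = n_marker_genes,
              n_normal_samples = n_normal_samples, seed = as.integer(seed))
  if (cfg$n_genes < 1 || cfg$n_chromosomes < 1 || cfg$chromosome_length < 1) {
    stop("configuration error: non-positive genome dimensions")
  }
  if (any(cfg$cells_per_population < 0)) {
    stop("configuration error: negative cell counts")
  }
  if (cfg$cnv_attenuation < 0 || cfg$cnv_attenuation > 1) {
    stop("configuration error: cnv_attenuation must be in (0, 1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Write / read a simulation configuration as YAML
#' @param cfg A `sim_config`.
#' @param path YAML file path.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$cells_per_population <- unlist(raw$cells_per_population)
  do.call(sim_config, raw)
}

#' Build a deterministic, evenly spaced gene annotation
#'
#' Genes are distributed as evenly as possible over chromosomes (counts
#' differing by at most one, earlier chromosomes taking the remainder) and
#' spaced evenly along each chromosome, 1-based inclusive coordinates.
#'
#' @param cfg A [sim_config()].
#' @return Annotation `data.frame` (gene_id, chromosome, start, end) sorted
#'   by (chromosome, start), with the chromosome length stored as an
#'   attribute for binning.
#' @export
make_annotation <- function(cfg) {
  n <- cfg$n_genes; k <- cfg$n_chromosomes
  per <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  width <- 1000L
  rows <- lapply(seq_len(k), function(ci) {
    m <- per[ci]
    if (m == 0) return(NULL)
    spacing <- floor(cfg$chromosome_length / (m + 1))
    start <- pmax(1L, as.integer(seq_len(m) * spacing))
    data.frame(chromosome = sprintf("chr%d", ci), start = start,
               end = pmin(as.integer(start + width - 1L),
                          as.integer(cfg$chromosome_length)),
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  ann <- data.frame(gene_id = sprintf("G%05d", seq_len(nrow(ann))), ann,
                    stringsAsFactors = FALSE)
  validate_annotation(ann)
  attr(ann, "chromosome_length") <- cfg$chromosome_length
  ann
}

#' Simulate one clone's copy-number landscape
#'
#' Draws `n_segments` non-overlapping segments, each covering 20-50% of a
#' chromosome, with integer copy number drawn from {0, 1, 3, 4}; the
#' uncovered remainder of the genome is implicitly diploid (CN 2).
#'
#' @param annotation Gene annotation (for chromosome names/lengths).
#' @param n_segments Number of aneuploid segments (>= 0).
#' @param seed Integer seed.
#' @param clone_id Label for the clone.
#' @return List of class `CloneCnv`: `clone_id` and `segments`
#'   (chromosome, start, end, copy_number).
#' @export
simulate_clone_cnv <- function(annotation, n_segments, seed = 1L,
                               clone_id = "clone1") {
  if (n_segments < 0) stop("n_segments must be >= 0")
  L <- attr(annotation, "chromosome_length")
  if (is.null(L)) L <- max(annotation$end)
  chroms <- unique(annotation$chromosome)
  set.seed(seed)
  segs <- data.frame(chromosome = character(), start = numeric(),
                     end = numeric(), copy_number = integer(),
                     stringsAsFactors = FALSE)
  tries <- 0
  while (nrow(segs) < n_segments) {
    tries <- tries + 1
    if (tries > 200 * max(1, n_segments)) {
      stop("simulation error: cannot place ", n_segments,
           " non-overlapping segments")
    }
    chrom <- sample(chroms, 1)
    len <- round(runif(1, 0.2, 0.5) * L)
    start <- floor(runif(1, 1, L - len))
    end <- start + len
    on_chrom <- segs[segs$chromosome == chrom, , drop = FALSE]
    if (nrow(on_chrom) && any(start <= on_chrom$end & end >= on_chrom$start)) {
      next
    }
    cn <- sample(c(0L, 1L, 3L, 4L), 1)
    segs <- rbind(segs, data.frame(chromosome = chrom, start = start,
                                   end = end, copy_number = cn,
                                   stringsAsFactors = FALSE))
  }
  structure(list(clone_id = clone_id, segments = segs), class = "CloneCnv")
}

#' Per-gene integer copy-number track for a clone
#'
#' A gene takes a segment's copy number when its interval overlaps the
#' segment; otherwise CN 2.
#'
#' @param clone A `CloneCnv`.
#' @param annotation Gene annotation.
#' @return Integer vector named by gene id.
#' @export
clone_cn_track <- function(clone, annotation) {
  cn <- setNames(rep(2L, nrow(annotation)), annotation$gene_id)
  segs <- clone$segments
  for (j in seq_len(nrow(segs))) {
    hit <- annotation$chromosome == segs$chromosome[j] &
      annotation$start <= segs$end[j] & annotation$end >= segs$start[j]
    cn[hit] <- segs$copy_number[j]
  }
  cn
}

#' Express a clone's copy numbers as log2-ratio segments
#'
#' Converts the integer copy-number segments of a clone to a `SegmentSet`
#' of log2(CN/2) ratios (CN 0 mapped to 0.1 copies), usable as the genomic
#' ground truth in concordance analyses.
#'
#' @param clone A `CloneCnv`.
#' @param min_length Passed to [as_segment_set()]; default 0 so that truth
#'   segments are never dropped.
#' @return A `SegmentSet`.
#' @export
clone_segments <- function(clone, min_length = 0) {
  segs <- clone$segments
  as_segment_set(data.frame(
    chromosome = segs$chromosome, start = segs$start, end = segs$end,
    log2_ratio = log2(pmax(segs$copy_number, 0.1) / 2)
  ), min_length = min_length)
}

#' Default marker modules for the synthetic populations
#'
#' Picks disjoint gene modules (deterministically under the config seed)
#' for each non-carcinoma population plus an epithelial module for
#' carcinoma cells, and derives the composite immune and stromal signature
#' sets used for marker-free classification.
#'
#' @param annotation Gene annotation.
#' @param cfg A [sim_config()].
#' @return Named list: per-population modules (`carcinoma`, `T`, `B`,
#'   `macrophage`, `stromal`) and composite sets `immune`, `stromal_sig`,
#'   `epithelial`.
#' @export
default_marker_sets <- function(annotation, cfg) {
  set.seed(cfg$seed + 7L)
  pops <- c("carcinoma", "T", "B", "macrophage", "stromal")
  pool <- sample(annotation$gene_id)
  idx <- split(pool[seq_len(cfg$n_marker_genes * length(pops))],
               rep(pops, each = cfg$n_marker_genes))
  sets <- idx[pops]
  sets$immune <- unique(c(sets$T, sets$B, sets$macrophage))
  sets$stromal_sig <- sets$stromal
  sets$epithelial <- sets$carcinoma
  sets
}

# Per-gene baseline log2 means, shared between tumour cells and the normal
# reference; drawn under a seed derived from the config.
baseline_means <- function(annotation, cfg) {
  set.seed(cfg$seed + 11L)
  setNames(rnorm(nrow(annotation), cfg$baseline_log_mean_sd[1],
                 cfg$baseline_log_mean_sd[2]), annotation$gene_id)
}

#' Simulate single cells with clonal CNVs, markers, dropout and spike-ins
#'
#' Carcinoma cells are split evenly across the supplied clones; each
#' clone's cells form one tumour group (`BC1`, `BC2`, ...), while
#' non-carcinoma cells are spread cyclically over the tumour groups
#' (immune/stromal infiltration is shared across patients). Latent log2
#' expression is baseline + clone dosage shift + marker shift + Gaussian
#' noise; values are exponentiated, zeroed with mean-dependent logistic
#' dropout probability, joined by fixed-copy spike-ins and renormalized so
#' every column sums to 10^6 TPM.
#'
#' @param annotation Gene annotation.
#' @param clones List of `CloneCnv` (may be empty when no carcinoma cells
#'   are requested).
#' @param marker_sets Named list of population marker modules; see
#'   [default_marker_sets()].
#' @param cfg A [sim_config()].
#' @return List: `sce` (the expression container, spike rows appended),
#'   `truth` (`data.frame`: cell_id, population, clone_id, group),
#'   `cn_tracks` (gene x clone integer matrix), `baseline` (per-gene log2
#'   means), `spike_ids`.
#' @export
simulate_cells <- function(annotation, clones, marker_sets, cfg) {
  pops <- cfg$cells_per_population
  n_carc <- if ("carcinoma" %in% names(pops)) pops[["carcinoma"]] else 0L
  if (n_carc > 0 && length(clones) == 0) {
    stop("configuration error: carcinoma cells requested but no clones")
  }
  base <- baseline_means(annotation, cfg)
  genes <- annotation$gene_id
  g <- length(genes)

  pop_of <- unlist(lapply(names(pops), function(p) rep(p, pops[[p]])))
  n_cells <- length(pop_of)
  cell_id <- sprintf("cell%04d", seq_len(n_cells))
  clone_of <- rep(NA_character_, n_cells)
  if (n_carc > 0) {
    clone_of[pop_of == "carcinoma"] <-
      vapply(clones, `[[`, character(1), "clone_id")[
        rep_len(seq_along(clones), n_carc)]
  }
  tumours <- if (length(clones)) {
    setNames(sprintf("BC%d", seq_along(clones)),
             vapply(clones, `[[`, character(1), "clone_id"))
  } else c(none = "BC1")
  group <- ifelse(is.na(clone_of),
                  unname(tumours)[rep_len(seq_along(tumours),
                                          n_cells)],
                  tumours[clone_of])

  cn_tracks <- if (length(clones)) {
    vapply(clones, clone_cn_track, integer(g), annotation = annotation)
  } else {
    matrix(2L, g, 0)
  }
  if (length(clones)) {
    colnames(cn_tracks) <- vapply(clones, `[[`, character(1), "clone_id")
  }

  set.seed(cfg$seed + 23L)
  mu <- matrix(base, g, n_cells, dimnames = list(genes, cell_id))
  for (i in seq_len(n_cells)) {
    if (!is.na(clone_of[i])) {
      cn <- cn_tracks[, clone_of[i]]
      mu[, i] <- mu[, i] +
        cfg$cnv_attenuation * log2(pmax(cn, 0.1) / 2)
      mk <- marker_sets[["carcinoma"]]
    } else {
      mk <- marker_sets[[pop_of[i]]]
    }
    if (!is.null(mk)) {
      mu[match(intersect(mk, genes), genes), i] <-
        mu[match(intersect(mk, genes), genes), i] + cfg$marker_effect
    }
  }
  x <- mu + matrix(rnorm(g * n_cells, 0, cfg$noise_sd), g, n_cells)
  v <- 2^x
  p_drop <- 1 - plogis(cfg$dropout_slope * (mu - cfg$dropout_midpoint))
  keep <- matrix(runif(g * n_cells), g, n_cells) >= p_drop
  v <- v * keep

  spike_ids <- sprintf("SPIKE%d", seq_along(cfg$spikein_copies))
  sp <- matrix(rep(cfg$spikein_copies, n_cells), length(spike_ids), n_cells,
               dimnames = list(spike_ids, cell_id))
  full <- rbind(v, sp)
  tpm <- sweep(full, 2, colSums(full), "/") * 1e6

  sce <- expression_matrix(tpm, annotation = annotation,
                           groups = setNames(group, cell_id),
                           spike_ids = spike_ids)
  truth <- data.frame(cell_id = cell_id, population = pop_of,
                      clone_id = clone_of, group = group,
                      stringsAsFactors = FALSE)
  list(sce = sce, truth = truth, cn_tracks = cn_tracks, baseline = base,
       spike_ids = spike_ids)
}

#' Simulate a bulk normal-tissue reference matrix
#'
#' Normal samples share the tumour simulation's per-gene baselines (same
#' config seed), carry Gaussian log2 noise but no CNV shifts, markers,
#' dropout or spike-ins, and are TPM-renormalized. They stand in for a
#' normal-tissue expression compendium when building the CNV reference.
#'
#' @param annotation Gene annotation.
#' @param cfg A [sim_config()].
#' @return Expression container of `cfg$n_normal_samples` samples.
#' @export
simulate_normals <- function(annotation, cfg) {
  base <- baseline_means(annotation, cfg)
  n <- cfg$n_normal_samples
  if (n < 2) stop("configuration error: need >= 2 normal samples")
  set.seed(cfg$seed + 31L)
  g <- length(base)
  x <- matrix(base, g, n) + matrix(rnorm(g * n, 0, cfg$noise_sd), g, n)
  v <- 2^x
  tpm <- sweep(v, 2, colSums(v), "/") * 1e6
  dimnames(tpm) <- list(annotation$gene_id, sprintf("normal%03d", seq_len(n)))
  expression_matrix(tpm, annotation = annotation, groups = "normal")
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper: builds the annotation, draws `n_clones` clones with
#' `segments_per_clone` aneuploid segments each, the default marker
#' modules, the tumour cell mixture and the matched normal reference.
#'
#' @param cfg A [sim_config()].
#' @return List: everything from [simulate_cells()] plus `annotation`,
#'   `clones`, `marker_sets`, `normals`.
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  ann <- make_annotation(cfg)
  clones <- lapply(seq_len(cfg$n_clones), function(i) {
    simulate_clone_cnv(ann, cfg$segments_per_clone,
                       seed = cfg$seed + 100L + i,
                       clone_id = sprintf("clone%d", i))
  })
  marker_sets <- default_marker_sets(ann, cfg)
  sim <- simulate_cells(ann, clones, marker_sets, cfg)
  sim$annotation <- ann
  sim$clones <- clones
  sim$marker_sets <- marker_sets
  sim$normals <- simulate_normals(ann, cfg)
  sim
}

#' Simulate synthetic subtype centroids
#'
#' Builds a signature-gene x subtype centroid table: signature genes are
#' sampled from the annotation and each subtype's centroid is the shared
#' baseline plus an independent Gaussian subtype shift, on the
#' log2(TPM+1)-like scale. A synthetic stand-in for proprietary
#' subtype-centroid tables in tests and examples.
#'
#' @param annotation Gene annotation.
#' @param subtypes Subtype names (default six TNBC subgroups).
#' @param n_signature_genes Signature genes sampled.
#' @param shift_sd Sd of the per-gene subtype shift (log2 units).
#' @param seed Integer seed.
#' @return Numeric gene x subtype matrix.
#' @export
make_centroids <- function(annotation,
                           subtypes = c("BL1", "BL2", "IM", "LAR", "M",
                                        "MSL"),
                           n_signature_genes = 200, shift_sd = 2,
                           seed = 1L) {
  set.seed(seed)
  genes <- sort(sample(annotation$gene_id, n_signature_genes))
  base <- rnorm(n_signature_genes, 3, 1)
  cent <- vapply(subtypes, function(s) {
    pmax(base + rnorm(n_signature_genes, 0, shift_sd), 0)
  }, numeric(n_signature_genes))
  rownames(cent) <- genes
  cent
}

#' Write the synthetic experiment to disk
#'
#' Expression as TSV (genes x cells), annotation as BED, truth and group
#' map as TSV, marker sets as GMT, config as YAML.
#'
#' @param sim Result of [simulate_experiment()].
#' @param cfg The [sim_config()] used.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_experiment <- function(sim, cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(
    SummarizedExperiment::assay(sim$sce, "tpm"),
    file.path(outdir, "expression_tpm.tsv"))
  write_annotation_bed(sim$annotation, file.path(outdir, "genes.bed"))
  write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(cell_id = sim$truth$cell_id,
                         group = sim$truth$group),
              file.path(outdir, "groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_gmt(sim$marker_sets, file.path(outdir, "marker_sets.gmt"))
  write_sim_config(cfg, file.path(outdir, "sim_config.yaml"))
  invisible(outdir)
}
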