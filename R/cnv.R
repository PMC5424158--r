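#' Build a normal-tissue expression reference
#'
#' Per-gene mean and standard deviation of log2(TPM+1) over normal-tissue
#' samples, with the sd floored at `sd_floor` so zero-variance genes cannot
#' blow up downstream Z-scores.
#'
#' @param normals Expression container of normal samples (>= 2), or a
#'   plain log2(TPM+1) gene x sample matrix.
#' @param sd_floor Lower bound on the per-gene sd (log2 units).
#' @return `data.frame`: gene_id, mean_log, sd_log.
#' @export
build_reference <- function(normals, sd_floor = 0.1) {
  lg <- if (is(normals, "SummarizedExperiment")) {
    SummarizedExperiment::assay(normals, "logtpm")
  } else {
    as.matrix(normals)
  }
  if (ncol(lg) < 2) stop("need >= 2 normal samples")
  data.frame(
    gene_id = rownames(lg),
    mean_log = rowMeans(lg),
    sd_log = pmax(apply(lg, 1, sd), sd_floor),
    stringsAsFactors = FALSE
  )
}

#' Z-score single-cell expression against the normal reference
#'
#' `Z = (log2(TPM+1) - mean_log) / sd_log` per gene, clamped to
#' `[-clamp, clamp]` so that isolated extreme values (dropouts, bursts)
#' cannot dominate a 150-gene window. Spike-ins and genes absent from the
#' reference are dropped with a message; an overlap below 50% of the
#' analysis genes warns, zero overlap errors.
#'
#' @param sce Expression container.
#' @param reference Output of [build_reference()].
#' @param clamp Symmetric Z bound (default 3).
#' @return Numeric gene x cell Z matrix restricted to shared genes.
#' @export
zscore <- function(sce, reference, clamp = 3) {
  lg <- SummarizedExperiment::assay(sce, "logtpm")
  keep_rows <- !SummarizedExperiment::rowData(sce)$is_spike
  lg <- lg[keep_rows, , drop = FALSE]
  shared <- intersect(rownames(lg), reference$gene_id)
  if (length(shared) == 0) stop("no genes shared with the reference")
  if (length(shared) < 0.5 * nrow(lg)) {
    warning("reference covers < 50% of analysis genes (",
            length(shared), "/", nrow(lg), ")")
  }
  dropped <- nrow(lg) - length(shared)
  if (dropped > 0) {
    message(dropped, " gene(s) absent from reference dropped")
  }
  idx <- match(shared, reference$gene_id)
  z <- (lg[shared, , drop = FALSE] - reference$mean_log[idx]) /
    reference$sd_log[idx]
  pmin(pmax(z, -clamp), clamp)
}

#' Smooth Z-scores along chromosomes into per-cell CNV profiles
#'
#' Genes are sorted by (chromosome, start); each gene's value becomes the
#' mean Z over a window of `window` position-sorted genes centred on it.
#' Windows never span a chromosome boundary and shrink at chromosome ends
#' (so the profile keeps one value per gene). The smoothed track is then
#' centred: by default each cell's genome-wide mean smoothed value is
#' subtracted (`centre = "cell"`); per-gene centring or none are available.
#'
#' @param z Gene x cell Z matrix ([zscore()]).
#' @param annotation Gene annotation covering the Z-matrix genes; genes
#'   missing from the annotation are excluded.
#' @param window Window size in genes (default 150).
#' @param centre `"cell"`, `"gene"` or `"none"`.
#' @return Object of class `CnvProfiles`: list with `smoothed` (gene x
#'   cell matrix in chromosomal order), `annotation` (ordered), `window`,
#'   `centred`.
#' @export
smooth_chromosomal <- function(z, annotation, window = 150,
                               centre = c("cell", "gene", "none")) {
  centre <- match.arg(centre)
  stopifnot(window >= 1)
  ann <- sort_annotation(annotation[annotation$gene_id %in% rownames(z), ,
                                    drop = FALSE])
  if (nrow(ann) == 0) stop("no annotated genes in Z matrix")
  z <- z[ann$gene_id, , drop = FALSE]
  sm <- matrix(NA_real_, nrow(z), ncol(z), dimnames = dimnames(z))
  for (chrom in unique(ann$chromosome)) {
    rows <- which(ann$chromosome == chrom)
    n <- length(rows)
    if (n == 0) {
      message("chromosome ", chrom, " has no genes; skipped")
      next
    }
    block <- z[rows, , drop = FALSE]
    cs <- rbind(0, apply(block, 2, cumsum))
    half_lo <- floor((window - 1) / 2)
    half_hi <- floor(window / 2)
    lo <- pmax(seq_len(n) - half_lo, 1L)
    hi <- pmin(seq_len(n) + half_hi, n)
    sm[rows, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1L)
  }
  if (centre == "cell") {
    sm <- sweep(sm, 2, colMeans(sm))
  } else if (centre == "gene") {
    sm <- sm - rowMeans(sm)
  }
  structure(list(smoothed = sm, annotation = ann, window = window,
                 centred = centre), class = "CnvProfiles")
}

#' @export
print.CnvProfiles <- function(x, ...) {
  cat("CnvProfiles:", nrow(x$smoothed), "genes x", ncol(x$smoothed),
      "cells; window", x$window, "genes; centring:", x$centred, "\n")
  invisible(x)
}

# Half-open 0-based bins tiling [0, L) per chromosome.
make_bins <- function(chrom_lengths, bin_size) {
  do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    starts <- seq(0, chrom_lengths[[ch]] - 1, by = bin_size)
    data.frame(chromosome = ch, bin_start = starts,
               bin_end = pmin(starts + bin_size, chrom_lengths[[ch]]),
               stringsAsFactors = FALSE)
  }))
}

#' Chromosome lengths implied by an annotation
#'
#' Uses the annotation's `chromosome_length` attribute when present
#' (synthetic genomes), otherwise the maximum gene end per chromosome.
#'
#' @param annotation Gene annotation `data.frame`.
#' @return Named numeric vector of lengths in bp.
#' @export
chrom_lengths_from <- function(annotation) {
  L <- attr(annotation, "chromosome_length")
  chroms <- unique(annotation$chromosome)
  if (!is.null(L)) return(setNames(rep(L, length(chroms)), chroms))
  vapply(chroms, function(ch) {
    max(annotation$end[annotation$chromosome == ch])
  }, numeric(1))
}

#' Bin smoothed CNV profiles onto fixed genomic windows
#'
#' Each bin's value is the mean smoothed value of the genes whose start
#' position falls inside the half-open bin; bins containing no gene are
#' `NA` (missing) and are excluded from correlations.
#'
#' @param profiles A `CnvProfiles` object.
#' @param bin_size Bin width in bp (default 10 Mb).
#' @param chrom_lengths Optional named chromosome lengths; derived from
#'   the annotation otherwise.
#' @return List of class `BinnedTrack`: `bins` (chromosome, bin_start,
#'   bin_end) and `values` (bin x cell matrix).
#' @export
bin_profile <- function(profiles, bin_size = 1e7, chrom_lengths = NULL) {
  ann <- profiles$annotation
  if (is.null(chrom_lengths)) chrom_lengths <- chrom_lengths_from(ann)
  bins <- make_bins(chrom_lengths, bin_size)
  pos0 <- ann$start - 1
  bin_of <- match(
    paste(ann$chromosome, floor(pos0 / bin_size) * bin_size),
    paste(bins$chromosome, bins$bin_start))
  vals <- apply(profiles$smoothed, 2, function(col) {
    tapply(col, factor(bin_of, levels = seq_len(nrow(bins))), mean)
  })
  vals <- matrix(vals, nrow = nrow(bins),
                 dimnames = list(NULL, colnames(profiles$smoothed)))
  structure(list(bins = bins, values = vals, bin_size = bin_size),
            class = "BinnedTrack")
}

#' Bin copy-number segments onto fixed genomic windows
#'
#' Each bin's value is the overlap-length-weighted mean of segment
#' log2 ratios, with uncovered bases contributing ratio 0 (diploid).
#' Segments failing the SegmentSet length filter have already been
#' dropped on construction.
#'
#' @param segs A [as_segment_set()] `SegmentSet`.
#' @param bin_size Bin width in bp (default 10 Mb).
#' @param chrom_lengths Named chromosome lengths; derived from segment
#'   extents otherwise.
#' @return A `BinnedTrack` with a single `values` column.
#' @export
bin_segments <- function(segs, bin_size = 1e7, chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    chroms <- unique(segs$chromosome)
    chrom_lengths <- vapply(chroms, function(ch) {
      max(segs$end[segs$chromosome == ch])
    }, numeric(1))
  }
  bins <- make_bins(chrom_lengths, bin_size)
  vals <- numeric(nrow(bins))
  for (i in seq_len(nrow(bins))) {
    b <- bins[i, ]
    width <- b$bin_end - b$bin_start
    on <- segs[segs$chromosome == b$chromosome, , drop = FALSE]
    if (!nrow(on)) { vals[i] <- 0; next }
    # segments are 1-based inclusive; convert to 0-based half-open
    s0 <- on$start - 1; e0 <- on$end
    ov <- pmax(0, pmin(e0, b$bin_end) - pmax(s0, b$bin_start))
    vals[i] <- sum(ov * on$log2_ratio) / width
  }
  structure(list(bins = bins,
                 values = matrix(vals, ncol = 1,
                                 dimnames = list(NULL, "segments")),
                 bin_size = bin_size),
            class = "BinnedTrack")
}

#' Concordance between inferred and genomic copy-number tracks
#'
#' Averages the binned inferred profiles across cells, aligns bins with
#' the binned genomic segments, and returns the Pearson correlation over
#' bins that are non-missing in both tracks.
#'
#' @param profiles A `CnvProfiles` object (one or more cells).
#' @param segs A `SegmentSet` of genomic copy-number ratios.
#' @param bin_size Bin width in bp.
#' @param chrom_lengths Optional named chromosome lengths shared by both
#'   tracks; defaults to the profile annotation's.
#' @return Pearson correlation coefficient (single number).
#' @export
cnv_concordance <- function(profiles, segs, bin_size = 1e7,
                            chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- chrom_lengths_from(profiles$annotation)
  }
  bp <- bin_profile(profiles, bin_size, chrom_lengths)
  bs <- bin_segments(segs, bin_size, chrom_lengths)
  inferred <- rowMeans(bp$values, na.rm = TRUE)
  inferred[is.nan(inferred)] <- NA
  genomic <- bs$values[, 1]
  ok <- !is.na(inferred) & !is.na(genomic)
  if (sum(ok) < 3) stop("fewer than 3 shared non-missing bins")
  if (sd(genomic[ok]) == 0 || sd(inferred[ok]) == 0) {
    stop("degenerate variance: a track is constant over shared bins")
  }
  cor(inferred[ok], genomic[ok])
}

#' Write per-cell smoothed profiles as TSV (genes x cells)
#' @param profiles A `CnvProfiles` object.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  write_expression_matrix(profiles$smoothed, path)
}

#' Write a binned track as BED-like TSV
#' @param track A `BinnedTrack`.
#' @param path Output path.
#' @export
write_binned_track <- function(track, path) {
  df <- cbind(track$bins, as.data.frame(track$values))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
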