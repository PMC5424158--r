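#' Read a GMT gene-set file
#'
#' GMT is the MSigDB tab-separated format: set name, description, then one
#' gene id per remaining field.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("malformed GMT line (need name, description, >=1 gene): ", f[1])
    }
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in ", path)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, genes, d) {
    paste(c(nm, d, genes), collapse = "\t")
  }, names(sets), sets, description)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotation from BED or GTF
#'
#' BED input is 0-based half-open on disk and converted to 1-based inclusive
#' coordinates in memory; GTF is already 1-based inclusive. For GTF, `gene`
#' features are used and the `gene_id` attribute becomes the gene id.
#'
#' @param path Path to a `.bed` or `.gtf`/`.gff` file.
#' @return A `data.frame` with columns `gene_id`, `chromosome`, `start`,
#'   `end`, sorted by (chromosome, start).
#' @export
read_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) {
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr))) {
      keep <- as.character(gr$type) == "gene"
      if (any(keep)) gr <- gr[keep]
    }
    ids <- if ("gene_id" %in% names(S4Vectors::mcols(gr))) {
      as.character(gr$gene_id)
    } else {
      as.character(gr$name)
    }
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- as.character(gr$name)
  }
  ann <- data.frame(
    gene_id = ids,
    chromosome = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  )
  validate_annotation(ann)
  sort_annotation(ann)
}

#' Write gene annotation as BED (0-based half-open)
#'
#' @param annotation Annotation `data.frame` (1-based inclusive in memory).
#' @param path Output path.
#' @export
write_annotation_bed <- function(annotation, path) {
  validate_annotation(annotation)
  bed <- data.frame(
    chrom = annotation$chromosome,
    start = annotation$start - 1L,
    end = annotation$end,
    name = annotation$gene_id
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_annotation <- function(ann) {
  req <- c("gene_id", "chromosome", "start", "end")
  if (!all(req %in% names(ann))) {
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene ids in annotation")
  if (any(ann$start < 1)) stop("annotation starts must be >= 1")
  if (any(ann$end < ann$start)) stop("annotation end < start")
  invisible(ann)
}

# Sort by (chromosome order, start). Chromosome order is numeric where the
# name carries a number (chr1 < chr2 < chr10), otherwise lexicographic, with
# non-numeric names (chrX, spike contigs) after numeric ones.
sort_annotation <- function(ann) {
  num <- suppressWarnings(as.numeric(sub("^chr", "", ann$chromosome)))
  key <- order(is.na(num), num, ann$chromosome, ann$start)
  ann[key, , drop = FALSE]
}

#' Read copy-number segments (SEG-style TSV)
#'
#' Expects tab-separated columns `chromosome`, `start`, `end`, `log2_ratio`
#' (header optional; the first four columns are used). Segments spanning no
#' more than `min_length` bp are dropped on load, mirroring the restriction
#' of genomic-concordance analyses to large-scale events.
#'
#' @param path Path to the segment file.
#' @param min_length Minimum segment span in bp (exclusive); default 10000.
#' @return A `data.frame` of class `SegmentSet` with the four columns above.
#' @export
read_segments <- function(path, min_length = 10000) {
  first <- readLines(path, n = 1)
  has_header <- grepl("chrom", tolower(first))
  seg <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  seg <- seg[, 1:4]
  names(seg) <- c("chromosome", "start", "end", "log2_ratio")
  as_segment_set(seg, min_length = min_length)
}

#' Construct a SegmentSet from a data frame
#'
#' @param seg `data.frame` with columns chromosome, start, end, log2_ratio.
#' @param min_length Minimum span in bp (exclusive).
#' @return The filtered, validated `data.frame` with class `SegmentSet`.
#' @export
as_segment_set <- function(seg, min_length = 10000) {
  req <- c("chromosome", "start", "end", "log2_ratio")
  if (!all(req %in% names(seg))) {
    stop("segments need columns: ", paste(req, collapse = ", "))
  }
  if (!is.numeric(seg$start) || !is.numeric(seg$end) ||
      any(is.na(seg$start)) || any(is.na(seg$end))) {
    stop("malformed segment coordinates")
  }
  if (any(seg$end <= seg$start)) stop("segment end must exceed start")
  seg <- seg[(seg$end - seg$start) > min_length, , drop = FALSE]
  rownames(seg) <- NULL
  attr(seg, "min_length") <- min_length
  class(seg) <- c("SegmentSet", "data.frame")
  seg
}

#' Read an expression matrix from TSV or MatrixMarket files
#'
#' TSV input: first column gene ids, remaining columns one cell each.
#' MTX input (`.mtx`): triplet matrix plus one-id-per-line row (gene) and
#' column (cell) files.
#'
#' @param path Matrix path (`.tsv`/`.txt` or `.mtx`).
#' @param rows_path,cols_path Row/column id files, required for MTX input.
#' @return Numeric gene x cell matrix with dimnames.
#' @export
read_expression_matrix <- function(path, rows_path = NULL, cols_path = NULL) {
  if (tolower(tools::file_ext(path)) == "mtx") {
    if (is.null(rows_path) || is.null(cols_path)) {
      stop("MTX input needs rows_path and cols_path")
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(rows_path)
    colnames(m) <- readLines(cols_path)
    return(m)
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix as TSV (genes x cells)
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
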