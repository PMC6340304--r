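#' Count matrix container
#'
#' The central container of the pipeline: a genes x units matrix of
#' non-negative integer counts, where units are single cells or bulk samples,
#' together with per-unit metadata (donor, plate column, population label,
#' group) and per-gene metadata (technical-control flag for ERCC-like
#' spike-ins, optional gene length).
#'
#' Invariants enforced at construction: counts are non-negative and integral,
#' gene and unit ids are unique, and metadata row counts match the matrix
#' dimensions.
#'
#' @param counts numeric matrix of non-negative integers with rownames
#'   (gene ids) and colnames (unit ids).
#' @param unit_meta optional data.frame, one row per unit. Recognized columns:
#'   `donor`, `plate_col`, `population`, `group`.
#' @param gene_meta optional data.frame, one row per gene. Recognized columns:
#'   `is_technical` (logical), `length`.
#' @return object of class `count_matrix` with elements `counts`, `unit_meta`,
#'   `gene_meta`.
#' @export
count_matrix <- function(counts, unit_meta = NULL, gene_meta = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("counts must carry gene ids as rownames")
  if (ncol(counts) > 0 && is.null(colnames(counts)))
    stop("counts must carry unit ids as colnames")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "malformed-input: count at gene '%s', unit '%s' is not a non-negative integer",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate-id: duplicated gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate-id: duplicated unit ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  storage.mode(counts) <- "double"

  if (is.null(unit_meta)) {
    unit_meta <- data.frame(row.names = colnames(counts))
  } else {
    unit_meta <- as.data.frame(unit_meta)
    if (nrow(unit_meta) != ncol(counts))
      stop("unit_meta has ", nrow(unit_meta), " rows but matrix has ",
           ncol(counts), " units")
    rownames(unit_meta) <- colnames(counts)
  }
  if (is.null(gene_meta)) {
    gene_meta <- data.frame(is_technical = rep(FALSE, nrow(counts)),
                            row.names = rownames(counts))
  } else {
    gene_meta <- as.data.frame(gene_meta)
    if (nrow(gene_meta) != nrow(counts))
      stop("gene_meta has ", nrow(gene_meta), " rows but matrix has ",
           nrow(counts), " genes")
    if (is.null(gene_meta$is_technical)) gene_meta$is_technical <- FALSE
    rownames(gene_meta) <- rownames(counts)
  }
  structure(list(counts = counts, unit_meta = unit_meta, gene_meta = gene_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "units\n")
  cat("  technical genes:", sum(x$gene_meta$is_technical), "\n")
  if (ncol(x$unit_meta) > 0)
    cat("  unit metadata:", paste(colnames(x$unit_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

gene_ids <- function(x) rownames(x$counts)
unit_ids <- function(x) colnames(x$counts)

#' Subset a count matrix
#'
#' Keeps metadata aligned. Indices may be logical, integer, or id character
#' vectors.
#'
#' @param x a `count_matrix`.
#' @param genes,units subsets (default: keep all).
#' @return a `count_matrix`.
#' @export
subset_count_matrix <- function(x, genes = NULL, units = NULL) {
  g <- genes %||% seq_len(nrow(x$counts))
  u <- units %||% seq_len(ncol(x$counts))
  count_matrix(x$counts[g, u, drop = FALSE],
               unit_meta = x$unit_meta[u, , drop = FALSE],
               gene_meta = x$gene_meta[g, , drop = FALSE])
}

#' Read a count matrix from TSV or MatrixMarket
#'
#' TSV dialect: header row of unit ids, first column gene ids, tab-separated.
#' MTX dialect: MatrixMarket coordinate file with `genes.tsv` and `units.tsv`
#' sidecars (one id per line) in the same directory, 1-based indices.
#' An optional unit-metadata TSV (keyed by unit id, column `unit_id`) supplies
#' donor/plate/population annotations; missing optional fields are tolerated.
#'
#' @param path path to the `.tsv` or `.mtx` file.
#' @param format `"tsv"` or `"mtx"`.
#' @param unit_meta_path optional TSV of per-unit metadata.
#' @param gene_meta_path optional TSV of per-gene metadata (column `gene_id`).
#' @return a validated [count_matrix()]; id order preserved from file.
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx"),
                              unit_meta_path = NULL, gene_meta_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (format == "tsv") {
    m <- read_matrix_tsv(path)
  } else {
    m <- as.matrix(Matrix::readMM(path))
    gid <- readLines(file.path(dirname(path), "genes.tsv"))
    uid <- readLines(file.path(dirname(path), "units.tsv"))
    if (length(gid) != nrow(m) || length(uid) != ncol(m))
      stop("sidecar id files do not match matrix dimensions")
    dimnames(m) <- list(gid, uid)
  }
  um <- NULL
  if (!is.null(unit_meta_path)) {
    um <- utils::read.delim(unit_meta_path, stringsAsFactors = FALSE)
    if (is.null(um$unit_id)) stop("unit metadata must have a unit_id column")
    if (!all(colnames(m) %in% um$unit_id))
      stop("unit metadata missing units: ",
           paste(setdiff(colnames(m), um$unit_id), collapse = ", "))
    um <- um[match(colnames(m), um$unit_id), setdiff(colnames(um), "unit_id"),
             drop = FALSE]
  }
  gm <- NULL
  if (!is.null(gene_meta_path)) {
    gm <- utils::read.delim(gene_meta_path, stringsAsFactors = FALSE)
    if (is.null(gm$gene_id)) stop("gene metadata must have a gene_id column")
    gm <- gm[match(rownames(m), gm$gene_id), setdiff(colnames(gm), "gene_id"),
             drop = FALSE]
  }
  count_matrix(m, unit_meta = um, gene_meta = gm)
}

#' Write a count matrix to TSV or MatrixMarket
#'
#' @param x a `count_matrix`.
#' @param path output path (`.tsv` or `.mtx`). For MTX, `genes.tsv` and
#'   `units.tsv` sidecars are written beside it.
#' @param format `"tsv"` or `"mtx"`.
#' @export
write_count_matrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write_matrix_tsv(x$counts, path)
  } else {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    writeLines(rownames(x$counts), file.path(dirname(path), "genes.tsv"))
    writeLines(colnames(x$counts), file.path(dirname(path), "units.tsv"))
  }
  invisible(path)
}

#' Tissue atlas container
#'
#' A genes x tissue-group table of non-negative expression values (for example
#' RLE-normalized CAGE tag expression aggregated into tissue groups), the input
#' of the tau tissue-specificity index. The study design this emulates uses
#' 107 tissue groups.
#'
#' @param expression non-negative numeric matrix, genes x tissue groups, with
#'   dimnames.
#' @param group_map optional data.frame recording the raw-sample to
#'   tissue-group assignment used to build the table.
#' @return object of class `tissue_atlas`.
#' @export
tissue_atlas <- function(expression, group_map = NULL) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("atlas must carry gene and tissue-group ids as dimnames")
  if (anyDuplicated(rownames(expression)) || anyDuplicated(colnames(expression)))
    stop("duplicate-id: atlas gene or group ids are duplicated")
  if (any(!is.finite(expression)) || any(expression < 0))
    stop("atlas expression values must be finite and non-negative")
  if (ncol(expression) < 2) stop("atlas needs at least 2 tissue groups")
  structure(list(expression = expression, group_map = group_map),
            class = "tissue_atlas")
}

#' @export
print.tissue_atlas <- function(x, ...) {
  cat("tissue_atlas:", nrow(x$expression), "genes x", ncol(x$expression),
      "tissue groups\n")
  invisible(x)
}

#' Read a tissue atlas, aggregating raw samples into tissue groups
#'
#' The raw table has one column per sample; `group_map_path` is a two-column
#' TSV (`sample_id`, `group_id`) assigning every sample column to exactly one
#' tissue group. Sample columns are aggregated within a group by the
#' arithmetic mean (configurable to the median).
#'
#' @param path TSV of raw genes x samples expression.
#' @param group_map_path TSV mapping sample ids to tissue-group ids.
#' @param aggregate `"mean"` or `"median"`.
#' @return a [tissue_atlas()] with one column per tissue group, groups in
#'   first-appearance order of the map.
#' @export
read_tissue_atlas <- function(path, group_map_path, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  raw <- read_matrix_tsv(path)
  map <- utils::read.delim(group_map_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group_id") %in% colnames(map)))
    stop("group map needs sample_id and group_id columns")
  aggregate_atlas(raw, map, aggregate)
}

#' Aggregate raw atlas samples into tissue groups
#'
#' @param raw genes x samples matrix.
#' @param map data.frame with `sample_id`, `group_id`.
#' @param aggregate `"mean"` or `"median"`.
#' @return a [tissue_atlas()].
#' @export
aggregate_atlas <- function(raw, map, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (anyDuplicated(map$sample_id)) stop("group map assigns a sample twice")
  unmapped <- setdiff(colnames(raw), map$sample_id)
  if (length(unmapped) > 0)
    stop("unmapped-sample: no tissue group for: ", paste(unmapped, collapse = ", "))
  groups <- unique(map$group_id)
  empty <- groups[!groups %in% map$group_id[map$sample_id %in% colnames(raw)]]
  if (length(empty) > 0)
    stop("empty-group: ", paste(empty, collapse = ", "))
  fun <- if (aggregate == "mean") rowMeans else function(m) apply(m, 1, stats::median)
  agg <- vapply(groups, function(g) {
    cols <- map$sample_id[map$group_id == g]
    fun(raw[, cols, drop = FALSE])
  }, numeric(nrow(raw)))
  dimnames(agg) <- list(rownames(raw), groups)
  tissue_atlas(agg, group_map = map)
}

#' Gene set
#'
#' A named list of gene identifiers, e.g. homologs of murine Aire-dependent
#' tissue-restricted antigens, or trajectory anchor markers.
#'
#' @param name set name.
#' @param ids character vector of gene ids, no duplicates.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate-id: gene set contains duplicates")
  structure(list(name = name, ids = ids), class = "gene_set")
}

#' Read a gene list (one id per line)
#'
#' @param path file with one gene id per line; blank lines ignored.
#' @param name set name; defaults to the file name.
#' @return a [gene_set()].
#' @export
read_gene_set <- function(path, name = basename(path)) {
  ids <- readLines(path)
  gene_set(name, ids[nzchar(ids)])
}
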