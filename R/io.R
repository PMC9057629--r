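#' Read a gene-set GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Empty gene
#' fields are dropped.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    f[-(1:2)][nzchar(f[-(1:2)])]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors, or a list of
#'   [gene_signature] objects.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (length(sets) == 0L) stop("no gene sets to write")
  genes <- lapply(sets, function(s) if (inherits(s, "gene_signature")) s$genes else s)
  nms <- names(genes)
  if (is.null(nms)) nms <- vapply(sets, function(s)
    if (inherits(s, "gene_signature")) s$name else stop("sets must be named"),
    character(1))
  if (any(lengths(genes) == 0L)) stop("refusing to write an empty gene set")
  if (is.null(descriptions)) descriptions <- rep("na", length(genes))
  lines <- mapply(function(nm, d, g) paste(c(nm, d, g), collapse = "\t"),
                  nms, descriptions, genes)
  writeLines(lines, path)
  invisible(path)
}

#' Export derived signatures as a GMT file
#'
#' Convenience wrapper around [write_gmt()] preserving signature order.
#'
#' @param signatures list of [gene_signature] objects.
#' @param path output path.
#' @export
export_signatures <- function(signatures, path) {
  if (length(signatures) == 0L) stop("no signatures to export")
  write_gmt(signatures, path,
            descriptions = vapply(signatures, function(s)
              if (!is.null(s$method)) s$method else "na", character(1)))
}

#' Write a counts matrix as a MatrixMarket triplet directory
#'
#' Emits `matrix.mtx` (1-based coordinate format), `genes.tsv` and
#' `barcodes.tsv`, the layout produced by droplet pipelines.
#'
#' @param counts genes x cells matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_mtx_dir <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a MatrixMarket triplet directory
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return dense genes x cells matrix with dimnames.
#' @export
read_mtx_dir <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  m
}

#' Write simulated objects as plain-text fixtures
#'
#' Writes every recognized element of a simulation result to `dir`:
#' expression/HTO/ADT matrices as MTX triplet directories or CSV, clonotype
#' and clinical tables as CSV, signatures as GMT. The files round-trip
#' through the package's readers.
#'
#' @param objects named list; recognized names are `expr` (genes x cells
#'   counts), `hto`, `adt` (tags/antibodies x cells, written as CSV),
#'   `clonotypes`, `clinical`, `cell_meta` (data frames, written as CSV),
#'   `signatures` (list of signatures or gene sets, written as GMT).
#' @param dir writable output directory.
#' @return named character vector of the paths written.
#' @export
write_fixtures <- function(objects, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  put_csv <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    p
  }
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    paths[[nm]] <- switch(nm,
      expr = write_mtx_dir(obj, file.path(dir, "expr")),
      hto = ,
      adt = put_csv(data.frame(id = rownames(obj), obj, check.names = FALSE), nm),
      clonotypes = ,
      clinical = ,
      cell_meta = put_csv(obj, nm),
      signatures = write_gmt(obj, file.path(dir, "signatures.gmt")),
      {
        if (is.matrix(obj))
          put_csv(data.frame(id = rownames(obj), obj, check.names = FALSE), nm)
        else if (is.data.frame(obj)) put_csv(obj, nm)
        else stop("cannot write object of class ", class(obj)[1], ": ", nm)
      })
  }
  paths
}

#' Read a tags/antibodies x cells count table written by [write_fixtures()]
#'
#' @param path CSV with an `id` column of row identifiers.
#' @return numeric matrix with dimnames.
#' @export
read_tag_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
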