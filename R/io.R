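#' Read a sparse count matrix with gene/cell sidecars
#'
#' Reads a Matrix Market coordinate file plus two TSV sidecars (genes with a
#' \code{gene_id} column, cells with \code{cell_id} and \code{cell_type}
#' columns) into a validated \linkS4class{SenescenceExperiment}. Entries
#' omitted from the sparse file are zeros; the result is independent of the
#' order of entries in the MTX file.
#'
#' @param matrixPath path to the \code{.mtx} coordinate file.
#' @param genesPath path to the gene sidecar TSV (header, column
#'   \code{gene_id}).
#' @param cellsPath path to the cell sidecar TSV (header, columns
#'   \code{cell_id} and \code{cell_type}).
#' @param orientation on-disk orientation of the MTX file:
#'   \code{"genes_x_cells"} (default) or \code{"cells_x_genes"} (the matrix
#'   is transposed on read). The in-memory result is always genes x cells.
#' @param datasetTag tag stored on the returned object; defaults to the
#'   matrix file name.
#' @return A \linkS4class{SenescenceExperiment}.
#' @seealso \code{\link{writeCountMatrix}}
#' @export
readCountMatrix <- function(matrixPath, genesPath, cellsPath,
                            orientation = c("genes_x_cells", "cells_x_genes"),
                            datasetTag = basename(matrixPath)) {
  orientation <- match.arg(orientation)
  m <- Matrix::readMM(matrixPath)
  if (orientation == "cells_x_genes") m <- Matrix::t(m)
  m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
  genes <- read.delim(genesPath, stringsAsFactors = FALSE)
  cells <- read.delim(cellsPath, stringsAsFactors = FALSE)
  if (!"gene_id" %in% colnames(genes)) {
    stop("gene sidecar ", genesPath, " lacks a 'gene_id' column")
  }
  if (!all(c("cell_id", "cell_type") %in% colnames(cells))) {
    stop("cell sidecar ", cellsPath, " lacks 'cell_id'/'cell_type' columns")
  }
  if (nrow(m) != nrow(genes) || ncol(m) != nrow(cells)) {
    stop("dimension mismatch: ", matrixPath, " is ", nrow(m), " x ", ncol(m),
         " (as genes x cells) but ", genesPath, " has ", nrow(genes),
         " genes and ", cellsPath, " has ", nrow(cells), " cells")
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in ", genesPath)
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell ids in ", cellsPath)
  if (any(m@x < 0)) stop("negative counts in ", matrixPath)
  if (any(m@x != floor(m@x))) stop("non-integer counts in ", matrixPath)
  dimnames(m) <- list(genes$gene_id, cells$cell_id)
  SenescenceExperiment(m, cells$cell_type, datasetTag = datasetTag)
}

#' Write a SenescenceExperiment as MTX + TSV sidecars
#'
#' @param x a \linkS4class{SenescenceExperiment}.
#' @param dir output directory (created if needed); files
#'   \code{matrix.mtx}, \code{genes.tsv}, \code{cells.tsv} are written.
#' @return \code{dir}, invisibly.
#' @export
writeCountMatrix <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(SummarizedExperiment::assay(x, "counts"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeTable(data.frame(gene_id = rownames(x)), file.path(dir, "genes.tsv"))
  writeTable(data.frame(cell_id = colnames(x), cell_type = x$cell_type),
             file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read gene sets from GMT or a plain gene list
#'
#' GMT lines are \code{name<TAB>description<TAB>gene1<TAB>gene2...}; a file
#' without tabs is treated as one gene per line, yielding a single set named
#' after the file. Duplicate genes within a set are removed with a warning.
#' Genes absent from a count matrix are retained here and filtered at use
#' sites.
#'
#' @param path input file.
#' @return A named list of character vectors (the gene sets).
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty gene-set file: ", path)
  if (any(grepl("\t", lines))) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) {
      if (length(p) < 3) stop("GMT line with no genes in ", path)
      p[-(1:2)]
    })
    names(sets) <- vapply(parts, `[`, "", 1L)
  } else {
    sets <- list(lines)
    names(sets) <- sub("\\.[^.]*$", "", basename(path))
  }
  sets <- lapply(names(sets), function(nm) {
    g <- sets[[nm]]
    if (!length(g)) stop("empty gene set '", nm, "' in ", path)
    if (anyDuplicated(g)) {
      warning("duplicated genes in set '", nm, "' deduplicated")
      g <- unique(g)
    }
    g
  })
  names(sets) <- if (any(grepl("\t", lines))) {
    vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  } else sub("\\.[^.]*$", "", basename(path))
  sets
}

#' Write a table as TSV with full float precision
#'
#' @param rows a data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTable <- function(rows, path) {
  out <- rows
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  tryCatch(
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop("cannot write table to ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' Read a TSV written by [writeTable()]
#'
#' @param path input path.
#' @return data.frame.
#' @export
readTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
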