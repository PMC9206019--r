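#' Read a 10x-style sparse count matrix
#'
#' Reads a matrix-market triplet directory (`matrix.mtx` plus `features.tsv`
#' and `barcodes.tsv` sidecars, optionally gzipped) as written by 10x Genomics
#' pipelines and by [write_fixture()]. On disk the matrix is stored genes x
#' cells; in memory it is exposed cells x genes, with barcodes as row names
#' and feature identifiers as column names.
#'
#' @param dir Directory containing `matrix.mtx[.gz]`, `features.tsv[.gz]`
#'   (or `genes.tsv[.gz]`) and `barcodes.tsv[.gz]`.
#' @return A sparse `dgCMatrix`, cells x genes, with a `gene_symbols`
#'   attribute mapping feature id to symbol when the feature file has a
#'   second column.
#' @export
read_counts <- function(dir) {
  if (!dir.exists(dir)) abort(paste0("counts directory not found: ", dir))
  mtx <- find_sidecar(dir, "matrix.mtx")
  feat <- find_sidecar(dir, c("features.tsv", "genes.tsv"))
  bc <- find_sidecar(dir, "barcodes.tsv")

  m <- Matrix::readMM(open_maybe_gz(mtx))
  if (is(m, "nsparseMatrix")) m <- methods::as(m, "dsparseMatrix")
  features <- read_tsv_nohead(feat)
  barcodes <- read_tsv_nohead(bc)

  if (nrow(features) != nrow(m) || nrow(barcodes) != ncol(m)) {
    abort(sprintf(
      "matrix is %d x %d but sidecars list %d features and %d barcodes",
      nrow(m), ncol(m), nrow(features), nrow(barcodes)
    ))
  }
  gene_ids <- as.character(features[[1]])
  cell_ids <- as.character(barcodes[[1]])
  if (anyDuplicated(gene_ids)) abort("duplicate feature identifiers")
  if (anyDuplicated(cell_ids)) abort("duplicate cell barcodes")
  if (length(m@x) && any(m@x < 0)) abort("negative values in count matrix")

  counts <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(counts) <- list(cell_ids, gene_ids)
  if (ncol(features) >= 2) {
    attr(counts, "gene_symbols") <- setNames(as.character(features[[2]]), gene_ids)
  }
  counts
}

find_sidecar <- function(dir, names) {
  for (nm in names) {
    for (cand in c(file.path(dir, nm), file.path(dir, paste0(nm, ".gz")))) {
      if (file.exists(cand)) return(cand)
    }
  }
  abort(paste0("no ", paste(names, collapse = "/"), " in ", dir))
}

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

read_tsv_nohead <- function(path) {
  con <- open_maybe_gz(path)
  lines <- readLines(con)
  if (inherits(con, "connection")) close(con)
  if (length(lines) == 0) {
    return(data.frame(V1 = character(0)))
  }
  read.delim(text = lines, header = FALSE, colClasses = "character")
}

#' Read a GMT gene-set file
#'
#' Each line is `set_name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are dropped with a warning; set order and within-set
#' gene order are preserved.
#'
#' @param file Path to a GMT file (optionally gzipped).
#' @return A named list of character vectors of gene symbols, with the file
#'   base name as a `collection` attribute.
#' @export
read_gmt <- function(file) {
  con <- open_maybe_gz(file)
  lines <- readLines(con)
  if (inherits(con, "connection")) close(con)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(paste0("malformed GMT line (fewer than 3 fields): ", substr(ln, 1, 50)))
    }
    nm <- fields[[1]]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warn(paste0("gene set '", nm, "' lists duplicate genes; keeping first occurrences"))
      genes <- genes[!duplicated(genes)]
    }
    if (length(genes) == 0) abort(paste0("gene set '", nm, "' is empty"))
    sets[[nm]] <- genes
  }
  if (anyDuplicated(names(sets))) abort("duplicate gene-set names in GMT file")
  attr(sets, "collection") <- sub("\\.gmt(\\.gz)?$", "", basename(file))
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character gene vectors.
#' @param file Output path.
#' @export
write_gmt <- function(sets, file) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Write a simulated dataset as an on-disk fixture
#'
#' Emits the 10x-style triplet (`matrix.mtx`, `features.tsv`, `barcodes.tsv`),
#' a `truth.tsv` with the per-cell ground truth, and GMT files for the
#' simulated cycle and functional gene sets. Round-trips losslessly through
#' [read_counts()].
#'
#' @param sim A simulation result from [simulate_counts()], or a bare
#'   cells x genes sparse matrix.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  counts <- if (is(sim, "Matrix") || is.matrix(sim)) sim else sim$counts
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(paste0("cannot create directory ", dir))

  Matrix::writeMM(methods::as(Matrix::t(counts), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  gene_ids <- as.character(colnames(counts) %||% character(0))
  features <- if (length(gene_ids)) paste(gene_ids, gene_ids, sep = "\t") else character(0)
  writeLines(features, file.path(dir, "features.tsv"))
  writeLines(as.character(rownames(counts) %||% character(0)),
             file.path(dir, "barcodes.tsv"))

  if (is.list(sim) && !is.null(sim$truth)) {
    write.table(sim$truth, file.path(dir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (is.list(sim) && !is.null(sim$cycle_sets)) {
    write_gmt(sim$cycle_sets, file.path(dir, "cycle_sets.gmt"))
  }
  if (is.list(sim) && !is.null(sim$program_sets)) {
    write_gmt(sim$program_sets, file.path(dir, "program_sets.gmt"))
  }
  invisible(dir)
}
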