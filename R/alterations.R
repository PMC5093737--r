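#' Binary gene-by-sample alteration matrix
#'
#' Rows are genes, columns are tumor samples; a cell is 1 when the gene
#' carries a qualifying somatic alteration (mutation or copy-number event)
#' in that sample. Alteration type is deliberately collapsed to
#' presence/absence: the mutual exclusivity score only uses presence.
#'
#' @param x numeric/logical matrix with gene rownames and sample colnames;
#'   values must be exactly 0 or 1 (or logical).
#' @return An integer 0/1 matrix of class `alteration_matrix`.
#' @export
alteration_matrix <- function(x) {
  x <- as.matrix(x)
  if (is.logical(x)) storage.mode(x) <- "integer"
  if (!all(x %in% c(0L, 1L))) stop("alteration values must be exactly 0 or 1")
  storage.mode(x) <- "integer"
  if ((nrow(x) && is.null(rownames(x))) || (ncol(x) && is.null(colnames(x)))) {
    stop("alteration matrix needs gene rownames and sample colnames")
  }
  if (is.null(dimnames(x))) dimnames(x) <- list(character(), character())
  if (anyDuplicated(rownames(x))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate sample identifiers")
  class(x) <- c("alteration_matrix", class(x))
  x
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat(sprintf("alteration_matrix: %d genes x %d samples, %d alterations\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Read a binary gene-by-sample alteration matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; all cells must be 0 or 1. Duplicate gene rows are OR-combined
#' with a warning; duplicate sample columns are an error.
#'
#' @param path file path.
#' @return An [alteration_matrix()].
#' @export
read_alterations <- function(path) {
  if (!file.exists(path)) stop("alteration file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", comment.char = "#")
  if (ncol(df) < 2L) stop("alteration TSV needs a gene column plus samples")
  genes <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample column: ", samples[duplicated(samples)][1L])
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  ok <- vals %in% c("0", "1")
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("non-binary cell value '%s' in %s", vals[bad], path))
  }
  m <- matrix(as.integer(vals), nrow = nrow(df),
              dimnames = list(genes, samples))
  if (anyDuplicated(genes)) {
    warning("duplicate gene rows OR-combined: ",
            paste(unique(genes[duplicated(genes)]), collapse = ", "))
    m <- rowsum(m, group = genes)
    m[m > 1L] <- 1L
    m <- m[order(rownames(m)), , drop = FALSE]
  }
  alteration_matrix(m)
}

#' Write an alteration matrix as TSV
#'
#' @param mat an [alteration_matrix()].
#' @param path output file path.
#' @export
write_alterations <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), unclass(mat)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a MAF-like variant table to a binary alteration matrix
#'
#' Any (gene, sample) pair with at least one variant row becomes 1;
#' per-pair variant multiplicity is discarded.
#'
#' @param path tab-separated variant table with at least a gene-symbol and a
#'   sample-barcode column.
#' @param gene_col,sample_col column names holding gene symbol and sample
#'   barcode (MAF defaults).
#' @return An [alteration_matrix()].
#' @export
maf_to_matrix <- function(path, gene_col = "Hugo_Symbol",
                          sample_col = "Tumor_Sample_Barcode") {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", comment.char = "#")
  for (col in c(gene_col, sample_col)) {
    if (!col %in% colnames(df)) stop("missing required column: ", col)
  }
  genes <- sort(unique(df[[gene_col]]))
  samples <- sort(unique(df[[sample_col]]))
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  if (nrow(df)) {
    m[cbind(match(df[[gene_col]], genes), match(df[[sample_col]], samples))] <- 1L
  }
  alteration_matrix(m)
}

#' Remove hypermutator samples
#'
#' Drops samples whose total alteration count is strictly greater than
#' `max_alterations` (default 500), a standard guard against hypermutators
#' that would otherwise blur mutual exclusivity signal. Gene rows are never
#' removed; removed sample identifiers are reported via `message()`.
#'
#' @param mat an [alteration_matrix()].
#' @param max_alterations non-negative integer threshold; a sample with
#'   exactly this many alterations is retained.
#' @return The filtered [alteration_matrix()].
#' @export
filter_hypermutators <- function(mat, max_alterations = 500L) {
  stopifnot(max_alterations >= 0L)
  tot <- colSums(mat)
  drop <- tot > max_alterations
  if (any(drop)) {
    message(sprintf("filter_hypermutators: removed %d sample(s): %s",
                    sum(drop), paste(colnames(mat)[drop], collapse = ", ")))
  }
  out <- as_altmat(unclass(mat)[, !drop, drop = FALSE])
  if (ncol(out) == 0L) warning("all samples removed as hypermutators")
  out
}

# re-tag a plain 0/1 integer matrix without re-validating (internal)
as_altmat <- function(m) {
  class(m) <- c("alteration_matrix", "matrix", "array")
  m
}
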