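## Gene-family copy-number matrices ("phyletic patterns") and pangenome
## summaries. The matrix is the pipeline's central input: rows are gene
## families (COG-like clusters including paralogs), columns are genomes,
## cells are non-negative integer copy numbers.

#' Construct a phyletic copy-number matrix
#'
#' @param counts integer matrix, families x genomes, with unique row names
#'   (family ids) and column names (genome ids, matching the tree leaves).
#' @param categories optional named character vector mapping family id to a
#'   single-letter COG functional category.
#' @return an integer matrix of class `phyletic_matrix`. Families absent
#'   from every genome are rejected: an input matrix only ever contains
#'   families that survived somewhere, an assumption the model's
#'   ascertainment correction depends on.
#' @export
phyletic_matrix <- function(counts, categories = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have family row names and genome column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate family ids")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate genome ids")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  zero <- rowSums(counts) == 0
  if (any(zero))
    stop("families absent from all genomes are not allowed: ",
         paste(head(rownames(counts)[zero], 5), collapse = ", "))
  if (!is.null(categories)) {
    categories <- categories[rownames(counts)]
    names(categories) <- rownames(counts)
  }
  structure(counts, categories = categories, class = c("phyletic_matrix",
                                                       "matrix", "array"))
}

#' Read a phyletic matrix from TSV
#'
#' Expected layout: header row of genome ids, first column named
#' `family_id`, integer cells. An optional sidecar TSV
#' (`family_id<TAB>category`) supplies COG functional categories.
#'
#' @param path path to the TSV file.
#' @param categories_path optional path to the category sidecar TSV.
#' @return a [phyletic_matrix()].
#' @export
read_phyletic_matrix <- function(path, categories_path = NULL) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix must have a family_id column and >= 1 genome")
  fam <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(suppressWarnings(as.numeric(m))) |
                 as.numeric(m) != round(as.numeric(m)) |
                 as.numeric(m) < 0)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    stop("parse error: non-integer or negative cell at row ", rc[1],
         " (", fam[rc[1]], "), column ", rc[2], " (", colnames(m)[rc[2]], ")")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- fam
  categories <- NULL
  if (!is.null(categories_path)) {
    cdf <- read.delim(categories_path, header = TRUE,
                      stringsAsFactors = FALSE)
    categories <- setNames(as.character(cdf[[2]]), as.character(cdf[[1]]))
  }
  phyletic_matrix(m, categories = categories)
}

#' Write a phyletic matrix as TSV
#'
#' Inverse of [read_phyletic_matrix()]: `read(write(m))` round-trips
#' bit-identically.
#'
#' @param matrix a [phyletic_matrix()].
#' @param path output path.
#' @export
write_phyletic_matrix <- function(matrix, path) {
  df <- data.frame(family_id = rownames(matrix), matrix,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pangenome summary statistics
#'
#' `F` is the median number of gene families per genome (a family is present
#' iff its copy number is >= 1; paralogs do not inflate the count), `P` the
#' pangenome size (number of distinct families), and `n_singletons` the
#' number of families present in exactly one genome. For an even number of
#' genomes the median is the midpoint of the two central values.
#'
#' @param matrix a [phyletic_matrix()].
#' @param mean_gene_length_nt optional mean CDS length in nucleotides,
#'   carried as metadata for per-gene rate conversion.
#' @return a list of class `pangenome_summary` with elements `F`, `P`,
#'   `n_genomes`, `n_singletons`, `mean_gene_length_nt`.
#' @export
summarize_pangenome <- function(matrix, mean_gene_length_nt = NA_real_) {
  stopifnot(inherits(matrix, "phyletic_matrix"))
  present <- matrix >= 1L
  fam_per_genome <- colSums(present)
  out <- list(
    F = median(fam_per_genome),
    P = nrow(matrix),
    n_genomes = ncol(matrix),
    n_singletons = sum(rowSums(present) == 1L),
    mean_gene_length_nt = mean_gene_length_nt
  )
  class(out) <- "pangenome_summary"
  out
}

#' @export
print.pangenome_summary <- function(x, ...) {
  cat("Pangenome summary\n")
  cat(sprintf("  genomes: %d\n  families per genome (F, median): %g\n",
              x$n_genomes, x$F))
  cat(sprintf("  pangenome size (P): %d\n  singletons: %d\n",
              x$P, x$n_singletons))
  invisible(x)
}

## Genome ids must exactly match the tree leaves before inference.
check_tree_matrix <- function(tree, matrix) {
  tips <- tree$tip.label
  gens <- colnames(matrix)
  if (!setequal(tips, gens)) {
    stop("validation error: tree leaves and matrix genomes differ; ",
         "only in tree: [", paste(setdiff(tips, gens), collapse = ", "),
         "]; only in matrix: [", paste(setdiff(gens, tips), collapse = ", "),
         "]")
  }
  invisible(TRUE)
}
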