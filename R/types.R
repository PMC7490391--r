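#' Construct a feature (ASV/taxon) count table
#'
#' A feature table holds non-negative integer read counts with features as
#' rows and samples as columns, tagged as coming from the DNA (standing
#' community) or RNA (active community) profile of the same biological
#' samples.
#'
#' @param counts Numeric matrix of non-negative integers; rownames are
#'   feature ids, colnames are sample ids. Both must be unique.
#' @param dataset_label `"DNA"` or `"RNA"`.
#' @return An object of class `feature_table` with elements `counts`,
#'   `feature_ids`, `sample_ids`, `dataset_label`.
#' @export
feature_table <- function(counts, dataset_label = c("DNA", "RNA")) {
  dataset_label <- match.arg(dataset_label)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature ids as rownames and sample ids as colnames")
  ft <- structure(
    list(counts = counts,
         feature_ids = rownames(counts),
         sample_ids = colnames(counts),
         dataset_label = dataset_label),
    class = "feature_table")
  viol <- validate_feature_table(ft)
  if (length(viol)) stop("invalid feature_table: ", paste(viol, collapse = "; "))
  ft
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table %s: %d features x %d samples, %s reads>\n",
              x$dataset_label, nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Validate a feature table
#'
#' @param ft A `feature_table`.
#' @return Character vector of violations (empty when valid). Never errors
#'   on invalid content.
#' @export
validate_feature_table <- function(ft) {
  v <- character()
  cts <- ft$counts
  if (anyDuplicated(rownames(cts)))
    v <- c(v, paste0("duplicate feature ids: ",
                     paste(unique(rownames(cts)[duplicated(rownames(cts))]), collapse = ",")))
  if (anyDuplicated(colnames(cts)))
    v <- c(v, paste0("duplicate sample ids: ",
                     paste(unique(colnames(cts)[duplicated(colnames(cts))]), collapse = ",")))
  bad <- which(cts < 0 | cts != round(cts), arr.ind = TRUE)
  if (nrow(bad)) {
    for (i in seq_len(min(nrow(bad), 10L)))
      v <- c(v, sprintf("count at (%s, %s) is not a non-negative integer",
                        rownames(cts)[bad[i, 1]], colnames(cts)[bad[i, 2]]))
  }
  if (!identical(ft$feature_ids, rownames(cts)) ||
      !identical(ft$sample_ids, colnames(cts)))
    v <- c(v, "id lists do not match count matrix dimnames")
  if (!ft$dataset_label %in% c("DNA", "RNA"))
    v <- c(v, paste0("dataset_label not DNA/RNA: ", ft$dataset_label))
  v
}

#' Construct a symmetric distance matrix with ids
#'
#' @param m Square numeric matrix with matching row/col names, symmetric,
#'   zero diagonal, non-negative.
#' @return Matrix of class `c("distance_matrix","matrix")`.
#' @export
distance_matrix <- function(m) {
  m <- as.matrix(m)
  viol <- validate_distance_matrix(m)
  if (length(viol)) stop("invalid distance matrix: ", paste(viol, collapse = "; "))
  class(m) <- c("distance_matrix", class(m))
  m
}

#' Validate a distance matrix
#'
#' @param m Square numeric matrix.
#' @param tol Symmetry tolerance.
#' @return Character vector of violations, empty when valid.
#' @export
validate_distance_matrix <- function(m, tol = 1e-10) {
  v <- character()
  m <- unclass(as.matrix(m))
  if (nrow(m) != ncol(m)) return("matrix not square")
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  asym <- which(abs(m - t(m)) > tol, arr.ind = TRUE)
  if (nrow(asym)) {
    asym <- asym[asym[, 1] < asym[, 2], , drop = FALSE]
    for (i in seq_len(min(nrow(asym), 10L)))
      v <- c(v, sprintf("asymmetric at (%s, %s)", ids[asym[i, 1]], ids[asym[i, 2]]))
  }
  dg <- which(abs(diag(m)) > tol)
  for (i in dg) v <- c(v, sprintf("nonzero diagonal at %s", ids[i]))
  neg <- which(m < -tol, arr.ind = TRUE)
  if (nrow(neg)) v <- c(v, sprintf("%d negative entries", nrow(neg)))
  v
}

#' Construct a microsatellite genotype table
#'
#' Each cell holds an unordered diploid allele pair (integer allele sizes)
#' or is missing entirely (both alleles `NA`).
#'
#' @param a1,a2 Integer matrices (individuals x loci) of allele sizes;
#'   rownames are individual ids, colnames locus ids. Missing cells have
#'   `NA` in both.
#' @return Object of class `genotype_table`.
#' @export
genotype_table <- function(a1, a2) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(identical(dim(a1), dim(a2)),
            identical(dimnames(a1), dimnames(a2)))
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)[1, ]
    stop(sprintf("cell (%s, %s) has exactly one allele; need 0 or 2",
                 rownames(a1)[idx[1]], colnames(a1)[idx[2]]))
  }
  structure(list(individual_ids = rownames(a1), locus_ids = colnames(a1),
                 a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' Construct a (possibly aligned) nucleotide sequence set
#'
#' @param seqs Named character vector over the alphabet `A,C,G,T,N,-`.
#' @param aligned Logical; aligned sets must have equal-length sequences.
#' @return Object of class `sequence_set` (named character vector with an
#'   `aligned` attribute).
#' @export
sequence_set <- function(seqs, aligned = FALSE) {
  seqs <- toupper(unlist(seqs))
  if (is.null(names(seqs))) stop("sequences must be named")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) stop("non-ACGTN- characters in: ", paste(names(seqs)[bad], collapse = ","))
  if (aligned && length(unique(nchar(seqs))) > 1)
    stop("aligned sequence set has unequal lengths")
  structure(seqs, aligned = aligned, class = "sequence_set")
}
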