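# A study bundle collects everything one analysis run needs: paired DNA/RNA
# feature tables, sample metadata, taxonomy, a rooted phylogeny over the
# features, D-loop sequences, microsatellite genotypes, and (for synthetic
# bundles) the planted ground truth.

#' Construct a study bundle
#'
#' @param dna,rna [feature_table()] objects (either may be `NULL`, not both).
#' @param metadata Metadata data.frame (see [read_metadata()]).
#' @param taxonomy Optional taxonomy data.frame.
#' @param tree Optional rooted `phylo` tree whose tips cover the features.
#' @param dloop Optional aligned [sequence_set()] of mitochondrial D-loop
#'   haplotypes (one per wild individual).
#' @param genotypes Optional [genotype_table()].
#' @param truth Optional truth-label list (synthetic bundles only), with
#'   elements `contaminants`, `taxa` (data.frame taxon/group/category),
#'   `params` (data.frame key/value), `clusters` (data.frame
#'   individual_id/cluster).
#' @return Object of class `study_bundle`.
#' @export
study_bundle <- function(dna = NULL, rna = NULL, metadata,
                         taxonomy = NULL, tree = NULL, dloop = NULL,
                         genotypes = NULL, truth = NULL) {
  if (is.null(dna) && is.null(rna)) stop("bundle needs at least one feature table")
  structure(list(dna = dna, rna = rna, metadata = metadata,
                 taxonomy = taxonomy, tree = tree, dloop = dloop,
                 genotypes = genotypes, truth = truth),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("<study_bundle>\n")
  for (nm in c("dna", "rna"))
    if (!is.null(x[[nm]]))
      cat(sprintf("  %s: %d features x %d samples\n", toupper(nm),
                  nrow(x[[nm]]$counts), ncol(x[[nm]]$counts)))
  cat(sprintf("  metadata: %d samples, %d groups\n", nrow(x$metadata),
              length(unique(x$metadata$group[!x$metadata$is_negative_control %in% TRUE]))))
  for (nm in c("taxonomy", "tree", "dloop", "genotypes", "truth"))
    if (!is.null(x[[nm]])) cat("  has", nm, "\n")
  invisible(x)
}

#' Validate a study bundle
#'
#' Collects every invariant violation (feature-table integrity, metadata
#' cross-references, concentrations, coordinates for spatially structured
#' groups, taxonomy coverage, tree tip coverage, aligned-sequence lengths)
#' without raising on invalid content.
#'
#' @param bundle A [study_bundle()].
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_bundle <- function(bundle) {
  v <- character()
  md <- bundle$metadata
  if (anyDuplicated(md$sample_id))
    v <- c(v, paste0("duplicate metadata sample ids: ",
                     paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ",")))
  for (nm in c("dna", "rna")) {
    ft <- bundle[[nm]]
    if (is.null(ft)) next
    fv <- validate_feature_table(ft)
    if (length(fv)) v <- c(v, paste0(nm, ": ", fv))
    orphans <- setdiff(ft$sample_ids, md$sample_id)
    if (length(orphans))
      v <- c(v, paste0(nm, ": samples missing from metadata: ",
                       paste(orphans, collapse = ",")))
  }
  for (cc in c("conc_dna", "conc_rna")) {
    bad <- which(!is.na(md[[cc]]) & md[[cc]] < 0)
    for (i in bad) v <- c(v, sprintf("negative %s for sample %s", cc, md$sample_id[i]))
  }
  # spatially structured groups: any group whose samples carry coordinates
  # must have them for every non-control sample
  ctrl <- md$is_negative_control %in% TRUE
  spatial_groups <- unique(md$group[!ctrl & !is.na(md$x_km)])
  need <- !ctrl & md$group %in% spatial_groups & (is.na(md$x_km) | is.na(md$y_km))
  for (i in which(need))
    v <- c(v, sprintf("sample %s of spatial group %s lacks coordinates",
                      md$sample_id[i], md$group[i]))
  if (!is.null(bundle$taxonomy)) {
    feats <- unique(c(if (!is.null(bundle$dna)) bundle$dna$feature_ids,
                      if (!is.null(bundle$rna)) bundle$rna$feature_ids))
    miss <- setdiff(feats, bundle$taxonomy$feature_id)
    if (length(miss))
      v <- c(v, paste0("taxonomy missing features: ",
                       paste(utils::head(miss, 10), collapse = ",")))
  }
  if (!is.null(bundle$tree)) {
    feats <- unique(c(if (!is.null(bundle$dna)) bundle$dna$feature_ids,
                      if (!is.null(bundle$rna)) bundle$rna$feature_ids))
    miss <- setdiff(feats, bundle$tree$tip.label)
    if (length(miss))
      v <- c(v, paste0("tree missing tips: ", paste(utils::head(miss, 10), collapse = ",")))
    if (!is.null(bundle$tree$edge.length) && any(bundle$tree$edge.length < 0))
      v <- c(v, "tree has negative branch lengths")
  }
  if (!is.null(bundle$dloop) && isTRUE(attr(bundle$dloop, "aligned")) &&
      length(unique(nchar(unclass(bundle$dloop)))) > 1)
    v <- c(v, "aligned D-loop sequences have unequal lengths")
  v
}

.bundle_files <- list(
  dna = "feature_table_dna.tsv", rna = "feature_table_rna.tsv",
  metadata = "metadata.tsv", taxonomy = "taxonomy.tsv", tree = "tree.nwk",
  dloop = "dloop.fasta", genotypes = "genotypes.tsv",
  truth_contaminants = "truth_contaminants.tsv", truth_taxa = "truth_taxa.tsv",
  truth_params = "truth_params.tsv", truth_clusters = "truth_clusters.tsv")

#' Write a study bundle to a directory
#'
#' Serialization is byte-stable: writing the same bundle twice yields
#' identical checksums.
#'
#' @param bundle A valid [study_bundle()].
#' @param dir Output directory (created if needed).
#' @return Manifest data.frame with columns `file`, `md5`.
#' @export
write_bundle <- function(bundle, dir) {
  viol <- validate_bundle(bundle)
  if (length(viol)) stop("bundle does not validate: ", paste(viol, collapse = "; "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  f <- character()
  p <- function(x) file.path(dir, x)
  if (!is.null(bundle$dna)) { write_feature_table(bundle$dna, p(.bundle_files$dna)); f <- c(f, .bundle_files$dna) }
  if (!is.null(bundle$rna)) { write_feature_table(bundle$rna, p(.bundle_files$rna)); f <- c(f, .bundle_files$rna) }
  write_metadata(bundle$metadata, p(.bundle_files$metadata)); f <- c(f, .bundle_files$metadata)
  if (!is.null(bundle$taxonomy)) { write_taxonomy(bundle$taxonomy, p(.bundle_files$taxonomy)); f <- c(f, .bundle_files$taxonomy) }
  if (!is.null(bundle$tree)) { ape::write.tree(bundle$tree, p(.bundle_files$tree)); f <- c(f, .bundle_files$tree) }
  if (!is.null(bundle$dloop)) { write_fasta_set(bundle$dloop, p(.bundle_files$dloop)); f <- c(f, .bundle_files$dloop) }
  if (!is.null(bundle$genotypes)) { write_genotypes(bundle$genotypes, p(.bundle_files$genotypes)); f <- c(f, .bundle_files$genotypes) }
  tr <- bundle$truth
  if (!is.null(tr)) {
    if (!is.null(tr$contaminants)) {
      .write_tsv(data.frame(feature_id = tr$contaminants), p(.bundle_files$truth_contaminants))
      f <- c(f, .bundle_files$truth_contaminants)
    }
    if (!is.null(tr$taxa)) { .write_tsv(tr$taxa, p(.bundle_files$truth_taxa)); f <- c(f, .bundle_files$truth_taxa) }
    if (!is.null(tr$params)) { .write_tsv(tr$params, p(.bundle_files$truth_params)); f <- c(f, .bundle_files$truth_params) }
    if (!is.null(tr$clusters)) { .write_tsv(tr$clusters, p(.bundle_files$truth_clusters)); f <- c(f, .bundle_files$truth_clusters) }
  }
  manifest <- data.frame(file = f,
                         md5 = unname(tools::md5sum(file.path(dir, f))),
                         stringsAsFactors = FALSE)
  manifest
}

#' Load a study bundle from a directory
#'
#' @param dir Directory previously written by [write_bundle()] (or hand
#'   assembled in the same dialects).
#' @return A validated [study_bundle()].
#' @export
load_bundle <- function(dir) {
  p <- function(x) file.path(dir, x)
  have <- function(x) file.exists(p(x))
  if (!have(.bundle_files$dna) && !have(.bundle_files$rna))
    stop("load error: no feature table (expected ", .bundle_files$dna,
         " or ", .bundle_files$rna, ") in ", dir)
  if (!have(.bundle_files$metadata))
    stop("load error: missing required file ", .bundle_files$metadata, " in ", dir)
  dna <- if (have(.bundle_files$dna)) read_feature_table(p(.bundle_files$dna), "DNA")
  rna <- if (have(.bundle_files$rna)) read_feature_table(p(.bundle_files$rna), "RNA")
  md <- read_metadata(p(.bundle_files$metadata))
  tax <- if (have(.bundle_files$taxonomy)) read_taxonomy(p(.bundle_files$taxonomy))
  tree <- if (have(.bundle_files$tree)) ape::read.tree(p(.bundle_files$tree))
  dloop <- if (have(.bundle_files$dloop)) read_fasta_set(p(.bundle_files$dloop), aligned = TRUE)
  gt <- if (have(.bundle_files$genotypes)) read_genotypes(p(.bundle_files$genotypes))
  truth <- NULL
  if (have(.bundle_files$truth_taxa) || have(.bundle_files$truth_contaminants)) {
    truth <- list()
    if (have(.bundle_files$truth_contaminants))
      truth$contaminants <- as.character(.read_tsv(p(.bundle_files$truth_contaminants))$feature_id)
    if (have(.bundle_files$truth_taxa)) truth$taxa <- .read_tsv(p(.bundle_files$truth_taxa))
    if (have(.bundle_files$truth_params)) truth$params <- .read_tsv(p(.bundle_files$truth_params))
    if (have(.bundle_files$truth_clusters)) truth$clusters <- .read_tsv(p(.bundle_files$truth_clusters))
  }
  b <- study_bundle(dna = dna, rna = rna, metadata = md, taxonomy = tax,
                    tree = tree, dloop = dloop, genotypes = gt, truth = truth)
  viol <- validate_bundle(b)
  if (length(viol))
    stop("validation error loading ", dir, ": ", paste(viol, collapse = "; "))
  b
}
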