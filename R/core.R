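# Core-community machinery: taxonomic collapsing, top-taxa summaries, the
# >=25%-prevalence core definition, shared/unique/partial partitioning, and
# core-abundance fractions per category.

.tax_ranks <- c("phylum", "class", "order", "family", "genus")

#' Collapse a feature table to a taxonomic level
#'
#' Counts are summed per (taxon, sample). Features unclassified at the
#' requested level are pooled under
#' `"Unclassified_<rank>_<name>"` of their nearest classified parent rank
#' (or `"Unclassified"` if no rank is classified). Column sums are
#' invariant under collapsing.
#'
#' @param table A [feature_table()].
#' @param taxonomy Taxonomy data.frame (see [read_taxonomy()]); every
#'   feature in `table` must have an entry.
#' @param level One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return A taxon-level [feature_table()].
#' @export
collapse_taxonomy <- function(table, taxonomy, level = "genus") {
  if (!level %in% .tax_ranks) stop("parameter error: unknown level ", level)
  idx <- match(table$feature_ids, taxonomy$feature_id)
  if (anyNA(idx))
    stop("taxonomy missing features: ",
         paste(utils::head(table$feature_ids[is.na(idx)], 5), collapse = ","))
  tx <- taxonomy[idx, , drop = FALSE]
  lev_i <- match(level, .tax_ranks)
  label <- tx[[level]]
  uncl <- is.na(label) | label == "Unclassified"
  if (any(uncl)) {
    for (i in which(uncl)) {
      lab <- "Unclassified"
      for (r in rev(seq_len(lev_i - 1))) {
        val <- tx[[.tax_ranks[r]]][i]
        if (!is.na(val) && val != "Unclassified") {
          lab <- paste("Unclassified", .tax_ranks[r], val, sep = "_")
          break
        }
      }
      label[i] <- lab
    }
  }
  m <- rowsum(table$counts, group = label)
  m <- m[order(rownames(m)), , drop = FALSE]
  feature_table(m, table$dataset_label)
}

#' Taxa ranking in the top k of enough groups
#'
#' A taxon qualifies when it ranks among the top `k` taxa by group-mean
#' relative abundance (mean over the group's samples of per-sample
#' fractions) in at least `min_groups` groups. Ties at rank `k` are broken
#' by lexicographic taxon name.
#'
#' @param tables_by_group Named list of [feature_table()] objects (or count
#'   matrices), one per group, sharing a taxon universe.
#' @param k Rank cutoff (default 5).
#' @param min_groups Minimum number of groups (default 2).
#' @return Character vector of qualifying taxa ordered by decreasing
#'   overall mean relative abundance.
#' @export
top_taxa <- function(tables_by_group, k = 5, min_groups = 2) {
  if (length(tables_by_group) < min_groups)
    stop("need at least min_groups groups")
  getm <- function(x) if (inherits(x, "feature_table")) x$counts else as.matrix(x)
  taxa <- sort(unique(unlist(lapply(tables_by_group, function(x) rownames(getm(x))))))
  means <- vapply(tables_by_group, function(x) {
    m <- getm(x)
    rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
    mu <- rowMeans(rel)
    out <- stats::setNames(numeric(length(taxa)), taxa)
    out[names(mu)] <- mu
    out
  }, numeric(length(taxa)))
  hits <- apply(means, 2, function(mu) {
    ord <- order(-mu, names(mu))
    names(mu)[ord][seq_len(min(k, length(mu)))]
  })
  counts <- table(unlist(hits))
  qual <- names(counts)[counts >= min_groups]
  overall <- rowMeans(means)
  qual[order(-overall[qual], qual)]
}

#' Core taxon set of one group
#'
#' A taxon is core when present (count > 0) in at least `prevalence` of the
#' group's samples, boundary inclusive.
#'
#' @param table A [feature_table()].
#' @param group_samples Sample ids belonging to the group.
#' @param prevalence Fraction threshold (default 0.25).
#' @return Character vector of core taxa.
#' @export
core_set <- function(table, group_samples, prevalence = 0.25) {
  group_samples <- intersect(group_samples, table$sample_ids)
  if (!length(group_samples)) stop("group has no samples in table")
  m <- table$counts[, group_samples, drop = FALSE]
  prev <- rowSums(m > 0) / length(group_samples)
  rownames(m)[prev >= prevalence]
}

#' Partition core sets into shared, unique and partial taxa
#'
#' `shared_all` is the intersection over all groups; `unique[[g]]` is core
#' in group g and in no other group; `partial` is core in at least two but
#' not all groups. Output is invariant to group order.
#'
#' @param core_sets Named list (one per group) of core taxon vectors.
#' @return Object of class `core_partition`: list with `shared_all`,
#'   `unique` (named list), `partial`, and the input `core_sets`.
#' @export
partition_core <- function(core_sets) {
  if (length(core_sets) < 2) stop("need at least 2 groups")
  all_taxa <- unique(unlist(core_sets))
  n_in <- vapply(all_taxa, function(t)
    sum(vapply(core_sets, function(s) t %in% s, TRUE)), 0L)
  shared_all <- all_taxa[n_in == length(core_sets)]
  uniq <- lapply(core_sets, function(s) s[n_in[match(s, all_taxa)] == 1L])
  partial <- all_taxa[n_in >= 2L & n_in < length(core_sets)]
  structure(list(shared_all = sort(shared_all),
                 unique = lapply(uniq, sort),
                 partial = sort(partial),
                 core_sets = core_sets),
            class = "core_partition")
}

#' Per-individual fraction of core abundance by category
#'
#' For each individual in the group, the fraction of its core-taxon reads
#' (denominator: the group's whole core set) falling in each category
#' (`shared_all`, `partial`, `unique`). Fractions sum to 1 per individual;
#' individuals with zero core reads are excluded with a warning.
#'
#' @param table A [feature_table()] at the partition's taxonomic level.
#' @param group_samples Sample ids of the group.
#' @param partition A [partition_core()] result.
#' @param group Group name (to select its core and unique sets).
#' @return List with `per_individual` (data.frame sample_id x category
#'   fractions) and `mean` (named mean fraction per category).
#' @export
category_fraction <- function(table, group_samples, partition, group) {
  core_g <- partition$core_sets[[group]]
  if (!length(core_g)) stop("empty core for group ", group)
  cats <- list(shared_all = intersect(core_g, partition$shared_all),
               partial = intersect(core_g, partition$partial),
               unique = intersect(core_g, partition$unique[[group]]))
  group_samples <- intersect(group_samples, table$sample_ids)
  m <- table$counts[intersect(core_g, table$feature_ids), group_samples, drop = FALSE]
  denom <- colSums(m)
  zero <- denom == 0
  if (any(zero)) {
    warning("individuals with zero core abundance excluded: ",
            paste(group_samples[zero], collapse = ","))
    m <- m[, !zero, drop = FALSE]
    denom <- denom[!zero]
    group_samples <- group_samples[!zero]
  }
  fr <- vapply(cats, function(tx) {
    if (!length(tx)) return(stats::setNames(numeric(length(denom)), names(denom)))
    colSums(m[intersect(tx, rownames(m)), , drop = FALSE]) / denom
  }, numeric(length(denom)))
  fr <- matrix(fr, ncol = length(cats),
               dimnames = list(names(denom), names(cats)))
  per <- data.frame(sample_id = group_samples, fr, stringsAsFactors = FALSE,
                    row.names = NULL)
  list(per_individual = per, mean = colMeans(as.matrix(fr)))
}
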