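# Frequency-method contaminant screening. A reagent contaminant contributes
# a roughly constant number of molecules per reaction, so its relative
# frequency in a sequencing library varies inversely with the sample's
# nucleic-acid concentration. The score contrasts two one-parameter models
# in log-log space: contaminant (slope fixed at -1) versus non-contaminant
# (slope 0), each fit by least squares, and converts the residual ratio
# through the F(n-1, n-1) CDF. Low scores mean the inverse model fits far
# better.

#' Frequency-method contaminant score
#'
#' Only samples with frequency > 0 and known concentration > 0 are used;
#' with fewer than `min_samples` such samples the score is undefined (`NA`,
#' no call). In log-log space two one-parameter models are fit: contaminant
#' `log f = b - log c` and non-contaminant `log f = b`; with residual sums
#' `SS_contam` and `SS_noncontam`, each on n-1 degrees of freedom, the score
#' is `pf(SS_contam / SS_noncontam, n-1, n-1)`.
#'
#' The score is invariant to rescaling all concentrations or all
#' frequencies by a positive constant (the intercept absorbs the shift).
#'
#' @param freq Per-sample relative frequencies of one feature.
#' @param conc Matching nucleic-acid concentrations (ng/ul).
#' @param min_samples Minimum usable samples for a call (default 5).
#' @return Score in `[0,1]`, or `NA` when undefined; attribute `n_used`
#'   records the number of samples entering the fit.
#' @export
frequency_score <- function(freq, conc, min_samples = 5) {
  stopifnot(length(freq) == length(conc))
  use <- !is.na(freq) & freq > 0 & !is.na(conc)
  if (any(use & conc <= 0))
    stop("input error: non-positive concentration among used samples")
  use <- use & conc > 0
  n <- sum(use)
  if (n < min_samples || all(freq[use] == 0))
    return(structure(NA_real_, n_used = n))
  lf <- log(freq[use]); lc <- log(conc[use])
  ss_contam <- sum((lf + lc - mean(lf + lc))^2)
  ss_noncontam <- sum((lf - mean(lf))^2)
  p <- if (ss_noncontam == 0 && ss_contam == 0) NA_real_
  else if (ss_noncontam == 0) 1
  else stats::pf(ss_contam / ss_noncontam, n - 1, n - 1)
  structure(p, n_used = n)
}

#' Select negative controls with enough processed reads
#'
#' @param metadata Sample metadata with `is_negative_control`.
#' @param table A [feature_table()] containing the control columns.
#' @param min_reads Inclusion threshold on the column sum (default 40,
#'   boundary inclusive).
#' @return Character vector of retained control sample ids; attribute
#'   `excluded` is a data.frame of dropped controls with their read sums.
#' @export
eligible_controls <- function(metadata, table, min_reads = 40) {
  ctl <- metadata$sample_id[metadata$is_negative_control %in% TRUE]
  ctl <- intersect(ctl, table$sample_ids)
  if (!length(ctl)) {
    warning("no negative controls present in table")
    return(structure(character(), excluded = data.frame(sample_id = character(),
                                                        reads = numeric())))
  }
  sums <- colSums(table$counts[, ctl, drop = FALSE])
  keep <- ctl[sums >= min_reads]
  structure(keep, excluded = data.frame(sample_id = ctl[sums < min_reads],
                                        reads = unname(sums[sums < min_reads])))
}

.screen_dataset <- function(ft, metadata, threshold, min_reads, min_samples) {
  ds <- tolower(ft$dataset_label)
  conc_col <- paste0("conc_", ds)
  ctl_keep <- suppressWarnings(eligible_controls(metadata, ft, min_reads))
  real <- setdiff(ft$sample_ids,
                  metadata$sample_id[metadata$is_negative_control %in% TRUE])
  use_samples <- c(real, ctl_keep)
  conc <- metadata[[conc_col]][match(use_samples, metadata$sample_id)]
  cts <- ft$counts[, use_samples, drop = FALSE]
  freq <- sweep(cts, 2, pmax(colSums(cts), 1), "/")
  scores <- numeric(nrow(freq)); nused <- integer(nrow(freq))
  for (i in seq_len(nrow(freq))) {
    s <- frequency_score(freq[i, ], conc, min_samples)
    scores[i] <- s; nused[i] <- attr(s, "n_used")
  }
  data.frame(feature_id = ft$feature_ids, dataset = ft$dataset_label,
             score_P = scores, n_samples_used = nused,
             is_contaminant = !is.na(scores) & scores < threshold,
             stringsAsFactors = FALSE)
}

#' Screen both datasets and remove the union of contaminants
#'
#' Contaminant calls are computed distinctly in the DNA and RNA datasets
#' (frequencies from pre-normalization counts against the matching
#' concentration series); the union of called features is removed from both
#' tables. Features without a defined score are retained (conservative).
#'
#' @param dna,rna [feature_table()] objects sharing a feature universe
#'   (union allowed).
#' @param metadata Sample metadata with concentrations and control flags.
#' @param threshold Probability threshold in (0,1); calls are `score_P <
#'   threshold` (default 0.1). `threshold = 0` yields no calls.
#' @param min_reads Control inclusion threshold (default 40).
#' @param min_samples Minimum samples for a score (default 5).
#' @return List with `dna`, `rna` (filtered tables), `calls` (per-dataset
#'   data.frame), `union` (removed feature ids), `removed_fraction`
#'   (per-sample per-dataset read fraction removed).
#' @export
screen_and_filter <- function(dna, rna, metadata, threshold = 0.1,
                              min_reads = 40, min_samples = 5) {
  if (threshold < 0 || threshold >= 1)
    stop("parameter error: threshold must be in [0, 1)")
  calls <- rbind(.screen_dataset(dna, metadata, threshold, min_reads, min_samples),
                 .screen_dataset(rna, metadata, threshold, min_reads, min_samples))
  union_ids <- sort(unique(calls$feature_id[calls$is_contaminant]))
  strip <- function(ft) {
    keep <- setdiff(ft$feature_ids, union_ids)
    removed <- 1 - colSums(ft$counts[keep, , drop = FALSE]) /
      pmax(colSums(ft$counts), 1)
    list(ft = feature_table(ft$counts[keep, , drop = FALSE], ft$dataset_label),
         removed = removed)
  }
  d <- strip(dna); r <- strip(rna)
  list(dna = d$ft, rna = r$ft, calls = calls, union = union_ids,
       removed_fraction = list(DNA = d$removed, RNA = r$removed))
}
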