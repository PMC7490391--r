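# Repeated-rarefaction reliability filter. For each sample, many
# independent equal-depth draws without replacement (multivariate
# hypergeometric) measure how reliably each feature is detected at the
# target depth; features whose occurrence frequency falls below the 10%
# quantile of the sample's present features are discarded, and a final
# equal-depth draw is taken exclusively from the selected features.

# R draws of D reads without replacement from integer counts, returning the
# per-feature presence count across draws. Sequential hypergeometric chain,
# vectorized across draws (one rhyper call per feature).
.rmvhyper_presence <- function(counts, D, R) {
  total <- sum(counts)
  remaining_pool <- total - cumsum(counts)  # reads in features after i
  left <- rep.int(D, R)
  presence <- integer(length(counts))
  for (i in seq_along(counts)) {
    if (counts[i] == 0L) next
    x <- stats::rhyper(R, counts[i], remaining_pool[i], left)
    presence[i] <- sum(x > 0L)
    left <- left - x
    if (all(left == 0L)) break
  }
  presence
}

# one draw of D reads without replacement; returns counts vector
.rmvhyper_draw <- function(counts, D) {
  total <- sum(counts)
  remaining_pool <- total - cumsum(counts)
  left <- D
  out <- integer(length(counts))
  for (i in seq_along(counts)) {
    if (counts[i] == 0L || left == 0L) next
    x <- stats::rhyper(1, counts[i], remaining_pool[i], left)
    out[i] <- x
    left <- left - x
  }
  out
}

#' Occurrence frequency of features across repeated rarefactions
#'
#' Draws `D` reads without replacement (multivariate hypergeometric) `R`
#' times independently from one sample's counts; the occurrence frequency
#' of a feature is the fraction of draws in which it appears at least once.
#' As `R` grows this converges to the closed-form presence probability
#' `1 - choose(T-c, D)/choose(T, D)`.
#'
#' @param counts Named non-negative integer vector (one sample).
#' @param D Target depth (default 4000); requires `sum(counts) >= D`.
#' @param R Number of draws (default 1000).
#' @param seed Integer seed (draws are deterministic given it).
#' @return Named numeric vector of occurrence frequencies in `[0,1]`
#'   (0 for absent features).
#' @export
occurrence_frequency <- function(counts, D = 4000, R = 1000, seed = 1) {
  counts <- round(counts)
  total <- sum(counts)
  if (total < D)
    stop("excluded: insufficient depth (total ", total, " < D ", D, ")")
  set.seed(as.integer(seed))
  stats::setNames(.rmvhyper_presence(as.integer(counts), D, R) / R,
                  names(counts))
}

#' Reliability filter: keep features at or above the 10% occurrence quantile
#'
#' The threshold is the empirical `q`-quantile (linear interpolation
#' between order statistics at position `(n+1) q`, R quantile type 6) of
#' the occurrence frequencies of the sample's present features; features
#' with frequency greater than or equal to the threshold are selected
#' (boundary inclusive).
#'
#' @param freq Named occurrence frequencies of the sample's present
#'   (count > 0) features.
#' @param q Quantile (default 0.10); `q = 0` selects all present features.
#' @return Character vector of selected feature names; attribute
#'   `threshold` records the cutoff.
#' @export
reliability_filter <- function(freq, q = 0.10) {
  if (!length(freq)) return(structure(character(), threshold = NA_real_))
  thr <- unname(stats::quantile(freq, probs = q, type = 6, names = FALSE))
  structure(names(freq)[freq >= thr], threshold = thr)
}

#' Final equal-depth subsample from the selected features
#'
#' One draw of `D` reads without replacement from the counts restricted to
#' the selected features; unselected features get 0.
#'
#' @param counts Named integer vector (one sample).
#' @param selected Feature names to draw from.
#' @param D Target depth.
#' @param seed Integer seed.
#' @return Named integer vector over all features summing exactly to `D`.
#' @export
final_subsample <- function(counts, selected, D, seed = 1) {
  counts <- round(counts)
  restricted <- counts
  restricted[!(names(counts) %in% selected)] <- 0L
  if (sum(restricted) < D)
    stop("excluded: post-filter depth shortfall (", sum(restricted), " < ", D, ")")
  set.seed(as.integer(seed))
  if (sum(restricted) == D) return(stats::setNames(as.integer(restricted), names(counts)))
  stats::setNames(.rmvhyper_draw(as.integer(restricted), D), names(counts))
}

#' Normalize a feature table by repeated-rarefaction filtering
#'
#' Applies [occurrence_frequency()], [reliability_filter()] and
#' [final_subsample()] per sample with per-sample derived seeds. Samples
#' below depth (or falling below it after filtering) are excluded with a
#' flag rather than an error. All-zero features are dropped from the
#' result.
#'
#' @param table A [feature_table()].
#' @param D Target depth (4000 for a single dataset; the combined
#'   wild-plus-laboratory analysis uses 2000).
#' @param R Draws per sample (default 1000).
#' @param q Occurrence quantile (default 0.10).
#' @param seed Integer seed.
#' @return List with `table` (normalized [feature_table()], every retained
#'   column summing to `D`), `report` (per-sample data.frame: `sample_id`,
#'   `total_reads`, `target_depth`, `draws`, `n_present`, `n_selected`,
#'   `excluded_read_fraction`, `threshold`, `flag`), `occurrence` (feature
#'   x sample matrix of occurrence frequencies), `selected` (list of
#'   per-sample selected feature sets).
#' @export
normalize_table <- function(table, D = 4000, R = 1000, q = 0.10, seed = 1) {
  cts <- table$counts
  nsamp <- ncol(cts)
  seeds <- .derive_seeds(seed, 2L * nsamp)
  occ <- matrix(0, nrow(cts), nsamp, dimnames = dimnames(cts))
  out <- matrix(0L, nrow(cts), nsamp, dimnames = dimnames(cts))
  sel_list <- vector("list", nsamp)
  names(sel_list) <- colnames(cts)
  rep_rows <- vector("list", nsamp)
  for (j in seq_len(nsamp)) {
    cj <- cts[, j]
    total <- sum(cj)
    flag <- ""
    n_present <- sum(cj > 0)
    n_selected <- NA_integer_
    excl <- NA_real_
    thr <- NA_real_
    if (total < D) {
      flag <- "excluded: insufficient depth"
    } else if (n_present == 0) {
      flag <- "excluded: no present features"
    } else {
      fr <- occurrence_frequency(cj, D = D, R = R, seed = seeds[2 * j - 1])
      occ[, j] <- fr
      sel <- reliability_filter(fr[cj > 0], q = q)
      thr <- attr(sel, "threshold")
      sel_list[[j]] <- as.character(sel)
      n_selected <- length(sel)
      restricted_total <- sum(cj[names(cj) %in% sel])
      excl <- 1 - restricted_total / total
      if (restricted_total < D) {
        flag <- "excluded: post-filter depth shortfall"
      } else {
        out[, j] <- final_subsample(cj, sel, D, seed = seeds[2 * j])
      }
    }
    rep_rows[[j]] <- data.frame(
      sample_id = colnames(cts)[j], total_reads = total, target_depth = D,
      draws = R, n_present = n_present, n_selected = n_selected,
      excluded_read_fraction = excl, threshold = thr, flag = flag,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rep_rows)
  keep_samples <- report$flag == ""
  out <- out[, keep_samples, drop = FALSE]
  out <- out[rowSums(out) > 0, , drop = FALSE]
  list(table = feature_table(out, table$dataset_label),
       report = report, occurrence = occ, selected = sel_list)
}
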