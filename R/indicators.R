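# Group-equalized point-biserial indicator statistic with permutation
# p-values and Benjamini-Hochberg correction. Each sample is weighted by
# the inverse of its group size so every group contributes equal total
# weight, making the statistic insensitive to unbalanced designs.

#' Group-equalized point-biserial indicator statistic (r.g)
#'
#' Weighted Pearson correlation between the values `x` and the target
#' indicator `t` (`t_i = 1` when sample i's group is in the target set),
#' with per-sample weights `w_i = 1 / n_g(i)`. With equal group sizes this
#' reduces to the ordinary point-biserial correlation. Presence mode is
#' obtained by binarizing `x` upstream.
#'
#' @param x Numeric values (abundance or presence), one per sample.
#' @param labels Group labels, same length.
#' @param target Character vector: the target group set.
#' @return `r_g` in `[-1, 1]`; `NA` when x or the indicator is constant
#'   under the weights (undefined, flagged via `NA`).
#' @export
rg_statistic <- function(x, labels, target) {
  stopifnot(length(x) == length(labels))
  if (length(unique(labels)) < 2) stop("need >= 2 groups")
  n_g <- table(labels)
  w <- 1 / as.numeric(n_g[as.character(labels)])
  t <- as.numeric(labels %in% target)
  sw <- sum(w)
  mx <- sum(w * x) / sw
  mt <- sum(w * t) / sw
  vx <- sum(w * (x - mx)^2)
  vt <- sum(w * (t - mt)^2)
  if (vx <= 0 || vt <= 0) return(NA_real_)
  sum(w * (x - mx) * (t - mt)) / sqrt(vx * vt)
}

#' Permutation p-value for an indicator statistic
#'
#' Permutes the sample-to-group assignment and computes the one-sided
#' p-value `(1 + #\{r_perm >= r_obs\}) / (1 + nperm)`. The smallest
#' attainable p is `1 / (1 + nperm)`.
#'
#' @param x Values per sample.
#' @param labels Group labels.
#' @param target Target group set.
#' @param nperm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return One-sided p-value, `NA` if the statistic is undefined.
#' @export
indicator_pvalue <- function(x, labels, target, nperm = 999, seed = 1) {
  if (nperm < 99) stop("nperm must be >= 99")
  r_obs <- rg_statistic(x, labels, target)
  if (is.na(r_obs)) return(NA_real_)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(nperm)) {
    rp <- rg_statistic(x, sample(labels), target)
    if (!is.na(rp) && rp >= r_obs - 1e-12) exceed <- exceed + 1L
  }
  (1 + exceed) / (1 + nperm)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_(j>=i) p_(j) m / j`, capped at 1, mapped back to input
#' order. `q >= p` elementwise.
#'
#' @param p Vector of p-values in `[0,1]` (NA passed through).
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(q)
  pv <- p[ok]
  m <- length(pv)
  ord <- order(pv)
  qs <- pv[ord] * (m / seq_len(m))  # m/j first so q == p exactly at j = m
  qs <- rev(cummin(rev(qs)))
  qs <- pmin(qs, 1)
  q[ok][ord] <- qs
  q
}

.canonical_subsets <- function(groups) {
  groups <- sort(unique(groups))
  G <- length(groups)
  sets <- list()
  for (size in seq_len(G - 1)) {
    cmb <- utils::combn(groups, size, simplify = FALSE)
    for (s in cmb) {
      comp <- sort(setdiff(groups, s))
      key_s <- paste(s, collapse = "+")
      key_c <- paste(comp, collapse = "+")
      # keep one of each complement pair (the lexicographically smaller key)
      if (length(s) < length(comp) ||
          (length(s) == length(comp) && key_s < key_c))
        sets[[key_s]] <- s
    }
  }
  sets
}

#' Indicator species analysis over a table
#'
#' Computes the group-equalized statistic, permutation p and BH-adjusted q
#' for every taxon against every non-trivial target group set (all subsets
#' up to complementation), in abundance (relative) or presence mode.
#'
#' @param table A [feature_table()] (counts; converted to relative
#'   abundance, or presence for `mode = "presence"`).
#' @param labels Named group labels (names = sample ids) or vector aligned
#'   to the table's samples.
#' @param mode `"abundance"` or `"presence"`.
#' @param nperm Permutations per test (default 999).
#' @param seed Integer seed.
#' @param targets Optional list of target group sets; default all
#'   non-trivial subsets up to complement.
#' @return data.frame with columns `taxon`, `target`, `stat`, `p`, `q`,
#'   `mode`; BH correction applied across all rows.
#' @export
indicator_analysis <- function(table, labels, mode = c("abundance", "presence"),
                               nperm = 999, seed = 1, targets = NULL) {
  mode <- match.arg(mode)
  m <- table$counts
  if (!is.null(names(labels))) labels <- labels[colnames(m)]
  labels <- as.character(labels)
  vals <- if (mode == "presence") (m > 0) + 0
  else sweep(m, 2, pmax(colSums(m), 1), "/")
  if (is.null(targets)) targets <- .canonical_subsets(labels)
  seeds <- .derive_seeds(seed, nrow(m) * length(targets))
  rows <- vector("list", nrow(m) * length(targets))
  k <- 0L
  for (i in seq_len(nrow(m))) {
    for (j in seq_along(targets)) {
      k <- k + 1L
      st <- rg_statistic(vals[i, ], labels, targets[[j]])
      pv <- if (is.na(st)) NA_real_
      else indicator_pvalue(vals[i, ], labels, targets[[j]], nperm, seeds[k])
      rows[[k]] <- data.frame(
        taxon = rownames(m)[i],
        target = paste(sort(targets[[j]]), collapse = "+"),
        stat = st, p = pv, mode = mode, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[, c("taxon", "target", "stat", "p", "q", "mode")]
}
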