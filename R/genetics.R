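# Genetic and geographic distances and (partial) Mantel machinery for
# distance-decay analyses.

#' Pairwise p-distance between two aligned sequences
#'
#' Proportion of differing nucleotide sites; sites where either sequence
#' has a gap (`-`) or `N` are excluded (pairwise deletion).
#'
#' @param a,b Equal-length aligned nucleotide strings.
#' @return p in `[0,1]`, `NA` when no comparable sites remain.
#' @export
p_distance <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  valid <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(valid)) return(NA_real_)
  sum(a[valid] != b[valid]) / sum(valid)
}

#' p-distance matrix of an aligned sequence set
#' @param seqs An aligned [sequence_set()].
#' @return A [distance_matrix()].
#' @export
p_distance_matrix <- function(seqs) {
  s <- unclass(seqs)
  n <- length(s)
  d <- matrix(0, n, n, dimnames = list(names(s), names(s)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- p_distance(s[[i]], s[[j]])
  distance_matrix(d)
}

.cs_locus <- function(p, q) {
  ov <- sum(sqrt(p * q))
  (2 / pi) * sqrt(2 * (1 - min(ov, 1)))
}

#' Cavalli-Sforza chord distance between two individuals
#'
#' Per locus, individual allele frequencies are 0, 0.5 or 1; over the union
#' allele universe of the pair,
#' `D_l = (2/pi) sqrt(2 (1 - sum_a sqrt(p_a q_a)))`; the distance is the
#' mean of `D_l` over loci typed in both individuals (missing loci
#' skipped). Each per-locus value lies in `[0, (2/pi) sqrt 2]`.
#'
#' @param gt A [genotype_table()].
#' @param i,j Individual ids.
#' @return Mean chord distance, `NA` if no shared typed loci.
#' @export
cavalli_sforza_distance <- function(gt, i, j) {
  ii <- match(i, gt$individual_ids); jj <- match(j, gt$individual_ids)
  if (is.na(ii) || is.na(jj)) stop("unknown individual id")
  vals <- numeric(); k <- 0L
  for (l in seq_along(gt$locus_ids)) {
    ai <- c(gt$a1[ii, l], gt$a2[ii, l])
    aj <- c(gt$a1[jj, l], gt$a2[jj, l])
    if (anyNA(ai) || anyNA(aj)) next
    universe <- union(ai, aj)
    p <- tabulate(match(ai, universe), length(universe)) / 2
    q <- tabulate(match(aj, universe), length(universe)) / 2
    k <- k + 1L
    vals[k] <- .cs_locus(p, q)
  }
  if (!k) return(NA_real_)
  mean(vals)
}

#' Cavalli-Sforza chord distance matrix over all individuals
#' @param gt A [genotype_table()].
#' @return A [distance_matrix()].
#' @export
cavalli_sforza_matrix <- function(gt) {
  ids <- gt$individual_ids
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- cavalli_sforza_distance(gt, ids[i], ids[j])
  distance_matrix(d)
}

#' Euclidean geographic distance matrix (km)
#'
#' @param metadata Data.frame with `sample_id`, `x_km`, `y_km` (samples
#'   with missing coordinates are excluded with a warning).
#' @return A [distance_matrix()] in km.
#' @export
geographic_distance <- function(metadata) {
  ok <- !is.na(metadata$x_km) & !is.na(metadata$y_km)
  if (any(!ok))
    warning("excluding samples without coordinates: ",
            paste(utils::head(metadata$sample_id[!ok], 5), collapse = ","))
  md <- metadata[ok, ]
  d <- as.matrix(stats::dist(cbind(md$x_km, md$y_km)))
  dimnames(d) <- list(md$sample_id, md$sample_id)
  distance_matrix(d)
}

.upper_vec <- function(m) m[upper.tri(m)]

# symmetric matrix of ranks of the upper-triangle entries (for fast
# Spearman Mantel under row/column permutation)
.rank_matrix <- function(m) {
  n <- nrow(m)
  r <- matrix(0, n, n)
  r[upper.tri(r)] <- rank(.upper_vec(m))
  r + t(r)
}

#' Mantel test with Spearman correlation
#'
#' `r` is the Spearman correlation of the corresponding off-diagonal
#' upper-triangle entries; the one-sided p-value permutes rows and columns
#' of `da` simultaneously: `p = (1 + #\{r_perm >= r_obs\}) / (1 + nperm)`.
#' Being rank-based, `r` is invariant under any common strictly monotone
#' transform of either matrix's entries.
#'
#' @param da,db [distance_matrix()] objects sharing ids (db is aligned to
#'   da's id order).
#' @param nperm Permutations (default 1000).
#' @param seed Integer seed.
#' @return List of class `mantel_result`: `r`, `p`, `nperm`.
#' @export
mantel <- function(da, db, nperm = 1000, seed = 1) {
  da <- unclass(as.matrix(da)); db <- unclass(as.matrix(db))
  if (!is.null(rownames(da)) && !is.null(rownames(db)))
    db <- db[rownames(da), rownames(da)]
  n <- nrow(da)
  ra <- .rank_matrix(da)
  rb_vec <- rank(.upper_vec(db))
  ra_vec <- .upper_vec(ra)
  if (stats::sd(ra_vec) == 0 || stats::sd(rb_vec) == 0)
    return(structure(list(r = NA_real_, p = NA_real_, nperm = nperm),
                     class = "mantel_result"))
  r_obs <- stats::cor(ra_vec, rb_vec)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(nperm)) {
    p <- sample.int(n)
    rp <- stats::cor(.upper_vec(ra[p, p]), rb_vec)
    if (rp >= r_obs - 1e-12) exceed <- exceed + 1L
  }
  structure(list(r = r_obs, p = (1 + exceed) / (1 + nperm), nperm = nperm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel (Spearman): r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$nperm))
  if (!is.null(x$conditions))
    cat("  conditioned on:", paste(x$conditions, collapse = ", "), "\n")
  invisible(x)
}

#' Partial Mantel test
#'
#' Partial Spearman correlation of `da` and `db` given one or more
#' condition matrices, computed by recursive partialling of the rank
#' correlations; the permutation test permutes `da` and recomputes the
#' partial statistic.
#'
#' @param da Main distance matrix (permuted under the null).
#' @param db Response distance matrix.
#' @param conditions List of condition distance matrices.
#' @param nperm Permutations (default 1000).
#' @param seed Integer seed.
#' @return `mantel_result` with `conditions` listing the conditioned
#'   matrices; `r` is `NA` (degenerate) when a conditioning correlation is
#'   +-1.
#' @export
partial_mantel <- function(da, db, conditions, nperm = 1000, seed = 1) {
  if (!is.list(conditions)) conditions <- list(conditions)
  da <- unclass(as.matrix(da))
  ids <- rownames(da)
  align <- function(m) {
    m <- unclass(as.matrix(m))
    if (!is.null(ids) && !is.null(rownames(m))) m <- m[ids, ids]
    m
  }
  db <- align(db)
  conditions <- lapply(conditions, align)
  n <- nrow(da)
  ra <- .rank_matrix(da)
  vecs <- c(list(A = .upper_vec(ra), B = rank(.upper_vec(db))),
            lapply(conditions, function(m) rank(.upper_vec(m))))
  stat <- function(va) {
    vs <- vecs; vs$A <- va
    R <- stats::cor(do.call(cbind, vs))
    .partial_recursive(R)
  }
  r_obs <- stat(vecs$A)
  if (is.na(r_obs))
    return(structure(list(r = NA_real_, p = NA_real_, nperm = nperm,
                          conditions = paste0("C", seq_along(conditions))),
                     class = "mantel_result"))
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(nperm)) {
    p <- sample.int(n)
    rp <- stat(.upper_vec(ra[p, p]))
    if (!is.na(rp) && rp >= r_obs - 1e-12) exceed <- exceed + 1L
  }
  structure(list(r = r_obs, p = (1 + exceed) / (1 + nperm), nperm = nperm,
                 conditions = paste0("C", seq_along(conditions))),
            class = "mantel_result")
}

# r_AB | C1..Ck by recursion on the last condition; R is the correlation
# matrix of (A, B, C1..Ck)
.partial_recursive <- function(R) {
  k <- nrow(R)
  if (k == 2) return(R[1, 2])
  sub <- function(keep) R[keep, keep, drop = FALSE]
  idx <- seq_len(k)
  r_ab <- .partial_recursive(sub(idx[-k]))
  r_ac <- .partial_recursive(sub(c(1, k, setdiff(idx, c(1, 2, k)))))
  r_bc <- .partial_recursive(sub(c(2, k, setdiff(idx, c(1, 2, k)))))
  den <- (1 - r_ac^2) * (1 - r_bc^2)
  if (is.na(r_ab) || is.na(den) || den <= 1e-12) return(NA_real_)
  (r_ab - r_ac * r_bc) / sqrt(den)
}
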