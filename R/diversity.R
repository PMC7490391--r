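# Alpha diversity, phylogenetic diversity, beta-diversity distances,
# principal coordinates, and permutational multivariate ANOVA.

#' Shannon diversity (natural log)
#' @param counts Non-negative count or abundance vector.
#' @return `H = -sum p_i ln p_i` over positive entries, in nats.
#' @export
shannon <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(NA_real_)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Bias-corrected Chao1 richness estimator
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, with F1 the number of singletons
#' and F2 the number of doubletons. Always at least `S_obs`.
#'
#' @param counts Integer count vector.
#' @return Estimated richness.
#' @export
chao1 <- function(counts) {
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

# edge x sample matrix of reads descending each edge, plus edge lengths.
# Works on any sample matrix whose rownames are tips of the tree.
.edge_profile <- function(m, tree) {
  miss <- setdiff(rownames(m)[rowSums(m) > 0], tree$tip.label)
  if (length(miss))
    stop("input error: features missing from tree: ",
         paste(utils::head(miss, 5), collapse = ","))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  acc <- matrix(0, ntip + nnode, ncol(m))
  idx <- match(tree$tip.label, rownames(m))
  has <- !is.na(idx)
  acc[seq_len(ntip)[has], ] <- m[idx[has], , drop = FALSE]
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    acc[par, ] <- acc[par, ] + acc[child, ]
  }
  ed <- tr$edge[, 2]
  list(desc = acc[ed, , drop = FALSE], lengths = tr$edge.length,
       totals = colSums(m))
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree connecting the present tips
#' and the root (root path included).
#'
#' @param presence Named logical/0-1/count vector; positive entries are
#'   present tips.
#' @param tree Rooted `phylo` with branch lengths.
#' @return PD in branch-length units.
#' @export
faith_pd <- function(presence, tree) {
  m <- matrix(as.numeric(presence > 0), ncol = 1,
              dimnames = list(names(presence), "s"))
  if (!any(m > 0)) return(NA_real_)
  ep <- .edge_profile(m, tree)
  sum(ep$lengths[ep$desc[, 1] > 0])
}

#' Beta-diversity distance between two samples
#'
#' Bray-Curtis `sum|x-y| / sum(x+y)`; Jaccard on presence
#' `1 - |intersection| / |union|`; unweighted UniFrac = branch length unique
#' to one sample's tip set over branch length in either; weighted UniFrac
#' (normalized) = `sum l_b |pA_b - pB_b| / sum l_b (pA_b + pB_b)` with
#' `p_b` the fraction of a sample's reads descending branch b.
#'
#' @param x,y Named count vectors over the same feature universe.
#' @param kind One of `"bray_curtis"`, `"jaccard"`,
#'   `"unweighted_unifrac"`, `"weighted_unifrac"`.
#' @param tree Rooted `phylo`; required for the UniFrac kinds.
#' @return Distance in `[0,1]`, `NA` if both samples are empty.
#' @export
beta_distance <- function(x, y, kind = c("bray_curtis", "jaccard",
                                         "unweighted_unifrac",
                                         "weighted_unifrac"), tree = NULL) {
  kind <- match.arg(kind)
  if (sum(x) == 0 && sum(y) == 0) return(NA_real_)
  switch(kind,
    bray_curtis = sum(abs(x - y)) / sum(x + y),
    jaccard = {
      a <- x > 0; b <- y > 0
      1 - sum(a & b) / sum(a | b)
    },
    {
      if (is.null(tree)) stop("tree required for UniFrac")
      m <- cbind(A = x, B = y)
      ep <- .edge_profile(m, tree)
      if (kind == "unweighted_unifrac") {
        inA <- ep$desc[, 1] > 0; inB <- ep$desc[, 2] > 0
        sum(ep$lengths[xor(inA, inB)]) / sum(ep$lengths[inA | inB])
      } else {
        pA <- ep$desc[, 1] / ep$totals[1]
        pB <- ep$desc[, 2] / ep$totals[2]
        sum(ep$lengths * abs(pA - pB)) / sum(ep$lengths * (pA + pB))
      }
    })
}

#' All pairwise beta-diversity distances of a table's samples
#'
#' @param table A [feature_table()] or count matrix (features x samples).
#' @param kind See [beta_distance()].
#' @param tree Rooted `phylo` for UniFrac kinds.
#' @return A [distance_matrix()] over samples.
#' @export
beta_diversity <- function(table, kind = "bray_curtis", tree = NULL) {
  m <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  S <- ncol(m)
  d <- matrix(0, S, S, dimnames = list(colnames(m), colnames(m)))
  if (kind %in% c("unweighted_unifrac", "weighted_unifrac")) {
    if (is.null(tree)) stop("tree required for UniFrac")
    ep <- .edge_profile(m, tree)
    pres <- ep$desc > 0
    prop <- sweep(ep$desc, 2, pmax(ep$totals, 1), "/")
    for (i in seq_len(S - 1)) for (j in (i + 1):S) {
      if (kind == "unweighted_unifrac") {
        either <- pres[, i] | pres[, j]
        d[i, j] <- d[j, i] <-
          sum(ep$lengths[xor(pres[, i], pres[, j])]) / sum(ep$lengths[either])
      } else {
        d[i, j] <- d[j, i] <-
          sum(ep$lengths * abs(prop[, i] - prop[, j])) /
          sum(ep$lengths * (prop[, i] + prop[, j]))
      }
    }
  } else {
    for (i in seq_len(S - 1)) for (j in (i + 1):S)
      d[i, j] <- d[j, i] <- beta_distance(m[, i], m[, j], kind)
  }
  distance_matrix(d)
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-D^2/2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their
#' (positive) eigenvalues. Negative eigenvalues are reported, not
#' corrected.
#'
#' @param d A [distance_matrix()] (or symmetric matrix).
#' @return List of class `ordination`: `coordinates` (samples x axes, only
#'   positive-eigenvalue axes), `eigenvalues` (all, descending),
#'   `proportion` (share of positive-eigenvalue variance per kept axis).
#' @export
pcoa <- function(d) {
  d <- unclass(as.matrix(d))
  n <- nrow(d)
  G <- .gower_center(d)
  eg <- eigen(G, symmetric = TRUE)
  ev <- eg$values
  keep <- which(ev > max(ev) * 1e-9 & ev > 0)
  coords <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev[keep]), length(keep))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_along(keep))
  structure(list(coordinates = coords, eigenvalues = ev,
                 proportion = ev[keep] / sum(ev[ev > 0])),
            class = "ordination")
}

.gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% a %*% J
}

#' Permutational multivariate analysis of variance (sequential)
#'
#' Sequential (Type-I) decomposition of the Gower-centered inner-product
#' matrix via projection (hat) matrices of the cumulative model; pseudo-F
#' and p-values by free permutation of sample labels.
#'
#' @param d A [distance_matrix()] over samples.
#' @param terms data.frame of factors (one column per term, in model
#'   order), rows matching `d`'s samples.
#' @param nperm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return Object of class `permanova` : data.frame with per-term `df`,
#'   `SS`, `R2`, `F`, `p`, plus Residual and Total rows.
#' @export
permanova <- function(d, terms, nperm = 999, seed = 1) {
  if (nperm < 1) stop("parameter error: nperm must be >= 1")
  d <- unclass(as.matrix(d))
  n <- nrow(d)
  terms <- as.data.frame(terms)
  stopifnot(nrow(terms) == n)
  G <- .gower_center(d)
  hats <- list(matrix(1 / n, n, n))
  dfs <- integer(length(terms))
  X <- matrix(1, n, 1)
  for (k in seq_along(terms)) {
    Xk <- cbind(X, stats::model.matrix(~factor(terms[[k]]))[, -1, drop = FALSE])
    qrk <- qr(Xk)
    Q <- qr.Q(qrk)[, seq_len(qrk$rank), drop = FALSE]
    hats[[k + 1]] <- tcrossprod(Q)
    dfs[k] <- qrk$rank - qr(X)$rank
    X <- Xk
  }
  ss_of <- function(Gm) {
    tot <- sum(diag(Gm))
    ss <- numeric(length(terms))
    for (k in seq_along(terms))
      ss[k] <- sum((hats[[k + 1]] - hats[[k]]) * Gm)
    res <- tot - sum(hats[[length(hats)]] * Gm) + sum(hats[[1]] * Gm)
    c(ss, res, tot - sum(hats[[1]] * Gm))
  }
  obs <- ss_of(G)
  ss <- obs[seq_along(terms)]
  ss_res <- obs[length(terms) + 1]
  ss_tot <- obs[length(terms) + 2]
  df_res <- n - 1 - sum(dfs)
  f_obs <- (ss / dfs) / (ss_res / df_res)
  set.seed(as.integer(seed))
  exceed <- numeric(length(terms))
  for (b in seq_len(nperm)) {
    p <- sample.int(n)
    sb <- ss_of(G[p, p])
    fb <- (sb[seq_along(terms)] / dfs) / (sb[length(terms) + 1] / df_res)
    exceed <- exceed + (fb >= f_obs - 1e-12)
  }
  pval <- (1 + exceed) / (1 + nperm)
  out <- data.frame(
    term = c(names(terms), "Residual", "Total"),
    df = c(dfs, df_res, n - 1),
    SS = c(ss, ss_res, ss_tot),
    R2 = c(ss / ss_tot, ss_res / ss_tot, 1),
    F = c(f_obs, NA, NA),
    p = c(pval, NA, NA),
    stringsAsFactors = FALSE)
  class(out) <- c("permanova", "data.frame")
  out
}
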