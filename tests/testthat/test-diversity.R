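test_that("shannon and chao1 match closed forms", {
  expect_equal(shannon(rep(5, 4)), log(4))
  expect_equal(shannon(c(7, 0, 0)), 0)
  cts <- c(1, 2, 3, 4)
  p <- cts / sum(cts)
  expect_equal(shannon(cts), -sum(p * log(p)))
  expect_equal(chao1(c(3, 4, 5)), 3)               # no singletons
  expect_equal(chao1(c(1, 1, 2)), 3 + 2 * 1 / (2 * 2))
  set.seed(1)
  for (i in 1:20) {
    x <- rpois(30, 1)
    expect_gte(chao1(x), sum(x > 0))
  }
})

test_that("faith_pd sums the minimal root-connected subtree", {
  tr <- toy_tree()
  all_len <- sum(tr$edge.length)
  expect_equal(faith_pd(c(t1 = 1, t2 = 1, t3 = 1, t4 = 1), tr), all_len)
  # single tip: path to root
  expect_equal(faith_pd(c(t1 = 1, t2 = 0, t3 = 0, t4 = 0), tr), 0.1 + 0.3)
  # two tips across the root
  expect_equal(faith_pd(c(t1 = 1, t2 = 0, t3 = 0, t4 = 1), tr),
               0.1 + 0.3 + 0.5 + 0.6)
  expect_error(faith_pd(c(t9 = 1), tr), "missing from tree")
})

test_that("beta distances match brute-force branch enumeration and vegan", {
  tr <- toy_tree()
  x <- c(t1 = 5, t2 = 0, t3 = 3, t4 = 0)
  y <- c(t1 = 0, t2 = 2, t3 = 3, t4 = 1)
  edges <- toy_tree_edges()
  pres <- function(v, tips) sum(v[tips]) > 0
  prop <- function(v, tips) sum(v[tips]) / sum(v)
  uw_num <- uw_den <- w_num <- w_den <- 0
  for (e in edges) {
    a <- pres(x, e$tips); b <- pres(y, e$tips)
    if (xor(a, b)) uw_num <- uw_num + e$len
    if (a || b) uw_den <- uw_den + e$len
    pa <- prop(x, e$tips); pb <- prop(y, e$tips)
    w_num <- w_num + e$len * abs(pa - pb)
    w_den <- w_den + e$len * (pa + pb)
  }
  expect_equal(beta_distance(x, y, "unweighted_unifrac", tree = tr),
               uw_num / uw_den, tolerance = 1e-8)
  expect_equal(beta_distance(x, y, "weighted_unifrac", tree = tr),
               w_num / w_den, tolerance = 1e-8)
  expect_equal(beta_distance(x, y, "bray_curtis"),
               sum(abs(x - y)) / sum(x + y))
  expect_equal(beta_distance(x, y, "jaccard"), 1 - 1 / 4)  # shared {t3} of 4 present
  # identity and disjoint-presence extremes
  expect_equal(beta_distance(x, x, "weighted_unifrac", tree = tr), 0)
  star <- ape::read.tree(text = "(t1:1,t2:1,t3:1,t4:1);")
  a <- c(t1 = 2, t2 = 3, t3 = 0, t4 = 0); b <- c(t1 = 0, t2 = 0, t3 = 1, t4 = 5)
  expect_equal(beta_distance(a, b, "jaccard"), 1)
  expect_equal(beta_distance(a, b, "unweighted_unifrac", tree = star), 1)
  # matrix builder agrees with vegan on bray and jaccard
  skip_if_not_installed("vegan")
  set.seed(2)
  m <- matrix(rpois(5 * 40, 4), 40, 5,
              dimnames = list(sprintf("f%02d", 1:40), paste0("s", 1:5)))
  bc <- beta_diversity(m, "bray_curtis")
  expect_equal(unclass(bc)[lower.tri(bc)],
               as.numeric(vegan::vegdist(t(m), "bray")), tolerance = 1e-12)
  jc <- beta_diversity(m, "jaccard")
  vj <- as.matrix(vegan::vegdist(t(m) > 0, "jaccard"))
  expect_equal(unclass(jc)[lower.tri(jc)], vj[lower.tri(vj)], tolerance = 1e-12)
})

test_that("weighted UniFrac is invariant to per-sample scaling", {
  tr <- toy_tree()
  x <- c(t1 = 5, t2 = 1, t3 = 3, t4 = 0)
  y <- c(t1 = 0, t2 = 2, t3 = 3, t4 = 1)
  expect_equal(beta_distance(7 * x, y, "weighted_unifrac", tree = tr),
               beta_distance(x, y, "weighted_unifrac", tree = tr))
})

test_that("beta distances are valid distance matrices; triangle inequality holds", {
  set.seed(3)
  m <- matrix(rpois(6 * 30, 3), 30, 6,
              dimnames = list(sprintf("f%02d", 1:30), paste0("s", 1:6)))
  tr <- ape::rtree(30, tip.label = sample(rownames(m)))
  for (kind in c("bray_curtis", "jaccard", "unweighted_unifrac")) {
    d <- beta_diversity(m, kind, tree = tr)
    expect_length(validate_distance_matrix(d), 0)
  }
  for (kind in c("jaccard", "unweighted_unifrac")) {
    d <- unclass(beta_diversity(m, kind, tree = tr))
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("pcoa embeds Euclidean-compatible distances exactly", {
  set.seed(4)
  pts <- matrix(rnorm(14), 7, 2, dimnames = list(paste0("s", 1:7), NULL))
  d <- distance_matrix(as.matrix(dist(pts)))
  ord <- pcoa(d)
  rec <- as.matrix(dist(ord$coordinates[, 1:2]))
  expect_equal(unname(rec), unname(unclass(d)), tolerance = 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-10))
  # 2 samples at distance 2 -> one axis, coordinates +-1
  d2 <- distance_matrix(matrix(c(0, 2, 2, 0), 2, 2,
                               dimnames = list(c("a", "b"), c("a", "b"))))
  o2 <- pcoa(d2)
  expect_equal(ncol(o2$coordinates), 1)
  expect_setequal(round(o2$coordinates[, 1], 10), c(1, -1))
})

test_that("permanova matches brute-force within/between decomposition", {
  # 6 samples, 2 groups, hand distance matrix
  set.seed(5)
  pts <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- c("a", "a", "a", "b", "b", "b")
  pm <- permanova(distance_matrix(d), data.frame(g = g), nperm = 99, seed = 1)
  ss_tot <- sum(d[upper.tri(d)]^2) / 6
  ss_within <- 0
  for (gg in unique(g)) {
    idx <- which(g == gg)
    sub <- d[idx, idx]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  expect_equal(pm$SS[pm$term == "Total"], ss_tot, tolerance = 1e-10)
  expect_equal(pm$SS[pm$term == "g"], ss_tot - ss_within, tolerance = 1e-10)
  expect_equal(sum(pm$R2[1:2]), 1)
  # one sample per group -> R2 = 1
  d3 <- distance_matrix(d[1:3, 1:3])
  pm3 <- permanova(d3, data.frame(g = c("x", "y", "z")), nperm = 99, seed = 1)
  expect_equal(pm3$R2[1], 1)
  expect_error(permanova(d3, data.frame(g = c("x", "y", "z")), nperm = 0), "nperm")
})

test_that("permanova agrees with vegan::adonis2 on sequential terms", {
  skip_if_not_installed("vegan")
  set.seed(6)
  pts <- matrix(rnorm(40), 20, 2)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:20), paste0("s", 1:20))
  df <- data.frame(g = rep(c("a", "b"), 10), h = rep(c("x", "y", "z", "w"), 5))
  pm <- permanova(distance_matrix(d), df, nperm = 99, seed = 1)
  av <- vegan::adonis2(as.dist(d) ~ g + h, data = df, permutations = 99, by = "terms")
  expect_equal(pm$SS[1:3], av$SumOfSqs[1:3], tolerance = 1e-10)
  expect_equal(pm$F[1:2], av$F[1:2], tolerance = 1e-10)
  expect_equal(pm$R2[1:2], av$R2[1:2], tolerance = 1e-10)
})
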