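mk_tax <- function(features, genus, family = "f_x") {
  data.frame(feature_id = features, phylum = "Firmicutes", class = "c",
             order = "o", family = family, genus = genus,
             stringsAsFactors = FALSE)
}

test_that("collapse_taxonomy sums counts and pools unclassified by parent", {
  m <- matrix(c(1, 2, 3, 4,
                5, 6, 7, 8), 4, 2,
              dimnames = list(c("f1", "f2", "f3", "f4"), c("s1", "s2")))
  ft <- feature_table(m, "DNA")
  tax <- mk_tax(rownames(m), c("gA", "gA", "gB", "Unclassified"),
                family = c("fam1", "fam1", "fam1", "fam2"))
  coll <- collapse_taxonomy(ft, tax, "genus")
  expect_equal(colSums(coll$counts), colSums(m))
  expect_equal(unname(coll$counts["gA", ]), c(1 + 2, 5 + 6))
  expect_equal(unname(coll$counts["gB", ]), c(3, 7))
  expect_true("Unclassified_family_fam2" %in% rownames(coll$counts))
  # single genus collapses to one row preserving sums
  coll1 <- collapse_taxonomy(ft, mk_tax(rownames(m), "g1"), "genus")
  expect_equal(nrow(coll1$counts), 1)
  expect_equal(unname(coll1$counts[1, ]), unname(colSums(m)))
  expect_error(collapse_taxonomy(ft, tax, "kingdom"), "unknown level")
})

test_that("core-calling commutes with genus collapsing", {
  b <- simulate_bundle(small_config(), seed = 6, genetics = FALSE)
  md <- b$metadata
  wild <- md$sample_id[md$group == "wild" & !(md$is_negative_control %in% TRUE)]
  coll <- collapse_taxonomy(b$dna, b$taxonomy, "genus")
  core_then <- core_set(coll, wild)
  # collapse a pre-restricted table: same genus-level prevalence
  sub <- feature_table(b$dna$counts[, wild], "DNA")
  core_alt <- core_set(collapse_taxonomy(sub, b$taxonomy, "genus"), wild)
  expect_setequal(core_then, core_alt)
})

test_that("top_taxa applies the top-k-in-enough-groups rule", {
  g1 <- matrix(c(50, 30, 10, 5, 3, 2), 6, 1,
               dimnames = list(paste0("t", 1:6), "a"))
  g2 <- g1[c(2, 1, 3, 5, 4, 6), , drop = FALSE]
  rownames(g2) <- paste0("t", 1:6)
  tt <- top_taxa(list(G1 = g1, G2 = g2), k = 5, min_groups = 2)
  # brute force: taxa in top 5 of both rankings
  in_top <- function(m) {
    rel <- m[, 1] / sum(m[, 1])
    names(sort(rel, decreasing = TRUE))[1:5]
  }
  expect_setequal(tt, intersect(in_top(g1), in_top(g2)))
  # identical groups, 3 taxa, k = 5 -> all qualify
  s <- matrix(c(3, 2, 1), 3, 1, dimnames = list(c("x", "y", "z"), "a"))
  expect_setequal(top_taxa(list(A = s, B = s), k = 5), c("x", "y", "z"))
  # top-5 in exactly 1 of 4 groups -> excluded
  g_hit <- matrix(c(10, rep(1, 5)), 6, 1, dimnames = list(paste0("t", 1:6), "a"))
  g_other <- matrix(c(0.01, 10, 9, 8, 7, 6), 6, 1, dimnames = list(paste0("t", 1:6), "a"))
  tt4 <- top_taxa(list(A = g_hit, B = g_other, C = g_other, D = g_other), k = 5)
  expect_false("t1" %in% tt4)
})

test_that("core_set boundary is inclusive at 25%", {
  m <- matrix(0, 2, 12, dimnames = list(c("in3", "in2"), sprintf("s%02d", 1:12)))
  m["in3", 1:3] <- 1   # 3/12 = 25%
  m["in2", 1:2] <- 1   # 2/12 = 16.7%
  ft <- feature_table(m, "DNA")
  core <- core_set(ft, colnames(m), prevalence = 0.25)
  expect_true("in3" %in% core)
  expect_false("in2" %in% core)
  # single sample: all present taxa are core
  expect_setequal(core_set(ft, "s01"), c("in3", "in2"))
})

test_that("partition_core categories and order invariance", {
  same <- list(A = c("x", "y"), B = c("x", "y"))
  p1 <- partition_core(same)
  expect_setequal(p1$shared_all, c("x", "y"))
  expect_length(unlist(p1$unique), 0)
  disj <- list(A = "x", B = "y")
  p2 <- partition_core(disj)
  expect_length(p2$shared_all, 0)
  expect_equal(sort(unlist(p2$unique, use.names = FALSE)), c("x", "y"))
  # 4-group Venn with 17 in the 4-way intersection
  shared <- sprintf("sh%02d", 1:17)
  sets <- list(A = c(shared, "uA", "pAB"), B = c(shared, "uB", "pAB"),
               C = c(shared, "uC"), D = c(shared, "uD1", "uD2"))
  p3 <- partition_core(sets)
  expect_length(p3$shared_all, 17)
  expect_equal(p3$partial, "pAB")
  expect_setequal(unlist(p3$unique, use.names = FALSE),
                  c("uA", "uB", "uC", "uD1", "uD2"))
  p3r <- partition_core(rev(sets))
  expect_equal(p3$shared_all, p3r$shared_all)
  expect_setequal(p3$partial, p3r$partial)
})

test_that("category_fraction computes per-individual core shares", {
  m <- matrix(c(30, 70,
                30, 70,
                60, 140), 2, 3,
              dimnames = list(c("shared", "uniq"), c("i1", "i2", "i3")))
  ft <- feature_table(m, "DNA")
  part <- partition_core(list(G = c("shared", "uniq"), H = "shared"))
  cf <- category_fraction(ft, colnames(m), part, "G")
  expect_equal(unname(cf$mean["shared_all"]), 0.3)
  expect_equal(unname(cf$mean["unique"]), 0.7)
  expect_equal(rowSums(cf$per_individual[, c("shared_all", "partial", "unique")]),
               rep(1, 3), ignore_attr = TRUE)
  # single category holding the whole core -> fraction 1
  cf2 <- category_fraction(ft, colnames(m),
                           partition_core(list(G = "shared", H = "other")), "G")
  expect_equal(unname(cf2$mean["unique"]), 1)
})
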