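test_that("p_distance excludes gap/N sites and counts mismatches", {
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("AC-T", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ANGT", "ACGA"), 1 / 3)
  expect_true(is.na(p_distance("NN--", "ACGT")))
  expect_error(p_distance("ACG", "ACGT"), "equal length")
})

test_that("Cavalli-Sforza chord distance matches closed forms", {
  mk <- function(g1, g2) {
    a1 <- rbind(i = g1[1], j = g2[1]); a2 <- rbind(i = g1[2], j = g2[2])
    colnames(a1) <- colnames(a2) <- "L1"
    genotype_table(a1, a2)
  }
  # identical homozygotes -> 0
  expect_equal(cavalli_sforza_distance(mk(c(100, 100), c(100, 100)), "i", "j"), 0)
  # disjoint alleles -> per-locus maximum (2/pi) sqrt(2)
  expect_equal(cavalli_sforza_distance(mk(c(100, 100), c(102, 102)), "i", "j"),
               (2 / pi) * sqrt(2))
  # heterozygote AB vs homozygote AA
  expect_equal(cavalli_sforza_distance(mk(c(100, 102), c(100, 100)), "i", "j"),
               (2 / pi) * sqrt(2 * (1 - sqrt(0.5))))
  # missing locus skipped; no shared typed loci -> NA
  a1 <- cbind(L1 = c(i = 100L, j = NA), L2 = c(i = 100L, j = 100L))
  gt <- genotype_table(a1, a1)
  expect_equal(cavalli_sforza_distance(gt, "i", "j"), 0)
  a1b <- cbind(L1 = c(i = 100L, j = NA), L2 = c(i = NA, j = 100L))
  expect_true(is.na(cavalli_sforza_distance(genotype_table(a1b, a1b), "i", "j")))
  # per-locus values bounded by (2/pi) sqrt(2) on random genotypes
  set.seed(1)
  n <- 8
  r1 <- matrix(sample(100:108, n * 5, TRUE), n, 5,
               dimnames = list(paste0("i", 1:n), paste0("L", 1:5)))
  r2 <- matrix(sample(100:108, n * 5, TRUE), n, 5, dimnames = dimnames(r1))
  cs <- cavalli_sforza_matrix(genotype_table(r1, r2))
  expect_length(validate_distance_matrix(cs), 0)
  expect_true(all(unclass(cs) <= (2 / pi) * sqrt(2) + 1e-12))
})

test_that("geographic_distance is Euclidean and translation invariant", {
  md <- data.frame(sample_id = c("a", "b"), x_km = c(0, 3), y_km = c(0, 4))
  d <- geographic_distance(md)
  expect_equal(d["a", "b"], 5)
  expect_equal(d["a", "a"], 0)
  md2 <- md; md2$x_km <- md2$x_km + 100; md2$y_km <- md2$y_km - 7
  expect_equal(unclass(geographic_distance(md2)), unclass(d))
  md3 <- rbind(md, data.frame(sample_id = "c", x_km = NA, y_km = 1))
  expect_warning(d3 <- geographic_distance(md3), "without coordinates")
  expect_equal(dim(d3), c(2, 2))
})

test_that("mantel: perfect correlation, rank invariance, id alignment", {
  set.seed(2)
  pts <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:10), paste0("s", 1:10))
  m <- mantel(distance_matrix(d), distance_matrix(d), nperm = 199, seed = 1)
  expect_equal(m$r, 1)
  expect_lte(m$p, 0.01)
  # any common monotone transform leaves r unchanged
  m2 <- mantel(distance_matrix(d), distance_matrix(d^2), nperm = 99, seed = 1)
  expect_equal(m2$r, 1)
  # id alignment: permuting db's id order must not change r
  perm <- sample(rownames(d))
  m3 <- mantel(distance_matrix(d), distance_matrix(d[perm, perm]), nperm = 99, seed = 1)
  expect_equal(m3$r, 1)
})

test_that("partial_mantel: degenerate condition flagged, independent condition harmless, chain partialled out", {
  set.seed(3)
  pts <- matrix(rnorm(30), 15, 2)
  A <- as.matrix(dist(pts))
  dimnames(A) <- list(paste0("s", 1:15), paste0("s", 1:15))
  B <- A + matrix(runif(225, 0, 0.1), 15); B <- (B + t(B)) / 2; diag(B) <- 0
  dimnames(B) <- dimnames(A)
  # db equal to the condition -> undefined
  pm0 <- partial_mantel(distance_matrix(A), distance_matrix(B), list(distance_matrix(B)),
                        nperm = 99, seed = 1)
  expect_true(is.na(pm0$r))
  # condition independent of both: partial r close to simple r
  C <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  dimnames(C) <- dimnames(A)
  r_simple <- mantel(distance_matrix(A), distance_matrix(B), nperm = 99, seed = 1)$r
  r_part <- partial_mantel(distance_matrix(A), distance_matrix(B),
                           list(distance_matrix(C)), nperm = 99, seed = 1)$r
  expect_lt(abs(r_part - r_simple), 0.15)
  # planted chain A <- C -> B: partial near 0, simple clearly positive
  rs <- rp <- numeric(20)
  for (s in 1:20) {
    set.seed(100 + s)
    z <- matrix(rnorm(40), 20, 2)
    Cz <- as.matrix(dist(z)); ids <- paste0("s", 1:20)
    dimnames(Cz) <- list(ids, ids)
    Az <- as.matrix(dist(z + matrix(rnorm(40, 0, 0.4), 20)))
    Bz <- as.matrix(dist(z + matrix(rnorm(40, 0, 0.4), 20)))
    dimnames(Az) <- dimnames(Bz) <- list(ids, ids)
    rs[s] <- mantel(distance_matrix(Az), distance_matrix(Bz), nperm = 99, seed = s)$r
    rp[s] <- partial_mantel(distance_matrix(Az), distance_matrix(Bz),
                            list(distance_matrix(Cz)), nperm = 99, seed = s)$r
  }
  expect_gt(mean(rs), 0.3)
  expect_lt(abs(mean(rp)), 0.1)
})
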