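# Shared fixtures, all built in code.

# small, fast simulation config for IO/pipeline tests
small_config <- function(...) {
  sim_config(
    n_per_group = c(wild = 16, `HL-Lab` = 8, `MPI-Lab` = 6, `C57BL/6J` = 4),
    n_farms = 6, n_lab_units = c(`HL-Lab` = 2, `MPI-Lab` = 2, `C57BL/6J` = 1),
    n_shared_core = 10,
    n_group_specific = c(wild = 8, `HL-Lab` = 4, `MPI-Lab` = 4, `C57BL/6J` = 3),
    n_carry_over = 3, n_transient = 20, n_rare_tail = 60,
    n_contaminants = 8, n_controls = 3,
    depth_meanlog = log(3000), min_depth = 1500,
    ...)
}

toy_tree <- function() {
  ape::read.tree(text = "((t1:0.1,t2:0.2):0.3,(t3:0.4,t4:0.5):0.6):0;")
}

# edge list of toy_tree() for brute-force branch-enumeration oracles:
# descendant tip set and length per branch
toy_tree_edges <- function() {
  list(list(tips = c("t1", "t2"), len = 0.3),
       list(tips = "t1", len = 0.1),
       list(tips = "t2", len = 0.2),
       list(tips = c("t3", "t4"), len = 0.6),
       list(tips = "t3", len = 0.4),
       list(tips = "t4", len = 0.5))
}

toy_table <- function(dataset = "DNA") {
  m <- matrix(c(5, 0, 3, 0,
                0, 2, 3, 1,
                1, 1, 0, 4), nrow = 4,
              dimnames = list(c("t1", "t2", "t3", "t4"), c("s1", "s2", "s3")))
  feature_table(m, dataset)
}

toy_metadata <- function(ids, group = "wild") {
  data.frame(sample_id = ids, group = group, farm_id = NA, x_km = NA_real_,
             y_km = NA_real_, sex = "F", weight = NA_real_,
             body_length = NA_real_, tail_length = NA_real_, pregnancy = FALSE,
             conc_dna = 1, conc_rna = 1, is_negative_control = FALSE,
             stringsAsFactors = FALSE)
}

# independent weighted-moment oracle for the group-equalized statistic
rg_oracle <- function(x, labels, target) {
  w <- 1 / table(labels)[as.character(labels)]
  t <- as.numeric(labels %in% target)
  W <- sum(w)
  mx <- sum(w * x) / W; mt <- sum(w * t) / W
  num <- sum(w * (x - mx) * (t - mt))
  num / sqrt(sum(w * (x - mx)^2) * sum(w * (t - mt)^2))
}

# exhaustive global-alignment oracle under the package's gap convention:
# gap of length k scores open + (k-1) * extend. Recursively enumerates all
# alignments of two short sequences and returns the best score.
align_enum_oracle <- function(a, b, match = 1, mismatch = -1,
                              open = -2, extend = -1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    # prev: "m" aligned column, "ga" gap in a (b consumed), "gb" gap in b
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (j <= length(b))
      best <- max(best, (if (prev == "ga") extend else open) + rec(i, j + 1, "ga"))
    if (i <= length(a))
      best <- max(best, (if (prev == "gb") extend else open) + rec(i + 1, j, "gb"))
    best
  }
  rec(1, 1, "m")
}

mutate_seq <- function(s, n_mut, seed) {
  set.seed(seed)
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), n_mut)
  v[pos] <- vapply(v[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(v, collapse = "")
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
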