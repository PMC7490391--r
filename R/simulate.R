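# Synthetic study-bundle generator. The generator plants, with known
# quantitative structure, everything the downstream pipeline is supposed to
# detect: reagent contaminants whose relative frequency scales as
# 1/concentration, a per-group core community plus group-specific taxa, DNA-
# only "carry-over" taxa silent at the RNA level, a wild-only rare
# biosphere, spatially autocorrelated farm effects producing distance decay,
# and spatially clustered host genetics.
#
# Composition model: per sample, expected log relative abundances =
# group profile + farm effect + individual noise (logistic-normal), counts
# multinomial at the sample's sequencing depth. Farm effects are drawn per
# taxon across farms with covariance sigma2_farm * exp(-d_ij / rho).

.derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

#' Simulation configuration
#'
#' The `"desk"` preset shrinks the study design (fewer mice, farms and taxa)
#' so the full pipeline runs in minutes; the `"paper"` preset reproduces the
#' study scale (wild n=203 over 34 farms; laboratory groups 225/29/13).
#'
#' @param preset `"desk"` (default) or `"paper"`.
#' @param ... Named overrides for any configuration field (see Details).
#' @details Fields: `n_per_group` (named sample counts), `n_farms`,
#'   `n_lab_units` (cages per laboratory group),
#'   `target_mean_site_distance_km` (10) and `site_distance_sd_km` (6),
#'   taxon pool sizes `n_shared_core`, `n_group_specific` (named),
#'   `n_carry_over`, `n_transient`, `n_rare_tail`, `rare_tail_shape`
#'   (sd of log tail abundance), spatial decay `rho_km` and `sigma2_farm`,
#'   `sigma_indiv`, `activity_sdlog` (spread of RNA activity multipliers),
#'   contaminant settings `n_contaminants`, `ambient_meanlog`,
#'   `ambient_sdlog`, concentration distribution `conc_meanlog`,
#'   `conc_sdlog`, depth distribution `depth_meanlog`, `depth_sdlog`,
#'   `min_depth`, controls `n_controls`, `control_depth_meanlog`,
#'   `control_depth_sdlog`, `cross_talk`, genetics `n_loci`, `n_clusters`,
#'   `dloop_length`, `genetics_missing_rate`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n_per_group = c(wild = 60, `HL-Lab` = 20, `MPI-Lab` = 10, `C57BL/6J` = 8),
    n_farms = 12,
    n_lab_units = c(`HL-Lab` = 5, `MPI-Lab` = 3, `C57BL/6J` = 2),
    target_mean_site_distance_km = 10,
    site_distance_sd_km = 6,
    n_shared_core = 25,
    n_group_specific = c(wild = 30, `HL-Lab` = 12, `MPI-Lab` = 10, `C57BL/6J` = 8),
    n_carry_over = 8,
    n_transient = 50,
    n_rare_tail = 200,
    rare_tail_shape = 1,
    rho_km = 5,
    sigma2_farm = 0.64,
    sigma_indiv = 0.5,
    activity_sdlog = 0.5,
    n_contaminants = 20,
    ambient_meanlog = log(0.02),
    ambient_sdlog = 0.5,
    conc_meanlog = log(5),
    conc_sdlog = 0.8,
    control_conc_meanlog = log(0.2),
    control_conc_sdlog = 0.4,
    depth_meanlog = log(9000),
    depth_sdlog = 0.25,
    min_depth = 5000,
    n_controls = 4,
    control_depth_meanlog = log(500),
    control_depth_sdlog = 1,
    cross_talk = 0.02,
    n_loci = 18,
    n_clusters = 3,
    dloop_length = 300,
    genetics_missing_rate = 0.03)
  if (preset == "paper") {
    cfg$n_per_group <- c(wild = 203, `HL-Lab` = 225, `MPI-Lab` = 29, `C57BL/6J` = 13)
    cfg$n_farms <- 34
    cfg$n_lab_units <- c(`HL-Lab` = 20, `MPI-Lab` = 6, `C57BL/6J` = 3)
    cfg$n_shared_core <- 60
    cfg$n_group_specific <- c(wild = 90, `HL-Lab` = 30, `MPI-Lab` = 25, `C57BL/6J` = 20)
    cfg$n_rare_tail <- 2000
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ","))
  cfg[names(dots)] <- dots
  stopifnot(all(cfg$n_per_group >= 0), cfg$rho_km > 0, cfg$sigma2_farm >= 0,
            cfg$n_farms >= 2, cfg$activity_sdlog >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate spatially distributed sampling sites (farms)
#'
#' Sites are drawn uniformly in a square scaled so the expected mean
#' pairwise distance matches the target; draws are rejected and resampled
#' until the realized mean is within 15% of the target.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return data.frame with columns `farm_id`, `x_km`, `y_km`.
#' @export
simulate_sites <- function(config, seed) {
  stopifnot(config$n_farms >= 2)
  set.seed(as.integer(seed))
  target <- config$target_mean_site_distance_km
  side <- target / 0.5214  # E[dist] of two uniform points in unit square = 0.5214
  for (i in 1:500) {
    x <- stats::runif(config$n_farms, 0, side)
    y <- stats::runif(config$n_farms, 0, side)
    mpd <- mean(stats::dist(cbind(x, y)))
    if (abs(mpd - target) <= 0.15 * target)
      return(data.frame(farm_id = sprintf("farm%02d", seq_len(config$n_farms)),
                        x_km = x, y_km = y, stringsAsFactors = FALSE))
  }
  stop("parameter error: could not reach target mean site distance after 500 tries")
}

.taxon_universe <- function(config) {
  groups <- names(config$n_per_group)
  ids <- list(
    shared = sprintf("core%03d", seq_len(config$n_shared_core)),
    specific = lapply(stats::setNames(groups, groups), function(g)
      if (config$n_group_specific[[g]] > 0)
        sprintf("spec_%s_%03d", gsub("[^A-Za-z0-9]", "", g),
                seq_len(config$n_group_specific[[g]])) else character()),
    carry = if (config$n_carry_over > 0) sprintf("carry%03d", seq_len(config$n_carry_over)) else character(),
    transient = if (config$n_transient > 0) sprintf("trans%03d", seq_len(config$n_transient)) else character(),
    rare = if (config$n_rare_tail > 0) sprintf("rare%04d", seq_len(config$n_rare_tail)) else character(),
    contam = if (config$n_contaminants > 0) sprintf("contam%03d", seq_len(config$n_contaminants)) else character())
  ids$all <- c(ids$shared, unlist(ids$specific, use.names = FALSE), ids$carry,
               ids$transient, ids$rare, ids$contam)
  ids
}

#' Simulate paired DNA/RNA communities, metadata, taxonomy and tree
#'
#' @param config A [sim_config()].
#' @param sites Output of [simulate_sites()].
#' @param seed Integer seed.
#' @return List with elements `dna`, `rna` ([feature_table()]), `metadata`,
#'   `taxonomy`, `tree` (`phylo`), `truth`. Contaminant features exist as
#'   all-zero rows until [simulate_contamination()] fills them, so the tree
#'   and taxonomy cover the full feature universe. Expected per-sample
#'   compositions are attached to `truth` as attributes `expected_dna` /
#'   `expected_rna` (not serialized).
#' @export
simulate_communities <- function(config, sites, seed) {
  seeds <- .derive_seeds(seed, 6)
  groups <- names(config$n_per_group)
  ids <- .taxon_universe(config)
  taxa <- ids$all
  ntax <- length(taxa)

  set.seed(seeds[1])
  # group x taxon baseline log weights
  base <- matrix(-20, length(groups), ntax, dimnames = list(groups, taxa))
  base[, ids$shared] <- rep(stats::rnorm(length(ids$shared), 2, 0.7),
                            each = length(groups))
  for (g in groups) {
    sp <- ids$specific[[g]]
    if (length(sp)) {
      base[, sp] <- -12
      base[g, sp] <- stats::rnorm(length(sp), 2, 0.7)
    }
  }
  if (length(ids$carry))
    base[, ids$carry] <- rep(stats::rnorm(length(ids$carry), 1.5, 0.5),
                             each = length(groups))
  if (length(ids$transient))
    base[, ids$transient] <- rep(stats::rnorm(length(ids$transient), -0.4, 0.3),
                                 each = length(groups))
  if (length(ids$rare)) {
    base[, ids$rare] <- -20
    base["wild", ids$rare] <- stats::rnorm(length(ids$rare), -7.5,
                                           config$rare_tail_shape)
  }
  base[, ids$contam] <- -Inf  # filled by simulate_contamination

  # activity multipliers (RNA = DNA composition x multiplier, renormalized)
  mult <- stats::setNames(stats::rlnorm(ntax, 0, config$activity_sdlog), taxa)
  mult[ids$carry] <- 0

  # units: wild farms (spatially correlated effects) + lab cages (iid)
  set.seed(seeds[2])
  dmat <- as.matrix(stats::dist(sites[, c("x_km", "y_km")]))
  Sig <- config$sigma2_farm * exp(-dmat / config$rho_km)
  L <- if (config$sigma2_farm > 0) chol(Sig + diag(1e-8, nrow(Sig))) else NULL
  farm_eff <- matrix(0, nrow(sites), ntax,
                     dimnames = list(sites$farm_id, taxa))
  if (!is.null(L))
    farm_eff[] <- t(L) %*% matrix(stats::rnorm(nrow(sites) * ntax), nrow(sites))
  lab_units <- list()
  for (g in setdiff(groups, "wild")) {
    nu <- if (g %in% names(config$n_lab_units)) config$n_lab_units[[g]] else 1
    u <- sprintf("%s_cage%d", gsub("[^A-Za-z0-9]", "", g), seq_len(nu))
    lab_units[[g]] <- u
    ue <- matrix(stats::rnorm(length(u) * ntax, 0, sqrt(config$sigma2_farm)),
                 length(u), ntax, dimnames = list(u, taxa))
    farm_eff <- rbind(farm_eff, ue)
  }

  # metadata
  set.seed(seeds[3])
  md <- list()
  prefix <- c(wild = "W", `HL-Lab` = "HL", `MPI-Lab` = "MP", `C57BL/6J` = "B6")
  for (g in groups) {
    n <- config$n_per_group[[g]]
    if (n == 0) next
    pg <- if (g %in% names(prefix)) prefix[[g]] else substr(gsub("[^A-Za-z0-9]", "", g), 1, 2)
    sid <- sprintf("%s%03d", pg, seq_len(n))
    if (g == "wild") {
      unit <- sites$farm_id[rep_len(seq_len(nrow(sites)), n)]
      xy <- sites[match(unit, sites$farm_id), c("x_km", "y_km")]
    } else {
      unit <- lab_units[[g]][rep_len(seq_along(lab_units[[g]]), n)]
      xy <- data.frame(x_km = NA_real_, y_km = NA_real_)[rep(1, n), ]
    }
    sex <- sample(c("F", "M"), n, replace = TRUE)
    md[[g]] <- data.frame(
      sample_id = sid, group = g, farm_id = unit,
      x_km = xy$x_km, y_km = xy$y_km, sex = sex,
      weight = round(stats::rnorm(n, if (g == "wild") 16 else 22, 3), 1),
      body_length = round(stats::rnorm(n, 80, 6), 1),
      tail_length = round(stats::rnorm(n, 75, 7), 1),
      pregnancy = sex == "F" & stats::runif(n) < (if (g == "wild") 0.15 else 0),
      conc_dna = round(stats::rlnorm(n, config$conc_meanlog, config$conc_sdlog), 4),
      conc_rna = round(stats::rlnorm(n, config$conc_meanlog, config$conc_sdlog), 4),
      is_negative_control = FALSE, stringsAsFactors = FALSE)
  }
  md <- do.call(rbind, md)
  rownames(md) <- NULL

  # per-sample expected compositions and counts
  set.seed(seeds[4])
  nsamp <- nrow(md)
  depth_dna <- pmax(round(stats::rlnorm(nsamp, config$depth_meanlog, config$depth_sdlog)),
                    config$min_depth)
  depth_rna <- pmax(round(stats::rlnorm(nsamp, config$depth_meanlog, config$depth_sdlog)),
                    config$min_depth)
  exp_dna <- exp_rna <- matrix(0, ntax, nsamp, dimnames = list(taxa, md$sample_id))
  cnt_dna <- cnt_rna <- matrix(0L, ntax, nsamp, dimnames = list(taxa, md$sample_id))
  for (i in seq_len(nsamp)) {
    lw <- base[md$group[i], ] + farm_eff[md$farm_id[i], ] +
      stats::rnorm(ntax, 0, config$sigma_indiv)
    w <- exp(lw - max(lw[is.finite(lw)]))
    w[!is.finite(w)] <- 0
    p <- w / sum(w)
    exp_dna[, i] <- p
    pr <- p * mult
    pr <- if (sum(pr) > 0) pr / sum(pr) else p
    exp_rna[, i] <- pr
    cnt_dna[, i] <- stats::rmultinom(1, depth_dna[i], p)
    cnt_rna[, i] <- stats::rmultinom(1, depth_rna[i], pr)
  }

  # taxonomy: planted categories get their own genus; rare tail is genus-
  # unclassified (classified at family) to exercise unclassified pooling
  phyla <- c("Firmicutes", "Actinobacteria", "Proteobacteria", "Bacteroidetes")
  tax <- data.frame(feature_id = taxa,
                    phylum = phyla[(seq_len(ntax) - 1L) %% 4L + 1L],
                    stringsAsFactors = FALSE)
  tax$class <- paste0("c_", tax$phylum)
  tax$order <- paste0("o_", tax$phylum)
  tax$family <- paste0("f_", sub("[0-9]+$", "", taxa))
  tax$genus <- paste0("g_", taxa)
  tax$genus[taxa %in% ids$rare] <- "Unclassified"

  set.seed(seeds[5])
  tree <- ape::rtree(ntax, rooted = TRUE, tip.label = sample(taxa),
                     br = function(n) stats::rexp(n, 10))

  truth_taxa <- rbind(
    data.frame(taxon = ids$shared, category = "shared_core", group = NA_character_),
    do.call(rbind, lapply(groups, function(g)
      if (length(ids$specific[[g]]))
        data.frame(taxon = ids$specific[[g]], category = "specific", group = g))),
    if (length(ids$carry)) data.frame(taxon = ids$carry, category = "carry_over", group = NA_character_),
    if (length(ids$transient)) data.frame(taxon = ids$transient, category = "transient", group = NA_character_),
    if (length(ids$rare)) data.frame(taxon = ids$rare, category = "rare", group = NA_character_))
  truth <- list(
    contaminants = ids$contam,
    taxa = truth_taxa,
    params = data.frame(key = c("rho_km", "sigma2_farm", "sigma_indiv"),
                        value = c(config$rho_km, config$sigma2_farm,
                                  config$sigma_indiv)))
  attr(truth, "expected_dna") <- exp_dna
  attr(truth, "expected_rna") <- exp_rna
  attr(truth, "activity_multipliers") <- mult

  list(dna = feature_table(cnt_dna, "DNA"),
       rna = feature_table(cnt_rna, "RNA"),
       metadata = md, taxonomy = tax, tree = tree, truth = truth)
}

#' Plant reagent contamination and negative controls
#'
#' Each contaminant carries a fixed ambient load `a_j` (relative-frequency
#' units at concentration 1 ng/ul); in a sample with concentration `c` its
#' expected relative frequency is `a_j / c`, so expected added reads are
#' Poisson with mean `depth * a_j / c` — frequency inversely proportional
#' to biomass. Negative controls contain contaminants plus a small
#' cross-talk fraction of the mean real community at low total depth.
#'
#' @param com Output of [simulate_communities()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return `com` with contaminant counts added, control samples appended to
#'   both tables and the metadata, and `truth$contaminants` set.
#' @export
simulate_contamination <- function(com, config, seed) {
  if (config$n_contaminants == 0) return(com)
  set.seed(as.integer(seed))
  ids <- .taxon_universe(config)
  load <- stats::setNames(
    stats::rlnorm(config$n_contaminants, config$ambient_meanlog, config$ambient_sdlog),
    ids$contam)
  md <- com$metadata
  for (ds in c("dna", "rna")) {
    ft <- com[[ds]]
    conc <- md[[paste0("conc_", ds)]][match(ft$sample_ids, md$sample_id)]
    depth <- colSums(ft$counts)
    lam <- outer(load, 1 / conc) * rep(depth, each = length(load))
    add <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
    ft$counts[ids$contam, ] <- ft$counts[ids$contam, ] + add
    # negative controls: ambient contaminants + trace cross-talk
    nctl <- config$n_controls
    if (nctl > 0) {
      cid <- sprintf("NC%s%d", toupper(substr(ds, 1, 1)), seq_len(nctl))
      mean_real <- rowMeans(sweep(ft$counts, 2, pmax(colSums(ft$counts), 1), "/"))
      w <- stats::setNames(numeric(nrow(ft$counts)), rownames(ft$counts))
      w[ids$contam] <- load
      w <- w / sum(w) * (1 - config$cross_talk) + config$cross_talk * mean_real
      cdepth <- round(stats::rlnorm(nctl, config$control_depth_meanlog,
                                    config$control_depth_sdlog))
      ctl <- vapply(cdepth, function(d) stats::rmultinom(1, d, w)[, 1],
                    numeric(nrow(ft$counts)))
      colnames(ctl) <- cid
      ft$counts <- cbind(ft$counts, ctl)
      ft$sample_ids <- colnames(ft$counts)
      cmd <- md[rep(1, nctl), ]
      cmd[] <- NA
      cmd$sample_id <- cid
      cmd$group <- "control"
      cmd$is_negative_control <- TRUE
      cmd$pregnancy <- FALSE
      cc <- round(stats::rlnorm(nctl, config$control_conc_meanlog,
                                config$control_conc_sdlog), 4)
      cmd$conc_dna <- cc
      cmd$conc_rna <- cc
      md <- rbind(md, cmd)
    }
    com[[ds]] <- ft
  }
  rownames(md) <- NULL
  com$metadata <- md
  com$truth$contaminants <- ids$contam
  com
}

#' Simulate microsatellite genotypes and D-loop haplotypes
#'
#' Wild individuals are assigned to genetic clusters by spatial k-means over
#' their farms, so genetic distance correlates with geographic distance by
#' construction. Microsatellite allele frequencies are cluster-specific;
#' D-loop haplotypes arise by mutating a root sequence along a haplogroup
#' star tree with individual private mutations.
#'
#' @param config A [sim_config()].
#' @param sites Output of [simulate_sites()].
#' @param metadata Metadata containing the wild individuals.
#' @param seed Integer seed.
#' @return List with `genotypes` ([genotype_table()]), `dloop`
#'   ([sequence_set()], aligned), `clusters` (data.frame individual/cluster).
#' @export
simulate_genetics <- function(config, sites, metadata, seed) {
  set.seed(as.integer(seed))
  wild <- metadata[metadata$group == "wild" & !(metadata$is_negative_control %in% TRUE), ]
  if (nrow(wild) == 0) stop("no wild individuals in metadata")
  k <- min(config$n_clusters, nrow(sites))
  km <- stats::kmeans(sites[, c("x_km", "y_km")], centers = k, nstart = 10)
  farm_cluster <- stats::setNames(km$cluster, sites$farm_id)
  cl <- farm_cluster[wild$farm_id]

  nl <- config$n_loci
  loci <- sprintf("locus%02d", seq_len(nl))
  a1 <- a2 <- matrix(NA_integer_, nrow(wild), nl,
                     dimnames = list(wild$sample_id, loci))
  for (l in seq_len(nl)) {
    nall <- 4 + (l - 1) %% 4
    sizes <- 100 + 2 * seq_len(nall) + 10 * l
    freqs <- lapply(seq_len(k), function(cc) {
      f <- stats::rgamma(nall, 0.5)
      f / sum(f)
    })
    for (i in seq_len(nrow(wild))) {
      f <- freqs[[cl[i]]]
      a <- sort(sample(sizes, 2, replace = TRUE, prob = f))
      a1[i, l] <- a[1]; a2[i, l] <- a[2]
    }
  }
  miss <- matrix(stats::runif(length(a1)) < config$genetics_missing_rate,
                 nrow(a1), ncol(a1))
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_

  alph <- c("A", "C", "G", "T")
  root <- sample(alph, config$dloop_length, replace = TRUE)
  hap <- lapply(seq_len(k), function(cc) {
    s <- root
    pos <- sample(config$dloop_length, 10)
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(alph, b), 1), "")
    s
  })
  seqs <- vapply(seq_len(nrow(wild)), function(i) {
    s <- hap[[cl[i]]]
    pos <- sample(config$dloop_length, 2)
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(alph, b), 1), "")
    paste(s, collapse = "")
  }, "")
  names(seqs) <- wild$sample_id

  list(genotypes = genotype_table(a1, a2),
       dloop = sequence_set(seqs, aligned = TRUE),
       clusters = data.frame(individual_id = wild$sample_id,
                             cluster = unname(cl), stringsAsFactors = FALSE))
}

#' Simulate a complete study bundle
#'
#' Orchestrates [simulate_sites()], [simulate_communities()],
#' [simulate_contamination()] and [simulate_genetics()] into a validated
#' [study_bundle()] with truth labels. Identical config and seed give
#' byte-identical bundles on disk.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; every stage derives its own sub-seed from it.
#' @param genetics Include genotypes and D-loop sequences (default TRUE).
#' @return A [study_bundle()].
#' @export
simulate_bundle <- function(config = sim_config(), seed = 1, genetics = TRUE) {
  seeds <- .derive_seeds(seed, 4)
  sites <- simulate_sites(config, seeds[1])
  com <- simulate_communities(config, sites, seeds[2])
  com <- simulate_contamination(com, config, seeds[3])
  truth <- com$truth
  gen <- NULL
  if (genetics && "wild" %in% com$metadata$group) {
    gen <- simulate_genetics(config, sites, com$metadata, seeds[4])
    truth$clusters <- gen$clusters
  }
  study_bundle(dna = com$dna, rna = com$rna, metadata = com$metadata,
               taxonomy = com$taxonomy, tree = com$tree,
               dloop = if (!is.null(gen)) gen$dloop,
               genotypes = if (!is.null(gen)) gen$genotypes,
               truth = truth)
}
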