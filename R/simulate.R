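# Seeded synthetic-data generators with planted ground truth. Every generator
# is a pure function of its parameters and seed.

#' Simulate a pure-birth phylogeny
#'
#' Yule (pure-birth) topology with independent exponential branch lengths
#' (mean 1, in arbitrary tree units). A stand-in for an estimated 16S
#' phylogeny at desk scale.
#'
#' @param n_tips Number of tips (at least 2).
#' @param seed Integer seed.
#' @return An [ape::phylo] object with tip labels `t1..tn`.
#' @export
simulate_tree <- function(n_tips, seed = 1) {
  if (n_tips < 2) stop("`n_tips` must be at least 2", call. = FALSE)
  with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    tree$edge.length <- rexp(nrow(tree$edge), rate = 1)
    tree
  })
}

# Edge indices of the subtree rooted at `node` (all edges below it).
subtree_edges <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  internal_below <- descendant_internal(tree, node)
  parents <- c(node, internal_below[internal_below > n_tip])
  which(tree$edge[, 1] %in% parents)
}

descendant_internal <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  out <- integer(0)
  n_tip <- length(tree$tip.label)
  for (k in kids) {
    out <- c(out, k)
    if (k > n_tip) out <- c(out, descendant_internal(tree, k))
  }
  out
}

#' Plant core clades into a simulated phylogeny
#'
#' Selects `n_core` disjoint clades of roughly `clade_size` tips, labels all
#' their tips as host-derived with occurrence in every culture, and collapses
#' every branch inside each clade to length zero (complete homology). All
#' other tips are labelled host with probability `host_fraction_background`
#' (with sparse culture sets of 1-3 cultures) and environment otherwise.
#'
#' The defaults plant a strong, detectable effect: with clades of 12 tips and
#' a background host fraction of 0.3 on a 500-tip tree, the one-sided binomial
#' enrichment p-value of a planted clade survives a Bonferroni correction over
#' all internal nodes with a wide margin.
#'
#' @param tree An [ape::phylo] object (will be modified: planted clades get
#'   zero-length internal branches).
#' @param n_core Number of clades to plant (default 3).
#' @param clade_size Target clade size in tips (default 12; clades of up to
#'   twice this size are eligible).
#' @param n_cultures Number of cultures in the universe (default 12).
#' @param host_fraction_background Probability that a non-planted tip is
#'   host-class (default 0.3).
#' @param seed Integer seed.
#' @return A list with elements `tree` (modified), `annotations`
#'   ([tip_annotations()]), and `ground_truth` (planted node ids, tip sets,
#'   culture universe).
#' @export
plant_core_clades <- function(tree, n_core = 3, clade_size = 12, n_cultures = 12,
                              host_fraction_background = 0.3, seed = 1) {
  tree <- validate_tree(tree)
  n_tip <- length(tree$tip.label)
  if (n_core * clade_size > n_tip / 2) {
    stop("infeasible: n_core * clade_size exceeds half the tips", call. = FALSE)
  }
  stopifnot(host_fraction_background >= 0, host_fraction_background <= 1)
  with_seed(seed, {
    sets <- clade_tip_sets(tree)
    root <- n_tip + 1L
    candidates <- which(vapply(sets, length, integer(1)) >= clade_size &
                          vapply(sets, length, integer(1)) <= 2 * clade_size)
    candidates <- setdiff(candidates[candidates > n_tip], root)
    candidates <- sample(candidates)
    chosen <- integer(0)
    used_tips <- integer(0)
    for (nd in candidates) {
      if (length(chosen) == n_core) break
      if (!any(sets[[nd]] %in% used_tips)) {
        chosen <- c(chosen, nd)
        used_tips <- c(used_tips, sets[[nd]])
      }
    }
    if (length(chosen) < n_core) {
      stop("could not find enough disjoint clades of the requested size", call. = FALSE)
    }
    for (nd in chosen) tree$edge.length[subtree_edges(tree, nd)] <- 0

    cultures_all <- paste0("C", seq_len(n_cultures))
    planted_tips <- tree$tip.label[used_tips]
    source_class <- rep("environment", n_tip)
    names(source_class) <- tree$tip.label
    source_class[planted_tips] <- "host"
    background <- setdiff(tree$tip.label, planted_tips)
    bg_host <- background[runif(length(background)) < host_fraction_background]
    source_class[bg_host] <- "host"
    cultures <- rep(list(character(0)), n_tip)
    names(cultures) <- tree$tip.label
    for (tp in planted_tips) cultures[[tp]] <- cultures_all
    for (tp in bg_host) cultures[[tp]] <- sample(cultures_all, sample(1:3, 1))

    ann <- tip_annotations(tree$tip.label, unname(source_class), unname(cultures))
    gt <- list(
      core_nodes = chosen,
      core_tips = lapply(chosen, function(nd) tree$tip.label[sets[[nd]]]),
      cultures = cultures_all,
      host_fraction_background = host_fraction_background
    )
    list(tree = tree, annotations = ann, ground_truth = gt)
  })
}

#' Simulate cluster occurrence frequencies from a power law
#'
#' Each cluster's occurrence frequency f is drawn from
#' \eqn{P(f) \propto f^{-a}} on \eqn{f \in \{1, ..., f_{max}\}}, and the
#' cluster is assigned that many cultures uniformly without replacement.
#'
#' @param n_clusters Number of clusters.
#' @param exponent_a True power-law exponent (> 1).
#' @param f_max Number of cultures in the universe (>= 2).
#' @param seed Integer seed.
#' @return A list with `cluster_cultures` (named list: cluster -> culture ids)
#'   and `ground_truth` (the exponent and parameters).
#' @export
simulate_occurrences <- function(n_clusters, exponent_a = 3.6, f_max = 12, seed = 1) {
  if (exponent_a <= 1) stop("`exponent_a` must exceed 1", call. = FALSE)
  if (f_max < 2) stop("`f_max` must be at least 2", call. = FALSE)
  stopifnot(n_clusters >= 1)
  with_seed(seed, {
    f_support <- seq_len(f_max)
    prob <- f_support^(-exponent_a)
    f <- sample(f_support, n_clusters, replace = TRUE, prob = prob)
    cultures_all <- paste0("C", f_support)
    cc <- lapply(f, function(fi) sample(cultures_all, fi))
    names(cc) <- paste0("cluster", seq_len(n_clusters))
    list(
      cluster_cultures = cc,
      ground_truth = list(exponent_a = exponent_a, f_max = f_max,
                          n_clusters = n_clusters)
    )
  })
}

#' Simulate a compositional survival dataset with a planted nonlinear signal
#'
#' Feature compositions follow a log-normal scheme (per-feature baseline mean
#' plus sample-level noise, closed to sum 1). Survival is a nonlinear function
#' of the relative abundances of `n_signal` designated features — a sum of
#' saturating (Monod-type) terms plus one pairwise interaction — rescaled to a
#' realistic range (roughly 0.3 to 0.8), with Gaussian noise added and the
#' result clipped to \[0, 1\]. Optionally a fraction of samples enters a
#' collapse regime: a designated pathogen-like feature is forced above 50%
#' relative abundance and survival drops to near zero.
#'
#' @param n_samples Number of samples (tanks).
#' @param n_features Number of features (ASVs).
#' @param n_signal Number of signal features (< n_features).
#' @param noise_sd Gaussian noise on survival, in survival units (default 0.05).
#' @param collapse_fraction Fraction of samples in the collapse regime
#'   (default 0).
#' @param seed Integer seed.
#' @return A list with `table` (relative `abundance_table` whose metadata has
#'   `survival_rate`) and `ground_truth` (signal feature ids, signal function
#'   id, pathogen feature id, collapsed sample ids).
#' @export
simulate_survival_data <- function(n_samples = 130, n_features = 100, n_signal = 5,
                                   noise_sd = 0.05, collapse_fraction = 0, seed = 1) {
  stopifnot(n_samples >= 3, n_features >= 2)
  if (n_signal >= n_features) stop("`n_signal` must be below `n_features`", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  stopifnot(collapse_fraction >= 0, collapse_fraction <= 1)
  with_seed(seed, {
    feature_ids <- sprintf("ASV%03d", seq_len(n_features))
    sample_ids <- sprintf("tank%03d", seq_len(n_samples))
    signal_ids <- feature_ids[seq_len(max(n_signal, 0))]
    pathogen_id <- feature_ids[n_signal + 1]

    mu <- rnorm(n_features, 0, 1.2)
    if (n_signal > 0) mu[seq_len(n_signal)] <- mu[seq_len(n_signal)] + 1
    w <- exp(matrix(rnorm(n_samples * n_features, 0, 1), n_samples, n_features,
                    byrow = FALSE) + matrix(mu, n_samples, n_features, byrow = TRUE))
    dimnames(w) <- list(sample_ids, feature_ids)
    rel <- w / rowSums(w)

    if (n_signal > 0) {
      s <- rel[, signal_ids, drop = FALSE]
      k <- apply(s, 2, stats::median)
      k[k == 0] <- 1e-6
      sat <- sweep(s, 2, k, function(a, b) a / (a + b))
      b <- rep(c(1, -1), length.out = n_signal)
      raw <- as.numeric(sat %*% b)
      if (n_signal >= 2) raw <- raw + 1.5 * sat[, 1] * sat[, 2]
      raw_sd <- sd(raw)
      if (raw_sd == 0) raw_sd <- 1
      survival <- 0.55 + 0.12 * (raw - mean(raw)) / raw_sd
    } else {
      survival <- rep(0.55, n_samples)
    }
    survival <- survival + rnorm(n_samples, 0, noise_sd)
    survival <- pmin(pmax(survival, 0), 1)

    collapsed <- character(0)
    n_collapse <- round(collapse_fraction * n_samples)
    if (n_collapse > 0) {
      idx <- sample.int(n_samples, n_collapse)
      collapsed <- sample_ids[idx]
      for (i in idx) {
        other <- sum(w[i, -match(pathogen_id, feature_ids)])
        w[i, pathogen_id] <- 1.5 * other
        survival[i] <- runif(1, 0, 0.03)
      }
      rel <- w / rowSums(w)
    }

    md <- data.frame(sample_id = sample_ids, site = "hatchery",
                     survival_rate = survival, stringsAsFactors = FALSE)
    tab <- abundance_table(rel, md, relative = TRUE)
    gt <- list(
      signal_features = if (n_signal > 0) signal_ids else character(0),
      signal_function = "saturating_sum_plus_interaction",
      pathogen_feature = pathogen_id,
      collapsed_samples = collapsed,
      noise_sd = noise_sd
    )
    list(table = tab, ground_truth = gt)
  })
}

#' Simulate a pan-genome matrix with planted gene sweeps
#'
#' Builds a genome-by-gene-family presence/absence matrix over one or more
#' clade groups of focal genera. Swept families are present in every focal
#' genome of their group and rare (realised prevalence strictly below 0.10) in
#' that group's congeneric background; decoy families occur independently in
#' every genome at rates drawn from `decoy_bg_prevalence_range`. Any decoy
#' that would accidentally satisfy the sweep criterion has one focal entry
#' cleared, so the planted set is exactly the ground truth.
#'
#' @param genera_spec Data frame with columns `genus`, `clade_group`,
#'   `n_focal`, `n_background`; the default emulates two clade groups with 5
#'   and 4 focal isolates (one per genus) and 12 congeneric background genomes
#'   per genus.
#' @param n_families Total number of gene families (default 2000).
#' @param n_swept Number of planted sweep families (default 8), assigned
#'   round-robin to the clade groups.
#' @param decoy_bg_prevalence_range Range of decoy occurrence rates
#'   (default c(0.2, 0.9)).
#' @param seed Integer seed.
#' @return A list with `matrix` (a [gene_pa_matrix()]) and `ground_truth`
#'   (swept family ids and their clade groups).
#' @export
simulate_gene_matrix <- function(genera_spec = NULL, n_families = 2000, n_swept = 8,
                                 decoy_bg_prevalence_range = c(0.2, 0.9), seed = 1) {
  if (is.null(genera_spec)) {
    genera_spec <- data.frame(
      genus = paste0("genus", 1:9),
      clade_group = rep(c("Rhodobacterales", "Flavobacteriales"), c(5, 4)),
      n_focal = 1,
      n_background = 12,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("genus", "clade_group", "n_focal", "n_background") %in% names(genera_spec)))
  if (n_swept > n_families) stop("`n_swept` exceeds `n_families`", call. = FALSE)
  rng <- decoy_bg_prevalence_range
  stopifnot(length(rng) == 2, rng[1] >= 0, rng[2] <= 1, rng[1] <= rng[2])

  with_seed(seed, {
    md <- do.call(rbind, lapply(seq_len(nrow(genera_spec)), function(i) {
      g <- genera_spec[i, ]
      data.frame(
        genome_id = c(sprintf("%s_focal%d", g$genus, seq_len(g$n_focal)),
                      sprintf("%s_bg%02d", g$genus, seq_len(g$n_background))),
        genus = g$genus,
        clade_group = g$clade_group,
        focal = rep(c(TRUE, FALSE), c(g$n_focal, g$n_background)),
        stringsAsFactors = FALSE
      )
    }))
    rownames(md) <- md$genome_id
    n_genomes <- nrow(md)
    fam_ids <- sprintf("fam%04d", seq_len(n_families))
    v <- matrix(0, n_genomes, n_families, dimnames = list(md$genome_id, fam_ids))

    groups <- unique(md$clade_group[md$focal])
    swept_ids <- fam_ids[seq_len(n_swept)]
    swept_groups <- rep(groups, length.out = n_swept)
    for (j in seq_len(n_swept)) {
      grp <- swept_groups[j]
      focal_ids <- md$genome_id[md$focal & md$clade_group == grp]
      bg_ids <- md$genome_id[!md$focal & md$clade_group == grp]
      v[focal_ids, swept_ids[j]] <- 1
      max_carriers <- ceiling(0.10 * length(bg_ids)) - 1
      n_carriers <- sample.int(max_carriers + 1, 1) - 1
      if (n_carriers > 0) v[sample(bg_ids, n_carriers), swept_ids[j]] <- 1
    }

    decoy_ids <- setdiff(fam_ids, swept_ids)
    rates <- runif(length(decoy_ids), rng[1], rng[2])
    for (j in seq_along(decoy_ids)) {
      v[, decoy_ids[j]] <- rbinom(n_genomes, 1, rates[j])
    }
    # Guard: no decoy may satisfy the sweep criterion in any clade group.
    for (grp in groups) {
      focal_ids <- md$genome_id[md$focal & md$clade_group == grp]
      bg_ids <- md$genome_id[!md$focal & md$clade_group == grp]
      fp <- colMeans(v[focal_ids, decoy_ids, drop = FALSE]) == 1
      bp <- colMeans(v[bg_ids, decoy_ids, drop = FALSE]) < 0.10
      for (fam in decoy_ids[fp & bp]) v[focal_ids[1], fam] <- 0
    }

    mat <- gene_pa_matrix(v, md)
    gt <- list(swept_families = swept_ids,
               swept_groups = swept_groups,
               n_families = n_families)
    list(matrix = mat, ground_truth = gt)
  })
}

#' Simulate larval communities shifting between two sources across stages
#'
#' Generates a seawater-like and a feed-like source profile over a shared
#' feature universe (partially overlapping supports), then builds larval
#' samples at each developmental stage as the mixture
#' \eqn{w(s) \cdot feed + (1 - w(s)) \cdot seawater} with multiplicative
#' log-normal noise and closure to relative abundances.
#'
#' @param n_stages Number of developmental stages.
#' @param n_features Size of the feature universe (default 80).
#' @param mixing_schedule Feed weight per stage, each in \[0, 1\]
#'   (default linear 0 to 1).
#' @param n_replicates Larval samples per stage (default 3).
#' @param noise_sd Log-scale noise on larval compositions (default 0.3).
#' @param seed Integer seed.
#' @return A list with `larvae` (relative `abundance_table` with `stage`
#'   metadata), `sources` (named list of relative `abundance_table`s:
#'   `seawater`, `feed`), and `ground_truth` (the mixing schedule).
#' @export
simulate_stage_series <- function(n_stages = 9, n_features = 80,
                                  mixing_schedule = seq(0, 1, length.out = n_stages),
                                  n_replicates = 3, noise_sd = 0.3, seed = 1) {
  stopifnot(n_stages >= 2, n_features >= 4, n_replicates >= 1, noise_sd >= 0)
  if (length(mixing_schedule) != n_stages) {
    stop("`mixing_schedule` must have one weight per stage", call. = FALSE)
  }
  if (any(mixing_schedule < 0 | mixing_schedule > 1)) {
    stop("mixing weights must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    feature_ids <- sprintf("ASV%03d", seq_len(n_features))
    third <- floor(n_features / 4)
    sw_support <- seq_len(n_features - third)
    feed_support <- (third + 1):n_features
    sw <- rep(0, n_features)
    sw[sw_support] <- rlnorm(length(sw_support), 0, 1)
    feed <- rep(0, n_features)
    feed[feed_support] <- rlnorm(length(feed_support), 0, 1)
    sw <- sw / sum(sw)
    feed <- feed / sum(feed)

    stage_ids <- sprintf("stage%02d", seq_len(n_stages))
    rows <- list()
    meta <- list()
    for (s in seq_len(n_stages)) {
      w <- mixing_schedule[s]
      base <- w * feed + (1 - w) * sw
      for (r in seq_len(n_replicates)) {
        noisy <- base * exp(rnorm(n_features, 0, noise_sd))
        rows[[length(rows) + 1]] <- noisy / sum(noisy)
        meta[[length(meta) + 1]] <- data.frame(
          sample_id = sprintf("larvae_%s_r%d", stage_ids[s], r),
          stage = stage_ids[s], stringsAsFactors = FALSE
        )
      }
    }
    lv <- do.call(rbind, rows)
    md <- do.call(rbind, meta)
    rownames(lv) <- md$sample_id
    colnames(lv) <- feature_ids
    md$stage <- factor(md$stage, levels = stage_ids, ordered = TRUE)
    larvae <- abundance_table(lv, md, relative = TRUE)

    make_source <- function(profile, name) {
      m <- matrix(profile, 1, n_features,
                  dimnames = list(paste0(name, "_1"), feature_ids))
      abundance_table(m, relative = TRUE)
    }
    sources <- list(seawater = make_source(sw, "seawater"),
                    feed = make_source(feed, "feed"))
    gt <- list(mixing_schedule = mixing_schedule, stages = stage_ids)
    list(larvae = larvae, sources = sources, ground_truth = gt)
  })
}
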