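test_that("simulate_tree produces seeded pure-birth trees", {
  cherry <- simulate_tree(2, seed = 1)
  expect_equal(length(cherry$tip.label), 2)
  expect_error(simulate_tree(1), "at least 2")

  t1 <- simulate_tree(100, seed = 42)
  t2 <- simulate_tree(100, seed = 42)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))

  # deeper trees on average with more tips (root-to-tip path length)
  depth <- function(n, s) {
    tr <- simulate_tree(n, seed = s)
    mean(ape::node.depth.edgelength(tr)[seq_len(n)])
  }
  d_small <- mean(vapply(1:10, function(s) depth(10, s), numeric(1)))
  d_large <- mean(vapply(1:10, function(s) depth(200, s), numeric(1)))
  expect_gt(d_large, d_small)
})

test_that("plant_core_clades plants zero-diameter all-host ubiquitous clades", {
  tr <- simulate_tree(400, seed = 13)
  pc <- plant_core_clades(tr, n_core = 3, seed = 13)
  gt <- pc$ground_truth
  expect_length(gt$core_nodes, 3)
  for (i in 1:3) {
    tips <- gt$core_tips[[i]]
    expect_equal(clade_max_within_distance(pc$tree, tips), 0)
    ann_rows <- match(tips, pc$annotations$tip_id)
    expect_true(all(pc$annotations$source_class[ann_rows] == "host"))
    expect_equal(clade_ubiquity(tips, pc$annotations, gt$cultures), 1.0)
  }
  # validators accept the emitted annotations
  expect_silent(validate_tip_annotations(pc$annotations, pc$tree))

  none_bg <- plant_core_clades(simulate_tree(200, seed = 2), n_core = 1,
                               host_fraction_background = 0, seed = 2)
  bg_tips <- setdiff(none_bg$tree$tip.label, unlist(none_bg$ground_truth$core_tips))
  cls <- none_bg$annotations$source_class[match(bg_tips, none_bg$annotations$tip_id)]
  expect_true(all(cls == "environment"))

  expect_error(plant_core_clades(simulate_tree(20, seed = 1), n_core = 3,
                                 clade_size = 12), "infeasible")
})

test_that("simulate_occurrences draws from the stated occupancy law", {
  occ <- simulate_occurrences(300, 3.6, f_max = 2, seed = 4)
  f <- lengths(occ$cluster_cultures)
  expect_true(all(f %in% 1:2))

  o1 <- simulate_occurrences(100, 2.5, 8, seed = 6)
  o2 <- simulate_occurrences(100, 2.5, 8, seed = 6)
  expect_identical(o1$cluster_cultures, o2$cluster_cultures)

  big <- simulate_occurrences(5000, 3.6, 12, seed = 8)
  spec <- occurrence_spectrum(big$cluster_cultures)
  expect_true(all(diff(spec$N[spec$f <= 5]) < 0))

  expect_error(simulate_occurrences(10, exponent_a = 1), "exceed 1")
  expect_error(simulate_occurrences(10, f_max = 1), "at least 2")
})

test_that("simulate_survival_data plants signal, noise and collapse regimes", {
  sim <- simulate_survival_data(n_samples = 130, collapse_fraction = 0.1, seed = 9)
  expect_silent(validate_abundance_table(sim$table))
  expect_true(sim$table$relative)
  gt <- sim$ground_truth
  expect_length(gt$collapsed_samples, 13)
  v <- sim$table$values
  expect_true(all(v[gt$collapsed_samples, gt$pathogen_feature] > 0.5))
  expect_true(all(sim$table$metadata[gt$collapsed_samples, "survival_rate"] < 0.05))
  expect_true(all(sim$table$metadata$survival_rate >= 0 &
                    sim$table$metadata$survival_rate <= 1))

  s1 <- simulate_survival_data(n_samples = 20, n_features = 10, seed = 3)
  s2 <- simulate_survival_data(n_samples = 20, n_features = 10, seed = 3)
  expect_identical(s1$table$values, s2$table$values)
  expect_identical(s1$table$metadata$survival_rate, s2$table$metadata$survival_rate)

  expect_error(simulate_survival_data(n_features = 10, n_signal = 10), "n_signal")
  expect_error(simulate_survival_data(noise_sd = -1), "non-negative")
})

test_that("simulate_gene_matrix respects its planted sweep count", {
  none <- simulate_gene_matrix(n_families = 50, n_swept = 0, seed = 3)
  expect_equal(nrow(find_sweep_genes(none$matrix)), 0)

  high_decoy <- simulate_gene_matrix(n_families = 200, n_swept = 3,
                                     decoy_bg_prevalence_range = c(0.2, 0.3),
                                     seed = 5)
  rep <- find_sweep_genes(high_decoy$matrix)
  expect_setequal(rep$family_id, high_decoy$ground_truth$swept_families)

  g1 <- simulate_gene_matrix(n_families = 100, seed = 11)
  g2 <- simulate_gene_matrix(n_families = 100, seed = 11)
  expect_identical(g1$matrix$values, g2$matrix$values)

  expect_error(simulate_gene_matrix(n_families = 5, n_swept = 6), "exceeds")
})

test_that("simulate_stage_series mixes sources per schedule", {
  flat <- simulate_stage_series(n_stages = 4, mixing_schedule = rep(0, 4),
                                noise_sd = 0.1, seed = 7)
  traj <- source_trajectory(flat$larvae, flat$sources)
  sw <- traj$bray_curtis[traj$source == "seawater"]
  expect_true(all(sw > 0.8))

  s1 <- simulate_stage_series(seed = 15)
  s2 <- simulate_stage_series(seed = 15)
  expect_identical(s1$larvae$values, s2$larvae$values)

  expect_error(simulate_stage_series(n_stages = 3, mixing_schedule = c(0, 0.5, 1.2)),
               "\\[0, 1\\]")
  expect_error(simulate_stage_series(n_stages = 3, mixing_schedule = c(0, 1)),
               "one weight per stage")
})

test_that("ground truth round-trips through JSON losslessly", {
  sim <- simulate_survival_data(n_samples = 12, n_features = 8,
                                collapse_fraction = 0.25, seed = 2)
  gt <- sim$ground_truth
  back <- jsonlite::fromJSON(jsonlite::toJSON(gt, auto_unbox = TRUE, digits = NA))
  expect_equal(back$signal_features, gt$signal_features)
  expect_equal(back$collapsed_samples, gt$collapsed_samples)
  expect_equal(back$noise_sd, gt$noise_sd)

  occ <- simulate_occurrences(10, 2.2, 5, seed = 1)
  back2 <- jsonlite::fromJSON(jsonlite::toJSON(occ$ground_truth, auto_unbox = TRUE,
                                               digits = NA))
  expect_equal(back2$exponent_a, occ$ground_truth$exponent_a)
})
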