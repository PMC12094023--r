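test_that("enumerate_clades lists non-root internal nodes above the size floor", {
  balanced <- tree_from_text("((A:1,B:1):1,(C:1,D:1):1);")
  cl <- enumerate_clades(balanced, min_tips = 2)
  expect_length(cl, 2)
  expect_setequal(unlist(lapply(cl, function(x) sort(x$tips))), c("A", "B", "C", "D"))

  expect_length(enumerate_clades(balanced, min_tips = 5), 0)

  caterpillar <- tree_from_text("(((A:1,B:1):1,C:1):1,D:1);")
  expect_length(enumerate_clades(caterpillar, min_tips = 3), 1)
  expect_length(enumerate_clades(caterpillar, min_tips = 2), 2)
})

test_that("binomial enrichment p equals direct pmf summation", {
  expect_equal(clade_enrichment_p(5, 5, 0.5), 0.03125)
  expect_equal(clade_enrichment_p(0, 7, 0.3), 1.0)
  expect_equal(clade_enrichment_p(3, 10, 0.3), brute_force_binom_tail(3, 10, 0.3),
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:25, 1)
    k <- sample(0:n, 1)
    p <- runif(1, 0.05, 0.95)
    expect_equal(clade_enrichment_p(k, n, p), brute_force_binom_tail(k, n, p),
                 tolerance = 1e-12)
  }
  expect_error(clade_enrichment_p(1, 2, 0), "p_global")
  expect_error(clade_enrichment_p(1, 2, 1), "p_global")
})

test_that("bonferroni multiplies by the test count and caps at 1", {
  expect_equal(bonferroni(0.01), 0.01)
  expect_equal(bonferroni(c(0.01, 0.02)), c(0.02, 0.04))
  expect_equal(bonferroni(c(0.9, 0.9)), c(1, 1))
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("clade ubiquity is the covered fraction of the culture universe", {
  ann <- tip_annotations(
    c("A", "B", "C"), c("host", "host", "environment"),
    list(paste0("C", 1:6), paste0("C", 5:10), character(0))
  )
  all12 <- paste0("C", 1:12)
  expect_equal(clade_ubiquity(c("A", "B"), ann, all12), 10 / 12)
  expect_equal(clade_ubiquity(c("A", "B"), ann, paste0("C", 1:10)), 1.0)
  expect_equal(clade_ubiquity("C", ann, all12), 0)
})

test_that("clade diameter is the maximum within-clade patristic distance", {
  tr <- tree_from_text("((A:0.1,B:0.2):1,C:1);")
  expect_equal(clade_max_within_distance(tr, c("A", "B")), 0.3)
  expect_equal(clade_max_within_distance(tr, "A"), 0)
  zero <- tree_from_text("((A:0,B:0):1,C:1);")
  expect_equal(clade_max_within_distance(zero, c("A", "B")), 0)
})

test_that("find_core_clades recovers a planted clade and applies all criteria", {
  tr <- simulate_tree(300, seed = 31)
  pc <- plant_core_clades(tr, n_core = 1, seed = 31)
  rep <- find_core_clades(pc$tree, pc$annotations)
  expect_s3_class(rep, "clade_report")
  expect_setequal(rep$clade_id[rep$is_core], pc$ground_truth$core_nodes)
  expect_false(is.unsorted(rep$p_adj))

  # drop ubiquity of the planted clade to 0.5: reported but no longer core
  ann2 <- pc$annotations
  planted <- pc$ground_truth$core_tips[[1]]
  half <- paste0("C", 1:6)
  ann2$cultures[ann2$tip_id %in% planted] <- rep(list(half), length(planted))
  rep2 <- find_core_clades(pc$tree, ann2,
                           all_cultures = pc$ground_truth$cultures)
  row <- rep2[rep2$clade_id == pc$ground_truth$core_nodes[1], ]
  expect_equal(row$ubiquity_fraction, 0.5)
  expect_false(row$is_core)
})

test_that("find_core_clades rejects single-class trees", {
  tr <- simulate_tree(20, seed = 1)
  all_env <- tip_annotations(tr$tip.label, rep("environment", 20))
  expect_error(find_core_clades(tr, all_env), "no host")
})

test_that("nested passing clades collapse to the maximal clade", {
  # two zero-length cherries under a zero-length parent: parent and both
  # cherries pass every criterion; only the parent is flagged core. The large
  # environment star keeps the global host fraction low enough that even the
  # two-tip cherries survive the Bonferroni correction.
  env <- paste0("E", 1:46)
  tr <- tree_from_text(sprintf("(((A:0,B:0):0,(C:0,D:0):0):1,(%s):1);",
                               paste0(env, ":1", collapse = ",")))
  cls <- c(rep("host", 4), rep("environment", 46))
  ann <- tip_annotations(c("A", "B", "C", "D", env), cls,
                         c(rep(list(paste0("C", 1:12)), 4),
                           rep(list(character(0)), 46)))
  rep <- find_core_clades(tr, ann, min_tips = 2)
  core <- rep[rep$is_core, ]
  expect_equal(nrow(core), 1)
  expect_setequal(core$tips[[1]], c("A", "B", "C", "D"))
})

test_that("clade report includes maximal clade relative abundance when given", {
  tr <- tree_from_text("((A:0,B:0):1,(C:1,D:1):1);")
  ann <- tip_annotations(c("A", "B", "C", "D"),
                         c("host", "host", "environment", "environment"),
                         list("C1", "C1", character(0), character(0)))
  vals <- rbind(S1 = c(A = 0.2, B = 0.3, C = 0.4, D = 0.1),
                S2 = c(A = 0.05, B = 0.05, C = 0.8, D = 0.1))
  tab <- abundance_table(vals, relative = TRUE)
  rep <- find_core_clades(tr, ann, all_cultures = "C1", abundance = tab)
  ab <- rep$max_relative_abundance[vapply(rep$tips, setequal, TRUE, y = c("A", "B"))]
  expect_equal(ab, 0.5)
})

test_that("occurrence_spectrum counts clusters by occupancy and conserves totals", {
  spec <- occurrence_spectrum(list(a = "C1", b = "C2", c = c("C1", "C2")))
  expect_equal(spec$f, c(1, 2))
  expect_equal(spec$N, c(2, 1))

  single <- occurrence_spectrum(list(a = paste0("C", 1:5)))
  expect_equal(single$f, 5)
  expect_equal(single$N, 1)

  expect_error(occurrence_spectrum(list()), "empty")
  expect_error(occurrence_spectrum(list(a = character(0))), "empty culture")

  occ <- simulate_occurrences(400, 2.5, 10, seed = 6)
  spec2 <- occurrence_spectrum(occ$cluster_cultures)
  expect_equal(sum(spec2$N), 400)
})

test_that("fit_power_law recovers a noiseless exponent exactly", {
  f <- 1:10
  spec <- data.frame(f = f, N = 1000 * f^(-2))
  fit <- fit_power_law(spec)
  expect_equal(fit$exponent, 2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$n_points, 10)

  expect_error(fit_power_law(data.frame(f = 1:2, N = c(5, 1))), "at least 3")
})
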