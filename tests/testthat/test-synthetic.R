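test_that("Yule tree simulation gives binary rooted trees, reproducibly", {
  tr2 <- simulate_tree(2, seed = 1)
  expect_identical(ape::Ntip(tr2), 2L)
  expect_error(simulate_tree(1), ">= 2")

  tr <- simulate_tree(50, seed = 9)
  expect_identical(ape::Ntip(tr), 50L)
  expect_identical(tr$Nnode, 49L)
  expect_true(ape::is.rooted(tr))
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulate_tree(50, seed = 9)))
  expect_false(identical(ape::write.tree(tr),
                         ape::write.tree(simulate_tree(50, seed = 10))))
})

test_that("Brownian traits have the variance and covariance the model implies", {
  tr <- simulate_tree(12, seed = 3)
  expect_identical(evolve_trait_bm(tr, 0, seed = 1),
                   stats::setNames(rep(0, 12), tr$tip.label))

  # tip variance across replicates ~ sigma^2 * root-to-tip depth
  sigma <- 0.8
  depths <- ape::node.depth.edgelength(tr)[seq_len(12)]
  reps <- 1000
  tips <- matrix(0, reps, 12)
  for (r in seq_len(reps)) tips[r, ] <- evolve_trait_bm(tr, sigma, seed = r)
  v <- apply(tips, 2, var)
  expected <- sigma^2 * depths
  se <- expected * sqrt(2 / (reps - 1))   # var of a sample variance, normal
  expect_true(all(abs(v - expected) < 3 * se))

  # sister tips diverge less than phylogenetically distant tips
  D <- patristic_distances(tr)
  diff_close <- diff_far <- numeric(500)
  pair_close <- which(D == min(D[D > 0]), arr.ind = TRUE)[1, ]
  pair_far <- which(D == max(D), arr.ind = TRUE)[1, ]
  for (r in 1:500) {
    x <- evolve_trait_bm(tr, sigma, seed = 2000 + r)
    diff_close[r] <- x[pair_close[1]] - x[pair_close[2]]
    diff_far[r] <- x[pair_far[1]] - x[pair_far[2]]
  }
  # BM: var of tip difference = sigma^2 * patristic distance
  expect_lt(var(diff_close), var(diff_far))
  expect_equal(var(diff_far), sigma^2 * max(D), tolerance = 0.2)
})

test_that("assembled scenarios satisfy the structural contracts", {
  cfg <- scenario_config(n_taxa = 60, n_samples_per_group = 4,
                         regime = "selection", depth_mean = 1500, seed = 2)
  sim <- assemble_samples(cfg)
  expect_s3_class(sim$table, "zotu_table")
  expect_identical(nrow(sim$metadata), ncol(sim$table))
  expect_identical(sort(unique(sim$metadata$habitat)), c("MP", "SW"))
  expect_true(all(sim$metadata$size_fraction %in% c("micro", "nano", "pico")))
  # ground truth covers every emitted sample
  expect_setequal(sim$truth$sample_id, colnames(sim$table))
  # alignment with the generating tree is the identity
  al <- align_table_tree(sim$table, sim$tree)
  expect_identical(rownames(al$table), rownames(sim$table))
  expect_identical(ape::Ntip(al$tree), ape::Ntip(sim$tree))
  # salinity tracks the habitat means
  sal <- tapply(sim$metadata$salinity, sim$metadata$habitat, mean)
  expect_lt(abs(sal[["SW"]] - 29), 3)
  expect_lt(abs(sal[["MP"]] - 2.5), 3)
  # reproducibility
  sim2 <- assemble_samples(cfg)
  expect_identical(unclass(sim$table), unclass(sim2$table))

  expect_error(scenario_config(n_taxa = 2), ">= 4")
  expect_error(scenario_config(subset_fraction = 0), "subset_fraction")
})

test_that("an infinitely wide niche filter reduces selection to neutrality", {
  cfg <- scenario_config(n_taxa = 30, n_samples_per_group = 2, seed = 4)
  tree <- simulate_tree(30, seed = 4)
  traits <- evolve_trait_bm(tree, 1, seed = 4)
  pool <- rep(1 / 30, 30)
  w_sel <- pool * exp(-(traits - 2)^2 / (2 * Inf^2))
  w_sel <- w_sel / sum(w_sel)
  expect_lt(0.5 * sum(abs(w_sel - pool)), 1e-6)   # total-variation distance
})

test_that("no taxon is systematically enriched by habitat under neutrality", {
  # two-sided binomial screen per taxon on pooled counts, multiplicity
  # controlled; under the shared-pool null the MP share of a taxon's reads
  # follows its MP share of total reads
  n_sig <- 0; n_tests <- 0
  for (s in 1:40) {
    sim <- assemble_samples(scenario_config(n_taxa = 25,
                                            n_samples_per_group = 5,
                                            regime = "neutral_drift",
                                            depth_mean = 900,
                                            drift_sigma = 0,
                                            seed = 6000 + s))
    m <- unclass(sim$table)
    mp <- sim$metadata$habitat == "MP"
    tot_mp <- sum(m[, mp]); tot <- sum(m)
    for (t in seq_len(nrow(m))) {
      n_t <- sum(m[t, ])
      if (n_t < 10) next
      p <- binom.test(sum(m[t, mp]), n_t, tot_mp / tot)$p.value
      n_tests <- n_tests + 1
      n_sig <- n_sig + (p < 0.01 / nrow(m))   # Bonferroni within scenario
    }
  }
  expect_lt(n_sig / n_tests, 0.01)
})

test_that("dispersal clusters share more taxa within than between", {
  within_frac <- between_frac <- numeric(0)
  for (s in 1:60) {
    sim <- assemble_samples(scenario_config(n_taxa = 50,
                                            n_samples_per_group = 4,
                                            regime = "dispersal_limited",
                                            depth_mean = 1200,
                                            seed = 7000 + s))
    pres <- unclass(sim$table) > 0
    cl <- stats::setNames(sim$truth$cluster, sim$truth$sample_id)
    ids <- colnames(pres)
    for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
      shared <- sum(pres[, i] & pres[, j]) / sum(pres[, i] | pres[, j])
      if (cl[ids[i]] == cl[ids[j]]) within_frac <- c(within_frac, shared)
      else between_frac <- c(between_frac, shared)
    }
  }
  expect_gt(mean(within_frac), mean(between_frac))
})

test_that("the mixed regime labels habitats with their generating process", {
  sim <- assemble_samples(scenario_config(regime = "mixed", seed = 11,
                                          n_taxa = 30,
                                          n_samples_per_group = 3,
                                          depth_mean = 500))
  reg <- stats::setNames(sim$truth$regime, sim$truth$sample_id)
  hab <- stats::setNames(sim$metadata$habitat, sim$metadata$sample_id)
  expect_true(all(reg[hab == "SW"] == "dispersal_limited"))
  expect_true(all(reg[hab == "MP"] == "neutral_drift"))
})
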