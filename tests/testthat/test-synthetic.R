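test_that("the pure-birth simulator is seeded, ultrametric and rescalable", {
  cfg <- sim_config(n_taxa = 15, birth_rate = 0.03, root_age = 100,
                    n_samples = 1, seed = 5)
  a <- simulate_yule(cfg)
  b <- simulate_yule(cfg)
  expect_identical(ape::write.tree(a, digits = 12),
                   ape::write.tree(b, digits = 12))  # bit-reproducible
  expect_true(check_ultrametric(a))
  expect_equal(max(ape::node.depth.edgelength(a)), 100)
  expect_equal(ape::Ntip(a), 15)

  # no rescale: root age keeps its simulated value
  cfg_free <- sim_config(n_taxa = 6, birth_rate = 0.03, root_age = NULL,
                         n_samples = 1, seed = 5)
  free <- simulate_yule(cfg_free)
  expect_true(check_ultrametric(free))
  expect_gt(max(ape::node.depth.edgelength(free)), 0)
})

test_that("two-tip root ages are exponential with mean 1/birth_rate", {
  cfg2 <- list(n_taxa = 2L, birth_rate = 0.1, root_age = NULL)
  set.seed(202)
  roots <- vapply(sample.int(1e7, 3000), function(s)
    max(ape::node.depth.edgelength(simulate_yule(cfg2, seed = s))),
    numeric(1))
  se <- sd(roots) / sqrt(length(roots))
  expect_lt(abs(mean(roots) - 10), 3 * se)
})

test_that("pseudo-posterior with no noise reproduces the chronogram exactly", {
  cfg <- sim_config(n_taxa = 9, birth_rate = 0.05, root_age = 120,
                    n_samples = 8, height_cv = 0, rate_cv = 0,
                    rate_mean = 2e-4, seed = 8)
  chr <- simulate_yule(cfg)
  ps <- pseudo_posterior(chr, cfg)
  expect_equal(ps$unit, "substitutions")
  chr_ord <- ape::reorder.phylo(chr, "cladewise")
  for (tr in ps$trees) {
    expect_equal(tr$edge.length, chr_ord$edge.length * 2e-4)
  }
})

test_that("pseudo-posterior trees stay ultrametric with unchanged topology", {
  cfg <- sim_config(n_taxa = 12, birth_rate = 0.05, root_age = 200,
                    n_samples = 100, height_cv = 0.2, rate_cv = 0.3, seed = 16)
  chr <- simulate_yule(cfg)
  ps <- pseudo_posterior(chr, cfg)
  expect_true(all(vapply(ps$trees, check_ultrametric, logical(1),
                         tol = 1e-8)))
  expect_true(all(vapply(ps$trees, function(tr)
    isTRUE(all.equal(tr, chr, use.edge.length = FALSE)), logical(1))))
  # reproducibility
  ps2 <- pseudo_posterior(chr, cfg)
  expect_identical(ps$trees[[40]]$edge.length, ps2$trees[[40]]$edge.length)
})

test_that("jittered relative depths are unbiased within Monte Carlo error", {
  cfg <- sim_config(n_taxa = 10, birth_rate = 0.05, root_age = 150,
                    n_samples = 1000, height_cv = 0.05, seed = 23)
  chr <- simulate_yule(cfg)
  ps <- pseudo_posterior(chr, cfg)
  pp <- ape::prop.part(chr)
  tips <- attr(pp, "labels")[pp[[2]]]
  truth <- relative_node_depth(chr, tips)
  rds <- vapply(ps$trees, relative_node_depth, numeric(1), taxon_set = tips)
  se <- sd(rds) / sqrt(length(rds))
  # 3 SE plus the O(cv^2/2) lognormal mean offset of the jitter ratio
  expect_lt(abs(mean(rds) - truth), 3 * se + truth * cfg$height_cv^2)
})

test_that("fossil simulation records coverage-scaled ages and ground truth", {
  chr <- ladder4()  # node ages: {A,B} 20, {A,B,C} 90, root 100
  sim <- simulate_fossils(chr, list(root = c("A", "B", "C", "D")),
                          coverage = 1, seed = 2)
  expect_equal(sim$fossils$root$min_age, 100)
  expect_equal(sim$truth$root_age, 100)

  sim2 <- simulate_fossils(chr, list(ab = c("A", "B")), coverage = 0.8,
                           seed = 2)
  expect_equal(sim2$fossils$ab$min_age, 0.8 * 20)
  expect_equal(sim2$truth$fossils$true_age, 20)
  expect_false(sim2$truth$fossils$misplaced)

  expect_error(simulate_fossils(chr, list(tip = "A"), coverage = 1, seed = 1),
               "tip")
  expect_error(simulate_fossils(chr, list(ab = c("A", "B")), coverage = 2,
                                seed = 1), "coverage")

  # uniform coverage draws stay inside their bounds and are seeded
  many <- simulate_fossils(chr, list(ab = c("A", "B"), abc = c("A", "B", "C")),
                           coverage = c(0.7, 0.95), seed = 33)
  expect_true(all(many$truth$fossils$coverage >= 0.7 &
                    many$truth$fossils$coverage <= 0.95))
  again <- simulate_fossils(chr, list(ab = c("A", "B"), abc = c("A", "B", "C")),
                            coverage = c(0.7, 0.95), seed = 33)
  expect_identical(many$truth$fossils, again$truth$fossils)
})

test_that("a misplaced fossil inflates S_i by the depth ratio of its nodes", {
  chr <- ladder4()
  # fossil truly from the 90 Ma node (coverage 0.9 -> age 81) bound to the
  # 20 Ma node: S_i = 81 / 0.2 = 405, i.e. 4.5x the well-placed value 90
  sim <- simulate_fossils(chr, list(deep = c("A", "B", "C")), coverage = 0.9,
                          misplace = list(deep = c("A", "B")), seed = 3)
  expect_equal(sim$fossils$deep$min_age, 81)
  expect_setequal(sim$fossils$deep$taxon_set, c("A", "B"))
  expect_true(sim$truth$fossils$misplaced)
  expect_equal(compute_si(chr, sim$fossils$deep), 405)
  well_placed <- fossil_constraint("w", c("A", "B", "C"), 81)
  expect_equal(compute_si(chr, sim$fossils$deep) /
                 compute_si(chr, well_placed), 4.5)
})

test_that("no-noise end-to-end: max S_i equals max coverage times root age", {
  cfg <- sim_config(n_taxa = 10, birth_rate = 0.05, root_age = 100,
                    n_samples = 20, height_cv = 0, rate_cv = 0, seed = 44)
  chr <- simulate_yule(cfg)
  pp <- ape::prop.part(chr)
  labs <- attr(pp, "labels")
  placements <- lapply(pp[1:5], function(i) labs[i])
  names(placements) <- paste0("f", 1:5)
  sim <- simulate_fossils(chr, placements, coverage = c(0.7, 0.95), seed = 45)
  ps <- pseudo_posterior(chr, cfg)
  si_max <- max(vapply(sim$fossils, function(f)
    si_distribution(ps, f)$mean, numeric(1)))
  expect_equal(si_max, max(sim$truth$fossils$coverage) * 100)
  expect_lte(si_max, 100)
  expect_true(all(sim$truth$fossils$min_age <= sim$truth$fossils$true_age))
  expect_true(all(sim$truth$fossils$true_age <= 100 + 1e-9))
})

test_that("misplacement replicates behave as the analytic overlap model predicts", {
  study <- misplacement_study()
  # the misplaced fossil (implied root ~3x the truth) is flagged as an
  # outlier at max_age = 1.5x the true root age in at least 95% of replicates
  expect_gte(study$exclusion_rate, 0.95)
  # the all-five-retained rate is governed by 95%-interval overlap geometry:
  # compare against an independent lognormal-jitter oracle
  oracle <- retention_rate_oracle(n_rep = 1000)
  expect_lt(abs(study$retention_rate - oracle), 0.15)
})
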