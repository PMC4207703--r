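test_that("hpd returns the shortest window with lowest-start tie-breaking", {
  expect_equal(hpd(c(rep(1, 9), 10), 0.9), c(1, 1))
  expect_equal(hpd(rep(3.2, 12)), c(3.2, 3.2))
  expect_equal(hpd(1:100, 0.95), c(1, 95))  # all windows tie; lowest start
  expect_error(hpd(numeric(0)), "no samples")
  expect_error(hpd(1:5, 1.2), "level")
})

test_that("hpd matches an exhaustive interval search on random vectors", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    x <- switch(1 + i %% 3,
                rnorm(n),
                rexp(n, 0.2),
                c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), mean = 8)))
    for (lv in c(0.5, 0.9, 0.95)) {
      expect_equal(hpd(x, lv), hpd_oracle(x, lv))
    }
  }
})

test_that("node age samples require dated trees and track the per-tree MRCA", {
  tr <- balanced4()
  ts <- tree_sample(rep(list(tr), 4), unit = "Ma")
  expect_equal(node_age_samples(ts, c("A", "B")), rep(1, 4))
  expect_equal(node_age_samples(ts, c("A", "B", "C", "D")), rep(2, 4))
  sub <- tree_sample(list(tr), unit = "substitutions")
  expect_error(node_age_samples(sub, c("A", "B")), "Ma")

  # posterior mean of a jittered node age is close to the truth
  cfg <- sim_config(n_taxa = 10, birth_rate = 0.05, root_age = 200,
                    n_samples = 1000, height_cv = 0.05, seed = 12)
  chr <- simulate_yule(cfg)
  dated <- pseudo_posterior(chr, cfg)
  dated <- tree_sample(lapply(dated$trees, function(tr) {
    tr$edge.length <- tr$edge.length / cfg$rate_mean  # back to Ma scale
    tr
  }), unit = "Ma")
  pp <- ape::prop.part(chr)
  tips <- attr(pp, "labels")[pp[[2]]]
  truth <- max(ape::node.depth.edgelength(chr)) -
    ape::node.depth.edgelength(chr)[ape::getMRCA(chr, tips)]
  ages <- node_age_samples(dated, tips)
  se <- sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) / truth - 1), max(3 * se / truth, 0.02))
})

test_that("clade posterior probability is the monophyly fraction", {
  t1 <- balanced4()
  t2 <- ape::read.tree(text = "(((A:0.5,C:0.5):0.5,B:1):1,D:2);")
  ts <- tree_sample(list(t1, t1, t1, t2), unit = "Ma")
  expect_equal(clade_posterior(ts, c("A", "B")), 0.75)
  expect_equal(clade_posterior(ts, c("C", "D")), 0.75)
  expect_equal(clade_posterior(ts, c("A", "C")), 0.25)
  expect_equal(clade_posterior(ts, c("A", "B", "C", "D")), 1)
})

test_that("scenario summaries pool HPDs and flag low-support clades", {
  t1 <- balanced4()
  t2 <- ape::read.tree(text = "(((A:0.5,C:0.5):0.5,B:1):1,D:2);")
  s1 <- tree_sample(list(t1, t1, t1, t2), unit = "Ma")
  clades <- list(ab = c("A", "B"), all = c("A", "B", "C", "D"))

  # single scenario: pooled range equals the scenario's HPD
  one <- summarize_scenarios(list(only = s1), clades)
  expect_equal(one$pooled_low, one$hpd_low)
  expect_equal(one$pooled_high, one$hpd_high)

  # identical scenarios: pooling is idempotent
  two <- summarize_scenarios(list(a = s1, b = s1), clades)
  expect_equal(two$pooled_low, two$hpd_low)
  expect_equal(two$pooled_high, two$hpd_high)

  # pooled range always contains each scenario's HPD
  s2 <- tree_sample(lapply(unclass(s1$trees), function(tr) {
    tr$edge.length <- tr$edge.length * 1.4
    tr
  }), unit = "Ma")
  mix <- summarize_scenarios(list(a = s1, b = s2), clades)
  expect_true(all(mix$pooled_low <= mix$hpd_low))
  expect_true(all(mix$pooled_high >= mix$hpd_high))

  # low-PP clades are flagged, never dropped
  weak <- summarize_scenarios(list(a = s1), list(ac = c("A", "C")))
  expect_equal(nrow(weak), 1)
  expect_true(weak$low_pp)
  expect_equal(weak$pp, 0.25)
})

test_that("pool_ranges spans the scenario HPDs per clade", {
  tab <- data.frame(clade = c("x", "x", "y", "y"),
                    scenario = c("p10", "p50", "p10", "p50"),
                    hpd_low = c(202, 224, 9, 11),
                    hpd_high = c(233, 284, 43, 51))
  pooled <- pool_ranges(tab)
  expect_equal(pooled$pooled_low[pooled$clade == "x"], 202)
  expect_equal(pooled$pooled_high[pooled$clade == "x"], 284)
  expect_equal(pooled$pooled_low[pooled$clade == "y"], 9)
  expect_equal(pooled$pooled_high[pooled$clade == "y"], 51)
})

test_that("the MCC tree maximizes clade-frequency product with median heights", {
  t1 <- balanced4()
  t2 <- ape::read.tree(text = "(((A:0.5,C:0.5):0.5,B:1):1,D:2);")

  same <- tree_sample(rep(list(t1), 5), unit = "Ma")
  m0 <- mcc_tree(same)
  expect_true(all.equal(m0, t1, use.edge.length = FALSE))
  expect_equal(sort(m0$node.ages), c(1, 1, 2))

  ts <- tree_sample(list(t1, t1, t1, t2), unit = "Ma")
  m <- mcc_tree(ts)
  expect_true(all.equal(m, t1, use.edge.length = FALSE))
  # tie at equal frequency: the first-occurring topology wins
  tie <- tree_sample(list(t2, t1, t1, t2), unit = "Ma")
  expect_true(all.equal(mcc_tree(tie), t2, use.edge.length = FALSE))
  # order invariance up to the tie-break: majority topology always selected
  perm <- tree_sample(list(t2, t1, t1, t1), unit = "Ma")
  expect_true(all.equal(mcc_tree(perm), t1, use.edge.length = FALSE))
})

test_that("the MCC topology agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  cfg <- sim_config(n_taxa = 8, birth_rate = 0.05, root_age = 80,
                    n_samples = 60, height_cv = 0.35, seed = 14)
  chr <- simulate_yule(cfg)
  # topology variation comes from mixing pseudo-posteriors of two chronograms
  cfg2 <- sim_config(n_taxa = 8, birth_rate = 0.05, root_age = 80,
                     n_samples = 40, height_cv = 0.35, seed = 15)
  chr2 <- simulate_yule(cfg2)
  mix <- tree_sample(c(lapply(pseudo_posterior(chr, cfg)$trees, identity),
                       lapply(pseudo_posterior(chr2, cfg2)$trees, identity)),
                     unit = "substitutions")
  ours <- mcc_tree(mix)
  ref <- phangorn::maxCladeCred(mix$trees, rooted = TRUE)
  expect_true(all.equal(ours, ref, use.edge.length = FALSE))
})

test_that("annotated Newick output carries node heights and round-trips", {
  t1 <- balanced4()
  ts <- tree_sample(rep(list(t1), 3), unit = "Ma")
  m <- mcc_tree(ts)
  path <- withr::local_tempfile(fileext = ".tre")
  write_annotated_tree(m, path)
  txt <- readLines(path)
  expect_length(txt, 1)
  expect_equal(lengths(regmatches(txt, gregexpr("\\[&height=", txt))), 3)
  expect_match(txt, "\\[&height=2\\]")
  # comments strip on re-reading; topology and lengths survive
  back <- read_trees(path, format = "newick", unit = "Ma")
  expect_true(all.equal(back$trees[[1]], t1, use.edge.length = TRUE))
})

test_that("ess matches iid and AR(1) expectations and is affine invariant", {
  set.seed(101)
  x <- rnorm(10000)
  e <- ess(x)
  expect_gt(e, 8000)
  expect_lte(e, 12000)

  # AR(1) with phi = 0.5: ESS ~= N (1-phi)/(1+phi) = N/3
  phi <- 0.5
  ar <- as.numeric(arima.sim(list(ar = phi), n = 10000))
  e_ar <- ess(ar)
  expect_lt(abs(e_ar - 10000 / 3) / (10000 / 3), 0.2)

  expect_equal(ess(3 * ar - 2), e_ar)
  expect_error(ess(rep(1, 100)), "constant")
  expect_error(ess(1:5), "at least 10")
})

test_that("asdsf averages two-run split-frequency deviations", {
  t_ab <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  t_ac <- ape::read.tree(text = "((A:1,C:1):1,B:2);")
  run_a <- tree_sample(list(t_ab, t_ab), unit = "substitutions")
  run_b <- tree_sample(list(t_ab, t_ac), unit = "substitutions")

  expect_equal(asdsf(run_a, run_a), 0)
  # with min_freq 0.6 only {A,B} qualifies: f_a = 1, f_b = 0.5
  expect_equal(asdsf(run_a, run_b, min_freq = 0.6), 0.5 / sqrt(2),
               tolerance = 1e-12)
  # both non-trivial splits qualify at the default threshold
  expect_equal(asdsf(run_a, run_b), 0.5 / sqrt(2), tolerance = 1e-12)

  # no split reaches the threshold when every clade has frequency 0.5
  expect_error(asdsf(run_b, run_b, min_freq = 0.9), "min_freq")
  t_other <- ape::read.tree(text = "((A:1,B:1):1,X:2);")
  expect_error(asdsf(run_a, tree_sample(list(t_other), unit = "substitutions")),
               "tip sets")
})

test_that("diagnostics reports apply the conventional thresholds", {
  rep_ok <- diagnostics_report(c(alpha = 450, height = 320), 0.004)
  expect_true(all(rep_ok$ess_ok))
  expect_true(rep_ok$asdsf_ok)
  rep_bad <- diagnostics_report(c(alpha = 120), 0.02)
  expect_false(any(rep_bad$ess_ok))
  expect_false(rep_bad$asdsf_ok)
  expect_output(print(rep_ok), "ASDSF")
})
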