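# shared fixtures and independent oracles for the test suite

balanced4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# chronogram with node ages 20 ({A,B}), 90 ({A,B,C}) and root 100
ladder4 <- function() {
  ape::read.tree(text = "(((A:20,B:20):70,C:90):10,D:100);")
}

table1_candidates <- function() {
  path <- system.file("extdata", "araucaria_si_candidates.tsv",
                      package = "calcross")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

table2_hpds <- function() {
  path <- system.file("extdata", "araucaria_node_hpd.tsv",
                      package = "calcross")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# exhaustive-search HPD oracle: minimal-width closed interval [xs_i, xs_j]
# over ALL index pairs covering at least ceiling(level * n) points
hpd_oracle <- function(x, level = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  need <- ceiling(level * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1L >= need && (xs[j] - xs[i]) < (best[2] - best[1])) {
        best <- c(xs[i], xs[j])
      }
    }
  }
  best
}

# one misplacement replicate: 10-taxon chronogram, 5 fossils on the deepest
# internal nodes (coverage U(0.7, 0.95)), plus one fossil whose age comes from
# the root but which is bound to the shallowest internal node
run_misplacement_replicate <- function(seed, n_samples = 300) {
  root_age <- 100
  cfg <- calcross::sim_config(n_taxa = 10, birth_rate = 0.05,
                              root_age = root_age, n_samples = n_samples,
                              height_cv = 0.05, rate_cv = 0.1, seed = seed)
  chr <- calcross::simulate_yule(cfg)
  pp <- ape::prop.part(chr)
  labs <- attr(pp, "labels")
  ntip <- ape::Ntip(chr)
  ages <- max(ape::node.depth.edgelength(chr)) -
    ape::node.depth.edgelength(chr)
  int_ages <- ages[ntip + seq_len(chr$Nnode)]
  ord <- order(int_ages, decreasing = TRUE)   # ord[1] is the root
  # deepest internal nodes below the root: a fossil placed on the root
  # itself would have relative depth exactly 1 with no posterior spread
  placements <- lapply(ord[2:6], function(k) labs[pp[[k]]])
  names(placements) <- paste0("f", 1:5)
  placements$mis <- labs[pp[[1L]]]            # true node: the root
  shallow <- labs[pp[[ord[length(ord)]]]]     # wrong node: shallowest clade
  sim <- calcross::simulate_fossils(chr, placements, coverage = c(0.7, 0.95),
                                    misplace = list(mis = shallow),
                                    seed = seed + 10000L)
  ps <- calcross::pseudo_posterior(chr, cfg, seed = seed + 20000L)
  fit <- calcross::fossil_cv(ps, sim$fossils, n_trees = n_samples,
                             max_age = 1.5 * root_age)
  tab <- fit$selection$table
  list(misplaced_excluded = tab$status[tab$fossil_id == "mis"] == "outlier",
       all5_retained = all(paste0("f", 1:5) %in% fit$selection$retained),
       n_retained = fit$selection$n_retained)
}

# memoized 100-replicate misplacement study (shared by several test files)
misplacement_study <- local({
  cache <- NULL
  function(n_rep = 100, base_seed = 1) {
    if (is.null(cache)) {
      res <- lapply(seq_len(n_rep), function(i)
        run_misplacement_replicate(base_seed + i))
      cache <<- list(
        exclusion_rate = mean(vapply(res, `[[`, logical(1),
                                     "misplaced_excluded")),
        retention_rate = mean(vapply(res, `[[`, logical(1), "all5_retained")))
    }
    cache
  }
})

# analytic oracle for the all-5-retained rate: marginal lognormal jitter of
# node and root heights, coverage U(0.7, 0.95), HPD overlap against the
# highest-mean fossil; independent of every package code path
retention_rate_oracle <- function(n_rep = 1000, n_samples = 300,
                                  height_cv = 0.05, seed = 424242) {
  s <- sqrt(log(1 + height_cv^2))
  # vectorized shortest-window HPD (exhaustive hpd_oracle is O(n^2), too slow
  # at this n; the window scan is equivalent for contiguous sorted data)
  hpd_fast <- function(x, level = 0.95) {
    xs <- sort(x); n <- length(xs); w <- ceiling(level * n)
    widths <- xs[w:n] - xs[1:(n - w + 1)]
    i <- which.min(widths)
    c(xs[i], xs[i + w - 1])
  }
  set.seed(seed)
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cc <- stats::runif(5, 0.7, 0.95)
    root <- exp(stats::rnorm(n_samples, 0, s))
    si <- sapply(cc, function(c) c * exp(stats::rnorm(n_samples, 0, s)) / root)
    iv <- apply(si, 2, hpd_fast)
    ref <- which.max(colMeans(si))
    ok[r] <- all(iv[1, ] <= iv[2, ref] & iv[1, ref] <= iv[2, ])
  }
  mean(ok)
}
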