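#' Configuration for the synthetic pseudo-posterior generator
#'
#' Defaults emulate the observable output of a Bayesian relaxed-clock dating
#' run on a conifer-scale problem: 45 taxa, a root around 300 Ma, 1000
#' posterior samples, mild node-height uncertainty (5% CV), and a plastid-like
#' substitution rate (5e-4 substitutions/site/Ma, 10% CV across samples).
#'
#' @param n_taxa number of tips, at least 3.
#' @param birth_rate pure-birth speciation rate, events per lineage per Ma.
#' @param root_age target root age in Ma; the simulated chronogram is rescaled
#'   to it. `NULL` leaves the simulated depth untouched.
#' @param n_samples number of pseudo-posterior trees to draw.
#' @param height_cv multiplicative lognormal coefficient of variation of the
#'   per-node height jitter (0 = no node-height uncertainty).
#' @param rate_mean real-space mean of the per-sample global clock rate, in
#'   substitutions/site/Ma.
#' @param rate_cv coefficient of variation of the per-sample rate draw.
#' @param seed RNG seed; required, so every simulation is reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 45, birth_rate = 0.01, root_age = 300,
                       n_samples = 1000, height_cv = 0.05,
                       rate_mean = 5e-4, rate_cv = 0.1, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  if (!is.null(root_age) && root_age <= 0) stop("root_age must be > 0")
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (height_cv < 0 || rate_cv < 0 || rate_mean <= 0)
    stop("rates and CVs must be non-negative (rate_mean > 0)")
  structure(list(n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
                 root_age = root_age, n_samples = as.integer(n_samples),
                 height_cv = height_cv, rate_mean = rate_mean,
                 rate_cv = rate_cv, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a pure-birth chronogram
#'
#' Draws a tree from the pure-birth (Yule) process conditioned on the number
#' of tips, with a uniform prior on the origin time: the `n - 1` node ages
#' are independent Exponential(`birth_rate`) draws, attached by joining
#' uniformly random lineage pairs from youngest to oldest — the same
#' conditioned-Yule process used as a tree prior in Bayesian dating. For
#' `n_taxa = 2` the root age is a single Exponential draw with mean
#' `1 / birth_rate`. If `root_age` is set, all ages are rescaled so the root
#' sits exactly there.
#'
#' @param config a [sim_config()] (for this function, `n_taxa >= 2` is
#'   accepted).
#' @param seed RNG seed; defaults to `config$seed`.
#' @return an ultrametric `phylo` with ages in Ma and tips `t1..tn`.
#' @export
simulate_yule <- function(config, seed = config$seed) {
  n <- config$n_taxa
  if (n < 2) stop("need at least 2 taxa")
  with_seed(seed, {
    ages <- sort(stats::rexp(n - 1L, rate = config$birth_rate))
    # join random pairs, youngest event first; the k-th new internal node
    # gets id 2n - k so the final (oldest) join is the root, id n + 1
    active <- seq_len(n)
    node_age <- numeric(2L * n - 1L)
    parent <- integer(0); child <- integer(0)
    for (k in seq_len(n - 1L)) {
      pick <- sample(seq_along(active), 2L)
      new_node <- 2L * n - k
      node_age[new_node] <- ages[k]
      parent <- c(parent, new_node, new_node)
      child <- c(child, active[pick])
      active <- c(active[-pick], new_node)
    }
    tr <- structure(list(edge = cbind(parent, child, deparse.level = 0),
                         edge.length = node_age[parent] - node_age[child],
                         tip.label = paste0("t", seq_len(n)),
                         Nnode = n - 1L),
                    class = "phylo")
    tr <- ape::reorder.phylo(tr, "cladewise")
    if (!is.null(config$root_age)) {
      tr$edge.length <- tr$edge.length * config$root_age / ages[n - 1L]
    }
    tr
  })
}

#' Draw a pseudo-posterior sample of uncalibrated ultrametric trees
#'
#' Stands in for an MCMC posterior over clock trees: per sample, (i) each
#' internal node height of the chronogram is jittered multiplicatively by a
#' lognormal factor (median 1, CV `height_cv`), with parent-child ordering
#' restored by clamping each node to at most 0.999 times its parent's height,
#' then (ii) all heights are multiplied by a per-sample global rate drawn
#' lognormally with real-space mean `rate_mean` and CV `rate_cv`, giving
#' branch lengths in substitutions/site. The topology never changes and every
#' sample is exactly ultrametric. With both CVs zero every sample equals the
#' chronogram times `rate_mean`.
#'
#' @param chronogram an ultrametric `phylo` with ages in Ma.
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return a [tree_sample()] with `unit = "substitutions"`.
#' @export
pseudo_posterior <- function(chronogram, config, seed = config$seed) {
  if (!check_ultrametric(chronogram))
    stop("chronogram must be ultrametric")
  tr <- ape::reorder.phylo(chronogram, "cladewise")  # parents precede children
  ntip <- ape::Ntip(tr)
  ages0 <- node_ages(tr)
  sd_h <- cv_to_sdlog(config$height_cv)
  sd_r <- cv_to_sdlog(config$rate_cv)
  meanlog_r <- log(config$rate_mean) - sd_r^2 / 2
  internal <- ntip + seq_len(tr$Nnode)
  ep <- tr$edge[, 1]; ec <- tr$edge[, 2]
  int_child <- which(ec > ntip)  # edges whose child is internal
  trees <- with_seed(seed, {
    lapply(seq_len(config$n_samples), function(s) {
      ages <- ages0
      ages[internal] <- ages[internal] *
        stats::rlnorm(length(internal), 0, sd_h)
      for (e in int_child)  # cladewise: parents already final
        ages[ec[e]] <- min(ages[ec[e]], 0.999 * ages[ep[e]])
      rate <- stats::rlnorm(1, meanlog_r, sd_r)
      out <- tr
      out$edge.length <- (ages[ep] - ages[ec]) * rate
      out
    })
  })
  tree_sample(trees, unit = "substitutions",
              source = sprintf("pseudo-posterior (seed %s)", seed))
}

#' Simulate fossil constraints with known coverage
#'
#' For each placement (a taxon set resolving to an internal node of the
#' chronogram), draws a coverage fraction `c` — the proportion of the
#' lineage's true duration represented by its oldest fossil — and sets the
#' fossil's minimum age to `c` times the node's true age. Optionally,
#' selected fossils are *misplaced*: they keep the age derived from their
#' true node but are bound to a different (typically much shallower) taxon
#' set, emulating a fossil assigned to the wrong clade.
#'
#' @param chronogram an ultrametric `phylo` with ages in Ma.
#' @param placements named list of taxon sets (character vectors, each of at
#'   least two tips).
#' @param coverage either a single fraction in `(0, 1]` (fixed coverage) or a
#'   length-2 vector `c(a, b)` for Uniform(a, b) draws.
#' @param misplace optional named list mapping fossil ids (names of
#'   `placements`) to the wrong taxon set to bind them to.
#' @param seed RNG seed (required).
#' @return a list with `fossils` (named list of [fossil_constraint()], bound
#'   to the wrong node where misplaced) and `truth`: the chronogram, its root
#'   age, and a per-fossil data frame of true node age, coverage, minimum
#'   age and misplacement flag.
#' @export
simulate_fossils <- function(chronogram, placements, coverage = 0.8,
                             misplace = NULL, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (is.null(names(placements)) || any(!nzchar(names(placements))))
    stop("placements must be a named list of taxon sets")
  ages <- node_ages(chronogram)
  root_age <- ages[ape::Ntip(chronogram) + 1L]
  ids <- names(placements)
  true_age <- vapply(ids, function(id) {
    ts <- placements[[id]]
    if (length(unique(ts)) < 2L)
      stop("placement '", id, "' resolves to a tip, not an internal node")
    ages[mrca_node(chronogram, ts)]
  }, numeric(1))
  cov <- with_seed(seed, {
    if (length(coverage) == 1L) {
      if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
      rep(coverage, length(ids))
    } else if (length(coverage) == 2L) {
      if (coverage[1] >= coverage[2]) stop("need coverage[1] < coverage[2]")
      stats::runif(length(ids), coverage[1], coverage[2])
    } else stop("coverage must have length 1 or 2")
  })
  min_age <- cov * true_age
  fossils <- lapply(seq_along(ids), function(i) {
    ts <- placements[[ids[i]]]
    mis <- !is.null(misplace) && ids[i] %in% names(misplace)
    if (mis) ts <- misplace[[ids[i]]]
    fossil_constraint(ids[i], ts, min_age[i])
  })
  names(fossils) <- ids
  truth <- list(chronogram = chronogram, root_age = root_age,
                fossils = data.frame(
                  id = ids, true_age = unname(true_age),
                  coverage = unname(cov), min_age = unname(min_age),
                  misplaced = ids %in% names(misplace),
                  stringsAsFactors = FALSE, row.names = NULL))
  list(fossils = fossils, truth = truth)
}

#' Write a synthetic study to disk
#'
#' Emits the pseudo-posterior trees (Newick), the fossil table (TSV), the
#' ground truth (TSV) and the configuration (key=value text) so a simulated
#' study can be rerun through the file-based pipeline.
#'
#' @param sim output of [simulate_fossils()].
#' @param sample output of [pseudo_posterior()].
#' @param config the [sim_config()] used.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_synthetic_study <- function(sim, sample, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trees(sample, file.path(dir, "posterior.trees"), "newick")
  write_fossil_table(sim$fossils, file.path(dir, "fossils.tsv"),
                     header_comment = "synthetic fossil constraints")
  write_tsv(sim$truth$fossils, file.path(dir, "ground_truth.tsv"),
            header_comment = sprintf("synthetic ground truth; root age %g Ma",
                                     sim$truth$root_age))
  cfg <- unclass(config)
  cfg$root_age <- if (is.null(cfg$root_age)) "NULL" else cfg$root_age
  writeLines(paste0(names(cfg), "=", unlist(cfg)),
             file.path(dir, "config.txt"))
  invisible(dir)
}
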