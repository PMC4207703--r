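#' Highest posterior density interval of a sample
#'
#' The empirical HPD: the shortest contiguous window of the sorted sample
#' containing `ceiling(level * N)` points. Ties in width are broken by the
#' lowest starting value. No density is fitted.
#'
#' @param samples numeric vector of posterior draws (at least one).
#' @param level interval mass in `(0, 1)`, default 0.95.
#' @return `c(low, high)`.
#' @export
#' @examples
#' hpd(c(rep(1, 9), 10), level = 0.9)  # c(1, 1)
hpd <- function(samples, level = 0.95) {
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n == 0L) stop("no samples")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  xs <- sort(samples)
  w <- max(1L, ceiling(level * n))
  if (w >= n) return(c(xs[1L], xs[n]))
  starts <- seq_len(n - w + 1L)
  widths <- xs[starts + w - 1L] - xs[starts]
  i <- which.min(widths)  # which.min takes the first (lowest-start) tie
  c(xs[i], xs[i + w - 1L])
}

#' Posterior node-age draws for a clade
#'
#' Per tree of a dated sample, the age (depth) of the MRCA of the taxon set,
#' in sample order. The MRCA is resolved per tree, so the vector is defined
#' even for trees in which the set is not monophyletic.
#'
#' @param sample a [tree_sample()] with `unit = "Ma"`.
#' @param taxon_set character vector of at least two tip labels.
#' @return numeric vector of ages in Ma, one per tree.
#' @export
node_age_samples <- function(sample, taxon_set) {
  stopifnot(inherits(sample, "tree_sample"))
  if (sample$unit != "Ma")
    stop("node ages require a dated sample (unit = 'Ma'); got unit = '",
         sample$unit, "'")
  vapply(sample$trees, function(tr) {
    node_ages(tr)[mrca_node(tr, taxon_set)]
  }, numeric(1))
}

#' Posterior probability that a taxon set is a clade
#'
#' The fraction of trees in the sample in which the taxon set is exactly
#' monophyletic.
#'
#' @param sample a [tree_sample()].
#' @param taxon_set character vector of tip labels.
#' @return a fraction in `[0, 1]`.
#' @export
clade_posterior <- function(sample, taxon_set) {
  stopifnot(inherits(sample, "tree_sample"))
  taxon_set <- unique(as.character(taxon_set))
  mean(vapply(sample$trees, function(tr) {
    if (length(taxon_set) == ape::Ntip(tr)) TRUE
    else ape::is.monophyletic(tr, taxon_set)
  }, logical(1)))
}

#' Pool per-scenario HPD intervals into a single plausible range
#'
#' Given one HPD per prior scenario for each clade, the pooled range runs
#' from the smallest HPD lower bound to the largest HPD upper bound across
#' scenarios: when no scenario is favoured a priori, the union of the
#' scenarios' credible ranges is the honest summary.
#'
#' @param hpd_table data frame with columns `clade`, `scenario`, `hpd_low`,
#'   `hpd_high`.
#' @return data frame with columns `clade`, `pooled_low`, `pooled_high`.
#' @export
#' @examples
#' pool_ranges(data.frame(clade = "stem", scenario = c("plus10", "plus50"),
#'                        hpd_low = c(202, 224), hpd_high = c(233, 284)))
pool_ranges <- function(hpd_table) {
  need <- c("clade", "scenario", "hpd_low", "hpd_high")
  if (!all(need %in% names(hpd_table)))
    stop("need columns: ", paste(need, collapse = ", "))
  lo <- tapply(hpd_table$hpd_low, hpd_table$clade, min)
  hi <- tapply(hpd_table$hpd_high, hpd_table$clade, max)
  data.frame(clade = names(lo), pooled_low = as.numeric(lo),
             pooled_high = as.numeric(hi[names(lo)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize node ages across prior scenarios
#'
#' For each clade and each scenario's dated tree sample: the posterior median
#' age, the HPD interval, and the clade's posterior probability. Scenarios
#' are then pooled with [pool_ranges()]. Clades whose posterior probability
#' falls below `min_pp` in a scenario are flagged (`low_pp`), not dropped;
#' their age summaries use the per-tree MRCA as usual.
#'
#' @param scenario_samples named list of dated [tree_sample()] objects, one
#'   per prior scenario.
#' @param clades named list of taxon sets (character vectors of tip labels).
#' @param level HPD mass, default 0.95.
#' @param min_pp posterior-probability flag threshold, default 0.75.
#' @return data frame with one row per clade x scenario: `clade`, `scenario`,
#'   `median`, `hpd_low`, `hpd_high`, `pp`, `low_pp`, `pooled_low`,
#'   `pooled_high`.
#' @export
summarize_scenarios <- function(scenario_samples, clades, level = 0.95,
                                min_pp = 0.75) {
  if (length(scenario_samples) == 0L) stop("need at least one scenario")
  if (is.null(names(scenario_samples)) || any(!nzchar(names(scenario_samples))))
    stop("scenario_samples must be a named list")
  if (is.null(names(clades)) || any(!nzchar(names(clades))))
    stop("clades must be a named list of taxon sets")
  rows <- list()
  for (cl in names(clades)) {
    for (sc in names(scenario_samples)) {
      ages <- node_age_samples(scenario_samples[[sc]], clades[[cl]])
      iv <- hpd(ages, level)
      pp <- clade_posterior(scenario_samples[[sc]], clades[[cl]])
      rows[[length(rows) + 1L]] <- data.frame(
        clade = cl, scenario = sc, median = stats::median(ages),
        hpd_low = iv[1], hpd_high = iv[2], pp = pp, low_pp = pp < min_pp,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  pooled <- pool_ranges(out)
  merge(out, pooled, by = "clade", sort = FALSE)
}

# clade frequency table of a sample: named numeric vector of frequencies,
# keyed by the sorted tip labels of each clade (root clade included, freq 1)
clade_freqs <- function(trees) {
  pp <- ape::prop.part(trees)
  labs <- attr(pp, "labels")
  n <- attr(pp, "number")
  keys <- vapply(pp, function(idx) paste(sort(labs[idx]), collapse = "\r"),
                 character(1))
  stats::setNames(n / length(trees), keys)
}

# keys of the clades present in one tree, in the same encoding
tree_clade_keys <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  vapply(pp, function(idx) paste(sort(labs[idx]), collapse = "\r"),
         character(1))
}

#' Maximum clade credibility tree with median node heights
#'
#' Selects, among the sampled trees, the one maximizing the product of its
#' clades' posterior frequencies (computed as a sum of log frequencies); ties
#' are broken by first occurrence in the sample. Each internal node of the
#' selected topology is then dated with the median of the per-tree MRCA ages
#' of its clade across the whole sample, and branch lengths are rebuilt from
#' those median heights.
#'
#' @param sample a non-empty [tree_sample()].
#' @return a `phylo` whose branch lengths encode the median node heights;
#'   the heights themselves are attached as `$node.ages` (one per internal
#'   node, in ape node order) and the log clade-credibility score as
#'   `$log_clade_credibility`.
#' @export
mcc_tree <- function(sample) {
  stopifnot(inherits(sample, "tree_sample"))
  trees <- sample$trees
  freqs <- clade_freqs(trees)
  scores <- vapply(trees, function(tr)
    sum(log(freqs[tree_clade_keys(tr)])), numeric(1))
  best <- which.max(scores)  # first occurrence on ties
  tr <- trees[[best]]
  ntip <- ape::Ntip(tr)
  internal <- ntip + seq_len(tr$Nnode)
  ages <- numeric(ntip + tr$Nnode)
  pp <- ape::prop.part(tr)  # clades in internal-node order, root first
  all_ages <- lapply(trees, node_ages)
  for (v in internal) {
    tips <- tr$tip.label[pp[[v - ntip]]]
    ages[v] <- stats::median(vapply(seq_along(trees), function(j)
      all_ages[[j]][mrca_node(trees[[j]], tips)], numeric(1)))
  }
  tr$edge.length <- ages[tr$edge[, 1]] - ages[tr$edge[, 2]]
  tr$node.ages <- ages[internal]
  tr$log_clade_credibility <- scores[best]
  tr
}

#' Write an annotated chronogram with node heights in bracketed comments
#'
#' Writes one Newick string in which every internal node carries a
#' `[&height=...]` metadata comment (the node's age recomputed from branch
#' lengths, or the median heights attached by [mcc_tree()]), the format tree
#' annotation tools exchange.
#'
#' @param tree a rooted `phylo`, typically from [mcc_tree()].
#' @param path output file path.
#' @param digits significant digits for lengths and heights.
#' @return `path`, invisibly.
#' @export
write_annotated_tree <- function(tree, path, digits = 10) {
  ntip <- ape::Ntip(tree)
  ages <- if (!is.null(tree$node.ages))
    c(numeric(ntip), tree$node.ages) else node_ages(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- numeric(ntip + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  fmt <- function(x) format(x, digits = digits, trim = TRUE,
                            scientific = FALSE)
  render <- function(v) {
    if (v <= ntip) return(paste0(tree$tip.label[v], ":", fmt(elen[v])))
    inner <- paste(vapply(kids[[as.character(v)]], render, character(1)),
                   collapse = ",")
    brlen <- if (v == ntip + 1L) "" else paste0(":", fmt(elen[v]))
    paste0("(", inner, ")", "[&height=", fmt(ages[v]), "]", brlen)
  }
  writeLines(paste0(render(ntip + 1L), ";"), path)
  invisible(path)
}

#' Effective sample size of an MCMC trace
#'
#' `N / (1 + 2 * sum(rho_k))`, with empirical autocorrelations summed from
#' lag 1 up to (not including) the first non-positive autocorrelation, and
#' the result capped at `N`. Values above ~200 are conventionally taken to
#' indicate adequate mixing for a parameter.
#'
#' @param samples numeric vector of at least 10 non-constant draws.
#' @return the effective sample size.
#' @export
ess <- function(samples) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 10L) stop("need at least 10 samples")
  if (stats::var(samples) == 0)
    stop("constant series: autocorrelation undefined")
  lag_max <- min(n - 1L, max(100L, floor(10 * sqrt(n))))
  rho <- stats::acf(samples, lag.max = lag_max, plot = FALSE)$acf[-1L]
  nonpos <- which(rho <= 0)
  k <- if (length(nonpos)) nonpos[1L] - 1L else length(rho)
  min(n, n / (1 + 2 * sum(rho[seq_len(k)])))
}

#' Average standard deviation of split frequencies between two runs
#'
#' Topological convergence diagnostic for two independent MCMC runs: over all
#' non-trivial clades reaching frequency `min_freq` in at least one run, the
#' mean of the two-run sample standard deviation of the clade's frequency,
#' `|f_a - f_b| / sqrt(2)`. Values below 0.01 conventionally indicate that
#' the runs sample the same topology distribution.
#'
#' @param run_a,run_b [tree_sample()] objects over the same tip set.
#' @param min_freq minimum clade frequency for inclusion, default 0.1.
#' @return the ASDSF.
#' @export
asdsf <- function(run_a, run_b, min_freq = 0.1) {
  stopifnot(inherits(run_a, "tree_sample"), inherits(run_b, "tree_sample"))
  tips_a <- sort(run_a$trees[[1L]]$tip.label)
  tips_b <- sort(run_b$trees[[1L]]$tip.label)
  if (!identical(tips_a, tips_b)) stop("tip sets differ between runs")
  root_key <- paste(tips_a, collapse = "\r")
  fa <- clade_freqs(run_a$trees)
  fb <- clade_freqs(run_b$trees)
  keys <- setdiff(union(names(fa), names(fb)), root_key)
  get0 <- function(f, k) ifelse(k %in% names(f), f[k], 0)
  f1 <- vapply(keys, function(k) as.numeric(get0(fa, k)), numeric(1))
  f2 <- vapply(keys, function(k) as.numeric(get0(fb, k)), numeric(1))
  keep <- pmax(f1, f2) >= min_freq
  if (!any(keep))
    stop("no split reaches min_freq ", min_freq, " in either run")
  mean(abs(f1[keep] - f2[keep]) / sqrt(2))
}

#' Convergence diagnostics report
#'
#' Bundles per-parameter effective sample sizes and a between-run ASDSF with
#' the conventional thresholds (ESS > 200, ASDSF < 0.01) into pass/fail
#' flags.
#'
#' @param ess_values named numeric vector of per-parameter ESS.
#' @param asdsf_value between-run ASDSF, or `NA` when a single run is
#'   available.
#' @param ess_min minimum acceptable ESS, default 200.
#' @param asdsf_max maximum acceptable ASDSF, default 0.01.
#' @return an object of class `diagnostics_report`.
#' @export
diagnostics_report <- function(ess_values, asdsf_value = NA_real_,
                               ess_min = 200, asdsf_max = 0.01) {
  stopifnot(all(ess_values > 0), is.na(asdsf_value) || asdsf_value >= 0)
  structure(list(ess = ess_values, asdsf = asdsf_value,
                 ess_min = ess_min, asdsf_max = asdsf_max,
                 ess_ok = ess_values > ess_min,
                 asdsf_ok = if (is.na(asdsf_value)) NA
                            else asdsf_value < asdsf_max),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("convergence diagnostics\n")
  for (p in names(x$ess))
    cat(sprintf("  ESS[%s] = %.1f (%s %g)\n", p, x$ess[[p]],
                if (x$ess_ok[[p]]) ">" else "<=", x$ess_min))
  if (!is.na(x$asdsf))
    cat(sprintf("  ASDSF = %.5f (%s %g)\n", x$asdsf,
                if (isTRUE(x$asdsf_ok)) "<" else ">=", x$asdsf_max))
  invisible(x)
}
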