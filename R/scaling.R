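#' Empirical scaling factor of one fossil on one tree
#'
#' For a fossil with minimum age `t` (Ma) constraining a node at relative
#' depth `r` in an ultrametric tree, the empirical scaling factor is
#' `S_i = t / r`: the root age (Ma) implied by assuming the fossil exactly
#' dates its node. Because `r <= 1`, `S_i >= t` always. Uniformly rescaling
#' all branch lengths leaves `S_i` unchanged, so uncalibrated clock trees
#' (substitutions/site) are valid input.
#'
#' @param tree a rooted ultrametric `phylo`.
#' @param fossil a [fossil_constraint()].
#' @return the implied root age `S_i` in Ma.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' f <- fossil_constraint("f1", c("A", "B"), min_age = 55)
#' compute_si(tr, f)  # 55 / 0.5 = 110
compute_si <- function(tree, fossil) {
  stopifnot(inherits(fossil, "fossil_constraint"))
  fossil$min_age / relative_node_depth(tree, fossil$taxon_set)
}

#' Distribution of the empirical scaling factor over a posterior tree sample
#'
#' Computes `S_i` for one fossil on `n_trees` trees drawn uniformly without
#' replacement from the sample (all trees, in order, when `n_trees` equals
#' the sample size), and summarizes the draw by its mean and a 95% interval —
#' by default the highest-density (shortest) interval of [hpd()].
#'
#' @param sample a [tree_sample()] of ultrametric trees.
#' @param fossil a [fossil_constraint()].
#' @param n_trees number of trees to use (default: all).
#' @param interval_kind `"hpd"` (shortest interval) or `"central"`
#'   (equal-tail quantiles).
#' @param level interval mass, default 0.95.
#' @param seed RNG seed for the subsample; required when
#'   `n_trees < length(sample)`.
#' @param indices optional explicit tree indices (overrides `n_trees`/`seed`);
#'   used to share one subsample across fossils.
#' @return an object of class `si_dist` with fields `fossil_id`, `values`
#'   (one `S_i` per tree, Ma), `n_trees`, `mean`, `lo`, `hi`,
#'   `interval_kind`, `level`.
#' @export
si_distribution <- function(sample, fossil, n_trees = NULL,
                            interval_kind = c("hpd", "central"),
                            level = 0.95, seed = NULL, indices = NULL) {
  interval_kind <- match.arg(interval_kind)
  stopifnot(inherits(sample, "tree_sample"))
  n <- length(sample)
  if (n == 0L) stop("empty tree sample")
  if (is.null(indices)) {
    if (is.null(n_trees)) n_trees <- n
    if (n_trees > n)
      stop(sprintf("n_trees (%d) exceeds sample size (%d)", n_trees, n))
    if (n_trees < 1L) stop("n_trees must be >= 1")
    indices <- if (n_trees == n) seq_len(n) else {
      if (is.null(seed)) stop("seed is required when subsampling trees")
      with_seed(seed, sample.int(n, n_trees, replace = FALSE))
    }
  }
  si <- vapply(indices, function(i) compute_si(sample$trees[[i]], fossil),
               numeric(1))
  si_summary(fossil$id, values = si, interval_kind = interval_kind,
             level = level)
}

# build an si_dist either from raw per-tree values or from printed summaries
si_summary <- function(fossil_id, values = NULL, mean = NULL, lo = NULL,
                       hi = NULL, n_trees = length(values),
                       interval_kind = "hpd", level = 0.95) {
  if (!is.null(values)) {
    mean <- base::mean(values)
    iv <- if (interval_kind == "hpd") hpd(values, level)
          else unname(stats::quantile(values,
                                      c((1 - level) / 2, (1 + level) / 2)))
    lo <- iv[1]; hi <- iv[2]
  }
  if (is.null(mean) || is.null(lo) || is.null(hi))
    stop("need either raw values or mean/lo/hi summaries")
  if (lo > hi) stop("interval_low exceeds interval_high")
  structure(list(fossil_id = as.character(fossil_id), values = values,
                 n_trees = n_trees, mean = mean, lo = lo, hi = hi,
                 interval_kind = interval_kind, level = level),
            class = "si_dist")
}

#' @export
print.si_dist <- function(x, ...) {
  cat(sprintf("S_i for '%s': mean %.4g Ma, %g%% %s interval (%.4g-%.4g), n = %d trees\n",
              x$fossil_id, x$mean, 100 * x$level, x$interval_kind,
              x$hi, x$lo, x$n_trees))
  invisible(x)
}

#' Tabulate scaling-factor distributions
#'
#' Collapses a list of `si_dist` objects into the tabular form consumed by
#' [select_consistent()] and written by the pipeline: one row per fossil with
#' columns `fossil_id`, `n_trees`, `mean_si`, `lo95`, `hi95`,
#' `interval_kind`. A data frame already in that form passes through.
#'
#' @param dists a list of `si_dist` objects (or one), or a conforming
#'   data frame.
#' @return a data frame.
#' @export
si_table <- function(dists) {
  if (is.data.frame(dists)) {
    need <- c("fossil_id", "mean_si", "lo95", "hi95")
    if (!all(need %in% names(dists)))
      stop("data frame must have columns: ", paste(need, collapse = ", "))
    return(dists)
  }
  if (inherits(dists, "si_dist")) dists <- list(dists)
  data.frame(
    fossil_id = vapply(dists, `[[`, character(1), "fossil_id"),
    n_trees = vapply(dists, function(d) as.integer(d$n_trees), integer(1)),
    mean_si = vapply(dists, `[[`, numeric(1), "mean"),
    lo95 = vapply(dists, `[[`, numeric(1), "lo"),
    hi95 = vapply(dists, `[[`, numeric(1), "hi"),
    interval_kind = vapply(dists, `[[`, character(1), "interval_kind"),
    stringsAsFactors = FALSE)
}
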