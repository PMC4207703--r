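#' Cross-validate fossil calibrations against a posterior tree sample
#'
#' The central fitting function: given a posterior sample of uncalibrated
#' ultrametric trees and a set of candidate fossil constraints, it
#' (i) computes each fossil's empirical scaling-factor distribution over one
#' shared subsample of trees, (ii) excludes candidates whose implied root
#' ages consistently exceed `max_age` and selects the internally consistent
#' set by 95% interval overlap with the highest-coverage fossil, and
#' (iii) builds offset-lognormal calibration priors for the retained fossils
#' under each taphonomic-bias scenario, checking them against the
#' stratigraphic upper bound computed from the oldest retained fossil and the
#' size of the consistent set.
#'
#' @param sample a [tree_sample()] of rooted ultrametric trees
#'   (substitutions/site or Ma; the scaling factor is scale-invariant).
#' @param fossils a list of [fossil_constraint()] objects (or a path read via
#'   [read_fossil_table()]).
#' @param n_trees number of trees used per fossil (default 1000, capped at
#'   the sample size); drawn uniformly without replacement, one draw shared
#'   by all fossils.
#' @param max_age outlier bound in Ma (default 310, the age of the earliest
#'   known conifers).
#' @param interval_kind,level see [si_distribution()].
#' @param offset_fractions named numeric vector of prior-median offsets as
#'   fractions of the fossil age; default `c(plus10 = 0.1, plus50 = 0.5)`.
#' @param sigma log-space SD of every calibration prior, default 0.5.
#' @param confidence confidence for the stratigraphic bound, default 0.95.
#' @param exponent_denominator see [marshall_upper_bound()].
#' @param seed RNG seed for the tree subsample (required when subsampling).
#' @return an object of class `fossil_cv`; see [print.fossil_cv()],
#'   [summary.fossil_cv()], [coef.fossil_cv()], [plot.fossil_cv()].
#' @export
fossil_cv <- function(sample, fossils, n_trees = 1000, max_age = 310,
                      interval_kind = c("hpd", "central"), level = 0.95,
                      offset_fractions = c(plus10 = 0.1, plus50 = 0.5),
                      sigma = 0.5, confidence = 0.95,
                      exponent_denominator = c("n", "n_minus_1"),
                      seed = NULL) {
  interval_kind <- match.arg(interval_kind)
  exponent_denominator <- match.arg(exponent_denominator)
  stopifnot(inherits(sample, "tree_sample"))
  if (is.character(fossils)) fossils <- read_fossil_table(fossils)
  if (inherits(fossils, "fossil_constraint")) fossils <- list(fossils)
  n <- length(sample)
  n_trees <- min(n_trees, n)
  indices <- if (n_trees == n) seq_len(n) else {
    if (is.null(seed)) stop("seed is required when subsampling trees")
    with_seed(seed, sample.int(n, n_trees, replace = FALSE))
  }
  dists <- lapply(fossils, function(f)
    si_distribution(sample, f, interval_kind = interval_kind, level = level,
                    indices = indices))
  names(dists) <- vapply(fossils, `[[`, character(1), "id")
  tab <- si_table(dists)
  sel <- select_consistent(tab, max_age = max_age)
  retained_fossils <- fossils[match(sel$retained,
                                    vapply(fossils, `[[`, character(1), "id"))]
  oldest <- max(vapply(retained_fossils, `[[`, numeric(1), "min_age"))
  bound <- marshall_upper_bound(oldest, sel$n_retained, confidence,
                                exponent_denominator)
  priors <- list()
  for (sc in names(offset_fractions))
    for (f in retained_fossils)
      priors[[length(priors) + 1L]] <-
        build_prior(f, offset_fractions[[sc]], sigma = sigma, scenario = sc)
  structure(list(si = dists, table = tab, selection = sel,
                 priors = priors,
                 prior_table = prior_table(priors, bound = bound,
                                           level = level),
                 marshall_bound = bound, oldest_fossil_age = oldest,
                 n_trees = n_trees, seed = seed, level = level,
                 interval_kind = interval_kind, max_age = max_age,
                 call = match.call()),
            class = "fossil_cv")
}

#' @rdname fossil_cv
#' @param x,object a `fossil_cv` object.
#' @param ... unused.
#' @export
print.fossil_cv <- function(x, ...) {
  cat(sprintf("fossil calibration cross-validation (%d candidates, %d trees)\n",
              length(x$si), x$n_trees))
  print(x$selection)
  cat(sprintf(" stratigraphic upper bound: %.4g Ma (oldest retained fossil %g Ma, n = %d)\n",
              x$marshall_bound, x$oldest_fossil_age,
              x$selection$n_retained))
  invisible(x)
}

#' @rdname fossil_cv
#' @export
summary.fossil_cv <- function(object, ...) {
  structure(list(si = object$table[, setdiff(names(object$table), "reason")],
                 selection = object$selection,
                 priors = object$prior_table,
                 marshall_bound = object$marshall_bound),
            class = "summary.fossil_cv")
}

#' @export
print.summary.fossil_cv <- function(x, ...) {
  cat("Empirical scaling factors (implied root ages, Ma):\n")
  print(x$si, row.names = FALSE, digits = 4)
  cat("\n")
  print(x$selection)
  cat("\nCalibration priors for the consistent set:\n")
  print(x$priors, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname fossil_cv
#' @export
coef.fossil_cv <- function(object, ...) {
  stats::setNames(object$table$mean_si, object$table$fossil_id)
}

#' @rdname fossil_cv
#' @details `plot()` draws each fossil's mean and 95% interval of the implied
#'   root age on a log axis, marks the outlier bound, and colours the
#'   reference, retained and excluded candidates differently.
#' @export
plot.fossil_cv <- function(x, ...) {
  tab <- x$table
  k <- nrow(tab)
  cols <- c(reference = "#D55E00", retained = "#0072B2",
            outlier = "grey55", nonoverlapping = "grey30")[tab$status]
  graphics::plot(NA, xlim = range(c(tab$lo95, tab$hi95, x$max_age)),
                 ylim = c(0.5, k + 0.5), log = "x",
                 xlab = "implied root age S_i (Ma)", ylab = "",
                 yaxt = "n", ...)
  graphics::axis(2, at = seq_len(k), labels = tab$fossil_id, las = 1)
  graphics::abline(v = x$max_age, lty = 2)
  graphics::segments(tab$lo95, seq_len(k), tab$hi95, seq_len(k),
                     col = cols, lwd = 2)
  graphics::points(tab$mean_si, seq_len(k), pch = 19, col = cols)
  graphics::legend("topright", bty = "n", pch = 19,
                   col = c("#D55E00", "#0072B2", "grey55"),
                   legend = c("reference", "retained", "excluded"))
  invisible(x)
}

# parse a key=value run-configuration file into a list (numbers coerced,
# comma-separated values split)
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    key <- trimws(p[[1]])
    val <- trimws(paste(p[-1], collapse = "="))
    if (grepl(",", val)) val <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[order(names(config))]), tf)
  unname(tools::md5sum(tf))
}

#' Run the full calibration cross-validation pipeline
#'
#' File-level driver wiring the stages end to end: read the tree sample(s),
#' compute convergence diagnostics, fit [fossil_cv()] (scaling factors,
#' consistent-set selection, priors, stratigraphic bound), and — when dated
#' scenario samples are supplied — summarize node ages across scenarios.
#' Every output table is tab-separated with a header comment recording the
#' package version, the seed and a hash of the configuration, so reruns with
#' identical inputs are byte-identical.
#'
#' @param config a named list, or the path of a `key=value` text file.
#'   Recognized fields: `trees` (one or more tree file paths; several paths
#'   are treated as independent runs and pooled after burn-in), `format`,
#'   `burnin`, `fossils` (fossil table path or a list of
#'   [fossil_constraint()]), `n_trees`, `max_age`, `interval_kind`, `level`,
#'   `offset_fractions`, `sigma`, `confidence`, `exponent_denominator`,
#'   `seed`, `out` (output directory), and optionally `scenario_samples`
#'   (named list of dated [tree_sample()]s or file paths), `clades` (named
#'   list of taxon sets), `min_pp`.
#' @return invisibly, a list with the fitted `fossil_cv` object, the
#'   diagnostics, the node-age summary (or `NULL`) and the paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  get_cfg <- function(key, default) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  seed <- get_cfg("seed", NULL)
  out_dir <- get_cfg("out", NULL)
  header <- sprintf("calcross %s; seed=%s; config=%s", pkg_version(),
                    if (is.null(seed)) "none" else seed,
                    config_hash(config[setdiff(names(config), "out")]))

  runs <- stage("read", {
    paths <- config$trees
    if (is.null(paths)) stop("config field 'trees' is required")
    lapply(paths, read_trees, format = get_cfg("format", "auto"),
           burnin = get_cfg("burnin", 0))
  })
  pooled <- stage("read", {
    if (length(runs) == 1L) runs[[1L]]
    else tree_sample(do.call(c, lapply(runs, function(r)
      unclass(r$trees))), unit = runs[[1L]]$unit,
      source = "pooled runs", burnin = runs[[1L]]$burnin)
  })

  diag <- stage("diagnostics", {
    root_ess <- tryCatch(
      ess(vapply(pooled$trees, function(tr)
        node_ages(tr)[ape::Ntip(tr) + 1L], numeric(1))),
      error = function(e) NA_real_)
    asdsf_val <- if (length(runs) >= 2L)
      asdsf(runs[[1L]], runs[[2L]], min_freq = get_cfg("min_freq", 0.1))
    else NA_real_
    ev <- c(root_height = root_ess)
    diagnostics_report(ev[!is.na(ev)], asdsf_val)
  })

  fossils <- stage("fossils", {
    f <- config$fossils
    if (is.null(f)) stop("config field 'fossils' is required")
    if (is.character(f)) read_fossil_table(f) else f
  })

  fit <- stage("scaling/select/priors", {
    fossil_cv(pooled, fossils,
              n_trees = get_cfg("n_trees", 1000),
              max_age = get_cfg("max_age", 310),
              interval_kind = get_cfg("interval_kind", "hpd"),
              level = get_cfg("level", 0.95),
              offset_fractions = get_cfg("offset_fractions",
                                         c(plus10 = 0.1, plus50 = 0.5)),
              sigma = get_cfg("sigma", 0.5),
              confidence = get_cfg("confidence", 0.95),
              exponent_denominator = get_cfg("exponent_denominator", "n"),
              seed = seed)
  })

  stage("warnings", {
    # flag calibration clades that are not consistently monophyletic
    for (f in fossils) {
      pp <- clade_posterior(pooled, f$taxon_set)
      if (pp < get_cfg("min_pp", 0.75))
        message(sprintf(
          "[warn] calibration clade '%s' monophyletic in only %.0f%% of trees",
          f$id, 100 * pp))
    }
  })

  ages <- NULL
  if (!is.null(config$scenario_samples) && !is.null(config$clades)) {
    ages <- stage("summarize", {
      ss <- lapply(config$scenario_samples, function(s)
        if (is.character(s)) read_trees(s, burnin = get_cfg("burnin", 0),
                                        unit = "Ma") else s)
      out <- summarize_scenarios(ss, config$clades,
                                 level = get_cfg("level", 0.95),
                                 min_pp = get_cfg("min_pp", 0.75))
      for (i in which(out$low_pp))
        message(sprintf(
          "[warn] clade '%s' has posterior probability %.2f (< %g) in scenario '%s'",
          out$clade[i], out$pp[i], get_cfg("min_pp", 0.75), out$scenario[i]))
      out
    })
  }

  paths <- character(0)
  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      w <- function(df, name) {
        p <- file.path(out_dir, name)
        write_tsv(df, p, header_comment = header)
        p
      }
      paths <- c(
        w(fit$table, "si.tsv"),
        w(fit$selection$table, "selection.tsv"),
        w(fit$prior_table, "priors.tsv"),
        w(data.frame(parameter = names(diag$ess), ess = as.numeric(diag$ess),
                     asdsf = diag$asdsf, stringsAsFactors = FALSE),
          "diagnostics.tsv"))
      if (!is.null(ages)) paths <- c(paths, w(ages, "node_ages.tsv"))
    })
  }
  invisible(list(fit = fit, diagnostics = diag, node_ages = ages,
                 paths = paths))
}
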