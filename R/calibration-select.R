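#' Exclude calibrations whose scaling factors are implausibly old
#'
#' A candidate is an outlier when its whole 95% interval lies above
#' `max_age`, i.e. its interval lower bound strictly exceeds the bound: the
#' implied root ages *consistently* exceed the oldest acceptable age. The
#' default bound, 310 Ma, is the age of the earliest known conifer fossils,
#' the natural cap when the root is a conifer clade.
#'
#' @param dists scaling-factor distributions: a list of `si_dist` objects or
#'   a data frame as produced by [si_table()].
#' @param max_age upper plausibility bound in Ma (default 310).
#' @return a list with character vectors `excluded` and `retained`
#'   (fossil ids).
#' @export
exclude_outliers <- function(dists, max_age = 310) {
  if (!is.numeric(max_age) || max_age <= 0) stop("max_age must be > 0")
  tab <- si_table(dists)
  if (nrow(tab) == 0L) stop("no scaling-factor distributions supplied")
  out <- tab$lo95 > max_age
  list(excluded = tab$fossil_id[out], retained = tab$fossil_id[!out])
}

#' Select the internally consistent fossil calibration set
#'
#' After dropping outliers (see [exclude_outliers()]), the reference is the
#' remaining fossil with the highest mean scaling factor — the candidate with
#' the highest apparent coverage. The consistent set is the reference plus
#' every other non-outlier whose 95% interval overlaps the reference's
#' interval (closed intervals: `lo_a <= hi_b` and `lo_b <= hi_a`). Overlap is
#' assessed pairwise against the reference only; no minimum overlap fraction
#' is required by default.
#'
#' @inheritParams exclude_outliers
#' @param overlap_fraction minimum required overlap, measured as intersection
#'   length divided by the shorter interval's length. The default 0 accepts
#'   any non-empty (including point) intersection.
#' @return an object of class `consistency_selection` with fields
#'   `candidates`, `excluded_outliers` (data frame of id + reason),
#'   `reference_id`, `retained`, `n_retained`, `max_age_bound`, `table`
#'   (the input table with a `status` column).
#' @export
#' @examples
#' tab <- data.frame(fossil_id = c("a", "b", "c"),
#'                   mean_si = c(150, 368, 900),
#'                   lo95 = c(120, 198, 500), hi95 = c(220, 565, 1300))
#' select_consistent(tab, max_age = 310)
select_consistent <- function(dists, max_age = 310, overlap_fraction = 0) {
  tab <- si_table(dists)
  if (anyDuplicated(tab$fossil_id)) stop("duplicated fossil ids")
  ex <- exclude_outliers(tab, max_age)
  if (length(ex$retained) == 0L)
    stop("all candidates excluded as outliers (interval lower bounds: ",
         paste(sprintf("%s=%g", tab$fossil_id, tab$lo95), collapse = ", "),
         ")")
  nonout <- tab[tab$fossil_id %in% ex$retained, , drop = FALSE]
  # reference: highest mean; ties by larger interval high, then id
  ord <- order(-nonout$mean_si, -nonout$hi95, nonout$fossil_id)
  ref <- nonout[ord[1L], ]
  keep <- vapply(seq_len(nrow(nonout)), function(i) {
    lo <- nonout$lo95[i]; hi <- nonout$hi95[i]
    if (lo > ref$hi95 || ref$lo95 > hi) return(FALSE)
    if (overlap_fraction <= 0) return(TRUE)
    inter <- min(hi, ref$hi95) - max(lo, ref$lo95)
    shorter <- max(.Machine$double.eps, min(hi - lo, ref$hi95 - ref$lo95))
    inter / shorter >= overlap_fraction
  }, logical(1))
  retained <- sort(nonout$fossil_id[keep])
  status <- ifelse(tab$fossil_id %in% ex$excluded, "outlier",
                   ifelse(tab$fossil_id == ref$fossil_id, "reference",
                          ifelse(tab$fossil_id %in% retained, "retained",
                                 "nonoverlapping")))
  reason <- ifelse(status == "outlier",
                   sprintf("95%% interval entirely above %g Ma", max_age),
                   ifelse(status == "nonoverlapping",
                          "95% interval disjoint from reference", ""))
  tab$status <- status
  tab$reason <- reason
  structure(list(candidates = tab$fossil_id,
                 excluded_outliers = data.frame(
                   fossil_id = tab$fossil_id[status != "retained" &
                                               status != "reference"],
                   reason = reason[status != "retained" &
                                     status != "reference"],
                   stringsAsFactors = FALSE),
                 reference_id = ref$fossil_id,
                 retained = retained,
                 n_retained = length(retained),
                 max_age_bound = max_age,
                 table = tab),
            class = "consistency_selection")
}

#' @export
print.consistency_selection <- function(x, ...) {
  cat(sprintf("consistent calibration set: %d of %d candidates retained\n",
              x$n_retained, length(x$candidates)))
  cat(sprintf(" reference (highest mean S_i): %s\n", x$reference_id))
  cat(" retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$excluded_outliers) > 0) {
    cat(" excluded:\n")
    for (i in seq_len(nrow(x$excluded_outliers)))
      cat(sprintf("   %s: %s\n", x$excluded_outliers$fossil_id[i],
                  x$excluded_outliers$reason[i]))
  }
  invisible(x)
}
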