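#' Posterior samples of rooted ultrametric trees
#'
#' A `tree_sample` is an ordered collection of rooted trees over a common tip
#' set, tagged with the unit of its branch lengths: `"substitutions"` for
#' uncalibrated clock trees (substitutions/site) or `"Ma"` for dated trees
#' (millions of years). All downstream computation recomputes node ages from
#' branch lengths; annotations carried by the input files are ignored.
#'
#' @param trees a `multiPhylo` object, a list of `phylo` objects, or a single
#'   `phylo`. Every tree must be rooted, with unique tip labels, non-negative
#'   branch lengths, and the same tip-label set as the first tree.
#' @param unit branch-length unit, `"substitutions"` or `"Ma"`.
#' @param source free-text label recording where the sample came from
#'   (e.g. a run id or file name).
#' @param burnin burn-in fraction already applied to `trees` (recorded, not
#'   re-applied). Must lie in `[0, 1)`.
#' @param tol relative ultrametricity tolerance used to validate each tree;
#'   trees failing it are rejected, not repaired.
#'
#' @return An object of class `tree_sample`: a list with elements `trees`
#'   (`multiPhylo`), `unit`, `source` and `burnin`.
#' @seealso [read_trees()] to build one from a Newick or NEXUS file.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' ts <- tree_sample(list(tr, tr), unit = "Ma")
#' length(ts)
tree_sample <- function(trees, unit = c("substitutions", "Ma"), source = "",
                        burnin = 0, tol = 1e-4) {
  unit <- match.arg(unit)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unname(as.list(trees))
  if (length(trees) == 0L) stop("empty tree sample")
  if (!all(vapply(trees, inherits, logical(1), "phylo")))
    stop("all elements must be 'phylo' trees")
  if (!is.numeric(burnin) || burnin < 0 || burnin >= 1)
    stop("burnin must be a fraction in [0, 1)")
  ref <- sort(trees[[1L]]$tip.label)
  if (anyDuplicated(ref)) stop("duplicated tip labels in tree 1")
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!ape::is.rooted(tr))
      stop(sprintf("tree %d is not rooted", i))
    if (is.null(tr$edge.length))
      stop(sprintf("tree %d has no branch lengths", i))
    if (any(tr$edge.length < 0))
      stop(sprintf("tree %d has negative branch lengths", i))
    if (!identical(sort(tr$tip.label), ref))
      stop(sprintf("tree %d has a different tip set from tree 1", i))
    if (!check_ultrametric(tr, tol = tol))
      stop(sprintf("tree %d is not ultrametric within relative tolerance %g",
                   i, tol))
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, unit = unit, source = source, burnin = burnin),
            class = "tree_sample")
}

#' @export
length.tree_sample <- function(x) length(x$trees)

#' @export
`[.tree_sample` <- function(x, i) {
  structure(list(trees = structure(unclass(x$trees)[i], class = "multiPhylo"),
                 unit = x$unit, source = x$source, burnin = x$burnin),
            class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("tree sample: %d rooted ultrametric trees, %d tips, unit = %s\n",
              length(x$trees), length(x$trees[[1L]]$tip.label), x$unit))
  if (nzchar(x$source)) cat(" source:", x$source, "\n")
  if (x$burnin > 0) cat(sprintf(" burn-in fraction applied: %g\n", x$burnin))
  invisible(x)
}

#' Read a posterior tree sample from a Newick or NEXUS file
#'
#' Reads trees in file order, drops the first `floor(burnin * N)` as burn-in,
#' maps NEXUS translate-table indices back to tip labels, and strips (does not
#' parse) bracketed metadata comments. The result is validated as a set of
#' rooted ultrametric trees over one tip set.
#'
#' @param path path to the tree file.
#' @param format `"newick"` (one tree per line), `"nexus"` (TREES block,
#'   optional TRANSLATE), or `"auto"` to sniff a `#NEXUS` header.
#' @param burnin fraction of initial trees to discard, in `[0, 1)`.
#' @inheritParams tree_sample
#' @return a [tree_sample()].
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus"),
                       burnin = 0, unit = c("substitutions", "Ma"),
                       source = basename(path), tol = 1e-4) {
  format <- match.arg(format)
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (format == "auto") {
    head1 <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(head1, "#NEXUS")) "nexus" else "newick"
  }
  trees <- if (format == "nexus") {
    out <- ape::read.nexus(path)
    if (inherits(out, "phylo")) list(out) else unname(as.list(out))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(seq_along(lines), function(i) {
      tr <- tryCatch(
        suppressWarnings(ape::read.tree(text = strip_nhx_comments(lines[[i]]))),
        error = function(e) NULL)
      if (!inherits(tr, "phylo"))
        stop(sprintf("malformed Newick at tree %d", i), call. = FALSE)
      tr
    })
  }
  trees <- lapply(trees, function(tr) {
    tr$node.label <- NULL  # annotations are ignored by computation
    tr
  })
  n <- length(trees)
  drop <- floor(burnin * n)
  if (drop >= n) stop("burn-in removes every tree")
  if (drop > 0) trees <- trees[-seq_len(drop)]
  tree_sample(trees, unit = unit, source = source, burnin = burnin, tol = tol)
}

# remove [...] comment blocks (BEAST/NHX metadata) from a newick string
strip_nhx_comments <- function(x) gsub("\\[[^]]*\\]", "", x)

#' Write a tree sample to Newick or NEXUS
#'
#' Newick output has one tree per line; NEXUS output uses a TREES block with a
#' TRANSLATE table. Branch lengths are written with 10 significant digits so a
#' write/read round trip preserves them.
#'
#' @param sample a [tree_sample()] or `multiPhylo`.
#' @param path output file path.
#' @param format `"newick"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_trees <- function(sample, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  trees <- if (inherits(sample, "tree_sample")) sample$trees else sample
  if (format == "newick") {
    ape::write.tree(trees, file = path, digits = 10)
  } else {
    ape::write.nexus(trees, file = path, translate = TRUE, digits = 10)
  }
  invisible(path)
}

# ages (depths) of every node: distance to any descendant tip.
# returns a vector indexed by ape node number (tips first, then internals).
node_ages <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  ages <- max(d[seq_len(ape::Ntip(tree))]) - d
  # tips of an ultrametric tree sit at age ~0; clear float dust
  ages[abs(ages) < .Machine$double.eps * 64 * max(1, max(ages))] <- 0
  ages
}

#' Test ultrametricity of a rooted tree
#'
#' A tree is ultrametric within relative tolerance `tol` when all root-to-tip
#' path lengths agree: `(max - min) / max <= tol`.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param tol relative tolerance (default `1e-4`).
#' @return `TRUE` or `FALSE`. A single-tip tree is trivially ultrametric.
#' @export
#' @examples
#' check_ultrametric(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
#' check_ultrametric(ape::read.tree(text = "((A:1,B:2):1,C:2);"))
check_ultrametric <- function(tree, tol = 1e-4) {
  if (ape::Ntip(tree) < 2L) return(TRUE)
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  mx <- max(d)
  if (mx == 0) return(TRUE)
  (mx - min(d)) / mx <= tol
}

# MRCA node number of a set of >= 2 tip labels, computed per tree regardless
# of whether the set is monophyletic in that tree.
mrca_node <- function(tree, taxon_set) {
  taxon_set <- unique(as.character(taxon_set))
  unknown <- setdiff(taxon_set, tree$tip.label)
  if (length(unknown) > 0)
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (length(taxon_set) < 2L)
    stop("a calibration must define an internal node: need >= 2 tips")
  if (length(taxon_set) == ape::Ntip(tree)) return(ape::Ntip(tree) + 1L)
  ape::getMRCA(tree, taxon_set)
}

#' Relative depth of the MRCA of a taxon set
#'
#' The depth of a node is its distance to any descendant tip; the relative
#' depth divides by the root depth, so the root has relative depth 1 exactly.
#' The MRCA is resolved per tree, whether or not the taxon set is
#' monophyletic in that tree, which is the convention needed when summing
#' over a posterior sample of topologies.
#'
#' @param tree a rooted ultrametric `phylo`.
#' @param taxon_set character vector of at least two tip labels.
#' @return the MRCA's relative depth, a fraction in `(0, 1]`.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' relative_node_depth(tr, c("A", "B"))   # 0.5
#' relative_node_depth(tr, c("A", "C"))   # 1: MRCA is the root
relative_node_depth <- function(tree, taxon_set) {
  ages <- node_ages(tree)
  node <- mrca_node(tree, taxon_set)
  root_age <- ages[ape::Ntip(tree) + 1L]
  if (root_age <= 0) stop("tree has zero root depth")
  rd <- ages[node] / root_age
  if (rd <= 0) stop("taxon set resolves to a node of zero depth")
  rd
}

#' Fossil minimum-age constraints
#'
#' A fossil constraint binds a hard minimum age (Ma) to the most recent
#' common ancestor of a defining taxon set. Stem-node constraints are encoded
#' purely by the taxon set: include the sister lineage's tips, and the MRCA
#' is the stem node. No crown/stem flag exists.
#'
#' @param id short identifier used in tables and reports.
#' @param taxon_set character vector of at least two tip labels defining the
#'   calibrated node as their MRCA.
#' @param min_age minimum age of the clade in Ma; must be positive.
#' @param fossil_name free-text name of the fossil taxon.
#' @return an object of class `fossil_constraint`.
#' @export
fossil_constraint <- function(id, taxon_set, min_age, fossil_name = "") {
  taxon_set <- unique(as.character(taxon_set))
  if (length(taxon_set) < 2L)
    stop("taxon_set must contain at least 2 tip labels")
  if (!is.numeric(min_age) || length(min_age) != 1L || min_age <= 0)
    stop("min_age must be a single positive number (Ma)")
  structure(list(id = as.character(id), fossil_name = fossil_name,
                 taxon_set = taxon_set, min_age = as.numeric(min_age)),
            class = "fossil_constraint")
}

#' @export
print.fossil_constraint <- function(x, ...) {
  cat(sprintf("fossil constraint '%s'%s: min age %g Ma, node = MRCA of {%s}\n",
              x$id, if (nzchar(x$fossil_name)) paste0(" (", x$fossil_name, ")")
              else "", x$min_age, paste(x$taxon_set, collapse = ", ")))
  invisible(x)
}

#' Read a fossil-constraint table
#'
#' Expects a tab-separated file with a header row and columns `id`,
#' `fossil_name`, `min_age_ma` and `taxa` (comma-separated tip labels).
#' Lines starting with `#` are treated as comments.
#'
#' @param path path to the TSV file.
#' @return a list of [fossil_constraint()] objects, named by id.
#' @export
read_fossil_table <- function(path) {
  if (!file.exists(path)) stop("fossil table not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "fossil_name", "min_age_ma", "taxa")
  if (!all(need %in% names(df)))
    stop("fossil table must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    fossil_constraint(df$id[i], trimws(strsplit(df$taxa[i], ",")[[1]]),
                      df$min_age_ma[i], df$fossil_name[i]))
  names(out) <- df$id
  out
}

#' Write a fossil-constraint table
#'
#' @param fossils a list of [fossil_constraint()] objects.
#' @param path output TSV path.
#' @param header_comment optional `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_fossil_table <- function(fossils, path, header_comment = NULL) {
  df <- data.frame(
    id = vapply(fossils, `[[`, character(1), "id"),
    fossil_name = vapply(fossils, `[[`, character(1), "fossil_name"),
    min_age_ma = vapply(fossils, `[[`, numeric(1), "min_age"),
    taxa = vapply(fossils, function(f) paste(f$taxon_set, collapse = ","),
                  character(1)),
    stringsAsFactors = FALSE)
  write_tsv(df, path, header_comment)
  invisible(path)
}

# TSV writer shared by all tabular outputs: header row, optional comment lines
write_tsv <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
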