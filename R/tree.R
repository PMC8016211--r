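# Distance-based tree construction, bipartitions, nonparametric bootstrap
# clade supports, Newick I/O and rooting. Trees are ape "phylo" objects;
# supports are kept as a bipartition-keyed map so they survive re-rooting.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via [ape::nj()]). Negative branch-length
#' estimates are clamped to zero with the deficit transferred to the
#' adjacent branches so path lengths through the node are preserved where
#' possible.
#'
#' @param dm Square symmetric distance matrix with labels as dimnames.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  rg_check(nrow(dm) >= 3, "need at least 3 taxa", "parameter_error")
  rg_check(isTRUE(all.equal(dm, t(dm), tolerance = 1e-8,
                            check.attributes = FALSE)),
           "distance matrix must be symmetric", "validation_error")
  rg_check(!is.null(rownames(dm)), "distance matrix needs labels",
           "validation_error")
  tree <- ape::nj(as.dist(dm))
  clamp_negative_edges(tree)
}

# Zero out negative edges; add the deficit to the other edges incident to
# the child node so distances across the node are least disturbed.
clamp_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[which.min(tree$edge.length[neg])]
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    child <- tree$edge[e, 2]
    adj <- which(tree$edge[, 1] == child)
    if (length(adj)) {
      tree$edge.length[adj] <- tree$edge.length[adj] + deficit
      tree$edge.length[adj] <- pmax(tree$edge.length[adj], 0)
    }
  }
  tree
}

.bip_key <- function(labels) paste(sort(labels), collapse = "|")

#' Non-trivial bipartitions of a tree
#'
#' One canonical bipartition per internal edge: the split is represented by
#' its smaller-side leaf set (ties broken toward the side holding the
#' alphabetically first leaf), so equal splits compare equal regardless of
#' rooting or leaf order. Trivial single-leaf splits are excluded.
#'
#' @param tree A `phylo` with at least 4 leaves for non-trivial output.
#' @return Character vector of canonical keys (leaf labels sorted, joined
#'   by `|`); attribute `"sides"` holds the leaf-set list.
#' @export
bipartitions <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  unrooted <- ape::unroot(tree)
  desc <- phangorn::Descendants(unrooted, type = "tips")
  ntip <- length(unrooted$tip.label)
  internal <- setdiff(unique(unrooted$edge[, 2]), seq_len(ntip))
  sides <- list()
  for (node in internal) {
    clade <- unrooted$tip.label[desc[[node]]]
    if (length(clade) <= 1 || length(clade) >= n - 1) next
    other <- setdiff(tips, clade)
    side <- if (length(clade) < length(other)) clade
      else if (length(other) < length(clade)) other
      else if (min(tips) %in% clade) clade else other
    sides[[.bip_key(side)]] <- sort(side)
  }
  keys <- unique(names(sides))
  structure(keys, sides = sides[keys])
}

#' Bootstrap bipartition supports
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with `builder`, and scores each internal edge of the reference
#' tree by the percentage of replicate trees containing the same
#' bipartition.
#'
#' @param aln A [locus_alignment()].
#' @param builder Deterministic function `alignment -> phylo`; default is
#'   neighbor joining on the p-distance matrix.
#' @param n_replicates Number of bootstrap replicates (conventional: 100).
#' @param seed Integer seed; replicates are reproducible given a seed.
#' @return List of class `bootstrap_supports`: `tree` (reference, with
#'   percentages as internal node labels), `supports` (bipartition key ->
#'   percentage), `counts`, `n_replicates`.
#' @export
bootstrap_supports <- function(aln, builder = nj_builder(),
                               n_replicates = 100, seed = 1) {
  rg_check(n_replicates >= 1, "n_replicates must be >= 1", "parameter_error")
  ref <- builder(aln)
  ref_bips <- bipartitions(ref)
  counts <- setNames(integer(length(ref_bips)), ref_bips)
  set.seed(seed)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(aln$n_columns, aln$n_columns, replace = TRUE)
    rep_aln <- locus_alignment(aln$mat[, cols, drop = FALSE],
                               locus = aln$locus)
    rep_tree <- builder(rep_aln)
    hits <- intersect(ref_bips, bipartitions(rep_tree))
    counts[hits] <- counts[hits] + 1L
  }
  supports <- 100 * counts / n_replicates
  structure(list(tree = attach_supports(ref, supports),
                 supports = supports, counts = counts,
                 n_replicates = n_replicates),
            class = "bootstrap_supports")
}

#' @export
print.bootstrap_supports <- function(x, ...) {
  cat(sprintf("<bootstrap_supports> %d replicates, %d internal edges, median support %.0f%%\n",
              x$n_replicates, length(x$supports), stats::median(x$supports)))
  invisible(x)
}

#' Default tree builder for bootstrapping
#'
#' @param model Distance used: `"p"` (uncorrected) or one of the corrected
#'   models of [corrected_distance()].
#' @return A function `alignment -> phylo` suitable for
#'   [bootstrap_supports()].
#' @export
nj_builder <- function(model = "p") {
  function(aln) {
    d <- if (identical(model, "p")) p_distance(aln)
         else corrected_distance(aln, model)
    neighbor_joining(d)
  }
}

#' Write bipartition supports onto a tree's internal node labels
#'
#' Supports are matched by canonical bipartition, so the map can be applied
#' to any re-rooting of the same topology. Unmatched internal nodes get an
#' empty label.
#'
#' @param tree A `phylo`.
#' @param supports Named numeric vector, bipartition key -> percentage.
#' @export
attach_supports <- function(tree, supports) {
  tips <- tree$tip.label
  desc <- phangorn::Descendants(tree, type = "tips")
  n <- length(tips)
  labels <- character(tree$Nnode)
  for (i in seq_len(tree$Nnode)) {
    node <- n + i
    clade <- tips[desc[[node]]]
    if (length(clade) <= 1 || length(clade) >= n - 1) next
    other <- setdiff(tips, clade)
    side <- if (length(clade) < length(other)) clade
      else if (length(other) < length(clade)) other
      else if (min(tips) %in% clade) clade else other
    key <- .bip_key(side)
    if (key %in% names(supports))
      labels[i] <- format(supports[[key]], trim = TRUE)
  }
  tree$node.label <- labels
  tree
}

#' Read / write Newick trees
#'
#' Supports, if present, travel as internal node labels. A round trip
#' preserves topology, branch lengths (to printed precision) and supports.
#'
#' @param path File path.
#' @return `read_newick`: a `phylo`.
#' @export
read_newick <- function(path) {
  rg_check(file.exists(path), sprintf("file not found: %s", path), "io_error")
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(path)),
    error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    rg_abort(sprintf("malformed Newick in %s", path), "parse_error")
  }
  tree
}

#' @rdname read_newick
#' @param tree A `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Root a tree for clade logic
#'
#' Outgroup rooting when an outgroup id is supplied, midpoint rooting
#' otherwise.
#'
#' @param tree A `phylo`.
#' @param outgroup Optional tip label (or vector of labels).
#' @export
root_tree <- function(tree, outgroup = NULL) {
  if (!is.null(outgroup)) {
    rg_check(all(outgroup %in% tree$tip.label),
             "outgroup not among tip labels", "parameter_error")
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else {
    phangorn::midpoint(tree)
  }
}
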