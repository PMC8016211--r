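# Reference-anchored genospecies assignment, genospecies x symbiovar
# cross-tabulation, and the collection-composition test.

#' Assign query strains to reference-anchored clades
#'
#' Implements the smallest-supported-clade rule: for each query leaf, walk
#' ancestors rootward and anchor at the first clade whose support exceeds
#' `support_threshold` and which contains at least one reference leaf; the
#' label is the consensus reference species in that clade (ties broken by
#' smallest patristic distance to the query, flagged as ambiguous).
#' Queries whose smallest supported reference-containing clade is the root
#' are unclustered; maximal supported query-only clades of two or more such
#' strains become novel genospecies (`novel:1`, `novel:2`, ... in
#' decreasing size order), the rest keep deterministic
#' `unclustered:<strain_id>` labels.
#'
#' @param tree A rooted `phylo` with bootstrap percentages as internal node
#'   labels (see [bootstrap_supports()], [attach_supports()],
#'   [root_tree()]).
#' @param meta Strain metadata data frame with columns `strain_id`,
#'   `collection` (`"reference"` marks reference leaves) and
#'   `reference_species` (required for references).
#' @param support_threshold Support percentage that a clade must exceed
#'   (conventional value 60).
#' @return A `clade_assignment` data frame: `strain_id`, `label`,
#'   `support`, `anchor_size`, `n_references`, `ambiguous`.
#' @export
assign_clades <- function(tree, meta, support_threshold = 60) {
  rg_check(ape::is.rooted(tree), "tree must be rooted (root_tree())",
           "rooting_required_error")
  if (is.null(tree$node.label)) {
    rg_abort("tree has no support labels", "support_missing_error")
  }
  validate_metadata(meta)
  tips <- tree$tip.label
  n <- length(tips)
  root <- n + 1L
  refs <- meta$strain_id[meta$collection == "reference"]
  ref_species <- stats::setNames(meta$reference_species, meta$strain_id)
  is_ref_tip <- tips %in% refs
  supports <- suppressWarnings(as.numeric(tree$node.label))
  desc <- phangorn::Descendants(tree, type = "tips")
  parent_of <- integer(n + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  node_supported <- function(v) {
    if (v == root) return(TRUE)
    s <- supports[v - n]
    !is.na(s) && s > support_threshold
  }
  node_support_value <- function(v) {
    if (v == root) return(NA_real_)
    supports[v - n]
  }
  patristic <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  dimnames(patristic) <- list(tips, tips)

  queries <- which(!is_ref_tip)
  out <- data.frame(strain_id = tips[queries], label = NA_character_,
                    support = NA_real_, anchor_size = NA_integer_,
                    n_references = 0L, ambiguous = FALSE,
                    stringsAsFactors = FALSE)
  root_anchored <- logical(length(queries))
  for (i in seq_along(queries)) {
    q <- queries[i]
    v <- parent_of[q]
    anchor <- NA_integer_
    repeat {
      clade_refs <- tips[desc[[v]]][is_ref_tip[desc[[v]]]]
      if (node_supported(v) && length(clade_refs) > 0) { anchor <- v; break }
      if (v == root) break
      v <- parent_of[v]
    }
    if (is.na(anchor) || anchor == root) {
      root_anchored[i] <- TRUE
      next
    }
    clade_refs <- tips[desc[[anchor]]][is_ref_tip[desc[[anchor]]]]
    species <- ref_species[clade_refs]
    counts <- sort(table(species), decreasing = TRUE)
    top <- names(counts)[counts == max(counts)]
    if (length(top) > 1) {
      # tie: reference species nearest to the query by patristic distance
      dist_by_sp <- tapply(patristic[tips[q], clade_refs], species, min)
      label <- names(which.min(dist_by_sp[top]))
      out$ambiguous[i] <- TRUE
    } else {
      label <- top
    }
    out$label[i] <- label
    out$support[i] <- node_support_value(anchor)
    out$anchor_size[i] <- length(desc[[anchor]])
    out$n_references[i] <- length(clade_refs)
  }

  # novel genospecies: maximal supported clades made only of root-anchored
  # queries, size >= 2
  unplaced <- out$strain_id[root_anchored]
  if (length(unplaced)) {
    candidate <- list()
    internal_nonroot <- if (tree$Nnode >= 2) (n + 2L):(n + tree$Nnode) else integer(0)
    for (v in internal_nonroot) {
      clade <- tips[desc[[v]]]
      if (length(clade) >= 2 && all(clade %in% unplaced) && node_supported(v))
        candidate[[length(candidate) + 1L]] <- list(node = v, clade = clade)
    }
    if (length(candidate)) {
      sizes <- vapply(candidate, function(x) length(x$clade), integer(1))
      candidate <- candidate[order(-sizes)]
      taken <- character(0)
      novel_n <- 0L
      for (cand in candidate) {
        if (any(cand$clade %in% taken)) next  # keep only maximal clades
        novel_n <- novel_n + 1L
        idx <- match(cand$clade, out$strain_id)
        out$label[idx] <- paste0("novel:", novel_n)
        out$support[idx] <- node_support_value(cand$node)
        out$anchor_size[idx] <- length(cand$clade)
        taken <- c(taken, cand$clade)
      }
    }
    solo <- is.na(out$label) & root_anchored
    out$label[solo] <- paste0("unclustered:", out$strain_id[solo])
  }
  class(out) <- c("clade_assignment", class(out))
  out
}

#' @export
print.clade_assignment <- function(x, ...) {
  cat(sprintf("<clade_assignment> %d strains, %d labels\n",
              nrow(x), length(unique(x$label))))
  print(sort(table(x$label), decreasing = TRUE))
  invisible(x)
}

#' Validate a strain metadata table
#'
#' @param meta Data frame with columns `strain_id`, `collection`
#'   (`current` / `previous` / `reference`), `reference_species` (non-NA
#'   iff reference), and optional `latitude`, `longitude`, `elevation`,
#'   `soil_pH`.
#' @export
validate_metadata <- function(meta) {
  rg_check(all(c("strain_id", "collection") %in% names(meta)),
           "metadata needs strain_id and collection columns",
           "metadata_error")
  rg_check(!anyDuplicated(meta$strain_id), "duplicate strain ids in metadata",
           "metadata_error")
  rg_check(all(meta$collection %in% c("current", "previous", "reference")),
           "collection must be current/previous/reference", "metadata_error")
  if ("reference_species" %in% names(meta)) {
    is_ref <- meta$collection == "reference"
    rg_check(all(!is.na(meta$reference_species[is_ref]) &
                   nzchar(meta$reference_species[is_ref])),
             "reference strains need reference_species", "metadata_error")
    rg_check(all(is.na(meta$reference_species[!is_ref]) |
                   !nzchar(meta$reference_species[!is_ref])),
             "non-reference strains must not carry reference_species",
             "metadata_error")
  } else {
    rg_check(!any(meta$collection == "reference"),
             "reference strains need a reference_species column",
             "metadata_error")
  }
  if ("latitude" %in% names(meta)) {
    ok <- is.na(meta$latitude) | (meta$latitude >= -90 & meta$latitude <= 90)
    rg_check(all(ok), "latitude out of [-90, 90]", "metadata_error")
  }
  if ("longitude" %in% names(meta)) {
    ok <- is.na(meta$longitude) |
      (meta$longitude >= -180 & meta$longitude <= 180)
    rg_check(all(ok), "longitude out of [-180, 180]", "metadata_error")
  }
  if ("soil_pH" %in% names(meta)) {
    ok <- is.na(meta$soil_pH) | (meta$soil_pH >= 0 & meta$soil_pH <= 14)
    rg_check(all(ok), "soil_pH out of [0, 14]", "metadata_error")
  }
  invisible(meta)
}

#' Cross-tabulate genospecies against symbiovars
#'
#' Counts strains per (housekeeping genospecies, symbiotic symbiovar)
#' label pair over the strains present in both assignments; margins are
#' recomputed from the cells. Strains lacking one of the classifications
#' (e.g. no symbiotic locus) are dropped and counted in `n_dropped`.
#'
#' @param assign_hk,assign_sym `clade_assignment` tables (or data frames
#'   with `strain_id` and `label`).
#' @return A `cross_tab`: `counts` matrix, `row_totals`, `col_totals`,
#'   `grand_total`, `n_dropped`.
#' @export
cross_tabulate <- function(assign_hk, assign_sym) {
  shared <- intersect(assign_hk$strain_id, assign_sym$strain_id)
  n_dropped <- length(union(assign_hk$strain_id, assign_sym$strain_id)) -
    length(shared)
  g <- assign_hk$label[match(shared, assign_hk$strain_id)]
  s <- assign_sym$label[match(shared, assign_sym$strain_id)]
  counts <- as.matrix(table(genospecies = g, symbiovar = s))
  structure(list(counts = counts,
                 row_totals = rowSums(counts),
                 col_totals = colSums(counts),
                 grand_total = sum(counts),
                 n_dropped = n_dropped),
            class = "cross_tab")
}

#' Build a cross_tab from a pre-counted matrix
#'
#' @param counts Non-negative integer matrix (genospecies x symbiovars).
#' @export
cross_tab_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  rg_check(all(counts >= 0) && all(counts == round(counts)),
           "counts must be non-negative integers", "parameter_error")
  structure(list(counts = counts, row_totals = rowSums(counts),
                 col_totals = colSums(counts), grand_total = sum(counts),
                 n_dropped = 0L),
            class = "cross_tab")
}

#' @export
print.cross_tab <- function(x, ...) {
  m <- cbind(x$counts, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, x$grand_total))
  print(m)
  if (x$n_dropped > 0)
    cat(sprintf("(%d strains dropped: missing one classification)\n",
                x$n_dropped))
  invisible(x)
}

#' Test for a difference in category composition between groups
#'
#' Fisher's exact test on a groups x categories contingency table; exact
#' enumeration where feasible, otherwise Monte-Carlo with fixed margins.
#'
#' @param counts Contingency table (typically 2 x K: collections x
#'   genospecies).
#' @param method `"auto"` (exact, falling back to Monte-Carlo), `"exact"`
#'   or `"monte_carlo"`.
#' @param n_mc Monte-Carlo replicates.
#' @param seed Seed for the Monte-Carlo path.
#' @return List: `p_value`, `method`.
#' @export
composition_test <- function(counts, method = c("auto", "exact", "monte_carlo"),
                             n_mc = 10000, seed = 1) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  rg_check(sum(counts) > 0, "all-zero table", "degenerate_table_error")
  rg_check(ncol(counts) >= 2 || nrow(counts) >= 2,
           "need at least 2 categories", "parameter_error")
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    # one group or one category left: compositions cannot differ
    return(list(p_value = 1, method = "degenerate"))
  }
  mc <- function() {
    set.seed(seed)
    stats::fisher.test(counts, simulate.p.value = TRUE, B = n_mc)
  }
  res <- switch(method,
    exact = stats::fisher.test(counts, workspace = 2e7),
    monte_carlo = mc(),
    auto = tryCatch(stats::fisher.test(counts, workspace = 2e7),
                    error = function(e) mc()))
  list(p_value = res$p.value,
       method = if (identical(res$method, "Fisher's Exact Test for Count Data"))
         "exact" else "monte_carlo")
}
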