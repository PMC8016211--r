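# Genetic diversity at three levels of genomic hierarchy: nucleotide
# (mean pairwise p-distance), locus (Nei's unbiased haplotype diversity,
# averaged across loci), and species (Shannon / Gini-Simpson over
# genospecies counts), plus allele-sharing distances and a permutation
# test for diversity differences between strain sets.

#' Nucleotide diversity (pi)
#'
#' Mean pairwise proportion of differing sites (pairwise deletion) over
#' all unordered strain pairs in the subset.
#'
#' @param aln A [locus_alignment()].
#' @param strains Optional subset of strain ids (default: all).
#' @return Numeric in `[0, 1]`.
#' @export
nucleotide_diversity <- function(aln, strains = NULL) {
  if (is.null(strains)) strains <- strain_ids(aln)
  rg_check(length(strains) >= 2, "need at least 2 strains",
           "insufficient_data_error")
  sub <- locus_alignment(aln$mat[strains, , drop = FALSE], aln$locus)
  d <- p_distance(sub)
  mean(d[upper.tri(d)])
}

#' Haplotype labels by exact sequence identity
#'
#' Haplotypes are defined by exact sequence identity after masking
#' ambiguity/gap characters to `N` (so strains differing only at masked
#' sites share a haplotype only if the unmasked residues agree).
#'
#' @param aln A [locus_alignment()].
#' @return Named integer vector: strain id -> haplotype index.
#' @export
haplotypes <- function(aln) {
  mat <- aln$mat
  mat[!(mat %in% UNAMBIG)] <- "N"
  keys <- apply(mat, 1, paste, collapse = "")
  stats::setNames(match(keys, unique(keys)), rownames(mat))
}

#' Nei's unbiased haplotype diversity
#'
#' `h = n/(n-1) * (1 - sum(p_i^2))` with `p_i` the haplotype frequencies.
#'
#' @param labels Vector of haplotype labels, one per strain.
#' @return Numeric in `[0, 1]` (the unbiased estimator reaches 1 when all
#'   haplotypes are distinct).
#' @export
haplotype_diversity <- function(labels) {
  n <- length(labels)
  rg_check(n >= 2, "need at least 2 strains", "insufficient_data_error")
  p <- table(labels) / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Mean locus (haplotype) diversity across loci
#'
#' @param loci List of [locus_alignment()] objects over a shared strain
#'   set.
#' @param strains Optional subset of strain ids.
#' @return Mean across loci of [haplotype_diversity()].
#' @export
locus_diversity <- function(loci, strains = NULL) {
  vals <- vapply(loci, function(l) {
    ids <- if (is.null(strains)) strain_ids(l)
           else intersect(strains, strain_ids(l))
    rg_check(length(ids) >= 2, "need at least 2 strains per locus",
             "insufficient_data_error")
    sub <- locus_alignment(l$mat[ids, , drop = FALSE], l$locus)
    haplotype_diversity(haplotypes(sub))
  }, numeric(1))
  mean(vals)
}

#' Allele-sharing distance between multilocus genotypes
#'
#' `d(i, j)` = fraction of co-typed loci at which strains i and j carry
#' different haplotypes.
#'
#' @param loci List of [locus_alignment()] objects; strains need not be
#'   typed at every locus, but every pair must share at least one locus.
#' @return Square symmetric distance matrix over the union of strain ids.
#' @export
allele_sharing_distance <- function(loci) {
  ids <- Reduce(union, lapply(loci, strain_ids))
  haps <- lapply(loci, haplotypes)
  diff_sum <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  typed_sum <- diff_sum
  for (h in haps) {
    typed <- ids %in% names(h)
    tt <- outer(typed, typed, `&`)
    hv <- h[ids]
    dd <- outer(hv, hv, `!=`)
    dd[!tt] <- FALSE
    diff_sum <- diff_sum + dd
    typed_sum <- typed_sum + tt
  }
  off <- upper.tri(typed_sum)
  if (any(typed_sum[off] == 0)) {
    bad <- which(typed_sum == 0 & off, arr.ind = TRUE)
    rg_abort(sprintf("no co-typed locus for pair %s / %s",
                     ids[bad[1, 1]], ids[bad[1, 2]]),
             "undefined_distance_error")
  }
  .as_dist_matrix(diff_sum / typed_sum, ids, "allele-sharing")
}

#' Species-level diversity indices
#'
#' Shannon `H' = -sum(p log p)` (natural log) and Gini-Simpson
#' `1 - sum(p^2)` over category (genospecies) counts.
#'
#' @param counts Non-negative counts per category (zero categories are
#'   ignored).
#' @return List with `shannon` and `simpson`.
#' @export
species_diversity <- function(counts) {
  counts <- counts[counts > 0]
  rg_check(length(counts) >= 1, "all categories empty", "degenerate_error")
  list(shannon = vegan::diversity(counts, index = "shannon"),
       simpson = vegan::diversity(counts, index = "simpson"))
}

#' Three-level diversity profile of a strain set
#'
#' @param loci Locus alignments (harmonized).
#' @param strains Strain ids of the group.
#' @param labels Genospecies labels per strain (named by strain id) for
#'   the species level; omit to skip.
#' @param group_name Name recorded in the profile.
#' @return A `diversity_profile` list: `group_name`, `n_strains`, `pi`,
#'   `locus`, `shannon`, `simpson`.
#' @export
diversity_profile <- function(loci, strains, labels = NULL,
                              group_name = "group") {
  rg_check(length(strains) >= 2, "need at least 2 strains",
           "insufficient_data_error")
  concat <- concatenate(harmonize(loci, strains = strains))
  pi <- nucleotide_diversity(concat, strains)
  loc <- locus_diversity(loci, strains)
  sh <- si <- NA_real_
  if (!is.null(labels)) {
    sp <- species_diversity(table(labels[strains]))
    sh <- sp$shannon
    si <- sp$simpson
  }
  structure(list(group_name = group_name, n_strains = length(strains),
                 pi = pi, locus = loc, shannon = sh, simpson = si),
            class = "diversity_profile")
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat(sprintf("%s: n = %d, pi = %.4f, locus = %.3f, H' = %s, Simpson = %s\n",
              x$group_name, x$n_strains, x$pi, x$locus,
              ifelse(is.na(x$shannon), "NA", sprintf("%.3f", x$shannon)),
              ifelse(is.na(x$simpson), "NA", sprintf("%.3f", x$simpson))))
  invisible(x)
}

#' Permutation test for a diversity difference between two strain sets
#'
#' Strain ids are shuffled between the groups `n_perm` times; the two-sided
#' p-value is the +1-corrected fraction of permuted absolute differences at
#' least as large as the observed one.
#'
#' @param loci Locus alignments covering both groups.
#' @param group_a,group_b Strain id vectors (each of size >= 2).
#' @param metric `"nucleotide"` (pi on the concatenation) or `"locus"`
#'   (mean haplotype diversity).
#' @param n_perm Number of permutations (minimum 19).
#' @param seed Integer seed.
#' @return List: `observed_difference` (a - b), `p_value`, `n_perm`.
#' @export
compare_diversity <- function(loci, group_a, group_b,
                              metric = c("nucleotide", "locus"),
                              n_perm = 999, seed = 1) {
  metric <- match.arg(metric)
  rg_check(n_perm >= 19, "n_perm must be >= 19", "parameter_error")
  rg_check(length(group_a) >= 2 && length(group_b) >= 2,
           "both groups need >= 2 strains", "insufficient_data_error")
  all_ids <- c(group_a, group_b)
  loci_h <- harmonize(loci, strains = all_ids)
  concat <- concatenate(loci_h)
  stat <- function(ids) {
    if (metric == "nucleotide") nucleotide_diversity(concat, ids)
    else locus_diversity(loci_h, ids)
  }
  obs <- stat(group_a) - stat(group_b)
  set.seed(seed)
  na <- length(group_a)
  perm <- vapply(seq_len(n_perm), function(i) {
    shuffled <- sample(all_ids)
    stat(shuffled[seq_len(na)]) - stat(shuffled[-seq_len(na)])
  }, numeric(1))
  list(observed_difference = obs,
       p_value = (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm),
       n_perm = n_perm)
}
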