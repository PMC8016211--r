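# Multilocus alignment handling: FASTA I/O, harmonization over a common
# strain set, concatenation with locus boundaries, site classification,
# nucleotide distances (p, JC69, K2P, T92) and MLSA-based ANI.

IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
DNA_ALPHABET <- c("A", "C", "G", "T", "-", "N", IUPAC_AMBIG)
UNAMBIG <- c("A", "C", "G", "T")

#' Construct a single-locus alignment
#'
#' A `locus_alignment` holds one gene's aligned sequences keyed by strain id.
#' Sequences are stored upper-case over the alphabet A/C/G/T/-/N plus IUPAC
#' ambiguity codes; `U` is normalized to `T` on input.
#'
#' @param seqs Named character vector of aligned sequences (equal lengths),
#'   or a character matrix with one row per strain and one column per site.
#' @param locus Locus name.
#' @return An object of class `locus_alignment` with elements `locus`
#'   (name), `mat` (strain x site character matrix) and `n_columns`.
#' @export
locus_alignment <- function(seqs, locus = "locus") {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    rg_check(length(seqs) >= 1, "alignment needs at least one sequence",
             "alignment_error")
    rg_check(!is.null(names(seqs)) && all(nzchar(names(seqs))),
             "sequences must be named by strain id", "alignment_error")
    widths <- nchar(seqs)
    if (length(unique(widths)) != 1L) {
      rg_abort(sprintf(
        "unequal sequence lengths (%s): alignment required",
        paste(unique(widths), collapse = ", ")), "alignment_error")
    }
    mat <- do.call(rbind, strsplit(as.character(seqs), ""))
    rownames(mat) <- names(seqs)
  }
  mat[] <- toupper(mat)
  mat[mat == "U"] <- "T"
  ids <- rownames(mat)
  if (anyDuplicated(ids)) {
    rg_abort(sprintf("duplicate strain ids: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "duplicate_id_error")
  }
  bad <- setdiff(unique(as.vector(mat)), DNA_ALPHABET)
  if (length(bad)) {
    rg_abort(sprintf("illegal characters in alignment: %s",
                     paste(bad, collapse = ", ")), "alphabet_error")
  }
  structure(list(locus = locus, mat = mat, n_columns = ncol(mat)),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d strains x %d columns\n",
              x$locus, nrow(x$mat), x$n_columns))
  invisible(x)
}

#' @rdname locus_alignment
#' @param x A `locus_alignment`.
#' @export
strain_ids <- function(x) rownames(x$mat)

#' @rdname locus_alignment
#' @export
n_columns <- function(x) x$n_columns

#' Read an aligned FASTA file
#'
#' Reads a multi-record FASTA (wrapped or single-line) into a validated
#' [locus_alignment()]. All records must have equal length; ids must be
#' unique; characters outside A/C/G/T/U/-/N and the IUPAC ambiguity codes
#' are rejected. Input order of records is preserved.
#'
#' @param path Path to a FASTA file.
#' @param locus Locus name; defaults to the file name without extension.
#' @return A [locus_alignment()].
#' @export
read_fasta <- function(path, locus = NULL) {
  rg_check(file.exists(path), sprintf("file not found: %s", path),
           "io_error")
  if (is.null(locus)) locus <- sub("\\.[^.]*$", "", basename(path))
  dna <- ape::read.FASTA(path)
  rg_check(length(dna) >= 1, sprintf("no FASTA records in %s", path),
           "io_error")
  widths <- lengths(dna)
  if (length(unique(widths)) != 1L) {
    rg_abort(sprintf("unequal sequence lengths in %s (%s)", path,
                     paste(unique(widths), collapse = ", ")),
             "alignment_error")
  }
  seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
  # first whitespace-delimited token of the header is the strain id
  names(seqs) <- sub("\\s.*$", "", names(dna))
  locus_alignment(seqs, locus = locus)
}

#' Write an alignment to FASTA
#'
#' @param aln A [locus_alignment()] or concatenated alignment.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(aln, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in rownames(aln$mat)) {
    s <- paste(aln$mat[id, ], collapse = "")
    writeLines(paste0(">", id), con)
    writeLines(substring(s, seq(1, nchar(s), width),
                         pmin(seq(1, nchar(s), width) + width - 1, nchar(s))),
               con)
  }
  invisible(path)
}

#' Restrict loci to a common strain set
#'
#' Subsets each locus alignment to the intersection of all loci's strain
#' ids (the default policy) or to an explicitly supplied id vector. Columns
#' are never touched here; trimming is a separate, explicit step
#' ([trim_alignment()]).
#'
#' @param loci List of [locus_alignment()] objects.
#' @param strains Optional explicit character vector of strain ids.
#' @return List of alignments, each restricted to the shared strains (kept
#'   in first-locus order).
#' @export
harmonize <- function(loci, strains = NULL) {
  rg_check(length(loci) >= 1, "need at least one locus", "parameter_error")
  if (is.null(strains)) {
    strains <- Reduce(intersect, lapply(loci, strain_ids))
  } else {
    missing <- lapply(loci, function(l) setdiff(strains, strain_ids(l)))
    if (any(lengths(missing) > 0)) {
      rg_abort("requested strains missing from some loci", "empty_overlap_error")
    }
  }
  if (length(strains) == 0) {
    rg_abort("no strains shared by all loci", "empty_overlap_error")
  }
  keep <- intersect(strain_ids(loci[[1]]), strains)
  lapply(loci, function(l) {
    locus_alignment(l$mat[keep, , drop = FALSE], locus = l$locus)
  })
}

#' Trim alignment columns to an explicit interval
#'
#' @param aln A [locus_alignment()].
#' @param start,end 1-based inclusive column interval to keep.
#' @export
trim_alignment <- function(aln, start, end) {
  rg_check(start >= 1 && end <= aln$n_columns && start <= end,
           "invalid trim interval", "parameter_error")
  locus_alignment(aln$mat[, start:end, drop = FALSE], locus = aln$locus)
}

#' Concatenate harmonized locus alignments
#'
#' Joins loci column-wise in input order, recording each locus's half-open
#' column interval. All loci must already share an identical strain set
#' (see [harmonize()]).
#'
#' @param loci List of [locus_alignment()] objects over the same strains.
#' @return A `concat_alignment` (also a `locus_alignment`) with a
#'   `boundaries` data frame (locus, start, end; 1-based inclusive).
#' @export
concatenate <- function(loci) {
  rg_check(length(loci) >= 1, "need at least one locus", "parameter_error")
  ids <- strain_ids(loci[[1]])
  for (l in loci) {
    if (!setequal(strain_ids(l), ids)) {
      rg_abort("loci have different strain sets; harmonize() first",
               "harmonization_error")
    }
  }
  mats <- lapply(loci, function(l) l$mat[ids, , drop = FALSE])
  widths <- vapply(mats, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1) + 1L)
  out <- locus_alignment(do.call(cbind, mats), locus = "concatenated")
  out$boundaries <- data.frame(
    locus = vapply(loci, function(l) l$locus, character(1)),
    start = starts, end = ends, stringsAsFactors = FALSE)
  class(out) <- c("concat_alignment", class(out))
  out
}

#' Extract one locus from a concatenated alignment
#'
#' @param aln A `concat_alignment`.
#' @param locus Locus name present in `aln$boundaries`.
#' @export
extract_locus <- function(aln, locus) {
  b <- aln$boundaries[aln$boundaries$locus == locus, ]
  rg_check(nrow(b) == 1, sprintf("locus %s not in concatenation", locus),
           "parameter_error")
  locus_alignment(aln$mat[, b$start:b$end, drop = FALSE], locus = locus)
}

#' Classify alignment sites
#'
#' Per column, considering only unambiguous bases (A/C/G/T): conserved =
#' exactly one distinct base present; variable = two or more; among
#' variable columns, parsimony-informative = at least two bases each
#' carried by at least two sequences, the rest are singletons. Columns with
#' no unambiguous base count in `n_sites` only.
#'
#' @param aln A [locus_alignment()] with at least two rows.
#' @return A `site_classification` list: `n_sites`, `n_conserved`,
#'   `n_variable`, `n_parsimony_informative`, `n_singleton`.
#' @export
classify_sites <- function(aln) {
  mat <- aln$mat
  rg_check(nrow(mat) >= 2, "need at least 2 sequences", "insufficient_data_error")
  counts <- vapply(UNAMBIG, function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  if (ncol(mat) == 1L) counts <- matrix(counts, nrow = 1)
  n_bases <- rowSums(counts > 0)
  pi_col <- rowSums(counts >= 2) >= 2 & n_bases >= 2
  res <- list(
    n_sites = ncol(mat),
    n_conserved = sum(n_bases == 1),
    n_variable = sum(n_bases >= 2),
    n_parsimony_informative = sum(pi_col),
    n_singleton = sum(n_bases >= 2 & !pi_col))
  class(res) <- "site_classification"
  res
}

#' @export
print.site_classification <- function(x, ...) {
  cat(sprintf(
    "sites %d | conserved %d | variable %d (PI %d, singleton %d)\n",
    x$n_sites, x$n_conserved, x$n_variable,
    x$n_parsimony_informative, x$n_singleton))
  invisible(x)
}

# Indicator matrices over the unambiguous alphabet; the workhorse for all
# pairwise counting (matches, transitions, transversions) via crossprods.
.pair_counts <- function(mat) {
  ind <- lapply(UNAMBIG, function(b) (mat == b) * 1)
  names(ind) <- UNAMBIG
  unamb <- Reduce(`+`, ind)
  comparable <- tcrossprod(unamb)
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  transitions <- tcrossprod(ind$A, ind$G) + tcrossprod(ind$G, ind$A) +
    tcrossprod(ind$C, ind$T) + tcrossprod(ind$T, ind$C)
  list(comparable = comparable, matches = matches,
       transitions = transitions,
       diff = comparable - matches)
}

.complete_deletion <- function(mat) {
  keep <- colSums(!matrix(mat %in% UNAMBIG, nrow(mat))) == 0
  rg_check(any(keep), "no columns survive complete deletion",
           "undefined_distance_error")
  mat[, keep, drop = FALSE]
}

.check_comparable <- function(cmp, labels) {
  bad <- which(cmp == 0 & upper.tri(cmp), arr.ind = TRUE)
  if (nrow(bad)) {
    rg_abort(sprintf("no comparable sites for pair %s / %s",
                     labels[bad[1, 1]], labels[bad[1, 2]]),
             "undefined_distance_error")
  }
}

.as_dist_matrix <- function(values, labels, metric) {
  dimnames(values) <- list(labels, labels)
  diag(values) <- 0
  attr(values, "metric") <- metric
  values
}

#' Uncorrected pairwise distance (p-distance)
#'
#' Proportion of differing sites over sites where both sequences carry an
#' unambiguous base. `deletion = "pairwise"` (default) drops gap/ambiguous
#' sites per pair; `"complete"` drops any column containing one anywhere.
#'
#' @param aln A [locus_alignment()] with at least 2 rows.
#' @param deletion `"pairwise"` or `"complete"`.
#' @return Square symmetric matrix with strain ids as dimnames and a
#'   `"metric"` attribute.
#' @export
p_distance <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  mat <- aln$mat
  rg_check(nrow(mat) >= 2, "need at least 2 sequences", "insufficient_data_error")
  if (deletion == "complete") mat <- .complete_deletion(mat)
  pc <- .pair_counts(mat)
  .check_comparable(pc$comparable, rownames(mat))
  .as_dist_matrix(pc$diff / pc$comparable, rownames(mat), "p-distance")
}

#' Model-corrected pairwise distances
#'
#' Closed-form corrections from the observed transition proportion P and
#' transversion proportion Q (and GC content for T92):
#' JC69 \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)};
#' K2P \eqn{d = -\frac{1}{2}\ln(1-2P-Q) - \frac{1}{4}\ln(1-2Q)};
#' T92 \eqn{d = -c\,\ln(1 - P/c - Q) - \frac{1-c}{2}\ln(1-2Q)} with
#' \eqn{c = 2\theta(1-\theta)} and \eqn{\theta} the GC content of the
#' compared sequences.
#'
#' @inheritParams p_distance
#' @param model One of `"JC69"`, `"K2P"`, `"T92"`.
#' @return Distance matrix as in [p_distance()]. Saturated pairs (a log
#'   argument at or below zero) raise a saturation error naming the pair.
#' @export
corrected_distance <- function(aln, model = c("JC69", "K2P", "T92"),
                               deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  mat <- aln$mat
  rg_check(nrow(mat) >= 2, "need at least 2 sequences", "insufficient_data_error")
  if (deletion == "complete") mat <- .complete_deletion(mat)
  pc <- .pair_counts(mat)
  .check_comparable(pc$comparable, rownames(mat))
  P <- pc$transitions / pc$comparable
  Q <- (pc$diff - pc$transitions) / pc$comparable
  p <- pc$diff / pc$comparable
  d <- switch(model,
    JC69 = {
      arg <- 1 - 4 / 3 * p
      .check_saturation(arg, rownames(mat), model)
      -3 / 4 * log(arg)
    },
    K2P = {
      a1 <- 1 - 2 * P - Q
      a2 <- 1 - 2 * Q
      .check_saturation(pmin(a1, a2), rownames(mat), model)
      -1 / 2 * log(a1) - 1 / 4 * log(a2)
    },
    T92 = {
      unamb <- matrix(mat %in% UNAMBIG, nrow(mat))
      gc <- rowSums(mat == "G" | mat == "C") / rowSums(unamb)
      # per-pair GC content averaged over the two sequences
      theta <- outer(gc, gc, `+`) / 2
      cc <- 2 * theta * (1 - theta)
      a1 <- 1 - P / cc - Q
      a2 <- 1 - 2 * Q
      .check_saturation(pmin(a1, a2), rownames(mat), model)
      -cc * log(a1) - (1 - cc) / 2 * log(a2)
    })
  .as_dist_matrix(d, rownames(mat), model)
}

.check_saturation <- function(arg, labels, model) {
  diag(arg) <- 1
  bad <- which(arg <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    rg_abort(sprintf("%s distance saturated for pair %s / %s", model,
                     labels[bad[1, 1]], labels[bad[1, 2]]),
             "saturation_error")
  }
}

#' MLSA average nucleotide identity
#'
#' Percent identity is `100 * (1 - p_distance)` over the (typically
#' concatenated) alignment; this is alignment-fraction identity over shared
#' MLSA loci, not whole-genome ANI. With one strain set, all unordered
#' within-set pairs are used (self-pairs excluded); with two sets, all
#' cross pairs.
#'
#' @param aln A [locus_alignment()].
#' @param ids_a,ids_b Strain id vectors; `ids_b = NULL` gives within-set
#'   ANI of `ids_a`.
#' @param threshold Species-membership cutoff on mean identity (conventional
#'   value 95).
#' @return List with `mean`, `min`, `max`, `n_pairs`, and `same_species`
#'   (mean identity above `threshold`).
#' @export
ani <- function(aln, ids_a, ids_b = NULL, threshold = 95) {
  ids <- strain_ids(aln)
  rg_check(length(ids_a) >= 1 && all(ids_a %in% ids),
           "ids_a empty or not in alignment", "parameter_error")
  within <- is.null(ids_b)
  if (within) {
    rg_check(length(ids_a) >= 2,
             "within-set ANI needs at least 2 strains",
             "insufficient_pairs_error")
    ids_b <- ids_a
  } else {
    rg_check(length(ids_b) >= 1 && all(ids_b %in% ids),
             "ids_b empty or not in alignment", "parameter_error")
  }
  d <- p_distance(aln)
  idm <- 100 * (1 - d[ids_a, ids_b, drop = FALSE])
  if (within) {
    vals <- idm[upper.tri(idm)]
  } else {
    keep <- outer(ids_a, ids_b, `!=`)
    vals <- idm[keep]
  }
  rg_check(length(vals) >= 1, "no strain pairs for ANI",
           "insufficient_pairs_error")
  list(mean = mean(vals), min = min(vals), max = max(vals),
       n_pairs = length(vals), same_species = mean(vals) > threshold)
}

# Conversions to the containers the tree/likelihood layers expect.
as_DNAbin <- function(aln) ape::as.DNAbin(tolower(aln$mat))
as_phyDat <- function(aln) phangorn::phyDat(aln$mat, type = "DNA")
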