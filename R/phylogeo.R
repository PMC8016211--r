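# Spatial and environmental association statistics: great-circle
# distances, Mantel and partial Mantel tests (with an exact-enumeration
# option), PCoA, sliding-window diversity curves against a random-distance
# null, and distance-based permutational ANOVA over environmental
# covariates.

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance matrix (km)
#'
#' Haversine distances at Earth mean radius 6371.0088 km. Strains with
#' missing coordinates are excluded; their ids are recorded in the
#' `"excluded"` attribute.
#'
#' @param meta Metadata data frame with `strain_id`, `latitude`,
#'   `longitude`.
#' @return Square symmetric matrix in kilometres.
#' @export
geo_distance <- function(meta) {
  rg_check(all(c("strain_id", "latitude", "longitude") %in% names(meta)),
           "metadata needs strain_id, latitude, longitude", "metadata_error")
  ok <- !is.na(meta$latitude) & !is.na(meta$longitude)
  excluded <- meta$strain_id[!ok]
  m <- meta[ok, ]
  rg_check(nrow(m) >= 2, "fewer than 2 strains with coordinates",
           "insufficient_data_error")
  p <- cbind(m$longitude, m$latitude)
  # geosphere's default sphere radius rescaled to the mean Earth radius
  d <- geosphere::distm(p, p, fun = geosphere::distHaversine)
  d <- d / 6378137 * (EARTH_RADIUS_KM * 1000) / 1000
  d <- .as_dist_matrix(d, m$strain_id, "haversine-km")
  attr(d, "excluded") <- excluded
  d
}

#' Pair distance at species level
#'
#' 0 if two strains share a genospecies label, 1 otherwise: the minimal
#' pair distance consistent with species-level Mantel and window analyses.
#'
#' @param labels Named character vector, strain id -> genospecies.
#' @export
species_distance <- function(labels) {
  ids <- names(labels)
  rg_check(!is.null(ids), "labels must be named by strain id",
           "parameter_error")
  d <- outer(labels, labels, `!=`) * 1
  .as_dist_matrix(d, ids, "species-indicator")
}

.upper_vec <- function(m) m[upper.tri(m)]

.align_matrices <- function(...) {
  mats <- list(...)
  labs <- Reduce(intersect, lapply(mats, rownames))
  rg_check(length(labs) >= 4, "need >= 4 shared strains", "parameter_error")
  lapply(mats, function(m) m[labs, labs])
}

#' Mantel test
#'
#' Pearson correlation of the upper triangles of two distance matrices;
#' significance by simultaneous row/column permutation of the first
#' matrix. One-sided (greater) by default, matching the
#' isolation-by-distance direction; p-values carry the +1 Monte-Carlo
#' correction. With `permutations = "exact"` all `n!` relabelings are
#' enumerated (n <= 8) and the p-value is the exact fraction.
#'
#' @param d_gen,d_geo Conformable square distance matrices with strain ids
#'   as dimnames (matched on shared ids).
#' @param permutations Number of random permutations, or `"exact"`.
#' @param seed Integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A `mantel_result`: `r`, `p_value`, `n_permutations`, `partial`.
#' @export
mantel <- function(d_gen, d_geo, permutations = 999, seed = 1,
                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  m <- .align_matrices(d_gen, d_geo)
  x <- .upper_vec(m[[1]])
  y <- .upper_vec(m[[2]])
  rg_check(stats::sd(x) > 0 && stats::sd(y) > 0,
           "constant distance matrix: correlation undefined",
           "undefined_correlation_error")
  r_obs <- stats::cor(x, y)
  n <- nrow(m[[1]])
  score <- function(r) if (alternative == "greater") r else abs(r)
  if (identical(permutations, "exact")) {
    rg_check(n <= 8, "exact enumeration limited to n <= 8", "parameter_error")
    perms <- .all_permutations(n)
    r_null <- vapply(perms, function(p)
      stats::cor(.upper_vec(m[[1]][p, p]), y), numeric(1))
    p_val <- mean(score(r_null) >= score(r_obs))
    n_perm <- length(perms)
  } else {
    rg_check(permutations >= 19, "need >= 19 permutations", "parameter_error")
    set.seed(seed)
    r_null <- vapply(seq_len(permutations), function(i) {
      p <- sample.int(n)
      stats::cor(.upper_vec(m[[1]][p, p]), y)
    }, numeric(1))
    p_val <- (1 + sum(score(r_null) >= score(r_obs))) / (1 + permutations)
    n_perm <- permutations
  }
  structure(list(r = r_obs, p_value = p_val, n_permutations = n_perm,
                 partial = FALSE, covariate = NULL,
                 alternative = alternative),
            class = "mantel_result")
}

.all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (i in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = i - 1L)
    }
  }
  out
}

#' Partial Mantel test
#'
#' Correlation of the residuals of `d_gen` and `d_geo`, each regressed (on
#' the upper-triangle vectors) on the covariate matrix `d_cov`;
#' significance by simultaneous row/column permutation of the genetic
#' residual matrix.
#'
#' @inheritParams mantel
#' @param d_cov Covariate distance matrix.
#' @param covariate Name recorded in the result.
#' @return A `mantel_result` with `partial = TRUE`.
#' @export
partial_mantel <- function(d_gen, d_geo, d_cov, permutations = 999,
                           seed = 1, alternative = c("greater", "two.sided"),
                           covariate = "covariate") {
  alternative <- match.arg(alternative)
  m <- .align_matrices(d_gen, d_geo, d_cov)
  n <- nrow(m[[1]])
  resid_mat <- function(dm, cv) {
    fit <- stats::lm(.upper_vec(dm) ~ .upper_vec(cv))
    r <- dm * 0
    r[upper.tri(r)] <- stats::resid(fit)
    r + t(r)
  }
  geo_res <- .upper_vec(m[[2]]) -
    stats::fitted(stats::lm(.upper_vec(m[[2]]) ~ .upper_vec(m[[3]])))
  rg_check(stats::sd(geo_res) > 1e-12,
           "d_geo collinear with d_cov", "collinearity_error")
  gen_res <- resid_mat(m[[1]], m[[3]])
  x <- .upper_vec(gen_res)
  r_obs <- stats::cor(x, geo_res)
  score <- function(r) if (alternative == "greater") r else abs(r)
  rg_check(permutations >= 19, "need >= 19 permutations", "parameter_error")
  set.seed(seed)
  r_null <- vapply(seq_len(permutations), function(i) {
    p <- sample.int(n)
    stats::cor(.upper_vec(gen_res[p, p]), geo_res)
  }, numeric(1))
  structure(list(
    r = r_obs,
    p_value = (1 + sum(score(r_null) >= score(r_obs))) / (1 + permutations),
    n_permutations = permutations, partial = TRUE, covariate = covariate,
    alternative = alternative),
    class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<%s> r = %.4f, p = %.4f (%d permutations%s)\n",
              if (x$partial) "partial Mantel" else "Mantel",
              x$r, x$p_value, x$n_permutations,
              if (x$partial) paste0(", covariate ", x$covariate) else ""))
  invisible(x)
}

#' Principal coordinates analysis
#'
#' Gower double-centering of the squared distance matrix followed by
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Negative eigenvalues are reported
#' but their axes omitted.
#'
#' @param dm Square symmetric distance matrix.
#' @param n_axes Number of axes to return (truncated with a warning if
#'   fewer positive eigenvalues exist).
#' @return A `pcoa_result`: `coordinates`, `eigenvalues` (all, descending),
#'   `proportion_explained` (over positive eigenvalues).
#' @export
pcoa <- function(dm, n_axes = 2) {
  dm <- as.matrix(dm)
  rg_check(isTRUE(all.equal(dm, t(dm), tolerance = 1e-8,
                            check.attributes = FALSE)),
           "distance matrix must be symmetric", "validation_error")
  n <- nrow(dm)
  B <- -0.5 * (diag(n) - 1 / n) %*% (dm^2) %*% (diag(n) - 1 / n)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  values <- eig$values
  pos <- which(values > max(values) * 1e-10 & values > 0)
  if (n_axes > length(pos)) {
    warning(sprintf("only %d positive axes available; truncating",
                    length(pos)))
    n_axes <- length(pos)
  }
  axes <- pos[seq_len(n_axes)]
  coords <- eig$vectors[, axes, drop = FALSE] %*%
    diag(sqrt(values[axes]), n_axes)
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("Axis", seq_len(n_axes))
  structure(list(coordinates = coords, eigenvalues = values,
                 proportion_explained = values[pos] / sum(values[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d points, %d axes; first axes explain %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%",
                            100 * x$proportion_explained[seq_len(ncol(x$coordinates))]),
                    collapse = ", ")))
  invisible(x)
}

#' Sliding-window diversity against a random-distance null
#'
#' Windows of `width_km` advance by `step_km` across the range of pairwise
#' geographic distances. Per window, the observed value is the mean
#' genetic distance of `n_resamples` randomly selected strain pairs whose
#' separation falls inside the window; the null value draws pairs
#' irrespective of distance. Windows without eligible pairs are reported
#' absent (`NA`), not zero.
#'
#' @param d_geo Geographic distance matrix (km).
#' @param d_gen Genetic distance matrix on the same strains (nucleotide,
#'   haplotype/allele-sharing, or species indicator - see
#'   [species_distance()]).
#' @param width_km Window width (default 80).
#' @param step_km Step between window centers (default 10).
#' @param n_resamples Pairs sampled per window (default 1, the
#'   high-variance single-pair curve; raise for smoother curves).
#' @param seed Integer seed.
#' @return A `sliding_window_curve` data frame: `center_km`, `n_pairs`,
#'   `observed`, `null`.
#' @export
sliding_window <- function(d_geo, d_gen, width_km = 80, step_km = 10,
                           n_resamples = 1, seed = 1) {
  rg_check(width_km > 0 && step_km > 0, "width and step must be positive",
           "parameter_error")
  m <- .align_matrices(d_geo, d_gen)
  geo <- .upper_vec(m[[1]])
  gen <- .upper_vec(m[[2]])
  centers <- seq(width_km / 2, max(geo) + step_km, by = step_km)
  set.seed(seed)
  rows <- lapply(centers, function(cc) {
    eligible <- which(abs(geo - cc) <= width_km / 2)
    if (!length(eligible)) {
      return(data.frame(center_km = cc, n_pairs = 0L,
                        observed = NA_real_, null = NA_real_))
    }
    obs <- mean(gen[sample(eligible, n_resamples, replace = TRUE)])
    nul <- mean(gen[sample.int(length(gen), n_resamples, replace = TRUE)])
    data.frame(center_km = cc, n_pairs = length(eligible),
               observed = obs, null = nul)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sliding_window_curve", class(out))
  out
}

#' Distance-based permutational ANOVA over environmental covariates
#'
#' Sequential (Type-I) partitioning of the Gower-centered genetic distance
#' matrix over an ordered list of numeric covariates, with pseudo-F
#' statistics and permutation p-values (via [vegan::adonis2()]). The
#' sum-of-squares column is labelled `pseudo_chisq` in keeping with the
#' usual reporting of distance-based partitioning for these data.
#'
#' @param d_gen Genetic distance matrix.
#' @param covariates Data frame of numeric covariates (rows matched to
#'   `d_gen` by `rownames` or a `strain_id` column), e.g. longitude,
#'   latitude, elevation, soil pH. Complete cases only.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `permanova_table` data frame: `term`, `Df`, `pseudo_chisq`,
#'   `F`, `p_value`, with `Residual` and `Total` rows.
#' @export
permanova <- function(d_gen, covariates, n_perm = 999, seed = 1) {
  if ("strain_id" %in% names(covariates)) {
    rownames(covariates) <- covariates$strain_id
    covariates$strain_id <- NULL
  }
  ids <- intersect(rownames(d_gen), rownames(covariates))
  covariates <- covariates[ids, , drop = FALSE]
  keep <- stats::complete.cases(covariates)
  ids <- ids[keep]
  covariates <- covariates[keep, , drop = FALSE]
  rg_check(all(vapply(covariates, is.numeric, logical(1))),
           "covariates must be numeric", "parameter_error")
  rg_check(length(ids) >= ncol(covariates) + 2,
           "too few complete cases for the model", "rank_error")
  d <- stats::as.dist(d_gen[ids, ids])
  set.seed(seed)
  form <- stats::as.formula(paste("d ~", paste(names(covariates), collapse = " + ")))
  res <- vegan::adonis2(form, data = covariates, permutations = n_perm,
                        by = "terms")
  out <- data.frame(term = rownames(res), Df = res$Df,
                    pseudo_chisq = res$SumOfSqs, F = res$F,
                    p_value = res$`Pr(>F)`, row.names = NULL)
  class(out) <- c("permanova_table", class(out))
  out
}
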