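# Maximum-likelihood layer: model parsing, likelihood evaluation and
# optimization (phangorn), model selection by BIC/AICc, alignment
# simulation under GTR-family models with +G/+I, and the
# parametric-bootstrap (SOWH-style) test of gene-tree congruence.

ML_BASE_MODELS <- c(JC69 = "JC", K2P = "K80", HKY = "HKY", GTR = "GTR")

# "GTR+G+I" -> list(base="GTR", phangorn="GTR", gamma=TRUE, inv=TRUE)
parse_model <- function(model) {
  parts <- strsplit(model, "+", fixed = TRUE)[[1]]
  base <- parts[1]
  rg_check(base %in% names(ML_BASE_MODELS),
           sprintf("unknown model '%s' (supported: %s, each optionally +G and/or +I)",
                   base, paste(names(ML_BASE_MODELS), collapse = ", ")),
           "parameter_error")
  extras <- parts[-1]
  rg_check(all(extras %in% c("G", "I")),
           sprintf("unknown model suffix in '%s'", model), "parameter_error")
  list(name = model, base = base, phangorn = ML_BASE_MODELS[[base]],
       gamma = "G" %in% extras, inv = "I" %in% extras)
}

# Free parameters of the substitution model (excluding branch lengths).
.model_k <- function(spec) {
  k <- switch(spec$base, JC69 = 0, K2P = 1, HKY = 4, GTR = 8)
  k + spec$gamma + spec$inv
}

.pml_for <- function(tree, data, spec, k_gamma = 4) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  phangorn::pml(tree, data, model = spec$phangorn,
                k = if (spec$gamma) k_gamma else 1,
                inv = if (spec$inv) 0.05 else 0,
                shape = if (spec$gamma) 1 else 1)
}

.optim_args <- function(spec, rearrangement = "none") {
  list(optBf = spec$base %in% c("HKY", "GTR"),
       optQ = spec$base %in% c("K2P", "HKY", "GTR"),
       optGamma = spec$gamma, optInv = spec$inv,
       optEdge = TRUE, rearrangement = rearrangement,
       control = phangorn::pml.control(trace = 0))
}

.as_fit <- function(fit, spec, tree_free = FALSE) {
  n <- sum(attr(fit$data, "weight"))
  n_branches <- nrow(fit$tree$edge)
  k <- n_branches + .model_k(spec)
  ll <- as.numeric(stats::logLik(fit))
  aicc <- if (n > k + 1) -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  structure(list(log_likelihood = ll, n_free_parameters = k,
                 n_columns = n, model = spec$name,
                 BIC = -2 * ll + k * log(n), AICc = aicc,
                 tree = fit$tree, pml = fit,
                 topology_searched = tree_free),
            class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  cat(sprintf("<ml_fit> %s  lnL = %.3f  k = %d  BIC = %.2f  AICc = %s\n",
              x$model, x$log_likelihood, x$n_free_parameters, x$BIC,
              ifelse(is.na(x$AICc), "NA", sprintf("%.2f", x$AICc))))
  invisible(x)
}

#' @export
logLik.ml_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_free_parameters,
            class = "logLik")
}

#' Log-likelihood of a tree under a substitution model
#'
#' Felsenstein-pruning likelihood over compressed site patterns; `+G` uses
#' discrete equal-probability gamma categories (default 4) and `+I` a
#' zero-rate mixture class. Ambiguity codes contribute partial likelihoods
#' over their compatible bases.
#'
#' @param tree A `phylo` whose tips are a subset of the alignment rows.
#' @param aln A [locus_alignment()].
#' @param model Model string: `"JC69"`, `"K2P"`, `"HKY"` or `"GTR"`,
#'   optionally with `+G` and/or `+I` (e.g. `"GTR+G+I"`).
#' @param shape,p_inv,base_freq,Q Optional fixed parameter values; defaults
#'   are the model's neutral starting values.
#' @return Numeric log-likelihood.
#' @export
log_likelihood <- function(tree, aln, model = "JC69", shape = NULL,
                           p_inv = NULL, base_freq = NULL, Q = NULL) {
  missing <- setdiff(tree$tip.label, strain_ids(aln))
  if (length(missing)) {
    rg_abort(sprintf("tree leaves without sequence: %s",
                     paste(missing, collapse = ", ")), "mapping_error")
  }
  spec <- parse_model(model)
  data <- as_phyDat(aln)
  fit <- phangorn::pml(
    tree, data, model = spec$phangorn,
    k = if (spec$gamma) 4 else 1,
    shape = if (is.null(shape)) 1 else shape,
    inv = if (is.null(p_inv)) 0 else p_inv,
    bf = base_freq, Q = Q)
  as.numeric(stats::logLik(fit))
}

#' Optimize branch lengths and model parameters on a fixed topology
#'
#' Coordinate ascent via [phangorn::optim.pml()]: branch lengths plus the
#' free parameters of the chosen model (`+G` shape, `+I` proportion, base
#' frequencies and exchangeabilities where the model has them). The
#' log-likelihood is non-decreasing across optimizer rounds.
#'
#' @inheritParams log_likelihood
#' @return An `ml_fit`: log-likelihood, parameter count, `BIC`, `AICc`
#'   (`NA` when columns <= parameters + 1), optimized `tree` and the
#'   underlying `pml` object.
#' @export
optimize_fit <- function(tree, aln, model = "GTR+G") {
  spec <- parse_model(model)
  fit <- .pml_for(tree, as_phyDat(aln), spec)
  opt <- do.call(phangorn::optim.pml, c(list(fit), .optim_args(spec)))
  .as_fit(opt, spec)
}

#' Hill-climbing topology search by nearest-neighbour interchange
#'
#' Repeated best-improving NNI moves with branch-length and model
#' re-optimization, terminating at a local optimum. The returned
#' log-likelihood is never below the starting value.
#'
#' @inheritParams log_likelihood
#' @param start_tree Unrooted starting topology (at least 4 taxa).
#' @return An `ml_fit` with the locally optimal topology.
#' @export
nni_search <- function(start_tree, aln, model = "GTR+G") {
  rg_check(length(start_tree$tip.label) >= 4, "need at least 4 taxa",
           "parameter_error")
  spec <- parse_model(model)
  fit <- .pml_for(ape::unroot(start_tree), as_phyDat(aln), spec)
  opt <- do.call(phangorn::optim.pml,
                 c(list(fit), .optim_args(spec, rearrangement = "NNI")))
  .as_fit(opt, spec, tree_free = TRUE)
}

#' Rank substitution models by information criterion
#'
#' Each candidate is optimized on the same topology and ranked ascending by
#' the chosen criterion. `BIC = -2 lnL + k ln(n)` and
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)` with `n` = alignment columns and
#' `k` = free parameters (branches + model).
#'
#' @inheritParams log_likelihood
#' @param candidates Character vector of model strings.
#' @param criterion `"BIC"` (default) or `"AICc"`.
#' @return List: `table` (data frame ranked by the criterion), `fits`
#'   (named list of `ml_fit`), `best` (best model string).
#' @export
model_select <- function(aln, tree, candidates = c("JC69", "K2P", "HKY+G", "GTR+G", "GTR+G+I"),
                         criterion = c("BIC", "AICc")) {
  criterion <- match.arg(criterion)
  rg_check(length(candidates) >= 2, "need at least 2 candidate models",
           "parameter_error")
  fits <- lapply(candidates, function(m) optimize_fit(tree, aln, m))
  names(fits) <- candidates
  if (criterion == "AICc" && anyNA(vapply(fits, `[[`, numeric(1), "AICc"))) {
    rg_abort("AICc undefined: columns <= parameters + 1", "criterion_error")
  }
  tab <- data.frame(
    model = candidates,
    logLik = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    k = vapply(fits, `[[`, numeric(1), "n_free_parameters"),
    BIC = vapply(fits, `[[`, numeric(1), "BIC"),
    AICc = vapply(fits, `[[`, numeric(1), "AICc"),
    row.names = NULL)
  tab <- tab[order(tab[[criterion]]), ]
  list(table = tab, fits = fits, best = tab$model[1], criterion = criterion)
}

#' Simulate an alignment along a tree
#'
#' Root states are drawn from the model's base frequencies and evolved
#' along branches via transition probabilities; `+G` sites draw a discrete
#' gamma rate category (4 classes), `+I` sites are invariant with
#' probability `p_inv`. Deterministic under a fixed seed.
#'
#' @param tree A `phylo` with branch lengths.
#' @param model Model string (see [log_likelihood()]).
#' @param n_columns Number of columns to simulate.
#' @param seed Integer seed.
#' @param shape Gamma shape (used when the model has `+G`).
#' @param p_inv Invariant proportion (when `+I`).
#' @param base_freq,Q Base frequencies and exchangeabilities (defaults
#'   uniform).
#' @param locus Locus name for the result.
#' @return A [locus_alignment()] whose rows are the tree's tips.
#' @export
simulate_alignment <- function(tree, model = "JC69", n_columns = 1000,
                               seed = 1, shape = 1, p_inv = 0,
                               base_freq = NULL, Q = NULL,
                               locus = "simulated") {
  rg_check(n_columns >= 1, "n_columns must be >= 1", "parameter_error")
  spec <- parse_model(model)
  if (is.null(base_freq)) base_freq <- rep(0.25, 4)
  if (is.null(Q)) Q <- rep(1, 6)
  set.seed(seed)
  rates <- rep(1, n_columns)
  if (spec$gamma) {
    cats <- phangorn::discrete.gamma(shape, 4)
    rates <- sample(cats, n_columns, replace = TRUE)
  }
  if (spec$inv && p_inv > 0) {
    rates[stats::runif(n_columns) < p_inv] <- 0
  }
  cols <- vector("list", n_columns)
  bases <- c("a", "c", "g", "t")
  invariant <- rates == 0
  n_tips <- length(tree$tip.label)
  if (any(invariant)) {
    root_states <- sample(bases, sum(invariant), replace = TRUE,
                          prob = base_freq)
    inv_mat <- matrix(rep(root_states, each = n_tips), nrow = n_tips)
  }
  mat <- matrix("", nrow = n_tips, ncol = n_columns,
                dimnames = list(tree$tip.label, NULL))
  if (any(invariant)) mat[, invariant] <- inv_mat
  for (r in unique(rates[!invariant])) {
    idx <- which(rates == r & !invariant)
    sim <- phangorn::simSeq(tree, l = length(idx), Q = Q, bf = base_freq,
                            type = "DNA", rate = r)
    mat[, idx] <- as.character(sim)[tree$tip.label, , drop = FALSE]
  }
  locus_alignment(toupper(mat), locus = locus)
}

# Simulate under a fitted model (used by the parametric bootstrap):
# reuses the fitted tree, Q, bf, shape and p_inv.
simulate_under_fit <- function(fit, n_columns, seed) {
  spec <- parse_model(fit$model)
  pml <- fit$pml
  simulate_alignment(
    pml$tree, model = fit$model, n_columns = n_columns, seed = seed,
    shape = if (spec$gamma) pml$shape else 1,
    p_inv = if (spec$inv) pml$inv else 0,
    base_freq = pml$bf, Q = pml$Q)
}

#' Parametric-bootstrap test of gene-tree congruence
#'
#' Tests whether a locus's freely optimized phylogeny fits significantly
#' better than the reference (multilocus) topology. The observed statistic
#' is `delta = lnL_free - lnL_constrained`; its null distribution is built
#' by simulating `n_bootstrap` alignments under the constrained fit and
#' recomputing `delta` per replicate. The Monte-Carlo p-value uses the +1
#' correction: `p = (1 + #{delta* >= delta}) / (1 + B)`.
#'
#' @param locus_aln The locus alignment under test.
#' @param reference_tree The reference topology (pruned to the locus's
#'   taxa as needed).
#' @param model Model string used for all fits.
#' @param n_bootstrap Number of parametric-bootstrap replicates (minimum
#'   19 for any resolution at the 5% level).
#' @param seed Integer seed.
#' @return A `congruence_result`: `locus_name`, `lnL_free`,
#'   `lnL_constrained`, `delta`, `delta_null`, `p_value`, `n_bootstrap`.
#' @export
congruence_test <- function(locus_aln, reference_tree, model = "JC69",
                            n_bootstrap = 100, seed = 1) {
  rg_check(n_bootstrap >= 19, "n_bootstrap must be >= 19", "parameter_error")
  shared <- intersect(reference_tree$tip.label, strain_ids(locus_aln))
  rg_check(length(shared) >= 4, "need >= 4 shared taxa", "parameter_error")
  ref <- ape::unroot(ape::keep.tip(reference_tree, shared))
  aln <- locus_alignment(locus_aln$mat[shared, , drop = FALSE],
                         locus = locus_aln$locus)
  one_delta <- function(a) {
    constrained <- optimize_fit(ref, a, model)
    free <- nni_search(constrained$tree, a, model)
    list(constrained = constrained, free = free,
         delta = max(free$log_likelihood - constrained$log_likelihood, 0))
  }
  obs <- one_delta(aln)
  null_delta <- numeric(n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    sim <- simulate_under_fit(obs$constrained, aln$n_columns,
                              seed = seed + b)
    null_delta[b] <- one_delta(sim)$delta
  }
  structure(list(
    locus_name = aln$locus,
    lnL_free = obs$free$log_likelihood,
    lnL_constrained = obs$constrained$log_likelihood,
    delta = obs$delta, delta_null = null_delta,
    p_value = (1 + sum(null_delta >= obs$delta)) / (1 + n_bootstrap),
    n_bootstrap = n_bootstrap), class = "congruence_result")
}

#' @export
print.congruence_result <- function(x, ...) {
  cat(sprintf(
    "<congruence_result> %s: delta lnL = %.3f, p = %.4f (B = %d)\n",
    x$locus_name, x$delta, x$p_value, x$n_bootstrap))
  invisible(x)
}
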