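# Synthetic-study generator: genospecies backbone + within-genospecies
# subtrees, multilocus sequences with optional symbiotic-locus horizontal
# transfer, spatially clustered geography, per-collection soil pH, and a
# reference panel - all with known ground truth for downstream validation.

REFERENCE_SPECIES <- c(
  "R. phaseoli", "R. etli", "R. aethiopicum", "R. sophoriradicis",
  "R. ecuadorense", "R. leucaenae", "R. tropici", "A. tumefaciens",
  "R. giardinii", "R. lentis", "R. sophorae", "R. chutanense")
OFFPANEL_SPECIES <- c("R. galegae", "R. gallicum", "R. anhuiense",
                      "R. mesoamericanum")

#' Configuration for a synthetic rhizobial study
#'
#' Defaults emulate the structure of the Ethiopian common-bean rhizobia
#' collections: ~95 local strains in 8 genospecies with two dominant
#' species holding ~70% of strains, four housekeeping loci (548, 461, 349,
#' 784 bp, concatenating to 2142) plus one 465-bp symbiotic locus, two
#' collections sampled over a ~400 km region with soil pH 4.68-6.44
#' (current) and 6.0-8.78 (previous), and one reference strain per
#' genospecies plus off-panel deep lineages.
#'
#' @param n_genospecies Number of genospecies.
#' @param n_strains Total local (non-reference) strains.
#' @param proportions Expected genospecies proportions (recycled /
#'   normalized to `n_genospecies`).
#' @param locus_lengths Named lengths of the housekeeping loci.
#' @param sym_locus_length Length of the symbiotic locus.
#' @param model Substitution model for sequence simulation.
#' @param shape Gamma shape (rate heterogeneity) for simulation.
#' @param between_depth Expected substitutions/site from root to tip of
#'   the genospecies backbone (between-genospecies divergence scale).
#' @param within_depth Crown depth of each genospecies (within-genospecies
#'   divergence scale); must be < `between_depth`.
#' @param hgt_probability Chance a strain's symbiotic locus descends from
#'   another genospecies' symbiotic clade.
#' @param spatial_decay Spatial clustering strength lambda; 0 = uniform
#'   field (no structure), larger = tighter genospecies-specific clusters.
#' @param ph_ranges List of two pH ranges, `current` and `previous`.
#' @param ph_associated_clade Optional genospecies index confined to pH
#'   above `ph_cutoff` (hence effectively to the high-pH collection).
#' @param ph_cutoff pH cutoff for the associated clade.
#' @param region_extent_km Side of the square sampling region.
#' @param current_fraction Fraction of local strains in the "current"
#'   collection.
#' @param n_offpanel Number of off-panel reference species (deep lineages
#'   without local strains).
#' @param sym_missing_genospecies Optional genospecies index whose strains
#'   lack the symbiotic locus.
#' @return A `study_config` list.
#' @export
study_config <- function(n_genospecies = 8, n_strains = 95,
                         proportions = c(0.35, 0.35, 0.08, 0.06, 0.05,
                                         0.04, 0.04, 0.03),
                         locus_lengths = c("16S" = 548, glnII = 461,
                                           recA = 349, rpoB = 784),
                         sym_locus_length = c(nodC = 465),
                         model = "GTR+G", shape = 0.5,
                         between_depth = 0.08, within_depth = 0.01,
                         hgt_probability = 0, spatial_decay = 0,
                         ph_ranges = list(current = c(4.68, 6.44),
                                          previous = c(6.0, 8.78)),
                         ph_associated_clade = NULL, ph_cutoff = 6.5,
                         region_extent_km = 400,
                         current_fraction = 72 / 95,
                         n_offpanel = 3,
                         sym_missing_genospecies = NULL) {
  rg_check(within_depth < between_depth,
           "within_depth must be smaller than between_depth", "config_error")
  rg_check(hgt_probability >= 0 && hgt_probability <= 1,
           "hgt_probability must be in [0, 1]", "config_error")
  rg_check(spatial_decay >= 0, "spatial_decay must be >= 0", "config_error")
  if (!is.null(ph_associated_clade)) {
    hi <- vapply(ph_ranges, max, numeric(1))
    rg_check(any(hi > ph_cutoff),
             "no collection's pH range reaches above ph_cutoff",
             "config_error")
  }
  proportions <- rep_len(proportions, n_genospecies)
  structure(list(
    n_genospecies = n_genospecies, n_strains = n_strains,
    proportions = proportions / sum(proportions),
    locus_lengths = locus_lengths, sym_locus_length = sym_locus_length,
    model = model, shape = shape,
    between_depth = between_depth, within_depth = within_depth,
    hgt_probability = hgt_probability, spatial_decay = spatial_decay,
    ph_ranges = ph_ranges, ph_associated_clade = ph_associated_clade,
    ph_cutoff = ph_cutoff, region_extent_km = region_extent_km,
    current_fraction = current_fraction, n_offpanel = n_offpanel,
    sym_missing_genospecies = sym_missing_genospecies),
    class = "study_config")
}

# Graft subtree y (with y$root.edge set) in place of tip `tip` of x.
.graft_at_tip <- function(x, y, tip) {
  ape::bind.tree(x, y, where = which(x$tip.label == tip))
}

# GC-rich base composition and GTR exchangeabilities used for all
# simulated loci (rhizobial housekeeping genes are ~60% GC).
.SIM_BF <- c(0.19, 0.31, 0.30, 0.20)
.SIM_Q <- c(1.1, 3.2, 0.8, 0.9, 3.5, 1.0)

#' Simulate a complete synthetic study
#'
#' Builds a genospecies backbone tree with within-genospecies subtrees and
#' a reference panel, simulates housekeeping loci on that tree and the
#' symbiotic locus on a copy in which flagged strains are re-grafted into
#' donor genospecies clades (horizontal transfer), then draws geography
#' (genospecies-clustered with strength `spatial_decay`), collections and
#' soil pH. Deterministic for a fixed seed.
#'
#' @param config A [study_config()].
#' @param seed Integer seed.
#' @return A `synthetic_study` list: `loci` (housekeeping
#'   [locus_alignment()]s), `sym` (symbiotic locus), `metadata` (strain
#'   table), `truth` (ground-truth table: genospecies, symbiovar donor,
#'   coordinates, pH, collection), `hk_tree`, `sym_tree`, `config`.
#' @export
simulate_study <- function(config = study_config(), seed = 1) {
  set.seed(seed)
  ng <- config$n_genospecies
  # genospecies sizes: expected proportions, at least 2 strains each
  sizes <- pmax(2L, round(config$proportions * config$n_strains))
  species_names <- rep_len(REFERENCE_SPECIES, ng)

  # backbone over genospecies + off-panel lineages, scaled to between_depth
  n_back <- ng + config$n_offpanel
  backbone <- ape::rcoal(n_back, tip.label = c(
    paste0("G", seq_len(ng)),
    if (config$n_offpanel > 0) paste0("OFF", seq_len(config$n_offpanel))))
  backbone$edge.length <- backbone$edge.length /
    max(ape::node.depth.edgelength(backbone)) * config$between_depth

  strain_ids_by_g <- vector("list", ng)
  tree <- backbone
  for (g in seq_len(ng)) {
    ids <- sprintf("ST%02d_%03d", g, seq_len(sizes[g]))
    strain_ids_by_g[[g]] <- ids
    sub <- ape::rcoal(sizes[g] + 1L, tip.label = c(ids, paste0("REF", g)))
    sub$edge.length <- sub$edge.length /
      max(ape::node.depth.edgelength(sub)) * config$within_depth
    # reference = a deeper lineage within the genospecies clade
    ref_edge <- which(sub$edge[, 2] == which(sub$tip.label == paste0("REF", g)))
    sub$edge.length[ref_edge] <- sub$edge.length[ref_edge] +
      config$within_depth
    sub$root.edge <- config$within_depth / 2
    tree <- .graft_at_tip(tree, sub, paste0("G", g))
  }
  if (config$n_offpanel > 0) {
    tree$tip.label[grepl("^OFF", tree$tip.label)] <-
      paste0("REFX", seq_len(config$n_offpanel))
  }

  strains <- unlist(strain_ids_by_g)
  truth_g <- rep(seq_len(ng), sizes)

  # symbiotic tree: re-graft HGT strains into donor genospecies clades
  sym_tree <- tree
  hgt <- stats::runif(length(strains)) < config$hgt_probability
  donor <- truth_g
  for (i in which(hgt)) {
    donor[i] <- sample(setdiff(seq_len(ng), truth_g[i]), 1)
    host <- sample(strain_ids_by_g[[donor[i]]], 1)
    sym_tree <- ape::drop.tip(sym_tree, strains[i])
    graft <- list(edge = matrix(c(2L, 1L), 1), tip.label = strains[i],
                  edge.length = config$within_depth / 4, Nnode = 1L)
    class(graft) <- "phylo"
    graft$root.edge <- 0
    sym_tree <- ape::bind.tree(
      sym_tree, graft, where = which(sym_tree$tip.label == host),
      position = min(config$within_depth / 4,
                     sym_tree$edge.length[
                       which(sym_tree$edge[, 2] ==
                               which(sym_tree$tip.label == host))] / 2))
  }

  # sequences
  loci <- vector("list", length(config$locus_lengths))
  names(loci) <- names(config$locus_lengths)
  for (j in seq_along(config$locus_lengths)) {
    loci[[j]] <- simulate_alignment(
      tree, model = config$model, n_columns = config$locus_lengths[[j]],
      seed = seed * 101 + j, shape = config$shape,
      base_freq = .SIM_BF, Q = .SIM_Q, locus = names(loci)[j])
  }
  sym_ids_keep <- sym_tree$tip.label
  if (!is.null(config$sym_missing_genospecies)) {
    missing_ids <- unlist(strain_ids_by_g[config$sym_missing_genospecies])
    sym_ids_keep <- setdiff(sym_ids_keep, missing_ids)
  }
  sym_sim_tree <- if (length(sym_ids_keep) < length(sym_tree$tip.label))
    ape::keep.tip(sym_tree, sym_ids_keep) else sym_tree
  sym <- simulate_alignment(
    sym_sim_tree, model = config$model,
    n_columns = config$sym_locus_length[[1]],
    seed = seed * 101 + 99, shape = config$shape,
    base_freq = .SIM_BF, Q = .SIM_Q,
    locus = names(config$sym_locus_length))

  # collections: pH-associated clade confined to collections whose pH
  # range reaches above the cutoff
  set.seed(seed + 7)
  n_local <- length(strains)
  collection <- ifelse(stats::runif(n_local) < config$current_fraction,
                       "current", "previous")
  reaches <- vapply(config$ph_ranges, function(r) max(r) > config$ph_cutoff,
                    logical(1))
  if (!is.null(config$ph_associated_clade)) {
    in_clade <- truth_g %in% config$ph_associated_clade
    allowed <- names(config$ph_ranges)[reaches]
    collection[in_clade] <- sample(allowed, sum(in_clade), replace = TRUE)
  }
  ph <- numeric(n_local)
  for (cl in names(config$ph_ranges)) {
    idx <- collection == cl
    r <- config$ph_ranges[[cl]]
    ph[idx] <- stats::runif(sum(idx), r[1], r[2])
  }
  if (!is.null(config$ph_associated_clade)) {
    in_clade <- truth_g %in% config$ph_associated_clade
    for (cl in names(config$ph_ranges)) {
      idx <- in_clade & collection == cl
      r <- config$ph_ranges[[cl]]
      ph[idx] <- stats::runif(sum(idx), max(r[1], config$ph_cutoff), r[2])
    }
  }

  # geography: lambda = 0 -> uniform field; lambda > 0 -> genospecies
  # Gaussian clusters with dispersion extent / (2 * (1 + lambda))
  extent <- config$region_extent_km
  if (config$spatial_decay == 0) {
    xy <- cbind(stats::runif(n_local, 0, extent),
                stats::runif(n_local, 0, extent))
  } else {
    centers <- cbind(stats::runif(ng, 0, extent),
                     stats::runif(ng, 0, extent))
    sigma <- extent / (2 * (1 + config$spatial_decay))
    xy <- centers[truth_g, ] +
      matrix(stats::rnorm(2 * n_local, 0, sigma), ncol = 2)
    xy <- pmin(pmax(xy, 0), extent)
  }
  origin <- c(lat = 7.0, lon = 38.0)  # southern Ethiopia
  lat <- origin["lat"] + xy[, 2] / 111.195
  lon <- origin["lon"] + xy[, 1] /
    (111.195 * cos(origin["lat"] * pi / 180))

  ref_ids <- c(paste0("REF", seq_len(ng)),
               if (config$n_offpanel > 0)
                 paste0("REFX", seq_len(config$n_offpanel)))
  ref_species <- c(species_names,
                   if (config$n_offpanel > 0)
                     rep_len(OFFPANEL_SPECIES, config$n_offpanel))

  metadata <- rbind(
    data.frame(strain_id = strains, collection = collection,
               reference_species = NA_character_,
               latitude = lat, longitude = lon,
               elevation = round(1400 + 6 * xy[, 2] +
                                   stats::rnorm(n_local, 0, 80)),
               soil_pH = round(ph, 2), stringsAsFactors = FALSE),
    data.frame(strain_id = ref_ids, collection = "reference",
               reference_species = ref_species,
               latitude = NA_real_, longitude = NA_real_,
               elevation = NA_real_, soil_pH = NA_real_,
               stringsAsFactors = FALSE))
  truth <- data.frame(
    strain_id = strains,
    genospecies = species_names[truth_g],
    genospecies_index = truth_g,
    symbiovar_donor = species_names[donor],
    hgt = hgt, collection = collection,
    latitude = lat, longitude = lon, soil_pH = round(ph, 2),
    has_sym = strains %in% sym_sim_tree$tip.label,
    stringsAsFactors = FALSE)
  structure(list(loci = loci, sym = sym, metadata = metadata,
                 truth = truth, hk_tree = tree, sym_tree = sym_sim_tree,
                 config = config, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d local strains in %d genospecies, %d hk loci + %s; seed %d\n",
    nrow(x$truth), x$config$n_genospecies, length(x$loci),
    x$sym$locus, x$seed))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits `locus_<name>.fasta` per locus, `metadata.csv` (pipeline input)
#' and `truth.csv` (evaluation harness only).
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (l in c(study$loci, list(study$sym))) {
    write_fasta(l, file.path(dir, paste0("locus_", l$locus, ".fasta")))
  }
  utils::write.csv(study$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(study$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Score pipeline outputs against ground truth
#'
#' @param assignment A `clade_assignment` over the study's local strains.
#' @param truth The study's `truth` table.
#' @param mantel_result Optional `mantel_result` for the spatial decision.
#' @param composition_p Optional composition-test p-value.
#' @param alpha Decision level.
#' @return List: `assignment_accuracy` (fraction of strains whose label
#'   matches the reference species of their true genospecies),
#'   `mantel_decision`, `composition_decision`.
#' @export
evaluate_recovery <- function(assignment, truth, mantel_result = NULL,
                              composition_p = NULL, alpha = 0.05) {
  idx <- match(truth$strain_id, assignment$strain_id)
  ok <- !is.na(idx)
  acc <- mean(assignment$label[idx[ok]] == truth$genospecies[ok])
  list(
    assignment_accuracy = acc,
    n_scored = sum(ok),
    mantel_decision = if (!is.null(mantel_result)) {
      if (mantel_result$p_value <= alpha) "structure" else "no structure"
    } else NA_character_,
    composition_decision = if (!is.null(composition_p)) {
      if (composition_p <= alpha) "different" else "not different"
    } else NA_character_)
}
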