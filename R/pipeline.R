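# End-to-end orchestration: harmonize -> concatenate -> bootstrap trees ->
# genospecies/symbiovar assignment -> diversity tables -> spatial
# statistics -> congruence tests, from one configuration list (or YAML),
# with CSV artifacts and a machine-readable JSON summary.

#' Default pipeline configuration
#'
#' @param support_threshold Clade-support threshold (percent) for
#'   assignment.
#' @param bootstrap_reps Bootstrap replicates for clade supports.
#' @param mantel_perms Permutations for Mantel / partial Mantel /
#'   PERMANOVA.
#' @param window Sliding-window settings: `width_km`, `step_km`,
#'   `n_resamples`.
#' @param congruence Congruence-test settings: `enabled`, `model`,
#'   `n_bootstrap`, `max_taxa` (taxa are deterministically subsampled for
#'   tractability on large studies).
#' @param seed Base seed; each stochastic stage derives its own fixed
#'   offset from it.
#' @param out_dir Optional directory for CSV/Newick/JSON artifacts.
#' @export
pipeline_config <- function(support_threshold = 60, bootstrap_reps = 100,
                            mantel_perms = 999,
                            window = list(width_km = 80, step_km = 10,
                                          n_resamples = 1),
                            congruence = list(enabled = TRUE,
                                              model = "HKY+G",
                                              n_bootstrap = 24,
                                              max_taxa = 24),
                            seed = 1, out_dir = NULL) {
  list(support_threshold = support_threshold,
       bootstrap_reps = bootstrap_reps, mantel_perms = mantel_perms,
       window = window, congruence = congruence, seed = seed,
       out_dir = out_dir)
}

#' Read pipeline inputs from a directory
#'
#' Expects `locus_<name>.fasta` files and `metadata.csv` as written by
#' [write_study()].
#'
#' @param dir Input directory.
#' @param sym_locus Name of the symbiotic locus (default `nodC`).
#' @return List: `loci` (housekeeping), `sym`, `metadata`.
#' @export
read_study <- function(dir, sym_locus = "nodC") {
  files <- list.files(dir, pattern = "^locus_.*\\.fasta$", full.names = TRUE)
  rg_check(length(files) >= 2, sprintf("no locus FASTA files in %s", dir),
           "io_error")
  alns <- lapply(files, function(f)
    read_fasta(f, locus = sub("^locus_(.*)\\.fasta$", "\\1", basename(f))))
  names(alns) <- vapply(alns, `[[`, character(1), "locus")
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  validate_metadata(meta)
  list(loci = alns[setdiff(names(alns), sym_locus)],
       sym = alns[[sym_locus]], metadata = meta)
}

# assignment for one level: bootstrap supports on the concatenated (or
# single-locus) alignment, midpoint rooting, smallest-supported-clade rule
.assign_level <- function(aln, meta, config, seed_offset) {
  bs <- bootstrap_supports(aln, builder = nj_builder("p"),
                           n_replicates = config$bootstrap_reps,
                           seed = config$seed + seed_offset)
  rooted <- attach_supports(root_tree(bs$tree), bs$supports)
  meta_here <- meta[meta$strain_id %in% rooted$tip.label, ]
  list(assignment = assign_clades(rooted, meta_here,
                                  config$support_threshold),
       tree = rooted, supports = bs$supports)
}

#' Run the full phylogeographic analysis
#'
#' Housekeeping and symbiotic loci are analysed separately throughout
#' (separate concatenation/trees/assignments/diversity), then combined
#' only in the genospecies x symbiovar cross-tabulation.
#'
#' @param inputs List with `loci` (housekeeping [locus_alignment()]s),
#'   `sym` (symbiotic locus alignment or `NULL`), `metadata` - as from
#'   [read_study()] or a [simulate_study()] result.
#' @param config A [pipeline_config()].
#' @return A `rhizogeo_run` with components `assignment_hk`,
#'   `assignment_sym`, `trees`, `concat`, `crosstab`, `diversity`,
#'   `mantel`, `permanova`, `windows`, `composition`, `congruence`,
#'   `summary` (plain list mirrored to JSON).
#' @export
run_pipeline <- function(inputs, config = pipeline_config()) {
  meta <- validate_metadata(inputs$metadata)
  hk <- harmonize(inputs$loci)
  concat <- concatenate(hk)

  hk_level <- .assign_level(concat, meta, config, seed_offset = 11)
  assignment_hk <- hk_level$assignment

  assignment_sym <- NULL
  sym_level <- NULL
  n_sym_dropped <- 0L
  if (!is.null(inputs$sym)) {
    sym_level <- .assign_level(inputs$sym, meta, config, seed_offset = 13)
    assignment_sym <- sym_level$assignment
    n_sym_dropped <- sum(!meta$strain_id %in% strain_ids(inputs$sym))
  }

  crosstab <- if (!is.null(assignment_sym))
    cross_tabulate(assignment_hk, assignment_sym) else NULL

  # diversity per genospecies (groups with >= 2 strains) and per collection
  local_ids <- meta$strain_id[meta$collection != "reference" &
                                meta$strain_id %in% strain_ids(concat)]
  labels <- stats::setNames(assignment_hk$label, assignment_hk$strain_id)
  div_rows <- list()
  for (lab in unique(labels[local_ids])) {
    ids <- local_ids[labels[local_ids] == lab]
    if (length(ids) < 2) next
    p <- diversity_profile(hk, ids, group_name = lab)
    div_rows[[lab]] <- data.frame(group = lab, n = p$n_strains,
                                  pi = p$pi, locus = p$locus)
  }
  diversity_genospecies <- if (length(div_rows)) do.call(rbind, div_rows)
    else data.frame(group = character(), n = integer(),
                    pi = numeric(), locus = numeric())
  rownames(diversity_genospecies) <- NULL
  group_sets <- list(
    references = meta$strain_id[meta$collection == "reference" &
                                  meta$strain_id %in% strain_ids(concat)],
    previous = meta$strain_id[meta$collection == "previous" &
                                meta$strain_id %in% strain_ids(concat)],
    current = meta$strain_id[meta$collection == "current" &
                               meta$strain_id %in% strain_ids(concat)],
    all_local = local_ids)
  ref_labels <- stats::setNames(meta$reference_species, meta$strain_id)
  all_labels <- c(labels, ref_labels[!is.na(ref_labels)])
  div_groups <- list()
  for (gname in names(group_sets)) {
    ids <- group_sets[[gname]]
    if (length(ids) < 2) next
    p <- diversity_profile(hk, ids, labels = all_labels, group_name = gname)
    div_groups[[gname]] <- data.frame(
      group = gname, n = p$n_strains, pi = p$pi, locus = p$locus,
      shannon = p$shannon, simpson = p$simpson)
  }
  diversity_groups <- do.call(rbind, div_groups)
  rownames(diversity_groups) <- NULL

  # spatial statistics on local strains with coordinates
  d_geo <- geo_distance(meta[meta$collection != "reference", ])
  d_nuc <- p_distance(concat)
  d_hap <- allele_sharing_distance(hk)
  d_sp <- species_distance(labels)
  env_meta <- meta[match(rownames(d_geo), meta$strain_id), ]
  d_ph <- .abs_diff_matrix(env_meta$soil_pH, rownames(d_geo))
  d_alt <- .abs_diff_matrix(env_meta$elevation, rownames(d_geo))
  d_src <- .as_dist_matrix(outer(env_meta$collection, env_meta$collection,
                                 `!=`) * 1, rownames(d_geo), "source")
  gen_mats <- list(nucleotide = d_nuc, haplotype = d_hap, species = d_sp)
  mantel_rows <- list()
  for (lvl in names(gen_mats)) {
    combos <- list(
      list(d2 = d_geo, cov = NULL, d2n = "Geo", cn = ""),
      list(d2 = d_src, cov = NULL, d2n = "Source", cn = ""),
      list(d2 = d_ph, cov = NULL, d2n = "pH", cn = ""),
      list(d2 = d_alt, cov = NULL, d2n = "Alt", cn = ""),
      list(d2 = d_geo, cov = d_src, d2n = "Geo", cn = "Source"),
      list(d2 = d_geo, cov = d_ph, d2n = "Geo", cn = "pH"),
      list(d2 = d_geo, cov = d_alt, d2n = "Geo", cn = "Alt"),
      list(d2 = d_alt, cov = d_src, d2n = "Alt", cn = "Source"))
    for (cb in combos) {
      res <- if (is.null(cb$cov)) {
        mantel(gen_mats[[lvl]], cb$d2, permutations = config$mantel_perms,
               seed = config$seed + 17)
      } else {
        partial_mantel(gen_mats[[lvl]], cb$d2, cb$cov,
                       permutations = config$mantel_perms,
                       seed = config$seed + 17, covariate = cb$cn)
      }
      mantel_rows[[length(mantel_rows) + 1L]] <- data.frame(
        level = lvl, D1 = lvl, D2 = cb$d2n, covariate = cb$cn,
        r = res$r, p = res$p_value)
    }
  }
  mantel_table <- do.call(rbind, mantel_rows)

  covs <- data.frame(Long = env_meta$longitude, Lat = env_meta$latitude,
                     Alt = env_meta$elevation, pH = env_meta$soil_pH,
                     row.names = env_meta$strain_id)
  perm_table <- permanova(d_nuc, covs, n_perm = config$mantel_perms,
                          seed = config$seed + 19)

  windows <- lapply(gen_mats, function(m)
    sliding_window(d_geo, m, width_km = config$window$width_km,
                   step_km = config$window$step_km,
                   n_resamples = config$window$n_resamples,
                   seed = config$seed + 23))

  pcoa_gen <- pcoa(d_nuc[rownames(d_geo), rownames(d_geo)], n_axes = 2)
  pcoa_geo <- pcoa(d_geo, n_axes = 2)

  comp <- .composition_by_collection(assignment_hk, meta,
                                     seed = config$seed + 29)

  congruence <- NULL
  if (isTRUE(config$congruence$enabled)) {
    congruence <- .run_congruence(hk, inputs$sym, concat, hk_level$tree,
                                  config)
  }

  summary <- list(
    n_strains = length(local_ids),
    n_loci = length(hk),
    concat_columns = concat$n_columns,
    n_genospecies_labels = length(unique(labels[local_ids])),
    crosstab_total = if (!is.null(crosstab)) crosstab$grand_total else NA,
    n_sym_dropped = n_sym_dropped,
    mantel = mantel_table,
    composition_p = comp$p_value,
    congruence_p = if (!is.null(congruence))
      stats::setNames(vapply(congruence, `[[`, numeric(1), "p_value"),
                      vapply(congruence, `[[`, character(1), "locus_name"))
      else NULL,
    seed = config$seed)

  run <- structure(list(
    assignment_hk = assignment_hk, assignment_sym = assignment_sym,
    trees = list(hk = hk_level$tree,
                 sym = if (!is.null(sym_level)) sym_level$tree else NULL),
    concat = concat, crosstab = crosstab,
    diversity = list(genospecies = diversity_genospecies,
                     groups = diversity_groups),
    mantel = mantel_table, permanova = perm_table, windows = windows,
    pcoa = list(genetic = pcoa_gen, geographic = pcoa_geo),
    composition = comp, congruence = congruence,
    summary = summary, config = config), class = "rhizogeo_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

.abs_diff_matrix <- function(v, labels) {
  .as_dist_matrix(abs(outer(v, v, `-`)), labels, "abs-diff")
}

.composition_by_collection <- function(assignment, meta, seed) {
  coll <- meta$collection[match(assignment$strain_id, meta$strain_id)]
  keep <- coll %in% c("current", "previous")
  tab <- table(coll[keep], assignment$label[keep])
  if (nrow(tab) < 2) return(list(p_value = NA_real_, method = "degenerate"))
  c(composition_test(tab, seed = seed), list(table = tab))
}

.run_congruence <- function(hk, sym, concat, ref_tree, config) {
  cfg <- config$congruence
  ref <- ape::unroot(ref_tree)
  taxa <- ref$tip.label
  if (length(taxa) > cfg$max_taxa) {
    set.seed(config$seed + 31)
    taxa <- sort(sample(taxa, cfg$max_taxa))
  }
  loci <- c(hk, if (!is.null(sym)) list(sym))
  lapply(loci, function(l) {
    shared <- intersect(taxa, strain_ids(l))
    congruence_test(l, ape::keep.tip(ref, shared), model = cfg$model,
                    n_bootstrap = cfg$n_bootstrap,
                    seed = config$seed + 37)
  })
}

#' Write pipeline artifacts
#'
#' CSV tables, Newick trees and `summary.json` under `dir`.
#'
#' @param run A `rhizogeo_run`.
#' @param dir Output directory.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(
    df, file.path(dir, name), row.names = FALSE)
  w(as.data.frame(run$assignment_hk), "assignment_hk.csv")
  if (!is.null(run$assignment_sym))
    w(as.data.frame(run$assignment_sym), "assignment_sym.csv")
  if (!is.null(run$crosstab)) {
    m <- cbind(run$crosstab$counts, Total = run$crosstab$row_totals)
    m <- rbind(m, Total = c(run$crosstab$col_totals,
                            run$crosstab$grand_total))
    utils::write.csv(m, file.path(dir, "crosstab.csv"))
  }
  w(run$diversity$genospecies, "diversity_genospecies.csv")
  w(run$diversity$groups, "diversity_groups.csv")
  w(run$mantel, "mantel.csv")
  w(as.data.frame(run$permanova), "permanova.csv")
  for (lvl in names(run$windows))
    w(run$windows[[lvl]], paste0("window_", lvl, ".csv"))
  write_newick(run$trees$hk, file.path(dir, "tree_hk.nwk"))
  if (!is.null(run$trees$sym))
    write_newick(run$trees$sym, file.path(dir, "tree_sym.nwk"))
  if (!is.null(run$congruence)) {
    w(data.frame(
      locus = vapply(run$congruence, `[[`, character(1), "locus_name"),
      delta = vapply(run$congruence, `[[`, numeric(1), "delta"),
      p_value = vapply(run$congruence, `[[`, numeric(1), "p_value")),
      "congruence.csv")
  }
  writeLines(run_summary_json(run), file.path(dir, "summary.json"))
  invisible(dir)
}

#' JSON summary of a pipeline run
#'
#' Deterministic (byte-identical for identical inputs and seeds).
#'
#' @param run A `rhizogeo_run`.
#' @export
run_summary_json <- function(run) {
  as.character(jsonlite::toJSON(run$summary, auto_unbox = TRUE,
                                digits = 10, na = "null", null = "null"))
}

#' @export
print.rhizogeo_run <- function(x, ...) {
  cat("<rhizogeo_run>\n")
  cat(sprintf("  %d local strains, %d hk loci (%d concatenated columns)\n",
              x$summary$n_strains, x$summary$n_loci,
              x$summary$concat_columns))
  cat(sprintf("  genospecies labels: %d; composition p = %s\n",
              x$summary$n_genospecies_labels,
              format(x$summary$composition_p, digits = 3)))
  geo <- x$mantel[x$mantel$D2 == "Geo" & x$mantel$covariate == "", ]
  cat(sprintf("  Mantel (genetic ~ geographic): %s\n",
              paste(sprintf("%s r = %.3f (p = %.3f)", geo$level, geo$r,
                            geo$p), collapse = "; ")))
  if (!is.null(x$summary$congruence_p)) {
    cat("  congruence p:",
        paste(sprintf("%s = %.3f", names(x$summary$congruence_p),
                      x$summary$congruence_p), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.rhizogeo_run <- function(object, ...) {
  print(object)
  cat("\nDiversity by group:\n")
  print(object$diversity$groups, digits = 3)
  cat("\nPERMANOVA:\n")
  print(as.data.frame(object$permanova), digits = 3)
  invisible(object$summary)
}

#' Run the pipeline from a YAML configuration file
#'
#' The YAML may contain an `input: <dir>` block or a `simulate:` block of
#' [study_config()] fields, plus any [pipeline_config()] fields.
#'
#' @param path YAML file path.
#' @return A `rhizogeo_run`.
#' @export
run_pipeline_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  pconf <- do.call(pipeline_config,
                   cfg[intersect(names(cfg), names(formals(pipeline_config)))])
  inputs <- if (!is.null(cfg$input)) {
    read_study(cfg$input)
  } else if (!is.null(cfg$simulate)) {
    sim_seed <- cfg$simulate$seed %||% pconf$seed
    sc <- do.call(study_config,
                  cfg$simulate[intersect(names(cfg$simulate),
                                         names(formals(study_config)))])
    simulate_study(sc, seed = sim_seed)
  } else {
    rg_abort("config needs an 'input' directory or a 'simulate' block",
             "config_error")
  }
  run_pipeline(inputs, pconf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
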