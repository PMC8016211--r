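test_that("great-circle distances use the mean Earth radius", {
  md <- data.frame(strain_id = c("a", "b", "c"),
                   latitude = c(0, 0, 10), longitude = c(0, 1, 10))
  d <- geo_distance(md)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 111.195, tolerance = 1e-4)
  expect_equal(d, t(d))
  # triangle inequality on random triples
  set.seed(1)
  md2 <- data.frame(strain_id = paste0("s", 1:6),
                    latitude = runif(6, -30, 30),
                    longitude = runif(6, 0, 60))
  d2 <- geo_distance(md2)
  for (k in 1:20) {
    ijk <- sample(6, 3)
    expect_lte(d2[ijk[1], ijk[3]],
               d2[ijk[1], ijk[2]] + d2[ijk[2], ijk[3]] + 1e-9)
  }
  md3 <- data.frame(strain_id = c("a", "b", "x"),
                    latitude = c(0, 1, NA), longitude = c(0, 1, 5))
  d3 <- geo_distance(md3)
  expect_equal(attr(d3, "excluded"), "x")
  expect_equal(rownames(d3), c("a", "b"))
})

test_that("Mantel r and permutation p behave as specified", {
  A <- rand_dist(6, 11)
  self <- mantel(A, A, permutations = 99, seed = 1)
  expect_equal(self$r, 1)

  # exact enumeration equals independent brute force, and random-permutation
  # p converges to it
  A5 <- rand_dist(5, 21)
  B5 <- rand_dist(5, 22)
  me <- mantel(A5, B5, permutations = "exact")
  rs <- vapply(all_perms(5), function(p)
    cor(A5[p, p][upper.tri(A5)], B5[upper.tri(B5)]), numeric(1))
  expect_equal(me$p_value, mean(rs >= me$r))
  expect_equal(me$n_permutations, 120)
  mr <- mantel(A5, B5, permutations = 9999, seed = 5)
  expect_lt(abs(mr$p_value - me$p_value), 0.03)
  expect_equal(mr$r, me$r)

  # agreement with the community-standard implementation
  mv <- vegan::mantel(as.dist(A5), as.dist(B5), permutations = 999)
  expect_equal(me$r, unname(mv$statistic))

  flat <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(flat) <- 0
  expect_error(mantel(flat * 0, A[1:4, 1:4]),
               class = "undefined_correlation_error")
})

test_that("Mantel type-I error is controlled under independence", {
  set.seed(33)
  rej <- 0
  n_runs <- 60
  for (i in seq_len(n_runs)) {
    A <- rand_dist(8, 100 + i)
    B <- rand_dist(8, 900 + i)
    if (mantel(A, B, permutations = 99, seed = i)$p_value <= 0.05)
      rej <- rej + 1
  }
  # binomial(60, 0.05): observing > 9 rejections has probability < 1e-3
  expect_lte(rej, 9)
})

test_that("partial Mantel removes the covariate's contribution", {
  set.seed(8)
  n <- 20
  z <- runif(n)
  cov_d <- abs(outer(z, z, `-`))
  dimnames(cov_d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  noise <- function(seed) rand_dist(n, seed) * 0.1
  # genetic distance built purely from the covariate -> partial r ~ 0
  gen <- cov_d + noise(1)
  dimnames(gen) <- dimnames(cov_d)
  geo <- cov_d + noise(2)
  dimnames(geo) <- dimnames(cov_d)
  pm <- partial_mantel(gen, geo, cov_d, permutations = 199, seed = 3)
  simple <- mantel(gen, geo, permutations = 199, seed = 3)
  expect_lt(abs(pm$r), abs(simple$r))
  expect_true(abs(pm$r) <= 1)

  # covariate uncorrelated with both -> partial r ~ simple r
  unrel <- rand_dist(n, 77)
  dimnames(unrel) <- dimnames(cov_d)
  pm2 <- partial_mantel(gen, geo, unrel, permutations = 199, seed = 3)
  expect_equal(pm2$r, simple$r, tolerance = 0.1)
  expect_error(partial_mantel(gen, cov_d, cov_d, permutations = 99),
               class = "collinearity_error")
})

test_that("PCoA recovers planar configurations through Gower centering", {
  pts <- cbind(c(0, 3, 1, 4, 2), c(0, 1, 4, 3, 2))
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("p", 1:5), paste0("p", 1:5))
  pc <- pcoa(D, 2)
  expect_lt(max(abs(as.matrix(dist(pc$coordinates)) - D)), 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-9))

  # three equidistant points: two equal positive eigenvalues
  D3 <- matrix(1, 3, 3) - diag(3)
  dimnames(D3) <- list(letters[1:3], letters[1:3])
  pc3 <- pcoa(D3, 2)
  pos <- pc3$eigenvalues[pc3$eigenvalues > 1e-10]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2])

  # two points at distance d: one axis at +/- d/2
  D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  pc2 <- suppressWarnings(pcoa(D2, 2))
  expect_equal(sort(pc2$coordinates[, 1]), c(-1.5, 1.5),
               ignore_attr = TRUE)

  # matches the standard implementation on a non-Euclidean matrix
  R <- rand_dist(7, 5)
  mine <- pcoa(R, 2)
  ref <- ape::pcoa(as.dist(R))
  expect_equal(abs(mine$coordinates[, 1]),
               abs(ref$vectors[rownames(mine$coordinates), 1]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("sliding windows flag empty windows and expose spatial decay", {
  # two tight clusters 200 km apart: middle windows have no pairs
  md <- data.frame(strain_id = paste0("s", 1:8),
                   latitude = c(rep(0, 4), rep(1.8, 4)) +
                     rep(c(0, .01, .02, .03), 2),
                   longitude = 10)
  d_geo <- geo_distance(md)
  labels <- setNames(rep(c("A", "B"), each = 4), md$strain_id)
  d_gen <- species_distance(labels)
  sw <- sliding_window(d_geo, d_gen, width_km = 20, step_km = 10,
                       n_resamples = 5, seed = 2)
  mid <- sw[sw$center_km > 60 & sw$center_km < 140, ]
  expect_true(all(mid$n_pairs == 0))
  expect_true(all(is.na(mid$observed)))
  near <- sw[sw$center_km <= 20, ]
  far <- sw[sw$center_km >= 190 & sw$n_pairs > 0, ]
  expect_true(all(near$observed == 0, na.rm = TRUE))  # same-cluster pairs
  expect_true(all(far$observed == 1, na.rm = TRUE))   # cross-cluster pairs
  expect_error(sliding_window(d_geo, d_gen, width_km = 0),
               class = "parameter_error")
})

test_that("observed and null window curves separate only under spatial structure", {
  curves <- lapply(c(0, 4), function(lam) {
    s <- simulate_study(study_config(n_strains = 50, spatial_decay = lam),
                        seed = 91)
    d_geo <- geo_distance(s$metadata)
    labels <- setNames(s$truth$genospecies, s$truth$strain_id)
    sw <- sliding_window(d_geo, species_distance(labels),
                         n_resamples = 30, seed = 7)
    stats::na.omit(sw)
  })
  gap <- vapply(curves, function(sw) mean(abs(sw$observed - sw$null)),
                numeric(1))
  expect_gt(gap[2], gap[1])
  # unstructured study: observed ~ null (paired difference near zero)
  expect_lt(mean(curves[[1]]$observed - curves[[1]]$null), 0.12)
})

test_that("PERMANOVA partitions variance sequentially with additive SS", {
  set.seed(10)
  s <- simulate_study(study_config(n_strains = 40), seed = 41)
  concat <- concatenate(harmonize(s$loci))
  local <- s$truth$strain_id
  d <- p_distance(concat)[local, local]
  covs <- data.frame(strain_id = local,
                     Long = s$truth$longitude, Lat = s$truth$latitude,
                     pH = s$truth$soil_pH)
  tab <- permanova(d, covs, n_perm = 199, seed = 3)
  tot <- tab$pseudo_chisq[tab$term == "Total"]
  expect_equal(sum(tab$pseudo_chisq[!tab$term %in% "Total"]), tot)
  expect_equal(sum(tab$Df[tab$term != "Total"]), length(local) - 1)

  # a covariate equal to the first PCoA axis dominates the partition
  ax <- pcoa(d, 1)$coordinates[, 1]
  covs2 <- data.frame(strain_id = names(ax), axis = ax,
                      noise = rnorm(length(ax)))
  tab2 <- permanova(d, covs2, n_perm = 199, seed = 4)
  ss <- setNames(tab2$pseudo_chisq, tab2$term)
  expect_gt(ss[["axis"]], ss[["noise"]] * 5)
  expect_lte(tab2$p_value[tab2$term == "axis"], 0.05)
  expect_error(permanova(d[1:3, 1:3], covs[1:3, ], n_perm = 99),
               class = "rank_error")
})
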