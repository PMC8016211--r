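test_that("pruning likelihood matches closed forms on two sequences", {
  # identical 1-column sequences at t = 0 under JC69: lnL = ln(1/4)
  a <- aln_from(x = "A", y = "A")
  t0 <- ape::read.tree(text = "(x:0,y:0);")
  expect_equal(log_likelihood(t0, a, "JC69"), log(1 / 4), tolerance = 1e-9)

  # n matching + m mismatching columns at distance t: closed two-sequence
  # likelihood n*ln(pi*Pmatch) + m*ln(pi*Pmismatch)
  t <- 0.3
  n_match <- 8; n_mis <- 2
  a2 <- aln_from(x = paste(c(rep("A", n_match), rep("A", n_mis)), collapse = ""),
                 y = paste(c(rep("A", n_match), rep("C", n_mis)), collapse = ""))
  tr <- ape::read.tree(text = sprintf("(x:%f,y:%f);", t / 2, t / 2))
  p_same <- 1 / 4 + 3 / 4 * exp(-4 / 3 * t)
  p_diff <- 1 / 4 - 1 / 4 * exp(-4 / 3 * t)
  closed <- n_match * log(p_same / 4) + n_mis * log(p_diff / 4)
  expect_equal(log_likelihood(tr, a2, "JC69"), closed, tolerance = 1e-8)
})

test_that("pruning equals exhaustive state summation on small trees", {
  for (seed in c(9, 17)) {
    set.seed(seed)
    n <- sample(4:5, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.4)
    a <- simulate_alignment(tr, "JC69", 8, seed = seed)
    expect_equal(log_likelihood(tr, a, "JC69"),
                 brute_loglik_jc(tr, a$mat), tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to rooting under a reversible model", {
  set.seed(5)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  a <- simulate_alignment(tr, "JC69", 50, seed = 6)
  l0 <- log_likelihood(ape::unroot(tr), a, "JC69")
  for (tip in c(2, 4)) {
    rr <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[tip],
                    resolve.root = TRUE)
    expect_equal(log_likelihood(rr, a, "JC69"), l0, tolerance = 1e-6)
  }
  stranger <- ape::rtree(3)
  stranger$tip.label <- paste0("zz", 1:3)
  expect_error(log_likelihood(stranger, a, "JC69"),
               class = "mapping_error")
})

test_that("optimization improves the likelihood and counts parameters", {
  set.seed(8)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.3)
  a <- simulate_alignment(tr, "JC69", 500, seed = 8)
  start <- tr
  start$edge.length <- rep(0.1, nrow(tr$edge))
  fit <- optimize_fit(start, a, "JC69")
  expect_gte(fit$log_likelihood, log_likelihood(start, a, "JC69"))
  # JC69 on a fixed tree: free parameters = branches only
  expect_equal(fit$n_free_parameters, nrow(fit$tree$edge))
  expect_equal(fit$BIC, -2 * fit$log_likelihood +
                 fit$n_free_parameters * log(500))
  # nesting: GTR can never fit worse than JC69
  fit_gtr <- optimize_fit(start, a, "GTR")
  expect_gte(fit_gtr$log_likelihood, fit$log_likelihood - 1e-4)
})

test_that("branch lengths are recovered from simulated data", {
  set.seed(13)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  a <- simulate_alignment(tr, "GTR+G", 5000, seed = 13, shape = 0.5,
                          base_freq = c(0.19, 0.31, 0.30, 0.20),
                          Q = c(1.1, 3.2, 0.8, 0.9, 3.5, 1.0))
  fit <- optimize_fit(tr, a, "GTR+G")
  rec <- ape::cophenetic.phylo(fit$tree)
  truth <- ape::cophenetic.phylo(tr)
  rel <- abs(rec - truth[rownames(rec), colnames(rec)]) /
    truth[rownames(rec), colnames(rec)]
  expect_lt(max(rel[upper.tri(rel)]), 0.15)
})

test_that("NNI search recovers the generating topology and never worsens lnL", {
  set.seed(4)
  tr <- ape::unroot(ape::rtree(4))
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 0.3)
  a <- simulate_alignment(tr, "JC69", 2000, seed = 4)
  wrong <- ape::read.tree(text = sprintf("(%s,%s,(%s,%s));",
    tr$tip.label[1], tr$tip.label[3], tr$tip.label[2], tr$tip.label[4]))
  wrong$edge.length <- rep(0.1, nrow(wrong$edge))
  res <- nni_search(wrong, a, "JC69")
  expect_equal(phangorn::RF.dist(res$tree, tr), 0)
  start_fit <- optimize_fit(wrong, a, "JC69")
  expect_gte(res$log_likelihood, start_fit$log_likelihood - 1e-6)
})

test_that("model selection prefers the generating model by BIC", {
  set.seed(31)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.2)
  for (seed in c(41, 42)) {
    a <- simulate_alignment(tr, "JC69", 2000, seed = seed)
    ms <- model_select(a, tr, candidates = c("JC69", "GTR+G"))
    expect_equal(ms$best, "JC69")
    # lnL still ordered by nesting even though BIC prefers the small model
    expect_gte(ms$fits[["GTR+G"]]$log_likelihood,
               ms$fits[["JC69"]]$log_likelihood - 1e-4)
  }
  # 8 columns < branches + 1: AICc denominator vanishes
  expect_error(model_select(simulate_alignment(tr, "JC69", 8, seed = 1),
                            tr, candidates = c("JC69", "GTR+G"),
                            criterion = "AICc"),
               class = "criterion_error")
})

test_that("simulated alignments follow the generating model", {
  tr <- ape::rtree(4)
  tr$edge.length <- rep(0, nrow(tr$edge))
  a0 <- simulate_alignment(tr, "JC69", 50, seed = 2)
  expect_equal(length(unique(apply(a0$mat, 1, paste, collapse = ""))), 1)

  bf <- c(0.1, 0.4, 0.3, 0.2)
  tr2 <- ape::rtree(6)
  tr2$edge.length <- tr2$edge.length * 0.1
  a1 <- simulate_alignment(tr2, "HKY", 10000, seed = 3, base_freq = bf,
                           Q = c(1, 4, 1, 1, 4, 1))
  freq <- table(factor(a1$mat, levels = c("A", "C", "G", "T"))) / length(a1$mat)
  # multinomial 3-sigma check per base
  sigma <- sqrt(bf * (1 - bf) / length(a1$mat))
  expect_true(all(abs(freq - bf) < 3 * sigma + 0.01))

  # two-taxon expected p-distance matches the JC69 formula within 3 sigma
  t <- 0.2
  two <- ape::read.tree(text = sprintf("(x:%f,y:%f);", t / 2, t / 2))
  a2 <- simulate_alignment(two, "JC69", 10000, seed = 9)
  p_exp <- 3 / 4 * (1 - exp(-4 / 3 * t))
  p_obs <- p_distance(a2)["x", "y"]
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 10000))

  a_rep <- simulate_alignment(tr2, "JC69", 100, seed = 5)
  expect_identical(simulate_alignment(tr2, "JC69", 100, seed = 5)$mat,
                   a_rep$mat)
  expect_error(simulate_alignment(tr2, "JC69", 0), class = "parameter_error")
})

test_that("congruence test keeps its contracts on a congruent locus", {
  set.seed(12)
  tr <- ape::rtree(8)
  tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.15)
  a <- simulate_alignment(tr, "JC69", 300, seed = 12)
  res <- congruence_test(a, tr, model = "JC69", n_bootstrap = 19, seed = 3)
  expect_gte(res$delta, 0)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_equal(res$p_value,
               (1 + sum(res$delta_null >= res$delta)) / (1 + 19))
  expect_error(congruence_test(a, tr, n_bootstrap = 10),
               class = "parameter_error")
})
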