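# Shared fixtures and independent oracles, all built in code.

# small alignment from named sequence strings
aln_from <- function(..., locus = "toy") {
  locus_alignment(c(...), locus = locus)
}

# brute-force per-column site classifier (independent of classify_sites)
brute_classify <- function(mat) {
  res <- c(conserved = 0, variable = 0, pi = 0, singleton = 0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    tab <- table(col)
    if (length(tab) == 1) res["conserved"] <- res["conserved"] + 1
    if (length(tab) >= 2) {
      res["variable"] <- res["variable"] + 1
      if (sum(tab >= 2) >= 2) res["pi"] <- res["pi"] + 1
      else res["singleton"] <- res["singleton"] + 1
    }
  }
  res
}

# exhaustive-state-sum likelihood oracle under JC69 (small trees only)
brute_loglik_jc <- function(tree, mat) {
  tree <- ape::reorder.phylo(tree, "postorder")
  bases <- c("A", "C", "G", "T")
  n <- length(tree$tip.label)
  nodes <- max(tree$edge)
  Pm <- lapply(tree$edge.length,
               function(t) 0.25 + (diag(4) - 0.25) * exp(-4 / 3 * t))
  internals <- (n + 1):nodes
  states <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  total <- 0
  for (col in seq_len(ncol(mat))) {
    lik <- 0
    for (s in seq_len(nrow(states))) {
      st <- integer(nodes)
      st[internals] <- states[s, ]
      for (i in seq_len(n)) st[i] <- match(mat[tree$tip.label[i], col], bases)
      pr <- 0.25
      for (e in seq_len(nrow(tree$edge))) {
        pr <- pr * Pm[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
      }
      lik <- lik + pr
    }
    total <- total + log(lik)
  }
  total
}

# all permutations of 1..n (independent of the package's internal helper)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (i in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  }
  out
}

# random symmetric distance-like matrix with labels
rand_dist <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n), n)
  m <- m + t(m)
  diag(m) <- 0
  dimnames(m) <- list(letters[seq_len(n)], letters[seq_len(n)])
  m
}

# genospecies x symbiovar contingency cells as reported for the Ethiopian
# bean-rhizobia collections (margins recomputed from cells downstream)
crosstab_cells <- function() {
  cells <- rbind(
    c(0, 0, 0, 1, 1, 0, 3, 0),
    c(0, 1, 0, 2, 18, 5, 8, 0),
    c(2, 0, 0, 0, 0, 0, 0, 0),
    c(0, 3, 0, 26, 3, 0, 0, 2),
    c(0, 0, 0, 0, 0, 0, 8, 0),
    c(0, 0, 0, 0, 1, 1, 0, 0),
    c(0, 0, 0, 0, 0, 0, 3, 0),
    c(0, 0, 0, 0, 0, 1, 5, 0),
    c(0, 0, 4, 0, 0, 0, 0, 0))
  rownames(cells) <- c("Rhizobium sp.", "R. etli", "R. giardinii",
                       "R. phaseoli", "R. sophoriradicis", "Unclustered",
                       "Rhizobium sp. I", "R. aethiopicum", "R. leucaenae")
  colnames(cells) <- c("giardinii", "lentis", "leucaenae", "phaseoli-IV",
                       "phaseoli-I", "sophorae", "sophoriradicis",
                       "unclustered")
  cells
}

# small reference-anchored tree with supports for the assignment rule
toy_assignment_case <- function() {
  tr <- ape::read.tree(
    text = "((q1:1,(q2:1,REF_etli:1):1):1,REF_phaseoli:3):0;")
  tr$node.label <- c("", "99", "95")
  meta <- data.frame(
    strain_id = c("q1", "q2", "REF_etli", "REF_phaseoli"),
    collection = c("current", "current", "reference", "reference"),
    reference_species = c(NA, NA, "R. etli", "R. phaseoli"),
    stringsAsFactors = FALSE)
  list(tree = tr, meta = meta)
}
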