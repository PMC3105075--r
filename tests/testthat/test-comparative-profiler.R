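# Profile matrix, Pearson distance, UPGMA against an average-linkage
# oracle, planted-guild recovery.

test_that("profile rows normalise to percentages over the family universe", {
  pm <- build_profile_matrix(list(s1 = c(GH5 = 1, GH6 = 1)),
                             family_universe = c("GH5", "GH6", "GH48"))
  expect_equal(unname(pm$percents["s1", ]), c(50, 50, 0))
  expect_equal(colnames(pm$counts), c("GH5", "GH6", "GH48"))
  expect_equal(sum(pm$percents["s1", ]), 100)
})

test_that("all-zero rows are flagged and excluded from distances", {
  expect_warning(
    pm <- build_profile_matrix(list(a = c(GH5 = 3, GH6 = 1),
                                    b = c(GH5 = 0, GH6 = 0),
                                    c = c(GH5 = 1, GH6 = 3))),
    "all-zero")
  expect_equal(unname(pm$empty), c(FALSE, TRUE, FALSE))
  d <- pearson_distance(pm)
  expect_equal(attr(d, "Size"), 2)
})

test_that("Pearson distance matches hand-computed cases", {
  pm <- build_profile_matrix(list(a = c(x = 60, y = 30, z = 10),
                                  b = c(x = 60, y = 30, z = 10),
                                  c = c(x = 10, y = 30, z = 60)))
  d <- as.matrix(pearson_distance(pm))
  expect_equal(d["a", "b"], 0)                 # identical rows, r = 1
  # hand-computed: deviations (80,-10,-70)/3 vs (-70,-10,80)/3 give
  # r = -11100/11400 = -37/38, so d = 1 + 37/38 = 75/38
  expect_equal(d["a", "c"], 75 / 38)
  expect_equal(diag(d), setNames(rep(0, 3), letters[1:3]))
  expect_equal(d, t(d))

  # a true mirrored pair over two families is perfectly anticorrelated
  pm2 <- build_profile_matrix(list(d = c(x = 80, y = 20),
                                   e = c(x = 20, y = 80)))
  expect_equal(as.matrix(pearson_distance(pm2))["d", "e"], 2,
               tolerance = 1e-12)
})

test_that("Pearson distance is invariant to count scaling and strict on variance", {
  pm1 <- build_profile_matrix(list(a = c(x = 6, y = 3, z = 1),
                                   b = c(x = 1, y = 2, z = 7)))
  pm2 <- build_profile_matrix(list(a = c(x = 600, y = 300, z = 100),
                                   b = c(x = 1, y = 2, z = 7)))
  expect_equal(as.matrix(pearson_distance(pm1)),
               as.matrix(pearson_distance(pm2)))
  flat <- build_profile_matrix(list(a = c(x = 5, y = 5),
                                    b = c(x = 1, y = 9)))
  expect_error(pearson_distance(flat), "zero-variance.*a")
})

test_that("UPGMA merges follow the textbook recurrences", {
  d2 <- stats::as.dist(matrix(c(0, 0.4, 0.4, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  t2 <- upgma(d2)
  expect_equal(t2$height, 0.2)

  m <- matrix(c(0, 0.2, 0.6,
                0.2, 0, 0.6,
                0.6, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- upgma(stats::as.dist(m))
  expect_equal(t3$height, c(0.1, 0.3))
  # cophenetic distances recover the input exactly (heights are d/2)
  cd <- as.matrix(2 * stats::cophenetic(t3))
  expect_equal(cd[rownames(m), colnames(m)], m)
})

test_that("UPGMA equals the average-linkage oracle on random matrices", {
  set.seed(1234)
  for (trial in 1:100) {
    n <- sample(3:8, 1)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.05, 2)
    m <- m + t(m)
    dimnames(m) <- list(letters[1:n], letters[1:n])
    d <- stats::as.dist(m)
    mine <- upgma(d)
    oracle <- stats::hclust(d, method = "average")
    expect_equal(as.matrix(2 * stats::cophenetic(mine)),
                 as.matrix(stats::cophenetic(oracle)),
                 tolerance = 1e-10)
    # ultrametric: heights non-decreasing toward the root
    expect_true(all(diff(mine$height) >= -1e-12))
  }
})

test_that("UPGMA ties break deterministically by smallest label pair", {
  m <- matrix(0.5, 4, 4,
              dimnames = list(c("d", "b", "c", "a"), c("d", "b", "c", "a")))
  diag(m) <- 0
  tr <- upgma(stats::as.dist(m))
  # first merge must join the two lexicographically smallest labels, a and b
  first <- sort(tr$labels[-tr$merge[1, ]])
  expect_equal(first, c("a", "b"))
})

test_that("dendrograms export as valid ultrametric newick", {
  pm <- build_profile_matrix(list(a = c(x = 9, y = 1), b = c(x = 8, y = 2),
                                  c = c(x = 1, y = 9)))
  tree <- upgma(pearson_distance(pm))
  nwk <- as_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("a", "b", "c"))
  expect_true(ape::is.ultrametric(phy, tol = 1e-8))
})

test_that("planted guilds split at the root of the dendrogram", {
  path <- system.file("extdata", "synthetic_reference_gh_profiles.tsv",
                      package = "rumencazy")
  profiles <- read_profile_counts(path)
  pm <- build_profile_matrix(profiles)
  tree <- upgma(pearson_distance(pm))
  phy <- ape::read.tree(text = as_newick(tree))
  # the two subtrees under the root are exactly the two guilds
  root_children <- phy$edge[phy$edge[, 1] == ape::Ntip(phy) + 1, 2]
  clades <- lapply(root_children, function(node) {
    if (node <= ape::Ntip(phy)) phy$tip.label[node]
    else ape::extract.clade(phy, node)$tip.label
  })
  guilds <- lapply(clades, function(tips)
    unique(sub("_[AB]$", "", tips)))
  expect_true(all(lengths(guilds) == 1))
  expect_setequal(unlist(guilds), c("synthetic_cellulolytic",
                                    "synthetic_oligosaccharide"))
})

test_that("zero-noise two-sample profiles equal planted proportions", {
  sim1 <- simulate_dataset(n_contigs = 120, n_reads = 500, seed = 61)
  assoc <- build_association_table(sim1$family_defs, sim1$member_hits)
  calls <- call_modules(sim1$hits$domain, assoc = assoc)
  info <- data.frame(contig_id = names(sim1$contigs),
                     length = Biostrings::width(sim1$contigs))
  ann <- annotate_contigs(info, calls)
  own <- count_contigs_per_family(ann)
  truth_counts <- table(unique(sim1$truth$modules[
    c("contig_id", "label")])$label)
  expect_equal(own[order(names(own))],
               setNames(as.integer(truth_counts),
                        names(truth_counts))[sort(names(own))])
})
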