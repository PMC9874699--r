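block_matrix <- function() {
  # two clean gene/pathway blocks
  m <- matrix(0L, nrow = 8, ncol = 6,
              dimnames = list(paste0("g", 1:8), paste0("p", 1:6)))
  m[1:4, 1:3] <- 1L
  m[5:8, 4:6] <- 1L
  m
}

test_that("binary_distance is the Jaccard distance", {
  expect_equal(binary_distance(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(binary_distance(c(1, 0, 0), c(0, 1, 1)), 1)
  expect_equal(binary_distance(c(1, 1, 0), c(0, 1, 1)), 1 - 1 / 3)
  expect_error(binary_distance(c(0, 0), c(0, 0)), "all-zero")
  expect_error(binary_distance(c(1, 2), c(1, 0)), "binary")
  expect_error(binary_distance(c(1), c(1, 0)), "equal length")
  # agreement with the dist() metric used inside bicluster()
  set.seed(4)
  for (rep in 1:20) {
    u <- rbinom(10, 1, 0.5); v <- rbinom(10, 1, 0.5)
    if (sum(u) == 0 || sum(v) == 0 || sum(u | v) == 0) next
    expect_equal(binary_distance(u, v),
                 as.numeric(stats::dist(rbind(u, v), method = "binary")))
  }
})

test_that("membership_matrix prunes all-zero rows and columns", {
  pw <- data.frame(term_id = c("A", "B", "C"), term_name = c("a", "b", "c"),
                   stringsAsFactors = FALSE)
  pw$genes <- list(c("g1", "g2"), c("g2", "g3"), c("zz"))
  expect_message(m <- membership_matrix(c("g1", "g2", "g3", "g4"), pw),
                 "pruned")
  expect_equal(rownames(m), c("g1", "g2", "g3"))  # g4 in no pathway
  expect_equal(colnames(m), c("A", "B"))          # C hits no query gene
  expect_equal(m["g2", "A"], 1L)
})

test_that("bicluster recovers planted block structure", {
  m <- block_matrix()
  bc <- bicluster(m, k_pathways = 2, k_genes = 2)
  expect_equal(length(unique(bc$gene_clusters[1:4])), 1)
  expect_equal(length(unique(bc$gene_clusters[5:8])), 1)
  expect_false(bc$gene_clusters[1] == bc$gene_clusters[5])
  expect_false(bc$pathway_clusters[1] == bc$pathway_clusters[4])
})

test_that("cluster labels are invariant under input permutation", {
  m <- block_matrix()
  base <- bicluster(m, k_pathways = 2, k_genes = 2)
  set.seed(9)
  perm <- sample.int(nrow(m))
  bc <- bicluster(m[perm, ], k_pathways = 2, k_genes = 2)
  # same partition up to relabeling
  for (g in rownames(m)) for (h in rownames(m)) {
    expect_equal(bc$gene_clusters[g] == bc$gene_clusters[h],
                 base$gene_clusters[g] == base$gene_clusters[h],
                 ignore_attr = TRUE)
  }
})

test_that("cuts nest: k-1 clusters merge exactly two of the k clusters", {
  set.seed(21)
  m <- matrix(rbinom(15 * 8, 1, 0.4), nrow = 15,
              dimnames = list(paste0("g", 1:15), paste0("p", 1:8)))
  m <- m[rowSums(m) > 0, colSums(m) > 0]
  for (k in 3:5) {
    a <- stats::cutree(bicluster(m, k_pathways = 2, k_genes = k)$gene_hclust, k)
    b <- stats::cutree(bicluster(m, k_pathways = 2, k_genes = k - 1)$gene_hclust,
                       k - 1)
    crossed <- table(a, b)
    # every k-cluster maps into exactly one (k-1)-cluster
    expect_true(all(rowSums(crossed > 0) == 1))
    expect_equal(max(table(apply(crossed > 0, 1, which))), 2)
  }
})

test_that("degenerate cuts behave: k equal to leaves gives singletons; identical rows co-cluster", {
  m <- block_matrix()
  bc <- bicluster(m, k_pathways = ncol(m), k_genes = nrow(m))
  expect_equal(length(unique(bc$gene_clusters)), nrow(m))
  expect_error(bicluster(m, k_genes = nrow(m) + 1), "k_genes")
  # a duplicated row merges first and stays co-clustered while k is below
  # the number of distinct row patterns
  set.seed(33)
  m2 <- matrix(rbinom(12 * 8, 1, 0.4), nrow = 12,
               dimnames = list(paste0("g", 1:12), paste0("p", 1:8)))
  m2 <- m2[rowSums(m2) > 0, ]
  m2 <- m2[!duplicated(m2), ]
  m2 <- rbind(m2, dup = m2[1, ])
  for (k in 2:(nrow(m2) - 2)) {
    bc2 <- bicluster(m2, k_pathways = 2, k_genes = k)
    expect_equal(unname(bc2$gene_clusters[rownames(m2)[1]]),
                 unname(bc2$gene_clusters["dup"]))
  }
})
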