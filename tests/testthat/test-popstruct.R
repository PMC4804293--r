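test_that("pi-hat flags duplicates and stays near zero for unrelated pairs", {
  set.seed(71)
  freqs <- runif(200, 0.1, 0.9)
  g1 <- simDosage(1, freqs)[1, ]
  expect_gte(piHat(g1, g1, freqs), 0.95)
  ## 50 independent pairs from one homogeneous population
  vals <- replicate(50, {
    a <- simDosage(1, freqs)[1, ]; b <- simDosage(1, freqs)[1, ]
    as.numeric(piHat(a, b, freqs))
  })
  expect_lt(abs(mean(vals)), 0.1)
  expect_true(all(vals >= 0 & vals <= 1))
  ## IBD components clamp and renormalize
  ibd <- attr(piHat(g1, 1 - g1, freqs), "ibd")
  expect_true(all(ibd >= 0 & ibd <= 1))
  expect_equal(sum(ibd), 1)
  expect_error(piHat(c(0, 0), c(0, 0), c(0, 1)), "monomorphic")
})

test_that("greedy relatedness filtering removes one member per duplicate pair", {
  set.seed(72)
  freqs <- runif(300, 0.2, 0.8)
  X <- simDosage(20, freqs)
  X <- rbind(X, X[3, ])  # inject a duplicate of sample 3
  rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  codes <- ifelse(X == 1, "12", "22")
  g <- CNVGenotypes(codes, data.frame(region_id = paste0("CNV", seq_len(ncol(X))),
                                      chrom = "1", start = 1, end = 2,
                                      midpoint = 1, frequency = colMeans(X)),
                    data.frame(sample = rownames(X), breed = "b", group = "g"))
  kept <- relatednessFilter(g)
  expect_equal(length(kept), 20)
  expect_false(all(c("S003", "S021") %in% kept))
  expect_true(any(c("S003", "S021") %in% kept))
  ## nothing above the threshold leaves everything untouched
  g0 <- CNVGenotypes(codes[1:20, ], markerInfo(g), sampleInfo(g)[1:20, ])
  expect_equal(relatednessFilter(g0), rownames(X)[1:20])
})

test_that("cohort fixture: 300 samples with 95 injected relatives keep 205", {
  set.seed(73)
  freqs <- runif(500, 0.1, 0.9)
  base <- simDosage(205, freqs)
  rel <- base[sample.int(205, 95, replace = FALSE), ]
  flip <- matrix(runif(length(rel)) < 0.05, nrow(rel), ncol(rel))
  rel[flip] <- 1L - rel[flip]
  X <- rbind(base, rel)
  rownames(X) <- sprintf("S%03d", 1:300)
  codes <- ifelse(X == 1, "12", "22")
  g <- CNVGenotypes(codes, data.frame(region_id = paste0("CNV", 1:500),
                                      chrom = "1", start = 1, end = 2,
                                      midpoint = 1, frequency = colMeans(X)),
                    data.frame(sample = rownames(X), breed = "b", group = "g"))
  expect_equal(length(relatednessFilter(g)), 205)
})

test_that("IBS distance follows the PLINK sharing formula", {
  codes <- rbind(c("12", "22", "22", "12"),
                 c("22", "22", "12", "12"),
                 c("12", "22", "22", "12"))
  rownames(codes) <- c("a", "b", "c")
  g <- CNVGenotypes(codes, data.frame(region_id = paste0("M", 1:4), chrom = "1",
                                      start = 1, end = 2, midpoint = 1,
                                      frequency = colMeans(codes == "12")),
                    data.frame(sample = rownames(codes), breed = "b", group = "g"))
  D <- ibsDistance(g)
  ## IBS2 = 2, IBS1 = 2 -> D = 1 - (2 + 1)/4
  expect_equal(D["a", "b"], 0.25)
  expect_equal(D["a", "c"], 0)     # identical code vectors
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(D, t(D))
  expect_true(all(D >= 0 & D <= 0.5))  # two-code set caps D at 0.5
})

test_that("classical MDS embeds exact and rank-deficient configurations", {
  ## three points, all pairwise distances 1 -> an equilateral triangle
  D <- matrix(1, 3, 3) - diag(3)
  Y <- suppressWarnings(classicalMDS(D, dims = 2))
  expect_equal(as.vector(dist(Y)), rep(1, 3), tolerance = 1e-9)
  ## collinear points 0, 1, 3: the first coordinate recovers positions
  D2 <- as.matrix(dist(c(0, 1, 3)))
  Y2 <- suppressWarnings(classicalMDS(D2, dims = 2))
  got <- Y2[, 1] - min(Y2[, 1])
  expect_true(max(abs(sort(got) - c(0, 1, 3))) < 1e-9)
  ## sign convention: the largest-magnitude loading is positive
  expect_gte(Y2[which.max(abs(Y2[, 1])), 1], 0)
  ## a Euclidean rank-4 configuration is reproduced exactly in 4 dims
  set.seed(74)
  P <- matrix(rnorm(20 * 4), 20, 4)
  D4 <- as.matrix(dist(P))
  Y4 <- classicalMDS(D4, dims = 4)
  expect_equal(as.matrix(dist(Y4)), D4, tolerance = 1e-9)
})

test_that("neighbor joining recovers the spec'd additive tree exactly", {
  ## tree ((A:1,B:2):5,(C:3,D:4)) -> path distances below
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- 3; D["A", "C"] <- 9; D["A", "D"] <- 10
  D["B", "C"] <- 10; D["B", "D"] <- 11; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- njTree(D)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  coph <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(coph, D, tolerance = 1e-9)
  ## AB and CD are sister pairs in the unrooted topology
  expect_true(ape::is.monophyletic(ape::root(tr, "C"), c("A", "B")))
  ## three taxa solve the three-point equations exactly
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- njTree(D3)
  expect_equal(ape::cophenetic.phylo(tr3)[rownames(D3), colnames(D3)], D3,
               tolerance = 1e-9)
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ reproduces random additive trees (branch lengths within 1e-9)", {
  set.seed(75)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    tr0 <- ape::rtree(n, rooted = FALSE)
    tr0$edge.length <- runif(length(tr0$edge.length), 0.1, 1)
    D <- ape::cophenetic.phylo(tr0)
    tr <- njTree(D)
    coph <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_lt(max(abs(coph - D)), 1e-9)
    expect_equal(attr(tr, "n_clamped"), 0)
  }
})

test_that("average-linkage clustering follows the hand-traced merges", {
  ## 2-D points with pairwise distances 1, 2, 2
  pts <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(4 - 0.25)))
  rownames(pts) <- c("s1", "s2", "s3")
  hc <- hierCluster(pts)
  expect_equal(hc$height, c(1, 2), tolerance = 1e-9)
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))  # s1-s2 merge first
  expect_false(is.unsorted(hc$height))
  ## two well-separated profile groups split at the top
  set.seed(76)
  prof <- rbind(matrix(rnorm(5 * 10, 0, 0.1), 5, 10),
                matrix(rnorm(5 * 10, 5, 0.1), 5, 10))
  rownames(prof) <- sprintf("S%02d", 1:10)
  hc2 <- hierCluster(prof)
  grp <- stats::cutree(hc2, k = 2)
  expect_equal(length(unique(grp[1:5])), 1)
  expect_equal(length(unique(grp[6:10])), 1)
  expect_false(grp[1] == grp[6])
  ## Newick serialization keeps all leaves
  nw <- asNewick(hc2)
  expect_true(all(vapply(rownames(prof), grepl, TRUE, x = nw, fixed = TRUE)))
})

test_that("K = 1 admixture is the closed-form frequency fit", {
  set.seed(77)
  X <- simDosage(30, runif(50, 0.2, 0.8))
  fit <- admixtureFit(X, K = 1)
  expect_equal(unname(ancestryQ(fit)[, 1]), rep(1, 30))
  expect_equal(unname(clusterFreqs(fit)[1, ]), unname(colMeans(X)))
  p <- pmin(pmax(colMeans(X), 1e-12), 1 - 1e-12)
  ll <- sum(t(X) * log(p) + (1 - t(X)) * log(1 - p))
  expect_equal(logLikTrace(fit), ll)
})

test_that("two fixed populations are cleanly assigned at K = 2", {
  ## populations fixed for alternative deletion alleles at 50 markers
  set.seed(78)
  f1 <- rep(c(1, 0), 25)
  f2 <- rep(c(0, 1), 25)
  X <- rbind(simDosage(15, f1), simDosage(15, f2))
  fit <- admixtureFit(X, K = 2, seed = 4)
  expect_false(is.unsorted(logLikTrace(fit), strictly = FALSE))
  maxq <- apply(ancestryQ(fit), 1, max)
  expect_true(all(maxq >= 0.99))
  ## members of the same population share the same majority cluster
  lab <- apply(ancestryQ(fit), 1, which.max)
  expect_equal(length(unique(lab[1:15])), 1)
  expect_equal(length(unique(lab[16:30])), 1)
  expect_false(lab[1] == lab[16])
  expect_error(admixtureFit(X, K = 40), "exceeds")
})

test_that("the most diverged group separates on the first MDS coordinate", {
  sim <- simulateGenotypes(SimConfig())
  loss <- sim$locus_types == "loss"
  X <- (sim$genotypes[, loss, drop = FALSE] <= 1L) + 0L
  codes <- ifelse(X == 1L, "12", "22")
  g <- CNVGenotypes(codes,
                    data.frame(region_id = paste0("M", seq_len(ncol(X))),
                               chrom = "1", start = 1, end = 2, midpoint = 1,
                               frequency = colMeans(X)),
                    sim$samples)
  Y <- classicalMDS(ibsDistance(g), dims = 4)
  c1 <- Y[, 1]
  g1 <- sim$samples$group == "G1"
  rest <- sim$samples$group %in% c("G2", "G3")
  ## zero overlap between the differentiated group and the other groups
  expect_true(max(c1[g1]) < min(c1[rest]) || min(c1[g1]) > max(c1[rest]))
})
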