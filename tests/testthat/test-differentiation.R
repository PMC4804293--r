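test_that("Vst matches its hand oracles and conventions", {
  ## complete differentiation between constant groups
  v <- vst(c(rep(-1, 10), rep(0, 10)), rep(c("A", "B"), each = 10))
  expect_equal(as.numeric(v), 1)
  ## identical constants everywhere: degenerate, 0 by convention
  v0 <- vst(rep(0.2, 8), rep(c("A", "B"), each = 4))
  expect_equal(as.numeric(v0), 0)
  expect_true(attr(v0, "degenerate"))
  ## hand computation: V_T = 0.1875, V_S = 0.125, Vst = 1/3
  v3 <- vst(c(-1, -1, 0, 0, 0, 0, 0, 0), rep(c("A", "B"), each = 4))
  expect_equal(as.numeric(v3), 1 / 3, tolerance = 1e-12)
  expect_error(vst(1:4, rep("A", 4)), "two groups")
})

test_that("Vst is scale/shift invariant and bounded in [0, 1]", {
  set.seed(81)
  for (rep in 1:50) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    x <- c(rnorm(n1, -0.5, 0.4), rnorm(n2, 0, 0.2))
    lab <- rep(c("A", "B"), c(n1, n2))
    v <- as.numeric(vst(x, lab))
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(as.numeric(vst(x + 3.7, lab)), v, tolerance = 1e-9)
    expect_equal(as.numeric(vst(x * -2.5, lab)), v, tolerance = 1e-9)
  }
  ## the unbiased switch may go (slightly) negative and is reported unclamped
  set.seed(82)
  vals <- replicate(200, as.numeric(vst(rnorm(8), rep(c("A", "B"), each = 4),
                                        unbiased = TRUE)))
  expect_true(any(vals < 0))
})

test_that("Vst scan rows, flags and degenerate handling are correct", {
  means <- rbind(c(rep(-1, 6), rep(0, 6)),     # fully differentiated
                 rep(0.1, 12),                 # constant -> degenerate
                 c(rnorm(6, 0, 0.05), rnorm(6, 0, 0.05)))  # undifferentiated
  sheet <- data.frame(sample = sprintf("S%03d", 1:12), breed = "b",
                      group = rep(c("G1", "G2"), each = 6))
  reg <- makeRegionSet(matrix(0L, 3, 12) - cbind(matrix(1L, 3, 6), matrix(0L, 3, 6)),
                       "1", c(100, 300, 500), c(200, 400, 600),
                       rep("loss", 3), means = means, sheet = sheet,
                       region_id = paste0("CNV", 1:3))
  tab <- vstScan(reg, list(c("G1", "G2")))
  expect_equal(nrow(tab), 3)
  expect_true(tab$flag04[1] && tab$flag06[1])
  expect_true(tab$degenerate[2])
  expect_false(tab$flag04[2] || tab$flag06[2])
  expect_false(tab$flag04[3])
  expect_error(vstScan(reg, list(c("G1", "NOPE"))), "unknown or empty")
})

test_that("Vst approaches 1 at fixed differentiated loci as noise vanishes", {
  cfg <- SimConfig(n_cnv_loci = 3, n_differentiated_loci = 3,
                   diff_freq_pair = c(1, 0), noise_sd = 1e-3, seed = 83)
  sim <- simulateGenotypes(cfg)
  lm_ <- cfg@lrr_means
  span <- 20
  set.seed(83)
  for (l in 1:3) {
    mu <- lm_[as.character(sim$genotypes[, l])]
    seg_mean <- mu + rnorm(length(mu), 0, cfg@noise_sd / sqrt(span))
    keep <- sim$samples$group %in% c("G1", "G2")
    v <- as.numeric(vst(seg_mean[keep], sim$samples$group[keep]))
    expect_gt(v, 0.99)
  }
})

test_that("higher group frequency contrast gives non-decreasing median Vst", {
  set.seed(84)
  deltas <- c(0, 0.2, 0.4, 0.6, 0.8)
  med <- vapply(deltas, function(d) {
    v <- replicate(40, {
      p1 <- 0.1 + d; p2 <- 0.1
      x1 <- ifelse(runif(20) < 1 - (1 - p1)^2, -1, 0) + rnorm(20, 0, 0.1)
      x2 <- ifelse(runif(20) < 1 - (1 - p2)^2, -1, 0) + rnorm(20, 0, 0.1)
      as.numeric(vst(c(x1, x2), rep(c("A", "B"), each = 20)))
    })
    median(v)
  }, 0)
  expect_true(all(diff(med) > -0.05))  # non-decreasing up to simulation noise
  expect_gt(med[5], med[1] + 0.3)
})

test_that("unique differentiated regions are a set union across comparisons", {
  mk <- function(ids, v) data.frame(region_id = ids, comparison = "x",
                                    V_T = 1, V_S = 1 - v, V_ST = v,
                                    degenerate = FALSE, flag04 = v > 0.4,
                                    flag06 = v > 0.6)
  tabs <- list(mk(c("a", "b", "c"), 0.5), mk(c("b", "d"), 0.5),
               mk(c("c", "d", "e"), 0.5))
  expect_setequal(uniqueDifferentiated(tabs, 0.4), c("a", "b", "c", "d", "e"))
  expect_length(uniqueDifferentiated(list(mk("a", 0.1)), 0.4), 0)
  ## counts 41 / 11 / 48 with constructed overlaps union to 78
  A <- sprintf("CNV%03d", 1:41)
  B <- sprintf("CNV%03d", 20:30)          # 11, all inside A
  C <- sprintf("CNV%03d", 31:78)          # 48, 11 shared with A
  tabs2 <- list(mk(A, 0.55), mk(B, 0.45), mk(C, 0.62))
  expect_length(uniqueDifferentiated(tabs2, 0.4), 78)
})

test_that("gene overlap respects the 1 bp half-open boundary rule", {
  dir <- withr::local_tempdir()
  ## regions in half-open terms: [100,200) and [300,400)
  reg <- makeRegionSet(matrix(c(-1L, 0L), 2, 2, byrow = TRUE), "1",
                       c(101, 301), c(200, 400), c("loss", "loss"),
                       region_id = c("CNV1", "CNV2"))
  bed <- data.frame(chrom = "1", start = c(199, 200), end = c(300, 300),
                    name = c("geneTouch", "geneClear"))
  data.table::fwrite(bed, file.path(dir, "genes.bed"), sep = "\t",
                     col.names = FALSE)
  ov <- annotateOverlap(reg, file.path(dir, "genes.bed"))
  expect_equal(nrow(ov), 1)
  expect_equal(ov$gene_id, "geneTouch")
  expect_equal(ov$overlap_bp, 1)
})

test_that("toy region/gene annotation reports exactly the expected pairs", {
  reg <- makeRegionSet(matrix(-1L, 3, 2), c("1", "1", "2"),
                       c(1001, 5001, 1001), c(2000, 6000, 3000),
                       rep("loss", 3), region_id = paste0("CNV", 1:3))
  genes <- GenomicRanges::GRanges(
    c("1", "1", "1", "2", "2"),
    IRanges::IRanges(c(1500, 1990, 7000, 500, 2900),
                     c(1600, 2200, 8000, 1100, 3500)),
    Name = paste0("g", 1:5))
  ov <- annotateOverlap(reg, genes)
  expect_equal(nrow(ov), 4)
  expect_setequal(paste(ov$region_id, ov$gene_id),
                  c("CNV1 g1", "CNV1 g2", "CNV3 g4", "CNV3 g5"))
  expect_equal(ov$overlap_bp[ov$gene_id == "g1"], 101)
  expect_equal(ov$overlap_bp[ov$gene_id == "g2"], 11)
  ## overlap length is symmetric in the two interval sets
  ov_sw <- annotateOverlap(genes, SummarizedExperiment::rowRanges(reg))
  expect_equal(sort(ov_sw$overlap_bp), sort(ov$overlap_bp))
  ## malformed gene interval (start > end) in a BED file is rejected
  dir <- withr::local_tempdir()
  writeLines("1\t300\t200\tbadGene", file.path(dir, "bad.bed"))
  expect_error(annotateOverlap(reg, file.path(dir, "bad.bed")))
})

test_that("GFF3 gene rows are converted from 1-based inclusive coordinates", {
  dir <- withr::local_tempdir()
  gff <- c("##gff-version 3",
           paste("1", "src", "gene", "201", "300", ".", "+", ".",
                 "ID=geneG1;Name=geneG1", sep = "\t"),
           paste("1", "src", "exon", "201", "250", ".", "+", ".",
                 "ID=exon1", sep = "\t"))
  writeLines(gff, file.path(dir, "genes.gff3"))
  ## region half-open [100,200) = 1-based [101,200]: no overlap with [201,300]
  reg <- makeRegionSet(matrix(-1L, 2, 2), "1", c(101, 151), c(200, 250),
                       c("loss", "loss"), region_id = c("CNV1", "CNV2"))
  ov <- annotateOverlap(reg, file.path(dir, "genes.gff3"))
  expect_equal(nrow(ov), 1)
  expect_equal(ov$region_id, "CNV2")
  expect_equal(ov$overlap_bp, 50)  # [201,250] of gene within region
})

test_that("length/frequency contrasts match the Welch oracle", {
  ## direct formula evaluation as the independent oracle
  o <- welchTestSummary(20, sqrt(100 / 3), 3, 50, sqrt(100 / 3), 3)
  expect_equal(o$t, -30 / sqrt(200 / 3), tolerance = 1e-12)
  expect_equal(o$df, 4, tolerance = 1e-9)
  expect_equal(o$p, 2 * pt(-abs(o$t), 4), tolerance = 1e-12)
  ## agreement with stats::t.test on raw data
  tt <- t.test(c(10, 20, 30), c(40, 50, 60))
  expect_equal(o$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(o$p, tt$p.value, tolerance = 1e-9)
})

test_that("geneOverlapContrast summarizes classes and runs Welch tests", {
  carriers <- c(1, 2, 3, 1, 2, 3)
  states <- t(vapply(carriers, function(k) c(rep(-1L, k), rep(0L, 4 - k)),
                     integer(4)))
  reg <- makeRegionSet(states, "1",
                       c(1, 1001, 2001, 3001, 4001, 5001) * 100,
                       c(1, 1001, 2001, 3001, 4001, 5001) * 100 +
                         c(10, 20, 30, 40, 50, 60) - 1,
                       rep("loss", 6), region_id = paste0("CNV", 1:6))
  ov <- data.frame(region_id = c("CNV4", "CNV5", "CNV6"), gene_id = "g",
                   source = "s", overlap_bp = 1)
  res <- geneOverlapContrast(reg, ov)
  s <- res$summary
  expect_equal(s$N, c(3, 3))
  expect_equal(s$mean_length[s$class == "without_genes"], 20)
  expect_equal(s$mean_length[s$class == "with_genes"], 50)
  expect_equal(s$sem_length, rep(sd(c(10, 20, 30)) / sqrt(3), 2))
  o <- welchTestSummary(50, s$sem_length[2], 3, 20, s$sem_length[1], 3)
  expect_equal(res$tests$length$t, o$t, tolerance = 1e-9)
  expect_equal(res$tests$length$p, o$p, tolerance = 1e-9)
  ## identical classes: t = 0, p = 1 (frequency is equal by construction here)
  expect_equal(res$tests$frequency$t, 0)
  expect_equal(res$tests$frequency$p, 1)
  ## a singleton class skips the tests with a warning
  ov1 <- data.frame(region_id = "CNV6", gene_id = "g", source = "s",
                    overlap_bp = 1)
  expect_warning(res1 <- geneOverlapContrast(reg, ov1), "skipped")
  expect_null(res1$tests)
})
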