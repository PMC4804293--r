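suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(GenomicRanges)
})

## tiny LRRSet from a samples x probes matrix (one chromosome, flat GC unless
## a gc vector is given)
makeLRR <- function(x, chrom = "1", spacing = 1000, gc = NULL) {
  m <- ncol(x)
  n <- nrow(x)
  if (is.null(gc)) gc <- 0.4 + 0.2 * sin(seq_len(m) / 7)
  panel <- GRanges(chrom, IRanges(spacing * seq_len(m), width = 1L),
                   probe_id = sprintf("P%05d", seq_len(m)), gc = gc)
  sheet <- data.frame(sample = sprintf("S%03d", seq_len(n)),
                      breed = "B1", group = "G1")
  LRRSet(t(x), panel, sheet)
}

## SegmentSet from explicit probe spans and a segments x samples mean matrix
makeSegmentSet <- function(chrom, first, last, means, sheet = NULL,
                           spacing = 1000) {
  n <- ncol(means)
  if (is.null(sheet))
    sheet <- data.frame(sample = sprintf("S%03d", seq_len(n)),
                        breed = "B1", group = "G1")
  colnames(means) <- sheet$sample
  gr <- GRanges(chrom, IRanges(spacing * first, spacing * last),
                probe_first = as.integer(first), probe_last = as.integer(last),
                n_probes = as.integer(last - first + 1L))
  se <- SummarizedExperiment(assays = list(segMean = means), rowRanges = gr,
                             colData = S4Vectors::DataFrame(sheet, row.names = sheet$sample))
  new("SegmentSet", se)
}

## CNVRegionSet built directly from a regions x samples state matrix
makeRegionSet <- function(states, chrom, start, end, type,
                          means = NULL, sheet = NULL, region_id = NULL) {
  n <- ncol(states)
  if (is.null(sheet))
    sheet <- data.frame(sample = sprintf("S%03d", seq_len(n)),
                        breed = "B1", group = "G1")
  if (is.null(means)) means <- states * -0.6
  if (is.null(region_id)) region_id <- sprintf("R%04d", seq_len(nrow(states)))
  colnames(states) <- colnames(means) <- sheet$sample
  gr <- GRanges(chrom, IRanges(start, end),
                probe_first = NA_integer_, probe_last = NA_integer_,
                type = type, frequency = rowMeans(states != 0L),
                region_id = region_id)
  se <- SummarizedExperiment(assays = list(state = states, regionMean = means),
                             rowRanges = gr,
                             colData = S4Vectors::DataFrame(sheet, row.names = sheet$sample))
  new("CNVRegionSet", se)
}

## pooled within-segment SSE of a samples x probes matrix under breakpoints
## (left-segment end indices)
sseOf <- function(x, breaks) {
  first <- c(1L, breaks + 1L)
  last <- c(breaks, ncol(x))
  s <- 0
  for (i in seq_along(first)) {
    blk <- x[, first[i]:last[i], drop = FALSE]
    s <- s + sum((blk - rowMeans(blk))^2)
  }
  s
}

## exhaustive minimal-SSE partition into k segments with a min-probes bound
bruteSegment <- function(x, k, min_probes) {
  m <- ncol(x)
  if (k == 1L) return(list(breaks = integer(0), sse = sseOf(x, integer(0))))
  cuts <- utils::combn(seq_len(m - 1L), k - 1L, simplify = FALSE)
  best <- NULL; best_sse <- Inf
  for (b in cuts) {
    sizes <- diff(c(0L, b, m))
    if (any(sizes < min_probes)) next
    s <- sseOf(x, b)
    if (s < best_sse) { best_sse <- s; best <- b }
  }
  list(breaks = best, sse = best_sse)
}

## label-permutation-aligned mean absolute error between ancestry matrices
alignedQMAE <- function(Q, Qtrue) {
  K <- ncol(Q)
  perms <- if (K == 2L) list(1:2, 2:1) else
    list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  min(vapply(perms, function(p) mean(abs(Q[, p] - Qtrue)), 0))
}

## match every truth locus to the called region with the largest probe overlap;
## returns per-locus region index (NA = missed) and boundary error in probes
matchTruthRegions <- function(truth, ri) {
  idx <- rep(NA_integer_, nrow(truth))
  berr <- rep(NA_real_, nrow(truth))
  for (l in seq_len(nrow(truth))) {
    cand <- which(ri$seqnames == truth$chrom[l] &
                  ri$probe_first <= truth$last_probe[l] &
                  ri$probe_last >= truth$first_probe[l])
    if (!length(cand)) next
    ov <- pmin(ri$probe_last[cand], truth$last_probe[l]) -
          pmax(ri$probe_first[cand], truth$first_probe[l])
    r <- cand[which.max(ov)]
    idx[l] <- r
    berr[l] <- max(abs(ri$probe_first[r] - truth$first_probe[l]),
                   abs(ri$probe_last[r] - truth$last_probe[l]))
  }
  list(region = idx, boundary_err = berr)
}

## expected three-state call per sample for a truth locus
truthStates <- function(truth_row, genotypes) {
  g <- genotypes[, truth_row$locus]
  if (truth_row$type == "loss") ifelse(g < 2, -1L, 0L) else ifelse(g > 2, 1L, 0L)
}

## random 0/1 genotype cohort (samples x markers) at given event frequencies
simDosage <- function(n, freqs) {
  L <- length(freqs)
  matrix(stats::rbinom(n * L, 1L, rep(freqs, each = n)), n, L)
}
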