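## Multi-sample least-squares segmentation with permutation-tested splits.
## Chromosomes are partitioned by recursive binary splitting: each candidate
## split maximizes the reduction in total within-segment sum of squared
## deviations pooled across samples, and is accepted when a probe-shuffle
## permutation test (the shuffle applied identically across samples, so the
## per-probe cross-sample covariance is preserved) gives p <= p_threshold.

## Split statistics for all admissible split points of a samples x probes
## block. Returns numeric vector over k = left-segment probe count.
.split_stats <- function(x, min_probes) {
  m <- ncol(x)
  ks <- seq.int(min_probes, m - min_probes)
  if (m < 2L * min_probes || length(ks) == 0L) return(NULL)
  cs <- apply(x, 1L, cumsum)            # m x n: cumulative sums per sample
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = nrow(x))
  tot <- cs[m, ]                        # per-sample totals
  A <- rowSums(cs^2)                    # sum_i CS_i(k)^2
  crossT <- as.vector(cs %*% tot)       # sum_i tot_i CS_i(k)
  T2 <- sum(tot^2)
  k <- ks
  stat <- A[k] / k + (T2 - 2 * crossT[k] + A[k]) / (m - k) - T2 / m
  list(k = ks, stat = pmax(stat, 0))
}

#' Best least-squares split of a multi-sample block
#'
#' Finds the split point maximizing the pooled SSE reduction
#' \code{SSE(block) - [SSE(left) + SSE(right)]} over all splits leaving at
#' least \code{min_probes} probes on each side. Ties break toward the
#' smallest index; a block too short to split, or a constant block, returns
#' statistic 0 with no split.
#'
#' @param x numeric matrix, samples x probes (a single sample may be given as
#'   a one-row matrix or a vector).
#' @param min_probes minimum probes per resulting segment.
#' @return list with \code{index} (probes in the left segment, NA if no
#'   split) and \code{statistic}.
#' @export
bestSplit <- function(x, min_probes = 3) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  ss <- .split_stats(x, as.integer(min_probes))
  if (is.null(ss) || max(ss$stat) <= 1e-12)
    return(list(index = NA_integer_, statistic = 0))
  best <- which.max(ss$stat)  # which.max takes the first (smallest k) on ties
  list(index = ss$k[best], statistic = ss$stat[best])
}

## Permutation engine. Shuffles probe order identically across samples and
## recomputes the max split statistic. Returns the exceedance count; with
## early_stop_count set, stops as soon as the count makes significance
## impossible (used during segmentation; permutationP always runs the full
## n_perm for an exact p).
.perm_count <- function(x, observed, n_perm, min_probes, early_stop_count = Inf) {
  m <- ncol(x)
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    xp <- x[, sample.int(m), drop = FALSE]
    ss <- .split_stats(xp, min_probes)
    if (!is.null(ss) && max(ss$stat) >= observed) {
      cnt <- cnt + 1L
      if (cnt > early_stop_count) return(list(count = cnt, done = b))
    }
  }
  list(count = cnt, done = n_perm)
}

#' Permutation p-value of a split statistic
#'
#' \code{p = (1 + #\{permutations with max split statistic >= observed\}) /
#' (1 + n_perm)}. Each permutation shuffles probe order identically across
#' samples. Seeded via \code{cfg@seed} for reproducibility.
#'
#' @param x samples x probes block.
#' @param statistic observed split statistic (from \code{\link{bestSplit}}).
#' @param cfg a \code{\link{SegConfig}}.
#' @return the permutation p-value.
#' @export
permutationP <- function(x, statistic, cfg = SegConfig()) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  withr_seed(cfg@seed, {
    pc <- .perm_count(x, statistic, cfg@n_perm, cfg@min_probes)
    (1 + pc$count) / (1 + cfg@n_perm)
  })
}

## Recursive binary segmentation of a samples x probes matrix; returns sorted
## breakpoint indices (left-segment end positions, probe index space).
##
## A one-level lookahead guards against premature stopping: a block holding
## two CNV loci can have a weak best *single* split (both halves keep high
## within-variance) yet highly significant splits inside each half. When the
## block-level test rejects, the candidate split is still emitted if either
## half's own best split tests significant; recursion then re-finds those
## splits properly. On noise this adds at most two extra tests per rejected
## block, keeping the false-breakpoint rate near 3 x p_threshold.
.segment_block <- function(x, cfg, p_crit_count) {
  breaks <- integer(0)
  test_block <- function(lo, hi) {
    m <- hi - lo + 1L
    if (m < 2L * cfg@min_probes) return(list(cut = NA_integer_, sig = FALSE))
    blk <- x[, lo:hi, drop = FALSE]
    bs <- bestSplit(blk, cfg@min_probes)
    if (is.na(bs$index) || bs$statistic <= 0)
      return(list(cut = NA_integer_, sig = FALSE))
    sig <- if (cfg@p_threshold >= 1) TRUE else {
      pc <- .perm_count(blk, bs$statistic, cfg@n_perm, cfg@min_probes,
                        early_stop_count = p_crit_count)
      pc$count <= p_crit_count
    }
    list(cut = lo + bs$index - 1L, sig = sig)
  }
  rec <- function(lo, hi, depth) {
    if (hi - lo + 1L < 2L * cfg@min_probes || depth > cfg@max_depth) return()
    tb <- test_block(lo, hi)
    if (is.na(tb$cut)) return()
    accept <- tb$sig
    if (!accept) {
      lt <- test_block(lo, tb$cut)
      rt <- test_block(tb$cut + 1L, hi)
      accept <- isTRUE(lt$sig) || isTRUE(rt$sig)
    }
    if (!accept) return()
    breaks <<- c(breaks, tb$cut)
    rec(lo, tb$cut, depth + 1L)
    rec(tb$cut + 1L, hi, depth + 1L)
  }
  rec(1L, ncol(x), 1L)
  sort(breaks)
}

#' Segment one chromosome
#'
#' Recursive binary splitting with permutation-tested breakpoints shared
#' across all samples. A split is accepted when its permutation p-value is at
#' most \code{p_threshold}; recursion continues on both halves until no
#' admissible significant split remains (or \code{max_depth}).
#'
#' @param x an \code{\link{LRRSet}}.
#' @param chrom chromosome label present in the panel.
#' @param cfg a \code{\link{SegConfig}}.
#' @return a \code{\link{SegmentSet}} for that chromosome.
#' @export
segmentChromosome <- function(x, chrom, cfg = SegConfig()) {
  stopifnot(is(x, "LRRSet"))
  sel <- as.character(seqnames(rowRanges(x))) == as.character(chrom)
  if (!any(sel)) stop("chromosome '", chrom, "' not present in the panel")
  v <- t(lrrValues(x)[sel, , drop = FALSE])  # samples x probes
  pos <- start(rowRanges(x))[sel]
  ## largest count still significant: (1 + count)/(1 + n_perm) <= p_threshold
  p_crit_count <- floor(cfg@p_threshold * (1 + cfg@n_perm)) - 1L
  breaks <- withr_seed(cfg@seed + 1000L * match(as.character(chrom),
                                                unique(as.character(seqnames(rowRanges(x))))),
                       .segment_block(v, cfg, p_crit_count))
  first <- c(1L, breaks + 1L)
  last <- c(breaks, ncol(v))
  means <- t(vapply(seq_along(first), function(s)
    rowMeans(v[, first[s]:last[s], drop = FALSE]), numeric(nrow(v))))
  if (nrow(v) == 1L) means <- matrix(means, ncol = 1L)
  gr <- GRanges(as.character(chrom), IRanges(pos[first], pos[last]),
                probe_first = first, probe_last = last,
                n_probes = last - first + 1L)
  colnames(means) <- rownames(v)
  se <- SummarizedExperiment(assays = list(segMean = means), rowRanges = gr,
                             colData = colData(x))
  new("SegmentSet", se)
}

#' Segment every chromosome of an LRR set
#'
#' @param x an \code{\link{LRRSet}}.
#' @param cfg a \code{\link{SegConfig}}.
#' @return a genome-wide \code{\link{SegmentSet}}.
#' @export
segmentGenome <- function(x, cfg = SegConfig()) {
  chroms <- unique(as.character(seqnames(rowRanges(x))))
  parts <- lapply(chroms, function(ch) segmentChromosome(x, ch, cfg))
  ## per-chromosome parts carry disjoint seqlevels; combining them is intended
  out <- suppressWarnings(do.call(rbind, parts))
  new("SegmentSet", out)
}
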