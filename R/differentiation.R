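## Vst lineage-differentiation scans, unique unions across comparisons, gene
## overlap annotation, and length/frequency contrasts.

.pop_var <- function(x, unbiased = FALSE) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (unbiased) { if (n < 2L) return(0) else return(stats::var(x)) }
  sum((x - mean(x))^2) / n
}

#' Vst population differentiation of one region
#'
#' \code{Vst = (V_T - V_S) / V_T}, where V_T is the total variance of the
#' per-individual segment mean LRRs pooled over both groups and V_S the
#' size-weighted mean of the two within-group variances. Population variances
#' (denominator n) are used by default, which guarantees \code{Vst} lies in
#' [0, 1] by the law of total variance; \code{unbiased = TRUE} switches to
#' (n-1) variances, which can go slightly negative and is reported unclamped.
#' A region with V_T = 0 is degenerate and returns 0.
#'
#' @param values per-individual segment mean LRRs for the two groups pooled.
#' @param labels group label per value (exactly two distinct labels).
#' @param unbiased use sample (n-1) variances.
#' @return Vst, with logical attribute \code{degenerate}.
#' @export
vst <- function(values, labels, unbiased = FALSE) {
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) != 2L) stop("vst needs exactly two groups, got ", length(groups))
  n1 <- sum(labels == groups[1]); n2 <- sum(labels == groups[2])
  if (n1 == 0L || n2 == 0L) stop("empty group in vst input")
  vt <- .pop_var(values, unbiased)
  v1 <- .pop_var(values[labels == groups[1]], unbiased)
  v2 <- .pop_var(values[labels == groups[2]], unbiased)
  vs <- (n1 * v1 + n2 * v2) / (n1 + n2)
  if (!is.finite(vt) || vt < 1e-20) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (vt - vs) / vt
  attr(out, "degenerate") <- FALSE
  out
}

#' Vst scan over CNV regions for a set of group comparisons
#'
#' One row per region per comparison, with flags at the strict thresholds
#' \code{Vst > 0.4} and \code{Vst > 0.6}.
#'
#' @param regions a \code{\link{CNVRegionSet}} (uses assay
#'   \code{"regionMean"}).
#' @param comparisons list of length-2 character vectors of group labels,
#'   e.g. \code{list(c("G1","G2"))}.
#' @param by sample sheet column holding the labels (default "group"; use
#'   "breed" for breed-pair comparisons).
#' @param unbiased passed to \code{\link{vst}}.
#' @return data.frame: region_id, comparison, V_T, V_S, V_ST, degenerate,
#'   flag04, flag06.
#' @export
vstScan <- function(regions, comparisons, by = "group", unbiased = FALSE) {
  stopifnot(is(regions, "CNVRegionSet"))
  sheet <- sampleInfo(regions)
  means <- regionMeans(regions)
  rows <- list()
  for (cmp in comparisons) {
    stopifnot(length(cmp) == 2L)
    sel1 <- sheet[[by]] == cmp[1]; sel2 <- sheet[[by]] == cmp[2]
    if (!any(sel1)) stop("unknown or empty ", by, " label: '", cmp[1], "'")
    if (!any(sel2)) stop("unknown or empty ", by, " label: '", cmp[2], "'")
    lab <- c(rep(cmp[1], sum(sel1)), rep(cmp[2], sum(sel2)))
    sub <- cbind(means[, sel1, drop = FALSE], means[, sel2, drop = FALSE])
    cmp_name <- paste0(cmp[1], "_vs_", cmp[2])
    for (r in seq_len(nrow(sub))) {
      v <- vst(sub[r, ], lab, unbiased)
      vt <- .pop_var(sub[r, ], unbiased)
      n1 <- sum(sel1); n2 <- sum(sel2)
      vs <- (n1 * .pop_var(sub[r, seq_len(n1)], unbiased) +
             n2 * .pop_var(sub[r, n1 + seq_len(n2)], unbiased)) / (n1 + n2)
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = rowData(regions)$region_id[r], comparison = cmp_name,
        V_T = vt, V_S = vs, V_ST = as.numeric(v),
        degenerate = attr(v, "degenerate"),
        flag04 = !attr(v, "degenerate") & as.numeric(v) > 0.4,
        flag06 = !attr(v, "degenerate") & as.numeric(v) > 0.6)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Unique differentiated regions across comparisons
#'
#' Set union of the region ids whose Vst strictly exceeds the threshold in
#' any of the given comparison tables.
#'
#' @param tables a \code{\link{vstScan}} data.frame or a list of them.
#' @param threshold Vst cutoff (strict inequality; default 0.4).
#' @return character vector of unique region ids.
#' @export
uniqueDifferentiated <- function(tables, threshold = 0.4) {
  if (is.data.frame(tables)) tables <- list(tables)
  ids <- unlist(lapply(tables, function(tb)
    tb$region_id[!tb$degenerate & tb$V_ST > threshold]))
  unique(ids)
}

#' Annotate CNV regions with overlapping genes
#'
#' Reports every (region, gene) pair overlapping by at least 1 bp. Gene
#' annotation is read from BED (0-based half-open) or GFF3 (1-based
#' inclusive); both are converted to the same internal convention by
#' \code{rtracklayer}, so the boundary semantics follow the half-open rule:
#' a region ending where a gene starts does not overlap.
#'
#' @param regions a \code{\link{CNVRegionSet}} or \code{GRanges}.
#' @param genes path to a BED or GFF3 file, or a \code{GRanges}. For GFF3,
#'   rows with type "gene" are used when a type column exists.
#' @return data.frame: region_id, gene_id, source, overlap_bp (all >= 1).
#' @export
annotateOverlap <- function(regions, genes) {
  rr <- if (is(regions, "CNVRegionSet")) rowRanges(regions) else regions
  if (is.null(rr$region_id)) rr$region_id <- paste0("R", seq_along(rr))
  src <- "granges"
  if (is.character(genes)) {
    src <- basename(genes)
    genes <- rtracklayer::import(genes)
    if (!is.null(genes$type) && any(genes$type == "gene"))
      genes <- genes[genes$type == "gene"]
  }
  if (any(start(genes) > end(genes)))
    stop("malformed interval (start > end) in gene input at line ",
         which(start(genes) > end(genes))[1])
  gid <- genes$Name
  if (is.null(gid)) gid <- genes$name
  if (is.null(gid)) gid <- genes$ID
  if (is.null(gid)) gid <- genes$gene_id
  if (is.null(gid)) gid <- paste0("gene", seq_along(genes))
  hits <- findOverlaps(rr, genes, minoverlap = 1L, ignore.strand = TRUE)
  ov <- width(pintersect(rr[queryHits(hits)], genes[subjectHits(hits)],
                         ignore.strand = TRUE))
  data.frame(region_id = rr$region_id[queryHits(hits)],
             gene_id = gid[subjectHits(hits)],
             source = src, overlap_bp = ov)
}

#' Welch two-sample t-test from summary statistics
#'
#' @param m1,sem1,n1,m2,sem2,n2 per-class mean, standard error of the mean,
#'   and size.
#' @return list with t, Welch-Satterthwaite df, and two-sided p.
#' @export
welchTestSummary <- function(m1, sem1, n1, m2, sem2, n2) {
  se2 <- sem1^2 + sem2^2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Contrast gene-overlapping and non-overlapping CNV regions
#'
#' Classifies every region by whether it appears in the overlap table, then
#' reports per class the count, mean and SEM of region length (bp) and of
#' carrier frequency, plus Welch two-sample t-tests for both contrasts.
#'
#' @param regions a \code{\link{CNVRegionSet}}.
#' @param overlaps output of \code{\link{annotateOverlap}}.
#' @return list: \code{summary} (data.frame per class) and \code{tests}
#'   (Welch results for length and frequency; NULL with a warning when a
#'   class has fewer than 2 regions).
#' @export
geneOverlapContrast <- function(regions, overlaps) {
  rd <- rowData(regions)
  rr <- rowRanges(regions)
  with_gene <- rd$region_id %in% unique(overlaps$region_id)
  len <- end(rr) - start(rr) + 1
  freq <- rd$frequency
  cls <- ifelse(with_gene, "with_genes", "without_genes")
  smry <- do.call(rbind, lapply(c("without_genes", "with_genes"), function(cl) {
    sel <- cls == cl
    n <- sum(sel)
    data.frame(class = cl, N = n,
               mean_length = mean(len[sel]),
               sem_length = stats::sd(len[sel]) / sqrt(n),
               mean_frequency = mean(freq[sel]),
               sem_frequency = stats::sd(freq[sel]) / sqrt(n))
  }))
  tests <- NULL
  if (all(table(cls)[c("without_genes", "with_genes")] >= 2, na.rm = TRUE) &&
      length(unique(cls)) == 2L) {
    tl <- stats::t.test(len[cls == "with_genes"], len[cls == "without_genes"])
    tf <- stats::t.test(freq[cls == "with_genes"], freq[cls == "without_genes"])
    tests <- list(
      length = list(t = unname(tl$statistic), df = unname(tl$parameter),
                    p = tl$p.value),
      frequency = list(t = unname(tf$statistic), df = unname(tf$parameter),
                       p = tf$p.value))
  } else {
    warning("a class has fewer than 2 regions: Welch tests skipped")
  }
  list(summary = smry, tests = tests)
}

#' Write a Vst table (and optional Manhattan-style file)
#'
#' @param tab \code{\link{vstScan}} output.
#' @param path output file (tab-delimited).
#' @param regions optional \code{\link{CNVRegionSet}}; when given, a second
#'   file \code{<path>.manhattan} with chrom, midpoint_bp, V_ST per
#'   comparison is written for external plotting.
#' @export
writeVstTable <- function(tab, path, regions = NULL) {
  data.table::fwrite(tab, path, sep = "\t")
  if (!is.null(regions)) {
    rr <- rowRanges(regions)
    mid <- floor((start(rr) + end(rr)) / 2)
    key <- match(tab$region_id, rowData(regions)$region_id)
    man <- data.frame(comparison = tab$comparison,
                      chrom = as.character(seqnames(rr))[key],
                      midpoint_bp = mid[key], V_ST = tab$V_ST)
    data.table::fwrite(man, paste0(path, ".manhattan"), sep = "\t")
  }
  invisible(path)
}
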