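## Three-state CNV genotyping of segment means, merging into non-redundant
## regions, frequency filtering, and biallelic recoding of deletions.

#' Three-state call of a segment mean LRR
#'
#' \code{mean <= -threshold} is a loss, \code{mean >= +threshold} a gain,
#' anything between is neutral. The boundary is inclusive: exactly -0.3 is a
#' loss under the default threshold.
#'
#' @param segment_mean numeric vector (or matrix) of segment mean LRRs.
#' @param cfg a \code{\link{CallConfig}}.
#' @return integer codes of the same shape: -1 loss, 0 neutral, +1 gain.
#' @export
callState <- function(segment_mean, cfg = CallConfig()) {
  if (any(!is.finite(segment_mean)))
    stop("non-finite segment mean LRR; cannot call a state")
  out <- 0L * segment_mean
  out[segment_mean <= -cfg@state_threshold] <- -1L
  out[segment_mean >= cfg@state_threshold] <- 1L
  storage.mode(out) <- "integer"
  out
}

#' Call states for every segment and sample
#'
#' @param segset a \code{\link{SegmentSet}}.
#' @param cfg a \code{\link{CallConfig}}.
#' @return integer matrix, segments x samples.
#' @export
callStates <- function(segset, cfg = CallConfig()) {
  callState(segMeans(segset), cfg)
}

#' Merge called segments into non-redundant CNV regions
#'
#' Segments with at least one non-neutral sample become candidates; on each
#' chromosome, candidates whose probe-index spans overlap or are adjacent are
#' unioned into one region. A sample's state in a merged region comes from
#' the constituent segment with the largest absolute segment mean; the region
#' type is loss or gain when all non-neutral sample states agree, otherwise
#' mixed. Region coordinates are 1-based inclusive bp of the first and last
#' probe.
#'
#' @param segset a \code{\link{SegmentSet}}.
#' @param calls integer matrix from \code{\link{callStates}} (recomputed if
#'   missing).
#' @param cfg a \code{\link{CallConfig}}.
#' @return a \code{\link{CNVRegionSet}} (unfiltered; provisional ids).
#' @export
mergeRegions <- function(segset, calls = NULL, cfg = CallConfig()) {
  stopifnot(is(segset, "SegmentSet"))
  if (is.null(calls)) calls <- callStates(segset, cfg)
  means <- segMeans(segset)
  rd <- rowData(segset)
  chrom <- as.character(seqnames(rowRanges(segset)))
  cand <- which(rowSums(calls != 0L) > 0L)
  if (!length(cand)) {
    gr <- GRanges()
    se <- SummarizedExperiment(
      assays = list(state = matrix(integer(0), 0, ncol(segset)),
                    regionMean = matrix(numeric(0), 0, ncol(segset))),
      rowRanges = gr, colData = colData(segset))
    rowData(se)$region_id <- character(0)
    rowData(se)$type <- character(0)
    rowData(se)$frequency <- numeric(0)
    return(new("CNVRegionSet", se))
  }
  out_rows <- list()
  for (ch in unique(chrom[cand])) {
    ci <- cand[chrom[cand] == ch]
    ir <- IRanges(rd$probe_first[ci], rd$probe_last[ci])
    red <- reduce(ir)  # merges overlapping and adjacent index spans
    hits <- findOverlaps(ir, red)
    for (r in seq_along(red)) {
      members <- ci[queryHits(hits)[subjectHits(hits) == r]]
      ## per-sample state from the constituent with largest |mean LRR|
      sub_means <- means[members, , drop = FALSE]
      sub_calls <- calls[members, , drop = FALSE]
      pick <- max.col(t(abs(sub_means)), ties.method = "first")
      st <- sub_calls[cbind(pick, seq_len(ncol(sub_calls)))]
      npr <- rd$n_probes[members]
      rmean <- as.vector(crossprod(sub_means, npr)) / sum(npr)
      nn <- unique(st[st != 0L])
      type <- if (length(nn) == 1L) c(`-1` = "loss", `1` = "gain")[as.character(nn)]
              else "mixed"
      out_rows[[length(out_rows) + 1L]] <- list(
        chrom = ch,
        start = min(start(rowRanges(segset))[members]),
        end = max(end(rowRanges(segset))[members]),
        probe_first = min(rd$probe_first[members]),
        probe_last = max(rd$probe_last[members]),
        type = unname(type), state = st, regionMean = rmean)
    }
  }
  st_mat <- do.call(rbind, lapply(out_rows, `[[`, "state"))
  rm_mat <- do.call(rbind, lapply(out_rows, `[[`, "regionMean"))
  colnames(st_mat) <- colnames(rm_mat) <- colnames(means)
  gr <- GRanges(vapply(out_rows, `[[`, "", "chrom"),
                IRanges(vapply(out_rows, `[[`, 0, "start"),
                        vapply(out_rows, `[[`, 0, "end")),
                probe_first = vapply(out_rows, function(z) as.integer(z$probe_first), 0L),
                probe_last = vapply(out_rows, function(z) as.integer(z$probe_last), 0L),
                type = vapply(out_rows, `[[`, "", "type"))
  gr$frequency <- rowMeans(st_mat != 0L)
  gr$region_id <- sprintf("R%03d", seq_along(gr))
  se <- SummarizedExperiment(assays = list(state = st_mat, regionMean = rm_mat),
                             rowRanges = gr, colData = colData(segset))
  new("CNVRegionSet", se)
}

#' Filter CNV regions by carrier frequency
#'
#' Retains regions whose frequency is strictly above \code{min_freq}
#' ("above 1\%" under the default), then re-assigns ids CNV1..CNVn by
#' descending frequency, ties broken by (chrom, start).
#'
#' @param regions a \code{\link{CNVRegionSet}}.
#' @param cfg a \code{\link{CallConfig}}.
#' @return the filtered, re-identified \code{\link{CNVRegionSet}}.
#' @export
filterByFrequency <- function(regions, cfg = CallConfig()) {
  stopifnot(is(regions, "CNVRegionSet"))
  rd <- rowData(regions)
  keep <- which(rd$frequency > cfg@min_freq)
  out <- regions[keep, ]
  rd <- rowData(out)
  suppressWarnings(chr_num <- as.integer(as.character(seqnames(rowRanges(out)))))
  chr_key <- if (anyNA(chr_num)) as.character(seqnames(rowRanges(out))) else chr_num
  ord <- order(-rd$frequency, chr_key, start(rowRanges(out)))
  out <- out[ord, ]
  rowData(out)$region_id <- paste0("CNV", seq_len(nrow(out)))
  new("CNVRegionSet", out)
}

#' Recode deletion CNVs as biallelic markers
#'
#' Only loss-type regions are admitted. A sample's loss state becomes code
#' \code{"12"} (the deletion event), anything else \code{"22"}. Marker
#' positions are region midpoints.
#'
#' @param regions a \code{\link{CNVRegionSet}}.
#' @return a \code{\link{CNVGenotypes}} object (empty, with a warning, if no
#'   loss regions exist).
#' @export
recodeDeletions <- function(regions) {
  stopifnot(is(regions, "CNVRegionSet"))
  loss <- which(rowData(regions)$type == "loss")
  if (!length(loss)) {
    warning("no loss-type regions: returning an empty genotype matrix")
    return(CNVGenotypes(matrix(character(0), ncol(regions), 0),
                        data.frame(region_id = character(0), chrom = character(0),
                                   start = numeric(0), end = numeric(0),
                                   midpoint = numeric(0), frequency = numeric(0)),
                        sampleInfo(regions)))
  }
  sub <- regions[loss, ]
  st <- regionStates(sub)
  codes <- t(ifelse(st == -1L, "12", "22"))  # samples x markers
  rr <- rowRanges(sub)
  mi <- data.frame(region_id = rowData(sub)$region_id,
                   chrom = as.character(seqnames(rr)),
                   start = start(rr), end = end(rr),
                   midpoint = floor((start(rr) + end(rr)) / 2),
                   frequency = rowData(sub)$frequency)
  colnames(codes) <- mi$region_id
  rownames(codes) <- colnames(st)
  CNVGenotypes(codes, mi, sampleInfo(regions))
}

#' Per-group CNV carrier frequency
#'
#' @param regions a \code{\link{CNVRegionSet}}.
#' @param group one or more group labels from the sample sheet's
#'   \code{group} column.
#' @param by grouping column of the sample sheet (default "group"; use
#'   "breed" for breed-level frequencies).
#' @return matrix regions x groups of carrier fractions.
#' @export
regionFrequencyByGroup <- function(regions, group, by = "group") {
  stopifnot(is(regions, "CNVRegionSet"))
  sheet <- sampleInfo(regions)
  st <- regionStates(regions)
  out <- matrix(NA_real_, nrow(regions), length(group),
                dimnames = list(rowData(regions)$region_id, group))
  for (g in group) {
    sel <- sheet[[by]] == g
    if (!any(sel)) stop("unknown or empty ", by, " label: '", g, "'")
    out[, g] <- rowMeans(st[, sel, drop = FALSE] != 0L)
  }
  out
}

#' Write CNV regions as BED
#'
#' Internal 1-based inclusive coordinates are converted to BED's 0-based
#' half-open convention; the score column is frequency x 1000.
#'
#' @param regions a \code{\link{CNVRegionSet}}.
#' @param path output file.
#' @export
writeRegionsBED <- function(regions, path) {
  rr <- rowRanges(regions)
  df <- data.frame(chrom = as.character(seqnames(rr)), start = start(rr) - 1L,
                   end = end(rr), name = rowData(regions)$region_id,
                   score = round(rowData(regions)$frequency * 1000),
                   strand = ".")
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write recoded deletion genotypes as a PLINK-style PED/MAP pair
#'
#' Alleles are "1"/"2" with "1 2" marking a deletion event and "2 2" a
#' neutral one; MAP positions are region midpoints.
#'
#' @param g a \code{\link{CNVGenotypes}}.
#' @param prefix output path prefix; writes \code{prefix.ped} and
#'   \code{prefix.map}.
#' @export
writePedMap <- function(g, prefix) {
  codes <- genotypeCodes(g)
  sheet <- sampleInfo(g)
  al <- ifelse(codes == "12", "1 2", "2 2")
  ped <- data.frame(FID = sheet$breed, IID = sheet$sample, PAT = 0, MAT = 0,
                    SEX = 0, PHENO = -9)
  ped <- cbind(ped, as.data.frame(al, optional = TRUE))
  mi <- markerInfo(g)
  map <- data.frame(chrom = mi$chrom, id = mi$region_id, cm = 0, pos = mi$midpoint)
  data.table::fwrite(ped, paste0(prefix, ".ped"), sep = "\t", col.names = FALSE)
  data.table::fwrite(map, paste0(prefix, ".map"), sep = "\t", col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK-style PED/MAP pair written by \code{\link{writePedMap}}
#'
#' @param prefix path prefix of the .ped/.map pair.
#' @return a \code{\link{CNVGenotypes}}.
#' @export
readPedMap <- function(prefix) {
  ped <- data.table::fread(paste0(prefix, ".ped"), sep = "\t", header = FALSE,
                           colClasses = "character")
  map <- as.data.frame(data.table::fread(paste0(prefix, ".map"), sep = "\t",
                                         header = FALSE))
  names(map) <- c("chrom", "region_id", "cm", "midpoint")
  al <- as.matrix(ped[, -(1:6)])
  codes <- ifelse(al == "1 2" | al == "2 1", "12", "22")
  dimnames(codes) <- list(ped[[2]], map$region_id)
  sheet <- data.frame(sample = ped[[2]], breed = ped[[1]], group = NA_character_)
  mi <- data.frame(region_id = map$region_id, chrom = as.character(map$chrom),
                   start = NA_real_, end = NA_real_, midpoint = map$midpoint,
                   frequency = colMeans(codes == "12"))
  CNVGenotypes(codes, mi, sheet)
}
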