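#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## Configuration objects
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults describe the standard
#' desk-scale cohort used throughout the package: three ancestral groups of two
#' breeds each (8 animals per breed) plus admixed hybrid individuals, five
#' chromosomes of 400 probes at 2 kb spacing, 20 multi-probe CNV loci of which
#' ten deletion loci carry strongly group-differentiated allele frequencies.
#'
#' @slot n_groups number of ancestral groups.
#' @slot breeds_per_group breeds nested within each group.
#' @slot n_per_breed purebred individuals per breed.
#' @slot n_hybrids admixed individuals (ancestry drawn from a flat Dirichlet
#'   over the groups).
#' @slot n_chrom,probes_per_chrom,probe_spacing probe panel layout; positions
#'   are \code{probe_spacing * index} within each chromosome (bp).
#' @slot n_cnv_loci number of CNV loci placed on the panel.
#' @slot cnv_span_probes integer range (min, max) of probes spanned by a locus.
#' @slot p_loss probability that a locus is a deletion (the rest duplications).
#' @slot divergence_F Balding-Nichols drift parameters, length 2:
#'   group-from-ancestral and breed-from-group.
#' @slot base_freq_range ancestral allele frequencies are uniform on this interval.
#' @slot n_differentiated_loci deletion loci assigned fixed, strongly
#'   differentiated group frequencies.
#' @slot diff_freq_pair the two fixed frequencies: first group gets
#'   \code{diff_freq_pair[1]}, all other groups \code{diff_freq_pair[2]}.
#' @slot lrr_means expected LRR per copy state, named "0","1","2","3".
#' @slot noise_sd per-probe Gaussian LRR noise standard deviation.
#' @slot gc_wave_amplitude coefficient of the GC intensity wave
#'   \code{amplitude * (gc - mean(gc))} added to every probe.
#' @slot seed RNG seed; identical configs give bit-identical simulations.
#' @export
setClass("SimConfig", representation(
  n_groups = "integer", breeds_per_group = "integer", n_per_breed = "integer",
  n_hybrids = "integer", n_chrom = "integer", probes_per_chrom = "integer",
  probe_spacing = "integer", n_cnv_loci = "integer", cnv_span_probes = "integer",
  p_loss = "numeric", divergence_F = "numeric", base_freq_range = "numeric",
  n_differentiated_loci = "integer", diff_freq_pair = "numeric",
  lrr_means = "numeric", noise_sd = "numeric", gc_wave_amplitude = "numeric",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(n_groups = object@n_groups, breeds_per_group = object@breeds_per_group,
           n_per_breed = object@n_per_breed, n_chrom = object@n_chrom,
           probes_per_chrom = object@probes_per_chrom, probe_spacing = object@probe_spacing)
  bad <- names(cnt)[cnt < 1L | is.na(cnt)]
  if (length(bad)) msg <- c(msg, paste0("field '", bad, "' must be >= 1"))
  if (object@n_hybrids < 0L) msg <- c(msg, "field 'n_hybrids' must be >= 0")
  if (object@n_cnv_loci < 0L) msg <- c(msg, "field 'n_cnv_loci' must be >= 0")
  if (!(object@noise_sd > 0)) msg <- c(msg, "field 'noise_sd' must be > 0")
  if (object@gc_wave_amplitude < 0) msg <- c(msg, "field 'gc_wave_amplitude' must be >= 0")
  if (length(object@divergence_F) != 2L || any(object@divergence_F <= 0) ||
      any(object@divergence_F >= 1))
    msg <- c(msg, "field 'divergence_F' must be two values in (0, 1)")
  if (length(object@cnv_span_probes) != 2L || object@cnv_span_probes[1] < 1L ||
      diff(object@cnv_span_probes) < 0L)
    msg <- c(msg, "field 'cnv_span_probes' must be an increasing pair of counts")
  if (length(object@base_freq_range) != 2L || any(object@base_freq_range <= 0) ||
      any(object@base_freq_range >= 1) || diff(object@base_freq_range) < 0)
    msg <- c(msg, "field 'base_freq_range' must be an interval within (0, 1)")
  if (length(object@diff_freq_pair) != 2L || any(object@diff_freq_pair < 0) ||
      any(object@diff_freq_pair > 1))
    msg <- c(msg, "field 'diff_freq_pair' must be two values in [0, 1]")
  if (object@n_differentiated_loci > object@n_cnv_loci)
    msg <- c(msg, "field 'n_differentiated_loci' exceeds n_cnv_loci")
  if (!identical(names(object@lrr_means), c("0", "1", "2", "3")))
    msg <- c(msg, "field 'lrr_means' must be named '0','1','2','3'")
  if (object@p_loss < 0 || object@p_loss > 1) msg <- c(msg, "field 'p_loss' must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param n_groups,breeds_per_group,n_per_breed,n_hybrids cohort composition.
#' @param n_chrom,probes_per_chrom,probe_spacing panel layout.
#' @param n_cnv_loci,cnv_span_probes,p_loss CNV locus placement.
#' @param divergence_F,base_freq_range,n_differentiated_loci,diff_freq_pair
#'   allele-frequency model.
#' @param lrr_means,noise_sd,gc_wave_amplitude intensity model.
#' @param seed RNG seed.
#' @return A \code{SimConfig} object.
#' @rdname SimConfig-class
#' @export
SimConfig <- function(n_groups = 3, breeds_per_group = 2, n_per_breed = 8,
                      n_hybrids = 6, n_chrom = 5, probes_per_chrom = 400,
                      probe_spacing = 2000, n_cnv_loci = 20,
                      cnv_span_probes = c(10, 30), p_loss = 0.7,
                      divergence_F = c(0.15, 0.05), base_freq_range = c(0.1, 0.9),
                      n_differentiated_loci = min(10, n_cnv_loci),
                      diff_freq_pair = c(0.9, 0.05),
                      lrr_means = c("0" = -1.2, "1" = -0.5, "2" = 0, "3" = 0.3),
                      noise_sd = 0.1, gc_wave_amplitude = 0.2, seed = 1234) {
  new("SimConfig",
      n_groups = as.integer(n_groups), breeds_per_group = as.integer(breeds_per_group),
      n_per_breed = as.integer(n_per_breed), n_hybrids = as.integer(n_hybrids),
      n_chrom = as.integer(n_chrom), probes_per_chrom = as.integer(probes_per_chrom),
      probe_spacing = as.integer(probe_spacing), n_cnv_loci = as.integer(n_cnv_loci),
      cnv_span_probes = as.integer(cnv_span_probes), p_loss = as.numeric(p_loss),
      divergence_F = as.numeric(divergence_F), base_freq_range = as.numeric(base_freq_range),
      n_differentiated_loci = as.integer(n_differentiated_loci),
      diff_freq_pair = as.numeric(diff_freq_pair),
      lrr_means = stats::setNames(as.numeric(lrr_means), names(lrr_means)),
      noise_sd = as.numeric(noise_sd), gc_wave_amplitude = as.numeric(gc_wave_amplitude),
      seed = as.integer(seed))
}

#' Segmentation configuration
#'
#' @slot p_threshold permutation significance level for accepting a split
#'   (default 0.01).
#' @slot n_perm number of probe-order permutations (default 1000).
#' @slot min_probes minimum probes per segment (default 3).
#' @slot max_depth recursion bound of the binary splitting.
#' @slot seed RNG seed for the permutation stream.
#' @export
setClass("SegConfig", representation(
  p_threshold = "numeric", n_perm = "integer", min_probes = "integer",
  max_depth = "integer", seed = "integer"))

setValidity("SegConfig", function(object) {
  msg <- character()
  if (!(object@p_threshold > 0 && object@p_threshold <= 1))
    msg <- c(msg, "p_threshold must be in (0, 1]")
  if (object@n_perm < 100L) msg <- c(msg, "n_perm must be >= 100")
  if (object@min_probes < 1L) msg <- c(msg, "min_probes must be >= 1")
  if (object@max_depth < 1L) msg <- c(msg, "max_depth must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param p_threshold,n_perm,min_probes,max_depth,seed see slots.
#' @rdname SegConfig-class
#' @export
SegConfig <- function(p_threshold = 0.01, n_perm = 1000, min_probes = 3,
                      max_depth = 20, seed = 1) {
  new("SegConfig", p_threshold = as.numeric(p_threshold), n_perm = as.integer(n_perm),
      min_probes = as.integer(min_probes), max_depth = as.integer(max_depth),
      seed = as.integer(seed))
}

#' CNV calling configuration
#'
#' @slot state_threshold segment-mean LRR threshold for the three-state model;
#'   mean <= -threshold is a loss, mean >= +threshold a gain (default 0.3, the
#'   boundary inclusive).
#' @slot min_freq frequency filter; regions with carrier frequency strictly
#'   above this are retained (default 0.01).
#' @export
setClass("CallConfig", representation(state_threshold = "numeric", min_freq = "numeric"))

setValidity("CallConfig", function(object) {
  msg <- character()
  if (!(object@state_threshold > 0)) msg <- c(msg, "state_threshold must be > 0")
  if (object@min_freq < 0 || object@min_freq >= 1) msg <- c(msg, "min_freq must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param state_threshold,min_freq see slots.
#' @rdname CallConfig-class
#' @export
CallConfig <- function(state_threshold = 0.3, min_freq = 0.01) {
  new("CallConfig", state_threshold = as.numeric(state_threshold),
      min_freq = as.numeric(min_freq))
}

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' LRR probe-by-sample container
#'
#' A \linkS4class{RangedSummarizedExperiment} whose single assay \code{"LRR"}
#' holds log R ratios (rows = probes, columns = samples). \code{rowRanges}
#' carries the probe panel (probe_id, GC fraction), \code{colData} the sample
#' sheet (breed, group).
#' @export
setClass("LRRSet", contains = "RangedSummarizedExperiment")

setValidity("LRRSet", function(object) {
  msg <- character()
  if (!"LRR" %in% assayNames(object)) msg <- c(msg, "assay 'LRR' is required")
  rr <- rowRanges(object)
  if (!all(c("probe_id", "gc") %in% colnames(mcols(rr))))
    msg <- c(msg, "rowRanges must carry 'probe_id' and 'gc'")
  else {
    gc <- mcols(rr)$gc
    if (any(gc < 0 | gc > 1)) msg <- c(msg, "gc fractions must lie in [0, 1]")
    o <- order(as.integer(as.character(seqnames(rr))), start(rr))
    if (!identical(o, seq_along(rr))) msg <- c(msg, "probes must be sorted by (chrom, position)")
  }
  if (length(msg)) msg else TRUE
})

#' @param values numeric matrix, probes x samples.
#' @param panel \code{GRanges} probe panel with mcols \code{probe_id}, \code{gc}.
#' @param samples \code{data.frame} sample sheet with columns
#'   \code{sample}, \code{breed}, \code{group}.
#' @rdname LRRSet-class
#' @export
LRRSet <- function(values, panel, samples) {
  stopifnot(nrow(values) == length(panel), ncol(values) == nrow(samples))
  colnames(values) <- samples$sample
  rownames(values) <- mcols(panel)$probe_id
  cd <- S4Vectors::DataFrame(samples, row.names = samples$sample)
  new("LRRSet", SummarizedExperiment(assays = list(LRR = values),
                                     rowRanges = panel, colData = cd))
}

#' Shared multi-sample segmentation
#'
#' Rows are segments (tiling each chromosome's probe index range without gaps),
#' the assay \code{"segMean"} holds the per-sample mean LRR of every segment.
#' Row metadata records the probe index span (\code{probe_first},
#' \code{probe_last}) and probe count.
#' @export
setClass("SegmentSet", contains = "RangedSummarizedExperiment")

setValidity("SegmentSet", function(object) {
  msg <- character()
  if (!"segMean" %in% assayNames(object)) msg <- c(msg, "assay 'segMean' is required")
  rd <- rowData(object)
  need <- c("probe_first", "probe_last", "n_probes")
  if (!all(need %in% colnames(rd))) {
    msg <- c(msg, "rowData must carry probe_first, probe_last, n_probes")
  } else if (nrow(rd) > 0) {
    for (ch in unique(as.character(seqnames(rowRanges(object))))) {
      i <- which(as.character(seqnames(rowRanges(object))) == ch)
      i <- i[order(rd$probe_first[i])]
      if (any(rd$probe_first[i][-1] != rd$probe_last[i][-length(i)] + 1L))
        msg <- c(msg, paste0("segments on chrom ", ch, " do not tile the probe range"))
    }
    if (any(rd$n_probes != rd$probe_last - rd$probe_first + 1L))
      msg <- c(msg, "n_probes inconsistent with probe span")
  }
  if (length(msg)) msg else TRUE
})

#' Non-redundant CNV regions with per-sample states
#'
#' Assay \code{"state"} holds integer calls (-1 loss, 0 neutral, +1 gain),
#' assay \code{"regionMean"} the per-sample mean LRR over the region span.
#' Row metadata: \code{region_id} (CNV1..CNVn by descending frequency after
#' filtering), \code{type} (loss/gain/mixed), \code{frequency} (fraction of
#' samples with a non-neutral state), and the probe index span.
#' @export
setClass("CNVRegionSet", contains = "RangedSummarizedExperiment")

setValidity("CNVRegionSet", function(object) {
  msg <- character()
  if (!all(c("state", "regionMean") %in% assayNames(object)))
    msg <- c(msg, "assays 'state' and 'regionMean' are required")
  rd <- rowData(object)
  if (!all(c("region_id", "type", "frequency") %in% colnames(rd)))
    msg <- c(msg, "rowData must carry region_id, type, frequency")
  else if (nrow(object) > 0) {
    f <- rowMeans(assay(object, "state") != 0L)
    if (max(abs(f - rd$frequency)) > 1e-12)
      msg <- c(msg, "frequency must equal the fraction of non-neutral samples")
    if (!all(rd$type %in% c("loss", "gain", "mixed"))) msg <- c(msg, "invalid region type")
  }
  if (length(msg)) msg else TRUE
})

#' Biallelic deletion genotypes
#'
#' Deletion CNV regions recoded as biallelic markers: code \code{"12"} marks a
#' deletion (loss) event, \code{"22"} a neutral one. The dosage view maps
#' \code{"12"} to 1 and \code{"22"} to 0.
#'
#' @slot codes character matrix, samples x markers, values in {"12","22"}.
#' @slot markerInfo data.frame with one row per marker: region_id, chrom,
#'   start, end, midpoint, frequency.
#' @slot samples data.frame sample sheet (sample, breed, group).
#' @export
setClass("CNVGenotypes", representation(codes = "matrix", markerInfo = "data.frame",
                                        samples = "data.frame"))

setValidity("CNVGenotypes", function(object) {
  msg <- character()
  if (length(object@codes) && !all(object@codes %in% c("12", "22")))
    msg <- c(msg, "codes must all be '12' or '22'")
  if (ncol(object@codes) != nrow(object@markerInfo))
    msg <- c(msg, "markerInfo rows must match code columns")
  if (nrow(object@codes) != nrow(object@samples))
    msg <- c(msg, "samples rows must match code rows")
  if (length(msg)) msg else TRUE
})

#' @rdname CNVGenotypes-class
#' @param codes,markerInfo,samples see slots.
#' @export
CNVGenotypes <- function(codes, markerInfo, samples) {
  new("CNVGenotypes", codes = codes, markerInfo = markerInfo, samples = samples)
}

#' Maximum-likelihood admixture fit
#'
#' @slot K number of ancestral clusters.
#' @slot Q sample x K ancestry proportions (rows on the simplex).
#' @slot F K x marker cluster deletion-event frequencies.
#' @slot loglik per-iteration log-likelihood trace of the best restart
#'   (non-decreasing).
#' @slot converged logical.
#' @slot seed RNG seed used.
#' @export
setClass("AdmixtureFit", representation(K = "integer", Q = "matrix", F = "matrix",
                                        loglik = "numeric", converged = "logical",
                                        seed = "integer"))

setValidity("AdmixtureFit", function(object) {
  msg <- character()
  if (ncol(object@Q) != object@K) msg <- c(msg, "Q must have K columns")
  if (nrow(object@F) != object@K) msg <- c(msg, "F must have K rows")
  if (max(abs(rowSums(object@Q) - 1)) > 1e-8) msg <- c(msg, "Q rows must sum to 1")
  if (any(object@F < 0 | object@F > 1)) msg <- c(msg, "F entries must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "SimConfig", function(object) {
  n <- object@n_groups * object@breeds_per_group * object@n_per_breed + object@n_hybrids
  cat("SimConfig:", object@n_groups, "groups x", object@breeds_per_group,
      "breeds x", object@n_per_breed, "animals +", object@n_hybrids,
      "hybrids =", n, "samples\n")
  cat("  panel:", object@n_chrom, "chrom x", object@probes_per_chrom,
      "probes @", object@probe_spacing, "bp;", object@n_cnv_loci, "CNV loci (",
      object@n_differentiated_loci, "differentiated)\n")
  cat("  noise_sd:", object@noise_sd, " gc_wave:", object@gc_wave_amplitude,
      " seed:", object@seed, "\n")
})

setMethod("show", "CNVGenotypes", function(object) {
  cat("CNVGenotypes:", nrow(object@codes), "samples x", ncol(object@codes),
      "deletion markers ('12' = deletion event)\n")
})

setMethod("show", "AdmixtureFit", function(object) {
  cat("AdmixtureFit: K =", object@K, ",", nrow(object@Q), "samples,",
      ncol(object@F), "markers\n")
  cat("  log-likelihood:", format(utils::tail(object@loglik, 1), digits = 10),
      "after", length(object@loglik), "iterations; converged:", object@converged, "\n")
})

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' Accessors for cnvpopgen containers
#'
#' @param x a cnvpopgen object.
#' @return The requested component: a matrix, data.frame or vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
lrrValues <- function(x) assay(x, "LRR")

#' @rdname accessors
#' @export
probePanel <- function(x) rowRanges(x)

#' @rdname accessors
#' @export
sampleInfo <- function(x) {
  if (is(x, "CNVGenotypes")) return(x@samples)
  as.data.frame(colData(x))
}

#' @rdname accessors
#' @export
segMeans <- function(x) assay(x, "segMean")

#' @rdname accessors
#' @export
regionStates <- function(x) assay(x, "state")

#' @rdname accessors
#' @export
regionMeans <- function(x) assay(x, "regionMean")

#' @rdname accessors
#' @export
regionInfo <- function(x) {
  df <- as.data.frame(rowRanges(x))
  df$width <- NULL
  df
}

#' @rdname accessors
#' @export
genotypeCodes <- function(x) x@codes

#' @rdname accessors
#' @export
markerInfo <- function(x) x@markerInfo

#' Deletion dosage view: 1 if the sample carries the deletion event ("12")
#' @rdname accessors
#' @export
dosage <- function(x) (x@codes == "12") + 0L

#' @rdname accessors
#' @export
ancestryQ <- function(x) x@Q

#' @rdname accessors
#' @export
clusterFreqs <- function(x) x@F

#' @rdname accessors
#' @export
logLikTrace <- function(x) x@loglik
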