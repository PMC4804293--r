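## Reading LRR matrices / probe maps / sample sheets, autosome restriction,
## and removal of GC-content intensity waves.

#' Read a probe panel
#'
#' Tab-delimited file with columns probe_id, chrom, position, gc (a PLINK
#' MAP-like layout plus a GC track). Chromosome labels are opaque tokens.
#'
#' @param path file path.
#' @return \code{GRanges} sorted by (chrom, position).
#' @export
readPanel <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character")
  need <- c("probe_id", "chrom", "position", "gc")
  if (!all(need %in% names(dt)))
    stop("panel file must have columns: ", paste(need, collapse = ", "))
  pos <- .numeric_col(dt$position, path, "position")
  gc <- .numeric_col(dt$gc, path, "gc")
  gr <- GRanges(dt$chrom, IRanges(pos, width = 1L), probe_id = dt$probe_id, gc = gc)
  suppressWarnings(ord <- order(as.integer(dt$chrom), pos))
  if (anyNA(suppressWarnings(as.integer(dt$chrom))))
    ord <- order(dt$chrom, pos)
  gr[ord]
}

#' Read a sample sheet
#'
#' Tab-delimited with columns sample, breed, group.
#' @param path file path.
#' @return data.frame.
#' @export
readSampleSheet <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", colClasses = "character"))
  need <- c("sample", "breed", "group")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  df[need]
}

.numeric_col <- function(x, path, what) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v) && !all(is.na(v) == (x %in% c("NA", "")))) {
    bad <- which(is.na(v) & !(x %in% c("NA", "")))[1L]
    stop("parse error in ", path, ": non-numeric ", what, " at line ",
         bad + 1L, " ('", x[bad], "')")
  }
  v
}

#' Read an LRR matrix with its panel and sample sheet
#'
#' The matrix file is tab-delimited with columns Name, Chr, Position then one
#' LRR column per sample (a GenomeStudio final-report-like layout). Probes
#' whose chromosome label is not in \code{autosomes} are dropped and the count
#' reported. Missing LRR cells are imputed with the per-probe median across
#' samples when fewer than 5\% of a probe's values are missing; probes with
#' more missingness are dropped.
#'
#' @param matrixPath,panelPath,samplesheetPath input files.
#' @param autosomes character vector of retained chromosome labels
#'   (default \code{"1".."29"}, the cattle autosomes).
#' @return an \code{\link{LRRSet}}; \code{metadata()} records
#'   \code{n_dropped_nonautosome} and \code{n_dropped_missing}.
#' @export
readLRR <- function(matrixPath, panelPath, samplesheetPath,
                    autosomes = as.character(1:29)) {
  panel <- readPanel(panelPath)
  sheet <- readSampleSheet(samplesheetPath)
  dt <- data.table::fread(matrixPath, sep = "\t", colClasses = "character")
  meta_cols <- c("Name", "Chr", "Position")
  if (!all(meta_cols %in% names(dt)))
    stop("LRR matrix must have columns Name, Chr, Position")
  sample_cols <- setdiff(names(dt), meta_cols)
  missing_in_sheet <- setdiff(sample_cols, sheet$sample)
  missing_in_matrix <- setdiff(sheet$sample, sample_cols)
  if (length(missing_in_sheet) || length(missing_in_matrix))
    stop("sample header / sample sheet mismatch; in matrix only: [",
         paste(missing_in_sheet, collapse = ", "), "]; in sheet only: [",
         paste(missing_in_matrix, collapse = ", "), "]")
  vals <- matrix(NA_real_, nrow(dt), length(sheet$sample))
  for (j in seq_along(sheet$sample))
    vals[, j] <- .numeric_col(dt[[sheet$sample[j]]], matrixPath, "LRR value")
  ## align matrix rows to panel order
  idx <- match(mcols(panel)$probe_id, dt$Name)
  if (anyNA(idx))
    stop("panel probes absent from LRR matrix: ",
         paste(utils::head(mcols(panel)$probe_id[is.na(idx)], 5), collapse = ", "))
  vals <- vals[idx, , drop = FALSE]
  keep <- as.character(seqnames(panel)) %in% autosomes
  n_dropped <- sum(!keep)
  panel <- panel[keep]
  vals <- vals[keep, , drop = FALSE]
  ## missing-value policy
  n_dropped_missing <- 0L
  miss <- is.na(vals)
  if (any(miss)) {
    frac <- rowMeans(miss)
    drop <- frac >= 0.05
    imp <- which(frac > 0 & !drop)
    for (i in imp)
      vals[i, miss[i, ]] <- stats::median(vals[i, ], na.rm = TRUE)
    n_dropped_missing <- sum(drop)
    panel <- panel[!drop]
    vals <- vals[!drop, , drop = FALSE]
  }
  message(n_dropped, " probe(s) dropped (non-autosome); ",
          n_dropped_missing, " dropped (missingness)")
  out <- LRRSet(vals, panel, sheet)
  metadata(out)$n_dropped_nonautosome <- n_dropped
  metadata(out)$n_dropped_missing <- n_dropped_missing
  out
}

#' Remove GC-content intensity waves
#'
#' Per sample, regresses LRR on the panel's probe GC fraction (ordinary least
#' squares for \code{mode = "linear"}, local regression for
#' \code{mode = "loess"}) and subtracts the fit, adding back the sample mean
#' so each sample's mean LRR is retained. For the linear mode the corrected
#' LRR is exactly orthogonal to GC and the operation is idempotent.
#'
#' @param x an \code{\link{LRRSet}}.
#' @param mode "linear" (default) or "loess".
#' @param span loess span (mode = "loess" only).
#' @return a corrected \code{\link{LRRSet}}.
#' @export
gcCorrect <- function(x, mode = c("linear", "loess"), span = 0.5) {
  mode <- match.arg(mode)
  stopifnot(is(x, "LRRSet"))
  gc <- mcols(rowRanges(x))$gc
  if (stats::sd(gc) < 1e-12)
    stop("degenerate design: GC track is constant, cannot fit GC correction")
  v <- lrrValues(x)
  gcc <- gc - mean(gc)
  out <- v
  if (mode == "linear") {
    ## closed-form per-sample OLS on centred gc
    beta <- as.vector(crossprod(gcc, v)) / sum(gcc^2)
    alpha <- colMeans(v)  # intercept on centred gc = sample mean
    out <- v - outer(gcc, beta)  # residual + sample mean, mean retained
  } else {
    for (j in seq_len(ncol(v))) {
      fit <- stats::loess(v[, j] ~ gc, span = span, degree = 2)
      out[, j] <- v[, j] - stats::fitted(fit) + mean(v[, j])
    }
  }
  y <- x
  assay(y, "LRR") <- out
  y
}
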