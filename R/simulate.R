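## Synthetic cohort generator: probe panels, hierarchically diverged breed
## allele frequencies (Balding-Nichols), CNV genotypes, and LRR matrices with
## known truth. Everything is deterministic given the SimConfig seed.

#' Simulate a probe panel
#'
#' Builds an ordered probe panel: \code{probes_per_chrom} probes per
#' chromosome at positions \code{probe_spacing * index}, with a smooth
#' positional GC fraction track (two superimposed sinusoids with per-chromosome
#' random phases) so that a GC intensity wave can be injected and removed.
#'
#' @param cfg a \code{\link{SimConfig}}.
#' @return \code{GRanges} with mcols \code{probe_id} and \code{gc}.
#' @export
simulatePanel <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  m <- cfg@probes_per_chrom
  withr_seed(cfg@seed, {
    phases <- matrix(stats::runif(2L * cfg@n_chrom, 0, 2 * pi), nrow = 2L)
    grl <- lapply(seq_len(cfg@n_chrom), function(ch) {
      idx <- seq_len(m)
      gc <- 0.45 + 0.15 * sin(2 * pi * idx / 173 + phases[1L, ch]) +
        0.05 * sin(2 * pi * idx / 37 + phases[2L, ch])
      gc <- pmin(pmax(gc, 0), 1)
      GRanges(seqnames = as.character(ch),
              ranges = IRanges(start = cfg@probe_spacing * idx, width = 1L),
              probe_id = sprintf("P%d_%05d", ch, idx), gc = gc)
    })
    ## chromosomes carry disjoint seqlevels by construction
    suppressWarnings(do.call(c, grl))
  })
}

## Evaluate expr with a local, restored RNG state seeded at `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Balding-Nichols draw: Beta with mean p and dispersion F
.bn_draw <- function(n, p, F) {
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  stats::rbeta(n, a, b)
}

#' Simulate hierarchically diverged allele frequencies
#'
#' Draws an ancestral deletion-allele frequency per locus uniformly on
#' \code{base_freq_range}, then group frequencies by a Balding-Nichols Beta
#' draw with drift \code{divergence_F[1]}, then breed frequencies within
#' groups with drift \code{divergence_F[2]}. The first
#' \code{n_differentiated_loci} (deletion) loci instead receive fixed
#' frequencies: group 1 gets \code{diff_freq_pair[1]}, all other groups
#' \code{diff_freq_pair[2]}, with no breed-level noise.
#'
#' @param cfg a \code{\link{SimConfig}}.
#' @param seed optional seed overriding \code{cfg@seed}.
#' @return list with \code{breed_freqs} (loci x breeds), \code{group_freqs}
#'   (loci x groups), \code{ancestral}, and \code{diff_loci} (indices).
#' @export
simulateFreqs <- function(cfg, seed = cfg@seed) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  L <- cfg@n_cnv_loci
  G <- cfg@n_groups
  B <- cfg@breeds_per_group
  withr_seed(seed + 1L, {
    anc <- stats::runif(L, cfg@base_freq_range[1], cfg@base_freq_range[2])
    gf <- matrix(0, L, G, dimnames = list(NULL, paste0("G", seq_len(G))))
    bf <- matrix(0, L, G * B)
    colnames(bf) <- as.vector(outer(seq_len(B), seq_len(G),
                                    function(b, g) paste0("G", g, "B", b)))
    for (l in seq_len(L)) {
      gf[l, ] <- .bn_draw(G, anc[l], cfg@divergence_F[1])
      for (g in seq_len(G))
        bf[l, (g - 1L) * B + seq_len(B)] <- .bn_draw(B, gf[l, g], cfg@divergence_F[2])
    }
    diff_loci <- seq_len(cfg@n_differentiated_loci)
    if (length(diff_loci)) {
      gf[diff_loci, ] <- cfg@diff_freq_pair[2]
      gf[diff_loci, 1L] <- cfg@diff_freq_pair[1]
      for (g in seq_len(G))
        bf[diff_loci, (g - 1L) * B + seq_len(B)] <- gf[diff_loci, g]
    }
    list(breed_freqs = bf, group_freqs = gf, ancestral = anc, diff_loci = diff_loci)
  })
}

## Place n_cnv_loci non-overlapping loci on the panel, >= `buffer` probes from
## each other and from chromosome ends. Retries; overlap after retries is an
## internal error.
.place_loci <- function(cfg) {
  L <- cfg@n_cnv_loci
  if (L == 0L) return(data.frame())
  m <- cfg@probes_per_chrom
  buffer <- 5L
  occupied <- lapply(seq_len(cfg@n_chrom), function(i) integer(0))
  out <- vector("list", L)
  spans <- sample(seq(cfg@cnv_span_probes[1], cfg@cnv_span_probes[2]), L, replace = TRUE)
  types <- ifelse(stats::runif(L) < cfg@p_loss, "loss", "gain")
  if (cfg@n_differentiated_loci > 0L)
    types[seq_len(cfg@n_differentiated_loci)] <- "loss"
  for (l in seq_len(L)) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      ch <- sample.int(cfg@n_chrom, 1L)
      span <- spans[l]
      if (m - span - 2L * buffer < 1L) next
      first <- sample.int(m - span - 2L * buffer, 1L) + buffer
      last <- first + span - 1L
      block <- (first - buffer):(last + buffer)
      if (!any(block %in% occupied[[ch]])) {
        occupied[[ch]] <- c(occupied[[ch]], block)
        out[[l]] <- data.frame(locus = l, chrom = ch, first_probe = first,
                               last_probe = last, type = types[l])
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("internal error: could not place ", L, " non-overlapping CNV loci; ",
           "reduce n_cnv_loci or cnv_span_probes")
  }
  loci <- do.call(rbind, out)
  loci$differentiated <- loci$locus %in% seq_len(cfg@n_differentiated_loci)
  loci
}

## Sample sheet for a config: purebreds by group/breed, then hybrids.
.sample_sheet <- function(cfg) {
  G <- cfg@n_groups; B <- cfg@breeds_per_group; n <- cfg@n_per_breed
  breeds <- as.vector(outer(seq_len(B), seq_len(G),
                            function(b, g) paste0("G", g, "B", b)))
  df <- data.frame(
    sample = character(0), breed = character(0), group = character(0))
  k <- 0L
  rows <- list()
  for (g in seq_len(G)) for (b in seq_len(B)) for (i in seq_len(n)) {
    k <- k + 1L
    rows[[k]] <- data.frame(sample = sprintf("S%03d", k),
                            breed = paste0("G", g, "B", b), group = paste0("G", g))
  }
  for (i in seq_len(cfg@n_hybrids)) {
    k <- k + 1L
    rows[[k]] <- data.frame(sample = sprintf("S%03d", k), breed = "HYB", group = "HYB")
  }
  do.call(rbind, rows)
}

#' Simulate CNV genotypes with known truth
#'
#' Draws per-sample copy states at every CNV locus. Purebred individuals draw
#' deletion-allele counts from Hardy-Weinberg at their breed's allele
#' frequency; hybrids draw at an allele frequency mixed by their ancestry
#' proportions (a flat Dirichlet over the groups, using the locus's group
#' frequencies). Deletion loci yield copy states {0,1,2}; duplication loci are
#' collapsed to carrier/non-carrier states {3,2}.
#'
#' @param cfg a \code{\link{SimConfig}}.
#' @return list: \code{samples} (sample sheet), \code{genotypes} (samples x
#'   loci copy states), \code{freqs} (from \code{\link{simulateFreqs}}),
#'   \code{ancestry_Q} (samples x groups), \code{loci} (placement, may be
#'   empty until combined with a panel).
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  freqs <- simulateFreqs(cfg)
  sheet <- .sample_sheet(cfg)
  n <- nrow(sheet)
  G <- cfg@n_groups
  L <- cfg@n_cnv_loci
  withr_seed(cfg@seed + 2L, {
    types <- ifelse(stats::runif(L) < cfg@p_loss, "loss", "gain")
    if (cfg@n_differentiated_loci > 0L)
      types[seq_len(cfg@n_differentiated_loci)] <- "loss"
    Q <- matrix(0, n, G, dimnames = list(sheet$sample, paste0("G", seq_len(G))))
    is_hyb <- sheet$group == "HYB"
    for (g in seq_len(G)) Q[sheet$group == paste0("G", g), g] <- 1
    if (any(is_hyb)) {
      d <- matrix(stats::rgamma(sum(is_hyb) * G, shape = 1), ncol = G)
      Q[is_hyb, ] <- d / rowSums(d)
    }
    geno <- matrix(2L, n, L, dimnames = list(sheet$sample, NULL))
    if (L > 0L) {
      ## per-sample allele frequency: breed for purebreds, Q-mixed group
      ## frequency for hybrids
      pfreq <- matrix(0, n, L)
      pure <- which(!is_hyb)
      pfreq[pure, ] <- t(freqs$breed_freqs[, sheet$breed[pure], drop = FALSE])
      if (any(is_hyb))
        pfreq[is_hyb, ] <- Q[is_hyb, , drop = FALSE] %*% t(freqs$group_freqs)
      nall <- matrix(stats::rbinom(n * L, 2L, as.vector(pfreq)), n, L)
      for (l in seq_len(L)) {
        if (types[l] == "loss") geno[, l] <- 2L - nall[, l]
        else geno[, l] <- ifelse(nall[, l] > 0L, 3L, 2L)
      }
    }
    list(samples = sheet, genotypes = geno, freqs = freqs, ancestry_Q = Q,
         locus_types = types)
  })
}

#' Simulate a full LRR cohort with truth
#'
#' Combines \code{\link{simulatePanel}}, locus placement, and
#' \code{\link{simulateGenotypes}} into a probe-by-sample LRR matrix: probes
#' inside a CNV locus get \code{lrr_means[copy state]} plus Gaussian noise,
#' off-locus probes pure Gaussian noise, and every probe receives the GC wave
#' \code{gc_wave_amplitude * (gc - mean(gc))}.
#'
#' @param cfg a \code{\link{SimConfig}}.
#' @return list with \code{lrr} (an \code{\link{LRRSet}}) and \code{truth}
#'   (cnv_loci, genotypes, breed_freqs, group_freqs, ancestry_Q, diff_loci).
#' @export
simulateCohort <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  panel <- simulatePanel(cfg)
  gt <- simulateGenotypes(cfg)
  loci <- withr_seed(cfg@seed + 3L, .place_loci(cfg))
  if (nrow(loci)) {
    ## keep locus types consistent between placement and genotypes
    loci$type <- gt$locus_types[loci$locus]
    loci <- loci[order(loci$locus), , drop = FALSE]
  }
  n <- nrow(gt$samples)
  m <- length(panel)
  mpc <- cfg@probes_per_chrom
  lrr <- withr_seed(cfg@seed + 4L, {
    x <- matrix(stats::rnorm(m * n, 0, cfg@noise_sd), m, n)
    if (nrow(loci)) for (l in seq_len(nrow(loci))) {
      rows <- (loci$chrom[l] - 1L) * mpc + (loci$first_probe[l]:loci$last_probe[l])
      mu <- cfg@lrr_means[as.character(gt$genotypes[, loci$locus[l]])]
      x[rows, ] <- sweep(x[rows, , drop = FALSE], 2L, mu, "+")
    }
    x + cfg@gc_wave_amplitude * (mcols(panel)$gc - mean(mcols(panel)$gc))
  })
  if (nrow(loci)) {
    loci$start_bp <- cfg@probe_spacing * loci$first_probe
    loci$end_bp <- cfg@probe_spacing * loci$last_probe
  }
  truth <- list(cnv_loci = loci, genotypes = gt$genotypes,
                breed_freqs = gt$freqs$breed_freqs,
                group_freqs = gt$freqs$group_freqs,
                ancestry_Q = gt$ancestry_Q,
                diff_loci = gt$freqs$diff_loci)
  stopifnot(max(abs(rowSums(truth$ancestry_Q) - 1)) < 1e-9)
  list(lrr = LRRSet(lrr, panel, gt$samples), truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Writes the LRR matrix as tab-delimited text (columns Name, Chr, Position,
#' then one column per sample), the sample sheet, and the truth as JSON.
#'
#' @param sim result of \code{\link{simulateCohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- probePanel(sim$lrr)
  mat <- data.table::data.table(
    Name = mcols(panel)$probe_id,
    Chr = as.character(seqnames(panel)),
    Position = start(panel))
  vals <- data.table::as.data.table(lrrValues(sim$lrr))
  mat <- cbind(mat, vals)
  paths <- c(lrr = file.path(dir, "lrr_matrix.txt"),
             panel = file.path(dir, "panel.txt"),
             samples = file.path(dir, "samples.txt"),
             truth = file.path(dir, "truth.json"))
  data.table::fwrite(mat, paths["lrr"], sep = "\t")
  data.table::fwrite(data.table::data.table(
    probe_id = mcols(panel)$probe_id, chrom = as.character(seqnames(panel)),
    position = start(panel), gc = mcols(panel)$gc), paths["panel"], sep = "\t")
  data.table::fwrite(sampleInfo(sim$lrr), paths["samples"], sep = "\t")
  jsonlite::write_json(sim$truth, paths["truth"], digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(paths)
}
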