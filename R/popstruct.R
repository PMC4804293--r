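## Relatedness filtering, IBS distance, classical MDS, neighbor-joining,
## hierarchical clustering, and maximum-likelihood admixture inference on the
## biallelic deletion markers.

## Pairwise mismatch counts between samples (rows of a 0/1 dosage matrix).
.mismatch_matrix <- function(X) {
  X %*% t(1 - X) + (1 - X) %*% t(X)
}

#' Method-of-moments IBD sharing (pi-hat) for one sample pair
#'
#' With the one-state deletion coding only two identity-by-state classes are
#' observable per marker (codes match / codes differ), so the classical
#' three-equation moment system collapses: P(IBD=0) is estimated as the
#' observed mismatch count over its expectation under independence,
#' \code{sum(2 f (1-f))} with \code{f} the marker event frequencies; the
#' residual sharing is assigned to P(IBD=2) (P(IBD=1) is not identifiable
#' and set to 0). Estimates are clamped to [0,1] and
#' \code{pi-hat = P(IBD=1)/2 + P(IBD=2)}.
#'
#' @param g1,g2 dosage vectors (1 = deletion event) over the same markers.
#' @param freqs per-marker event frequencies (estimated from the cohort).
#' @return pi-hat in [0, 1], with attribute \code{ibd} = c(P0, P1, P2).
#' @export
piHat <- function(g1, g2, freqs) {
  stopifnot(length(g1) == length(g2), length(freqs) == length(g1))
  e0 <- sum(2 * freqs * (1 - freqs))
  if (e0 < 1e-9)
    stop("undefined estimate: all markers are monomorphic")
  p0 <- min(max(sum(g1 != g2) / e0, 0), 1)
  ibd <- c(p0, 0, 1 - p0)
  out <- ibd[2] / 2 + ibd[3]
  attr(out, "ibd") <- ibd
  out
}

## Full pairwise pi-hat matrix (vectorized).
.pihat_matrix <- function(X, freqs) {
  e0 <- sum(2 * freqs * (1 - freqs))
  if (e0 < 1e-9) stop("undefined estimate: all markers are monomorphic")
  M <- .mismatch_matrix(X)
  P <- 1 - pmin(pmax(M / e0, 0), 1)
  diag(P) <- 1
  dimnames(P) <- list(rownames(X), rownames(X))
  P
}

#' Greedy relatedness filter
#'
#' While any sample pair has pi-hat above \code{max_pihat}, the member of the
#' worst (highest pi-hat) pair with the larger mean pi-hat to all other
#' retained samples is removed; ties break toward removing the later sample,
#' so the procedure is deterministic.
#'
#' @param g a \code{\link{CNVGenotypes}}.
#' @param max_pihat removal threshold (default 0.4).
#' @param exclude optional sample ids excluded up front (e.g. from pedigree).
#' @return character vector of retained sample ids.
#' @export
relatednessFilter <- function(g, max_pihat = 0.4, exclude = character(0)) {
  X <- dosage(g)
  freqs <- colMeans(X)
  keep <- setdiff(rownames(X), exclude)
  P <- .pihat_matrix(X[keep, , drop = FALSE], freqs)
  diag(P) <- 0
  repeat {
    w <- which(P == max(P), arr.ind = TRUE)
    if (max(P) <= max_pihat) break
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE][1, ]
    i <- w[1]; j <- w[2]
    mi <- mean(P[i, -i]); mj <- mean(P[j, -j])
    drop <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    P <- P[-drop, -drop, drop = FALSE]
    if (nrow(P) < 2L) break
  }
  rownames(P)
}

#' Identity-by-state genetic distance
#'
#' For every pair, IBS2 counts markers where both codes match (both "12" or
#' both "22"), IBS1 markers where they differ (a "12"/"22" pair still shares
#' the "2" allele), and
#' \code{D = 1 - (IBS2 + 0.5 IBS1) / N} with N the marker count. With the
#' two-code set the largest attainable distance is 0.5.
#'
#' @param g a \code{\link{CNVGenotypes}}.
#' @return symmetric distance matrix with zero diagonal, entries in [0, 1].
#' @export
ibsDistance <- function(g) {
  X <- dosage(g)
  N <- ncol(X)
  if (N == 0L) stop("zero markers: IBS distance undefined")
  M <- .mismatch_matrix(X)          # mismatches = IBS1 count
  D <- M / (2 * N)                  # 1 - ((N - M) + 0.5 M)/N
  diag(D) <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers \code{-D^2/2}, takes the top \code{dims} eigenpairs with
#' positive eigenvalues and scales eigenvectors by the square root of their
#' eigenvalues. Each coordinate's sign is fixed so its largest-magnitude
#' loading is positive. If fewer than \code{dims} positive eigenvalues exist,
#' the available coordinates are returned with a warning.
#'
#' @param D symmetric distance matrix.
#' @param dims number of coordinates (default 4).
#' @return matrix n x <= dims with columns C1..; eigenvalues in
#'   \code{attr(, "eig")}.
#' @export
classicalMDS <- function(D, dims = 4) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(dims >= 1, dims < n)
  fit <- stats::cmdscale(D, k = dims, eig = TRUE)
  pos <- fit$eig[seq_len(dims)] > max(fit$eig[1], 1) * 1e-12
  if (!all(pos)) {
    warning("only ", sum(pos), " positive eigenvalue(s); returning ",
            sum(pos), " coordinate(s)")
  }
  Y <- fit$points[, pos, drop = FALSE]
  for (j in seq_len(ncol(Y))) {
    i <- which.max(abs(Y[, j]))
    if (Y[i, j] < 0) Y[, j] <- -Y[, j]
  }
  colnames(Y) <- paste0("C", seq_len(ncol(Y)))
  rownames(Y) <- rownames(D)
  attr(Y, "eig") <- fit$eig
  Y
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \code{ape::nj}); negative branch-length
#' estimates are clamped to zero and counted in attribute
#' \code{n_clamped}. The result is unrooted.
#'
#' @param D symmetric distance matrix with sample ids as dimnames.
#' @return an \code{ape} \code{phylo} tree.
#' @export
njTree <- function(D) {
  D <- as.matrix(D)
  if (max(abs(D - t(D))) > 1e-8) stop("input distance matrix is not symmetric")
  stopifnot(nrow(D) >= 3)
  tr <- ape::nj(stats::as.dist(D))
  n_clamped <- sum(tr$edge.length < 0)
  tr$edge.length <- pmax(tr$edge.length, 0)
  attr(tr, "n_clamped") <- n_clamped
  tr
}

#' Hierarchical clustering of mean-LRR profiles
#'
#' Agglomerative clustering of samples by Euclidean distance between their
#' per-region mean LRR profiles, average linkage by default.
#'
#' @param region_means matrix samples x regions of mean LRRs (e.g.
#'   \code{t(regionMeans(regions))}).
#' @param linkage hclust linkage method (default "average").
#' @return an \code{hclust} object.
#' @export
hierCluster <- function(region_means, linkage = "average") {
  stopifnot(!anyNA(region_means))
  stats::hclust(stats::dist(region_means), method = linkage)
}

#' Serialize an hclust dendrogram or phylo tree to Newick
#'
#' @param x an \code{hclust} or \code{phylo} object.
#' @param path optional output file; if missing the Newick string is returned.
#' @export
asNewick <- function(x, path = NULL) {
  if (inherits(x, "hclust")) x <- ape::as.phylo(x)
  s <- ape::write.tree(x)
  if (!is.null(path)) { writeLines(s, path); return(invisible(path)) }
  s
}

#' Maximum-likelihood admixture inference
#'
#' Fits the admixture model in which individual \code{i}'s markers are drawn
#' from a mixture over \code{K} ancestral clusters: with \code{c} allele
#' draws per marker and deletion-event count \code{x_il}, the log-likelihood
#' is \code{sum x_il log(sum_k q_ik f_kl) + (c - x_il) log(sum_k q_ik
#' (1-f_kl))}, maximized by expectation-maximization jointly over the
#' ancestry proportions Q (rows on the simplex) and the cluster event
#' frequencies F. The log-likelihood is non-decreasing every iteration; the
#' best of \code{n_restarts} seeded restarts is returned. Each deletion
#' marker contributes a single allele draw (\code{c = 1}), matching the
#' one-state deletion coding; set \code{c = 2} for standard biallelic data.
#'
#' @param g a \code{\link{CNVGenotypes}} or a numeric dosage matrix
#'   (samples x markers, entries in 0..c).
#' @param K number of ancestral clusters.
#' @param seed RNG seed.
#' @param max_iter,tol EM stopping rule (absolute log-likelihood change).
#' @param n_restarts random restarts; best final log-likelihood wins.
#' @param c allele draws per marker (default 1).
#' @return an \code{\link{AdmixtureFit}}.
#' @export
admixtureFit <- function(g, K, seed = 1, max_iter = 2000, tol = 1e-6,
                         n_restarts = 3, c = 1) {
  X <- if (is(g, "CNVGenotypes")) dosage(g) else as.matrix(g)
  n <- nrow(X); L <- ncol(X)
  K <- as.integer(K)
  if (K > n) stop("K exceeds the sample count")
  stopifnot(K >= 1, all(X >= 0), all(X <= c))
  if (K == 1L) {
    Fhat <- matrix(colMeans(X) / c, 1L, L)
    P <- pmin(pmax(Fhat[rep(1L, n), , drop = FALSE], 1e-12), 1 - 1e-12)
    ll <- sum(X * log(P) + (c - X) * log(1 - P))
    return(new("AdmixtureFit", K = 1L, Q = matrix(1, n, 1,
               dimnames = list(rownames(X), "K1")),
               F = Fhat, loglik = ll, converged = TRUE, seed = as.integer(seed)))
  }
  eps <- 1e-12
  run_em <- function(r) {
    set.seed(seed + r - 1L)
    Q <- matrix(stats::rgamma(n * K, 1), n, K); Q <- Q / rowSums(Q)
    F <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)
    trace <- numeric(0)
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      P1 <- Q %*% F
      P1c <- pmin(pmax(P1, eps), 1 - eps)
      ll <- sum(X * log(P1c) + (c - X) * log(1 - P1c))
      trace <- c(trace, ll)
      if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) { conv <- TRUE; break }
      Qn <- matrix(0, n, K)
      Fnum <- matrix(0, K, L); Fden <- matrix(0, K, L)
      for (k in seq_len(K)) {
        A <- outer(Q[, k], F[k, ]) / P1c          # responsibility, event allele
        B <- outer(Q[, k], 1 - F[k, ]) / (1 - P1c) # responsibility, other allele
        XA <- X * A; XB <- (c - X) * B
        Qn[, k] <- rowSums(XA + XB)
        Fnum[k, ] <- colSums(XA)
        Fden[k, ] <- colSums(XA + XB)
      }
      Q <- Qn / (c * L)
      Q <- Q / rowSums(Q)  # numerical guard; rows already ~1
      F <- ifelse(Fden > 0, Fnum / Fden, F)
    }
    list(Q = Q, F = F, trace = trace, conv = conv)
  }
  fits <- lapply(seq_len(n_restarts), run_em)
  best <- which.max(vapply(fits, function(f) utils::tail(f$trace, 1), 0))
  f <- fits[[best]]
  dimnames(f$Q) <- list(rownames(X), paste0("K", seq_len(K)))
  new("AdmixtureFit", K = K, Q = f$Q, F = pmin(pmax(f$F, 0), 1),
      loglik = f$trace, converged = f$conv, seed = as.integer(seed))
}
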