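#' FPKM from read counts
#'
#' `FPKM = counts * 1e9 / (gene_length_bp * total_mapped)`, computed from
#' uniquely mapped fragment counts.
#'
#' @param counts Genes x samples matrix of non-negative integer counts.
#' @param gene_lengths Gene lengths in bp (named or positionally matched).
#' @param total_mapped Per-sample total mapped fragment counts.
#' @return Genes x samples FPKM matrix.
#' @examples
#' compute_fpkm(matrix(100), gene_lengths = 1000, total_mapped = 1e6) # 100
#' @export
compute_fpkm <- function(counts, gene_lengths, total_mapped) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (length(gene_lengths) != nrow(counts))
    stop("need one gene length per row of 'counts'")
  bad <- which(gene_lengths <= 0)
  if (length(bad))
    stop("non-positive gene length for gene ",
         paste(rownames(counts)[bad] %||% bad, collapse = ", "))
  if (length(total_mapped) != ncol(counts))
    stop("need one total mapped count per sample")
  if (any(total_mapped <= 0)) stop("total mapped counts must be positive")
  sweep(counts * 1e9 / gene_lengths, 2L, total_mapped, "/")
}

#' Median-of-ratios size factors
#'
#' Reference profile = per-gene geometric mean over samples, computed on
#' genes with no zero and no missing value; each sample's size factor is
#' the median ratio of its values to the reference.
#'
#' @param mat Genes x samples matrix of non-negative values.
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(mat) {
  usable <- rowSums(is.na(mat) | mat == 0) == 0L
  if (sum(usable) < 10L)
    stop("fewer than 10 genes usable for the reference profile; ",
         "size factors would be unreliable")
  lm_ <- log(mat[usable, , drop = FALSE])
  ref <- rowMeans(lm_)
  f <- apply(lm_, 2L, function(x) exp(stats::median(x - ref)))
  stats::setNames(f, colnames(mat))
}

#' Normalize FPKM within species by median-of-ratios size factors
#'
#' Size factors are computed independently for the samples of each species
#' (so merging species never changes them) and each sample's values are
#' divided by its factor.  Factors are attached as attribute
#' `"size_factors"`.
#'
#' @param mat Genes x samples FPKM matrix.
#' @param metadata Optional sample metadata with columns `sample` and
#'   `species`; when `NULL` all columns are treated as one species.
#' @return The normalized matrix.
#' @export
normalize_within_species <- function(mat, metadata = NULL) {
  mat <- as.matrix(mat)
  if (is.null(metadata)) {
    groups <- list(colnames(mat) %||% seq_len(ncol(mat)))
  } else {
    idx <- match(colnames(mat), metadata$sample)
    if (anyNA(idx)) stop("samples missing from metadata: ",
                         paste(colnames(mat)[is.na(idx)], collapse = ", "))
    groups <- split(colnames(mat), metadata$species[idx])
  }
  sf <- numeric(0)
  for (g in groups) {
    if (length(g) < 2L)
      stop("need >= 2 samples per species to normalize")
    f <- size_factors(mat[, g, drop = FALSE])
    mat[, g] <- sweep(mat[, g, drop = FALSE], 2L, f, "/")
    sf <- c(sf, f)
  }
  attr(mat, "size_factors") <- sf[colnames(mat)]
  mat
}

#' Binary encoding of expression
#'
#' Values at or above the threshold (default FPKM 2.0) are coded expressed
#' (1), values below are coded not expressed (0), and missing values stay
#' missing.
#'
#' @param mat Genes x samples (or genes x taxa) FPKM matrix.
#' @param threshold Positive FPKM threshold; the boundary is inclusive
#'   (`>= threshold` codes 1).
#' @return Integer matrix of 0/1/NA with the input dimnames.
#' @export
binarize <- function(mat, threshold = 2.0) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be positive")
  out <- ifelse(is.na(mat), NA_integer_, as.integer(mat >= threshold))
  dimnames(out) <- dimnames(mat)
  out
}

#' Per-stage mean expression by species
#'
#' Arithmetic mean of (normalized) FPKM over the replicates of each
#' species x stage group; missing replicates are excluded from the mean,
#' never imputed as zero, and groups with no observed replicate are `NA`.
#'
#' @param mat Genes x samples matrix.
#' @param metadata Sample metadata with columns `sample`, `species`,
#'   `stage`.
#' @return Long data frame: `gene`, `species`, `stage`, `mean_fpkm`.
#' @export
stage_means <- function(mat, metadata) {
  idx <- match(colnames(mat), metadata$sample)
  if (anyNA(idx)) stop("samples missing from metadata")
  key <- paste(metadata$species[idx], metadata$stage[idx], sep = "\r")
  out <- NULL
  for (k in unique(key)) {
    sub <- mat[, key == k, drop = FALSE]
    m <- rowMeans(sub, na.rm = TRUE)
    m[rowSums(!is.na(sub)) == 0L] <- NA_real_
    sp_st <- strsplit(k, "\r", fixed = TRUE)[[1]]
    out <- rbind(out, data.frame(gene = rownames(mat), species = sp_st[1],
                                 stage = sp_st[2], mean_fpkm = unname(m)))
  }
  rownames(out) <- NULL
  out
}

#' Per-species consensus binary states at one stage
#'
#' Majority vote over the binarized replicates of each species at the
#' given stage; ties and all-missing groups are coded missing.  The result
#' (species x genes) is the leaf matrix used for ancestral reconstruction
#' on the species tree.
#'
#' @param bin Genes x samples 0/1/NA matrix from [binarize()].
#' @param metadata Sample metadata (`sample`, `species`, `stage`).
#' @param stage Stage label to extract.
#' @return Species x genes 0/1/NA matrix.
#' @export
stage_consensus_binary <- function(bin, metadata, stage) {
  idx <- match(colnames(bin), metadata$sample)
  if (anyNA(idx)) stop("samples missing from metadata")
  sel <- metadata$stage[idx] == stage
  if (!any(sel)) stop("no samples at stage ", stage)
  sp <- metadata$species[idx][sel]
  sub <- bin[, sel, drop = FALSE]
  species <- unique(sp)
  out <- matrix(NA_integer_, length(species), nrow(bin),
                dimnames = list(species, rownames(bin)))
  for (s in species) {
    m <- sub[, sp == s, drop = FALSE]
    ones <- rowSums(m == 1L, na.rm = TRUE)
    zeros <- rowSums(m == 0L, na.rm = TRUE)
    st <- rep(NA_integer_, nrow(bin))
    st[ones > zeros] <- 1L
    st[zeros > ones] <- 0L
    out[s, ] <- st
  }
  out
}

#' Principal component analysis of expression samples
#'
#' Centred (unscaled) PCA of the samples; genes with any missing value are
#' dropped first (reported).  By default expression is `log2(FPKM + 1)`
#' transformed, which exposes more structure than raw FPKM; set
#' `log_transform = FALSE` for raw values.
#'
#' @param mat Genes x samples matrix.
#' @param n_components Number of components to return.
#' @param log_transform Apply `log2(x + 1)` first (default `TRUE`).
#' @return List with `scores` (samples x components), `loadings`,
#'   `variance_fraction` (non-increasing, summing to <= 1) and
#'   `n_genes_used`.
#' @export
expression_pca <- function(mat, n_components = 2L, log_transform = TRUE) {
  if (ncol(mat) < 2L) stop("PCA needs >= 2 samples")
  keep <- rowSums(is.na(mat)) == 0L
  if (any(!keep))
    message(sum(!keep), " gene(s) with missing values dropped before PCA")
  x <- mat[keep, , drop = FALSE]
  if (nrow(x) < 2L) stop("fewer than 2 genes without missing values")
  if (log_transform) x <- log2(x + 1)
  p <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  vf <- p$sdev^2 / max(sum(p$sdev^2), .Machine$double.eps)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       variance_fraction = vf[seq_len(k)], n_genes_used = nrow(x))
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Logistic PCA of a binary expression matrix
#'
#' Rank-constrained factorization of the Bernoulli natural-parameter
#' matrix `Theta = mu + A B'` (per-gene offset `mu`, rank-`rank` factors),
#' fitted by majorization-minimization: the logistic log-likelihood is
#' majorized by a quadratic with curvature 1/4, giving working values
#' `Z = Theta + 4 (Y - sigmoid(Theta))` (left at `Theta` for missing
#' entries, which are excluded from the objective), followed by exact
#' alternating minimization of the majorizer (offset update, then
#' truncated SVD).  The observed-data log-likelihood is non-decreasing at
#' every iteration.
#'
#' @param bin Genes x samples matrix of 0/1/NA.
#' @param rank Number of components; must be < `min(dim(bin))`.
#' @param max_iter Iteration cap.
#' @param tol Relative objective-change convergence tolerance.
#' @return List with `scores` (samples x rank), `loadings` (genes x rank),
#'   `mu`, `objective` (per-iteration log-likelihood trace), `converged`,
#'   `iterations`.
#' @export
logistic_pca <- function(bin, rank = 2L, max_iter = 500L, tol = 1e-6) {
  Y <- as.matrix(bin)
  v <- Y[!is.na(Y)]
  if (length(v) && !all(v %in% c(0, 1))) stop("'bin' must be 0/1/NA")
  if (rank >= min(dim(Y)))
    stop("'rank' must be smaller than both dimensions of 'bin'")
  obs <- !is.na(Y)
  p_hat <- (rowSums(Y == 1L, na.rm = TRUE) + 0.5) / (rowSums(obs) + 1)
  mu <- stats::qlogis(p_hat)
  L <- matrix(0, nrow(Y), ncol(Y))          # low-rank part A B'
  theta <- mu + L
  loglik <- function(th)
    sum((Y * th - log1pexp(th))[obs])
  objective <- loglik(theta)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Z <- theta
    Z[obs] <- theta[obs] + 4 * (Y[obs] - stats::plogis(theta[obs]))
    mu <- rowMeans(Z - L)                   # offset given factors
    s <- svd(Z - mu, nu = rank, nv = rank)  # factors given offset
    d <- s$d[seq_len(rank)]
    L <- s$u %*% (d * t(s$v))
    theta <- mu + L
    obj <- loglik(theta)
    objective <- c(objective, obj)
    prev <- objective[it]
    if (abs(obj - prev) < tol * (abs(prev) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  scores <- s$v %*% diag(d, rank)
  rownames(scores) <- colnames(Y)
  loadings <- s$u
  rownames(loadings) <- rownames(Y)
  list(scores = scores, loadings = loadings, mu = mu,
       objective = objective, converged = converged, iterations = it)
}
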