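#' Hamming distance matrix between taxa
#'
#' Pairwise proportion of differing states over the characters observed in
#' both taxa (missing entries pairwise-excluded).  Used for the
#' neighbour-joining starting tree of [search_topology()].
#'
#' @param chars Taxa x characters 0/1/NA matrix.
#' @return A `dist` object over the taxa.
#' @export
hamming_distances <- function(chars) {
  check_char_matrix(chars)
  nt <- nrow(chars)
  d <- matrix(0, nt, nt, dimnames = list(rownames(chars), rownames(chars)))
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    ok <- !is.na(chars[i, ]) & !is.na(chars[j, ])
    d[i, j] <- d[j, i] <-
      if (any(ok)) mean(chars[i, ok] != chars[j, ok]) else NA_real_
  }
  if (anyNA(d)) d[is.na(d)] <- max(d, na.rm = TRUE)
  stats::as.dist(d)
}

# NNI neighbour topologies; phangorn compresses multiPhylo tip labels into
# a shared attribute, so restore them per tree.
nni_neighbours <- function(tree) {
  tree$node.label <- NULL
  nbs <- phangorn::nni(tree)
  lab <- attr(nbs, "TipLabel")
  lapply(nbs, function(t) {
    if (is.null(t$tip.label) && !is.null(lab)) t$tip.label <- lab
    t
  })
}

# Score a topology: fixed model, branch lengths optimized by short sweeps.
score_topology <- function(topo, model, cp, n_sweeps = 2L, x_tol = 1e-3) {
  if (is.null(topo$edge.length) || anyNA(topo$edge.length))
    topo$edge.length <- rep(0.1, nrow(topo$edge))
  topo$edge.length <- pmin(pmax(topo$edge.length, 1e-8), .fit_bounds$blen[2])
  ob <- NULL
  for (s in seq_len(n_sweeps)) {
    ob <- optimize_branch_lengths(topo, model, cp, x_tol = x_tol)
    topo <- ob$tree
  }
  list(tree = topo, loglik = ob$loglik)
}

#' Maximum-likelihood topology search by NNI hill climbing
#'
#' Starts from a neighbour-joining tree on Hamming distances (plus
#' `n_starts - 1` random topologies) and hill-climbs through
#' nearest-neighbour-interchange rearrangements, accepting the best
#' improving neighbour until the tree is a local optimum: its
#' log-likelihood is at least that of every NNI neighbour.  Model
#' parameters are estimated once on the starting tree and held fixed while
#' topologies are compared; the returned tree is refit in full.
#'
#' With fewer than 4 taxa there is a single unrooted topology, which is
#' returned without search.
#'
#' @inheritParams fit_model
#' @param n_starts Number of starting trees (1 = NJ start only).
#' @param seed Optional integer seed; the search is deterministic given it.
#' @param refit Refit model and branch lengths fully on the final topology.
#' @return The best `phylo` tree found (unrooted), with attributes
#'   `"loglik"`, `"model"` and (when `refit = TRUE`) `"fit"`.
#' @export
search_topology <- function(chars, rate_model = "plain", n_starts = 1L,
                            seed = NULL, refit = TRUE) {
  check_char_matrix(chars)
  if (!is.null(seed)) set.seed(seed)
  nt <- nrow(chars)
  cp <- compress_patterns(chars)
  nj <- ape::unroot(ape::nj(hamming_distances(chars)))
  nj$edge.length[nj$edge.length <= 0] <- 1e-4
  if (nt < 4L) {
    # single unrooted topology: no search, just branch lengths
    p1 <- min(max(mean(chars == 1, na.rm = TRUE), 1e-4), 1 - 1e-4)
    model <- two_state_model(p1, rate_model)
    sc <- score_topology(nj, model, cp, n_sweeps = 3L, x_tol = 1e-6)
    out <- sc$tree
    attr(out, "loglik") <- sc$loglik
    attr(out, "model") <- model
    return(out)
  }
  starts <- list(nj)
  if (n_starts > 1L)
    starts <- c(starts, replicate(n_starts - 1L, {
      tr <- ape::rtopology(nt, rooted = FALSE, tip.label = rownames(chars))
      tr$edge.length <- rep(0.1, nrow(tr$edge))
      tr
    }, simplify = FALSE))

  base_fit <- fit_model(nj, chars, rate_model, tol = 1e-4, max_sweeps = 5L)
  model <- base_fit$model

  best <- NULL
  for (start in starts) {
    cur <- score_topology(start, model, cp)
    repeat {
      nbs <- nni_neighbours(cur$tree)
      sc <- lapply(nbs, score_topology, model = model, cp = cp)
      ll <- vapply(sc, `[[`, numeric(1), "loglik")
      if (max(ll) > cur$loglik + 1e-8) cur <- sc[[which.max(ll)]]
      else break
    }
    if (is.null(best) || cur$loglik > best$loglik) best <- cur
  }
  out <- best$tree
  attr(out, "loglik") <- best$loglik
  attr(out, "model") <- model
  if (refit) {
    fit <- fit_model(out, chars, rate_model)
    out <- fit$tree
    attr(out, "loglik") <- fit$loglik
    attr(out, "model") <- fit$model
    attr(out, "fit") <- fit
  }
  out
}

#' Nonparametric bootstrap support for the ML tree
#'
#' Resamples characters with replacement, re-searches the topology on each
#' replicate, and reports for every internal branch of the ML tree the
#' percentage of replicates whose tree contains the same bipartition.
#'
#' @inheritParams search_topology
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param tree Optional ML tree; found by [search_topology()] when `NULL`.
#' @return The ML `phylo` tree with bootstrap percentages as `node.label`
#'   and the replicate trees attached as attribute `"boot_trees"`.
#' @export
bootstrap_support <- function(chars, rate_model = "plain", n_reps = 100L,
                              seed = NULL, tree = NULL) {
  check_char_matrix(chars)
  if (n_reps < 1L) stop("'n_reps' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree))
    tree <- search_topology(chars, rate_model, refit = FALSE)
  boot <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    idx <- sample.int(ncol(chars), replace = TRUE)
    boot[[b]] <- search_topology(chars[, idx, drop = FALSE], rate_model,
                                 refit = FALSE)
  }
  class(boot) <- "multiPhylo"
  counts <- ape::prop.clades(tree, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- formatC(100 * counts / n_reps, format = "g")
  attr(tree, "boot_trees") <- boot
  tree
}
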