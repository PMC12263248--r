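#' Simulate binary characters on a tree
#'
#' Evolves independent two-state characters along a tree under a
#' [two_state_model()], using the exact closed-form transition
#' probabilities of [transition_matrix()].  Each character is first
#' assigned a rate category (including the rate-0 invariant class when the
#' model has `+I`), the root state is drawn from the stationary
#' frequencies, and states are propagated root-to-tip.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param model A [two_state_model()].
#' @param n_sites Number of characters; 0 gives an empty matrix.
#' @param seed Optional integer seed.
#' @return Taxa x characters integer matrix of 0/1 with taxon rownames.
#' @export
simulate_binary_characters <- function(tree, model, n_sites, seed = NULL) {
  stopifnot(inherits(model, "two_state_model"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!is.null(seed)) set.seed(seed)
  n_sites <- as.integer(n_sites)
  nt <- length(tree$tip.label)
  out <- matrix(integer(0), nt, n_sites,
                dimnames = list(tree$tip.label, NULL))
  if (n_sites == 0L) return(out)
  tree <- stats::reorder(tree, "postorder")
  cats <- rate_categories(model)
  rate <- cats$rate[sample.int(nrow(cats), n_sites, replace = TRUE,
                               prob = cats$weight)]
  pi1 <- model$pi1
  s <- 1 / (2 * (1 - pi1) * pi1)
  nn <- tree$Nnode
  state <- matrix(NA_integer_, nt + nn, n_sites)
  root <- nt + 1L
  state[root, ] <- as.integer(stats::runif(n_sites) < pi1)
  e <- tree$edge
  for (k in rev(seq_len(nrow(e)))) {   # preorder: parents before children
    par <- e[k, 1L]; ch <- e[k, 2L]
    decay <- exp(-s * rate * tree$edge.length[k])
    p1 <- pi1 * (1 - decay) + state[par, ] * decay
    state[ch, ] <- as.integer(stats::runif(n_sites) < p1)
  }
  out <- state[seq_len(nt), , drop = FALSE]
  rownames(out) <- tree$tip.label
  colnames(out) <- sprintf("c%05d", seq_len(n_sites))
  out
}

#' Plant convergent expression in a set of taxa
#'
#' Overwrites a fraction of characters with a shared derived state in the
#' named taxa (and the opposite state elsewhere), emulating the convergent
#' late-stage expression programme of placental lineages that pulls
#' expression phylogenies away from the species tree.
#'
#' @param chars Taxa x characters 0/1 matrix.
#' @param taxa Taxa receiving the convergent state.
#' @param fraction Fraction of characters to overwrite.
#' @param state Derived state planted in `taxa` (default 1).
#' @param seed Optional integer seed for choosing the characters.
#' @return The modified matrix, with chosen columns in attribute
#'   `"convergent_sites"`.
#' @export
plant_convergence <- function(chars, taxa, fraction, state = 1L,
                              seed = NULL) {
  check_char_matrix(chars)
  if (!all(taxa %in% rownames(chars))) stop("unknown taxa")
  if (fraction < 0 || fraction > 1) stop("'fraction' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  k <- floor(fraction * ncol(chars))
  sites <- sort(sample.int(ncol(chars), k))
  chars[taxa, sites] <- as.integer(state)
  chars[setdiff(rownames(chars), taxa), sites] <- 1L - as.integer(state)
  attr(chars, "convergent_sites") <- sites
  chars
}
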