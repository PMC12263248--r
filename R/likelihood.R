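#' @importFrom ape reorder.phylo
NULL

# ---- internal machinery -----------------------------------------------------
#
# Character matrices are taxa x characters, entries 0/1/NA (NA = missing).
# Likelihood work is done on compressed site patterns: with <= 6 taxa there
# are at most 3^6 distinct columns, so pattern compression makes repeated
# likelihood evaluation (branch-length sweeps, tree search, bootstrap) cheap
# regardless of the number of characters.

check_char_matrix <- function(chars) {
  if (!is.matrix(chars)) stop("'chars' must be a matrix (taxa x characters)")
  if (is.null(rownames(chars))) stop("'chars' must have taxon rownames")
  v <- chars[!is.na(chars)]
  if (length(v) && !all(v %in% c(0, 1)))
    stop("character states must be 0, 1 or NA")
  invisible(chars)
}

compress_patterns <- function(chars) {
  check_char_matrix(chars)
  if (ncol(chars) == 0L)
    return(list(pat = chars, weight = numeric(0), index = integer(0)))
  key <- apply(chars, 2L, function(x) {
    x[is.na(x)] <- 9L
    paste(x, collapse = "")
  })
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(pat = chars[, u, drop = FALSE],
       weight = as.numeric(tabulate(idx, nbins = sum(u))),
       index = idx)
}

# Tip conditional likelihoods: list over taxa of 2 x npat matrices.
tip_likelihoods <- function(pat) {
  lapply(seq_len(nrow(pat)), function(i) {
    x <- pat[i, ]
    L <- matrix(1, 2L, length(x))
    L[1L, !is.na(x) & x == 1] <- 0
    L[2L, !is.na(x) & x == 0] <- 0
    L
  })
}

# Postorder pass for one rate category. Returns list of 2 x npat partial
# likelihood matrices for every node (tips + internal), plus the root index.
down_pass <- function(tree, model, rate, tipL, npat) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  down <- vector("list", nt + nn)
  down[seq_len(nt)] <- tipL
  e <- tree$edge
  el <- tree$edge.length
  root <- nt + 1L
  pi1 <- model$pi1
  for (k in seq_len(nt + nn)[-seq_len(nt)]) down[[k]] <- matrix(1, 2L, npat)
  for (k in seq_len(nrow(e))) {        # edges already in postorder
    par <- e[k, 1L]; ch <- e[k, 2L]
    down[[par]] <- down[[par]] * (trans2(pi1, el[k], rate) %*% down[[ch]])
  }
  list(down = down, root = root)
}

# Per-pattern site likelihoods, mixture-weighted over rate categories.
# Pattern rows are aligned to the tree's tip numbering by taxon name, so
# trees with permuted tip orderings (NNI neighbours, random starts) score
# correctly.
pattern_likelihoods <- function(tree, model, pat) {
  tree <- stats::reorder(tree, "postorder")
  if (!is.null(rownames(pat)) &&
      !identical(rownames(pat), tree$tip.label)) {
    if (!setequal(rownames(pat), tree$tip.label))
      stop("tree tip labels and character-matrix taxa do not match")
    pat <- pat[tree$tip.label, , drop = FALSE]
  }
  npat <- ncol(pat)
  tipL <- tip_likelihoods(pat)
  cats <- cat_list(model)
  pivec <- c(1 - model$pi1, model$pi1)
  lik <- numeric(npat)
  for (j in seq_along(cats$rate)) {
    dp <- down_pass(tree, model, cats$rate[j], tipL, npat)
    lik <- lik + cats$weight[j] * colSums(pivec * dp$down[[dp$root]])
  }
  lik
}

match_taxa <- function(tree, chars) {
  check_char_matrix(chars)
  if (!setequal(tree$tip.label, rownames(chars)))
    stop("tree tip labels and character-matrix taxa do not match")
  chars[tree$tip.label, , drop = FALSE]
}

# ---- public surface ---------------------------------------------------------

#' Log-likelihood of binary characters on a tree
#'
#' Felsenstein pruning over the rate mixture of a [two_state_model()].  The
#' invariant class (when present) is the rate-0 mixture category, so its
#' likelihood contribution reduces automatically to
#' `pi_s * [all observed states equal s]`.  Missing states enter as partial
#' likelihood `(1, 1)`; a character that is missing in every taxon therefore
#' contributes 0 to the log-likelihood (a message reports how many).
#'
#' @param tree A `phylo` tree (rooted or unrooted) with branch lengths; tip
#'   labels must match `rownames(chars)`.
#' @param model A [two_state_model()].
#' @param chars Taxa x characters matrix with entries 0/1/NA.
#' @return The total log-likelihood (sum over characters), with attribute
#'   `"site_loglik"` holding the per-character values.
#' @export
log_likelihood <- function(tree, model, chars) {
  chars <- match_taxa(tree, chars)
  if (ncol(chars) == 0L) {
    out <- 0
    attr(out, "site_loglik") <- numeric(0)
    return(out)
  }
  all_missing <- colSums(!is.na(chars)) == 0L
  if (any(all_missing))
    message(sum(all_missing),
            " character(s) missing in all taxa contribute 0 to lnL")
  cp <- compress_patterns(chars)
  lik <- pattern_likelihoods(tree, model, cp$pat)
  site_ll <- log(lik)[cp$index]
  out <- sum(site_ll * 1)
  attr(out, "site_loglik") <- site_ll
  out
}

# Fast path used by optimizers: lnL from a precompressed pattern list.
pattern_loglik <- function(tree, model, cp) {
  sum(cp$weight * log(pattern_likelihoods(tree, model, cp$pat)))
}
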