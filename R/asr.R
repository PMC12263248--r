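#' Marginal ancestral state reconstruction of binary expression characters
#'
#' For every internal node and character, computes the posterior probability
#' of each state by the standard up-down (inside-outside) algorithm: the
#' posterior is proportional to the mixture-weighted product of the
#' downward partial likelihood (the node's subtree) and the outside
#' likelihood (the rest of the tree, stationary prior folded in at the
#' root).  A state is called when its posterior reaches `min_posterior`
#' (inclusive floor, default 0.50); otherwise the node-character is
#' `"ambiguous"`.  Missing leaf states contribute partial likelihood (1, 1).
#'
#' @param tree Fixed `phylo` tree (typically the species phylogeny) with
#'   branch lengths.
#' @param model A fitted [two_state_model()].
#' @param chars Taxa x characters 0/1/NA matrix.
#' @param min_posterior Posterior floor for calling a state; must be >=
#'   0.5 or calls would not be unique.  Exact ties at 0.5/0.5 are called
#'   state 1.
#' @return Object of class `asr_reconstruction`: `posterior1` (internal
#'   nodes x characters matrix of P(state 1)), `calls` (same shape,
#'   `"0"`/`"1"`/`"ambiguous"`), `nodes` (ape node numbers), `node_labels`,
#'   `min_posterior`, `tree`, `model`.
#' @export
ancestral_reconstruction <- function(tree, model, chars,
                                     min_posterior = 0.50) {
  if (min_posterior < 0.5)
    stop("'min_posterior' must be >= 0.5: lower floors would allow ",
         "non-unique state calls")
  chars <- match_taxa(tree, chars)
  tree <- stats::reorder(tree, "postorder")
  cp <- compress_patterns(chars)
  npat <- ncol(cp$pat)
  tipL <- tip_likelihoods(cp$pat)
  cats <- rate_categories(model)
  pivec <- c(1 - model$pi1, model$pi1)
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  e <- tree$edge
  el <- tree$edge.length
  root <- nt + 1L
  edges_of <- split(seq_len(nrow(e)), e[, 1L])

  joint <- array(0, dim = c(2L, npat, nn))
  for (j in seq_len(nrow(cats))) {
    w <- cats$weight[j]
    r <- cats$rate[j]
    P <- lapply(el, function(b) transition_matrix(model, b, r))
    down <- vector("list", nt + nn)
    down[seq_len(nt)] <- tipL
    for (k in (nt + 1L):(nt + nn)) down[[k]] <- matrix(1, 2L, npat)
    M <- vector("list", nrow(e))            # per-edge child contribution
    for (k in seq_len(nrow(e))) {
      M[[k]] <- P[[k]] %*% down[[e[k, 2L]]]
      down[[e[k, 1L]]] <- down[[e[k, 1L]]] * M[[k]]
    }
    G <- vector("list", nt + nn)            # outside likelihoods
    G[[root]] <- matrix(pivec, 2L, npat)
    for (k in rev(seq_len(nrow(e)))) {      # preorder
      par <- e[k, 1L]; ch <- e[k, 2L]
      sib <- G[[par]]
      for (j2 in edges_of[[as.character(par)]])
        if (j2 != k) sib <- sib * M[[j2]]
      G[[ch]] <- crossprod(P[[k]], sib)     # t(P) %*% sib
    }
    for (v in (nt + 1L):(nt + nn))
      joint[, , v - nt] <- joint[, , v - nt] + w * G[[v]] * down[[v]]
  }

  post1_pat <- matrix(NA_real_, nn, npat)
  for (v in seq_len(nn))
    post1_pat[v, ] <- joint[2L, , v] / (joint[1L, , v] + joint[2L, , v])
  post1 <- post1_pat[, cp$index, drop = FALSE]
  colnames(post1) <- colnames(chars)
  labs <- if (!is.null(tree$node.label) && all(nzchar(tree$node.label)))
    tree$node.label else paste0("node", (nt + 1L):(nt + nn))
  rownames(post1) <- labs

  calls <- matrix("ambiguous", nn, ncol(post1), dimnames = dimnames(post1))
  calls[post1 >= min_posterior] <- "1"
  calls[(1 - post1) >= min_posterior & post1 < 0.5] <- "0"
  structure(list(posterior1 = post1, calls = calls,
                 nodes = (nt + 1L):(nt + nn), node_labels = labs,
                 min_posterior = min_posterior, tree = tree, model = model),
            class = "asr_reconstruction")
}

#' @export
print.asr_reconstruction <- function(x, ...) {
  cat("Marginal ancestral state reconstruction\n")
  cat(sprintf("  %d internal node(s) x %d character(s); posterior floor %.2f\n",
              nrow(x$posterior1), ncol(x$posterior1), x$min_posterior))
  amb <- mean(x$calls == "ambiguous")
  cat(sprintf("  ambiguous calls: %.1f%%\n", 100 * amb))
  invisible(x)
}

#' @export
as.data.frame.asr_reconstruction <- function(x, ...) {
  nchar_ <- ncol(x$posterior1)
  data.frame(node = rep(x$node_labels, nchar_),
             character = rep(colnames(x$posterior1) %||%
                               as.character(seq_len(nchar_)),
                             each = nrow(x$posterior1)),
             p0 = as.vector(1 - x$posterior1),
             p1 = as.vector(x$posterior1),
             call = as.vector(x$calls),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Internal node joining a species pair
#'
#' Convenience lookup of the most recent common ancestor node of a
#' placental/non-placental species pair on the species tree.
#'
#' @param tree A `phylo` tree.
#' @param species Character vector of two tip labels.
#' @return The ape node number of the MRCA.
#' @export
pair_ancestor_node <- function(tree, species) {
  if (length(species) != 2L || !all(species %in% tree$tip.label))
    stop("'species' must name two tips of the tree")
  ape::getMRCA(tree, species)
}

#' Ancestral expression states at a pair-ancestor node
#'
#' Extracts the called binary expression state of every gene (character) at
#' one internal node, typically the common ancestor of a
#' placental/non-placental species pair.  Ambiguous calls propagate: those
#' genes are reported as `"ambiguous"` and listed in the `"excluded"`
#' attribute so downstream filters can drop them.
#'
#' @param asr An [ancestral_reconstruction()] result.
#' @param node Internal node: an ape node number or a node label.
#' @return Named character vector over genes with values `"0"`, `"1"` or
#'   `"ambiguous"`; attribute `"excluded"` lists the ambiguous gene ids.
#' @export
ancestor_expression_states <- function(asr, node) {
  stopifnot(inherits(asr, "asr_reconstruction"))
  i <- if (is.numeric(node)) match(as.integer(node), asr$nodes)
       else match(node, asr$node_labels)
  if (is.na(i)) stop("node ", node, " is not an internal node of the tree")
  st <- asr$calls[i, ]
  names(st) <- colnames(asr$calls)
  excl <- names(st)[st == "ambiguous"]
  if (length(excl))
    message(length(excl),
            " gene(s) with ambiguous ancestral state excluded downstream")
  attr(st, "excluded") <- excl
  st
}
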