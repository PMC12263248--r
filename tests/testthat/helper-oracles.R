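# Independent oracles: brute-force enumeration over internal-node state
# assignments. Deliberately naive (no pruning, no pattern compression) so
# they share no code path with the implementation they check.

# Sum over all internal-node assignments of pi(root) * prod P(edge), mixed
# over rate categories. Missing leaf states are marginalized by summing the
# leaf over both states.
brute_site_joint <- function(tree, model, states, focal_node = NULL) {
  tree <- stats::reorder(tree, "postorder")
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  cats <- rate_categories(model)
  pivec <- c(1 - model$pi1, model$pi1)
  miss <- which(is.na(states))
  joint <- c(0, 0)   # by focal-node state (or total in [1] if no focal)
  for (j in seq_len(nrow(cats))) {
    Ps <- lapply(tree$edge.length, function(b)
      transition_matrix(model, b, cats$rate[j]))
    n_free <- nn + length(miss)
    for (a in 0:(2^n_free - 1L)) {
      bits <- as.integer(intToBits(a))[seq_len(max(n_free, 1L))]
      st <- rep(NA_integer_, nt + nn)
      st[seq_len(nt)] <- states
      st[nt + seq_len(nn)] <- bits[seq_len(nn)]
      if (length(miss)) st[miss] <- bits[nn + seq_along(miss)]
      pr <- pivec[st[nt + 1L] + 1L]
      for (k in seq_len(nrow(tree$edge)))
        pr <- pr * Ps[[k]][st[tree$edge[k, 1L]] + 1L,
                           st[tree$edge[k, 2L]] + 1L]
      if (is.null(focal_node)) joint[1] <- joint[1] + cats$weight[j] * pr
      else joint[st[focal_node] + 1L] <-
          joint[st[focal_node] + 1L] + cats$weight[j] * pr
    }
  }
  joint
}

brute_loglik <- function(tree, model, chars) {
  chars <- chars[tree$tip.label, , drop = FALSE]
  sum(vapply(seq_len(ncol(chars)), function(s)
    log(brute_site_joint(tree, model, chars[, s])[1]), numeric(1)))
}

brute_posterior1 <- function(tree, model, chars, node) {
  chars <- chars[tree$tip.label, , drop = FALSE]
  vapply(seq_len(ncol(chars)), function(s) {
    j <- brute_site_joint(tree, model, chars[, s], focal_node = node)
    j[2] / sum(j)
  }, numeric(1))
}

# Shared fixtures
five_taxon_tree <- function()
  ape::read.tree(text = "((A:0.3,B:0.2):0.15,(C:0.25,D:0.1):0.2,E:0.4);")

six_taxon_tree <- function()
  ape::read.tree(
    text = "(((A:0.2,B:0.3):0.1,C:0.4):0.15,(D:0.2,E:0.25):0.2,F:0.5);")

# long stage-mean table from named per-(species.stage) vectors
means_table <- function(...) {
  args <- list(...)
  out <- NULL
  for (key in names(args)) {
    sp_st <- strsplit(key, "\\.")[[1]]
    v <- args[[key]]
    out <- rbind(out, data.frame(gene = names(v), species = sp_st[1],
                                 stage = sp_st[2], mean_fpkm = unname(v)))
  }
  out
}

tiny_sim_config <- function(...) {
  args <- list(n_genes = 400L, n_neoteny = 10L, n_derived_up = 12L,
               n_derived_down = 12L, n_egg_provisioning = 20L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
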