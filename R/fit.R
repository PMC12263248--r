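# Parameter bounds used by every fit: pi1 in [1e-4, 1-1e-4], alpha in
# [0.05, 100], p_inv in [0, 0.99], branch lengths in [0, 10]. Free-rate R2 is
# parameterized by (v1, r1) with r2 = (1 - v1*r1)/(1 - v1), which keeps the
# weighted mean rate at 1 and orders r1 < 1 < r2 (no label switching).
.fit_bounds <- list(pi1 = c(1e-4, 1 - 1e-4), alpha = c(0.05, 100),
                    p_inv = c(0, 0.99), blen = c(0, 10),
                    v1 = c(1e-3, 1 - 1e-3), r1 = c(1e-4, 1 - 1e-4))

set_model_par <- function(model, name, value) {
  if (name == "pi1") model$pi1 <- value
  else if (name == "p_inv") model$p_inv <- value
  else if (name == "alpha") model$gamma_shape <- value
  else if (name == "v1") {
    v1 <- value; r1 <- model$freerate$rates[1]
    model$freerate <- list(rates = c(r1, (1 - v1 * r1) / (1 - v1)),
                           weights = c(v1, 1 - v1))
  } else if (name == "r1") {
    v1 <- model$freerate$weights[1]; r1 <- value
    model$freerate <- list(rates = c(r1, (1 - v1 * r1) / (1 - v1)),
                           weights = c(v1, 1 - v1))
  } else stop("unknown parameter: ", name)
  model
}

get_model_par <- function(model, name) {
  switch(name,
         pi1 = model$pi1, p_inv = model$p_inv, alpha = model$gamma_shape,
         v1 = model$freerate$weights[1], r1 = model$freerate$rates[1],
         stop("unknown parameter: ", name))
}

free_model_pars <- function(rate_model) {
  rm <- normalize_rate_model(rate_model)
  pars <- "pi1"
  if (grepl("I", rm, fixed = TRUE)) pars <- c(pars, "p_inv")
  if (grepl("G4", rm, fixed = TRUE)) pars <- c(pars, "alpha")
  if (grepl("R2", rm, fixed = TRUE)) pars <- c(pars, "v1", "r1")
  pars
}

# One round-robin sweep over branch lengths (preorder: root-to-tip edge
# order) by bounded scalar optimization. Returns tree and lnL.
optimize_branch_lengths <- function(tree, model, cp, x_tol = 1e-6) {
  tree <- stats::reorder(tree, "postorder")
  ord <- rev(seq_len(nrow(tree$edge)))   # reverse postorder = preorder
  for (k in ord) {
    f <- function(b) {
      tree$edge.length[k] <- b
      pattern_loglik(tree, model, cp)
    }
    opt <- stats::optimize(f, .fit_bounds$blen, maximum = TRUE, tol = x_tol)
    cur <- pattern_loglik(tree, model, cp)
    if (opt$objective > cur) tree$edge.length[k] <- opt$maximum
  }
  list(tree = tree, loglik = pattern_loglik(tree, model, cp))
}

#' Fit the two-state model (and branch lengths) by maximum likelihood
#'
#' Bounded coordinate-wise optimization: round-robin sweeps over branch
#' lengths (preorder), the stationary frequency `pi1` (frequencies
#' optimized, "+FO"), and the rate-mixture parameters of the chosen model,
#' repeated until the log-likelihood improves by less than `tol` across a
#' full sweep.
#'
#' @param tree Starting `phylo` tree (>= 4 taxa); missing branch lengths are
#'   initialized at 0.1.
#' @param chars Taxa x characters 0/1/NA matrix.
#' @param rate_model Rate-model label, see [two_state_model()].
#' @param optimize_blen Optimize branch lengths (default `TRUE`); set
#'   `FALSE` to fit model parameters on a fixed tree.
#' @param tol Convergence tolerance on the log-likelihood per sweep.
#' @param max_sweeps Upper bound on coordinate sweeps.
#' @param init Optional [two_state_model()] (same rate model) used as the
#'   starting point instead of data-driven initialization.
#' @return An object of class `twostate_fit`: list with elements `tree`
#'   (optimized branch lengths), `model` (fitted [two_state_model()]),
#'   `loglik`, `k` (free parameter count, branch lengths included),
#'   `n_char`, `converged`, `sweeps`.
#' @examples
#' tr <- ape::read.tree(text = "((A:.2,B:.2):.2,(C:.2,D:.2):.2,E:.4);")
#' m <- two_state_model(pi1 = 0.7)
#' x <- simulate_binary_characters(tr, m, n_sites = 300, seed = 1)
#' fit <- fit_model(tr, x, "plain")
#' fit$model$pi1
#' @export
fit_model <- function(tree, chars, rate_model = "plain",
                      optimize_blen = TRUE, tol = 1e-6, max_sweeps = 60L,
                      init = NULL) {
  chars <- match_taxa(tree, chars)
  if (length(tree$tip.label) < 4L) stop("fit_model requires >= 4 taxa")
  rm <- normalize_rate_model(rate_model)
  cp <- compress_patterns(chars)

  obs <- cp$pat
  variable <- apply(obs, 2L, function(x) {
    x <- x[!is.na(x)]
    length(unique(x)) > 1L
  })
  if (!any(variable & cp$weight > 0) && grepl("I", rm, fixed = TRUE))
    warning("all characters constant: p_inv is unidentifiable; ",
            "fit will sit on a boundary")

  p1 <- mean(chars == 1, na.rm = TRUE)
  p1 <- min(max(p1, .fit_bounds$pi1[1]), .fit_bounds$pi1[2])
  const_frac <- sum(cp$weight[!variable]) / sum(cp$weight)
  model <- if (!is.null(init)) {
    stopifnot(inherits(init, "two_state_model"),
              identical(init$rate_model, rm))
    init
  } else two_state_model(
    pi1 = p1, rate_model = rm,
    p_inv = if (grepl("I", rm, fixed = TRUE)) min(const_frac / 2, 0.5) else 0,
    gamma_shape = 1,
    freerate = if (grepl("R2", rm, fixed = TRUE))
      list(rates = c(0.5, 1.5), weights = c(0.5, 0.5)) else NULL)

  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length <- pmin(pmax(tree$edge.length, 1e-8), .fit_bounds$blen[2])
  tree <- stats::reorder(tree, "postorder")

  pars <- free_model_pars(rm)
  ll <- pattern_loglik(tree, model, cp)
  ll0 <- ll
  converged <- FALSE
  sweeps <- 0L
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    prev <- ll
    if (optimize_blen) {
      ob <- optimize_branch_lengths(tree, model, cp)
      tree <- ob$tree
      ll <- ob$loglik
    }
    # model parameters jointly (bounded quasi-Newton): the invariant
    # proportion, gamma shape and branch lengths are strongly correlated,
    # so 1-D coordinate steps alone zigzag
    cur <- vapply(pars, get_model_par, numeric(1), model = model)
    lo <- vapply(pars, function(p) .fit_bounds[[p]][1], numeric(1))
    hi <- vapply(pars, function(p) .fit_bounds[[p]][2], numeric(1))
    negll <- function(v) {
      m <- model
      for (i in seq_along(pars)) m <- set_model_par(m, pars[i], v[i])
      -pattern_loglik(tree, m, cp)
    }
    opt <- try(stats::optim(pmin(pmax(cur, lo), hi), negll,
                            method = "L-BFGS-B", lower = lo, upper = hi),
               silent = TRUE)
    if (!inherits(opt, "try-error") && -opt$value > ll) {
      for (i in seq_along(pars))
        model <- set_model_par(model, pars[i], unname(opt$par[i]))
      ll <- -opt$value
    }
    if (ll - prev < tol) {
      converged <- TRUE
      break
    }
  }
  if (ll < ll0) stop("internal error: optimization decreased the likelihood")
  structure(list(tree = tree, model = model, loglik = ll,
                 k = n_model_parameters(rm) + nrow(tree$edge),
                 n_char = ncol(chars), converged = converged,
                 sweeps = sweeps, rate_model = rm),
            class = "twostate_fit")
}

#' @export
print.twostate_fit <- function(x, ...) {
  cat(sprintf("Two-state phylogenetic fit (%s)\n", x$rate_model))
  cat(sprintf("  lnL = %.4f over %d characters (%d free parameters)\n",
              x$loglik, x$n_char, x$k))
  cat(sprintf("  converged: %s after %d sweep(s)\n", x$converged, x$sweeps))
  print(x$model)
  invisible(x)
}

#' @export
logLik.twostate_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_char,
            class = "logLik")
}

#' @export
coef.twostate_fit <- function(object, ...) {
  m <- object$model
  out <- c(pi1 = m$pi1)
  if (grepl("I", m$rate_model, fixed = TRUE)) out <- c(out, p_inv = m$p_inv)
  if (grepl("G4", m$rate_model, fixed = TRUE))
    out <- c(out, gamma_shape = m$gamma_shape)
  if (!is.null(m$freerate))
    out <- c(out, r1 = m$freerate$rates[1], r2 = m$freerate$rates[2],
             w1 = m$freerate$weights[1], w2 = m$freerate$weights[2])
  out
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n - k - 1)`, with `n` the number of
#' characters and `k` the number of free parameters (branch lengths
#' included).
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size (number of characters).
#' @return The AICc value; `NA` (with a warning) when `n <= k + 1`.
#' @examples
#' aicc(-5, k = 2, n = 10)  # 14 + 12/7
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) {
    warning("AICc undefined: n <= k + 1")
    return(NA_real_)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate rate models by AICc
#'
#' Fits each candidate rate model on the same tree and characters and ranks
#' by small-sample corrected AICc; ties are broken in favour of fewer
#' parameters.  Candidates with `n <= k + 1` are marked inadmissible and
#' sorted last.
#'
#' @inheritParams fit_model
#' @param candidates Character vector of rate-model labels.
#' @return A data frame sorted ascending by AICc with columns `model`,
#'   `loglik`, `k`, `AICc`, `admissible`; the fitted objects are attached as
#'   attribute `"fits"` (named by model label).
#' @export
select_model <- function(tree, chars, candidates = c("plain", "I", "G4",
                                                     "I+G4", "R2", "I+R2"),
                         ...) {
  fits <- lapply(candidates, function(m) fit_model(tree, chars, m, ...))
  names(fits) <- candidates
  n <- ncol(match_taxa(tree, chars))
  k <- vapply(fits, `[[`, numeric(1), "k")
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  adm <- n > k + 1
  ic <- rep(NA_real_, length(fits))
  if (any(adm))
    ic[adm] <- mapply(aicc, ll[adm], k[adm], MoreArgs = list(n = n))
  out <- data.frame(model = candidates, loglik = ll, k = k, AICc = ic,
                    admissible = adm, row.names = NULL)
  out <- out[order(!out$admissible, out$AICc, out$k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
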