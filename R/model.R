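#' Two-state reversible substitution model
#'
#' Constructs the binary-character substitution model used throughout the
#' package: a general time-reversible model restricted to two states
#' ("expressed" = 1, "not expressed" = 0).  With two states the
#' exchangeability matrix collapses to a single rate, so the model is fully
#' described by the stationary frequency of state 1 plus an optional
#' among-character rate mixture: an invariant class (`+I`), four discrete
#' gamma categories (`+G4`), two free-rate categories (`+R2`), or their
#' combinations.
#'
#' The rate matrix has `q01 = pi1 * s` and `q10 = pi0 * s` with `s` chosen so
#' that the expected number of changes per unit branch length is 1
#' (`2 * pi0 * pi1 * s = 1`).  Rates of the non-invariant mixture categories
#' are normalized to mean 1, so branch lengths are expected changes per
#' variable character.
#'
#' @param pi1 Stationary frequency of state 1, in (0, 1).
#' @param rate_model One of `"plain"`, `"I"`, `"G4"`, `"I+G4"`, `"R2"`,
#'   `"I+R2"`.  Labels may carry a `"GTR2"` and/or `"FO"` prefix and `"+"`
#'   separators (e.g. `"GTR2+FO+I+G4"`); a doubled `"I"` is collapsed.
#' @param p_inv Proportion of invariant characters, in \[0, 1).  Ignored
#'   unless the rate model contains `+I`.
#' @param gamma_shape Shape `alpha` of the discrete gamma distribution
#'   (4 equal-weight categories, mean-of-bin rates).  Ignored without `+G4`.
#' @param freerate For `+R2` models, a list with elements `rates` (length 2)
#'   and `weights` (length 2, summing to 1); weights are relative within the
#'   variable class and rates are rescaled to weighted mean 1.
#' @return An object of class `two_state_model`.
#' @examples
#' m <- two_state_model(pi1 = 0.7, rate_model = "I+G4",
#'                      p_inv = 0.2, gamma_shape = 0.5)
#' rate_categories(m)
#' @seealso [transition_matrix()], [fit_model()]
#' @export
two_state_model <- function(pi1 = 0.5, rate_model = "plain", p_inv = 0,
                            gamma_shape = 1, freerate = NULL) {
  rate_model <- normalize_rate_model(rate_model)
  if (!is.numeric(pi1) || length(pi1) != 1L || pi1 <= 0 || pi1 >= 1)
    stop("'pi1' must be a single value in (0, 1)")
  has_I <- grepl("I", rate_model, fixed = TRUE)
  if (!has_I) p_inv <- 0
  if (p_inv < 0 || p_inv >= 1)
    stop("'p_inv' must be in [0, 1)")
  if (gamma_shape <= 0) stop("'gamma_shape' must be positive")
  if (grepl("R2", rate_model, fixed = TRUE)) {
    if (is.null(freerate)) freerate <- list(rates = c(0.5, 1.5),
                                            weights = c(0.5, 0.5))
    if (length(freerate$rates) != 2L || length(freerate$weights) != 2L)
      stop("'freerate' needs 2 rates and 2 weights")
    if (any(freerate$rates <= 0) || any(freerate$weights <= 0))
      stop("'freerate' rates and weights must be positive")
    w <- freerate$weights / sum(freerate$weights)
    r <- freerate$rates / sum(w * freerate$rates)  # weighted mean 1
    freerate <- list(rates = r, weights = w)
  } else freerate <- NULL
  structure(list(pi1 = pi1, rate_model = rate_model, p_inv = p_inv,
                 gamma_shape = gamma_shape, freerate = freerate),
            class = "two_state_model")
}

# Canonical rate-model label: strip GTR2/FO decoration, collapse doubled +I.
normalize_rate_model <- function(label) {
  parts <- strsplit(toupper(gsub(" ", "", label)), "+", fixed = TRUE)[[1]]
  parts <- parts[!parts %in% c("", "GTR2", "FO", "PLAIN")]
  parts <- unique(parts)
  bad <- setdiff(parts, c("I", "G4", "R2"))
  if (length(bad))
    stop("unknown rate-model component(s): ", paste(bad, collapse = ", "))
  if (all(c("G4", "R2") %in% parts))
    stop("'+G4' and '+R2' cannot be combined")
  if (!length(parts)) return("plain")
  paste(parts[order(match(parts, c("I", "G4", "R2")))], collapse = "+")
}

#' Mean-of-bin discrete gamma rates
#'
#' Standard discretization of a Gamma(shape, rate = shape) distribution
#' (mean 1) into `k` equal-weight categories; each category rate is the mean
#' of its quantile bin, so the rates average exactly 1.
#'
#' @param shape Gamma shape parameter `alpha` (> 0).
#' @param k Number of categories.
#' @return Numeric vector of `k` category rates.
#' @export
discrete_gamma_rates <- function(shape, k = 4L) {
  stopifnot(shape > 0, k >= 1L)
  cuts <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape, rate = shape)
  # E[X; a<X<b] for Gamma(a,a) is pgamma(b, a+1, a) - pgamma(a, a+1, a)
  p <- stats::pgamma(cuts, shape + 1, rate = shape)
  k * diff(p)
}

# Fast internal mixture expansion (list, no data.frame overhead).
cat_list <- function(model) {
  rm <- model$rate_model
  if (grepl("G4", rm, fixed = TRUE)) {
    r <- discrete_gamma_rates(model$gamma_shape, 4L)
    w <- rep(0.25, 4L)
  } else if (grepl("R2", rm, fixed = TRUE)) {
    r <- model$freerate$rates
    w <- model$freerate$weights
  } else {
    r <- 1
    w <- 1
  }
  pv <- model$p_inv
  if (pv > 0) {
    r <- c(0, r)
    w <- c(pv, (1 - pv) * w)
  }
  list(rate = r, weight = w)
}

# Fast internal transition kernel (no validation, no dimnames).
trans2 <- function(pi1, t, r) {
  e <- exp(-r * t / (2 * pi1 * (1 - pi1)))
  matrix(c(1 - pi1 + pi1 * e, (1 - pi1) * (1 - e),
           pi1 * (1 - e), pi1 + (1 - pi1) * e), 2L, 2L)
}

#' Rate-mixture categories of a model
#'
#' Expands a [two_state_model()] into its full mixture: an invariant class of
#' rate 0 and weight `p_inv` (when present) plus the variable categories.
#' Weights sum to 1 and the weighted mean rate of the variable categories is
#' 1 (so the total mean rate is `1 - p_inv`).
#'
#' @param model A `two_state_model`.
#' @return A data frame with columns `rate` and `weight`.
#' @export
rate_categories <- function(model) {
  stopifnot(inherits(model, "two_state_model"))
  as.data.frame(cat_list(model))
}

#' Transition probability matrix of the two-state model
#'
#' Closed-form transition probabilities over a branch: with stationary
#' distribution `Pi` (rows `(pi0, pi1)`) and total rate `s = 1/(2 pi0 pi1)`,
#' `P(t) = Pi + exp(-s * r * t) * (I - Pi)` where `r` is the category rate
#' multiplier.
#'
#' @param model A [two_state_model()].
#' @param t Branch length (expected changes per variable character), >= 0.
#' @param rate_multiplier Non-negative category rate `r`.
#' @return A 2x2 row-stochastic matrix with dimnames `c("0","1")`.
#' @examples
#' transition_matrix(two_state_model(pi1 = 0.5), t = 0.5)[1, 2]
#' # 0.5 * (1 - exp(-1)) = 0.3160603
#' @export
transition_matrix <- function(model, t, rate_multiplier = 1) {
  stopifnot(inherits(model, "two_state_model"))
  if (t < 0) stop("branch length 't' must be non-negative")
  if (rate_multiplier < 0) stop("'rate_multiplier' must be non-negative")
  pi1 <- model$pi1
  pi0 <- 1 - pi1
  s <- 1 / (2 * pi0 * pi1)
  e <- exp(-s * rate_multiplier * t)
  P <- matrix(c(pi0 + pi1 * e, pi0 * (1 - e),
                pi1 * (1 - e), pi1 + pi0 * e),
              2L, 2L, dimnames = list(c("0", "1"), c("0", "1")))
  P
}

# Number of free model parameters (excluding branch lengths): pi1 always,
# plus p_inv, alpha, or the free-rate (r1, w1) pair as applicable.
n_model_parameters <- function(rate_model) {
  rm <- normalize_rate_model(rate_model)
  k <- 1L
  if (grepl("I", rm, fixed = TRUE)) k <- k + 1L
  if (grepl("G4", rm, fixed = TRUE)) k <- k + 1L
  if (grepl("R2", rm, fixed = TRUE)) k <- k + 2L
  k
}

#' @export
print.two_state_model <- function(x, ...) {
  cat("Two-state reversible model (GTR2)\n")
  cat(sprintf("  rate model: %s\n", x$rate_model))
  cat(sprintf("  pi1 = %.4f (pi0 = %.4f)\n", x$pi1, 1 - x$pi1))
  if (grepl("I", x$rate_model, fixed = TRUE))
    cat(sprintf("  p_inv = %.4f\n", x$p_inv))
  if (grepl("G4", x$rate_model, fixed = TRUE))
    cat(sprintf("  gamma shape = %.4f\n", x$gamma_shape))
  if (!is.null(x$freerate))
    cat(sprintf("  free rates = (%.4f, %.4f), weights = (%.4f, %.4f)\n",
                x$freerate$rates[1], x$freerate$rates[2],
                x$freerate$weights[1], x$freerate$weights[2]))
  invisible(x)
}
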