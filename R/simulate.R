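#' Default five-species study layout
#'
#' Two placental/non-placental sister pairs plus one non-placental
#' outgroup, mirroring the comparative design of the study system
#' (poeciliid fishes in which placentas evolved repeatedly).
#'
#' @return Data frame with columns `species`, `placental` (logical) and
#'   `pair` (1, 2 or `NA` for the outgroup).
#' @export
default_species_layout <- function() {
  data.frame(
    species = c("plac1", "nonplac1", "plac2", "nonplac2", "outgroup"),
    placental = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    pair = c(1L, 1L, 2L, 2L, NA_integer_))
}

#' Build the five-taxon species tree
#'
#' Unrooted topology `((plac1,nonplac1),(plac2,nonplac2),outgroup)`: each
#' placental/non-placental pair is a cherry and the outgroup hangs off the
#' central branch.  Within-pair terminal and stem branches get length
#' `0.1 * branch_scale`; the outgroup branch `0.2 * branch_scale`.
#'
#' @param layout Species layout, see [default_species_layout()].
#' @param branch_scale Positive multiplier for all branch lengths.
#' @return A `phylo` tree (unrooted, basal trichotomy).
#' @export
make_species_tree <- function(layout = default_species_layout(),
                              branch_scale = 1) {
  if (!is.numeric(branch_scale) || branch_scale <= 0)
    stop("'branch_scale' must be positive (branch lengths must be > 0)")
  check_species_layout(layout)
  pairs <- split(layout[!is.na(layout$pair), ], layout$pair[!is.na(layout$pair)])
  out <- layout$species[is.na(layout$pair)]
  b <- 0.1 * branch_scale
  cherry <- vapply(pairs, function(p)
    sprintf("(%s:%g,%s:%g):%g", p$species[1], b, p$species[2], b, b),
    character(1))
  txt <- sprintf("(%s,%s,%s:%g);", cherry[1], cherry[2], out, 2 * b)
  ape::read.tree(text = txt)
}

check_species_layout <- function(layout) {
  need <- c("species", "placental", "pair")
  if (!is.data.frame(layout) || !all(need %in% names(layout)))
    stop("layout must be a data frame with columns ",
         paste(need, collapse = ", "))
  if (nrow(layout) != 5L || anyDuplicated(layout$species))
    stop("layout must list exactly 5 distinct taxa")
  if (sum(is.na(layout$pair)) != 1L)
    stop("layout must contain exactly one outgroup (pair = NA)")
  pr <- layout[!is.na(layout$pair), ]
  ok <- all(vapply(split(pr, pr$pair), function(p)
    nrow(p) == 2L && sum(p$placental) == 1L, logical(1)))
  if (length(unique(pr$pair)) != 2L || !ok)
    stop("layout must contain 2 pairs, each one placental + one ",
         "non-placental species")
  invisible(layout)
}

#' Simulation configuration
#'
#' Bundles all knobs of the synthetic expression generator.  Defaults
#' describe the study conditions the generator emulates: five species (two
#' placental/non-placental pairs plus a non-placental outgroup), four
#' ordered follicle stages, a few replicates per stage, log-normal FPKM
#' noise, and planted heterochronic genes whose "expressed" and "silent"
#' regime means (10.0 and 0.2 FPKM) clear the fourfold and FPKM = 2
#' thresholds with margin at `noise_sd <= 0.4`.
#'
#' @param n_genes Number of genes.
#' @param n_replicates_per_stage Replicates per species x stage.
#' @param species_layout See [default_species_layout()].
#' @param stages Ordered stage labels; fixed vocabulary
#'   `egg, early, middle, late`.
#' @param n_neoteny Planted neoteny genes per species pair.
#' @param n_derived_up,n_derived_down Planted hypermorphosis genes per
#'   placental species.
#' @param n_egg_provisioning Planted ancestral egg-provisioning genes
#'   (egg-limited expression retained in every lineage; negative controls
#'   for the neoteny filter).
#' @param baseline_log_mean,baseline_log_sd Log-scale mean/sd of the
#'   background gene baseline FPKM distribution.
#' @param noise_sd Replicate-level sd of log-normal noise.
#' @param missing_rate Probability that a gene x species block is missing.
#' @param on_level,off_level Regime mean FPKM for expressed / silent states.
#' @param seed Integer seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000L, n_replicates_per_stage = 3L,
                       species_layout = default_species_layout(),
                       stages = c("egg", "early", "middle", "late"),
                       n_neoteny = 20L, n_derived_up = 30L,
                       n_derived_down = 30L, n_egg_provisioning = 50L,
                       baseline_log_mean = 1.5, baseline_log_sd = 1.5,
                       noise_sd = 0.3, missing_rate = 0.02,
                       on_level = 10.0, off_level = 0.2, seed = 1L) {
  if (!identical(stages, c("egg", "early", "middle", "late")))
    stop("stages must be exactly egg, early, middle, late")
  check_species_layout(species_layout)
  if (!(on_level > 2.0 && 2.0 > off_level && off_level >= 0))
    stop("need on_level > 2.0 > off_level >= 0")
  planted <- 2L * n_neoteny + 2L * n_derived_up + 2L * n_derived_down +
    n_egg_provisioning
  if (planted > n_genes)
    stop("planted gene counts exceed n_genes (", planted, " > ", n_genes, ")")
  if (n_replicates_per_stage < 1L) stop("need >= 1 replicate per stage")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must be in [0, 1)")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates_per_stage = as.integer(n_replicates_per_stage),
                 species_layout = species_layout, stages = stages,
                 n_neoteny = as.integer(n_neoteny),
                 n_derived_up = as.integer(n_derived_up),
                 n_derived_down = as.integer(n_derived_down),
                 n_egg_provisioning = as.integer(n_egg_provisioning),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 on_level = on_level, off_level = off_level,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Regime-mean FPKM for one gene class in one species at one stage.
# Classes: background regimes are handled separately (per-gene baseline).
regime_mean <- function(class, sp_placental, sp_pair, gene_pair, stage,
                        on, off) {
  late_half <- stage %in% c("middle", "late")
  is_focal_plac <- isTRUE(sp_placental) && identical(sp_pair, gene_pair)
  switch(class,
    egg_provisioning = if (late_half) off else on,
    neoteny = if (is_focal_plac) on else if (late_half) off else on,
    derived_up = if (is_focal_plac && late_half) on else off,
    derived_down = if (is_focal_plac && late_half) off else on,
    stop("unknown class: ", class))
}

#' Simulate a stage-resolved expression dataset with planted ground truth
#'
#' Generates per-species FPKM matrices over four follicle stages under
#' deterministic regime means with multiplicative log-normal replicate
#' noise.  Planted classes (relative to each placental/non-placental pair):
#'
#' * `egg_provisioning`: expressed at egg/early, silent at middle/late, in
#'   every species (the ancestral provisioning programme).
#' * `neoteny`: the egg-provisioning pattern everywhere except the focal
#'   placental species, where expression is retained at all stages.
#' * `derived_up`: silent everywhere except middle/late of the focal
#'   placental species.
#' * `derived_down`: expressed everywhere except middle/late of the focal
#'   placental species.
#' * `background`: a per-gene baseline FPKM shared across species and
#'   stages, replicate noise only.
#'
#' The outgroup (and the non-focal placental species) follow the
#' non-placental regime for all planted classes.  Whole gene x species
#' blocks are set missing with probability `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_expression`: list with `expression` (named
#'   list of genes x samples FPKM matrices per species), `metadata` (sample,
#'   species, stage, batch), `truth` (gene, class, pair, focal_species,
#'   anc_egg_state), `config`.
#' @export
simulate_expression_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config
  genes <- sprintf("g%05d", seq_len(cf$n_genes))
  lay <- cf$species_layout

  class <- rep("background", cf$n_genes)
  pair <- rep(NA_integer_, cf$n_genes)
  focal <- rep(NA_character_, cf$n_genes)
  plac_sp <- lay$species[which(lay$placental)]
  plac_pair <- lay$pair[which(lay$placental)]
  i <- 0L
  take <- function(n) { idx <- i + seq_len(n); i <<- i + n; idx }
  for (p in 1:2) {
    idx <- take(cf$n_neoteny)
    class[idx] <- "neoteny"; pair[idx] <- p
    focal[idx] <- plac_sp[plac_pair == p]
  }
  for (p in 1:2) {
    idx <- take(cf$n_derived_up)
    class[idx] <- "derived_up"; pair[idx] <- p
    focal[idx] <- plac_sp[plac_pair == p]
  }
  for (p in 1:2) {
    idx <- take(cf$n_derived_down)
    class[idx] <- "derived_down"; pair[idx] <- p
    focal[idx] <- plac_sp[plac_pair == p]
  }
  idx <- take(cf$n_egg_provisioning)
  class[idx] <- "egg_provisioning"

  baseline <- stats::rlnorm(cf$n_genes, cf$baseline_log_mean,
                            cf$baseline_log_sd)

  anc_state <- ifelse(
    class %in% c("egg_provisioning", "neoteny", "derived_down"), 1L,
    ifelse(class == "derived_up", 0L, as.integer(baseline >= 2)))

  nrep <- cf$n_replicates_per_stage
  samples_per_sp <- length(cf$stages) * nrep
  meta <- NULL
  expr <- list()
  for (s in seq_len(nrow(lay))) {
    sp <- lay$species[s]
    mu <- matrix(NA_real_, cf$n_genes, length(cf$stages),
                 dimnames = list(genes, cf$stages))
    for (st in cf$stages) {
      m <- baseline
      pl <- !is.na(class) & class != "background"
      for (g in which(pl))
        m[g] <- regime_mean(class[g], lay$placental[s], lay$pair[s],
                            pair[g], st, cf$on_level, cf$off_level)
      mu[, st] <- m
    }
    mat <- matrix(NA_real_, cf$n_genes, samples_per_sp)
    cn <- character(samples_per_sp)
    col <- 0L
    for (st in cf$stages) for (r in seq_len(nrep)) {
      col <- col + 1L
      cn[col] <- sprintf("%s_%s_r%d", sp, st, r)
      noise <- if (cf$noise_sd > 0)
        exp(stats::rnorm(cf$n_genes, 0, cf$noise_sd)) else 1
      mat[, col] <- mu[, st] * noise
    }
    dimnames(mat) <- list(genes, cn)
    drop <- stats::runif(cf$n_genes) < cf$missing_rate
    mat[drop, ] <- NA_real_
    expr[[sp]] <- mat
    meta <- rbind(meta, data.frame(
      sample = cn, species = sp,
      stage = rep(cf$stages, each = nrep),
      batch = rep(c("b1", "b2"), length.out = samples_per_sp)))
  }
  truth <- data.frame(gene = genes, class = class, pair = pair,
                      focal_species = focal, anc_egg_state = anc_state,
                      baseline = baseline)
  structure(list(expression = expr, metadata = meta, truth = truth,
                 config = cf),
            class = "sim_expression")
}

#' Planted class of every gene relative to one species pair
#'
#' A gene planted for pair 1 is, from pair 2's viewpoint, an ordinary
#' background or egg-provisioning gene; this helper resolves the per-pair
#' view of the global truth labels.
#'
#' @param truth Truth table from [simulate_expression_dataset()].
#' @param pair Pair id (1 or 2).
#' @return Named character vector over genes with values `neoteny`,
#'   `derived_up`, `derived_down`, `egg_provisioning` or `background`.
#' @export
planted_classes <- function(truth, pair) {
  cl <- ifelse(!is.na(truth$pair) & truth$pair == pair, truth$class,
               ifelse(truth$class == "egg_provisioning",
                      "egg_provisioning",
                      ifelse(truth$class == "neoteny", "egg_provisioning",
                             "background")))
  # a derived_* gene of the OTHER pair is flat 'on' or mostly-off background
  other <- !is.na(truth$pair) & truth$pair != pair &
    truth$class %in% c("derived_up", "derived_down")
  cl[other] <- "background"
  stats::setNames(cl, truth$gene)
}

#' @export
print.sim_expression <- function(x, ...) {
  cf <- x$config
  cat("Synthetic follicle expression dataset\n")
  cat(sprintf("  %d genes x %d species x %d stages x %d replicates\n",
              cf$n_genes, nrow(cf$species_layout), length(cf$stages),
              cf$n_replicates_per_stage))
  print(table(x$truth$class))
  invisible(x)
}
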