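#' Candidate-gene filter thresholds
#'
#' The published filter constants: a fourfold between-species fold-change
#' floor at the late stage, a twofold egg-vs-late floor within the
#' non-placental species, absolute expression floors of FPKM 2 (late) and
#' FPKM 1 (egg) in the placental species, and a small pseudocount added to
#' both sides of every ratio.
#'
#' @param fc_between Between-species fold-change floor (default 4).
#' @param fc_within Egg-vs-late fold-change floor in the non-placental
#'   species (default 2).
#' @param fpkm_late_min Placental late-stage FPKM floor (default 2).
#' @param fpkm_egg_min Placental egg-stage FPKM floor (default 1).
#' @param pseudocount FPKM added to numerator and denominator of every
#'   fold change (default 0.01).
#' @return Object of class `hc_thresholds`.
#' @export
thresholds <- function(fc_between = 4.0, fc_within = 2.0,
                       fpkm_late_min = 2.0, fpkm_egg_min = 1.0,
                       pseudocount = 0.01) {
  vals <- c(fc_between, fc_within, fpkm_late_min, fpkm_egg_min, pseudocount)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thresholds must be positive")
  structure(list(fc_between = fc_between, fc_within = fc_within,
                 fpkm_late_min = fpkm_late_min, fpkm_egg_min = fpkm_egg_min,
                 pseudocount = pseudocount),
            class = "hc_thresholds")
}

#' Pseudocounted fold change
#'
#' `(a + pseudocount) / (b + pseudocount)`; missing inputs give missing
#' output.  With strictly positive inputs the value converges to the exact
#' ratio as the pseudocount goes to 0.
#'
#' @param a,b Mean FPKM values (vectors recycle).
#' @param pseudocount Non-negative stabilizer (default 0.01).
#' @return Numeric fold change(s).
#' @examples
#' fold_change(8, 0, 0.01)  # 801
#' @export
fold_change <- function(a, b, pseudocount = 0.01) {
  if (pseudocount < 0) stop("'pseudocount' must be non-negative")
  (a + pseudocount) / (b + pseudocount)
}

#' Placental/non-placental pair design
#'
#' @param placental,nonplacental Species ids of the pair.
#' @param tree Optional species tree; when given, the pair must form a
#'   cherry and the ancestor node is their MRCA.
#' @param label Optional pair label.
#' @return Object of class `pair_design` with fields `placental`,
#'   `nonplacental`, `ancestor_node` (or `NA`), `label`.
#' @export
pair_design <- function(placental, nonplacental, tree = NULL,
                        label = paste0(placental, "/", nonplacental)) {
  anc <- NA_integer_
  if (!is.null(tree)) {
    anc <- pair_ancestor_node(tree, c(placental, nonplacental))
    kids <- tree$edge[tree$edge[, 1L] == anc, 2L]
    if (!all(kids <= length(tree$tip.label)))
      stop("pair (", placental, ", ", nonplacental,
           ") is not a cherry in the species tree")
  }
  structure(list(placental = placental, nonplacental = nonplacental,
                 ancestor_node = anc, label = label),
            class = "pair_design")
}

# Inclusive fold-change comparison with a 1e-8 relative tolerance: the
# pseudocount pulls a ratio of exactly-at-threshold means infinitesimally
# below the floor (e.g. (8+pc)/(2+pc) < 4), and "at least fourfold" must
# keep such genes.  Absolute FPKM floors involve no pseudocount and are
# compared exactly.
fc_geq <- function(fc, floor) fc >= floor * (1 - 1e-8)

stage_mean_vector <- function(means, species, stage) {
  sel <- means$species == species & means$stage == stage
  if (!any(sel))
    stop("no stage means for species ", species, " at stage ", stage)
  stats::setNames(means$mean_fpkm[sel], means$gene[sel])
}

new_candidate_set <- function(tab, evaluation, excluded, design, th) {
  structure(tab, evaluation = evaluation, excluded = excluded,
            design = design, thresholds = th, class = c("candidate_set",
                                                        "data.frame"))
}

#' Neoteny candidate genes
#'
#' A gene is a neoteny candidate for a pair when all of: (i) at least
#' `fc_between`-fold (default fourfold) higher late-stage expression in
#' the placental than the non-placental species; (ii) at least
#' `fc_within`-fold (default twofold) higher egg- than late-stage
#' expression in the non-placental species; (iii) placental FPKM of at
#' least `fpkm_late_min` (2) at late and `fpkm_egg_min` (1) at egg
#' stages.  All floors are inclusive; fold-change floors are compared with
#' a 1e-8 relative tolerance so the pseudocount cannot exclude a gene whose
#' true ratio sits exactly on the boundary.  Genes missing any required
#' stage mean are excluded and reported.
#'
#' @param means Long stage-mean table from [stage_means()].
#' @param design A [pair_design()].
#' @param th A [thresholds()] object.
#' @return A `candidate_set`: data frame of passing genes with the
#'   per-criterion values and flags; full evaluation in attribute
#'   `"evaluation"`, excluded gene ids in `"excluded"`.
#' @export
neoteny_candidates <- function(means, design, th = thresholds()) {
  stopifnot(inherits(design, "pair_design"))
  pl <- design$placental; npl <- design$nonplacental
  plac_late <- stage_mean_vector(means, pl, "late")
  plac_egg <- stage_mean_vector(means, pl, "egg")
  npl_late <- stage_mean_vector(means, npl, "late")
  npl_egg <- stage_mean_vector(means, npl, "egg")
  genes <- Reduce(intersect, list(names(plac_late), names(plac_egg),
                                  names(npl_late), names(npl_egg)))
  ev <- data.frame(
    gene = genes,
    plac_late = plac_late[genes], plac_egg = plac_egg[genes],
    nonplac_late = npl_late[genes], nonplac_egg = npl_egg[genes],
    row.names = NULL)
  incomplete <- !stats::complete.cases(ev)
  if (any(incomplete))
    message(sum(incomplete),
            " gene(s) excluded: required stage mean missing")
  excluded <- ev$gene[incomplete]
  ev <- ev[!incomplete, , drop = FALSE]
  ev$fc_between <- fold_change(ev$plac_late, ev$nonplac_late, th$pseudocount)
  ev$fc_within <- fold_change(ev$nonplac_egg, ev$nonplac_late,
                              th$pseudocount)
  ev$pass_fc_between <- fc_geq(ev$fc_between, th$fc_between)
  ev$pass_fc_within <- fc_geq(ev$fc_within, th$fc_within)
  ev$pass_late_min <- ev$plac_late >= th$fpkm_late_min
  ev$pass_egg_min <- ev$plac_egg >= th$fpkm_egg_min
  pass <- ev$pass_fc_between & ev$pass_fc_within & ev$pass_late_min &
    ev$pass_egg_min
  tab <- ev[pass, , drop = FALSE]
  tab$class <- if (nrow(tab)) "neoteny" else character(0)
  rownames(tab) <- NULL
  new_candidate_set(tab, ev, excluded, design, th)
}

#' Hypermorphosis candidate genes (derived-up / derived-down)
#'
#' Classifies genes whose late-stage placental expression is derived
#' relative to both the non-placental sister species and the reconstructed
#' pair ancestor, in the same direction.  With ancestral states taken from
#' binary-character reconstruction (state 1 standing for ancestral FPKM >
#' 2, state 0 for FPKM < 2):
#'
#' * `derived_up`: placental late at least `fc_between`-fold above
#'   non-placental late, placental late FPKM strictly above
#'   `fpkm_late_min`, ancestor state 0.
#' * `derived_down`: non-placental late at least `fc_between`-fold above
#'   placental late, placental late FPKM strictly below `fpkm_late_min`,
#'   ancestor state 1.
#'
#' The two classes are mutually exclusive by construction.  Genes with an
#' ambiguous or missing ancestral state are skipped and reported.
#'
#' @inheritParams neoteny_candidates
#' @param ancestor Named vector of ancestral states per gene
#'   (`"0"`/`"1"`/`"ambiguous"`), e.g. from
#'   [ancestor_expression_states()].
#' @return A `candidate_set` with classes `derived_up` / `derived_down`.
#' @export
hypermorphosis_candidates <- function(means, ancestor, design,
                                      th = thresholds()) {
  stopifnot(inherits(design, "pair_design"))
  pl <- design$placental; npl <- design$nonplacental
  plac_late <- stage_mean_vector(means, pl, "late")
  npl_late <- stage_mean_vector(means, npl, "late")
  genes <- intersect(names(plac_late), names(npl_late))
  anc <- as.character(ancestor[genes])
  names(anc) <- genes
  skip <- is.na(anc) | anc == "ambiguous"
  if (any(skip))
    message(sum(skip), " gene(s) skipped: ancestral state ambiguous ",
            "or unavailable")
  excluded <- genes[skip]
  genes <- genes[!skip]
  ev <- data.frame(
    gene = genes,
    plac_late = plac_late[genes], nonplac_late = npl_late[genes],
    ancestor_state = anc[genes], row.names = NULL)
  incomplete <- !stats::complete.cases(ev)
  if (any(incomplete))
    message(sum(incomplete),
            " gene(s) excluded: required stage mean missing")
  excluded <- c(excluded, ev$gene[incomplete])
  ev <- ev[!incomplete, , drop = FALSE]
  ev$fc_up <- fold_change(ev$plac_late, ev$nonplac_late, th$pseudocount)
  ev$fc_down <- fold_change(ev$nonplac_late, ev$plac_late, th$pseudocount)
  up <- fc_geq(ev$fc_up, th$fc_between) &
    ev$plac_late > th$fpkm_late_min & ev$ancestor_state == "0"
  down <- fc_geq(ev$fc_down, th$fc_between) &
    ev$plac_late < th$fpkm_late_min & ev$ancestor_state == "1"
  ev$class <- ifelse(up, "derived_up", ifelse(down, "derived_down", NA))
  tab <- ev[up | down, , drop = FALSE]
  rownames(tab) <- NULL
  new_candidate_set(tab, ev, excluded, design, th)
}

#' @export
print.candidate_set <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("Candidate gene set for pair %s\n", d$label))
  if (nrow(x)) print(table(x$class)) else cat("  (no candidates)\n")
  cat(sprintf("  evaluated: %d; excluded: %d\n",
              nrow(attr(x, "evaluation")), length(attr(x, "excluded"))))
  invisible(x)
}

#' Overlap (Venn) summary of candidate sets
#'
#' Counts, per candidate class, how many gene ids fall in each region of
#' the Venn diagram over the supplied sets (exclusive regions and every
#' shared combination).
#'
#' @param sets Named list (>= 2) of `candidate_set` objects or data frames
#'   with columns `gene` and `class`.
#' @return Data frame with columns `class`, `region` (set names joined by
#'   `&`), `count`.
#' @export
overlap_summary <- function(sets) {
  if (length(sets) < 2L) stop("need >= 2 candidate sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  classes <- sort(unique(unlist(lapply(sets, function(s) s$class))))
  out <- NULL
  for (cl in classes) {
    ids <- lapply(sets, function(s) unique(s$gene[s$class == cl]))
    all_ids <- unique(unlist(ids))
    sig <- vapply(all_ids, function(g)
      paste(names(sets)[vapply(ids, function(v) g %in% v, logical(1))],
            collapse = "&"), character(1))
    regions <- table(sig)
    out <- rbind(out, data.frame(class = cl, region = names(regions),
                                 count = as.integer(regions),
                                 row.names = NULL))
  }
  out
}

#' Matrotrophy index from embryo dry-mass observations
#'
#' The matrotrophy index (MI) is the dry mass of embryos at birth divided
#' by the dry mass of the egg at fertilization, estimated from an ordinary
#' least-squares regression of mean dry mass on developmental stage
#' ordinal: MI = predicted mass at the final stage / predicted mass at
#' stage 0.  MI < 1 indicates lecithotrophy (embryos lose mass), MI > 1
#' indicates substantial post-fertilization provisioning.
#'
#' @param stage Numeric stage ordinals (>= 2 distinct values).
#' @param mass Positive mean dry masses (mg), one per observation.
#' @param log_mass Regress on `log(mass)` and back-transform (default
#'   `FALSE`: raw mass).
#' @return The MI (single number), with the fitted `lm` in attribute
#'   `"fit"`.
#' @examples
#' matrotrophy_index(0:10, seq(1, 0.7, length.out = 11))  # 0.7
#' @export
matrotrophy_index <- function(stage, mass, log_mass = FALSE) {
  if (length(stage) != length(mass)) stop("'stage' and 'mass' lengths differ")
  if (length(unique(stage)) < 2L) stop("need >= 2 distinct stages")
  if (any(mass <= 0)) stop("masses must be positive")
  y <- if (log_mass) log(mass) else mass
  fit <- stats::lm(y ~ stage)
  pr <- stats::predict(fit, data.frame(stage = c(0, max(stage))))
  if (log_mass) pr <- exp(pr)
  if (any(pr <= 0))
    stop("regression predicts non-positive mass at an endpoint ",
         sprintf("(fertilization: %.4g, birth: %.4g); ", pr[1], pr[2]),
         "consider log_mass = TRUE")
  structure(unname(pr[2] / pr[1]), fit = fit)
}
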