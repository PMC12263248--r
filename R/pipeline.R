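#' Pipeline configuration
#'
#' Bundles every knob of [run_pipeline()]: the simulation design, the
#' candidate-gene thresholds, the rate models used for the stage trees and
#' the ancestral reconstruction, orthology settings, and the output
#' directory.  The seed flows into every stochastic stage and is recorded
#' in the provenance header of every output file.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed.
#' @param sim A [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param th A [thresholds()] object.
#' @param egg_tree_model,late_tree_model Rate models for the stage
#'   expression phylogenies.
#' @param asr_model Rate model for the ancestral reconstruction fit.
#' @param evalue_cutoff,flank_window,end_policy Orthology settings.
#' @param paralog_rate,rearrangement_events Perturbations for the
#'   simulated genomes.
#' @param n_boot Bootstrap replicates for stage-tree support (0 = skip).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = file.path(tempdir(), "hetchron_run"),
                            seed = 1L, sim = sim_config(seed = seed),
                            th = thresholds(),
                            egg_tree_model = "I+G4",
                            late_tree_model = "I+R2",
                            asr_model = "I+G4",
                            evalue_cutoff = 1e-7, flank_window = 1L,
                            end_policy = "strict",
                            paralog_rate = 0.1, rearrangement_events = 0L,
                            n_boot = 0L) {
  stopifnot(inherits(sim, "sim_config"), inherits(th, "hc_thresholds"))
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 th = th, egg_tree_model = egg_tree_model,
                 late_tree_model = late_tree_model, asr_model = asr_model,
                 evalue_cutoff = evalue_cutoff,
                 flank_window = as.integer(flank_window),
                 end_policy = end_policy, paralog_rate = paralog_rate,
                 rearrangement_events = as.integer(rearrangement_events),
                 n_boot = as.integer(n_boot)),
            class = "pipeline_config")
}

# Sensitivity/precision of a candidate set against planted truth classes.
recovery_stats <- function(called_genes, truth_classes, class) {
  planted <- names(truth_classes)[truth_classes == class]
  tp <- length(intersect(called_genes, planted))
  data.frame(class = class,
             n_planted = length(planted), n_called = length(called_genes),
             sensitivity = if (length(planted)) tp / length(planted)
                           else NA_real_,
             precision = if (length(called_genes)) tp / length(called_genes)
                         else NA_real_)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Chains every stage of the inference: simulate expression and genomes,
#' map one-to-one orthologues (RBH + synteny + merge), normalize and
#' binary-encode expression, infer egg- and late-stage expression
#' phylogenies, reconstruct ancestral expression states on the species
#' tree, classify neoteny and hypermorphosis candidates per species pair,
#' and score recovery of the planted genes.  All intermediate artifacts
#' are written under `config$outdir` with seed and parameter provenance
#' headers; a rerun with the same config is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `hetchron_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(seed = config$seed, fc_between = config$th$fc_between,
               fc_within = config$th$fc_within,
               fpkm_late_min = config$th$fpkm_late_min,
               fpkm_egg_min = config$th$fpkm_egg_min,
               pseudocount = config$th$pseudocount,
               evalue_cutoff = config$evalue_cutoff,
               flank_window = config$flank_window,
               end_policy = config$end_policy)
  out <- function(...) file.path(config$outdir, ...)

  # -- simulate ---------------------------------------------------------
  sim <- simulate_expression_dataset(config$sim)
  genomes <- simulate_synteny_genomes(
    config$sim$n_genes, rearrangement_events = config$rearrangement_events,
    paralog_rate = config$paralog_rate, seed = config$seed + 1L,
    species = config$sim$species_layout$species)
  lay <- config$sim$species_layout
  tree <- make_species_tree(lay)
  write_newick(tree, out("species_tree.nwk"), prov)
  for (sp in names(sim$expression))
    write_expression_tsv(sim$expression[[sp]],
                         out(sprintf("expression_%s.tsv", sp)), prov)
  write_sample_metadata(sim$metadata, out("metadata.tsv"), prov)
  write_table_tsv(sim$truth, out("truth_labels.tsv"), prov)

  # -- orthology --------------------------------------------------------
  ref <- genomes$reference
  pairwise <- list()
  for (sp in setdiff(lay$species, ref)) {
    h <- genomes$hits[[sp]]
    rbh <- reciprocal_best_hits(
      filter_hits(h$ab, config$evalue_cutoff),
      filter_hits(h$ba, config$evalue_cutoff),
      genomes$lengths[[ref]], genomes$lengths[[sp]])
    pairwise[[sp]] <- synteny_filter(rbh, genomes$coords[[ref]],
                                     genomes$coords[[sp]],
                                     config$flank_window,
                                     config$end_policy)
  }
  ortho <- merge_orthologues(pairwise, genomes$coords[[ref]], ref)
  write_table_tsv(ortho, out("orthologues.tsv"), prov)
  # species-specific ids carry a "<species>:" prefix; strip to the shared
  # gene id space used by the expression matrices
  ortho_genes <- sub("^[^:]+:", "", ortho$ref_gene)

  # -- encode -----------------------------------------------------------
  norm <- list()
  for (sp in lay$species)
    norm[[sp]] <- normalize_within_species(
      sim$expression[[sp]][ortho_genes, , drop = FALSE])
  all_mat <- do.call(cbind, unname(norm))
  means <- stage_means(all_mat, sim$metadata)
  bin_samples <- binarize(all_mat)
  write_phylip_binary(t(bin_samples), out("binary_samples.phy"), prov)

  stage_states <- lapply(c(egg = "egg", late = "late"), function(st)
    stage_consensus_binary(bin_samples, sim$metadata, st))
  write_phylip_binary(stage_states$egg, out("binary_egg_species.phy"), prov)
  write_phylip_binary(stage_states$late, out("binary_late_species.phy"), prov)

  # -- stage phylogenies ------------------------------------------------
  egg_tree <- search_topology(stage_states$egg, config$egg_tree_model,
                              n_starts = 2L, seed = config$seed + 2L)
  late_tree <- search_topology(stage_states$late, config$late_tree_model,
                               n_starts = 2L, seed = config$seed + 3L)
  if (config$n_boot > 0L) {
    egg_tree <- bootstrap_support(stage_states$egg, config$egg_tree_model,
                                  config$n_boot, seed = config$seed + 4L,
                                  tree = egg_tree)
    late_tree <- bootstrap_support(stage_states$late,
                                   config$late_tree_model, config$n_boot,
                                   seed = config$seed + 5L, tree = late_tree)
  }
  write_newick(egg_tree, out("egg_tree.nwk"), prov)
  write_newick(late_tree, out("late_tree.nwk"), prov)
  plac <- lay$species[lay$placental]
  plac_clade <- ape::is.monophyletic(late_tree, plac)

  # -- ancestral reconstruction ----------------------------------------
  asr_fit <- fit_model(tree, stage_states$egg, config$asr_model)
  asr <- ancestral_reconstruction(asr_fit$tree, asr_fit$model,
                                  stage_states$egg)
  write_table_tsv(as.data.frame(asr), out("asr_egg.tsv"), prov)

  # -- candidates -------------------------------------------------------
  sets_neo <- list(); sets_hyp <- list(); recovery <- NULL
  for (p in 1:2) {
    pls <- lay$species[lay$placental & !is.na(lay$pair) & lay$pair == p]
    npl <- lay$species[!lay$placental & !is.na(lay$pair) & lay$pair == p]
    design <- pair_design(pls, npl, tree = asr_fit$tree,
                          label = sprintf("pair%d", p))
    anc <- ancestor_expression_states(
      asr, pair_ancestor_node(asr_fit$tree, c(pls, npl)))
    neo <- neoteny_candidates(means, design, config$th)
    hyp <- hypermorphosis_candidates(means, anc, design, config$th)
    sets_neo[[design$label]] <- neo
    sets_hyp[[design$label]] <- hyp
    write_table_tsv(as.data.frame(neo),
                    out(sprintf("candidates_neoteny_pair%d.tsv", p)), prov)
    write_table_tsv(as.data.frame(hyp),
                    out(sprintf("candidates_hypermorphosis_pair%d.tsv", p)),
                    prov)
    tc <- planted_classes(sim$truth, p)
    tc <- tc[ortho_genes]
    recovery <- rbind(
      recovery,
      cbind(pair = p, recovery_stats(neo$gene, tc, "neoteny")),
      cbind(pair = p, recovery_stats(hyp$gene[hyp$class == "derived_up"],
                                     tc, "derived_up")),
      cbind(pair = p, recovery_stats(hyp$gene[hyp$class == "derived_down"],
                                     tc, "derived_down")))
  }
  venn <- rbind(cbind(kind = "neoteny", overlap_summary(sets_neo)),
                cbind(kind = "hypermorphosis", overlap_summary(sets_hyp)))
  write_table_tsv(venn, out("overlap_summary.tsv"), prov)
  write_table_tsv(recovery, out("recovery.tsv"), prov)

  counts <- do.call(rbind, lapply(names(sets_neo), function(lb)
    data.frame(pair = lb,
               neoteny = nrow(sets_neo[[lb]]),
               derived_up = sum(sets_hyp[[lb]]$class == "derived_up"),
               derived_down = sum(sets_hyp[[lb]]$class == "derived_down"))))
  report <- structure(
    list(counts = counts, recovery = recovery, venn = venn,
         n_orthologues = nrow(ortho), plac_clade_late = plac_clade,
         egg_tree = egg_tree, late_tree = late_tree,
         species_tree = tree, asr = asr, config = config,
         outdir = config$outdir),
    class = "hetchron_report")
  rep_lines <- c(
    sprintf("orthologues: %d", nrow(ortho)),
    sprintf("placental clade in late tree: %s", plac_clade),
    sprintf("%s pair=%s neoteny=%d derived_up=%d derived_down=%d",
            "counts", counts$pair, counts$neoteny, counts$derived_up,
            counts$derived_down))
  write_lines_tsv(rep_lines, out("report.txt"), prov)
  report
}

#' @export
print.hetchron_report <- function(x, ...) {
  cat("hetchron pipeline report\n")
  cat(sprintf("  one-to-one orthologues: %d\n", x$n_orthologues))
  cat(sprintf("  placental species form a clade in the late tree: %s\n",
              x$plac_clade_late))
  cat("  candidate counts:\n")
  print(x$counts, row.names = FALSE)
  cat("  planted-gene recovery:\n")
  print(x$recovery, row.names = FALSE, digits = 3)
  invisible(x)
}
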