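test_that("species tree construction validates the layout", {
  tr <- make_species_tree()
  expect_s3_class(tr, "phylo")
  expect_true(all(tr$edge.length > 0))
  expect_true(ape::is.monophyletic(tr, c("plac1", "nonplac1")))
  expect_true(ape::is.monophyletic(tr, c("plac2", "nonplac2")))
  expect_identical(ape::write.tree(make_species_tree()),
                   ape::write.tree(make_species_tree()))
  expect_error(make_species_tree(branch_scale = 0), "positive")
  bad <- default_species_layout()
  bad$pair <- c(1L, 1L, 2L, 2L, 2L)
  expect_error(make_species_tree(bad), "outgroup")
  bad2 <- default_species_layout()
  bad2$placental <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_error(make_species_tree(bad2), "placental")
})

test_that("sim_config enforces its invariants", {
  expect_error(sim_config(n_genes = 50, n_neoteny = 50), "exceed")
  expect_error(sim_config(stages = c("egg", "late")), "exactly")
  expect_error(sim_config(on_level = 1.5), "on_level")
  expect_error(sim_config(off_level = 2.5), "on_level")
  cf <- sim_config()
  expect_s3_class(cf, "sim_config")
})

test_that("planted counts match the configuration exactly", {
  cf <- tiny_sim_config(n_neoteny = 7L, n_derived_up = 5L,
                        n_derived_down = 4L)
  sim <- simulate_expression_dataset(cf)
  tab <- table(sim$truth$class, sim$truth$pair, useNA = "ifany")
  expect_equal(unname(tab["neoteny", "1"]), 7)
  expect_equal(unname(tab["neoteny", "2"]), 7)
  expect_equal(unname(tab["derived_up", "1"]), 5)
  expect_equal(unname(tab["derived_down", "2"]), 4)
  expect_equal(sum(sim$truth$class == "egg_provisioning"), 20)
})

test_that("identical seeds regenerate bit-identical datasets", {
  cf <- tiny_sim_config(seed = 99L)
  s1 <- simulate_expression_dataset(cf)
  s2 <- simulate_expression_dataset(cf)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$truth, s2$truth)
  g1 <- simulate_synteny_genomes(50, 2, 0.2, seed = 7)
  g2 <- simulate_synteny_genomes(50, 2, 0.2, seed = 7)
  expect_identical(g1, g2)
})

test_that("noiseless generation hits the regime means exactly and binarizes
           to the planted regimes", {
  cf <- tiny_sim_config(noise_sd = 0, missing_rate = 0)
  sim <- simulate_expression_dataset(cf)
  tr <- sim$truth
  e_np <- sim$expression[["nonplac1"]]
  e_pl <- sim$expression[["plac1"]]
  md <- sim$metadata
  late_np <- md$sample[md$species == "nonplac1" & md$stage == "late"]
  egg_np <- md$sample[md$species == "nonplac1" & md$stage == "egg"]
  late_pl <- md$sample[md$species == "plac1" & md$stage == "late"]
  neo <- tr$gene[tr$class == "neoteny" & tr$pair == 1]
  expect_true(all(e_np[neo, egg_np] == cf$on_level))
  expect_true(all(e_np[neo, late_np] == cf$off_level))
  expect_true(all(e_pl[neo, late_pl] == cf$on_level))
  du <- tr$gene[tr$class == "derived_up" & tr$pair == 1]
  expect_true(all(e_np[du, ] == cf$off_level))
  expect_true(all(e_pl[du, late_pl] == cf$on_level))
  dd <- tr$gene[tr$class == "derived_down" & tr$pair == 1]
  expect_true(all(e_np[dd, ] == cf$on_level))
  expect_true(all(e_pl[dd, late_pl] == cf$off_level))
  # binarized outgroup egg-stage means equal the planted ancestral states
  # (the outgroup retains the ancestral regime for every planted class)
  allm <- do.call(cbind, unname(sim$expression))
  sm <- stage_means(allm, md)
  og <- sm[sm$species == "outgroup" & sm$stage == "egg", ]
  v <- setNames(og$mean_fpkm, og$gene)
  expect_equal(unname(as.integer(v[tr$gene] >= 2)), tr$anc_egg_state)
})

test_that("binary characters evolve to the stationary frequency on long
           branches", {
  tr <- make_species_tree(branch_scale = 1000)  # effectively independent
  m <- two_state_model(0.7)
  x <- simulate_binary_characters(tr, m, 10000, seed = 141)
  expect_equal(mean(x), 0.7, tolerance = 0.02)
})

test_that("zero branch lengths copy the root state everywhere", {
  tr <- make_species_tree()
  tr$edge.length[] <- 0
  x <- simulate_binary_characters(tr, two_state_model(0.4), 50, seed = 151)
  expect_true(all(apply(x, 2, function(cl) length(unique(cl)) == 1L)))
  expect_identical(
    simulate_binary_characters(tr, two_state_model(0.4), 20, seed = 3),
    simulate_binary_characters(tr, two_state_model(0.4), 20, seed = 3))
  expect_equal(ncol(simulate_binary_characters(
    make_species_tree(), two_state_model(0.4), 0)), 0L)
})

test_that("characters simulated under a model score best under it
           (identifiability smoke test)", {
  tr <- five_taxon_tree()
  m_true <- two_state_model(0.8)
  m_wrong <- two_state_model(0.2)
  x <- simulate_binary_characters(tr, m_true, 1000, seed = 161)
  expect_gt(as.numeric(log_likelihood(tr, m_true, x)),
            as.numeric(log_likelihood(tr, m_wrong, x)))
})

test_that("synthetic genomes plant decoys that straddle the E-value cutoff
           but never outscore the true hit", {
  g <- simulate_synteny_genomes(60, paralog_rate = 0.5, seed = 8)
  h <- g$hits[["nonplac1"]]$ab
  true_min <- min(h$bitscore[h$evalue < 1e-20])
  decoys <- h[h$evalue >= 1e-10, ]
  expect_gt(nrow(decoys), 0)
  expect_true(all(decoys$bitscore < true_min))
  expect_true(any(decoys$evalue <= 1e-7) && any(decoys$evalue > 1e-7))
  expect_error(simulate_synteny_genomes(5), ">= 10")
})
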