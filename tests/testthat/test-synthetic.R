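test_that("generators are deterministic given a seed", {
  a <- gen_xic_table(theta = 0.3, n_groups = 10, seed = 5)
  b <- gen_xic_table(theta = 0.3, n_groups = 10, seed = 5)
  expect_identical(a, b)
  expect_false(identical(
    a$data$area,
    gen_xic_table(theta = 0.3, n_groups = 10, seed = 6)$data$area))
  s1 <- gen_silac_experiment(n_proteins = 50, seed = 2)
  s2 <- gen_silac_experiment(n_proteins = 50, seed = 2)
  expect_identical(s1, s2)
  expect_lt(child_seed(123456, 9), 2^31)
})

test_that("persisted scenarios are byte-identical across regeneration", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_scenario(gen_methyl_profiles(c(0.7, 0.2, 0.05, 0.05),
                                           seed = 3), d1, "m")
  f2 <- write_scenario(gen_methyl_profiles(c(0.7, 0.2, 0.05, 0.05),
                                           seed = 3), d2, "m")
  expect_equal(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_true(any(grepl("truth\\.json$", f1)))  # truth beside the data
})

test_that("noise-free XIC tables carry the exact planted occupancy", {
  sim <- gen_xic_table(theta = 0.5, n_groups = 5, n_replicates = 2,
                       noise_sd = 1e-12, seed = 1)
  occ <- phospho_occupancy(sim$data)
  expect_equal(occ$fraction, rep(0.5, nrow(occ)), tolerance = 1e-9)
  zero <- gen_xic_table(theta = 0, n_groups = 3, noise_sd = 0.2,
                        seed = 1)
  expect_true(all(zero$data$area[zero$data$n_phospho == 1] == 0))
})

test_that("multi-site, co-elution and missed-cleavage structures emerge", {
  sim <- gen_xic_table(theta = 0.3, n_groups = 40, n_sites = 2,
                       coelute_fraction = 0.5,
                       missed_cleavage_fraction = 0.3, seed = 9)
  occ <- phospho_occupancy(sim$data)
  expect_true(any(occ$site_labels == "SA;SB"))       # pooled co-elution
  expect_true(any(grepl("_mc1$", occ$group_id)))     # separate mc group
  # separate-site forms recover theta each; pooled forms recover 2 theta
  single <- occ$fraction[occ$site_labels %in% c("SA", "SB")]
  pooled <- occ$fraction[occ$site_labels == "SA;SB"]
  expect_lt(abs(mean(single) - 0.3), 0.05)
  expect_lt(abs(mean(pooled) - 0.6), 0.05)
})

test_that("noise-free methyl profiles reproduce the planted distribution", {
  sim <- gen_methyl_profiles(c(0.25, 0.25, 0.25, 0.25), me1_split = 0.5,
                             n_replicates = 1, noise_sd = 1e-12, seed = 2)
  expect_equal(sort(unique(sim$data$form_id)),
               c("me0", "me1_free", "me1_prop", "me2", "me3"))
  expect_equal(max(sim$data$area) / min(sim$data$area), 2,
               tolerance = 1e-6)  # me1 split in half across two forms
  st <- methyl_stoichiometry(sim$data)
  expect_equal(st$fraction, rep(0.25, 4), tolerance = 1e-9)
  expect_error(gen_methyl_profiles(c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("methyl-state recovery stays within 0.05 under noise", {
  truth <- c(0.7, 0.2, 0.05, 0.05)
  sim <- gen_methyl_profiles(truth, n_replicates = 3, noise_sd = 0.2,
                             seed = 6)
  st <- methyl_stoichiometry(sim$data)
  means <- tapply(st$fraction, st$state, mean)
  expect_true(all(abs(means[c("me0", "me1", "me2", "me3")] - truth) <
                    0.05))
  expect_equal(sum(st$fraction[st$replicate == 1]), 1, tolerance = 1e-12)
})

test_that("silac generator plants offsets, junk and low-peptide rows", {
  sim <- gen_silac_experiment(n_proteins = 400, n_shifted = 10,
                              contaminant_fraction = 0.02,
                              low_peptide_fraction = 0.05, seed = 7)
  x <- sim$data
  expect_true(any(x$is_contaminant))
  expect_true(any(x$is_decoy))
  expect_true(any(x$n_peptides < 2))
  # injected mixing offset shows up in the raw medians, and
  # median-centring removes it
  fwd <- x$median_log2_hl[x$replicate_id == 1 & !x$is_contaminant &
                            !x$is_decoy]
  expect_gt(median(fwd), 0.2)
  o <- normalize_and_orient(filter_proteins(x))
  expect_equal(median(o$oriented_log2[o$replicate_id == 1]), 0,
               tolerance = 1e-12)
})

test_that("enrichment universe plants a recoverable term", {
  sim <- gen_enrichment_universe(n_genes = 2000, n_terms = 20,
                                 term_size = 20, n_planted = 1,
                                 odds_ratio = 10, study_size = 100,
                                 seed = 11)
  res <- hypergeometric_enrichment(sim$data$study, sim$data$background,
                                   sim$data$annotations)
  planted <- sim$truth$planted_terms
  expect_true(planted %in% res$term[1])  # smallest p
  expect_lt(res$q_value[res$term == planted], 0.05)
})

test_that("null enrichment universes rarely reach significance", {
  sig <- vapply(1:5, function(s) {
    sim <- gen_enrichment_universe(n_genes = 1000, n_terms = 20,
                                   odds_ratio = 1, study_size = 80,
                                   seed = s)
    res <- hypergeometric_enrichment(sim$data$study,
                                     sim$data$background,
                                     sim$data$annotations)
    sum(res$q_value < 0.05)
  }, 0)
  expect_lte(mean(sig > 0), 0.2)
})
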