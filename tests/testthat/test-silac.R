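toy_summaries <- function() {
  data.frame(
    protein_id = rep(c("A", "B", "C", "rev_D", "contam_E", "F"), each = 2),
    replicate_id = rep(1:2, 6),
    orientation = rep(c("forward", "reverse"), 6),
    median_log2_hl = rnorm(12),
    n_peptides = c(3, 3,  2, 2,  5, 1,  10, 10,  4, 4,  2, 2),
    is_contaminant = rep(c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
                         each = 2),
    is_decoy = rep(c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE), each = 2),
    stringsAsFactors = FALSE
  )
}

test_that("protein filters drop decoys, contaminants and <2-peptide ids", {
  set.seed(1)
  x <- toy_summaries()
  f <- filter_proteins(x)
  expect_setequal(unique(f$protein_id), c("A", "B", "F"))
  # boundary: exactly 2 peptides in both replicates is retained
  expect_true("B" %in% f$protein_id)
  # present in one replicate only -> removed
  y <- rbind(x, data.frame(protein_id = "G", replicate_id = 1,
                           orientation = "forward", median_log2_hl = 0.2,
                           n_peptides = 5, is_contaminant = FALSE,
                           is_decoy = FALSE))
  expect_false("G" %in% filter_proteins(y)$protein_id)
})

test_that("normalization median-centres then flips the reverse label", {
  x <- data.frame(
    protein_id = rep(letters[1:5], 2),
    replicate_id = rep(1:2, each = 5),
    orientation = rep(c("forward", "reverse"), each = 5),
    median_log2_hl = c(0.1 + c(-0.2, -0.1, 0, 0.1, 0.2),   # median 0.1
                       -0.5 + c(-0.2, -0.1, 0, 0.1, 0.2)), # median -0.5
    n_peptides = 3, is_contaminant = FALSE, is_decoy = FALSE)
  o <- normalize_and_orient(x)
  fwd <- o$oriented_log2[o$replicate_id == 1]
  rev <- o$oriented_log2[o$replicate_id == 2]
  expect_equal(median(fwd), 0, tolerance = 1e-12)
  expect_equal(median(rev), 0, tolerance = 1e-12)
  expect_equal(fwd, c(-0.2, -0.1, 0, 0.1, 0.2))
  expect_equal(rev, -c(-0.2, -0.1, 0, 0.1, 0.2))  # sign flip
  # flip twice restores centred raw values
  o2 <- o
  o2$median_log2_hl <- ifelse(o2$orientation == "reverse",
                              -o2$oriented_log2, o2$oriented_log2)
  expect_equal(normalize_and_orient(o2)$oriented_log2, o$oriented_log2)
})

test_that("a true shift appears equal-signed in both oriented replicates", {
  sim <- gen_silac_experiment(n_proteins = 500, n_shifted = 20,
                              effect_log2 = 1.5, replicate_noise_sd = 0.1,
                              seed = 3)
  o <- normalize_and_orient(filter_proteins(sim$data))
  shifted_up <- names(sim$truth$effect)[sim$truth$effect > 0]
  ok <- intersect(shifted_up, o$protein_id)
  for (id in ok[1:5]) {
    v <- o$oriented_log2[o$protein_id == id]
    expect_true(all(v > 0))
  }
})

test_that("differential testing handles degenerate proteins and calls", {
  oriented <- data.frame(
    protein_id = rep(c("const", "null", "up"), each = 2),
    oriented_log2 = c(1, 1, 0, 0, 2, 2.1))
  expect_warning(res <- differential_abundance(oriented), "1 df")
  expect_true(is.na(res$p_value[res$protein_id == "const"]))
  expect_true(is.na(res$q_value[res$protein_id == "const"]))
  expect_equal(res$call[res$protein_id == "null"], "unchanged")
  expect_equal(res$mean_log2_fc[res$protein_id == "up"], 2.05)
})

test_that("shifted-protein fold changes are recovered within 2 SE", {
  sim <- gen_silac_experiment(n_proteins = 1000, n_shifted = 30,
                              effect_log2 = 1.5, replicate_noise_sd = 0.2,
                              seed = 5)
  o <- normalize_and_orient(filter_proteins(sim$data))
  suppressWarnings(res <- differential_abundance(o))
  shifted <- intersect(sim$truth$shifted, res$protein_id)
  est <- res$mean_log2_fc[match(shifted, res$protein_id)]
  truth <- sim$truth$effect[shifted]
  se <- 0.2 / sqrt(2)
  expect_gt(mean(abs(est - truth) <= 2 * se), 0.9)
  # and the population mean is on target
  expect_lt(abs(mean(abs(est)) - 1.5), 2 * se)
})

test_that("null label-swap experiments yield zero differential calls", {
  sim <- gen_silac_experiment(n_proteins = 800, n_shifted = 0,
                              replicate_noise_sd = 0.2, seed = 8)
  o <- normalize_and_orient(filter_proteins(sim$data))
  suppressWarnings(res <- differential_abundance(o))
  expect_equal(sum(res$call != "unchanged"), 0)
})

test_that("label QC estimators implement the intensity-fraction means", {
  expect_equal(estimate_incorporation(data.frame(heavy = 99, light = 1)),
               0.99)
  expect_equal(estimate_incorporation(data.frame(heavy = 1, light = 0)), 1)
  expect_equal(estimate_incorporation(
    data.frame(heavy = c(995, 985, 0), light = c(5, 15, 0))), 0.99)
  expect_equal(estimate_proline_conversion(
    data.frame(pro6 = 6.3, pro0 = 93.7)), 0.063)
  expect_equal(estimate_proline_conversion(
    data.frame(pro6 = 0, pro0 = 50)), 0)
  expect_equal(estimate_proline_conversion(
    data.frame(pro6 = c(5, 7), pro0 = c(95, 93))), 0.06)
  expect_error(estimate_incorporation(data.frame(heavy = 0, light = 0)),
               "nonzero")
})
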