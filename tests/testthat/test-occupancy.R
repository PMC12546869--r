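make_group <- function(areas, n_phospho, sites, group = "g1",
                       sample = "s", replicate = 1) {
  data.frame(group_id = group, form_id = names(areas),
             n_phospho = n_phospho, site_labels = sites,
             area = unname(areas), sample = sample, replicate = replicate,
             stringsAsFactors = FALSE)
}

test_that("single-site occupancy is phospho over phospho plus unmodified", {
  cases <- list(list(areas = c(u = 100, p = 0), want = 0),
                list(areas = c(u = 50, p = 50), want = 0.5),
                list(areas = c(u = 25, p = 75), want = 0.75))
  for (cs in cases) {
    x <- make_group(cs$areas, c(0, 1), c("", "S1"))
    expect_equal(phospho_occupancy(x)$fraction, cs$want)
  }
})

test_that("multi-site groups share one denominator over all singly forms", {
  x <- make_group(c(u = 60, pA = 30, pB = 10), c(0, 1, 1),
                  c("", "S-A", "S-B"))
  res <- phospho_occupancy(x)
  expect_equal(res$fraction[res$form_id == "pA"], 0.30)
  expect_equal(res$fraction[res$form_id == "pB"], 0.10)
  # complement closes the composition
  expect_equal(sum(res$fraction) + 60 / 100, 1)
})

test_that("doubly phosphorylated forms are pooled separately", {
  x <- make_group(c(u = 60, pA = 30, pAB = 10), c(0, 1, 2),
                  c("", "S-A", "S-A;S-B"))
  res <- phospho_occupancy(x)
  expect_equal(res$fraction[res$form_class == "single"], 30 / 90)
  expect_equal(res$fraction[res$form_class == "multi"], 10 / 70)
  expect_equal(res$site_labels[res$form_class == "multi"], "S-A;S-B")
})

test_that("missing unmodified form and all-zero groups are handled", {
  x <- make_group(c(pA = 10), 1, "S-A")
  expect_error(phospho_occupancy(x), "no unmodified form")
  z <- make_group(c(u = 0, pA = 0), c(0, 1), c("", "S-A"))
  expect_true(is.na(phospho_occupancy(z)$fraction))
  dup <- rbind(make_group(c(u = 1, p = 1), c(0, 1), c("", "S1")),
               make_group(c(u = 1, p = 1), c(0, 1), c("", "S1")))
  expect_error(phospho_occupancy(dup), "duplicate")
})

test_that("occupancy is invariant to rescaling all areas", {
  x <- make_group(c(u = 60, pA = 30, pB = 10), c(0, 1, 1),
                  c("", "A", "B"))
  for (c_scale in c(0.001, 7, 1e6)) {
    y <- x
    y$area <- y$area * c_scale
    expect_equal(phospho_occupancy(y)$fraction,
                 phospho_occupancy(x)$fraction)
  }
})

test_that("methyl stoichiometry sums me1 forms and closes to one", {
  x <- make_methyl_records(c(me0 = 70, me1_free = 10, me1_prop = 10,
                             me2 = 5, me3 = 5))
  res <- methyl_stoichiometry(x)
  expect_equal(res$fraction[res$state == "me1"], 0.20)
  expect_equal(sum(res$fraction), 1)

  only0 <- make_methyl_records(c(me0 = 42, me1_free = 0, me1_prop = 0,
                                 me2 = 0, me3 = 0))
  expect_equal(methyl_stoichiometry(only0)$fraction, c(1, 0, 0, 0))

  unif <- make_methyl_records(c(me0 = 3, me1_free = 3, me1_prop = 3,
                                me2 = 3, me3 = 3))
  expect_equal(methyl_stoichiometry(unif)$fraction, c(0.2, 0.4, 0.2, 0.2))
})

test_that("methyl stoichiometry uses charge-3 areas unless told otherwise", {
  x3 <- make_methyl_records(c(me0 = 50, me1_free = 0, me1_prop = 0,
                              me2 = 50, me3 = 0), charge = 3)
  x2 <- make_methyl_records(c(me0 = 100, me1_free = 0, me1_prop = 0,
                              me2 = 0, me3 = 0), charge = 2)
  both <- rbind(x3, x2)
  res3 <- methyl_stoichiometry(both)
  expect_equal(res3$fraction[res3$state == "me0"], 0.5)
  res23 <- methyl_stoichiometry(both, include_charge2 = TRUE)
  expect_equal(res23$fraction[res23$state == "me0"], 150 / 200)
})

test_that("all-zero methyl replicates are flagged missing, not zero", {
  x <- make_methyl_records(c(me0 = 0, me1_free = 0, me1_prop = 0,
                             me2 = 0, me3 = 0))
  expect_true(all(is.na(methyl_stoichiometry(x)$fraction)))
  incomplete <- make_methyl_records(c(me0 = 1, me2 = 1, me3 = 1))
  expect_error(methyl_stoichiometry(incomplete), "missing form")
})

test_that("replicate summaries exclude flagged replicates from n", {
  res <- data.frame(group_id = "g", sample = "s", replicate = 1:3,
                    fraction = c(0.2, 0.4, NA))
  s <- summarize_occupancy(res, by = c("group_id", "sample"))
  expect_equal(s$mean, 0.3)
  expect_equal(s$n, 2)
  one <- summarize_occupancy(res[1, ], by = c("group_id", "sample"))
  expect_true(is.na(one$sd))
  flat <- data.frame(group_id = "g", sample = "s", replicate = 1:4,
                     fraction = rep(0.1, 4))
  sf <- summarize_occupancy(flat, by = c("group_id", "sample"))
  expect_equal(sf$mean, 0.1)
  expect_equal(sf$sd, 0)
})

test_that("occupancy recovers known truth from noisy synthetic tables", {
  for (theta in c(0.1, 0.5, 0.9)) {
    sim <- gen_xic_table(theta = theta, n_groups = 200, n_replicates = 4,
                         noise_sd = 0.2, seed = 20)
    occ <- phospho_occupancy(sim$data)
    expect_lt(abs(mean(occ$fraction) - theta), 0.05)
  }
})
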