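test_that("peptidoform notation parses positions, composites and errors", {
  p <- parse_modified_peptide(
    "K(Pr/56.03)SAPSTGGVK(Di/28.03)K(Pr/56.03)PHR")
  expect_equal(p$sequence, "KSAPSTGGVKKPHR")
  expect_equal(p$mods$position, c("1", "10", "11"))
  expect_equal(p$mods$name, c("propionyl", "dimethyl", "propionyl"))

  expect_equal(parse_modified_peptide("PEPTIDE"),
               modified_peptide("PEPTIDE"))

  comp <- parse_modified_peptide("K(Pr/56.03 + Me/14.012)SR")
  expect_equal(comp$mods$name, "propionyl-methyl")
  expect_equal(comp$mods$position, "1")

  expect_error(parse_modified_peptide("PEZTIDE"), "Z")
  expect_error(parse_modified_peptide("K(Foo/1.0)SR"), "Foo")
  expect_error(parse_modified_peptide("K(Pr/56.03SR"), "parenthes")
  expect_error(parse_modified_peptide("KR)SR"), "parenthes")
})

test_that("neutral mass sums residues, water and modification shifts", {
  expect_equal(neutral_mass(modified_peptide("G")), 75.03203,
               tolerance = 1e-7)
  expect_error(modified_peptide(""), "empty")
  p <- modified_peptide("KSAPSTGGVKKPHR", c(1, 10, 11),
                        rep("propionyl", 3))
  expect_equal(neutral_mass(p), 1616.8998, tolerance = 1e-4)
})

test_that("mass is additive in modifications to 1e-9 Da", {
  set.seed(42)
  cc <- chemical_constants()
  for (i in 1:20) {
    p <- random_peptidoform()
    bare <- modified_peptide(p$sequence)
    shift <- sum(cc$modification_masses[p$mods$name])
    if (nrow(p$mods) == 0) shift <- 0
    expect_equal(neutral_mass(p) - neutral_mass(bare), shift,
                 tolerance = 1e-9)
  }
})

test_that("precursor m/z matches the published H3K36 targets", {
  me0 <- modified_peptide("KSAPSTGGVKKPHR", c(1, 10, 11),
                          rep("propionyl", 3))
  expect_equal(precursor_mz(me0, 2), 809.45720, tolerance = 1e-3)
  expect_equal(precursor_mz(me0, 3), 539.97389, tolerance = 1e-3)
  me2 <- modified_peptide("KSAPSTGGVKKPHR", c(1, 10, 11),
                          c("propionyl", "dimethyl", "propionyl"))
  expect_equal(precursor_mz(me2, 2), 795.45974, tolerance = 1e-3)
  expect_error(precursor_mz(me0, 0), "charge")
})

test_that("m/z decreases with charge for any peptidoform", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_peptidoform()
    mzs <- vapply(1:4, function(z) precursor_mz(p, z), 0)
    expect_true(all(diff(mzs) < 0))
  }
})

test_that("tryptic digestion obeys K/R, proline and blocking rules", {
  seqs <- vapply(digest("AKRPK", digest_spec(max_missed_cleavages = 0)),
                 function(p) p$sequence, "")
  expect_equal(seqs, c("AK", "RPK"))

  seqs1 <- vapply(digest("AKRPK", digest_spec(max_missed_cleavages = 1)),
                  function(p) p$sequence, "")
  expect_setequal(seqs1, c("AK", "RPK", "AKRPK"))

  # H3 context: propionyl on K27/K36/K37 keeps 27-40 intact; K37-P38 is
  # shielded by proline anyway
  h3 <- "ATKAARKSAPSTGGVKKPHRYRPG"  # K27 at pos 7, K36 at 16, K37 at 17
  mods <- data.frame(position = c(7, 16, 17),
                     name = rep("propionyl", 3))
  prods <- digest(h3, digest_spec(max_missed_cleavages = 0), mods)
  seqs <- vapply(prods, function(p) p$sequence, "")
  expect_true("KSAPSTGGVKKPHR" %in% seqs)
  pep <- prods[[which(seqs == "KSAPSTGGVKKPHR")]]
  # protein-coordinate mods remapped to peptide coordinates
  expect_setequal(pep$mods$position, c("1", "10", "11"))
  expect_error(digest("AKZ", digest_spec()), "Z")
})

test_that("0-missed-cleavage products partition the protein", {
  set.seed(11)
  for (i in 1:10) {
    prot <- paste(sample(c("A", "K", "R", "P", "G", "S", "V"), 40,
                         replace = TRUE), collapse = "")
    prods <- digest(prot, digest_spec(max_missed_cleavages = 0))
    expect_equal(paste(vapply(prods, function(p) p$sequence, ""),
                       collapse = ""), prot)
  }
})

test_that("propionylation derivatizes free and monomethyl lysines only", {
  p <- modified_peptide("KSAPSTGGVKKPHR", 10, "methyl")
  d <- propionylate(p)
  expect_equal(ptmstoich:::.mod_name_at(d, 1), "propionyl")
  expect_equal(ptmstoich:::.mod_name_at(d, 10), "propionyl-methyl")
  expect_equal(ptmstoich:::.mod_name_at(d, 11), "propionyl")
  expect_true(is.na(ptmstoich:::.mod_name_at(d, "N-term")))

  p3 <- modified_peptide("KSAPSTGGVKKPHR", 10, "trimethyl")
  d3 <- propionylate(p3)
  expect_equal(ptmstoich:::.mod_name_at(d3, 10), "trimethyl")
  expect_equal(sum(d3$mods$name == "propionyl"), 2)

  nok <- modified_peptide("GASPV")
  expect_equal(propionylate(nok), nok)
  expect_equal(ptmstoich:::.mod_name_at(
    propionylate(nok, derivatize_nterm = TRUE), "N-term"), "propionyl")
})

test_that("parse/render round-trips generated peptidoforms", {
  set.seed(99)
  for (i in 1:25) {
    p <- random_peptidoform()
    expect_equal(parse_modified_peptide(render_modified_peptide(p)), p)
  }
})

test_that("constants can be overridden from a key = value config", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# test", "mymod = 100.5", "propionyl=56.026215"), f)
  cc <- chemical_constants(overrides = f)
  expect_equal(cc$modification_masses[["mymod"]], 100.5)
  p <- modified_peptide("GK", 2, "mymod")
  expect_equal(neutral_mass(p, cc),
               neutral_mass(modified_peptide("GK")) + 100.5)
})
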