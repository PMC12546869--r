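#' Derive a child seed from a root seed
#'
#' Generators fan a single root seed out to per-scenario child seeds by a
#' fixed counter scheme, so partial re-runs of one scenario reproduce the
#' same data as a full run. The child seed stays below 2^31 - 1.
#'
#' @param seed root seed (integer).
#' @param k scenario counter (integer >= 0).
#' @return integer child seed.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k)) %% 2147483647)
}

#' Synthetic XIC table with known phosphosite occupancies
#'
#' Emulates a label-free phosphopeptide quantification export: per group a
#' base abundance is drawn lognormally, split between the unmodified form
#' and the phosphorylated form(s) according to the true occupancy, and
#' perturbed by multiplicative lognormal noise (intensities are positive
#' and noise scales with signal). Optionally, a fraction of groups is
#' duplicated as a missed-cleavage variant (an independent group with the
#' same truth), and in multi-site groups a fraction of phospho forms
#' co-elute into a single row with pooled site labels.
#'
#' @param theta true occupancies in `[0, 1)`, recycled over `n_groups`;
#'   in multi-site groups each site carries occupancy `theta` (so
#'   `n_sites * theta < 1` is required).
#' @param n_groups number of quantification groups.
#' @param n_replicates replicates per sample.
#' @param noise_sd sd of the lognormal noise on the log scale.
#' @param n_sites phosphosites per group (1 or 2).
#' @param missed_cleavage_fraction fraction of groups duplicated as an
#'   independent missed-cleavage group.
#' @param coelute_fraction fraction of multi-site groups whose phospho
#'   forms co-elute into one pooled row.
#' @param base_area_meanlog,base_area_sdlog lognormal parameters of the
#'   per-group base abundance.
#' @param sample sample label.
#' @param seed root seed.
#' @return list with `data` (an XIC record table for
#'   [phospho_occupancy()]) and `truth` (scenario id, seed, per-group true
#'   occupancies).
#' @export
gen_xic_table <- function(theta, n_groups = 200, n_replicates = 4,
                          noise_sd = 0.2, n_sites = 1,
                          missed_cleavage_fraction = 0,
                          coelute_fraction = 0,
                          base_area_meanlog = log(1e6),
                          base_area_sdlog = 1, sample = "cond1",
                          seed = 1) {
  stopifnot(all(theta >= 0), all(theta * n_sites < 1), noise_sd >= 0,
            n_sites %in% c(1L, 2L))
  set.seed(child_seed(seed, 1L))
  theta <- rep_len(theta, n_groups)
  group_ids <- sprintf("g%04d", seq_len(n_groups))
  mc <- stats::runif(n_groups) < missed_cleavage_fraction
  coel <- n_sites == 2L & stats::runif(n_groups) < coelute_fraction

  rows <- list()
  emit_group <- function(gid, th) {
    base <- stats::rlnorm(1, base_area_meanlog, base_area_sdlog)
    for (r in seq_len(n_replicates)) {
      fracs <- c(unmod = 1 - n_sites * th, rep(th, n_sites))
      noise <- stats::rlnorm(length(fracs), 0, noise_sd)
      areas <- base * fracs * noise
      if (n_sites == 2L && coel[[match(sub("_mc1$", "", gid),
                                       group_ids)]]) {
        rows[[length(rows) + 1L]] <<- data.frame(
          group_id = gid, form_id = c("unmod", "pAB"),
          n_phospho = c(0L, 1L), site_labels = c("", "SA;SB"),
          area = c(areas[[1L]], sum(areas[-1L])), sample = sample,
          replicate = r, stringsAsFactors = FALSE)
      } else {
        forms <- c("unmod", paste0("p", LETTERS[seq_len(n_sites)]))
        labels <- c("", paste0("S", LETTERS[seq_len(n_sites)]))
        rows[[length(rows) + 1L]] <<- data.frame(
          group_id = gid, form_id = forms,
          n_phospho = c(0L, rep(1L, n_sites)), site_labels = labels,
          area = areas, sample = sample, replicate = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  for (i in seq_len(n_groups)) {
    emit_group(group_ids[[i]], theta[[i]])
    if (mc[[i]]) emit_group(paste0(group_ids[[i]], "_mc1"), theta[[i]])
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  truth_groups <- c(group_ids,
                    if (any(mc)) paste0(group_ids[mc], "_mc1"))
  truth_theta <- c(theta, theta[mc])
  list(data = data,
       truth = list(scenario = "xic_occupancy", seed = seed,
                    n_sites = n_sites, noise_sd = noise_sd,
                    occupancy = stats::setNames(truth_theta, truth_groups)))
}

#' Synthetic SILAC label-swap experiment
#'
#' Forward replicate: mutant heavy, so the protein-level log2 H/L ratio is
#' `truth + offset + noise`. Reverse replicate: wildtype heavy, so the raw
#' ratio is `-truth + offset + noise`. A global additive mixing offset is
#' injected per replicate so median-centring normalization is exercised.
#' Shifted proteins get effect `+/- effect_log2` (half each sign);
#' contaminant/decoy rows and a few single-peptide rows are planted so the
#' identification filters have work to do.
#'
#' @param n_proteins number of genuine proteins.
#' @param n_shifted number of truly shifted proteins.
#' @param effect_log2 absolute true log2 fold change of shifted proteins.
#' @param replicate_noise_sd sd of the per-replicate ratio noise.
#' @param mixing_offsets named numeric, additive offsets injected into the
#'   forward and reverse replicates.
#' @param contaminant_fraction fraction of extra contaminant/decoy rows.
#' @param low_peptide_fraction fraction of genuine proteins planted with a
#'   single peptide in one replicate.
#' @param seed root seed.
#' @return list with `data` (protein summaries for [filter_proteins()])
#'   and `truth` (shifted protein ids and their effects).
#' @export
gen_silac_experiment <- function(n_proteins = 3000, n_shifted = 50,
                                 effect_log2 = 1.5,
                                 replicate_noise_sd = 0.2,
                                 mixing_offsets = c(forward = 0.3,
                                                    reverse = -0.3),
                                 contaminant_fraction = 0.01,
                                 low_peptide_fraction = 0.01,
                                 seed = 1) {
  stopifnot(n_shifted <= n_proteins)
  set.seed(child_seed(seed, 2L))
  ids <- sprintf("P%05d", seq_len(n_proteins))
  effect <- numeric(n_proteins)
  if (n_shifted > 0L) {
    sign_up <- rep(c(1, -1), length.out = n_shifted)
    effect[seq_len(n_shifted)] <- sign_up * effect_log2
  }
  n_pep <- 2L + stats::rpois(n_proteins, 4)
  low <- stats::runif(n_proteins) < low_peptide_fraction

  make_rep <- function(rep_id, orientation) {
    sign <- if (orientation == "forward") 1 else -1
    off <- mixing_offsets[[orientation]]
    npep <- n_pep
    if (rep_id == 2L) npep[low] <- 1L
    data.frame(
      protein_id = ids, replicate_id = rep_id, orientation = orientation,
      median_log2_hl = sign * effect + off +
        stats::rnorm(n_proteins, 0, replicate_noise_sd),
      n_peptides = npep, is_contaminant = FALSE, is_decoy = FALSE,
      stringsAsFactors = FALSE)
  }
  fwd <- make_rep(1L, "forward")
  rev <- make_rep(2L, "reverse")

  n_junk <- ceiling(contaminant_fraction * n_proteins)
  if (n_junk > 0L) {
    junk_ids <- c(sprintf("contam_C%03d", seq_len(n_junk)),
                  sprintf("rev_D%03d", seq_len(n_junk)))
    junk <- do.call(rbind, lapply(1:2, function(r) {
      data.frame(protein_id = junk_ids, replicate_id = r,
                 orientation = c("forward", "reverse")[[r]],
                 median_log2_hl = stats::rnorm(length(junk_ids), 0, 1),
                 n_peptides = 2L + stats::rpois(length(junk_ids), 4),
                 is_contaminant = startsWith(junk_ids, "contam_"),
                 is_decoy = startsWith(junk_ids, "rev_"),
                 stringsAsFactors = FALSE)
    }))
  } else {
    junk <- NULL
  }
  data <- rbind(fwd, rev, junk)
  rownames(data) <- NULL
  list(data = data,
       truth = list(scenario = "silac_label_swap", seed = seed,
                    effect = stats::setNames(effect, ids),
                    shifted = ids[effect != 0],
                    mixing_offsets = mixing_offsets,
                    replicate_noise_sd = replicate_noise_sd))
}

#' Synthetic microplate growth curves
#'
#' Logistic curves whose exponential-phase rate corresponds to the given
#' doubling times, sampled on a fixed interval, with multiplicative
#' lognormal noise. A zero rate (infinite doubling time, `NA` or `Inf`)
#' produces a flat non-growing curve.
#'
#' @param doubling_min vector of true doubling times in minutes (one curve
#'   each; `NA`/`Inf` = non-growing).
#' @param od0 inoculation OD600.
#' @param carrying_capacity plateau OD600.
#' @param lag_min lag phase duration in minutes (OD stays at `od0`).
#' @param noise_sd sd of multiplicative lognormal noise on the log scale.
#' @param sampling_interval minutes between reads.
#' @param duration_min total assay duration in minutes.
#' @param strain,condition labels attached to every curve.
#' @param seed root seed.
#' @return list with `data` (long-format table for [fit_doubling_times()])
#'   and `truth` (true doubling time per well).
#' @export
gen_growth_curves <- function(doubling_min, od0 = 0.1,
                              carrying_capacity = 1.2, lag_min = 0,
                              noise_sd = 0, sampling_interval = 10,
                              duration_min = 1500, strain = "wt",
                              condition = "0M", seed = 1) {
  set.seed(child_seed(seed, 3L))
  times <- seq(0, duration_min, by = sampling_interval)
  rows <- list()
  wells <- sprintf("W%02d", seq_along(doubling_min))
  for (i in seq_along(doubling_min)) {
    dbl <- doubling_min[[i]]
    if (is.na(dbl) || !is.finite(dbl) || dbl <= 0) {
      od <- rep(od0, length(times))
    } else {
      r <- log(2) / dbl
      t_eff <- pmax(times - lag_min, 0)
      K <- carrying_capacity
      od <- K * od0 * exp(r * t_eff) / (K + od0 * (exp(r * t_eff) - 1))
    }
    if (noise_sd > 0) od <- od * stats::rlnorm(length(od), 0, noise_sd)
    rows[[i]] <- data.frame(time_min = times, od600 = od,
                            well = wells[[i]], strain = strain,
                            condition = condition, replicate = i,
                            stringsAsFactors = FALSE)
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  list(data = data,
       truth = list(scenario = "growth_curves", seed = seed,
                    doubling_min = stats::setNames(doubling_min, wells),
                    od0 = od0, carrying_capacity = carrying_capacity,
                    lag_min = lag_min, noise_sd = noise_sd))
}

#' Synthetic five-form methyl-state XIC profiles
#'
#' Generates XIC areas for the five chemical forms of a monitored lysine
#' (me0, the two me1 forms, me2, me3) from a true state distribution, with
#' multiplicative lognormal noise, in the shape consumed by
#' [methyl_stoichiometry()].
#'
#' @param probs numeric vector of length 4 (`me0`..`me3`) summing to 1, or
#'   a named list of such vectors (one per condition/sample).
#' @param me1_split fraction of the me1 state in the underivatized
#'   (`me1_free`) chemical form.
#' @param n_replicates replicates per sample.
#' @param noise_sd sd of lognormal noise on the log scale.
#' @param base_area mean total area per replicate.
#' @param seed root seed.
#' @return list with `data` (XIC table, `charge = 3`) and `truth`.
#' @export
gen_methyl_profiles <- function(probs, me1_split = 0.5, n_replicates = 3,
                                noise_sd = 0.2, base_area = 1e6,
                                seed = 1) {
  if (!is.list(probs)) probs <- list(cond1 = probs)
  for (pr in probs) {
    stopifnot(length(pr) == 4L, all(pr >= 0))
    if (abs(sum(pr) - 1) > 1e-8) stop("state distribution must sum to 1")
  }
  stopifnot(me1_split >= 0, me1_split <= 1)
  set.seed(child_seed(seed, 4L))
  rows <- list()
  for (cond in names(probs)) {
    pr <- probs[[cond]]
    form_frac <- c(me0 = pr[[1L]], me1_free = pr[[2L]] * me1_split,
                   me1_prop = pr[[2L]] * (1 - me1_split), me2 = pr[[3L]],
                   me3 = pr[[4L]])
    for (r in seq_len(n_replicates)) {
      noise <- stats::rlnorm(5L, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        form_id = names(form_frac), area = base_area * form_frac * noise,
        sample = cond, replicate = r, charge = 3L,
        stringsAsFactors = FALSE)
    }
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  list(data = data,
       truth = list(scenario = "methyl_profiles", seed = seed,
                    probs = probs, me1_split = me1_split,
                    noise_sd = noise_sd))
}

#' Synthetic gene/term universe with planted enrichment
#'
#' Builds a background of `n_genes` genes annotated to `n_terms` terms of
#' size `term_size` (sampled uniformly), then draws a study set in which
#' genes annotated to the first `n_planted` terms are over-represented at
#' the given odds ratio (weighted sampling without replacement).
#'
#' @param n_genes background size.
#' @param n_terms number of annotation terms.
#' @param term_size genes per term.
#' @param n_planted number of terms with planted enrichment.
#' @param odds_ratio sampling-weight ratio of planted-term genes.
#' @param study_size study-set size.
#' @param seed root seed.
#' @return list with `data` (list: `study`, `background`, `annotations`)
#'   and `truth` (planted term ids).
#' @export
gen_enrichment_universe <- function(n_genes = 6000, n_terms = 50,
                                    term_size = 20, n_planted = 1,
                                    odds_ratio = 10, study_size = 100,
                                    seed = 1) {
  stopifnot(term_size <= n_genes, n_planted <= n_terms,
            study_size <= n_genes)
  set.seed(child_seed(seed, 5L))
  genes <- sprintf("Y%04d", seq_len(n_genes))
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  ann <- do.call(rbind, lapply(seq_len(n_terms), function(i) {
    data.frame(gene = sample(genes, term_size), term = terms[[i]],
               stringsAsFactors = FALSE)
  }))
  planted_terms <- terms[seq_len(n_planted)]
  planted_genes <- unique(ann$gene[ann$term %in% planted_terms])
  w <- rep(1, n_genes)
  w[genes %in% planted_genes] <- odds_ratio
  study <- sample(genes, study_size, prob = w)
  list(data = list(study = study, background = genes, annotations = ann),
       truth = list(scenario = "enrichment_universe", seed = seed,
                    planted_terms = planted_terms,
                    odds_ratio = odds_ratio))
}

#' Persist a synthetic scenario beside its ground truth
#'
#' Writes the generated table(s) as CSV and the truth as JSON into `dir`,
#' prefixed with `name`. Regeneration with the same seed is byte-identical.
#'
#' @param scenario a list with `data` and `truth`, from any generator.
#' @param dir output directory (created if needed).
#' @param name file-name prefix.
#' @return character vector of the written paths, invisibly.
#' @export
write_scenario <- function(scenario, dir, name) {
  stopifnot(all(c("data", "truth") %in% names(scenario)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  data <- scenario$data
  if (is.data.frame(data)) data <- list(data = data)
  for (nm in names(data)) {
    d <- data[[nm]]
    path <- file.path(dir, paste0(name, "_", nm, ".csv"))
    if (is.data.frame(d)) {
      utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
    } else {
      writeLines(as.character(d), path)
    }
    paths <- c(paths, path)
  }
  truth_path <- file.path(dir, paste0(name, "_truth.json"))
  jsonlite::write_json(scenario$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, truth_path))
}
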