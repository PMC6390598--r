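#' One-stop variant calling for a library
#'
#' Runs the full per-library pipeline on a read tibble: amplicon
#' assignment, then either barcode-family consensus (MBS arm) or the raw
#' read pileup (without-MBS arm), then variant calling.
#'
#' @param reads Read tibble.
#' @param panel An `mbs_panel`.
#' @param arm `"mbs"` or `"raw"`.
#' @param sample_id Sample identifier for the calls.
#' @param min_family_size,min_agreement Consensus parameters (MBS arm).
#' @param min_af,min_alt_support Calling thresholds.
#' @param max_mismatch Assignment threshold.
#' @param aligned Optionally, a precomputed [assign_reads()] result to
#'   share between arms.
#' @return A call tibble (see [call_variants()]).
#' @export
call_sample <- function(reads, panel, arm = c("mbs", "raw"),
                        sample_id = reads$sample_id[1],
                        min_family_size = 2, min_agreement = 0.7,
                        min_af = 0.5, min_alt_support = 3,
                        max_mismatch = 0.2, aligned = NULL) {
  arm <- match.arg(arm)
  if (is.null(aligned)) aligned <- assign_reads(reads, panel, max_mismatch)
  if (nrow(aligned) == 0) {
    return(tibble::tibble(
      sample_id = character(0), arm = character(0), contig = character(0),
      pos = integer(0), ref = character(0), alt = character(0),
      label = character(0), class = character(0),
      alt_support = integer(0), depth = integer(0), af = numeric(0)
    ))
  }
  pile <- if (arm == "mbs") {
    consensus_pileup(
      consensus_families(aligned, min_family_size, min_agreement), panel
    )
  } else {
    raw_pileup(aligned, panel)
  }
  call_variants(pile, panel, arm = arm, sample_id = sample_id,
                min_af = min_af, min_alt_support = min_alt_support)
}

#' Default technical-replicate sample profiles
#'
#' Six ground-truth profiles with two hotspot variants each, all at true
#' fractions of at least 5%, spanning the EGFR exon 18/20/21 amplicons.
#' These are the study conditions of the bundled replicate experiment.
#'
#' @param panel An `mbs_panel` containing the EGFR ex18/ex20/ex21
#'   amplicons.
#' @return A list of six sample-profile tibbles.
#' @export
default_replicate_profiles <- function(panel) {
  specs <- list(
    R1 = c(L858R = 0.50, T790M = 0.10),
    R2 = c(L858R = 0.11, E709G = 0.066),
    R3 = c(G719S = 0.309, R776H = 0.481),
    R4 = c(G719A = 0.194, L861Q = 0.659),
    R5 = c(L858R = 0.066, E709G = 0.068),
    R6 = c(G719S = 0.118, T790M = 0.05)
  )
  purrr::imap(specs, function(s, id) make_sample_profile(s, panel, id))
}

# a random substitution site on the panel avoiding the given 0-based
# genomic positions (truth variants), drawn from the ambient RNG
random_artifact_site <- function(panel, avoid_pos = integer(0)) {
  repeat {
    ai <- sample.int(nrow(panel$amplicons), 1L)
    amp <- panel$amplicons[ai, ]
    local <- sample.int(amp$end - amp$start, 1L) - 1L
    pos <- amp$start + local
    if (pos %in% avoid_pos) next
    ref <- substr(amp$sequence, local + 1L, local + 1L)
    return(tibble::tibble(contig = amp$contig, pos = pos, ref = ref,
                          alt = sample(setdiff(DNA_BASES, ref), 1L)))
  }
}

#' Simulate and compare technical replicate libraries
#'
#' Runs the replicate-library experiment end to end for one seed: for each
#' sample, two libraries are simulated independently from the same
#' ground-truth profile, singleton artifact sites are injected privately
#' into one library each (at family size one, so barcode consensus can
#' reject them), and both arms are called and compared through
#' matched/orphan bookkeeping.
#'
#' @param seed Integer seed for the whole experiment.
#' @param panel Panel to sequence; default is the EGFR ex18/ex20/ex21
#'   subset of [build_default_panel()].
#' @param profiles List of sample profiles; default
#'   [default_replicate_profiles()].
#' @param config A [sim_config()]; defaults are the experiment's study
#'   conditions (2,000 molecules/amplicon, sequencing error 0.005/base,
#'   PCR error 1e-4).
#' @param artifacts_per_sample Number of singleton artifact sites injected
#'   per sample (distributed randomly over its two libraries).
#' @param artifact_rate Artifact support as a fraction of the library's
#'   read pairs at the amplicon.
#' @param arms Arms to evaluate.
#' @param min_family_size,min_agreement,min_af,min_alt_support Pipeline
#'   parameters.
#' @return A tibble with one row per sample and arm: seed, sample_id, arm,
#'   matched, orphan, reproducibility, af_r2.
#' @export
replication_experiment <- function(seed,
                                   panel = NULL,
                                   profiles = NULL,
                                   config = sim_config(),
                                   artifacts_per_sample = 4,
                                   artifact_rate = 0.01,
                                   arms = c("mbs", "raw"),
                                   min_family_size = 2, min_agreement = 0.7,
                                   min_af = 0.5, min_alt_support = 3) {
  if (is.null(panel)) {
    panel <- panel_subset(build_default_panel(),
                          c("EGFR_ex18", "EGFR_ex20", "EGFR_ex21"))
  }
  if (is.null(profiles)) profiles <- default_replicate_profiles(panel)
  withr::with_seed(seed, {
    purrr::map_dfr(profiles, function(profile) {
      libs <- purrr::map(1:2, function(l) {
        mol <- simulate_molecules(profile, panel, config)
        amplify_and_sequence(mol, config)
      })
      if (artifacts_per_sample > 0 && artifact_rate > 0) {
        for (k in seq_len(artifacts_per_sample)) {
          site <- random_artifact_site(panel, avoid_pos = profile$pos)
          libs <- inject_artifact(libs, panel, site, mode = "singleton",
                                  rate = artifact_rate)
        }
      }
      aligned <- purrr::map(libs, assign_reads, panel = panel)
      purrr::map_dfr(arms, function(arm) {
        cs <- purrr::map(1:2, function(l) {
          call_sample(libs[[l]], panel, arm = arm,
                      sample_id = profile$sample_id[1],
                      min_family_size = min_family_size,
                      min_agreement = min_agreement,
                      min_af = min_af, min_alt_support = min_alt_support,
                      aligned = aligned[[l]])
        })
        pair <- match_replicates(cs[[1]], cs[[2]])
        g <- glance(pair)
        tibble::add_column(g, seed = seed, .before = 1)
      })
    })
  })
}

#' Replicate reproducibility across seeds
#'
#' Repeats [replication_experiment()] over a vector of seeds and returns
#' the per-seed, per-sample, per-arm reproducibility table.
#'
#' @param seeds Integer vector of seeds.
#' @param ... Passed to [replication_experiment()].
#' @return A tibble as from [replication_experiment()], stacked over seeds.
#' @export
replication_study <- function(seeds, ...) {
  purrr::map_dfr(seeds, replication_experiment, ...)
}

#' Allele-fraction recovery experiment
#'
#' Simulates one MBS library per seed carrying truth variants at the given
#' fractions and measures each variant's consensus-family allele frequency
#' directly from the pileup (no calling threshold), for comparison with the
#' binomial sampling error.
#'
#' @param seeds Integer vector of seeds.
#' @param fractions Named numeric vector mapping hotspot labels to true
#'   molecule fractions.
#' @param config A [sim_config()].
#' @param panel Panel; defaults to the amplicons carrying `fractions`.
#' @return A tibble: seed, label, fraction, alt_support, depth, af.
#' @export
recovery_experiment <- function(seeds,
                                fractions = c(L861Q = 0.005, E709G = 0.037,
                                              G719S = 0.11, L858R = 0.5),
                                config = sim_config(),
                                panel = NULL) {
  full <- build_default_panel()
  profile0 <- make_sample_profile(fractions, full, "RC")
  if (is.null(panel)) panel <- panel_subset(full, unique(profile0$amplicon))
  purrr::map_dfr(seeds, function(s) {
    withr::with_seed(s, {
      profile <- make_sample_profile(fractions, panel, "RC")
      mol <- simulate_molecules(profile, panel, config)
      reads <- amplify_and_sequence(mol, config)
      cons <- consensus_families(assign_reads(reads, panel))
      pile <- consensus_pileup(cons, panel)
      purrr::map_dfr(seq_len(nrow(profile)), function(i) {
        v <- profile[i, ]
        row <- pile[pile$contig == v$contig &
                      pile$pos == (if (!is.na(v$del_len)) v$pos + 1L else v$pos), ]
        support <- if (!is.na(v$del_len)) row$del else row[[v$alt]]
        tibble::tibble(seed = s, label = v$label, fraction = v$fraction,
                       alt_support = support, depth = row$depth,
                       af = allele_frequency(support, row$depth))
      })
    })
  })
}

#' Cohort-scale artifact-reduction experiment
#'
#' Simulates a cohort sequenced with and without molecular barcoding,
#' injects one systematic artifact site (present in strictly more than
#' half of the samples) and several singleton artifact sites, filters
#' systematic sites per arm, and tabulates the artifact census.
#'
#' @param seed Integer seed.
#' @param n_samples Cohort size.
#' @param config A [sim_config()] (scaled-down defaults are fine).
#' @param panel Panel; default EGFR ex18 + ex21 subset.
#' @param n_singleton Number of singleton artifact sites injected.
#' @param artifact_rate Injection rate (fraction of amplicon read pairs).
#' @return A list: `census` (an `artifact_census`), `systematic` (sites
#'   removed by the cohort filter, per arm), `raw_calls`, `mbs_calls`,
#'   `truth`.
#' @export
artifact_reduction_experiment <- function(seed, n_samples = 28,
                                          config = sim_config(
                                            molecules_per_amplicon = 300L
                                          ),
                                          panel = NULL,
                                          n_singleton = 6,
                                          artifact_rate = 0.01) {
  if (is.null(panel)) {
    panel <- panel_subset(build_default_panel(), c("EGFR_ex18", "EGFR_ex21"))
  }
  withr::with_seed(seed, {
    labels <- panel$catalog$label
    profiles <- purrr::map(seq_len(n_samples), function(i) {
      k <- sample(1:2, 1L)
      f <- stats::runif(k, 0.05, 0.5)
      names(f) <- sample(labels, k)
      make_sample_profile(f, panel, sprintf("C%02d", i))
    })
    libs <- purrr::map(profiles, function(p) {
      amplify_and_sequence(simulate_molecules(p, panel, config), config)
    })
    truth_pos <- unique(unlist(purrr::map(profiles, "pos")))
    sys_site <- random_artifact_site(panel, avoid_pos = truth_pos)
    libs <- inject_artifact(libs, panel, sys_site, mode = "systematic",
                            rate = artifact_rate)
    single_sites <- purrr::map(seq_len(n_singleton), function(k) {
      site <- random_artifact_site(panel,
                                   avoid_pos = c(truth_pos, sys_site$pos))
      libs <<- inject_artifact(libs, panel, site, mode = "singleton",
                               rate = artifact_rate)
      site
    })
    aligned <- purrr::map(libs, assign_reads, panel = panel)
    calls_arm <- function(arm) {
      dplyr::bind_rows(purrr::map(seq_len(n_samples), function(i) {
        call_sample(libs[[i]], panel, arm = arm,
                    sample_id = profiles[[i]]$sample_id[1],
                    aligned = aligned[[i]])
      }))
    }
    raw <- filter_systematic(calls_arm("raw"), n_samples = n_samples)
    mbs <- filter_systematic(calls_arm("mbs"), n_samples = n_samples)
    truth <- dplyr::bind_rows(profiles)
    list(
      census = artifact_census(raw$calls, mbs$calls, truth = truth),
      systematic = dplyr::bind_rows(raw$systematic, mbs$systematic),
      raw_calls = raw$calls, mbs_calls = mbs$calls, truth = truth,
      systematic_site = sys_site,
      singleton_sites = dplyr::bind_rows(single_sites)
    )
  })
}

#' Cohort statistics report
#'
#' Applies the statistics layer to the bundled (or user-supplied) cohort
#' tables: exact Fisher 2x2 for two-level characteristics, the
#' Freeman-Halton exact test (plus Pearson chi-square) for r x 2 tables,
#' and pooled t-tests for the mean +/- SD rows.
#'
#' @param characteristics Tibble as [cohort_characteristics()].
#' @param summaries Tibble as [cohort_group_summaries()].
#' @return A tibble: parameter, method, statistic, p_value.
#' @export
cohort_stats_report <- function(characteristics = cohort_characteristics(),
                                summaries = cohort_group_summaries()) {
  cat_rows <- purrr::map_dfr(unique(characteristics$parameter), function(p) {
    sub <- characteristics[characteristics$parameter == p, ]
    m <- as.matrix(sub[, c("compound", "single")])
    rownames(m) <- sub$level
    if (nrow(m) == 2) {
      ht <- fisher_exact_2x2(m)
      tibble::tibble(parameter = p, method = "fisher_2x2",
                     statistic = NA_real_, p_value = ht$p.value)
    } else {
      fh <- freeman_halton_test(m)
      cq <- chisq_rxc(m)
      tibble::tibble(
        parameter = p,
        method = c("freeman_halton", "chi_square"),
        statistic = c(NA_real_, unname(cq$statistic)),
        p_value = c(fh$p.value, cq$p.value)
      )
    }
  })
  sum_rows <- purrr::map_dfr(unique(summaries$parameter), function(p) {
    sub <- summaries[summaries$parameter == p, ]
    stopifnot(nrow(sub) == 2)
    ht <- t_test_summary(sub$n[1], sub$mean[1], sub$sd[1],
                         sub$n[2], sub$mean[2], sub$sd[2])
    tibble::tibble(parameter = p, method = "t_test_summary",
                   statistic = unname(ht$statistic), p_value = ht$p.value)
  })
  dplyr::bind_rows(cat_rows, sum_rows)
}
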