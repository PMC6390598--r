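test_that("reads assign to their amplicon; garbage is dropped and counted", {
  panel <- build_default_panel()
  amp <- panel$amplicons[panel$amplicons$name == "EGFR_ex20", ]
  good <- tibble::tibble(
    sample_id = "a", read_id = "r1", barcode = "AAAACCCC",
    mate1 = substr(amp$sequence, 1, 100),
    mate2 = mbscall:::revcomp(substr(amp$sequence, 51, 150)),
    origin = "m1"
  )
  al <- assign_reads(good, panel)
  expect_equal(al$amplicon, "EGFR_ex20")
  expect_equal(al$mismatches, 0L)
  expect_equal(attr(al, "n_unassigned"), 0L)
  # error-free full pair covers the whole amplicon with no ambiguity
  expect_identical(al$aligned, amp$sequence)

  junk <- good
  junk$mate1 <- withr::with_seed(1, mbscall:::random_dna(1, 100))
  junk$mate2 <- withr::with_seed(2, mbscall:::random_dna(1, 100))
  al2 <- assign_reads(junk, panel)
  expect_equal(nrow(al2), 0)
  expect_equal(attr(al2, "n_unassigned"), 1L)
})

test_that("exon-19 deletion reads align gapped with deletion marks", {
  panel <- build_default_panel()
  prof <- make_sample_profile(c(ex19del = 1), panel)
  amp <- panel$amplicons[panel$amplicons$name == "EGFR_ex19", ]
  hap <- mbscall:::apply_variants(amp$sequence, amp$start, prof)
  reads <- tibble::tibble(
    sample_id = "d", read_id = "r1", barcode = "ACGTACGT",
    mate1 = substr(hap, 1, 100),
    mate2 = mbscall:::revcomp(substr(hap, nchar(hap) - 99, nchar(hap))),
    origin = "m1"
  )
  al <- assign_reads(reads, panel)
  expect_equal(al$amplicon, "EGFR_ex19")
  expect_equal(al$indel, "ex19del")
  expect_equal(al$mismatches, 0L)
  # local positions 50..64 marked deleted, everything else matches
  expect_identical(substr(al$aligned, 51, 65), strrep("-", 15))
  expect_identical(gsub("-", "", al$aligned), hap)
})

test_that("family grouping partitions reads by (barcode, amplicon)", {
  al <- make_aligned(rep("ACGT", 10),
                     barcode = rep(c("BB1", "BB2"), c(6, 4)))
  fams <- family_table(group_families(al))
  expect_equal(sort(fams$size), c(4, 6))

  # same barcode on two amplicons forms two families
  al2 <- make_aligned(rep("ACGT", 4), barcode = "BB1",
                      amplicon = rep(c("ampA", "ampB"), each = 2))
  expect_equal(nrow(family_table(group_families(al2))), 2)

  # partition law
  g <- group_families(al)
  expect_equal(sum(family_table(g)$size), nrow(al))
})

test_that("family count tracks molecules with at least one read", {
  panel <- tiny_panel("EGFR_ex18")
  cfg <- sim_config(molecules_per_amplicon = 300L, reads_mean = 2)
  prof <- make_sample_profile(c(G719S = 0.3), panel)
  lib <- quick_library(prof, panel, cfg, seed = 51)
  al <- assign_reads(lib$reads, panel)
  n_fam <- nrow(family_table(group_families(al)))
  n_mol_seen <- dplyr::n_distinct(lib$reads$origin)
  # exact up to rare barcode collisions
  expect_lt(abs(n_fam - n_mol_seen), 3)
})

test_that("majority consensus removes minority errors; ties are ambiguous", {
  truth <- strrep("ACGT", 10)
  bad <- truth
  substr(bad, 7, 7) <- "T"
  al <- make_aligned(c(rep(truth, 4), bad), barcode = "BB1")
  cons <- consensus_families(al, min_family_size = 2)
  expect_equal(nrow(cons), 1)
  expect_identical(cons$consensus, truth)

  # the raw arm still sees the error once
  panel_like <- structure(list(
    amplicons = tibble::tibble(name = "ampA", contig = "c1", start = 0L,
                               end = nchar(truth), sequence = truth),
    catalog = tibble::tibble(label = character(0), class = character(0),
                             amplicon = character(0), contig = character(0),
                             pos = integer(0), ref = character(0),
                             alt = character(0), del_start = integer(0),
                             del_len = integer(0))
  ), class = "mbs_panel")
  rp <- raw_pileup(al, panel_like)
  expect_equal(rp$T[7], 1L)
  cp <- consensus_pileup(cons, panel_like)
  expect_equal(cp$T[7], 0L)

  # 1-vs-1 disagreement is below the 0.7 agreement bar
  al2 <- make_aligned(c(truth, bad), barcode = "BB2")
  cons2 <- consensus_families(al2, min_family_size = 2)
  expect_identical(substr(cons2$consensus, 7, 7), "N")
  expect_identical(substr(cons2$consensus, 1, 6), substr(truth, 1, 6))

  # agreement exactly at the threshold is kept (>=, not >)
  al3 <- make_aligned(c(rep(truth, 7), rep(bad, 3)), barcode = "BB3")
  cons3 <- consensus_families(al3, min_agreement = 0.7)
  expect_identical(substr(cons3$consensus, 7, 7), substr(truth, 7, 7))
})

test_that("small families are rejected and counted; one consensus per family", {
  al <- make_aligned(rep("AAAA", 5),
                     barcode = c("B1", "B1", "B1", "B2", "B3"))
  cons <- consensus_families(al, min_family_size = 2)
  expect_equal(nrow(cons), 1)
  expect_equal(attr(cons, "n_rejected"), 2L)
  cons1 <- consensus_families(al, min_family_size = 1)
  expect_equal(nrow(cons1), 3)
  expect_equal(attr(cons1, "n_rejected"), 0L)
})

test_that("error-free consensus reproduces every origin haplotype", {
  panel <- tiny_panel(c("EGFR_ex18", "EGFR_ex19"))
  cfg <- sim_config(molecules_per_amplicon = 150L, pcr_error_rate = 0,
                    seq_error_rate = 0, reads_mean = 3)
  prof <- make_sample_profile(c(G719S = 0.4, ex19del = 0.3), panel)
  lib <- quick_library(prof, panel, cfg, seed = 61)
  al <- assign_reads(lib$reads, panel)
  cons <- consensus_families(al, min_family_size = 1)
  mol <- lib$molecules[match(cons$barcode, lib$molecules$barcode), ]
  expect_identical(gsub("-", "", cons$consensus), mol$haplotype)

  # allele-fraction recovery: family-level fraction equals molecule-level
  # fraction among sequenced molecules (same denominator)
  seen <- lib$molecules[lib$molecules$molecule_id %in% lib$reads$origin, ]
  seen18 <- seen[seen$amplicon == "EGFR_ex18", ]
  frac_mol <- mean(grepl("G719S", seen18$variants))
  pile <- consensus_pileup(cons, panel)
  v <- make_sample_profile(c(G719S = 0.4), panel)
  row <- pile[pile$pos == v$pos, ]
  expect_equal(row[[v$alt]] / row$depth, frac_mol)
})

test_that("MBS depth equals retained family count at covered positions", {
  panel <- tiny_panel("EGFR_ex18")
  cfg <- sim_config(molecules_per_amplicon = 120L, reads_mean = 4)
  prof <- make_sample_profile(c(G719S = 0.2), panel)
  lib <- quick_library(prof, panel, cfg, seed = 71)
  cons <- consensus_families(assign_reads(lib$reads, panel))
  pile <- consensus_pileup(cons, panel)
  # interior positions are covered by every retained family
  mid <- pile[pile$pos == panel$amplicons$start + 75, ]
  expect_equal(mid$depth + mid$amb, nrow(cons))
})
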