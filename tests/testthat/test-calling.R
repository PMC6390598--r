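test_that("allele frequency arithmetic and guards", {
  expect_equal(allele_frequency(11, 100), 11)
  expect_equal(allele_frequency(0, 500), 0)
  expect_error(allele_frequency(1, 0), "depth")
  expect_error(allele_frequency(5, 4), "alt_support")
})

test_that("AF differences reproduce the reported per-patient values", {
  tab <- egfr_af_table()
  expect_equal(af_difference(tab$common_af, tab$uncommon_af),
               tab$difference)
  expect_equal(af_difference(30.9, 48.1), 17.2)
  expect_equal(af_difference(6.56, 6.8), 0.24)
  expect_equal(af_difference(12.3, 12.3), 0)
})

test_that("the 0.5% threshold is boundary-inclusive with support guard", {
  panel <- tiny_panel("EGFR_ex18")
  pile <- base_pileup(panel, "EGFR_ex18", 1000)
  v <- make_sample_profile(c(G719S = 0.1), panel)
  i <- which(pile$pos == v$pos)
  # exactly 0.5% with support 5: called
  pile[[v$alt]][i] <- 5L
  pile[[v$ref]][i] <- pile[[v$ref]][i] - 5L
  calls <- call_variants(pile, panel, "mbs")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$af, 0.5)
  expect_equal(calls$label, "G719S")

  # 0.4%: not called
  pile2 <- base_pileup(panel, "EGFR_ex18", 1000)
  pile2[[v$alt]][i] <- 4L
  pile2[[v$ref]][i] <- pile2[[v$ref]][i] - 4L
  expect_equal(nrow(call_variants(pile2, panel, "mbs")), 0)

  # support below min_alt_support: not called even above min_af
  pile3 <- base_pileup(panel, "EGFR_ex18", 100)
  pile3[[v$alt]][i] <- 2L
  pile3[[v$ref]][i] <- pile3[[v$ref]][i] - 2L
  expect_equal(nrow(call_variants(pile3, panel, "mbs")), 0)
  expect_equal(nrow(call_variants(pile3, panel, "mbs",
                                  min_alt_support = 2)), 1)
})

test_that("raising min_af never adds calls", {
  panel <- tiny_panel("EGFR_ex18")
  pile <- base_pileup(panel, "EGFR_ex18", 400)
  withr::with_seed(81, {
    for (i in sample(nrow(pile), 12)) {
      alt <- sample(setdiff(c("A", "C", "G", "T"), pile$ref[i]), 1)
      k <- sample(3:40, 1)
      pile[[alt]][i] <- k
      pile[[pile$ref[i]]][i] <- pile[[pile$ref[i]]][i] - k
    }
  })
  afs <- c(0.5, 1, 2, 5, 10)
  ns <- vapply(afs, function(a) {
    nrow(call_variants(pile, panel, "mbs", min_af = a))
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
  key <- function(a) {
    cs <- call_variants(pile, panel, "mbs", min_af = a)
    paste(cs$pos, cs$alt)
  }
  expect_true(all(key(5) %in% key(0.5)))
})

test_that("classification separates clamp-detectable from uncommon calls", {
  panel <- build_default_panel()
  mk <- function(label) {
    v <- panel$catalog[panel$catalog$label == label, ]
    tibble::tibble(sample_id = "s", arm = "mbs", contig = v$contig,
                   pos = v$pos, ref = v$ref, alt = v$alt)
  }
  expect_equal(classify_variants(mk("G719S"), panel)$class, "common")
  expect_equal(classify_variants(mk("ex19del"), panel)$class, "common")
  expect_equal(classify_variants(mk("E709G"), panel)$class, "uncommon")
  expect_equal(classify_variants(mk("G598V"), panel)$class, "uncommon")

  # non-catalog substitution inside the footprint is uncommon
  amp <- panel$amplicons[1, ]
  novel <- tibble::tibble(sample_id = "s", arm = "mbs", contig = amp$contig,
                          pos = amp$start + 5L,
                          ref = substr(amp$sequence, 6, 6), alt = "N")
  novel$alt <- setdiff(c("A", "C", "G", "T"), novel$ref)[1]
  expect_equal(classify_variants(novel, panel)$class, "uncommon")

  outside <- dplyr::mutate(novel, pos = 1L)
  expect_error(classify_variants(outside, panel), "footprint")
})

test_that("systematic-artifact filter removes sites shared by >half", {
  mk_calls <- function(samples, pos) {
    tibble::tibble(sample_id = samples, arm = "raw", contig = "chr7",
                   pos = pos, ref = "A", alt = "T", label = NA_character_,
                   class = "uncommon", alt_support = 5L, depth = 500L,
                   af = 1)
  }
  cohort <- dplyr::bind_rows(
    mk_calls(sprintf("S%02d", 1:15), 100L),   # 15 of 28: systematic
    mk_calls(sprintf("S%02d", 1:14), 200L),   # 14 of 28: retained
    mk_calls("S01", 300L)                     # singleton: retained
  )
  res <- filter_systematic(cohort, n_samples = 28)
  expect_equal(nrow(res$systematic), 1)
  expect_equal(res$systematic$pos, 100L)
  expect_equal(res$systematic$n_shared, 15L)
  expect_setequal(unique(res$calls$pos), c(200L, 300L))

  # idempotence
  res2 <- filter_systematic(res$calls, n_samples = 28)
  expect_equal(res2$calls, res$calls)
  expect_equal(nrow(res2$systematic), 0)
  expect_error(filter_systematic(mk_calls("S01", 1L), n_samples = 1), "2")
})

test_that("compound status requires a common and an uncommon call", {
  mk <- function(sample_id, labels, classes) {
    tibble::tibble(sample_id = sample_id, contig = "chr7",
                   pos = seq_along(labels), ref = "A", alt = "C",
                   label = labels, class = classes)
  }
  calls <- dplyr::bind_rows(
    mk("p2233", c("G719S", "R776H"), c("common", "uncommon")),
    mk("p1", "L858R", "common"),
    mk("p2", "E709G", "uncommon")
  )
  st <- compound_status(calls)
  expect_equal(st$status[st$sample_id == "p2233"], "compound")
  expect_equal(st$status[st$sample_id == "p1"], "single")
  expect_equal(st$status[st$sample_id == "p2"], "single")
})

test_that("call reports write 1-based TSV and a VCF dialect", {
  panel <- tiny_panel("EGFR_ex18")
  pile <- base_pileup(panel, "EGFR_ex18", 1000)
  v <- make_sample_profile(c(G719S = 0.1), panel)
  i <- which(pile$pos == v$pos)
  pile[[v$alt]][i] <- 50L
  pile[[v$ref]][i] <- pile[[v$ref]][i] - 50L
  calls <- call_variants(pile, panel, "mbs")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_calls(calls, tsv = tsv, vcf = vcf)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$pos, calls$pos + 1L)
  expect_equal(back$af, 5)
  lines <- readLines(vcf)
  expect_true(any(grepl("^##fileformat=VCF", lines)))
  body <- lines[!startsWith(lines, "#")]
  expect_match(body, "AF=5.0;DP=1000;ARM=mbs", fixed = TRUE)
})
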