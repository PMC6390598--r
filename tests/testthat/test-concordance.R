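mk_cs <- function(sample_id, arm, pos, af = 10) {
  tibble::tibble(sample_id = sample_id, arm = arm, contig = "chr7",
                 pos = pos, ref = "A", alt = "G",
                 label = NA_character_, class = "uncommon",
                 alt_support = 5L, depth = 500L,
                 af = rep_len(af, length(pos)))
}

test_that("replicate matching splits union into matched and orphans", {
  # identical call sets: all matched
  a <- mk_cs("s", "mbs", c(10, 20, 30))
  pair <- match_replicates(a, a)
  expect_equal(nrow(pair$matched), 3)
  expect_equal(nrow(pair$orphans), 0)
  expect_equal(reproducibility(pair), 100)

  # 6 shared + 3 only-first + 2 only-second
  b1 <- mk_cs("s", "raw", c(1:6, 101:103))
  b2 <- mk_cs("s", "raw", c(1:6, 201:202))
  pair2 <- match_replicates(b1, b2)
  expect_equal(nrow(pair2$matched), 6)
  expect_equal(nrow(pair2$orphans), 5)
  expect_equal(reproducibility(pair2), 55)

  # disjoint sets
  pair3 <- match_replicates(mk_cs("s", "mbs", 1:2), mk_cs("s", "mbs", 3:4))
  expect_equal(nrow(pair3$matched), 0)
  expect_equal(nrow(pair3$orphans), 4)

  expect_error(match_replicates(mk_cs("s", "mbs", 1), mk_cs("s", "raw", 1)),
               "arm")
})

test_that("matching is symmetric and accounts for the whole union", {
  withr::with_seed(91, {
    for (i in 1:10) {
      p1 <- sample(1:30, sample(3:10, 1))
      p2 <- sample(1:30, sample(3:10, 1))
      cs1 <- mk_cs("s", "mbs", p1)
      cs2 <- mk_cs("s", "mbs", p2)
      ab <- match_replicates(cs1, cs2)
      ba <- match_replicates(cs2, cs1)
      expect_equal(nrow(ab$matched), nrow(ba$matched))
      expect_equal(nrow(ab$orphans), nrow(ba$orphans))
      expect_equal(nrow(ab$matched) + nrow(ab$orphans),
                   length(union(p1, p2)))
    }
  })
})

test_that("reproducibility reproduces the reported replicate percentages", {
  expect_equal(reproducibility(6, 5), 55)
  expect_equal(reproducibility(4, 7), 36)
  expect_equal(reproducibility(9, 0), 100)
  expect_error(reproducibility(0, 0), "undefined")

  rc <- replicate_counts()
  got <- mapply(reproducibility, rc$matched, rc$orphan)
  expect_equal(got, c(55, 36, 73, 100))
})

test_that("AF correlation matches a hand-computed OLS R^2", {
  base <- mk_cs("s", "mbs", c(1, 2, 3))
  pair <- match_replicates(base, base)
  pair$matched$af1 <- c(10, 20, 30)
  pair$matched$af2 <- c(12, 19, 33)
  x <- pair$matched$af1; y <- pair$matched$af2
  r2_hand <- (sum((x - mean(x)) * (y - mean(y)))^2) /
    (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(af_correlation(pair), r2_hand, tolerance = 1e-12)

  # identical AF vectors give R^2 = 1; two points always fit exactly
  pair$matched$af2 <- pair$matched$af1
  expect_equal(af_correlation(pair), 1)
  pair2 <- pair
  pair2$matched <- pair$matched[1:2, ]
  pair2$matched$af1 <- c(10, 20); pair2$matched$af2 <- c(20, 10)
  expect_equal(af_correlation(pair2), 1)

  pair3 <- pair
  pair3$matched <- pair$matched[1, ]
  expect_error(af_correlation(pair3), "2 matched")

  g <- glance(pair)
  expect_equal(g$matched, 3)
  expect_equal(g$reproducibility, 100)
})

test_that("clinical concordance counts per-sample label recovery", {
  calls <- tibble::tibble(
    sample_id = sprintf("P%02d", 1:64),
    label = c(rep("L858R", 41), "ex19del", rep("ex19del", 17),
              rep("G719S", 5)),
    class = "common"
  )
  clinical <- tibble::tibble(
    sample_id = sprintf("P%02d", 1:64),
    clinical_label = c(rep("L858R", 42), rep("ex19del", 17),
                       rep("G719X", 5))
  )
  # sample P42 has ex19del calls but clinical L858R: discordant
  res <- clinical_concordance(calls, clinical)
  expect_equal(res$concordant, 63)
  expect_equal(res$percent, 98.4)

  all_good <- clinical_concordance(
    calls[1:41, ], clinical[1:41, ]
  )
  expect_equal(all_good$percent, 100)

  expect_error(
    clinical_concordance(calls[1:10, ],
                         tibble::tibble(sample_id = "ZZ",
                                        clinical_label = "L858R")),
    "ZZ"
  )
})

test_that("artifact census classifies sharing and computes reduction", {
  raw <- dplyr::bind_rows(
    mk_cs("s1", "raw", c(10, 50)),
    mk_cs("s2", "raw", c(10, 60)),
    mk_cs("s3", "raw", 10)
  )
  mbs <- dplyr::bind_rows(
    mk_cs("s1", "mbs", 10),
    mk_cs("s2", "mbs", 10),
    mk_cs("s3", "mbs", 10)
  )
  cen <- artifact_census(raw, mbs)
  expect_equal(nrow(cen$census), 2)           # sites 50 and 60
  expect_true(all(cen$census$singleton))
  expect_equal(cen$summary$singleton_fraction, 1)
  expect_equal(cen$per_sample$reduction, c(1, 1, 0))

  # identical arms: zero reduction, empty census
  cen0 <- artifact_census(raw, dplyr::mutate(raw, arm = "mbs"))
  expect_equal(nrow(cen0$census), 0)
  expect_true(all(cen0$per_sample$reduction == 0))

  # known true variants are excluded from the census
  cen_t <- artifact_census(raw, mbs,
                           truth = tibble::tibble(contig = "chr7", pos = 50,
                                                  ref = "A", alt = "G"))
  expect_equal(cen_t$census$pos, 60)
})

test_that("bundled call-count cohort shows the expected mean reduction", {
  cc <- call_count_cohort()
  expect_equal(nrow(cc), 28)
  expect_equal(round(mean(cc$mbs_calls), 1), 2.4)
  expect_equal(round(mean(cc$raw_calls), 1), 3.3)
  expect_equal(round(mean(cc$raw_calls - cc$mbs_calls), 1), 0.9)
  expect_equal(sum(cc$raw_calls > cc$mbs_calls), 17)
})
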