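#' Match calls between two replicate libraries
#'
#' Compares the call sets of two independently prepared libraries of the
#' same DNA: calls present in both (by variant key contig:pos:ref:alt) are
#' matched; the symmetric difference are orphan calls, each counted once.
#'
#' @param cs1,cs2 Call tibbles for the two replicates (same sample, same
#'   arm).
#' @return An object of class `replicate_pair`: a list with `sample_id`,
#'   `arm`, `matched` (tibble with af1/af2 per matched variant) and
#'   `orphans` (tibble with the originating replicate).
#' @export
match_replicates <- function(cs1, cs2) {
  arm1 <- unique(cs1$arm); arm2 <- unique(cs2$arm)
  if (length(arm1) > 1 || length(arm2) > 1 ||
      (length(arm1) == 1 && length(arm2) == 1 && arm1 != arm2)) {
    stop("replicate call sets must come from the same arm")
  }
  key1 <- variant_key(cs1$contig, cs1$pos, cs1$ref, cs1$alt)
  key2 <- variant_key(cs2$contig, cs2$pos, cs2$ref, cs2$alt)
  shared <- intersect(key1, key2)
  matched <- tibble::tibble(
    key = shared,
    label = cs1$label[match(shared, key1)],
    af1 = cs1$af[match(shared, key1)],
    af2 = cs2$af[match(shared, key2)]
  )
  orphans <- dplyr::bind_rows(
    tibble::tibble(key = setdiff(key1, key2), replicate = 1L),
    tibble::tibble(key = setdiff(key2, key1), replicate = 2L)
  )
  structure(list(
    sample_id = c(cs1$sample_id, cs2$sample_id)[1],
    arm = c(arm1, arm2, "mbs")[1],
    matched = matched, orphans = orphans
  ), class = "replicate_pair")
}

#' @export
print.replicate_pair <- function(x, ...) {
  cat("<replicate_pair> sample ", x$sample_id, " (", x$arm, " arm): ",
      nrow(x$matched), " matched, ", nrow(x$orphans), " orphan calls; ",
      "reproducibility ",
      reproducibility(nrow(x$matched), nrow(x$orphans)), "%\n", sep = "")
  invisible(x)
}

#' Replicate reproducibility percentage
#'
#' `100 * matched / (matched + orphan)` — the fraction of the union of two
#' replicates' calls detected in both — rounded to a whole percent for
#' reporting (6 matched + 5 orphans gives 55%).
#'
#' @param matched,orphan Matched and orphan call counts (or a
#'   `replicate_pair` as first argument).
#' @return Integer percent.
#' @export
reproducibility <- function(matched, orphan) {
  if (inherits(matched, "replicate_pair")) {
    orphan <- nrow(matched$orphans)
    matched <- nrow(matched$matched)
  }
  if (matched + orphan == 0) {
    stop("reproducibility undefined: no calls in either replicate")
  }
  round(100 * matched / (matched + orphan))
}

#' Allele-frequency correlation between replicates
#'
#' Coefficient of determination (R^2) of an ordinary least-squares fit of
#' replicate-2 allele frequency on replicate-1 allele frequency over the
#' matched calls, on the percent scale.
#'
#' @param pair A `replicate_pair`.
#' @return R^2 in \[0, 1\].
#' @export
af_correlation <- function(pair) {
  stopifnot(inherits(pair, "replicate_pair"))
  if (nrow(pair$matched) < 2) {
    stop("af_correlation undefined with fewer than 2 matched calls")
  }
  # OLS R^2 of af2 on af1 with intercept equals the squared correlation;
  # degenerate spreads resolve to a perfect (constant response) or null
  # (constant predictor) fit
  if (stats::sd(pair$matched$af2) == 0) return(1)
  if (stats::sd(pair$matched$af1) == 0) return(0)
  cor(pair$matched$af1, pair$matched$af2)^2
}

#' @export
glance.replicate_pair <- function(x, ...) {
  m <- nrow(x$matched); o <- nrow(x$orphans)
  tibble::tibble(
    sample_id = x$sample_id, arm = x$arm, matched = m, orphan = o,
    reproducibility = reproducibility(m, o),
    af_r2 = if (m >= 2) af_correlation(x) else NA_real_
  )
}

#' @export
tidy.replicate_pair <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$matched, status = "matched", replicate = NA_integer_),
    dplyr::mutate(x$orphans, status = "orphan",
                  label = NA_character_, af1 = NA_real_, af2 = NA_real_)
  )
}

#' Concordance between sequencing calls and clinical genotyping
#'
#' A sample is concordant iff its clinically reported common mutation
#' appears in its filtered MBS call set.  `G719X` matches any of
#' G719A/S/C; `exon19del` matches the catalogued exon-19 deletion class.
#'
#' @param calls Combined filtered MBS call tibble with `sample_id`.
#' @param clinical Tibble with columns `sample_id` and `clinical_label`.
#' @return One-row tibble: concordant count, n, percent (one decimal).
#' @export
clinical_concordance <- function(calls, clinical) {
  missing <- setdiff(clinical$sample_id, calls$sample_id)
  if (length(missing) > 0) {
    stop("no call set for sample(s): ", paste(missing, collapse = ", "))
  }
  hit <- vapply(seq_len(nrow(clinical)), function(i) {
    labs <- calls$label[calls$sample_id == clinical$sample_id[i]]
    labs <- labs[!is.na(labs)]
    want <- clinical$clinical_label[i]
    if (want == "G719X") any(labs %in% c("G719A", "G719S", "G719C"))
    else want %in% labs
  }, logical(1))
  tibble::tibble(
    concordant = sum(hit), n = nrow(clinical),
    percent = round(100 * sum(hit) / nrow(clinical), 1)
  )
}

#' Census of potential sequence artifacts across a cohort
#'
#' A potential artifact is a raw-arm ("without MBS") call absent from the
#' same sample's MBS call set.  The census tabulates how many samples share
#' each artifact site (singletons — sites private to one sample — are the
#' class that cannot be told apart from real rare variants without
#' barcodes), and the per-sample reduction in call counts achieved by
#' consensus calling.
#'
#' @param raw_calls,mbs_calls Combined call tibbles for the two arms over
#'   the same samples (systematic artifacts should already be filtered).
#' @param truth Optional truth tibble with contig/pos/ref/alt of real
#'   variants; when given, true variants are excluded from the artifact
#'   census even if they escaped the MBS arm.
#' @return An object of class `artifact_census`: list with `census` (site,
#'   n_samples, singleton), `per_sample` (raw_calls, mbs_calls, reduction)
#'   and `summary` (n_artifact_sites, singleton_fraction, mean_reduction).
#' @export
artifact_census <- function(raw_calls, mbs_calls, truth = NULL) {
  if (dplyr::n_distinct(raw_calls$sample_id) < 2) {
    stop("artifact census needs at least 2 samples")
  }
  key_raw <- variant_key(raw_calls$contig, raw_calls$pos, raw_calls$ref,
                         raw_calls$alt)
  key_mbs <- variant_key(mbs_calls$contig, mbs_calls$pos, mbs_calls$ref,
                         mbs_calls$alt)
  suspect <- raw_calls[!paste(raw_calls$sample_id, key_raw) %in%
                         paste(mbs_calls$sample_id, key_mbs), ]
  if (!is.null(truth)) {
    tkey <- variant_key(truth$contig, truth$pos, truth$ref, truth$alt)
    skey <- variant_key(suspect$contig, suspect$pos, suspect$ref,
                        suspect$alt)
    suspect <- suspect[!skey %in% tkey, ]
  }
  census <- dplyr::summarise(
    dplyr::group_by(suspect, .data$contig, .data$pos, .data$ref, .data$alt),
    n_samples = dplyr::n_distinct(.data$sample_id), .groups = "drop"
  )
  census$singleton <- census$n_samples == 1L
  samples <- sort(unique(c(raw_calls$sample_id, mbs_calls$sample_id)))
  per_sample <- tibble::tibble(
    sample_id = samples,
    raw_calls = as.integer(table(factor(raw_calls$sample_id, samples))),
    mbs_calls = as.integer(table(factor(mbs_calls$sample_id, samples)))
  )
  per_sample$reduction <- per_sample$raw_calls - per_sample$mbs_calls
  structure(list(
    census = census, per_sample = per_sample,
    summary = tibble::tibble(
      n_artifact_sites = nrow(census),
      singleton_fraction = if (nrow(census) > 0)
        mean(census$singleton) else NA_real_,
      mean_reduction = mean(per_sample$reduction)
    )
  ), class = "artifact_census")
}

#' @export
print.artifact_census <- function(x, ...) {
  cat("<artifact_census> ", x$summary$n_artifact_sites,
      " potential artifact sites; singleton fraction ",
      round(x$summary$singleton_fraction, 3), "; mean per-sample reduction ",
      round(x$summary$mean_reduction, 2), "\n", sep = "")
  invisible(x)
}

#' @export
glance.artifact_census <- function(x, ...) x$summary

#' @export
tidy.artifact_census <- function(x, ...) x$census
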