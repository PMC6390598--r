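#' Allele frequency in percent
#'
#' @param alt_support Supporting count (families on the MBS arm, reads on
#'   the raw arm).
#' @param depth Total count at the position, same unit.
#' @return `100 * alt_support / depth` (vectorised, full precision; report
#'   writers round to one decimal).
#' @export
allele_frequency <- function(alt_support, depth) {
  if (any(depth <= 0)) stop("depth must be positive (no coverage at site)")
  if (any(alt_support < 0 | alt_support > depth)) {
    stop("alt_support must be in [0, depth]")
  }
  100 * alt_support / depth
}

#' Absolute allele-frequency difference between a mutation pair
#'
#' The per-patient difference between the common and uncommon mutation's
#' allele frequencies (both in percent), as tabulated for compound-mutant
#' tumours.
#'
#' @param common_af,uncommon_af Allele frequencies in percent.
#' @return `|uncommon_af - common_af|`, rounded to two decimals (the
#'   precision the frequencies themselves are reported at).
#' @export
af_difference <- function(common_af, uncommon_af) {
  stopifnot(all(common_af >= 0 & common_af <= 100),
            all(uncommon_af >= 0 & uncommon_af <= 100))
  round(abs(uncommon_af - common_af), 2)
}

#' Call variants from a pileup
#'
#' Emits a call for every non-reference allele whose allele frequency is at
#' least `min_af` percent (boundary inclusive) and whose support is at
#' least `min_alt_support`.  Substitutions are read directly from the
#' pileup base counts; catalogued deletions are supported by `-` symbols at
#' their first deleted position.  Calls are classified `common` (clamp
#' detectable: exon-19 deletions, L858R, L861Q, T790M, G719A/S/C) or
#' `uncommon` via [classify_variants()].
#'
#' @param pileup Tibble from [consensus_pileup()] or [raw_pileup()].
#' @param panel An `mbs_panel`.
#' @param arm `"mbs"` or `"raw"`; recorded on the calls.
#' @param sample_id Sample identifier recorded on the calls.
#' @param min_af Minimum allele frequency in percent (default 0.5, the
#'   design detection threshold).
#' @param min_alt_support Minimum supporting families/reads (default 3), a
#'   guard against single-molecule noise at low depth.
#' @return A call-set tibble: sample_id, arm, contig, pos (0-based), ref,
#'   alt, label, class, alt_support, depth, af.
#' @export
call_variants <- function(pileup, panel, arm = c("mbs", "raw"),
                          sample_id = "S1", min_af = 0.5,
                          min_alt_support = 3) {
  arm <- match.arg(arm)
  stopifnot(nrow(pileup) > 0)
  long <- tidyr::pivot_longer(
    pileup, cols = dplyr::all_of(c("A", "C", "G", "T")),
    names_to = "alt", values_to = "alt_support"
  )
  snv <- dplyr::filter(long, .data$alt != .data$ref, .data$depth > 0,
                       .data$alt_support >= min_alt_support,
                       100 * .data$alt_support / .data$depth >= min_af)
  snv <- tibble::tibble(
    contig = snv$contig, pos = snv$pos, ref = snv$ref, alt = snv$alt,
    alt_support = snv$alt_support, depth = snv$depth
  )

  dels <- dplyr::filter(panel$catalog, !is.na(.data$del_len))
  del_calls <- purrr::map_dfr(seq_len(nrow(dels)), function(i) {
    d <- dels[i, ]
    amp <- panel$amplicons[panel$amplicons$name == d$amplicon, ]
    first_deleted <- amp$start + d$del_start
    row <- pileup[pileup$contig == d$contig & pileup$pos == first_deleted, ]
    if (nrow(row) == 0) return(NULL)
    if (row$depth > 0 && row$del >= min_alt_support &&
        100 * row$del / row$depth >= min_af) {
      tibble::tibble(contig = d$contig, pos = d$pos, ref = d$ref,
                     alt = d$alt, alt_support = row$del, depth = row$depth)
    } else NULL
  })

  calls <- dplyr::bind_rows(snv, del_calls)
  calls <- dplyr::arrange(calls, .data$contig, .data$pos, .data$alt)
  calls <- tibble::add_column(calls, sample_id = sample_id, arm = arm,
                              .before = 1)
  calls <- classify_variants(calls, panel)
  calls$af <- ifelse(calls$depth > 0,
                     allele_frequency(calls$alt_support, calls$depth), 0)
  calls[, c("sample_id", "arm", "contig", "pos", "ref", "alt", "label",
            "class", "alt_support", "depth", "af")]
}

#' Classify calls as common or uncommon hotspot mutations
#'
#' A call is `common` iff it matches the clamp-detectable catalog class
#' (exon-19 deletions are matched as a class: any catalogued in-frame
#' deletion overlapping the exon-19 hotspot window).  Every other call
#' within the panel footprint is `uncommon`; positions outside the
#' footprint raise an error.
#'
#' @param calls A call tibble with contig, pos, ref, alt columns.
#' @param panel An `mbs_panel`.
#' @return `calls` with `label` and `class` columns filled.
#' @export
classify_variants <- function(calls, panel) {
  cat_key <- variant_key(panel$catalog$contig, panel$catalog$pos,
                         panel$catalog$ref, panel$catalog$alt)
  idx <- match(variant_key(calls$contig, calls$pos, calls$ref, calls$alt),
               cat_key)
  calls$label <- panel$catalog$label[idx]
  calls$class <- panel$catalog$class[idx]
  unmatched <- which(is.na(idx))
  if (length(unmatched) > 0) {
    in_footprint <- vapply(unmatched, function(i) {
      any(panel$amplicons$contig == calls$contig[i] &
            panel$amplicons$start <= calls$pos[i] &
            panel$amplicons$end > calls$pos[i])
    }, logical(1))
    if (any(!in_footprint)) {
      bad <- unmatched[!in_footprint][1]
      stop("variant outside panel footprint: ",
           variant_key(calls$contig[bad], calls$pos[bad],
                       calls$ref[bad], calls$alt[bad]))
    }
    calls$class[unmatched] <- "uncommon"
  }
  calls
}

#' Filter systematic sequence artifacts across a cohort
#'
#' A site present in strictly more than half of the cohort's call sets is a
#' systematic artifact: it is removed from every call set and reported.
#' Applied per arm, before any cross-arm or replicate comparison.  The
#' operation is idempotent.
#'
#' @param calls A combined call tibble covering several samples (column
#'   `sample_id`; `arm` optional).
#' @param n_samples Number of call sets per arm; defaults to the distinct
#'   sample count in `calls` (pass explicitly when some samples have zero
#'   calls).
#' @return A list with `calls` (filtered tibble) and `systematic` (tibble
#'   of removed sites with their sharing counts).
#' @export
filter_systematic <- function(calls, n_samples = NULL) {
  if (is.null(n_samples)) n_samples <- dplyr::n_distinct(calls$sample_id)
  if (n_samples < 2) stop("systematic filtering needs at least 2 call sets")
  if (!"arm" %in% names(calls)) calls$arm <- "mbs"
  shared <- dplyr::summarise(
    dplyr::group_by(calls, .data$arm, .data$contig, .data$pos, .data$ref,
                    .data$alt),
    n_shared = dplyr::n_distinct(.data$sample_id), .groups = "drop"
  )
  systematic <- dplyr::filter(shared, .data$n_shared > n_samples / 2)
  kept <- dplyr::anti_join(
    calls, systematic, by = c("arm", "contig", "pos", "ref", "alt")
  )
  list(calls = kept, systematic = systematic)
}

#' Compound-mutation status of call sets
#'
#' A sample has a compound mutation iff at least one common
#' (TKI-sensitizing) call and at least one uncommon call survive filtering
#' in its call set.
#'
#' @param calls A call tibble (one or many samples).
#' @return A tibble with columns `sample_id` and `status`
#'   (`"single"`/`"compound"`).
#' @export
compound_status <- function(calls) {
  dplyr::summarise(
    dplyr::group_by(calls, .data$sample_id),
    status = ifelse(any(.data$class == "common") &
                      any(.data$class == "uncommon"),
                    "compound", "single"),
    .groups = "drop"
  )
}

#' Write a call set to TSV and a minimal VCF-dialect file
#'
#' The TSV reports 1-based positions and allele frequency to one decimal;
#' the VCF dialect uses the fixed columns with INFO keys `AF`, `DP`, `ARM`.
#'
#' @param calls A call tibble.
#' @param tsv,vcf Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_calls <- function(calls, tsv = NULL, vcf = NULL) {
  if (!is.null(tsv)) {
    out <- dplyr::mutate(calls, pos = .data$pos + 1L,
                         af = round(.data$af, 1))
    readr::write_tsv(out, tsv)
  }
  if (!is.null(vcf)) {
    lines <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency (%)\">",
      "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth (families or reads)\">",
      "##INFO=<ID=ARM,Number=1,Type=String,Description=\"mbs or raw\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
      sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tAF=%.1f;DP=%d;ARM=%s",
              calls$contig, calls$pos + 1L,
              ifelse(is.na(calls$label), ".", calls$label),
              calls$ref, calls$alt, calls$af, calls$depth, calls$arm)
    )
    writeLines(lines, vcf)
  }
  invisible(list(tsv = tsv, vcf = vcf))
}
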