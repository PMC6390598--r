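#' Assign reads to panel amplicons
#'
#' The first step of the molecular-barcode analysis: every read pair is
#' placed on the amplicon it matches best under ungapped sliding placement
#' (mate 2 is reverse-complemented first; standard FR amplicon layout is
#' assumed).  Indel-applied copies of amplicons carrying a catalogued
#' deletion are scored as additional references, which is the gapped second
#' pass for known indel hotspots such as the exon-19 deletion.  Mates of a
#' pair are merged into one reference-coordinate record; positions where
#' overlapping mates disagree become `N`, deleted positions `-`.  Reads
#' whose best placement still mismatches more than `max_mismatch` of bases
#' are dropped and counted.
#'
#' @param reads Read tibble ([amplify_and_sequence()] or
#'   [read_tagged_fastq()]).
#' @param panel An `mbs_panel`.
#' @param max_mismatch Maximum tolerated mismatch fraction at the best
#'   placement.
#' @return A tibble of aligned (merged) read pairs: sample_id, read_id,
#'   barcode, amplicon, aligned (string over amplicon coordinates using
#'   `A C G T - N .`), mismatches, indel (catalog label when a mate aligned
#'   through a known deletion).  The number of dropped pairs is in
#'   `attr(, "n_unassigned")`.
#' @export
assign_reads <- function(reads, panel, max_mismatch = 0.2) {
  stopifnot(inherits(panel, "mbs_panel"))
  if (nrow(panel$amplicons) == 0) stop("empty panel")
  amp <- panel$amplicons
  dels <- dplyr::filter(panel$catalog, !is.na(.data$del_len))
  # reference set: plain amplicons first (so ties resolve to no-indel),
  # then one deletion-applied copy per catalogued indel
  refs_meta <- tibble::tibble(
    amplicon = c(amp$name, dels$amplicon),
    sequence = c(amp$sequence,
                 vapply(seq_len(nrow(dels)), function(i) {
                   a <- amp[amp$name == dels$amplicon[i], ]
                   apply_variants(a$sequence, a$start, dels[i, ])
                 }, character(1))),
    del_start = c(rep(NA_integer_, nrow(amp)), dels$del_start),
    del_len = c(rep(NA_integer_, nrow(amp)), dels$del_len),
    indel = c(rep(NA_character_, nrow(amp)), dels$label)
  )

  n <- nrow(reads)
  if (n == 0) {
    out <- tibble::tibble(sample_id = character(0), read_id = character(0),
                          barcode = character(0), amplicon = character(0),
                          aligned = character(0), mismatches = integer(0),
                          indel = character(0))
    attr(out, "n_unassigned") <- 0L
    return(out)
  }
  p1 <- cpp_best_placement(reads$mate1, refs_meta$sequence)
  p2 <- cpp_best_placement(revcomp(reads$mate2), refs_meta$sequence)
  ok1 <- !is.na(p1$ref) & p1$mismatches / nchar(reads$mate1) <= max_mismatch
  ok2 <- !is.na(p2$ref) & p2$mismatches / nchar(reads$mate2) <= max_mismatch
  amp1 <- refs_meta$amplicon[p1$ref]
  amp2 <- refs_meta$amplicon[p2$ref]
  # resolve the pair's amplicon; on cross-amplicon conflict keep the
  # better-matching mate only
  conflict <- ok1 & ok2 & amp1 != amp2
  better1 <- p1$mismatches / nchar(reads$mate1) <=
    p2$mismatches / nchar(reads$mate2)
  ok2[conflict & better1] <- FALSE
  ok1[conflict & !better1] <- FALSE
  keep <- ok1 | ok2
  pair_amp <- ifelse(ok1, amp1, amp2)

  kept <- which(keep)
  aligned <- character(length(kept))
  m2rc <- revcomp(reads$mate2)
  for (a in unique(pair_amp[kept])) {
    rows <- kept[pair_amp[kept] == a]
    alen <- nchar(amp$sequence[amp$name == a])
    off1 <- ifelse(ok1[rows], p1$offset[rows], NA_integer_)
    off2 <- ifelse(ok2[rows], p2$offset[rows], NA_integer_)
    aligned[match(rows, kept)] <- cpp_paired_aligned(
      alen,
      as.integer(off1), reads$mate1[rows],
      as.integer(refs_meta$del_start[p1$ref[rows]]),
      as.integer(refs_meta$del_len[p1$ref[rows]]),
      as.integer(off2), m2rc[rows],
      as.integer(refs_meta$del_start[p2$ref[rows]]),
      as.integer(refs_meta$del_len[p2$ref[rows]])
    )
  }
  indel <- dplyr::coalesce(
    ifelse(ok1[kept], refs_meta$indel[p1$ref[kept]], NA_character_),
    ifelse(ok2[kept], refs_meta$indel[p2$ref[kept]], NA_character_)
  )
  out <- tibble::tibble(
    sample_id = reads$sample_id[kept],
    read_id = reads$read_id[kept],
    barcode = reads$barcode[kept],
    amplicon = pair_amp[kept],
    aligned = aligned,
    mismatches = ifelse(ok1[kept], p1$mismatches[kept], 0L) +
      ifelse(ok2[kept], p2$mismatches[kept], 0L),
    indel = indel
  )
  attr(out, "n_unassigned") <- n - length(kept)
  out
}

#' Group aligned reads into molecular families
#'
#' Reads sharing an identical (barcode, amplicon) key form one molecular
#' family — the unit later collapsed to a single consensus read.  Grouping
#' is exact-match; no edit-distance clustering is attempted.
#'
#' @param aligned Tibble from [assign_reads()].
#' @return The input with `family_id` (dense integer) and `family_size`
#'   columns added.
#' @export
group_families <- function(aligned) {
  key <- paste(aligned$barcode, aligned$amplicon, sep = "\r")
  fid <- match(key, unique(key))
  aligned$family_id <- fid
  aligned$family_size <- tabulate(fid)[fid]
  aligned
}

#' Summarise molecular families
#'
#' @param aligned Output of [group_families()].
#' @return One row per family: family_id, barcode, amplicon, size.
#' @export
family_table <- function(aligned) {
  dplyr::summarise(
    dplyr::group_by(aligned, .data$family_id, .data$barcode, .data$amplicon),
    size = dplyr::n(), .groups = "drop"
  )
}

PILEUP_SYMBOLS <- c("A", "C", "G", "T", "-")

#' Collapse molecular families to consensus reads
#'
#' The error-removal step: each family is consolidated to one read per
#' molecular barcode.  Per reference position, the majority symbol among
#' family members wins if its fraction of the covering members is at least
#' `min_agreement` (ties at exactly the threshold are kept); otherwise the
#' position is ambiguous (`N`) and can never support a variant call.
#' Families smaller than `min_family_size` are rejected and counted,
#' because an error on a singleton family cannot be outvoted.
#'
#' @param aligned Tibble from [assign_reads()] (family columns are added if
#'   absent).
#' @param min_family_size Minimum member reads for a family to be retained.
#' @param min_agreement Minimum within-family agreement fraction for a
#'   confident consensus base.
#' @return A tibble with one consensus record per retained family:
#'   family_id, barcode, amplicon, size, consensus (string over amplicon
#'   coordinates).  Rejected-family count in `attr(, "n_rejected")`.
#' @export
consensus_families <- function(aligned, min_family_size = 2,
                               min_agreement = 0.7) {
  if (!"family_id" %in% names(aligned)) aligned <- group_families(aligned)
  fams <- family_table(aligned)
  out <- vector("list", 0)
  for (a in unique(aligned$amplicon)) {
    sub <- aligned[aligned$amplicon == a, ]
    f <- fams[fams$amplicon == a, ]
    local_id <- match(sub$family_id, f$family_id)
    len <- nchar(sub$aligned[1])
    cons <- cpp_group_consensus(sub$aligned, local_id, nrow(f), len,
                                min_agreement)
    out[[a]] <- tibble::tibble(
      family_id = f$family_id, barcode = f$barcode, amplicon = a,
      size = f$size, consensus = cons
    )
  }
  res <- dplyr::bind_rows(out)
  rejected <- sum(res$size < min_family_size)
  res <- res[res$size >= min_family_size, ]
  attr(res, "n_rejected") <- rejected
  res
}

# shared tabulation: per-position symbol counts for a set of
# amplicon-coordinate strings
pileup_one_amplicon <- function(strings, amp_row) {
  len <- nchar(amp_row$sequence)
  counts <- cpp_pileup_counts(strings, rep(1L, length(strings)), 1L, len)
  tibble::tibble(
    amplicon = amp_row$name,
    contig = amp_row$contig,
    pos = amp_row$start + seq_len(len) - 1L,
    ref = strsplit(amp_row$sequence, "", fixed = TRUE)[[1]],
    A = counts[, 1], C = counts[, 2], G = counts[, 3], T = counts[, 4],
    del = counts[, 5], amb = counts[, 6],
    depth = as.integer(rowSums(counts[, 1:5, drop = FALSE]))
  )
}

#' Per-position pileup of consensus families (the MBS arm)
#'
#' Counts each retained family's consensus symbol at every reference
#' position; depth is therefore denominated in molecular families, not
#' reads.
#'
#' @param consensus Tibble from [consensus_families()].
#' @param panel An `mbs_panel`.
#' @return A pileup tibble: amplicon, contig, pos (0-based), ref, A, C, G,
#'   T, del, amb, depth.
#' @export
consensus_pileup <- function(consensus, panel) {
  purrr::map_dfr(seq_len(nrow(panel$amplicons)), function(i) {
    amp_row <- panel$amplicons[i, ]
    strings <- consensus$consensus[consensus$amplicon == amp_row$name]
    if (length(strings) == 0) return(NULL)
    pileup_one_amplicon(strings, amp_row)
  })
}

#' Per-position pileup of raw reads (the "without MBS" arm)
#'
#' Counts every merged read pair's base at every covered position, ignoring
#' barcodes entirely.  This arm retains the PCR and sequencing errors that
#' family consensus removes and serves as the comparison arm.
#'
#' @param aligned Tibble from [assign_reads()].
#' @param panel An `mbs_panel`.
#' @return A pileup tibble with the same columns as [consensus_pileup()].
#' @export
raw_pileup <- function(aligned, panel) {
  purrr::map_dfr(seq_len(nrow(panel$amplicons)), function(i) {
    amp_row <- panel$amplicons[i, ]
    strings <- aligned$aligned[aligned$amplicon == amp_row$name]
    if (length(strings) == 0) return(NULL)
    pileup_one_amplicon(strings, amp_row)
  })
}
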