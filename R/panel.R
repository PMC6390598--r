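#' Build the default EGFR hotspot panel
#'
#' Constructs a synthetic amplicon panel standing in for the EGFR portion of a
#' hotspot capture design: one amplicon per EGFR exon 15 through 21, with a
#' catalog of clinically relevant hotspot variants embedded at fixed offsets
#' (L858R, L861Q, T790M, G719A/S/C and an in-frame exon-19 deletion as the
#' clamp-detectable "common" class; E709G, R776H, D761Y and G598V as the
#' "uncommon" class).  Amplicon sequences are generated deterministically
#' from `seed`, so two calls with the same seed return byte-identical panels.
#'
#' Coordinates are 0-based half-open throughout; the deletion is stored
#' left-aligned with an anchor base (`ref` = anchor plus deleted bases,
#' `alt` = anchor).
#'
#' @param seed Integer seed controlling the generated amplicon sequences.
#' @param amplicon_length Length in bp of every amplicon.
#' @return An object of class `mbs_panel`: a list with tibbles `amplicons`
#'   (name, contig, start, end, sequence) and `catalog` (label, class,
#'   amplicon, contig, pos, ref, alt, del_start, del_len).
#' @examples
#' panel <- build_default_panel()
#' panel$catalog
#' @export
build_default_panel <- function(seed = 8912L, amplicon_length = 150L) {
  stopifnot(amplicon_length >= 120L)
  exons <- 15:21
  amplicons <- tibble::tibble(
    name = paste0("EGFR_ex", exons),
    contig = "chr7",
    start = 55200000L + (exons - 15L) * 3000L,
    end = 55200000L + (exons - 15L) * 3000L + amplicon_length
  )
  amplicons$sequence <- withr::with_seed(
    seed,
    random_dna(nrow(amplicons), amplicon_length)
  )

  # hotspot layout: (label, class, amplicon, local 0-based offset)
  spots <- tibble::tribble(
    ~label,   ~class,     ~amplicon,   ~offset,
    "G598V",  "uncommon", "EGFR_ex15", 75L,
    "E709G",  "uncommon", "EGFR_ex18", 40L,
    "G719A",  "common",   "EGFR_ex18", 70L,
    "G719S",  "common",   "EGFR_ex18", 70L,
    "G719C",  "common",   "EGFR_ex18", 70L,
    "D761Y",  "uncommon", "EGFR_ex19", 100L,
    "R776H",  "uncommon", "EGFR_ex20", 45L,
    "T790M",  "common",   "EGFR_ex20", 95L,
    "L858R",  "common",   "EGFR_ex21", 60L,
    "L861Q",  "common",   "EGFR_ex21", 90L
  )
  spots <- dplyr::left_join(spots, amplicons, by = c(amplicon = "name"))
  ref <- substr(spots$sequence, spots$offset + 1L, spots$offset + 1L)
  # G719A/S/C share one position: assign the three non-reference bases in
  # A,S,C label order; every other SNV takes the next base in ACGT cycle
  alt <- character(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    others <- setdiff(DNA_BASES, ref[i])
    alt[i] <- switch(spots$label[i],
      G719A = others[1], G719S = others[2], G719C = others[3],
      others[ (match(ref[i], DNA_BASES)) %% 3L + 1L ]
    )
  }
  snvs <- tibble::tibble(
    label = spots$label, class = spots$class, amplicon = spots$amplicon,
    contig = spots$contig, pos = spots$start + spots$offset,
    ref = ref, alt = alt, del_start = NA_integer_, del_len = NA_integer_
  )

  # in-frame 15-bp exon-19 deletion: anchor at local offset 49,
  # deleted segment = local [50, 65)
  ex19 <- amplicons[amplicons$name == "EGFR_ex19", ]
  del <- tibble::tibble(
    label = "ex19del", class = "common", amplicon = "EGFR_ex19",
    contig = ex19$contig, pos = ex19$start + 49L,
    ref = substr(ex19$sequence, 50L, 65L),
    alt = substr(ex19$sequence, 50L, 50L),
    del_start = 50L, del_len = 15L
  )

  catalog <- dplyr::arrange(
    dplyr::bind_rows(snvs, del),
    .data$contig, .data$pos, .data$alt
  )
  structure(list(amplicons = amplicons, catalog = catalog),
            class = "mbs_panel")
}

#' @export
print.mbs_panel <- function(x, ...) {
  cat("<mbs_panel> ", nrow(x$amplicons), " amplicons, ",
      nrow(x$catalog), " catalogued hotspot variants\n", sep = "")
  print(x$amplicons[, c("name", "contig", "start", "end")])
  invisible(x)
}

#' Restrict a panel to a subset of amplicons
#'
#' @param panel An `mbs_panel`.
#' @param amplicons Character vector of amplicon names to keep.
#' @return An `mbs_panel` containing only the named amplicons and the
#'   catalog variants they carry.
#' @export
panel_subset <- function(panel, amplicons) {
  stopifnot(inherits(panel, "mbs_panel"))
  missing <- setdiff(amplicons, panel$amplicons$name)
  if (length(missing) > 0) {
    stop("unknown amplicon(s): ", paste(missing, collapse = ", "))
  }
  structure(list(
    amplicons = dplyr::filter(panel$amplicons, .data$name %in% amplicons),
    catalog = dplyr::filter(panel$catalog, .data$amplicon %in% amplicons)
  ), class = "mbs_panel")
}

#' Resolve a ground-truth sample profile from hotspot labels
#'
#' Turns a table of (label, fraction) pairs into a fully resolved profile of
#' variant records with true molecule fractions, e.g. the L858R 6.56% +
#' G598V 6.8% genotype of a tumour with a compound mutation.
#'
#' @param spec A data frame with columns `label` and `fraction`, or a named
#'   numeric vector of fractions keyed by hotspot label.  Fractions are
#'   molecule fractions in (0, 1].
#' @param panel An `mbs_panel` whose catalog resolves the labels.
#' @param sample_id Sample identifier attached to the profile.
#' @return A tibble with columns sample_id, label, class, amplicon, contig,
#'   pos, ref, alt, del_start, del_len, fraction.  Zero rows for a
#'   wild-type (empty) spec.
#' @examples
#' panel <- build_default_panel()
#' make_sample_profile(c(L858R = 0.0656, G598V = 0.068), panel, "pt2294")
#' @export
make_sample_profile <- function(spec, panel, sample_id = "S1") {
  stopifnot(inherits(panel, "mbs_panel"))
  if (is.numeric(spec)) {
    spec <- tibble::tibble(label = names(spec), fraction = unname(spec))
  }
  spec <- tibble::as_tibble(spec)
  if (nrow(spec) == 0) {
    out <- dplyr::mutate(panel$catalog[0, ], fraction = numeric(0))
    return(tibble::add_column(out, sample_id = character(0), .before = 1))
  }
  stopifnot(all(c("label", "fraction") %in% names(spec)))
  unknown <- setdiff(spec$label, panel$catalog$label)
  if (length(unknown) > 0) {
    stop("unknown hotspot label(s): ", paste(unknown, collapse = ", "))
  }
  bad <- spec$fraction <= 0 | spec$fraction > 1
  if (any(bad)) {
    stop("fraction out of (0, 1] for label(s): ",
         paste(spec$label[bad], collapse = ", "))
  }
  if (anyDuplicated(spec$label)) stop("duplicated label in profile spec")
  out <- dplyr::inner_join(spec, panel$catalog, by = "label")
  tibble::add_column(
    out[, c("label", "class", "amplicon", "contig", "pos", "ref", "alt",
            "del_start", "del_len", "fraction")],
    sample_id = sample_id, .before = 1
  )
}

# apply a set of catalog variant rows (with local coordinates derived from
# the amplicon start) to an amplicon sequence; variants are applied in
# descending local position so indel shifts cannot disturb earlier edits
apply_variants <- function(sequence, start, variants) {
  if (nrow(variants) == 0) return(sequence)
  local <- variants$pos - start
  ord <- order(local, decreasing = TRUE)
  for (i in ord) {
    if (!is.na(variants$del_len[i]) && variants$del_len[i] > 0) {
      ds <- variants$del_start[i]
      sequence <- paste0(substr(sequence, 1L, ds),
                         substr(sequence, ds + variants$del_len[i] + 1L,
                                nchar(sequence)))
    } else {
      substr(sequence, local[i] + 1L, local[i] + 1L) <- variants$alt[i]
    }
  }
  sequence
}
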