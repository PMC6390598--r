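#' Write simulator outputs to disk
#'
#' Emits the standard file set for one simulated library: the panel
#' reference FASTA, the amplicon BED (0-based half-open), paired FASTQ with
#' the molecular barcode encoded in the read name after the last `:`, and a
#' truth TSV recording the sample's ground-truth variants and fractions.
#' Base qualities are constant Q30.
#'
#' @param reads Read tibble from [amplify_and_sequence()].
#' @param panel An `mbs_panel`.
#' @param profile The sample profile the reads were simulated from.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; defaults to the sample id.
#' @return Invisibly, a named list of the written paths
#'   (fasta, bed, fastq1, fastq2, truth).
#' @export
write_sim_outputs <- function(reads, panel, profile, dir,
                              prefix = reads$sample_id[1]) {
  stopifnot(inherits(panel, "mbs_panel"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  paths <- list(
    fasta = file.path(dir, paste0(prefix, "_panel.fasta")),
    bed = file.path(dir, paste0(prefix, "_panel.bed")),
    fastq1 = file.path(dir, paste0(prefix, "_R1.fastq")),
    fastq2 = file.path(dir, paste0(prefix, "_R2.fastq")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv"))
  )
  refs <- Biostrings::DNAStringSet(
    setNames(panel$amplicons$sequence, panel$amplicons$name)
  )
  Biostrings::writeXStringSet(refs, paths$fasta)
  gr <- GenomicRanges::GRanges(
    seqnames = panel$amplicons$contig,
    ranges = IRanges::IRanges(start = panel$amplicons$start + 1L,
                              end = panel$amplicons$end),
    name = panel$amplicons$name
  )
  rtracklayer::export(gr, paths$bed, format = "BED")
  ids <- paste0(reads$read_id, ":", reads$barcode)
  for (m in 1:2) {
    sq <- Biostrings::DNAStringSet(setNames(reads[[paste0("mate", m)]], ids))
    qual <- Biostrings::BStringSet(strrep("?", Biostrings::width(sq)))
    Biostrings::writeXStringSet(sq, paths[[paste0("fastq", m)]],
                                format = "fastq", qualities = qual)
  }
  truth <- profile[, c("sample_id", "contig", "pos", "ref", "alt",
                       "fraction")]
  readr::write_tsv(truth, paths$truth)
  invisible(paths)
}

#' Read barcode-tagged paired FASTQ
#'
#' Reads the two-file FASTQ dialect written by [write_sim_outputs()], where
#' the molecular barcode is the read-name field after the last `:`.  As an
#' alternative dialect, a separate barcode (index) FASTQ may be supplied,
#' in which case barcodes are taken from its sequences by record order.
#'
#' @param fastq1,fastq2 Paths to the mate FASTQ files.
#' @param barcode_fastq Optional path to an index FASTQ carrying the
#'   barcodes as record sequences.
#' @param sample_id Sample identifier to attach.
#' @return A read tibble with columns sample_id, read_id, barcode, mate1,
#'   mate2, origin (`NA`; the truth channel does not travel via FASTQ).
#' @export
read_tagged_fastq <- function(fastq1, fastq2, barcode_fastq = NULL,
                              sample_id = "S1") {
  m1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  m2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq")
  if (length(m1) != length(m2)) stop("mate FASTQ files differ in length")
  ids <- sub("\\s.*$", "", names(m1))
  if (is.null(barcode_fastq)) {
    barcode <- sub("^.*:", "", ids)
    read_id <- sub(":[^:]*$", "", ids)
  } else {
    bc <- Biostrings::readDNAStringSet(barcode_fastq, format = "fastq")
    if (length(bc) != length(m1)) stop("barcode FASTQ length mismatch")
    barcode <- unname(as.character(bc))
    read_id <- ids
  }
  tibble::tibble(
    sample_id = sample_id, read_id = read_id, barcode = barcode,
    mate1 = unname(as.character(m1)), mate2 = unname(as.character(m2)),
    origin = NA_character_
  )
}

#' Read an amplicon panel from FASTA + BED
#'
#' Reconstructs an `mbs_panel` from a reference FASTA and amplicon BED as
#' written by [write_sim_outputs()].  The hotspot catalog is matched from
#' `catalog` (default: the built-in panel's catalog, joined by amplicon
#' name).
#'
#' @param fasta,bed Paths to the reference FASTA and BED.
#' @param catalog Catalog tibble to attach; defaults to the catalog of
#'   [build_default_panel()] restricted to the amplicons present.
#' @return An `mbs_panel`.
#' @export
read_panel <- function(fasta, bed, catalog = NULL) {
  refs <- Biostrings::readDNAStringSet(fasta)
  gr <- rtracklayer::import(bed, format = "BED")
  amp <- tibble::tibble(
    name = gr$name,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    sequence = unname(as.character(refs[gr$name]))
  )
  if (is.null(catalog)) {
    catalog <- dplyr::filter(build_default_panel()$catalog,
                             .data$amplicon %in% amp$name)
  }
  structure(list(amplicons = amp, catalog = catalog), class = "mbs_panel")
}

#' Write / read a flat key-value simulation config file
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  writeLines(paste(names(config), unlist(config), sep = "\t"), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  kv <- readr::read_tsv(path, col_names = c("key", "value"),
                        col_types = "cc")
  vals <- as.list(as.numeric(kv$value))
  names(vals) <- kv$key
  do.call(sim_config, vals)
}
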