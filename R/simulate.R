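#' Simulation configuration for barcoded amplicon sequencing
#'
#' Bundles and validates the knobs of the read simulator.  Defaults emulate a
#' moderately deep single-amplicon HaloPlex-HS-style library: 2,000 input
#' molecules per amplicon, each tagged with a 12-mer random barcode, a
#' Poisson-distributed number of read pairs per molecule, rare polymerase
#' errors introduced at a single pre-sequencing duplication, and independent
#' per-base sequencing errors on every read.
#'
#' @param molecules_per_amplicon Number of input molecules tagged per
#'   amplicon.
#' @param barcode_length Barcode length in bases.  The default 12 keeps the
#'   expected number of barcode collisions per amplicon below one at the
#'   default molecule count (birthday bound `n^2 / (2 * 4^L)`).
#' @param reads_mean Mean read pairs per molecule.
#' @param reads_dispersion Negative-binomial size parameter for read pairs
#'   per molecule; `Inf` (default) gives a Poisson count.
#' @param pcr_error_rate Per-base probability of a polymerase error at the
#'   duplication stage; such an error is shared by the random subset of the
#'   molecule's reads drawn from the mutated copy.
#' @param seq_error_rate Per-base, per-read sequencing error probability,
#'   independent across reads.
#' @param read_length Read length in bases for both mates.
#' @param seed Integer seed used by the simulation wrappers.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(molecules_per_amplicon = 2000L,
                       barcode_length = 12L,
                       reads_mean = 3,
                       reads_dispersion = Inf,
                       pcr_error_rate = 1e-4,
                       seq_error_rate = 0.005,
                       read_length = 100L,
                       seed = 1L) {
  cfg <- list(
    molecules_per_amplicon = as.integer(molecules_per_amplicon),
    barcode_length = as.integer(barcode_length),
    reads_mean = as.numeric(reads_mean),
    reads_dispersion = as.numeric(reads_dispersion),
    pcr_error_rate = as.numeric(pcr_error_rate),
    seq_error_rate = as.numeric(seq_error_rate),
    read_length = as.integer(read_length),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$molecules_per_amplicon > 0, cfg$barcode_length > 0,
    cfg$reads_mean > 0, cfg$reads_dispersion > 0, cfg$read_length > 0,
    cfg$pcr_error_rate >= 0, cfg$pcr_error_rate < 1,
    cfg$seq_error_rate >= 0, cfg$seq_error_rate < 1
  )
  structure(cfg, class = "sim_config")
}

#' Simulate barcode-tagged input molecules
#'
#' Draws `molecules_per_amplicon` molecules for every panel amplicon.  Each
#' molecule carries each of the sample's truth variants independently with
#' probability equal to its true fraction, and is tagged with a barcode
#' sampled uniformly from the 4^L barcode space.
#'
#' @param profile A sample profile from [make_sample_profile()].
#' @param panel An `mbs_panel`.
#' @param config A [sim_config()].
#' @param seed Optional seed; `NULL` uses the ambient RNG stream.
#' @return A tibble with one row per molecule: sample_id, molecule_id,
#'   amplicon, barcode, haplotype, variants (comma-joined truth labels,
#'   `""` for wild type).
#' @export
simulate_molecules <- function(profile, panel, config = sim_config(),
                               seed = NULL) {
  stopifnot(inherits(panel, "mbs_panel"), inherits(config, "sim_config"))
  sample_id <- if (nrow(profile) > 0) profile$sample_id[1] else "S1"
  with_seed_if(seed, {
    out <- purrr::map(seq_len(nrow(panel$amplicons)), function(ai) {
      amp <- panel$amplicons[ai, ]
      n <- config$molecules_per_amplicon
      vars <- profile[profile$amplicon == amp$name, , drop = FALSE]
      # carriage indicator per molecule per truth variant
      if (nrow(vars) > 0) {
        carry <- vapply(vars$fraction, function(f) {
          as.logical(rbinom(n, 1L, f))
        }, logical(n))
        carry <- matrix(carry, nrow = n)
      } else {
        carry <- matrix(FALSE, nrow = n, ncol = 0)
      }
      combo <- if (ncol(carry) > 0) {
        apply(carry, 1L, function(z) paste(which(z), collapse = ","))
      } else rep("", n)
      ucombo <- unique(combo)
      idx_for <- lapply(ucombo, function(cb) {
        if (cb == "") integer(0) else
          as.integer(strsplit(cb, ",", fixed = TRUE)[[1]])
      })
      hap_for <- vapply(idx_for, function(idx) {
        apply_variants(amp$sequence, amp$start, vars[idx, , drop = FALSE])
      }, character(1))
      lab_for <- vapply(idx_for, function(idx) {
        paste(vars$label[idx], collapse = ",")
      }, character(1))
      pick <- match(combo, ucombo)
      tibble::tibble(
        sample_id = sample_id,
        molecule_id = sprintf("%s_%s_m%05d", sample_id, amp$name, seq_len(n)),
        amplicon = amp$name,
        barcode = random_dna(n, config$barcode_length),
        haplotype = hap_for[pick],
        variants = lab_for[pick]
      )
    })
    dplyr::bind_rows(out)
  })
}

# substitute `n_err` random positions of each string with a random different
# base; x and n_err are parallel vectors (C++ kernel drawing from the R RNG)
mutate_bases <- function(x, n_err) {
  cpp_mutate_bases(x, as.integer(pmin(n_err, nchar(x))))
}

#' Amplify molecules and sequence paired reads
#'
#' Each molecule yields a Poisson / negative-binomial number of read pairs.
#' Polymerase (PCR) errors are modelled as a single duplication: per-base
#' Bernoulli errors are drawn once per molecule and placed on one of two
#' copies, and each read pair is drawn from either copy with equal
#' probability, so a PCR error is shared by a random subset of the family.
#' Sequencing errors are then injected independently per mate and per base.
#' Mate 1 reads the first `read_length` bases of the molecule, mate 2 the
#' reverse complement of the last `read_length` bases.  Barcodes are copied
#' into the read records without error.
#'
#' @inheritParams simulate_molecules
#' @param molecules Tibble from [simulate_molecules()].
#' @return A tibble of tagged read pairs: sample_id, read_id, barcode,
#'   mate1, mate2, origin (molecule_id; the truth channel, which is written
#'   to a side file rather than the FASTQ).
#' @export
amplify_and_sequence <- function(molecules, config = sim_config(),
                                 seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_if(seed, {
    n_mol <- nrow(molecules)
    k <- if (is.infinite(config$reads_dispersion)) {
      rpois(n_mol, config$reads_mean)
    } else {
      rnbinom(n_mol, mu = config$reads_mean, size = config$reads_dispersion)
    }
    # PCR errors on one copy of each molecule
    hap_len <- nchar(molecules$haplotype)
    n_pcr <- rbinom(n_mol, hap_len, config$pcr_error_rate)
    pcr_copy <- mutate_bases(molecules$haplotype, n_pcr)

    keep <- rep.int(seq_len(n_mol), k)
    n_reads <- length(keep)
    if (n_reads == 0) {
      return(tibble::tibble(sample_id = character(0), read_id = character(0),
                            barcode = character(0), mate1 = character(0),
                            mate2 = character(0), origin = character(0)))
    }
    from_mut <- as.logical(rbinom(n_reads, 1L, 0.5)) & (n_pcr[keep] > 0)
    template <- ifelse(from_mut, pcr_copy[keep], molecules$haplotype[keep])
    tlen <- nchar(template)
    rl <- pmin(config$read_length, tlen)
    mate1 <- substr(template, 1L, rl)
    mate2 <- revcomp(substr(template, tlen - rl + 1L, tlen))
    mate1 <- mutate_bases(mate1, rbinom(n_reads, rl, config$seq_error_rate))
    mate2 <- mutate_bases(mate2, rbinom(n_reads, rl, config$seq_error_rate))
    tibble::tibble(
      sample_id = molecules$sample_id[keep],
      read_id = sprintf("%s_r%07d", molecules$sample_id[keep], seq_len(n_reads)),
      barcode = molecules$barcode[keep],
      mate1 = mate1,
      mate2 = mate2,
      origin = molecules$molecule_id[keep]
    )
  })
}

#' Inject artifact-supporting reads into one or more read sets
#'
#' Adds alt-supporting read pairs at a site, emulating the sequence
#' artifacts seen without molecular barcoding.  `mode = "systematic"` plants
#' the artifact in strictly more than half of the read sets (the class the
#' cohort-level filter is designed to remove); `mode = "singleton"` plants
#' it in exactly one, where it is indistinguishable from a real rare variant
#' without barcodes.  Every injected pair carries a fresh random barcode, so
#' each artifact read forms a family of size one that barcode consensus can
#' reject.
#'
#' @param read_sets A list of read tibbles (one per sample or library).
#' @param panel An `mbs_panel`.
#' @param site A one-row data frame (or list) with contig, pos (0-based),
#'   ref, alt describing the artifact substitution.
#' @param mode `"systematic"` or `"singleton"`.
#' @param rate Fraction of each affected read set's pairs at the amplicon to
#'   add as artifact pairs (approximately the raw-arm allele frequency).
#' @param seed Optional seed.
#' @return The list of read tibbles with artifact reads appended; injected
#'   rows carry `origin = "artifact"`.
#' @export
inject_artifact <- function(read_sets, panel, site,
                            mode = c("systematic", "singleton"),
                            rate, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.list(read_sets), inherits(panel, "mbs_panel"))
  if (rate < 0) stop("rate must be >= 0")
  if (rate == 0) return(read_sets)
  if (mode == "systematic" && length(read_sets) < 3) {
    stop("systematic injection requires at least 3 read sets")
  }
  site <- as.list(site)
  amp <- panel$amplicons[panel$amplicons$start <= site$pos &
                           panel$amplicons$end > site$pos &
                           panel$amplicons$contig == site$contig, ]
  if (nrow(amp) != 1) stop("artifact site not covered by a panel amplicon")
  local <- site$pos - amp$start
  mutated <- amp$sequence
  substr(mutated, local + 1L, local + 1L) <- site$alt

  with_seed_if(seed, {
    n_sets <- length(read_sets)
    targets <- if (mode == "singleton") {
      sample.int(n_sets, 1L)
    } else {
      sample.int(n_sets, floor(n_sets / 2) + 1L)
    }
    for (i in targets) {
      rs <- read_sets[[i]]
      n_amp <- sum(startsWith(rs$origin, paste0(rs$sample_id[1], "_", amp$name)) |
                     rs$origin == "artifact")
      if (n_amp == 0) n_amp <- nrow(rs)
      n_inj <- max(1L, ceiling(rate * n_amp))
      rl <- min(nchar(rs$mate1[1]), nchar(mutated))
      inj <- tibble::tibble(
        sample_id = rs$sample_id[1],
        read_id = sprintf("%s_art%06d", rs$sample_id[1],
                          nrow(rs) + seq_len(n_inj)),
        barcode = random_dna(n_inj, nchar(rs$barcode[1])),
        mate1 = substr(mutated, 1L, rl),
        mate2 = revcomp(substr(mutated, nchar(mutated) - rl + 1L,
                               nchar(mutated))),
        origin = "artifact"
      )
      read_sets[[i]] <- dplyr::bind_rows(rs, inj)
    }
    read_sets
  })
}
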