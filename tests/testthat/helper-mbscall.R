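# shared fixtures, all built in code

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_panel <- function(amps = c("EGFR_ex18", "EGFR_ex21")) {
  panel_subset(build_default_panel(), amps)
}

# simulate one library under a fixed seed
quick_library <- function(profile, panel, config, seed = 1) {
  withr::with_seed(seed, {
    mol <- simulate_molecules(profile, panel, config)
    list(molecules = mol, reads = amplify_and_sequence(mol, config))
  })
}

# minimal aligned tibble for consensus unit tests
make_aligned <- function(strings, barcode, amplicon = "ampA",
                         sample_id = "S1") {
  tibble::tibble(
    sample_id = sample_id,
    read_id = sprintf("r%03d", seq_along(strings)),
    barcode = barcode,
    amplicon = amplicon,
    aligned = strings,
    mismatches = 0L,
    indel = NA_character_
  )
}

# independent R-side per-base error injector (kept separate from the
# simulator so consensus error-rate checks have an independent oracle)
inject_errors_r <- function(strings, rate) {
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(strings)) {
    len <- nchar(strings[i])
    n <- rbinom(1, len, rate)
    if (n == 0) next
    for (p in sample.int(len, n)) {
      cur <- substr(strings[i], p, p)
      substr(strings[i], p, p) <- sample(setdiff(bases, cur), 1)
    }
  }
  strings
}

hamming <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

# error-free pileup of `depth` reference molecules over one amplicon
base_pileup <- function(panel, amp_name, depth) {
  amp <- panel$amplicons[panel$amplicons$name == amp_name, ]
  refs <- strsplit(amp$sequence, "", fixed = TRUE)[[1]]
  out <- tibble::tibble(
    amplicon = amp_name, contig = amp$contig,
    pos = amp$start + seq_along(refs) - 1L, ref = refs,
    A = 0L, C = 0L, G = 0L, T = 0L, del = 0L, amb = 0L,
    depth = as.integer(depth)
  )
  for (b in c("A", "C", "G", "T")) out[[b]][refs == b] <- as.integer(depth)
  out
}

# random small contingency tables with positive margins
random_table <- function(nr = 2, nc = 2, max_n = 12) {
  repeat {
    m <- matrix(sample(0:max_n, nr * nc, replace = TRUE), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
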