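# Nearest-neighbor duplex parameters, unified set (SantaLucia 1998).
# dH in kcal/mol, dS in cal/(mol K); keys are 5'->3' dinucleotides of one
# strand, complements folded onto the same entry.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex initiation with a terminal G.C / A.T pair
INIT_DH <- c(GC = 0.1, AT = 2.3)
INIT_DS <- c(GC = -2.8, AT = 4.1)

#' Nearest-neighbor oligonucleotide melting temperature
#'
#' Unified nearest-neighbor thermodynamics with terminal initiation
#' corrections, evaluated at fixed default conditions: 50 mM monovalent
#' cations and 250 nM total oligo. The entropic salt correction is
#' `0.368 * (L - 1) * ln[Na+]` (one term per phosphate pair). Deterministic;
#' ambiguity codes are rejected.
#'
#' @param seq DNA string over A,C,G,T, length >= 8.
#' @param na_molar monovalent salt concentration (mol/L), default 0.05.
#' @param oligo_molar total oligo concentration (mol/L), default 250e-9.
#' @return melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq, na_molar = 0.05, oligo_molar = 250e-9) {
  seq <- toupper(seq)
  if (nchar(seq) < 8L) stop("Tm model needs length >= 8")
  if (grepl("[^ACGT]", seq)) stop("ambiguity codes not supported in Tm model")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  dinucs <- paste0(ch[-n], ch[-1L])
  dH <- sum(NN_DH[dinucs])
  dS <- sum(NN_DS[dinucs])
  term <- function(b) if (b %in% c("G", "C")) "GC" else "AT"
  dH <- dH + INIT_DH[[term(ch[1])]] + INIT_DH[[term(ch[n])]]
  dS <- dS + INIT_DS[[term(ch[1])]] + INIT_DS[[term(ch[n])]]
  self_comp <- identical(seq, revcomp(seq))
  if (self_comp) dS <- dS - 1.4
  dS <- dS + 0.368 * (n - 1L) * log(na_molar)
  ct <- if (self_comp) oligo_molar else oligo_molar / 4
  dH * 1000 / (dS + 1.9872 * log(ct)) - 273.15
}

gc_fraction <- function(seq) {
  # vectorized over a character vector
  nchar(gsub("[^GCgc]", "", seq)) / nchar(seq)
}

# 1-2 G/C bases among the terminal two positions at each primer end
# (vectorized; with two terminal bases, ">= 1" is exactly "1 or 2")
has_gc_clamps <- function(seq) {
  n <- nchar(seq)
  gc2 <- function(x) nchar(gsub("[^GCgc]", "", x))
  gc2(substr(seq, 1L, 2L)) >= 1L & gc2(substr(seq, n - 1L, n)) >= 1L
}

#' Default primer design constraints
#'
#' Length 18-22 bp, individual Tm within 55 +/- 3 C, pairwise Tm difference
#' below 5 C, GC fraction 0.40-0.60, 1-2 G/C bases among the two terminal
#' bases at each end, product length 425-470 bp.
#' @return named list of constraint values, overridable entry-wise in
#'   [design_pairs()].
#' @export
primer_constraints <- function() {
  list(len_range = c(18L, 22L), tm_opt = 55, tm_band = 3, max_tm_diff = 5,
       gc_range = c(0.40, 0.60), product_range = c(425L, 470L),
       motif_edge = 250L)
}

feasible_primers <- function(seqs, starts, lens, cons) {
  g <- gc_fraction(seqs)
  ok_gc <- g >= cons$gc_range[1] & g <= cons$gc_range[2] & has_gc_clamps(seqs)
  idx <- which(ok_gc)
  tm <- rep(NA_real_, length(seqs))
  tm[idx] <- vapply(seqs[idx], melting_temperature, 0, USE.NAMES = FALSE)
  ok <- ok_gc & !is.na(tm) &
    tm >= cons$tm_opt - cons$tm_band & tm <= cons$tm_opt + cons$tm_band
  data.frame(seq = seqs[ok], start = starts[ok], len = lens[ok], tm = tm[ok],
             stringsAsFactors = FALSE)
}

#' Design and rank primer pairs on a template
#'
#' Enumerates all primer placements satisfying the constraint set (see
#' [primer_constraints()]). For SSR templates, `motif_span` (0-based
#' half-open) must lie completely within the first or last `motif_edge`
#' bases of the amplicon so that paired reads merge over it, and primers may
#' not overlap the repeat. For EPIC templates, both primer footprints are
#' restricted to the supplied conserved windows. Pairs are ranked by
#' `|tm_fwd - 55| + |tm_rev - 55|`, then distance of the product length from
#' 450 bp, then 5'-most placement.
#'
#' @param template DNA string.
#' @param locus_id label carried into the output.
#' @param constraints list as from [primer_constraints()]; entries given
#'   here override the defaults.
#' @param motif_span optional `c(start, end)` of the complete SSR motif.
#' @param conserved_windows optional data.frame (`start`, `end`) restricting
#'   primer footprints (EPIC mode).
#' @return data.frame of accepted pairs (possibly 0 rows): `locus_id`,
#'   `fwd`, `rev` (both 5' to 3', `rev` on the opposite strand), `fwd_start`,
#'   `rev_end`, `tm_fwd`, `tm_rev`, `gc_fwd`, `gc_rev`, `product_len`,
#'   `tails_attached`, `flags`.
#' @export
design_pairs <- function(template, locus_id = "locus", constraints = list(),
                         motif_span = NULL, conserved_windows = NULL) {
  cons <- utils::modifyList(primer_constraints(), constraints)
  template <- toupper(template)
  n <- nchar(template)
  lens <- seq(cons$len_range[1], cons$len_range[2])
  # enumerate footprints [s, s+l) (0-based)
  grid <- expand.grid(start = 0:(n - cons$len_range[1]), len = lens)
  grid <- grid[grid$start + grid$len <= n, ]
  in_windows <- function(s, e) {
    if (is.null(conserved_windows)) return(rep(TRUE, length(s)))
    ok <- rep(FALSE, length(s))
    for (w in seq_len(nrow(conserved_windows)))
      ok <- ok | (s >= conserved_windows$start[w] & e <= conserved_windows$end[w])
    ok
  }
  keep <- in_windows(grid$start, grid$start + grid$len)
  if (!is.null(motif_span))  # primers must not sit in the repeat itself
    keep <- keep & (grid$start + grid$len <= motif_span[1] | grid$start >= motif_span[2])
  grid <- grid[keep, ]
  if (!nrow(grid)) return(empty_pairs())
  sub <- substring(template, grid$start + 1L, grid$start + grid$len)
  # reverse-strand candidates are substrings of the reverse-complemented
  # template at mirrored coordinates (one revcomp instead of thousands)
  rc <- revcomp(template)
  sub_rc <- substring(rc, n - grid$start - grid$len + 1L, n - grid$start)
  fwd <- feasible_primers(sub, grid$start, grid$len, cons)
  rev <- feasible_primers(sub_rc, grid$start, grid$len, cons)
  if (!nrow(fwd) || !nrow(rev)) return(empty_pairs())
  rev$end <- rev$start + rev$len
  rows <- list()
  for (i in seq_len(nrow(fwd))) {
    fs <- fwd$start[i]
    cand <- rev[rev$end >= fs + cons$product_range[1] &
                  rev$end <= fs + cons$product_range[2], , drop = FALSE]
    if (!nrow(cand)) next
    ok_tm <- abs(cand$tm - fwd$tm[i]) < cons$max_tm_diff
    cand <- cand[ok_tm, , drop = FALSE]
    if (!is.null(motif_span)) {
      inside <- motif_span[1] >= fs & motif_span[2] <= cand$end
      near_edge <- (motif_span[2] - fs <= cons$motif_edge) |
        (cand$end - motif_span[1] <= cons$motif_edge)
      cand <- cand[inside & near_edge, , drop = FALSE]
    }
    if (!nrow(cand)) next
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = locus_id,
      fwd = fwd$seq[i], rev = cand$seq,
      fwd_start = fs, rev_end = cand$end,
      tm_fwd = fwd$tm[i], tm_rev = cand$tm,
      gc_fwd = gc_fraction(fwd$seq[i]),
      gc_rev = gc_fraction(cand$seq),
      product_len = cand$end - fs,
      tails_attached = FALSE, flags = "",
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(empty_pairs())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ord <- order(abs(out$tm_fwd - cons$tm_opt) + abs(out$tm_rev - cons$tm_opt),
               abs(out$product_len - 450L), out$fwd_start, out$rev_end)
  out[ord, , drop = FALSE]
}

empty_pairs <- function() {
  data.frame(locus_id = character(), fwd = character(), rev = character(),
             fwd_start = integer(), rev_end = integer(),
             tm_fwd = double(), tm_rev = double(),
             gc_fwd = double(), gc_rev = double(), product_len = integer(),
             tails_attached = logical(), flags = character(),
             stringsAsFactors = FALSE)
}

#' Read-library duplication screen
#'
#' Counts shotgun reads containing a full-length match to each primer
#' (either strand, at most `max_mismatch` substitutions). A primer matched
#' by more than one read is flagged `DUPLICATED_READS` (a single-copy locus
#' in a shallow shotgun library should be covered at most once); zero-read
#' support passes under the rule as stated, unless `min_support` is raised.
#'
#' @param pair one row of [design_pairs()] output (or list with `fwd`,
#'   `rev`).
#' @param library_reads list of sequence records (or character vector).
#' @param max_mismatch allowed substitutions in a match (default 1).
#' @param min_support optional minimum read support per primer (default 0 =
#'   off).
#' @return list with per-primer counts and `flags` (character vector, empty
#'   when the pair passes).
#' @export
duplication_screen_reads <- function(pair, library_reads, max_mismatch = 1L,
                                     min_support = 0L) {
  seqs <- if (is.character(library_reads)) library_reads
          else vapply(library_reads, `[[`, "", "seq")
  subj <- Biostrings::DNAStringSet(seqs)
  count_reads <- function(primer) {
    hits <- Biostrings::vcountPattern(primer, subj, max.mismatch = max_mismatch) +
      Biostrings::vcountPattern(revcomp(primer), subj, max.mismatch = max_mismatch)
    sum(hits > 0L)
  }
  nf <- count_reads(pair$fwd)
  nr <- count_reads(pair$rev)
  flags <- character()
  if (nf > 1L || nr > 1L) flags <- "DUPLICATED_READS"
  if (min_support > 0L && (nf < min_support || nr < min_support))
    flags <- union(flags, "LOW_READ_SUPPORT")
  list(fwd_reads = nf, rev_reads = nr, flags = flags)
}

#' Reference-genome contamination / duplication screen
#'
#' Exact-match search of both primers against a reference genome (both
#' strands). Zero hits for either primer flags `NO_GENOME_HIT`
#' (contamination suspect); two or more hits flags `MULTI_GENOME_HIT`
#' (duplication suspect). The pair passes only when each primer hits exactly
#' once, on opposite strands, facing inward at a product-window-compatible
#' distance.
#'
#' @param pair list/row with `fwd`, `rev`.
#' @param reference_genome named character vector of contigs.
#' @param product_range acceptable amplicon length window, default
#'   `c(425, 470)`.
#' @return list with hit tables and `flags` (empty = pass).
#' @export
genome_screen <- function(pair, reference_genome, product_range = c(425L, 470L)) {
  reference_genome <- as_contig_vector(reference_genome)
  find_hits <- function(primer) {
    hits <- list()
    for (ctg in names(reference_genome)) {
      subj <- reference_genome[[ctg]]
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") primer else revcomp(primer)
        m <- gregexpr(pat, subj, fixed = TRUE)[[1]]
        if (m[1] == -1L) next
        for (p in as.integer(m))
          hits[[length(hits) + 1L]] <- data.frame(
            contig = ctg, strand = strand, start = p - 1L,
            end = p - 1L + nchar(pat), stringsAsFactors = FALSE)
      }
    }
    if (length(hits)) do.call(rbind, hits) else
      data.frame(contig = character(), strand = character(),
                 start = integer(), end = integer(), stringsAsFactors = FALSE)
  }
  hf <- find_hits(pair$fwd)
  hr <- find_hits(pair$rev)
  flags <- character()
  if (nrow(hf) == 0L || nrow(hr) == 0L) flags <- c(flags, "NO_GENOME_HIT")
  if (nrow(hf) >= 2L || nrow(hr) >= 2L) flags <- c(flags, "MULTI_GENOME_HIT")
  if (!length(flags)) {
    geom_ok <- FALSE
    if (hf$contig == hr$contig && hf$strand != hr$strand) {
      if (hf$strand == "+" && hr$strand == "-") {
        prod <- hr$end - hf$start
      } else {
        prod <- hf$end - hr$start
      }
      geom_ok <- prod >= product_range[1] && prod <= product_range[2]
    }
    if (!geom_ok) flags <- "BAD_GEOMETRY"
  }
  list(fwd_hits = hf, rev_hits = hr, flags = flags)
}

#' Partial Illumina adapter tails
#'
#' The 5' extensions added to locus-specific primers so a second, indexing
#' PCR can complete the P5/P7 adapters.
#' @return named character vector with elements `p5` and `p7`.
#' @export
adapter_tails <- function() {
  c(p5 = "TCTTTCCCTACACGACGCTCTTCCGATCT",
    p7 = "CTGGAGTTCAGACGTGTGCTCTTCCGATCT")
}

#' Attach partial Illumina adapter tails to a primer pair
#'
#' Prepends the partial P5 adapter to the forward primer and the partial P7
#' adapter to the reverse primer. Re-tailing an already tailed pair is an
#' error.
#'
#' @param pair list/row with `fwd`, `rev` and optional `tails_attached`.
#' @return the pair with `fwd`/`rev` extended and `tails_attached = TRUE`.
#' @export
attach_tails <- function(pair) {
  if (isTRUE(pair$tails_attached)) stop("pair is already tailed")
  tails <- adapter_tails()
  pair$fwd <- paste0(tails[["p5"]], pair$fwd)
  pair$rev <- paste0(tails[["p7"]], pair$rev)
  pair$tails_attached <- TRUE
  pair
}
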