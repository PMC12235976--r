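# Independent oracles and fixture builders, used across test files.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Brute-force microsatellite enumeration: for every unit length and start
# position, extend a perfect repeat maximally; keep runs that are maximal
# (not extendable by a full unit on the left), have minimal period equal to
# the unit length, meet the repeat threshold and the strict flank rule.
# Completely independent of the rle-based scanner.
brute_ssr <- function(seq, thresholds = c("2" = 10, "3" = 8, "4" = 4, "5" = 4),
                      min_flank = 20L) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  res <- list()
  for (u in as.integer(names(thresholds))) {
    min_rep <- thresholds[[as.character(u)]]
    for (s in seq_len(n)) {              # 1-based start
      if (s + u - 1L > n) break
      unit <- substr(seq, s, s + u - 1L)
      if (grepl("N", unit, fixed = TRUE)) next
      # minimal period must be u
      per <- u
      for (p in seq_len(u - 1L)) {
        if (u %% p == 0L &&
            unit == strrep(substr(unit, 1L, p), u %/% p)) { per <- p; break }
      }
      if (per < u) next
      # extend right
      k <- 1L
      while (s + (k + 1L) * u - 1L <= n &&
             substr(seq, s + k * u, s + (k + 1L) * u - 1L) == unit) k <- k + 1L
      if (k < min_rep) next
      # maximality/phase dedup: the run must not be extendable to the left
      # by a full unit, nor by a single base in phase (which would mean a
      # phase-shifted copy of the same run was already reported)
      if (s - u >= 1L && substr(seq, s - u, s - 1L) == unit) next
      if (s - 1L >= 1L && ch[s - 1L] == ch[s - 1L + u]) next
      e <- s + k * u - 1L
      lf <- s - 1L
      rf <- n - e
      if (lf <= min_flank || rf <= min_flank) next
      res[[length(res) + 1L]] <- data.frame(
        unit_len = u, n_repeats = k, start = lf, end = e, lf = lf, rf = rf)
    }
  }
  if (!length(res)) return(data.frame(unit_len = integer(), n_repeats = integer(),
                                      start = integer()))
  do.call(rbind, res)
}

# plant a perfect repeat in a read with flanks that cannot extend the run
plant_read <- function(flank_left, unit, reps, flank_right) {
  lf <- rand_dna(flank_left)
  u <- nchar(unit)
  last <- substr(unit, u, u)
  if (flank_left > 0 && substr(lf, flank_left, flank_left) == last)
    substr(lf, flank_left, flank_left) <- setdiff(c("A","C","G","T"), last)[1]
  rf <- rand_dna(flank_right)
  first <- substr(unit, 1, 1)
  if (flank_right > 0 && substr(rf, 1, 1) == first)
    substr(rf, 1, 1) <- setdiff(c("A","C","G","T"), first)[1]
  paste0(lf, strrep(unit, reps), rf)
}

# Exhaustive Smith-Waterman over the full subject (no seeding), same scoring
# as the mapper; used as the alignment oracle on small genomes.
sw_best_hits <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
  list(score = Biostrings::score(pa),
       start = Biostrings::start(Biostrings::subject(pa)) - 1L,
       end = Biostrings::end(Biostrings::subject(pa)))
}

# Hand-summed nearest-neighbor Tm oracle with its own copy of the unified
# parameter tables, written as explicit per-dinucleotide lookups.
oracle_tm <- function(seq, na = 0.05, ct = 250e-9) {
  dh_tab <- list(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
                 CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  ds_tab <- list(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
                 CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(seq, "")[[1]]
  dh <- 0; ds <- 0
  for (i in seq_len(length(ch) - 1)) {
    d <- paste0(ch[i], ch[i + 1])
    if (is.null(dh_tab[[d]])) {
      # read the antiparallel complement 5'->3'
      d <- paste0(comp[ch[i + 1]], comp[ch[i]])
    }
    dh <- dh + dh_tab[[d]]
    ds <- ds + ds_tab[[d]]
  }
  for (b in c(ch[1], ch[length(ch)])) {
    if (b %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (length(ch) - 1) * log(na)
  dh * 1000 / (ds + 1.9872 * log(ct / 4)) - 273.15
}

# two groups fixed for different alleles at n_fixed loci; a few shared
# polymorphic loci provide within-group variance (used by DAPC tests)
two_separated_clusters <- function(n_per = 10, n_fixed = 20, n_noise = 5) {
  set.seed(99)
  a_a <- matrix("100", n_per, n_fixed)
  a_b <- matrix("108", n_per, n_fixed)
  a1 <- rbind(a_a, a_b)
  a2 <- a1
  noise1 <- matrix(sample(c("50", "54"), 2 * n_per * n_noise, TRUE),
                   2 * n_per, n_noise)
  noise2 <- matrix(sample(c("50", "54"), 2 * n_per * n_noise, TRUE),
                   2 * n_per, n_noise)
  a1 <- cbind(a1, noise1); a2 <- cbind(a2, noise2)
  rownames(a1) <- rownames(a2) <- paste0("i", seq_len(2 * n_per))
  colnames(a1) <- colnames(a2) <- paste0("L", seq_len(n_fixed + n_noise))
  genotype_matrix(a1, a2, rep(c("A", "B"), each = n_per))
}

# small structured matrix used by several popgen tests
toy_two_pop_matrix <- function() {
  a1 <- matrix(c("100", "100", "100", "104",
                 "104", "104", "104", "104"), ncol = 1)
  a2 <- matrix(c("100", "100", "104", "104",
                 "104", "104", "104", "104"), ncol = 1)
  rownames(a1) <- rownames(a2) <- paste0("i", 1:8)
  colnames(a1) <- colnames(a2) <- "L1"
  genotype_matrix(a1, a2, pop = rep(c("A", "B"), each = 4))
}
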