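test_that("Tm is duplex-symmetric, GC-monotone, and matches the hand-summed oracle", {
  s <- "ACGTACGTACGTACGTACGT"
  expect_equal(melting_temperature(s), melting_temperature(revcomp(s)))
  # same length, 50% vs 30% GC
  hi <- "ACGCATGCGTACGCATGCGT"   # 55% GC
  lo <- "ACATATGATTACATATGATT"   # 20% GC
  expect_gt(melting_temperature(hi), melting_temperature(lo))
  # independent per-dinucleotide summation
  for (oligo in c("AGCGTAACGGTCAGTCCATG", "TTGACCTGAAGGATCGATCGA",
                  "CAAAAAACCCCCGGGGTTTT")) {
    expect_equal(melting_temperature(oligo), oracle_tm(oligo), tolerance = 1e-10)
  }
  expect_error(melting_temperature("ACGTACGN"), "ambiguity")
  expect_error(melting_temperature("ACGT"), "length")
})

make_designable_template <- function(seed, motif = "ACGT", reps = 6,
                                     left = 200, right = 400) {
  set.seed(seed)
  paste0(rand_dna(left), strrep(motif, reps), rand_dna(right))
}

test_that("designed SSR pairs satisfy every constraint predicate", {
  # independent re-check of every accepted pair, vectorized per template
  clamp <- function(s) {
    n <- nchar(s)
    gc2 <- function(x) nchar(gsub("[^GC]", "", x))
    gc2(substr(s, 1, 2)) >= 1 & gc2(substr(s, n - 1, n)) >= 1
  }
  n_checked <- 0
  for (seed in 1:12) {
    tmpl <- make_designable_template(seed)
    span <- c(200L, 200L + 24L)
    pp <- design_pairs(tmpl, motif_span = span)
    if (!nrow(pp)) next
    n_checked <- n_checked + nrow(pp)
    expect_true(all(nchar(pp$fwd) >= 18 & nchar(pp$fwd) <= 22 &
                      nchar(pp$rev) >= 18 & nchar(pp$rev) <= 22))
    expect_true(all(abs(pp$tm_fwd - pp$tm_rev) < 5))
    expect_true(all(abs(pp$tm_fwd - 55) <= 3 & abs(pp$tm_rev - 55) <= 3))
    expect_true(all(pp$gc_fwd >= 0.40 & pp$gc_fwd <= 0.60 &
                      pp$gc_rev >= 0.40 & pp$gc_rev <= 0.60))
    expect_true(all(pp$product_len >= 425 & pp$product_len <= 470))
    expect_true(all(clamp(pp$fwd) & clamp(pp$rev)))
    # reported Tm matches the standalone calculator (spot-check top pair)
    expect_equal(pp$tm_fwd[1], melting_temperature(pp$fwd[1]))
    expect_equal(pp$tm_rev[1], melting_temperature(pp$rev[1]))
    # primers are genuine template substrings in the right orientation
    expect_equal(substring(tmpl, pp$fwd_start + 1, pp$fwd_start + nchar(pp$fwd)),
                 pp$fwd)
    expect_equal(vapply(substring(tmpl, pp$rev_end - nchar(pp$rev) + 1, pp$rev_end),
                        revcomp, "", USE.NAMES = FALSE),
                 pp$rev)
    # full motif inside the amplicon, within 250 bases of one end, and not
    # under a primer footprint
    expect_true(all(span[1] >= pp$fwd_start & span[2] <= pp$rev_end))
    expect_true(all(span[2] - pp$fwd_start <= 250 | pp$rev_end - span[1] <= 250))
    expect_true(all(pp$fwd_start + nchar(pp$fwd) <= span[1]))
  }
  expect_gt(n_checked, 50)
})

test_that("templates that cannot host a product in the window give an empty list", {
  set.seed(101)
  # template shorter than the minimum product: nothing fits
  expect_equal(nrow(design_pairs(rand_dna(400))), 0L)
  # a 480 bp template can only host products <= 480 but >= 425: widen then
  # narrow the window to show the window is what rules pairs out
  tmpl <- rand_dna(480)
  pp_any <- design_pairs(tmpl, constraints = list(product_range = c(475L, 480L)))
  pp_window <- design_pairs(tmpl, constraints = list(product_range = c(481L, 500L)))
  expect_equal(nrow(pp_window), 0L)
})

test_that("EPIC-mode footprints stay inside conserved windows", {
  set.seed(102)
  tmpl <- rand_dna(540)
  wins <- data.frame(start = c(0L, 430L), end = c(80L, 540L))
  pp <- design_pairs(tmpl, conserved_windows = wins)
  expect_gt(nrow(pp), 0L)
  expect_true(all(pp$fwd_start >= 0 & pp$fwd_start + nchar(pp$fwd) <= 80))
  expect_true(all(pp$rev_end - nchar(pp$rev) >= 430 & pp$rev_end <= 540))
})

test_that("read-duplication screen counts full-length near-matches on either strand", {
  set.seed(103)
  fwd <- "ACGCATGCGTACGCATGGGT"
  rev <- "TGCCATGCGTACGCATGCAT"
  pair <- list(fwd = fwd, rev = rev)
  mk <- function(p, mut = 0) {
    s <- paste0(rand_dna(40), p, rand_dna(40))
    if (mut > 0) {
      pos <- 40 + sample(nchar(p), mut)
      for (q in pos) substr(s, q, q) <- setdiff(c("A","C","G","T"), substr(s, q, q))[1]
    }
    s
  }
  reads <- c(mk(fwd), mk(revcomp(fwd), mut = 1), mk(rev), rand_dna(100))
  v <- duplication_screen_reads(pair, reads)
  expect_equal(v$fwd_reads, 2L)  # exact + 1-mismatch revcomp copy
  expect_equal(v$rev_reads, 1L)
  expect_true("DUPLICATED_READS" %in% v$flags)
  v1 <- duplication_screen_reads(pair, c(mk(fwd), mk(rev)))
  expect_length(v1$flags, 0L)
  v0 <- duplication_screen_reads(pair, list(list(id = "r", seq = rand_dna(80))))
  expect_length(v0$flags, 0L)   # zero support passes the rule as stated
  expect_equal(v0$fwd_reads, 0L)
  # brute-force oracle: substring hamming scan over all offsets/strands
  brute <- function(primer, reads) {
    hit <- function(s) {
      n <- nchar(primer)
      for (o in 0:(nchar(s) - n)) {
        w <- substr(s, o + 1, o + n)
        d1 <- sum(strsplit(w, "")[[1]] != strsplit(primer, "")[[1]])
        d2 <- sum(strsplit(w, "")[[1]] != strsplit(revcomp(primer), "")[[1]])
        if (min(d1, d2) <= 1) return(TRUE)
      }
      FALSE
    }
    sum(vapply(reads, hit, TRUE))
  }
  expect_equal(v$fwd_reads, brute(fwd, reads))
  expect_equal(v$rev_reads, brute(rev, reads))
})

test_that("genome screen distinguishes unique, absent and duplicated primers", {
  set.seed(104)
  insert <- rand_dna(410)
  fwd <- "ACGCATGCGTACGCATGGGT"
  rev <- "TGCCATGCGTACGCATGCAT"
  template <- paste0(fwd, insert, revcomp(rev))  # 450 bp product
  genome <- c(chr1 = paste0(rand_dna(500), template, rand_dna(500)))
  pair <- list(fwd = fwd, rev = rev)
  expect_length(genome_screen(pair, genome)$flags, 0L)
  # absent forward primer
  v <- genome_screen(list(fwd = rand_dna(20), rev = rev), genome)
  expect_true("NO_GENOME_HIT" %in% v$flags)
  # duplicated template contig flips the verdict
  genome2 <- c(genome, chr2 = paste0(rand_dna(100), template, rand_dna(100)))
  v2 <- genome_screen(pair, genome2)
  expect_true("MULTI_GENOME_HIT" %in% v2$flags)
})

test_that("adapter tails are the exact partial P5/P7 strings and tailing is guarded", {
  pair <- list(fwd = "ACGTACGTACGTACGTACGT", rev = "TGCATGCATGCATGCATGCA",
               tails_attached = FALSE)
  t1 <- attach_tails(pair)
  expect_equal(t1$fwd, "TCTTTCCCTACACGACGCTCTTCCGATCTACGTACGTACGTACGTACGT")
  expect_equal(t1$rev, "CTGGAGTTCAGACGTGTGCTCTTCCGATCTTGCATGCATGCATGCATGCA")
  expect_error(attach_tails(t1), "already tailed")
})
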