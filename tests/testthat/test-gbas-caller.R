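test_that("read pairs reconstruct the insert exactly and respect geometry limits", {
  set.seed(201)
  insert <- rand_dna(450)
  r1 <- list(id = "p", seq = substr(insert, 1, 300), qual = rep(35L, 300))
  r2 <- list(id = "p", seq = revcomp(substr(insert, 151, 450)), qual = rep(35L, 300))
  m <- merge_pairs(r1, r2)
  expect_equal(m$seq, insert)
  expect_equal(nchar(m$seq), 450L)
  # 620 bp insert: overlap of 300 bp reads would be negative
  long <- rand_dna(620)
  expect_null(merge_pairs(list(id = "q", seq = substr(long, 1, 300), qual = rep(35L, 300)),
                          list(id = "q", seq = revcomp(substr(long, 321, 620)), qual = rep(35L, 300))))
  expect_error(merge_pairs(list(id = "z", seq = "", qual = integer()), r2),
               "zero-length")
})

test_that("overlap disagreements resolve to the higher-quality base", {
  set.seed(202)
  insert <- rand_dna(100)
  r1seq <- substr(insert, 1, 70)
  r2seq <- substr(insert, 31, 100)
  # plant a disagreement at insert position 50 (read1 pos 50, read2 pos 20)
  wrong <- setdiff(c("A", "C", "G", "T"), substr(insert, 50, 50))[1]
  r1bad <- r1seq
  substr(r1bad, 50, 50) <- wrong
  q1 <- rep(10L, 70); q2 <- rep(40L, 70)
  m <- merge_pairs(list(id = "x", seq = r1bad, qual = q1),
                   list(id = "x", seq = revcomp(r2seq), qual = rev(q2)))
  expect_equal(substr(m$seq, 50, 50), substr(insert, 50, 50))  # Q40 wins
  # flip the qualities: the error wins instead
  m2 <- merge_pairs(list(id = "x", seq = r1bad, qual = rep(40L, 70)),
                    list(id = "x", seq = revcomp(r2seq), qual = rev(rep(10L, 70))))
  expect_equal(substr(m2$seq, 50, 50), wrong)
})

make_panel <- function() {
  data.frame(locus_id = c("Bv7", "Bv9"),
             fwd = c("ACGCATGCGTACGCATGGGT", "TTGACCTGAAGGATCGATCG"),
             rev = c("TGCCATGCGTACGCATGCAT", "CAGGTTCAGGATCGGTTACG"),
             stringsAsFactors = FALSE)
}

test_that("demultiplexing assigns, trims, and routes conflicts to undetermined", {
  set.seed(203)
  panel <- make_panel()
  ins <- rand_dna(120)
  ok <- list(id = "r1", seq = paste0(panel$fwd[1], ins, revcomp(panel$rev[1])))
  # 3 mismatches in the forward primer: above the allowance of 2
  f3 <- panel$fwd[1]
  for (p in c(3, 9, 15))
    substr(f3, p, p) <- setdiff(c("A", "C", "G", "T"), substr(f3, p, p))[1]
  bad <- list(id = "r2", seq = paste0(f3, ins, revcomp(panel$rev[1])))
  chim <- list(id = "r3", seq = paste0(panel$fwd[1], ins, revcomp(panel$rev[2])))
  dm <- demultiplex_by_primer(list(ok, bad, chim), panel)
  expect_equal(dm$assigned$Bv7, ins)
  expect_length(dm$assigned$Bv9, 0L)
  expect_setequal(dm$undetermined$read_id, c("r2", "r3"))
  expect_equal(dm$undetermined$reason[dm$undetermined$read_id == "r3"],
               "chimeric/conflicting primer pair")
  # a shared primer between two loci is a configuration error
  panel2 <- make_panel(); panel2$fwd[2] <- panel2$fwd[1]
  expect_error(demultiplex_by_primer(list(ok), panel2), "configuration error")
})

test_that("genotype calling handles homozygotes, SNP heterozygotes, stutter and depth", {
  a <- paste0(rand_dna(30), strrep("ACGT", 8), rand_dna(30))
  b <- a; substr(b, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(a, 5, 5))[1]
  # single sequence: homozygote
  hom <- call_genotype(c(stats::setNames(100L, a)))
  expect_equal(hom$alleles, c(a, a))
  expect_length(hom$flags, 0L)
  # same-length SNP variant at 40/60: heterozygote
  het <- call_genotype(stats::setNames(c(60L, 40L), c(a, b)), error_ratio = 10)
  expect_setequal(het$alleles, c(a, b))
  # one-unit-shorter sequence below half the parent count: stutter fold
  stut_seq <- paste0(rand_dna(0), substr(a, 5, nchar(a)))  # 4 bp shorter, distinct
  stut_seq <- substr(a, 1, nchar(a) - 4)
  st <- call_genotype(stats::setNames(c(100L, 30L), c(a, stut_seq)), ssr_unit = 4L)
  expect_equal(st$alleles, c(a, a))
  expect_true("STUTTER_COLLAPSED" %in% st$flags)
  # the same minor count without ssr_unit stays a heterozygote
  no_unit <- call_genotype(stats::setNames(c(100L, 30L), c(a, stut_seq)))
  expect_setequal(no_unit$alleles, c(a, stut_seq))
  # below min_depth: missing with LOW_DEPTH
  low <- call_genotype(stats::setNames(5L, a))
  expect_null(low$alleles)
  expect_true("LOW_DEPTH" %in% low$flags)
  # sequencing-error collapse: singleton 1 edit away from a 100x sequence
  err <- b
  ec <- call_genotype(stats::setNames(c(100L, 4L), c(a, err)))
  expect_equal(ec$alleles, c(a, a))
})

test_that("sample, marker, monomorphic and population filters apply in order", {
  # 10 loci; sample s_bad misses 4/10 (40%), s_edge misses 3/10 (30%)
  set.seed(204)
  n <- 12; L <- 10
  a1 <- matrix("100", n, L, dimnames = list(paste0("s", 1:n), paste0("L", 1:L)))
  a2 <- a1
  # make loci polymorphic (alternate a second allele in half the rows)
  a2[seq(1, n, 2), ] <- "104"
  a1["s1", 1:4] <- NA; a2["s1", 1:4] <- NA          # 40% -> dropped
  a1["s2", 1:3] <- NA; a2["s2", 1:3] <- NA          # exactly 30% -> kept
  # marker L10 missing for 5 of the 11 remaining samples (45%) -> dropped
  a1[3:7, 10] <- NA; a2[3:7, 10] <- NA
  # L9 monomorphic
  a1[, 9] <- "200"; a2[, 9] <- "200"
  pop <- c(rep("A", 8), rep("B", 4))
  pop[1] <- "A"
  m <- genotype_matrix(a1, a2, pop)
  # make population B small after sample filtering: move s1 to B
  m$pop <- c("B", rep("A", 7), "B", "B", "B", "A")
  res <- apply_study_filters(m, min_pop_n = 4L)
  expect_false("s1" %in% gm_samples(res$matrix))
  expect_true("s2" %in% gm_samples(res$matrix))
  expect_false("L10" %in% gm_loci(res$matrix))
  expect_false("L9" %in% gm_loci(res$matrix))
  expect_false("B" %in% gm_populations(res$matrix))  # 3 left after s1 dropped
  expect_setequal(unique(res$report$stage),
                  c("sample_missing", "marker_missing", "monomorphic",
                    "small_population"))
})

test_that("filtering a filtered matrix changes nothing", {
  cfg <- sim_config(seed = 208, n_pops = 4, n_per_pop = c(10, 10, 10, 4),
                    n_loci = 30, F = 0.08, missing_rate = 0.10)
  m <- simulate_genotypes(cfg)$matrix
  res <- apply_study_filters(m)
  res2 <- apply_study_filters(res$matrix)
  expect_true(isTRUE(all.equal(res$matrix, res2$matrix)))
  expect_equal(nrow(res2$report), 0L)
})

test_that("samples are filtered before markers, as a constructed matrix shows", {
  # 4 samples x 4 loci. Sample s1 misses 3/4 loci (75%). Locus L1 is missing
  # only in s1 (25%) once s1 is still present, and in 0% after s1 is gone.
  # Under marker-first ordering L1 would still pass, but L2 (missing in 2/4
  # = 50% with s1 present, 1/3 = 33% without it) flips verdicts between
  # orderings; with sample-first, L2 is dropped at 33% > 30%.
  a1 <- matrix("1", 4, 4, dimnames = list(paste0("s", 1:4), paste0("L", 1:4)))
  a2 <- matrix(c("1", "2"), 4, 4)
  dimnames(a2) <- dimnames(a1)
  a1["s1", c("L1", "L2", "L3")] <- NA; a2["s1", c("L1", "L2", "L3")] <- NA
  a1["s2", "L2"] <- NA; a2["s2", "L2"] <- NA
  m <- genotype_matrix(a1, a2, pop = rep("P", 4))
  res <- apply_study_filters(m, min_pop_n = 1L, drop_monomorphic = FALSE)
  expect_false("s1" %in% gm_samples(res$matrix))
  expect_false("L2" %in% gm_loci(res$matrix))   # 1/3 missing > 30%
  expect_true(all(c("L1", "L3", "L4") %in% gm_loci(res$matrix)))
})

test_that("clean simulated amplicons are called back to the exact truth", {
  cfg <- sim_config(seed = 29, n_pops = 2, n_per_pop = c(5, 5), n_loci = 5,
                    F = 0.05, error_rate = 0, depth_mean = 40)
  sim <- simulate_genotypes(cfg)
  amps <- simulate_amplicons(sim, cfg)
  reads <- lapply(amps, function(a) {
    out <- list()
    for (i in seq_along(a$r1)) {
      mg <- merge_pairs(a$r1[[i]], a$r2[[i]])
      if (!is.null(mg)) out[[length(out) + 1L]] <- mg
    }
    out
  })
  called <- call_genotypes(reads, sim$panel,
                           pop = stats::setNames(gm_populations(sim$matrix),
                                                 gm_samples(sim$matrix)))
  expect_true(isTRUE(all.equal(
    canonicalize_labels(sim$matrix, sim$truth$allele_seqs),
    canonicalize_labels(called))))
})

test_that("calling stays >= 99% accurate at 0.1% error and >= 50x depth", {
  # depth_mean 80 keeps essentially every sample x locus at or above 50x
  cfg <- sim_config(seed = 30, n_pops = 2, n_per_pop = c(5, 5), n_loci = 5,
                    F = 0.05, error_rate = 0.001, depth_mean = 80)
  sim <- simulate_genotypes(cfg)
  amps <- simulate_amplicons(sim, cfg)
  reads <- lapply(amps, function(a) {
    out <- list()
    for (i in seq_along(a$r1)) {
      mg <- merge_pairs(a$r1[[i]], a$r2[[i]])
      if (!is.null(mg)) out[[length(out) + 1L]] <- mg
    }
    out
  })
  called <- call_genotypes(reads, sim$panel,
                           pop = stats::setNames(gm_populations(sim$matrix),
                                                 gm_samples(sim$matrix)))
  tr <- canonicalize_labels(sim$matrix, sim$truth$allele_seqs)
  ca <- canonicalize_labels(called)
  same <- (pmin(tr$a1, tr$a2) == pmin(ca$a1, ca$a2)) &
    (pmax(tr$a1, tr$a2) == pmax(ca$a1, ca$a2))
  expect_gte(mean(same, na.rm = TRUE), 0.99)
})
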