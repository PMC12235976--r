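make_gene <- function(gene_id, exon_lens, intron_lens, genome_prefix = 0L) {
  pos <- genome_prefix
  exons <- matrix(0L, length(exon_lens), 2L,
                  dimnames = list(NULL, c("start", "end")))
  for (e in seq_along(exon_lens)) {
    exons[e, ] <- c(pos, pos + exon_lens[e])
    pos <- pos + exon_lens[e]
    if (e < length(exon_lens)) pos <- pos + intron_lens[e]
  }
  list(gene_id = gene_id, contig = "c1", strand = "+", exons = exons)
}

test_that("exon pairs obey the strict intron and exon length bounds", {
  set.seed(5)
  genome <- c(c1 = rand_dna(3000))
  genes <- list(
    make_gene("ok", c(150, 200), 350),       # qualifies
    make_gene("intron400", c(150, 200), 400, 800),  # intron not < 400
    make_gene("shortExon", c(18, 200), 100, 1800),  # exon5 not > 20
    make_gene("exon20", c(20, 200), 100, 2300)      # boundary: 20 is not > 20
  )
  pairs <- select_exon_pairs(genes, genome)
  expect_equal(pairs$gene_id, "ok")
  expect_equal(pairs$intron_len, 350L)
  expect_equal(pairs$expected_span, 150L + 350L + 200L)
  # 399 passes the strict bound, 21 bp exons pass theirs
  genes2 <- list(make_gene("edge", c(21, 21), 399))
  expect_equal(nrow(select_exon_pairs(genes2, genome)), 1L)
})

test_that("selection is invariant to gene order", {
  set.seed(6)
  genome <- c(c1 = rand_dna(4000))
  genes <- list(make_gene("a", c(60, 60, 60), c(100, 500)),
                make_gene("b", c(100, 30), 250, 1500),
                make_gene("c", c(25, 25), 399, 2500))
  p1 <- select_exon_pairs(genes, genome)
  p2 <- select_exon_pairs(rev(genes), genome)
  o <- function(p) p[order(p$gene_id, p$pair_index), ]
  expect_equal(o(p1)$gene_id, o(p2)$gene_id)
  expect_equal(o(p1)$intron_len, o(p2)$intron_len)
})

test_that("mapping onto a diverged target recovers the locus with exon-covering windows", {
  set.seed(7)
  exon5 <- rand_dna(150); exon3 <- rand_dna(160); intron <- rand_dna(120)
  donor_region <- paste0(exon5, intron, exon3)
  # target: identical exons, 10% diverged intron, embedded in background
  intron_t <- intron
  hits <- sample(nchar(intron), 12)
  ch <- strsplit(intron_t, "")[[1]]
  for (i in hits) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  target <- c(chr = paste0(rand_dna(500), exon5, paste(ch, collapse = ""),
                           exon3, rand_dna(500)))
  pair <- list(gene_id = "g1", exon5 = exon5, exon3 = exon3, intron_len = 120L)
  loc <- map_to_target(pair, target, product_window = NULL)
  expect_s3_class(loc, "epic_locus")
  w <- loc$conserved_windows
  expect_equal(nrow(w), 2L)
  expect_equal(w$end - w$start, c(150L, 160L))  # full exon footprints
  expect_equal(loc$target_intron_len, 120L)
  # extracted region matches the planted homolog
  expect_equal(nchar(loc$target_region), 150L + 120L + 160L)
})

test_that("absent genes and duplicated exons yield no locus", {
  set.seed(8)
  exon5 <- rand_dna(150); exon3 <- rand_dna(160)
  pair <- list(gene_id = "g1", exon5 = exon5, exon3 = exon3, intron_len = 100L)
  expect_null(map_to_target(pair, c(chr = rand_dna(2000)), product_window = NULL))
  dup <- c(chr = paste0(rand_dna(300), exon5, rand_dna(100), exon3,
                        rand_dna(400), exon5, rand_dna(100), exon3,
                        rand_dna(300)))
  expect_null(suppressMessages(map_to_target(pair, dup, product_window = NULL)))
  expect_message(map_to_target(pair, dup, product_window = NULL), "ambiguous")
})

test_that("conserved windows split at mismatches and respect the length floor", {
  set.seed(9)
  exon5 <- rand_dna(150); exon3 <- rand_dna(160); intron <- rand_dna(100)
  # one exon5 mismatch at position 76 (1-based), i.e. 0-based column 75
  e5t <- exon5
  substr(e5t, 76, 76) <- setdiff(c("A", "C", "G", "T"), substr(exon5, 76, 76))[1]
  target <- c(chr = paste0(rand_dna(400), e5t, intron, exon3, rand_dna(400)))
  pair <- list(gene_id = "g", exon5 = exon5, exon3 = exon3, intron_len = 100L)
  loc <- map_to_target(pair, target, product_window = NULL)
  w5 <- loc$conserved_windows[loc$conserved_windows$start < 150, ]
  expect_equal(w5$end - w5$start, c(75L, 74L))
  expect_equal(w5$start[2] - w5$start[1], 76L)
  # mismatches every 10 bp leave no window of 18+
  e5bad <- exon5
  for (p in seq(5, 150, by = 10))
    substr(e5bad, p, p) <- setdiff(c("A", "C", "G", "T"), substr(exon5, p, p))[1]
  target2 <- c(chr = paste0(rand_dna(400), e5bad, intron, exon3, rand_dna(400)))
  loc2 <- map_to_target(pair, target2, product_window = NULL,
                        min_identity = 0.5)
  if (!is.null(loc2)) {
    w5b <- loc2$conserved_windows[loc2$conserved_windows$start < 160, ]
    expect_equal(nrow(w5b), 0L)
  }
})

test_that("seeded mapping agrees with the exhaustive Smith-Waterman oracle", {
  set.seed(10)
  cfg <- sim_config(seed = 91, n_genes = 6, exon_len_range = c(40, 160),
                    intron_divergence = 0.08)
  gp <- simulate_genome_pair(cfg)
  expect_lte(nchar(gp$target), 50000)
  gfile <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gp$donor_gff, gfile)
  genes <- read_gff3_genes(gfile, gp$donor)
  pairs <- select_exon_pairs(genes, gp$donor)
  for (i in seq_len(nrow(pairs))) {
    loc <- map_to_target(pairs[i, ], gp$target, product_window = NULL)
    if (!is.null(loc)) {
      subj <- if (loc$strand == "+") gp$target[["chr1"]] else
        revcomp(gp$target[["chr1"]])
      oracle <- sw_best_hits(pairs$exon5[i], subj)
      al5 <- loc$exon_alignments$exon5
      expect_equal(loc$target_start + al5$subject_start, oracle$start,
                   info = pairs$gene_id[i])
    }
  }
})

test_that("planted exon pairs are recovered exactly on a clean genome pair", {
  cfg <- sim_config(seed = 55, n_genes = 8, exon_divergence = 0,
                    intron_divergence = 0.1)
  gp <- simulate_genome_pair(cfg)
  gfile <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gp$donor_gff, gfile)
  genes <- read_gff3_genes(gfile, gp$donor)
  loci <- epic_mine(genes, gp$donor, gp$target, product_window = NULL)
  got <- sort(paste(vapply(loci, `[[`, "", "gene_id"),
                    vapply(loci, function(l) l$donor_intron_len, 0L)))
  want <- sort(paste(gp$truth$epic_pairs$gene_id, gp$truth$epic_pairs$intron_len))
  expect_equal(got, want)
  # windows cover the full exon footprints when exons are undiverged
  for (l in loci) {
    covered <- sum(l$conserved_windows$end - l$conserved_windows$start)
    exlen <- sum(!is.na(l$exon_alignments$exon5$match_flags)) +
      sum(!is.na(l$exon_alignments$exon3$match_flags))
    expect_equal(covered, exlen, info = l$gene_id)
  }
})
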