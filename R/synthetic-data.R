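#' Simulation configuration
#'
#' Bundles every knob of the simulators with defaults mirroring the scale of
#' a small urban/rural amphibian study: 5 populations of 5-16 individuals
#' and a few dozen co-dominant loci. Divergence follows the
#' Balding-Nichols model, whose drift parameter `F` equals the expected
#' FST between populations.
#'
#' @param seed mandatory RNG seed.
#' @param n_pops number of populations.
#' @param n_per_pop individuals per population (recycled).
#' @param n_loci number of loci.
#' @param n_alleles ancestral alleles per locus.
#' @param F Balding-Nichols drift parameter in `[0, 1)`, scalar or one per
#'   population.
#' @param null_rate null-allele frequency per locus.
#' @param missing_rate additional completely-at-random missingness.
#' @param variant_rate probability that an allele shares its length with
#'   another allele of the locus and differs only in sequence.
#' @param unit_len SSR repeat unit length of the simulated loci.
#' @param base_repeats repeats carried by the shortest allele.
#' @param flank_len flank length on each side of the repeat.
#' @param depth_mean,depth_dispersion read depth per sample x locus: Poisson
#'   mean, or negative binomial when `depth_dispersion` is finite (size
#'   parameter).
#' @param error_rate per-base substitution error rate of simulated reads.
#' @param stutter_rate probability that an SSR read loses one repeat unit.
#' @param read_len simulated read length.
#' @param n_genes,exon_len_range,intron_len_range,intergenic_range donor
#'   genome layout for [simulate_genome_pair()].
#' @param exon_divergence,intron_divergence,n_planted_ssr donor/target
#'   divergence rates and number of planted microsatellites.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_pops = 5L, n_per_pop = c(6L, 9L, 5L, 5L, 16L),
                       n_loci = 30L, n_alleles = 4L, F = 0.1,
                       null_rate = 0, missing_rate = 0,
                       variant_rate = 0.25, unit_len = 4L,
                       base_repeats = 6L, flank_len = 180L,
                       depth_mean = 100, depth_dispersion = Inf,
                       error_rate = 0.001, stutter_rate = 0,
                       read_len = 300L,
                       n_genes = 12L, exon_len_range = c(30L, 200L),
                       intron_len_range = c(80L, 600L),
                       intergenic_range = c(300L, 700L),
                       exon_divergence = 0, intron_divergence = 0.1,
                       n_planted_ssr = 6L) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(F >= 0), all(F < 1), null_rate >= 0, null_rate <= 1,
            missing_rate >= 0, missing_rate <= 1, n_loci >= 1)
  cfg <- as.list(environment())
  cfg$n_per_pop <- rep_len(n_per_pop, n_pops)
  cfg$F <- rep_len(F, n_pops)
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n, exclude_first = NULL, exclude_last = NULL) {
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (!is.null(exclude_first) && b[1] == exclude_first)
    b[1] <- sample(setdiff(c("A", "C", "G", "T"), exclude_first), 1)
  if (!is.null(exclude_last) && b[n] == exclude_last)
    b[n] <- sample(setdiff(c("A", "C", "G", "T"), exclude_last), 1)
  paste(b, collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate structured diploid genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies are symmetric-Dirichlet per locus;
#' population frequencies are Dirichlet around the ancestral vector with
#' concentration `(1 - F) / F` (for `F = 0` the ancestral frequencies are
#' used unchanged); genotypes are drawn under Hardy-Weinberg within
#' populations. Null alleles of frequency `null_rate` are injected as an
#' extra unamplifiable allele: null homozygotes become missing, null
#' heterozygotes apparent homozygotes. Additional missingness is applied at
#' `missing_rate`. Allele sequences are built as
#' `flank + unit x repeats + flank`, repeats varying between alleles;
#' `variant_rate` alleles duplicate an existing length and differ by one
#' flank substitution, so both length and sequence variation are exercised.
#'
#' @param cfg a [sim_config()].
#' @return list: `matrix` (the observed [genotype_matrix()]), `panel`
#'   (data.frame `locus_id`, `fwd`, `rev`, `ssr_unit`), `truth` (list with
#'   `ancestral_freqs`, `pop_freqs`, `allele_meta` label/sequence tables,
#'   `true_a1`/`true_a2` pre-corruption label matrices, `null_mask`,
#'   `missing_mask`).
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  n_ind <- sum(cfg$n_per_pop)
  pops <- paste0("pop", seq_len(cfg$n_pops))
  pop <- rep(pops, cfg$n_per_pop)
  samples <- paste0(pop, "_", unlist(lapply(cfg$n_per_pop, seq_len)))
  loci <- paste0("L", seq_len(cfg$n_loci))
  a1 <- matrix(NA_character_, n_ind, cfg$n_loci, dimnames = list(samples, loci))
  a2 <- a1
  anc <- list(); popf <- list(); meta <- list()
  null1 <- matrix(FALSE, n_ind, cfg$n_loci)
  null2 <- matrix(FALSE, n_ind, cfg$n_loci)
  panel <- data.frame(locus_id = loci, fwd = NA_character_,
                      rev = NA_character_, ssr_unit = cfg$unit_len,
                      stringsAsFactors = FALSE)
  for (j in seq_len(cfg$n_loci)) {
    k <- cfg$n_alleles
    unit <- random_dna(cfg$unit_len)
    while (min_period(unit) < cfg$unit_len) unit <- random_dna(cfg$unit_len)
    # flanks must not extend the planted repeat run
    lf <- random_dna(cfg$flank_len, exclude_last = substr(unit, cfg$unit_len, cfg$unit_len))
    rf <- random_dna(cfg$flank_len, exclude_first = substr(unit, 1L, 1L))
    reps <- cfg$base_repeats + seq_len(k) - 1L
    seqs <- character(k)
    for (i in seq_len(k)) {
      if (i > 1L && stats::runif(1) < cfg$variant_rate) {
        # same length as a previous allele, one flank SNP instead
        reps[i] <- reps[i - 1L]
        base <- seqs[i - 1L]
        pos <- sample(seq_len(cfg$flank_len %/% 2), 1)  # early in left flank
        ch <- strsplit(base, "", fixed = TRUE)[[1]]
        ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
        seqs[i] <- paste(ch, collapse = "")
      } else {
        seqs[i] <- paste0(lf, strrep(unit, reps[i]), rf)
      }
    }
    lens <- nchar(seqs)
    labels <- character(k)
    for (L in unique(lens)) {
      idx <- which(lens == L)
      labels[idx] <- if (length(idx) == 1L) as.character(L) else
        paste0(L, ".", seq_along(idx))
    }
    meta[[j]] <- data.frame(label = labels, seq = seqs, length = lens,
                            stringsAsFactors = FALSE)
    panel$fwd[j] <- random_dna(20L)
    panel$rev[j] <- random_dna(20L)
    p_anc <- rdirichlet1(rep(1, k))
    anc[[j]] <- p_anc
    pf <- matrix(0, cfg$n_pops, k, dimnames = list(pops, labels))
    for (pi in seq_len(cfg$n_pops)) {
      Fp <- cfg$F[pi]
      pf[pi, ] <- if (Fp == 0) p_anc else
        rdirichlet1(p_anc * (1 - Fp) / Fp)
    }
    popf[[j]] <- pf
    # genotypes: visible alleles plus a null allele at null_rate
    r <- cfg$null_rate
    for (i in seq_len(n_ind)) {
      pi <- match(pop[i], pops)
      pvis <- pf[pi, ] * (1 - r)
      probs <- c(pvis, r)
      g <- sample.int(k + 1L, 2L, replace = TRUE, prob = probs)
      is_null <- g == k + 1L
      null1[i, j] <- is_null[1]; null2[i, j] <- is_null[2]
      if (all(is_null)) next                      # null homozygote -> missing
      vis <- g[!is_null]
      if (length(vis) == 1L) vis <- c(vis, vis)   # null het -> apparent hom
      a1[i, j] <- labels[vis[1]]
      a2[i, j] <- labels[vis[2]]
    }
  }
  true_a1 <- a1; true_a2 <- a2
  missing_mask <- matrix(FALSE, n_ind, cfg$n_loci)
  if (cfg$missing_rate > 0) {
    missing_mask <- matrix(stats::runif(n_ind * cfg$n_loci) < cfg$missing_rate,
                           n_ind, cfg$n_loci)
    a1[missing_mask] <- NA; a2[missing_mask] <- NA
  }
  names(meta) <- loci
  allele_seqs <- lapply(meta, function(md) stats::setNames(md$seq, md$label))
  list(
    matrix = genotype_matrix(a1, a2, pop),
    panel = panel,
    truth = list(ancestral_freqs = anc, pop_freqs = popf, allele_meta = meta,
                 allele_seqs = allele_seqs,
                 true_a1 = true_a1, true_a2 = true_a2,
                 null_mask = null1 | null2, missing_mask = missing_mask)
  )
}

rdepth <- function(n, mean, dispersion) {
  if (is.finite(dispersion)) stats::rnbinom(n, size = dispersion, mu = mean)
  else stats::rpois(n, mean)
}

#' Simulate amplicon read pairs for a genotype matrix
#'
#' Per sample and locus, read depth is drawn from the configured
#' distribution and split binomially between the two alleles of the
#' (observed) genotype; missing cells yield no reads. Each read is the
#' allele sequence wrapped in the locus primers, with substitution errors at
#' `error_rate` per base and, for SSR loci, reads shortened by one repeat
#' unit at `stutter_rate`. Reads are emitted as overlapping pairs of length
#' `read_len` (read 2 reverse-complemented), qualities constant Q37.
#'
#' @param sim output of [simulate_genotypes()] (uses `matrix`, `panel`,
#'   `truth$allele_meta`).
#' @param cfg the same [sim_config()].
#' @param dir optional directory: when given, per-sample FASTQ pairs
#'   (`<sample>_R1.fastq`, `<sample>_R2.fastq`) are written there.
#' @return named list per sample: `list(r1 =, r2 =)` lists of records, plus
#'   attribute `truth` (data.frame of emitted fragment counts per sample,
#'   locus and allele, including stutter fragments).
#' @export
simulate_amplicons <- function(sim, cfg, dir = NULL) {
  set.seed(cfg$seed + 1L)
  m <- sim$matrix; panel <- sim$panel; meta <- sim$truth$allele_meta
  out <- list()
  truth_rows <- list()
  for (s in gm_samples(m)) {
    r1 <- list(); r2 <- list()
    for (j in seq_len(nrow(panel))) {
      lab1 <- m$a1[s, panel$locus_id[j]]
      if (is.na(lab1)) next
      lab2 <- m$a2[s, panel$locus_id[j]]
      md <- meta[[panel$locus_id[j]]]
      depth <- rdepth(1L, cfg$depth_mean, cfg$depth_dispersion)
      if (depth == 0L) next
      n1 <- stats::rbinom(1L, depth, 0.5)
      for (al in list(c(lab1, n1), c(lab2, depth - n1))) {
        nn <- as.integer(al[2])
        if (nn == 0L) next
        aseq <- md$seq[md$label == al[1]]
        for (rd in seq_len(nn)) {
          insert <- aseq
          stut <- cfg$stutter_rate > 0 && stats::runif(1) < cfg$stutter_rate
          if (stut) insert <- drop_one_unit(insert, cfg)
          amplicon <- paste0(panel$fwd[j], mutate_seq(insert, cfg$error_rate),
                             revcomp(panel$rev[j]))
          L <- nchar(amplicon)
          rl <- min(cfg$read_len, L)
          id <- sprintf("%s_%s_%s%s_%d", s, panel$locus_id[j], al[1],
                        if (stut) "_stutter" else "", rd)
          r1[[length(r1) + 1L]] <- list(id = id,
                                        seq = substr(amplicon, 1L, rl),
                                        qual = rep(37L, rl))
          r2[[length(r2) + 1L]] <- list(id = id,
                                        seq = revcomp(substr(amplicon, L - rl + 1L, L)),
                                        qual = rep(37L, rl))
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            sample = s, locus = panel$locus_id[j], allele = al[1],
            stutter = stut, stringsAsFactors = FALSE)
        }
      }
    }
    out[[s]] <- list(r1 = r1, r2 = r2)
    if (!is.null(dir)) {
      write_fastx(r1, file.path(dir, paste0(s, "_R1.fastq")), "FASTQ")
      write_fastx(r2, file.path(dir, paste0(s, "_R2.fastq")), "FASTQ")
    }
  }
  attr(out, "truth") <- do.call(rbind, truth_rows)
  out
}

# remove one repeat unit from an allele sequence (PCR slippage artifact)
drop_one_unit <- function(insert, cfg) {
  u <- cfg$unit_len
  # the repeat occupies [flank_len, len - flank_len); removing any unit is
  # equivalent for a perfect repeat
  start <- cfg$flank_len + 1L
  paste0(substr(insert, 1L, start - 1L), substr(insert, start + u, nchar(insert)))
}

#' Simulate a donor/target genome pair with annotation
#'
#' Builds a donor contig of `n_genes` gene models (alternating strands, one
#' decoy lncRNA gene included) separated by intergenic spacers, some of
#' which carry planted SSR motifs. The target contig is the donor mutated at
#' `exon_divergence` within exons, `intron_divergence` within introns and
#' 2% elsewhere. The truth record lists the exon pairs that satisfy the
#' EPIC criteria (both exons strictly longer than `min_exon`, intron
#' strictly shorter than `max_intron`) and the planted SSR positions.
#'
#' @param cfg a [sim_config()].
#' @param min_exon,max_intron criteria recorded in the truth (defaults 20
#'   and 400).
#' @param dir optional directory; when given writes `donor.fa`,
#'   `donor.gff3`, `target.fa`.
#' @return list: `donor` (named character), `donor_gff` (character lines),
#'   `target` (named character), `truth` (list `epic_pairs` data.frame,
#'   `ssr` data.frame).
#' @export
simulate_genome_pair <- function(cfg, min_exon = 20L, max_intron = 400L,
                                 dir = NULL) {
  set.seed(cfg$seed + 2L)
  pieces <- character(); kinds <- character(); gene_of <- integer()
  gff <- c("##gff-version 3")
  pos <- 0L  # 0-based
  genes <- list()
  ssr_truth <- list()
  spacer <- function(with_ssr) {
    len <- sample(seq(cfg$intergenic_range[1], cfg$intergenic_range[2]), 1)
    if (!with_ssr) return(list(seq = random_dna(len), ssr = NULL))
    unit <- random_dna(4L)
    while (min_period(unit) < 4L) unit <- random_dna(4L)
    reps <- sample(5:8, 1)
    lf <- random_dna(max(30L, len %/% 3),
                     exclude_last = substr(unit, 4L, 4L))
    rf <- random_dna(max(30L, len %/% 3),
                     exclude_first = substr(unit, 1L, 1L))
    list(seq = paste0(lf, strrep(unit, reps), rf),
         ssr = data.frame(unit = canonical_rotation(unit), unit_len = 4L,
                          n_repeats = reps, offset_in_spacer = nchar(lf),
                          stringsAsFactors = FALSE))
  }
  n_ssr_left <- cfg$n_planted_ssr
  for (g in seq_len(cfg$n_genes)) {
    sp <- spacer(n_ssr_left > 0L)
    if (!is.null(sp$ssr)) {
      sp$ssr$start <- pos + sp$ssr$offset_in_spacer
      ssr_truth[[length(ssr_truth) + 1L]] <- sp$ssr
      n_ssr_left <- n_ssr_left - 1L
    }
    pieces <- c(pieces, sp$seq); pos <- pos + nchar(sp$seq)
    n_exons <- sample(2:3, 1)
    exon_lens <- sample(seq(cfg$exon_len_range[1], cfg$exon_len_range[2]), n_exons)
    intron_lens <- sample(seq(cfg$intron_len_range[1], cfg$intron_len_range[2]),
                          n_exons - 1L)
    strand <- if (g %% 2L == 0L) "-" else "+"
    biotype <- if (g == cfg$n_genes) "lncRNA" else "protein_coding"
    gene_start <- pos
    exons <- matrix(0L, n_exons, 2L)
    for (e in seq_len(n_exons)) {
      exons[e, ] <- c(pos, pos + exon_lens[e])
      pieces <- c(pieces, random_dna(exon_lens[e]))
      pos <- pos + exon_lens[e]
      if (e < n_exons) {
        pieces <- c(pieces, random_dna(intron_lens[e]))
        pos <- pos + intron_lens[e]
      }
    }
    genes[[g]] <- list(gene_id = sprintf("g%02d", g), strand = strand,
                       biotype = biotype, exons = exons,
                       intron_lens = intron_lens, exon_lens = exon_lens)
    gid <- genes[[g]]$gene_id
    gff <- c(gff,
      sprintf("chr1\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_biotype=%s",
              gene_start + 1L, pos, strand, gid, biotype),
      sprintf("chr1\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              gene_start + 1L, pos, strand, gid, gid))
    for (e in seq_len(n_exons)) {
      gff <- c(gff,
        sprintf("chr1\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
                exons[e, 1] + 1L, exons[e, 2], strand, gid, e, gid))
    }
  }
  sp <- spacer(FALSE)
  pieces <- c(pieces, sp$seq)
  donor <- paste(pieces, collapse = "")
  donor_v <- c(chr1 = donor)
  # target: piecewise mutation at region-specific divergences
  ch <- strsplit(donor, "", fixed = TRUE)[[1]]
  region <- rep("intergenic", nchar(donor))
  for (g in genes) {
    for (e in seq_len(nrow(g$exons)))
      region[(g$exons[e, 1] + 1L):g$exons[e, 2]] <- "exon"
    if (nrow(g$exons) > 1L) for (e in seq_len(nrow(g$exons) - 1L))
      region[(g$exons[e, 2] + 1L):g$exons[e + 1L, 1]] <- "intron"
  }
  rate <- c(exon = cfg$exon_divergence, intron = cfg$intron_divergence,
            intergenic = 0.02)[region]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  target <- paste(ch, collapse = "")
  # truth: qualifying exon pairs
  ep <- list()
  for (g in genes) {
    if (g$biotype != "protein_coding") next
    for (e in seq_len(length(g$intron_lens))) {
      # transcription order: on minus strand pair e counts from the 3' end
      i5 <- if (g$strand == "+") e else nrow(g$exons) - e + 1L
      i3 <- if (g$strand == "+") e + 1L else nrow(g$exons) - e
      len5 <- g$exon_lens[i5]; len3 <- g$exon_lens[i3]
      ilen <- if (g$strand == "+") g$intron_lens[e] else
        rev(g$intron_lens)[e]
      if (len5 > min_exon && len3 > min_exon && ilen < max_intron) {
        ep[[length(ep) + 1L]] <- data.frame(
          gene_id = g$gene_id, pair_index = e, exon5_len = len5,
          exon3_len = len3, intron_len = ilen, stringsAsFactors = FALSE)
      }
    }
  }
  truth <- list(
    epic_pairs = if (length(ep)) do.call(rbind, ep) else
      data.frame(gene_id = character(), pair_index = integer(),
                 exon5_len = integer(), exon3_len = integer(),
                 intron_len = integer(), stringsAsFactors = FALSE),
    ssr = if (length(ssr_truth)) do.call(rbind, ssr_truth) else NULL
  )
  if (!is.null(dir)) {
    write_fastx(list(list(id = "chr1", seq = donor, qual = NULL)),
                file.path(dir, "donor.fa"), "FASTA")
    write_fastx(list(list(id = "chr1", seq = target, qual = NULL)),
                file.path(dir, "target.fa"), "FASTA")
    writeLines(gff, file.path(dir, "donor.gff3"))
  }
  list(donor = donor_v, donor_gff = gff, target = c(chr1 = target),
       truth = truth)
}
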