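#' Select contiguous exon pairs flanking short introns
#'
#' Walks every gene model and emits each consecutive exon pair whose exons
#' are both strictly longer than `min_exon` and whose intervening intron is
#' strictly shorter than `max_intron`. These are the anchor candidates for
#' exon-primed intron-crossing (EPIC) amplicons: conserved exons host the
#' primers, the variable intron provides the polymorphism. A gene may emit
#' several pairs.
#'
#' @param genes list of gene models ([read_gff3_genes()]).
#' @param genome named character vector of contig sequences.
#' @param max_intron maximum intron length, exclusive (default 400 bp).
#' @param min_exon minimum exon length, exclusive (default 20 bp).
#' @param product_window optional length-2 numeric: when given, a pair is
#'   annotated with whether exon5 + intron + exon3 can host a product in the
#'   window.
#' @return data.frame with columns `gene_id`, `pair_index`, `exon5`, `exon3`
#'   (sequences in transcription orientation), `intron_len`,
#'   `expected_span` (exon5 + intron + exon3 length).
#' @export
select_exon_pairs <- function(genes, genome, max_intron = 400L, min_exon = 20L,
                              product_window = NULL) {
  genome <- as_contig_vector(genome)
  rows <- list()
  for (gm in genes) {
    introns <- gene_intron_lengths(gm)
    if (!length(introns)) next
    exseqs <- gene_exon_seqs(gm, genome)
    exlens <- nchar(exseqs)
    for (i in seq_along(introns)) {
      if (exlens[i] <= min_exon || exlens[i + 1L] <= min_exon) next
      if (introns[i] >= max_intron) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gm$gene_id, pair_index = i,
        exon5 = exseqs[i], exon3 = exseqs[i + 1L],
        intron_len = introns[i],
        expected_span = exlens[i] + introns[i] + exlens[i + 1L],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), pair_index = integer(),
               exon5 = character(), exon3 = character(),
               intron_len = integer(), expected_span = integer(),
               stringsAsFactors = FALSE)
  if (!is.null(product_window) && nrow(out)) {
    out$window_compatible <- out$expected_span >= product_window[1]
  }
  out
}

# exact k-mer seed positions of any k-mer of `query` in `subject`;
# returns 0-based subject start positions of candidate query placements
seed_placements <- function(query, subject, k = 15L, step = 5L) {
  qn <- nchar(query)
  if (qn < k) return(integer())
  starts <- unique(c(seq(1L, qn - k + 1L, by = step), qn - k + 1L))
  hits <- integer()
  for (qs in starts) {
    kmer <- substr(query, qs, qs + k - 1L)
    m <- gregexpr(kmer, subject, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    # project seed hit back to an implied query placement (diagonal)
    hits <- c(hits, as.integer(m) - 1L - (qs - 1L))
  }
  sort(unique(hits[hits > -qn]))
}

# cluster nearby diagonals so indel jitter does not create fake "multiple
# placements"; returns representative 0-based starts
cluster_placements <- function(hits, tol = 30L) {
  if (!length(hits)) return(integer())
  groups <- cumsum(c(1L, diff(hits) > tol))
  as.integer(tapply(hits, groups, function(x) x[1]))
}

# local alignment of query against a window of subject; returns score,
# subject span (0-based half-open) and per-column match flags for query
# positions (NA where the query column is deleted/unaligned)
align_local <- function(query, subject_window, window_offset = 0L) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(subject_window),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 2
  )
  pat <- as.character(Biostrings::alignedPattern(pa))
  sub <- as.character(Biostrings::alignedSubject(pa))
  pc <- strsplit(pat, "", fixed = TRUE)[[1]]
  sc <- strsplit(sub, "", fixed = TRUE)[[1]]
  qstart <- Biostrings::start(Biostrings::pattern(pa))   # 1-based on query
  sstart0 <- window_offset + Biostrings::start(Biostrings::subject(pa)) - 1L
  matches <- rep(NA, nchar(query))
  subject_pos <- rep(NA_integer_, nchar(query))  # 0-based target position per query base
  qi <- qstart - 1L
  si <- sstart0
  for (i in seq_along(pc)) {
    if (pc[i] != "-") {
      qi <- qi + 1L
      if (sc[i] != "-") {
        subject_pos[qi] <- si
        matches[qi] <- pc[i] == sc[i]
      } else matches[qi] <- FALSE
    }
    if (sc[i] != "-") si <- si + 1L
  }
  list(
    score = Biostrings::score(pa),
    subject_start = sstart0,
    subject_end = window_offset + Biostrings::end(Biostrings::subject(pa)),
    query_start = qstart - 1L,
    query_end = Biostrings::end(Biostrings::pattern(pa)),
    identity = mean(matches, na.rm = TRUE),
    coverage = mean(!is.na(matches)),
    match_flags = matches,
    subject_pos = subject_pos
  )
}

#' Map a donor exon pair onto a target genome
#'
#' Locates the 5' donor exon in the target by exact 15-mer seeding followed
#' by windowed affine-gap local alignment (match +1, mismatch -2, gap open
#' -5, extend -2), extends the target region to cover the homologous intron
#' and 3' exon, and re-aligns both exons to the extended region. Returns
#' `NULL` when either exon fails the similarity floor, when no seed hits the
#' target, or when two distinct placements tie in score (suspected
#' duplication; logged as "ambiguous placement").
#'
#' @param pair one row of [select_exon_pairs()] output (or an equivalent
#'   list with `gene_id`, `exon5`, `exon3`, `intron_len`).
#' @param target_genome named character vector of target contigs.
#' @param min_seed seed k-mer length (default 15).
#' @param min_identity,min_coverage similarity floor per exon: identity over
#'   aligned columns and fraction of the exon aligned (defaults 0.70, 0.80).
#' @param max_intron search radius for the 3' exon beyond the 5' exon end.
#' @param product_window expected amplicon window (exon anchors + intron),
#'   default `c(425, 470)`; set `NULL` to skip the compatibility filter.
#' @param window_tol slack added to both sides of `product_window`.
#' @return an `epic_locus` list (`gene_id`, `contig`, `target_start`,
#'   `target_region`, `exon_alignments`, `conserved_windows`,
#'   `donor_intron_len`, `target_intron_len`) or `NULL`.
#' @export
map_to_target <- function(pair, target_genome, min_seed = 15L,
                          min_identity = 0.70, min_coverage = 0.80,
                          max_intron = 400L, product_window = c(425, 470),
                          window_tol = 0) {
  target_genome <- as_contig_vector(target_genome)
  exon5 <- pair$exon5; exon3 <- pair$exon3
  # the donor exons are in transcript orientation, so both target strands
  # must be searched; coordinates are kept on the searched orientation
  oriented <- list()
  for (ctg in names(target_genome)) {
    oriented[[paste0(ctg, "/+")]] <- target_genome[[ctg]]
    oriented[[paste0(ctg, "/-")]] <- revcomp(target_genome[[ctg]])
  }
  placements <- list()
  for (key in names(oriented)) {
    subj <- oriented[[key]]
    for (p0 in cluster_placements(seed_placements(exon5, subj, k = min_seed))) {
      pad <- 50L
      ws <- max(0L, p0 - pad)
      we <- min(nchar(subj), p0 + nchar(exon5) + pad)
      al <- align_local(exon5, substr(subj, ws + 1L, we), window_offset = ws)
      if (al$identity >= min_identity && al$coverage >= min_coverage)
        placements[[length(placements) + 1L]] <- c(list(key = key), al)
    }
  }
  if (!length(placements)) return(NULL)
  scores <- vapply(placements, function(p) p$score, 0)
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    message("ambiguous placement for ", pair$gene_id, ": ",
            length(best), " equally scoring hits")
    return(NULL)
  }
  p5 <- placements[[best]]
  subj <- oriented[[p5$key]]
  # search for exon3 downstream of the 5' exon within the intron radius
  search_start <- p5$subject_end
  search_end <- min(nchar(subj), search_start + max_intron + 2L * nchar(exon3) + 100L)
  if (search_end - search_start < min_seed) return(NULL)
  al3 <- align_local(exon3, substr(subj, search_start + 1L, search_end),
                     window_offset = search_start)
  if (!(al3$identity >= min_identity && al3$coverage >= min_coverage)) return(NULL)
  region_start <- p5$subject_start
  region_end <- al3$subject_end
  target_region <- substr(subj, region_start + 1L, region_end)
  # re-align both exons to the extracted region for final coordinates
  re5 <- align_local(exon5, target_region)
  re3_off <- re5$subject_end
  re3 <- align_local(exon3, substr(target_region, re3_off + 1L, nchar(target_region)),
                     window_offset = re3_off)
  target_intron_len <- re3$subject_start - re5$subject_end
  locus <- list(
    gene_id = pair$gene_id,
    contig = sub("/[+-]$", "", p5$key),
    strand = sub("^.*/", "", p5$key),
    target_start = region_start,
    target_region = target_region,
    donor_intron_len = pair$intron_len,
    target_intron_len = target_intron_len,
    exon_alignments = list(exon5 = re5, exon3 = re3),
    conserved_windows = NULL
  )
  class(locus) <- "epic_locus"
  locus$conserved_windows <- find_conserved_windows(locus)
  if (!is.null(product_window)) {
    span <- nchar(target_region)
    lo <- product_window[1] - window_tol
    hi <- product_window[2] + window_tol
    if (span < lo || span > hi) {
      locus$window_compatible <- FALSE
    } else locus$window_compatible <- TRUE
  }
  locus
}

#' Maximal fully conserved windows inside exon footprints
#'
#' Runs of consecutive alignment columns where donor and target are
#' identical (gaps count as mismatch), at least `min_len` long, restricted
#' to the aligned exon footprints on the target region. Conservation means
#' 100% identity: primers are only placed where donor and target agree at
#' every base.
#'
#' @param locus an `epic_locus` from [map_to_target()].
#' @param min_len minimum window length (default 18, the minimum primer
#'   length).
#' @return data.frame with 0-based half-open `start`, `end` on the target
#'   region, sorted by position.
#' @export
find_conserved_windows <- function(locus, min_len = 18L) {
  wins <- list()
  for (al in locus$exon_alignments) {
    flags <- al$match_flags
    ok <- !is.na(flags) & flags
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      # within an exact-match run there are no gaps, so the query->target
      # map recorded during alignment is consecutive over the run
      tstart <- al$subject_pos[starts[k]]
      wins[[length(wins) + 1L]] <- data.frame(
        start = tstart, end = tstart + r$lengths[k])
    }
  }
  if (!length(wins))
    return(data.frame(start = integer(), end = integer()))
  out <- do.call(rbind, wins)
  out[order(out$start), , drop = FALSE]
}

#' @export
print.epic_locus <- function(x, ...) {
  cat(sprintf("epic_locus %s on %s: region %d bp (intron donor %d / target %d bp), %d conserved window(s)\n",
              x$gene_id, x$contig, nchar(x$target_region),
              x$donor_intron_len, x$target_intron_len,
              nrow(x$conserved_windows)))
  invisible(x)
}

#' Mine EPIC loci from a donor genome against a target genome
#'
#' Convenience wrapper: [select_exon_pairs()] on the donor annotation, then
#' [map_to_target()] for each pair.
#'
#' @param genes donor gene models.
#' @param donor_genome,target_genome named character vectors of contigs.
#' @param ... passed through to [select_exon_pairs()] and [map_to_target()].
#' @inheritParams select_exon_pairs
#' @inheritParams map_to_target
#' @return list of `epic_locus` objects (pairs that failed to map are
#'   dropped).
#' @export
epic_mine <- function(genes, donor_genome, target_genome,
                      max_intron = 400L, min_exon = 20L,
                      product_window = c(425, 470), window_tol = 0) {
  pairs <- select_exon_pairs(genes, donor_genome,
                             max_intron = max_intron, min_exon = min_exon)
  loci <- list()
  for (i in seq_len(nrow(pairs))) {
    loc <- map_to_target(pairs[i, ], target_genome,
                         max_intron = max_intron,
                         product_window = product_window,
                         window_tol = window_tol)
    if (!is.null(loc) && isTRUE(loc$window_compatible %||% TRUE))
      loci[[length(loci) + 1L]] <- loc
  }
  loci
}

`%||%` <- function(a, b) if (is.null(a)) b else a
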