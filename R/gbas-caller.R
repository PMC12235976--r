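#' Merge a read pair by ungapped overlap
#'
#' Finds the best ungapped overlap of at least `min_overlap` bases between
#' the forward read and the reverse complement of the reverse read. The
#' overlap with the fewest mismatches wins (ties: longest overlap);
#' disagreeing bases are resolved to the higher-quality call, ties to read
#' 1. Returns `NULL` when no overlap satisfies the mismatch fraction.
#'
#' @param r1,r2 sequence records with `seq` and optional `qual`.
#' @param min_overlap minimum overlap length in bp (default 20).
#' @param max_mismatch_frac maximum mismatch fraction inside the overlap
#'   (default 0.1).
#' @return merged record (`id` from `r1`) or `NULL`.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 20L, max_mismatch_frac = 0.1) {
  if (!nchar(r1$seq) || !nchar(r2$seq)) stop("zero-length read")
  s1 <- toupper(r1$seq)
  s2 <- revcomp(toupper(r2$seq))
  q1 <- r1$qual %||% rep(30L, nchar(s1))
  q2 <- rev(r2$qual %||% rep(30L, nchar(r2$seq)))
  n1 <- nchar(s1); n2 <- nchar(s2)
  c1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(s2, "", fixed = TRUE)[[1]]
  if (min(n1, n2) < min_overlap) return(NULL)
  best <- NULL
  # overlap length L: suffix of s1 vs prefix of s2. Fast path: the longest
  # exact overlap is optimal (0 mismatches) and a plain string compare
  for (L in seq(min(n1, n2), min_overlap)) {
    if (substr(s1, n1 - L + 1L, n1) == substr(s2, 1L, L)) {
      best <- list(L = L, mm = 0L)
      break
    }
  }
  if (is.null(best)) {
    for (L in seq(min(n1, n2), min_overlap)) {
      a <- c1[(n1 - L + 1L):n1]
      b <- c2[1:L]
      mm <- sum(a != b)
      if (mm / L > max_mismatch_frac) next
      if (is.null(best) || mm < best$mm || (mm == best$mm && L > best$L)) {
        best <- list(L = L, mm = mm)
      }
    }
  }
  if (is.null(best)) return(NULL)
  L <- best$L
  head_len <- n1 - L
  merged <- c(c1[seq_len(head_len)], character(L),
              c2[seq(L + 1L, length.out = n2 - L)])
  mq <- c(q1[seq_len(head_len)], integer(L), q2[seq(L + 1L, length.out = n2 - L)])
  ov1 <- (head_len + 1L):n1
  ov2 <- 1:L
  take1 <- q1[ov1] >= q2[ov2]
  merged[head_len + seq_len(L)] <- ifelse(take1, c1[ov1], c2[ov2])
  mq[head_len + seq_len(L)] <- pmax(q1[ov1], q2[ov2])
  list(id = r1$id, seq = paste(merged, collapse = ""), qual = mq)
}

hamming_at_most <- function(a, b, k) {
  if (nchar(a) != nchar(b)) return(FALSE)
  if (a == b) return(TRUE)
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]]) <= k
}

#' Assign merged reads to panel loci by their primers
#'
#' A merged read is expected to start with a forward primer and end with the
#' reverse complement of a reverse primer. It is assigned to the unique
#' locus whose both primers match within `max_mismatch` substitutions;
#' primers are trimmed from the returned insert. Reads matching no locus, or
#' primers of different loci, go to the `undetermined` bin with a reason.
#'
#' @param reads list of merged sequence records.
#' @param panel data.frame with columns `locus_id`, `fwd`, `rev` (untailed
#'   primers). Loci sharing an identical primer are a configuration error.
#' @param max_mismatch allowed substitutions per primer (default 2).
#' @return list with `assigned` (named list locus_id -> character vector of
#'   trimmed inserts) and `undetermined` (data.frame `read_id`, `reason`).
#' @export
demultiplex_by_primer <- function(reads, panel, max_mismatch = 2L) {
  if (anyDuplicated(panel$fwd) || anyDuplicated(panel$rev))
    stop("panel configuration error: two loci share an identical primer")
  rev_rc <- vapply(panel$rev, revcomp, "")
  assigned <- stats::setNames(vector("list", nrow(panel)), panel$locus_id)
  for (i in seq_len(nrow(panel))) assigned[[i]] <- character()
  und <- list()
  for (r in reads) {
    s <- toupper(r$seq)
    fwd_hit <- which(vapply(seq_len(nrow(panel)), function(i) {
      p <- panel$fwd[i]
      nchar(s) > nchar(p) && hamming_at_most(substr(s, 1L, nchar(p)), p, max_mismatch)
    }, TRUE))
    rev_hit <- which(vapply(seq_len(nrow(panel)), function(i) {
      p <- rev_rc[i]
      nchar(s) > nchar(p) &&
        hamming_at_most(substr(s, nchar(s) - nchar(p) + 1L, nchar(s)), p, max_mismatch)
    }, TRUE))
    reason <- NULL
    if (!length(fwd_hit) || !length(rev_hit)) {
      reason <- "no primer match"
    } else if (length(fwd_hit) > 1L || length(rev_hit) > 1L) {
      reason <- "multiple primer matches"
    } else if (fwd_hit != rev_hit) {
      reason <- "chimeric/conflicting primer pair"
    }
    if (!is.null(reason)) {
      und[[length(und) + 1L]] <- data.frame(read_id = r$id, reason = reason,
                                            stringsAsFactors = FALSE)
      next
    }
    i <- fwd_hit
    insert <- substr(s, nchar(panel$fwd[i]) + 1L, nchar(s) - nchar(panel$rev[i]))
    assigned[[i]] <- c(assigned[[i]], insert)
  }
  list(
    assigned = assigned,
    undetermined = if (length(und)) do.call(rbind, und) else
      data.frame(read_id = character(), reason = character(),
                 stringsAsFactors = FALSE)
  )
}

#' Call a diploid genotype from per-sequence read counts at one locus
#'
#' Four stages: (1) error collapse - a sequence within edit distance 1 of a
#' sequence at least `error_ratio` times more abundant is folded into it;
#' (2) stutter collapse - with `ssr_unit` given, a sequence exactly one
#' repeat unit shorter than a more abundant sequence and below
#' `stutter_frac` of its count is folded into it (flag `STUTTER_COLLAPSED`);
#' (3) sequences with count >= `min_depth` are allele candidates, the top
#' one is allele 1 and the runner-up is allele 2 iff its count is at least
#' `min_allele_frac` of the top count (else homozygote); (4) no candidate ->
#' missing with flag `LOW_DEPTH`.
#'
#' @param seq_counts named integer vector: insert sequence -> read count.
#' @param min_depth minimum reads per allele (default 10).
#' @param min_allele_frac minimum second/first allele count ratio (default
#'   0.25).
#' @param stutter_frac stutter collapse threshold (default 0.5).
#' @param ssr_unit repeat unit length for stutter collapse, or `NULL`.
#' @param error_ratio abundance ratio for the edit-distance-1 collapse
#'   (default 10).
#' @return list: `alleles` (character vector of 2 sequences, or `NULL` when
#'   missing), `depths`, `flags`.
#' @export
call_genotype <- function(seq_counts, min_depth = 10L, min_allele_frac = 0.25,
                          stutter_frac = 0.5, ssr_unit = NULL,
                          error_ratio = 10) {
  stopifnot(length(seq_counts) > 0L, all(seq_counts > 0))
  flags <- character()
  cnt <- sort(seq_counts, decreasing = TRUE)
  # (1) error collapse, most abundant absorbers first
  i <- 1L
  while (i < length(cnt)) {
    j <- length(cnt)
    while (j > i) {
      if (cnt[i] >= error_ratio * cnt[j] &&
          utils::adist(names(cnt)[i], names(cnt)[j]) <= 1L) {
        cnt[i] <- cnt[i] + cnt[j]
        cnt <- cnt[-j]
        cnt <- sort(cnt, decreasing = TRUE)
      }
      j <- j - 1L
    }
    i <- i + 1L
  }
  # (2) stutter collapse
  if (!is.null(ssr_unit) && length(cnt) > 1L) {
    repeat {
      folded <- FALSE
      lens <- nchar(names(cnt))
      for (i in seq_along(cnt)) {
        shorter <- which(lens == lens[i] - ssr_unit &
                           cnt < stutter_frac * cnt[i] & cnt < cnt[i])
        shorter <- setdiff(shorter, i)
        if (length(shorter)) {
          cnt[i] <- cnt[i] + sum(cnt[shorter])
          cnt <- sort(cnt[-shorter], decreasing = TRUE)
          flags <- union(flags, "STUTTER_COLLAPSED")
          folded <- TRUE
          break
        }
      }
      if (!folded) break
    }
  }
  # (3) candidate alleles
  cand <- cnt[cnt >= min_depth]
  if (!length(cand)) {
    return(list(alleles = NULL, depths = integer(),
                flags = union(flags, "LOW_DEPTH")))
  }
  if (length(cand) >= 2L && cand[2] / cand[1] >= min_allele_frac) {
    if (length(cand) >= 3L && cand[3] / cand[1] >= min_allele_frac)
      flags <- union(flags, "AMBIGUOUS_RATIO")
    list(alleles = names(cand)[1:2], depths = unname(cand[1:2]), flags = flags)
  } else {
    list(alleles = rep(names(cand)[1], 2L), depths = unname(cand[1]),
         flags = flags)
  }
}

#' Call a genotype matrix from per-sample merged reads
#'
#' Runs [demultiplex_by_primer()] per sample, tallies insert sequences,
#' calls every sample x locus genotype with [call_genotype()], then assigns
#' stable allele labels per locus: alleles are labelled by amplicon insert
#' length, with a `.variant` suffix ranking equal-length sequence variants
#' by descending total count across samples (ties broken lexicographically).
#' Loci with a single variant per length use the bare length label.
#'
#' @param sample_reads named list: sample_id -> list of merged sequence
#'   records.
#' @param panel primer panel data.frame (`locus_id`, `fwd`, `rev`, optional
#'   `ssr_unit`).
#' @param pop named character vector or data.frame mapping sample_id to
#'   population.
#' @param ... passed to [call_genotype()].
#' @param max_mismatch primer mismatch allowance for demultiplexing.
#' @return a [genotype_matrix()].
#' @export
call_genotypes <- function(sample_reads, panel, pop, max_mismatch = 2L, ...) {
  if (is.data.frame(pop)) pop <- stats::setNames(pop[[2]], pop[[1]])
  samples <- names(sample_reads)
  loci <- panel$locus_id
  units <- if ("ssr_unit" %in% names(panel)) panel$ssr_unit else
    rep(NA_integer_, nrow(panel))
  calls <- vector("list", length(samples))
  names(calls) <- samples
  for (s in samples) {
    dm <- demultiplex_by_primer(sample_reads[[s]], panel, max_mismatch = max_mismatch)
    calls[[s]] <- lapply(seq_along(loci), function(j) {
      inserts <- dm$assigned[[loci[j]]]
      if (!length(inserts)) return(list(alleles = NULL, flags = "LOW_DEPTH"))
      tab <- table(inserts)
      cnts <- stats::setNames(as.integer(tab), names(tab))
      unit <- if (is.na(units[j])) NULL else units[j]
      call_genotype(cnts, ssr_unit = unit, ...)
    })
  }
  # global allele labels per locus
  a1 <- matrix(NA_character_, length(samples), length(loci),
               dimnames = list(samples, loci))
  a2 <- a1
  seq_maps <- stats::setNames(vector("list", length(loci)), loci)
  for (j in seq_along(loci)) {
    counts <- list()
    for (s in samples) {
      cl <- calls[[s]][[j]]
      if (is.null(cl$alleles)) next
      for (k in seq_along(cl$alleles)) {
        seq <- cl$alleles[k]
        d <- cl$depths[min(k, length(cl$depths))]
        counts[[seq]] <- (counts[[seq]] %||% 0L) + d
      }
    }
    if (!length(counts)) next
    labels <- allele_labels(names(counts), unlist(counts))
    seq_maps[[j]] <- stats::setNames(names(labels), unname(labels))
    for (s in samples) {
      cl <- calls[[s]][[j]]
      if (is.null(cl$alleles)) next
      a1[s, j] <- labels[[cl$alleles[1]]]
      a2[s, j] <- labels[[cl$alleles[2]]]
    }
  }
  gm <- genotype_matrix(a1, a2, pop = unname(pop[samples]))
  attr(gm, "allele_seqs") <- seq_maps   # label -> insert sequence, per locus
  gm
}

# deterministic (length, variant) labels: variants of equal length ordered
# by descending global count, then lexicographic sequence
allele_labels <- function(seqs, counts) {
  lens <- nchar(seqs)
  labels <- character(length(seqs))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    idx <- idx[order(-counts[idx], seqs[idx])]
    if (length(idx) == 1L) {
      labels[idx] <- as.character(L)
    } else {
      labels[idx] <- paste0(L, ".", seq_along(idx))
    }
  }
  stats::setNames(labels, seqs)
}

#' Apply the study's sample/marker/population filters
#'
#' Filters, in order: (1) samples with strictly more than
#' `max_sample_missing` missing calls across current loci; (2) markers
#' missing in strictly more than `max_marker_missing` of the remaining
#' samples; (3) markers monomorphic across the whole remaining dataset;
#' (4) populations with fewer than `min_pop_n` remaining individuals.
#' Missing fractions are recomputed from the current matrix at each stage.
#'
#' @param m a [genotype_matrix()].
#' @param max_sample_missing per-sample missing fraction cutoff (strict
#'   `>`, default 0.30).
#' @param max_marker_missing per-marker missing fraction cutoff (strict
#'   `>`, default 0.30).
#' @param min_pop_n minimum individuals per population (default 5).
#' @param drop_monomorphic drop markers with a single allele overall
#'   (default TRUE).
#' @return list with `matrix` (filtered [genotype_matrix()]) and `report`
#'   (data.frame of dropped entities: `stage`, `entity`, `statistic`).
#' @export
apply_study_filters <- function(m, max_sample_missing = 0.30,
                                max_marker_missing = 0.30, min_pop_n = 5L,
                                drop_monomorphic = TRUE) {
  report <- list()
  note <- function(stage, entity, stat) {
    report[[length(report) + 1L]] <<- data.frame(
      stage = stage, entity = entity, statistic = stat,
      stringsAsFactors = FALSE)
  }
  # (1) samples
  fr <- rowMeans(gm_missing(m))
  drop <- fr > max_sample_missing
  for (i in which(drop)) note("sample_missing", gm_samples(m)[i], fr[i])
  m <- m[!drop, ]
  if (!nrow(m$a1)) stop("empty matrix after filtering")
  # (2) markers, against remaining samples
  fr <- colMeans(gm_missing(m))
  drop <- fr > max_marker_missing
  for (j in which(drop)) note("marker_missing", gm_loci(m)[j], fr[j])
  m <- m[, !drop]
  if (!ncol(m$a1)) stop("empty matrix after filtering")
  # (3) monomorphic markers
  if (drop_monomorphic) {
    mono <- vapply(seq_len(ncol(m$a1)), function(j) {
      al <- c(m$a1[, j], m$a2[, j])
      length(unique(al[!is.na(al)])) <= 1L
    }, TRUE)
    for (j in which(mono)) note("monomorphic", gm_loci(m)[j], 1)
    m <- m[, !mono]
    if (!ncol(m$a1)) stop("empty matrix after filtering")
  }
  # (4) small populations
  tab <- table(m$pop)
  small <- names(tab)[tab < min_pop_n]
  for (p in small) note("small_population", p, as.integer(tab[[p]]))
  m <- m[!(m$pop %in% small), ]
  if (!nrow(m$a1)) stop("empty matrix after filtering")
  list(
    matrix = m,
    report = if (length(report)) do.call(rbind, report) else
      data.frame(stage = character(), entity = character(),
                 statistic = double(), stringsAsFactors = FALSE)
  )
}
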