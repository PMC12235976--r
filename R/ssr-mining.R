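#' Scan one read for perfect microsatellite runs
#'
#' Detects every maximal perfect tandem repeat of unit length 2-5 that meets
#' its per-unit-length minimum repeat count and has more than `min_flank`
#' bases of flanking sequence on both sides (strict inequality). Runs whose
#' unit is itself periodic (e.g. ATAT treated as a 4mer) are reported at
#' their smallest period only. Motifs are canonicalized to the
#' lexicographically minimal rotation on the read strand; reverse complements
#' are not merged. `N` bases terminate a run. Homopolymers are ignored.
#'
#' @param rec a sequence record (`list(id =, seq =, ...)`) or a bare string.
#' @param thresholds named integer vector mapping unit length to the minimum
#'   number of repeats; default `c("2" = 10, "3" = 8, "4" = 4, "5" = 4)`.
#' @param min_flank minimum flank length in bp, both sides, strict `>`.
#' @return data.frame with columns `read_id`, `motif`, `unit_len`,
#'   `n_repeats`, `start`, `end` (0-based half-open on the read),
#'   `left_flank_len`, `right_flank_len`. Zero rows when nothing qualifies.
#' @export
scan_read <- function(rec, thresholds = c("2" = 10, "3" = 8, "4" = 4, "5" = 4),
                      min_flank = 20L) {
  if (is.character(rec)) rec <- list(id = "read", seq = rec)
  s <- toupper(rec$seq)
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- list()
  for (u in as.integer(names(thresholds))) {
    min_rep <- thresholds[[as.character(u)]]
    if (n < u * min_rep) next
    # m[i] TRUE when base i matches base i+u and neither is N
    a <- ch[seq_len(n - u)]
    b <- ch[seq_len(n - u) + u]
    m <- a == b & a != "N" & b != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= u * (min_rep - 1L))) {
      a0 <- starts[k]                       # 1-based start of match stretch
      L <- r$lengths[k]
      reps <- L %/% u + 1L
      span_start <- a0 - 1L                 # 0-based
      span_end <- span_start + reps * u
      unit <- substr(s, a0, a0 + u - 1L)
      if (min_period(unit) < u) next        # report at smallest period only
      if (reps < min_rep) next
      lf <- span_start
      rf <- n - span_end
      if (lf <= min_flank || rf <= min_flank) next
      out[[length(out) + 1L]] <- data.frame(
        read_id = rec$id, motif = canonical_rotation(unit), unit_len = u,
        n_repeats = reps, start = span_start, end = span_end,
        left_flank_len = lf, right_flank_len = rf,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(read_id = character(), motif = character(),
                      unit_len = integer(), n_repeats = integer(),
                      start = integer(), end = integer(),
                      left_flank_len = integer(), right_flank_len = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

min_period <- function(unit) {
  u <- nchar(unit)
  for (p in seq_len(u - 1L)) {
    if (u %% p == 0L &&
        unit == paste(rep(substr(unit, 1L, p), u %/% p), collapse = ""))
      return(p)
  }
  u
}

canonical_rotation <- function(unit) {
  u <- nchar(unit)
  rots <- vapply(seq_len(u), function(i)
    paste0(substr(unit, i, u), substr(unit, 1L, i - 1L)), "")
  sort(rots)[1]
}

#' Scan a set of reads for microsatellites
#' @param reads list of sequence records.
#' @inheritParams scan_read
#' @return one data.frame of candidates across all reads.
#' @export
scan_reads <- function(reads, thresholds = c("2" = 10, "3" = 8, "4" = 4, "5" = 4),
                       min_flank = 20L) {
  res <- lapply(reads, scan_read, thresholds = thresholds, min_flank = min_flank)
  do.call(rbind, res)
}

#' Count microsatellite-bearing reads per unit-length class
#'
#' A read contributes once to each unit-length class in which it has at
#' least one candidate; a read carrying e.g. both a 2mer and a 4mer run is
#' counted in both classes.
#'
#' @param candidates data.frame from [scan_reads()].
#' @param unit_lens classes to report; default 2:5.
#' @return named integer vector of read counts per unit length.
#' @export
classify_counts <- function(candidates, unit_lens = 2:5) {
  out <- stats::setNames(integer(length(unit_lens)), as.character(unit_lens))
  if (nrow(candidates)) {
    for (u in unit_lens) {
      out[as.character(u)] <-
        length(unique(candidates$read_id[candidates$unit_len == u]))
    }
  }
  out
}
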