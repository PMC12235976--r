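#' Read FASTA or FASTQ into sequence records
#'
#' Sequences are uppercased; FASTQ qualities are decoded as Phred+33.
#' Internal coordinates throughout the package are 0-based half-open; file
#' formats keep their native conventions and conversion happens only in I/O.
#'
#' @param path file to read.
#' @param format `"FASTA"` or `"FASTQ"`; default guesses from the extension.
#' @return list of records, each `list(id =, seq =, qual =)`, `qual` being an
#'   integer vector of Phred scores or `NULL` for FASTA. An empty file yields
#'   an empty list.
#' @export
read_fastx <- function(path, format = c("auto", "FASTA", "FASTQ")) {
  format <- match.arg(toupper(format[1]), c("AUTO", "FASTA", "FASTQ"))
  if (format == "AUTO") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fq", "fastq")) "FASTQ" else "FASTA"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "FASTA") read_fasta_records(path) else read_fastq_records(path)
}

read_fasta_records <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) return(list())
  first <- which(keep)[1]
  if (!startsWith(lines[first], ">"))
    stop(sprintf("FASTA parse error at line %d: expected '>' header", first))
  # Biostrings does the heavy lifting once the shape is sane
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("FASTA record '", ids[which(bad)[1]], "' contains non-ACGTN characters")
  unname(Map(function(i, s) list(id = i, seq = s, qual = NULL), ids, seqs))
}

read_fastq_records <- function(path) {
  lines <- readLines(path)
  # drop a single trailing blank line, common on hand-edited files
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (!length(lines)) return(list())
  if (length(lines) %% 4L != 0L)
    stop(sprintf("FASTQ parse error at line %d: truncated record", length(lines) + 1L))
  idx <- seq(1L, length(lines), by = 4L)
  if (!all(startsWith(lines[idx], "@"))) {
    bad <- idx[!startsWith(lines[idx], "@")][1]
    stop(sprintf("FASTQ parse error at line %d: expected '@' header", bad))
  }
  plus <- idx + 2L
  if (!all(startsWith(lines[plus], "+"))) {
    bad <- plus[!startsWith(lines[plus], "+")][1]
    stop(sprintf("FASTQ parse error at line %d: expected '+' separator", bad))
  }
  seqs <- toupper(lines[idx + 1L])
  quals <- lines[idx + 3L]
  mism <- nchar(seqs) != nchar(quals)
  if (any(mism)) {
    bad <- idx[mism][1]
    stop(sprintf("FASTQ parse error at line %d: sequence and quality lengths differ", bad + 3L))
  }
  badc <- grepl("[^ACGTN]", seqs)
  if (any(badc))
    stop(sprintf("FASTQ parse error at line %d: non-ACGTN characters", idx[badc][1] + 1L))
  ids <- sub("\\s.*$", "", substring(lines[idx], 2L))
  unname(Map(function(i, s, q) list(id = i, seq = s, qual = utf8ToInt(q) - 33L),
             ids, seqs, quals))
}

#' Write sequence records to FASTA or FASTQ
#'
#' @param records list of records as returned by [read_fastx()].
#' @param path output file.
#' @param format `"FASTA"` or `"FASTQ"`. FASTQ requires qualities on every
#'   record; they are encoded Phred+33.
#' @return `path`, invisibly.
#' @export
write_fastx <- function(records, path, format = c("FASTA", "FASTQ")) {
  format <- match.arg(toupper(format[1]), c("FASTA", "FASTQ"))
  if (format == "FASTA") {
    out <- unlist(lapply(records, function(r) c(paste0(">", r$id), r$seq)))
  } else {
    out <- unlist(lapply(records, function(r) {
      if (is.null(r$qual)) stop("FASTQ output requires qualities on record ", r$id)
      if (length(r$qual) != nchar(r$seq))
        stop("record ", r$id, ": quality length does not match sequence length")
      c(paste0("@", r$id), r$seq, "+", intToUtf8(r$qual + 33L))
    }))
  }
  writeLines(if (is.null(out)) character() else out, path)
  invisible(path)
}

#' Read protein-coding gene models from a GFF3 file
#'
#' Only protein-coding genes are retained. Exon coordinates are converted
#' from GFF3 1-based inclusive to 0-based half-open and stored in
#' transcription order (minus-strand genes list their 3'-most genomic exon
#' first). For genes with several annotated transcripts the first mRNA is
#' used. Genes without exons are skipped with a warning.
#'
#' @param path GFF3 file with gene/mRNA/exon features.
#' @param genome named character vector (or list of records) of contig
#'   sequences, used for bounds checking and sequence extraction.
#' @return list of gene models: `list(gene_id, contig, strand, exons)` where
#'   `exons` is a 2-column matrix (`start`, `end`; 0-based half-open) in
#'   transcription order.
#' @export
read_gff3_genes <- function(path, genome) {
  genome <- as_contig_vector(genome)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  biotype <- biotype_of(md)
  genes <- which(type == "gene" & biotype %in% c("protein_coding", NA))
  # when a biotype column exists, NA means unstated; treat unstated as coding
  if (!all(is.na(biotype)))
    genes <- which(type == "gene" &
                     (is.na(biotype) | biotype == "protein_coding"))
  out <- list()
  ids <- as.character(md$ID)
  parents <- lapply(md$Parent, as.character)
  for (g in genes) {
    gid <- ids[g]
    mrnas <- which(type == "mRNA" & vapply(parents, function(p) gid %in% p, FALSE))
    owner <- if (length(mrnas)) ids[mrnas[1]] else gid
    ex <- which(type == "exon" & vapply(parents, function(p) owner %in% p, FALSE))
    if (!length(ex)) {
      warning("gene ", gid, " has no exons; skipped")
      next
    }
    contig <- as.character(GenomicRanges::seqnames(gr[g]))
    if (!contig %in% names(genome))
      stop("contig ", contig, " not present in supplied genome")
    starts <- GenomicRanges::start(gr[ex]) - 1L   # to 0-based half-open
    ends <- GenomicRanges::end(gr[ex])
    if (any(ends > nchar(genome[[contig]])) || any(starts < 0L))
      stop("gene ", gid, ": exon outside contig bounds")
    ord <- order(starts)
    strand <- as.character(GenomicRanges::strand(gr[g]))
    if (strand == "-") ord <- rev(ord)
    exons <- cbind(start = starts[ord], end = ends[ord])
    if (any(exons[, "end"] - exons[, "start"] < 1L))
      stop("gene ", gid, ": zero-length exon")
    out[[length(out) + 1L]] <- list(
      gene_id = sub("^gene[:-]", "", gid), contig = contig,
      strand = if (strand == "-") "-" else "+", exons = exons
    )
  }
  out
}

biotype_of <- function(md) {
  for (col in c("gene_biotype", "biotype", "gene_type")) {
    if (col %in% names(md)) return(as.character(md[[col]]))
  }
  rep(NA_character_, nrow(md))
}

as_contig_vector <- function(genome) {
  if (is.list(genome) && length(genome) && is.list(genome[[1]])) {
    v <- vapply(genome, `[[`, "", "seq")
    names(v) <- vapply(genome, `[[`, "", "id")
    return(v)
  }
  unlist(genome)
}

#' Intron lengths of a gene model
#'
#' Gaps between consecutive exons in genomic coordinates, reported in
#' transcription order.
#' @param gm gene model from [read_gff3_genes()].
#' @return integer vector (length = number of exons minus one).
#' @export
gene_intron_lengths <- function(gm) {
  ex <- gm$exons[order(gm$exons[, "start"]), , drop = FALSE]
  if (nrow(ex) < 2L) return(integer())
  gaps <- ex[-1L, "start"] - ex[-nrow(ex), "end"]
  if (gm$strand == "-") rev(as.integer(gaps)) else as.integer(gaps)
}

#' Exon sequences of a gene model in transcription orientation
#' @param gm gene model.
#' @param genome named character vector of contig sequences.
#' @return character vector of exon sequences, 5' to 3' of the transcript.
#' @export
gene_exon_seqs <- function(gm, genome) {
  genome <- as_contig_vector(genome)
  contig <- genome[[gm$contig]]
  seqs <- apply(gm$exons, 1L, function(e) substr(contig, e[1] + 1L, e[2]))
  if (gm$strand == "-") seqs <- vapply(seqs, revcomp, "")
  unname(seqs)
}

#' Reverse complement of a DNA string
#' @param seq DNA string over A,C,G,T,N (either case).
#' @return the reverse complement, same case.
#' @export
revcomp <- function(seq) {
  ch <- strsplit(chartr("ACGTacgt", "TGCAtgca", seq), "", fixed = TRUE)[[1]]
  paste(rev(ch), collapse = "")
}

# ---- GenAlEx-style co-dominant CSV ------------------------------------------

#' Write a genotype matrix as GenAlEx-style co-dominant CSV
#'
#' Layout: a counts row (`n_loci, n_samples, n_pops, size_1, ..., size_k`),
#' a title row carrying population names above their size columns, a header
#' row (`Sample, Pop, <locus>, , <locus>, , ...`), then one row per
#' individual with two columns per locus. Missing is coded `0`. Alleles are
#' serialized as `<length>` when the locus has a single sequence variant per
#' length in this matrix, else `<length>.<variant>`.
#'
#' @param m a [genotype_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(m, path) {
  pops <- unique(m$pop)
  sizes <- as.integer(table(factor(m$pop, levels = pops)))
  nl <- ncol(m$a1); ns <- nrow(m$a1)
  row1 <- c(nl, ns, length(pops), sizes)
  row2 <- c(m$title, "", "", pops)
  header <- c("Sample", "Pop",
              as.vector(rbind(colnames(m$a1), "")))
  enc <- function(x) ifelse(is.na(x), "0", x)
  # row order is preserved; the per-row Pop column is authoritative on read,
  # the header sizes are summaries
  body <- cbind(gm_samples(m), m$pop)
  for (j in seq_len(nl)) body <- cbind(body, enc(m$a1[, j]), enc(m$a2[, j]))
  pad <- function(v, w) c(v, rep("", max(0L, w - length(v))))
  w <- max(length(row1), length(row2), length(header), 2L + 2L * nl)
  lines <- c(
    paste(pad(as.character(row1), w), collapse = ","),
    paste(pad(row2, w), collapse = ","),
    paste(pad(header, w), collapse = ","),
    apply(body, 1L, function(r) paste(pad(r, w), collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a GenAlEx-style co-dominant CSV
#'
#' Tolerates leading metadata rows: the counts row is auto-detected as the
#' first row whose first three cells are integers. Populations can be
#' overridden with a two-column sample-to-population table.
#'
#' @param path CSV path (layout of [write_genotype_matrix()]).
#' @param pop_map optional data.frame (or TSV path) with columns `sample`,
#'   `pop`, overriding in-file population assignment.
#' @return a [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, pop_map = NULL) {
  raw <- strsplit(readLines(path), ",", fixed = TRUE)
  is_int <- function(x) !is.na(suppressWarnings(as.integer(x)))
  counts_row <- NA_integer_
  for (i in seq_along(raw)) {
    r <- raw[[i]]
    if (length(r) >= 3L && all(is_int(r[1:3]))) { counts_row <- i; break }
  }
  if (is.na(counts_row)) stop("no GenAlEx counts row found in ", path)
  cr <- raw[[counts_row]]
  nl <- as.integer(cr[1]); ns <- as.integer(cr[2]); np <- as.integer(cr[3])
  title_row <- raw[[counts_row + 1L]]
  pops_declared <- title_row[seq(4L, length.out = np)]
  header <- raw[[counts_row + 2L]]
  locus_ids <- header[seq(3L, by = 2L, length.out = nl)]
  if (any(!nzchar(locus_ids)))
    stop("odd column layout: expected two columns per locus in header")
  data_rows <- raw[seq(counts_row + 3L, length.out = ns)]
  need <- 2L + 2L * nl
  a1 <- matrix(NA_character_, ns, nl)
  a2 <- matrix(NA_character_, ns, nl)
  samples <- character(ns); pop <- character(ns)
  for (i in seq_len(ns)) {
    r <- data_rows[[i]]
    if (length(r) < need)
      stop("row ", counts_row + 2L + i, ": expected ", need, " columns, got ", length(r))
    samples[i] <- r[1]; pop[i] <- r[2]
    x1 <- r[seq(3L, by = 2L, length.out = nl)]
    x2 <- r[seq(4L, by = 2L, length.out = nl)]
    x1[x1 == "0"] <- NA; x2[x2 == "0"] <- NA
    a1[i, ] <- x1; a2[i, ] <- x2
  }
  rownames(a1) <- rownames(a2) <- samples
  colnames(a1) <- colnames(a2) <- locus_ids
  if (!is.null(pop_map)) {
    if (is.character(pop_map) && length(pop_map) == 1L)
      pop_map <- utils::read.table(pop_map, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
    idx <- match(samples, pop_map[[1]])
    if (anyNA(idx)) stop("pop_map lacks samples: ",
                         paste(samples[is.na(idx)], collapse = ", "))
    pop <- as.character(pop_map[[2]][idx])
  } else if (length(pops_declared) && !all(pop %in% pops_declared)) {
    stop("unknown population label(s): ",
         paste(setdiff(pop, pops_declared), collapse = ", "))
  }
  genotype_matrix(a1, a2, pop, title = title_row[1])
}
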