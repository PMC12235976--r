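#' Construct a co-dominant diploid genotype matrix
#'
#' The central container of the package: one row per individual, one column
#' per locus, two allele labels per non-missing cell (homozygotes repeat the
#' label). Allele labels are character tokens, either `"<length>"` or
#' `"<length>.<variant>"` when several sequence variants share an amplicon
#' length. Missing calls are `NA` in both allele matrices.
#'
#' @param a1,a2 character matrices of identical dimensions holding the first
#'   and second allele label of each call. Row names are sample ids, column
#'   names are locus ids. A cell is missing iff it is `NA` in both.
#' @param pop character vector of population labels, one per individual.
#' @param title optional dataset title carried through serialization.
#' @return An object of class `genotype_matrix`.
#' @examples
#' a1 <- matrix(c("451", "451"), 2, 1, dimnames = list(c("s1", "s2"), "L1"))
#' a2 <- matrix(c("451", "455"), 2, 1, dimnames = list(c("s1", "s2"), "L1"))
#' genotype_matrix(a1, a2, pop = c("A", "A"))
#' @export
genotype_matrix <- function(a1, a2, pop, title = "gbastk") {
  if (!is.matrix(a1) || !is.matrix(a2) || !identical(dim(a1), dim(a2)))
    stop("a1 and a2 must be character matrices of identical dimensions")
  storage.mode(a1) <- "character"
  storage.mode(a2) <- "character"
  if (is.null(rownames(a1)))
    rownames(a1) <- rownames(a2) <- paste0("ind", seq_len(nrow(a1)))
  if (is.null(colnames(a1)))
    colnames(a1) <- colnames(a2) <- paste0("locus", seq_len(ncol(a1)))
  dimnames(a2) <- dimnames(a1)
  if (anyDuplicated(colnames(a1))) stop("locus ids must be unique")
  if (length(pop) != nrow(a1))
    stop("pop must have one entry per individual")
  if (any(xor(is.na(a1), is.na(a2))))
    stop("half-missing calls: a cell must be NA in both allele matrices or neither")
  structure(
    list(a1 = a1, a2 = a2, pop = as.character(pop), title = title),
    class = "genotype_matrix"
  )
}

#' @export
dim.genotype_matrix <- function(x) dim(x$a1)

#' Sample, locus and population accessors
#' @param m a `genotype_matrix`
#' @return character vectors of ids / labels.
#' @rdname gm-accessors
#' @export
gm_samples <- function(m) rownames(m$a1)

#' @rdname gm-accessors
#' @export
gm_loci <- function(m) colnames(m$a1)

#' @rdname gm-accessors
#' @export
gm_populations <- function(m) m$pop

#' Logical matrix marking missing calls
#' @param m a `genotype_matrix`
#' @return logical matrix, `TRUE` where no genotype was called.
#' @export
gm_missing <- function(m) is.na(m$a1)

#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$a1))
  if (missing(j)) j <- seq_len(ncol(x$a1))
  genotype_matrix(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                  pop = x$pop[if (is.character(i)) match(i, gm_samples(x)) else i],
                  title = x$title)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci, %d population(s)\n",
              nrow(x$a1), ncol(x$a1), length(unique(x$pop))))
  miss <- mean(gm_missing(x))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  tab <- table(x$pop)
  cat("  populations:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Relabel alleles to a canonical, count-independent convention
#'
#' Allele labels of equal-length sequence variants (`<length>.<variant>`)
#' are rank-ordered by abundance when called from reads, which makes the
#' variant suffix depend on read depths. For comparing matrices on allele
#' identity (e.g. a called matrix against a simulated truth), this relabels
#' every locus deterministically: variants of equal length are ranked by
#' lexicographic order of their sequences.
#'
#' @param m a [genotype_matrix()].
#' @param allele_seqs per-locus named character vectors mapping current
#'   label to allele sequence; defaults to the `allele_seqs` attribute that
#'   [call_genotypes()] attaches.
#' @return the relabelled [genotype_matrix()].
#' @export
canonicalize_labels <- function(m, allele_seqs = attr(m, "allele_seqs")) {
  if (is.null(allele_seqs)) stop("no allele sequences available")
  for (j in seq_len(ncol(m$a1))) {
    map <- allele_seqs[[gm_loci(m)[j]]]
    if (is.null(map)) next
    observed <- unique(stats::na.omit(c(m$a1[, j], m$a2[, j])))
    map <- map[names(map) %in% observed]   # dialect: bare length when the
    if (!length(map)) next                 # observed locus has one variant
    lens <- nchar(map)
    new <- character(length(map))
    for (L in unique(lens)) {
      idx <- which(lens == L)
      idx <- idx[order(map[idx])]
      new[idx] <- if (length(idx) == 1L) as.character(L) else
        paste0(L, ".", seq_along(idx))
    }
    names(new) <- names(map)
    a1 <- m$a1[, j]; a2 <- m$a2[, j]
    m$a1[, j] <- ifelse(is.na(a1), NA, new[a1])
    m$a2[, j] <- ifelse(is.na(a2), NA, new[a2])
  }
  m
}

#' @method all.equal genotype_matrix
#' @export
all.equal.genotype_matrix <- function(target, current, ...) {
  msgs <- character()
  if (!identical(dimnames(target$a1), dimnames(current$a1)))
    msgs <- c(msgs, "dimnames differ")
  norm <- function(m) {
    # unordered pairs: sort the two labels within each cell
    lo <- pmin(m$a1, m$a2)
    hi <- pmax(m$a1, m$a2)
    list(lo = lo, hi = hi)
  }
  nt <- norm(target); nc <- norm(current)
  if (!identical(nt$lo, nc$lo) || !identical(nt$hi, nc$hi))
    msgs <- c(msgs, "genotype calls differ")
  if (!identical(target$pop, current$pop))
    msgs <- c(msgs, "population labels differ")
  if (length(msgs)) msgs else TRUE
}
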