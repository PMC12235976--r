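#' Per-population, per-locus allele frequencies
#'
#' @param m a [genotype_matrix()].
#' @return nested list `freqs[[pop]][[locus]]` of named numeric vectors
#'   (allele label -> frequency) with attribute `n_typed`; entries are
#'   `NULL` when no individual is typed. Frequencies sum to 1.
#' @export
allele_freqs <- function(m) {
  pops <- unique(m$pop)
  out <- stats::setNames(vector("list", length(pops)), pops)
  for (p in pops) {
    rows <- which(m$pop == p)
    out[[p]] <- stats::setNames(vector("list", ncol(m$a1)), gm_loci(m))
    for (j in seq_len(ncol(m$a1))) {
      al <- c(m$a1[rows, j], m$a2[rows, j])
      al <- al[!is.na(al)]
      if (!length(al)) next
      tab <- table(al)
      f <- as.numeric(tab) / sum(tab)
      names(f) <- names(tab)
      attr(f, "n_typed") <- length(al) / 2
      out[[p]][[j]] <- f
    }
  }
  out
}

#' Per-population variability summary (N, Na, Ne, Ho, He, FIS, HWE)
#'
#' Per population and locus: `N` = typed individuals, `Na` = number of
#' distinct alleles, `Ne` = effective number of alleles `1 / sum(p_i^2)`,
#' `Ho` = observed heterozygote fraction, `He` = gene diversity
#' `1 - sum(p_i^2)` (no small-sample correction), `FIS = (He - Ho) / He`
#' (undefined at `He = 0`). Population means carry standard errors
#' `sd / sqrt(L)` over the `L` loci with at least one typed individual.
#' HWE deviations are counted at `alpha` per [hwe_test()], no
#' multiple-testing correction.
#'
#' @param m a [genotype_matrix()].
#' @param alpha HWE significance threshold (default 0.05).
#' @return object of class `variability_summary`: list with `per_locus`
#'   (data.frame) and `summary` (data.frame of means and SEs plus HWE
#'   deviation counts per population).
#' @export
variability <- function(m, alpha = 0.05) {
  freqs <- allele_freqs(m)
  pops <- names(freqs)
  per <- list()
  for (p in pops) {
    rows <- which(m$pop == p)
    for (j in seq_len(ncol(m$a1))) {
      f <- freqs[[p]][[j]]
      if (is.null(f)) next
      a1 <- m$a1[rows, j]; a2 <- m$a2[rows, j]
      typed <- !is.na(a1)
      n <- sum(typed)
      ho <- mean(a1[typed] != a2[typed])
      he <- 1 - sum(f^2)
      ne <- 1 / sum(f^2)
      hw <- hwe_test_geno(a1[typed], a2[typed])
      per[[length(per) + 1L]] <- data.frame(
        pop = p, locus = gm_loci(m)[j], N = n,
        Na = length(f), Ne = ne, Ho = ho, He = he,
        FIS = if (he > 0) (he - ho) / he else NA_real_,
        hwe_p = hw$p, stringsAsFactors = FALSE
      )
    }
  }
  per <- do.call(rbind, per)
  msd <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  }
  summ <- do.call(rbind, lapply(pops, function(p) {
    d <- per[per$pop == p, ]
    s <- vapply(c("N", "Na", "Ne", "Ho", "He"), function(v) msd(d[[v]]), c(0, 0))
    data.frame(pop = p,
               N = s["mean", "N"], N_se = s["se", "N"],
               Na = s["mean", "Na"], Na_se = s["se", "Na"],
               Ne = s["mean", "Ne"], Ne_se = s["se", "Ne"],
               Ho = s["mean", "Ho"], Ho_se = s["se", "Ho"],
               He = s["mean", "He"], He_se = s["se", "He"],
               n_loci = nrow(d),
               hwe_dev = sum(d$hwe_p < alpha, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_locus = per, summary = summ),
            class = "variability_summary")
}

#' @export
print.variability_summary <- function(x, ...) {
  s <- x$summary
  cat("Variability by population (mean +/- SE over loci):\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-20s N %6.3f  Na %5.3f+/-%.3f  Ne %5.3f+/-%.3f  Ho %5.3f+/-%.3f  He %5.3f+/-%.3f  HWE dev. %d\n",
                s$pop[i], s$N[i], s$Na[i], s$Na_se[i], s$Ne[i], s$Ne_se[i],
                s$Ho[i], s$Ho_se[i], s$He[i], s$He_se[i], s$hwe_dev[i]))
  }
  invisible(x)
}

# internal: HWE from two allele-label vectors (typed individuals only)
hwe_test_geno <- function(a1, a2) {
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2L || !length(a1))
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                testable = FALSE))
  geno <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  counts <- table(factor(geno, levels = genotype_classes(alleles)))
  hwe_test(as.integer(counts), alleles = alleles)
}

genotype_classes <- function(alleles) {
  k <- length(alleles)
  cls <- character()
  for (i in seq_len(k)) for (j in i:k)
    cls <- c(cls, paste(min(alleles[i], alleles[j]),
                        max(alleles[i], alleles[j]), sep = "/"))
  cls
}

#' Chi-squared test for Hardy-Weinberg equilibrium at one locus
#'
#' Goodness-of-fit over all `k(k+1)/2` genotype classes, with expected
#' counts `n p_i^2` (homozygotes) and `2 n p_i p_j` (heterozygotes) from the
#' observed allele frequencies, `df = k(k-1)/2`. No pooling of rare classes
#' and no continuity correction. A monomorphic locus is not testable.
#'
#' @param genotype_counts integer vector of observed genotype counts in the
#'   order produced by enumerating `i <= j` over sorted alleles (the order
#'   used internally by [variability()]).
#' @param alleles optional allele labels; inferred count `k` from the
#'   vector length otherwise.
#' @return list `chi2`, `df`, `p`, `testable`.
#' @export
hwe_test <- function(genotype_counts, alleles = NULL) {
  g <- length(genotype_counts)
  k <- as.integer((sqrt(8 * g + 1) - 1) / 2)
  if (k * (k + 1) / 2 != g) stop("genotype_counts length is not k(k+1)/2")
  if (is.null(alleles)) alleles <- as.character(seq_len(k))
  n <- sum(genotype_counts)
  if (k < 2L || n < 1L)
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                testable = FALSE))
  # allele counts from genotype counts
  ac <- numeric(k)
  idx <- 0L
  pairs <- list()
  for (i in seq_len(k)) for (j in i:k) {
    idx <- idx + 1L
    pairs[[idx]] <- c(i, j)
    ac[i] <- ac[i] + genotype_counts[idx]
    ac[j] <- ac[j] + genotype_counts[idx]
  }
  p <- ac / (2 * n)
  if (sum(p > 0) < 2L)
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                testable = FALSE))
  expected <- vapply(pairs, function(ij) {
    if (ij[1] == ij[2]) n * p[ij[1]]^2 else 2 * n * p[ij[1]] * p[ij[2]]
  }, 0)
  keep <- expected > 0
  chi2 <- sum((genotype_counts[keep] - expected[keep])^2 / expected[keep])
  df <- k * (k - 1) / 2
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       testable = TRUE)
}

locus_freq_pair <- function(freqs, pa, pb, locus) {
  fa <- freqs[[pa]][[locus]]
  fb <- freqs[[pb]][[locus]]
  if (is.null(fa) || is.null(fb)) return(NULL)
  alleles <- union(names(fa), names(fb))
  list(a = stats::setNames(as.numeric(fa[alleles]), alleles) |>
         (\(x) { x[is.na(x)] <- 0; x })(),
       b = stats::setNames(as.numeric(fb[alleles]), alleles) |>
         (\(x) { x[is.na(x)] <- 0; x })(),
       na = attr(fa, "n_typed"), nb = attr(fb, "n_typed"))
}

#' Pairwise FST between two populations
#'
#' Default estimator (`nei_ratio_of_means`): per locus, `Hs` is the mean of
#' the two populations' gene diversities and `Ht` the gene diversity of the
#' unweighted mean allele-frequency vector; FST is the ratio of sums across
#' loci, `(sum Ht - sum Hs) / sum Ht`, clamped at 0. The Weir-Cockerham
#' theta (variance components, ratio-of-sums over loci and alleles) is
#' available as an alternative.
#'
#' @param m a [genotype_matrix()].
#' @param pop_a,pop_b population labels present in `m`.
#' @param estimator `"nei_ratio_of_means"` (default) or
#'   `"weir_cockerham"`.
#' @return a single FST value.
#' @export
pairwise_fst <- function(m, pop_a, pop_b,
                         estimator = c("nei_ratio_of_means", "weir_cockerham")) {
  estimator <- match.arg(estimator)
  if (identical(pop_a, pop_b)) return(0)
  if (!all(c(pop_a, pop_b) %in% m$pop))
    stop("population absent from matrix")
  freqs <- allele_freqs(m)
  if (estimator == "nei_ratio_of_means") {
    ht_sum <- 0; hs_sum <- 0; used <- 0L
    for (locus in gm_loci(m)) {
      fp <- locus_freq_pair(freqs, pop_a, pop_b, locus)
      if (is.null(fp)) next
      hs <- ((1 - sum(fp$a^2)) + (1 - sum(fp$b^2))) / 2
      pbar <- (fp$a + fp$b) / 2
      ht <- 1 - sum(pbar^2)
      hs_sum <- hs_sum + hs
      ht_sum <- ht_sum + ht
      used <- used + 1L
    }
    if (!used || ht_sum <= 0) stop("no informative loci for this pair")
    max(0, (ht_sum - hs_sum) / ht_sum)
  } else {
    wc_theta(m, pop_a, pop_b)
  }
}

# Weir & Cockerham (1984) theta for two populations, ratio of sums of the
# a (among-population) and a+b+c variance components over loci and alleles
wc_theta <- function(m, pop_a, pop_b) {
  rows_a <- which(m$pop == pop_a)
  rows_b <- which(m$pop == pop_b)
  num <- 0; den <- 0
  r <- 2
  for (j in seq_len(ncol(m$a1))) {
    ga <- cbind(m$a1[rows_a, j], m$a2[rows_a, j])
    gb <- cbind(m$a1[rows_b, j], m$a2[rows_b, j])
    ga <- ga[!is.na(ga[, 1]), , drop = FALSE]
    gb <- gb[!is.na(gb[, 1]), , drop = FALSE]
    n_i <- c(nrow(ga), nrow(gb))
    if (any(n_i == 0)) next
    alleles <- unique(c(ga, gb))
    if (length(alleles) < 2L) next
    nbar <- mean(n_i)
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    for (al in alleles) {
      p_i <- c(mean(ga == al), mean(gb == al))
      h_i <- c(mean(xor(ga[, 1] == al, ga[, 2] == al)),
               mean(xor(gb[, 1] == al, gb[, 2] == al)))
      pbar <- sum(n_i * p_i) / sum(n_i)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / sum(n_i)
      a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  if (den == 0) stop("no informative loci for this pair")
  max(0, num / den)
}

#' Full pairwise FST matrix
#'
#' @inheritParams pairwise_fst
#' @param populations populations to include; default all in `m`.
#' @return symmetric matrix with zero diagonal, attribute `estimator`.
#' @export
fst_matrix <- function(m, populations = unique(m$pop),
                       estimator = c("nei_ratio_of_means", "weir_cockerham")) {
  estimator <- match.arg(estimator)
  k <- length(populations)
  fst <- matrix(0, k, k, dimnames = list(populations, populations))
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    fst[i, j] <- fst[j, i] <-
      pairwise_fst(m, populations[i], populations[j], estimator = estimator)
  }
  attr(fst, "estimator") <- estimator
  fst
}

#' EM estimate of the null-allele frequency at one locus
#'
#' Expectation-maximization over allele frequencies augmented with a null
#' allele of frequency `r`. Observed homozygotes `i/i` are partitioned
#' between true homozygotes (`p_i^2`) and null heterozygotes (`2 p_i r`);
#' blank (non-amplifying) individuals are attributed to null homozygotes
#' (`r^2`) when `include_blanks = TRUE`, otherwise blank individuals are
#' dropped from the data (the alternative convention). The observed-data
#' log-likelihood is non-decreasing over iterations.
#'
#' @param het_counts named vector or data.frame of heterozygote counts with
#'   names `"a/b"`, or `NULL`; alternatively pass a genotype matrix column
#'   via [null_allele_em_matrix()].
#' @param hom_counts named integer vector: allele -> observed homozygote
#'   count.
#' @param n_blank number of individuals with no call at this locus.
#' @param include_blanks treat blanks as candidate null homozygotes
#'   (default TRUE).
#' @param tol convergence tolerance on successive `r` iterates (default
#'   1e-8).
#' @param max_iter iteration cap (default 1000).
#' @return object of class `null_allele_em`: list `r` (null-allele
#'   frequency), `p` (visible allele frequencies), `iterations`,
#'   `converged`, `loglik` (trace).
#' @export
null_allele_em <- function(het_counts, hom_counts, n_blank = 0L,
                           include_blanks = TRUE, tol = 1e-8,
                           max_iter = 1000L) {
  if (!include_blanks) n_blank <- 0L
  alleles <- unique(c(names(hom_counts),
                      unlist(strsplit(names(het_counts) %||% character(), "/", fixed = TRUE))))
  if (!length(alleles)) stop("no observed alleles")
  k <- length(alleles)
  hom <- stats::setNames(numeric(k), alleles)
  hom[names(hom_counts)] <- as.numeric(hom_counts)
  hetm <- matrix(0, k, k, dimnames = list(alleles, alleles))
  for (nm in names(het_counts)) {
    ab <- strsplit(nm, "/", fixed = TRUE)[[1]]
    hetm[ab[1], ab[2]] <- hetm[ab[1], ab[2]] + as.numeric(het_counts[[nm]])
  }
  het_by_allele <- rowSums(hetm) + colSums(hetm)
  N <- sum(hom) + sum(hetm) + n_blank
  # init: uniform over visible alleles plus a small null mass
  p <- rep((1 - 0.05) / k, k)
  r <- 0.05
  ll <- function(p, r) {
    v <- 0
    v <- v + sum(hom * log(pmax(p^2 + 2 * p * r, .Machine$double.xmin)))
    ij <- which(hetm > 0, arr.ind = TRUE)
    if (nrow(ij))
      v <- v + sum(hetm[ij] * log(2 * p[ij[, 1]] * p[ij[, 2]]))
    if (n_blank > 0) v <- v + n_blank * log(pmax(r^2, .Machine$double.xmin))
    v
  }
  trace <- numeric()
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # E-step: split observed homozygotes between i/i and i/null
    denom <- p + 2 * r
    w_true <- ifelse(denom > 0, p / denom, 1)
    x_ii <- hom * w_true
    x_i0 <- hom - x_ii
    # M-step
    allele_counts <- 2 * x_ii + x_i0 + het_by_allele
    null_count <- sum(x_i0) + 2 * n_blank
    tot <- 2 * N
    p_new <- allele_counts / tot
    r_new <- null_count / tot
    trace <- c(trace, ll(p_new, r_new))
    if (abs(r_new - r) < tol && max(abs(p_new - p)) < tol) {
      p <- p_new; r <- r_new
      converged <- TRUE
      break
    }
    p <- p_new; r <- r_new
  }
  structure(list(r = r, p = stats::setNames(p, alleles), iterations = it,
                 converged = converged, loglik = trace),
            class = "null_allele_em")
}

#' @export
print.null_allele_em <- function(x, ...) {
  cat(sprintf("null-allele EM: r = %.4f (%d iteration(s), %sconverged)\n",
              x$r, x$iterations, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Null-allele EM across every (population, locus) cell of a matrix
#'
#' @param m a [genotype_matrix()].
#' @param ... passed to [null_allele_em()].
#' @return data.frame `pop`, `locus`, `r`, `iterations`, `converged`.
#' @export
null_allele_em_matrix <- function(m, ...) {
  rows <- list()
  for (p in unique(m$pop)) {
    sel <- which(m$pop == p)
    for (j in seq_len(ncol(m$a1))) {
      a1 <- m$a1[sel, j]; a2 <- m$a2[sel, j]
      blank <- sum(is.na(a1))
      typed <- which(!is.na(a1))
      if (!length(typed)) next
      hom <- a1[typed] == a2[typed]
      hom_counts <- table(a1[typed][hom])
      hets <- paste(pmin(a1[typed][!hom], a2[typed][!hom]),
                    pmax(a1[typed][!hom], a2[typed][!hom]), sep = "/")
      het_counts <- table(hets)
      fit <- null_allele_em(
        het_counts = if (length(het_counts)) het_counts else NULL,
        hom_counts = hom_counts, n_blank = blank, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        pop = p, locus = gm_loci(m)[j], r = fit$r,
        iterations = fit$iterations, converged = fit$converged,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Flag markers for null alleles
#'
#' A marker is flagged in a population when its estimated null-allele
#' frequency strictly exceeds `threshold`; it is flagged globally only when
#' it exceeds the threshold in every population.
#'
#' @param estimates data.frame from [null_allele_em_matrix()].
#' @param threshold flagging cutoff (default 0.2, strict `>`).
#' @return list with `per_population` (the estimates with a `flagged`
#'   column) and `global` (data.frame `locus`, `global_flag`).
#' @export
flag_null_markers <- function(estimates, threshold = 0.2) {
  estimates$flagged <- estimates$r > threshold
  glob <- stats::aggregate(flagged ~ locus, data = estimates, FUN = all)
  names(glob)[2] <- "global_flag"
  list(per_population = estimates, global = glob)
}
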