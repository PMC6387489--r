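## ---------------------------------------------------------------------------
## SNP prioritization by phenotype-tail FST (Nei estimator).
## ---------------------------------------------------------------------------

#' Partition individuals into phenotype tails
#'
#' Splits a cohort into a low tail S1 (below the \code{lower} empirical
#' quantile), a middle group S0, and a high tail S2 (above the \code{upper}
#' quantile).  Membership is by order statistics: the lowest
#' \code{floor(lower * n)} individuals form S1 and the highest
#' \code{n - floor(upper * n)} form S2, with ties broken by individual index
#' so the partition is deterministic.  For n divisible by 20 and the default
#' 5\%/95\% quantiles the tail sizes are exactly n/20 each.
#'
#' @param phenotypes numeric vector.
#' @param lower,upper quantile fractions, \code{0 < lower < upper < 1}.
#' @return object of class \code{tail_groups}: index sets \code{S1},
#'   \code{S0}, \code{S2}, tail sizes \code{n_S1}, \code{n_S2} and the
#'   quantile fractions.
#' @export
#' @examples
#' tg <- partition_by_phenotype(1:100)
#' tg$S1  # indices of the 5 lowest phenotypes
partition_by_phenotype <- function(phenotypes, lower = 0.05, upper = 0.95) {
  y <- as.numeric(phenotypes)
  n <- length(y)
  .check_frac(lower, "lower", open_right = TRUE)
  .check_frac(upper, "upper", open_right = TRUE)
  if (lower >= upper) .fail("'lower' must be smaller than 'upper'")
  if (anyNA(y)) .fail("phenotypes must not contain NA")
  if (max(y) == min(y))
    .fail("constant phenotype vector: quantile partition undefined")
  n1 <- as.integer(floor(lower * n))
  n2 <- as.integer(n - floor(upper * n))
  if (n1 < 1 || n2 < 1)
    .fail("too few individuals for the requested tail fractions")
  if (n1 + n2 >= n) .fail("tails exhaust the cohort; middle group is empty")
  ord <- order(y, seq_len(n))            # stable, ties broken by index
  S1 <- sort(ord[seq_len(n1)])
  S2 <- sort(ord[seq.int(n - n2 + 1, n)])
  S0 <- sort(ord[seq.int(n1 + 1, n - n2)])
  structure(list(S1 = S1, S0 = S0, S2 = S2, n_S1 = n1, n_S2 = n2,
                 lower = lower, upper = upper),
            class = "tail_groups")
}

#' @export
print.tail_groups <- function(x, ...) {
  cat(sprintf("Phenotype tails: S1 %d | S0 %d | S2 %d (quantiles %g/%g)\n",
              x$n_S1, length(x$S0), x$n_S2, x$lower, x$upper))
  invisible(x)
}

#' Per-locus allele frequencies and heterozygosity in a subset
#'
#' Frequency of the counted allele is the dosage sum over called genotypes
#' divided by twice the number of called genotypes; expected heterozygosity
#' is \code{2 p q}.  Loci with zero called genotypes get NA and are flagged.
#'
#' @param genotypes dosage matrix (individuals x loci), NA = missing.
#' @param subset row indices of the subpopulation (default all).
#' @return data.frame with columns \code{p}, \code{q}, \code{het},
#'   \code{n_called}.
#' @export
#' @examples
#' allele_frequencies(matrix(c(2, 1, 1, 0, 0), 5, 1))  # p = 0.4, het = 0.48
allele_frequencies <- function(genotypes, subset = NULL) {
  genotypes <- .check_dosage(as.matrix(genotypes), miss_ok = TRUE)
  if (!is.null(subset)) {
    if (length(subset) == 0) .fail("subset must be non-empty")
    genotypes <- genotypes[subset, , drop = FALSE]
  }
  n_called <- colSums(!is.na(genotypes))
  s <- colSums(genotypes, na.rm = TRUE)
  p <- ifelse(n_called > 0, s / (2 * n_called), NA_real_)
  data.frame(p = p, q = 1 - p, het = 2 * p * (1 - p), n_called = n_called,
             row.names = colnames(genotypes))
}

#' Nei FST between the two phenotype tails, per locus
#'
#' For each locus the total heterozygosity is computed from the pooled-tail
#' allele frequency (individual-weighted pooling of S1 and S2 dosages,
#' i.e. the n-weighted mean of the tail frequencies), the subpopulation
#' heterozygosity is the n-weighted mean of the two tail heterozygosities,
#' and \code{FST = (H_T - H_S) / H_T}.  Loci monomorphic across both tails
#' (H_T = 0) carry no differentiation information: their score is set to 0
#' and they are flagged so they can never be prioritized.  Under this
#' estimator H_S never exceeds H_T, so all scores lie in [0, 1].
#'
#' @param genotypes dosage matrix over the cohort that was partitioned.
#' @param groups a \code{\link{partition_by_phenotype}} result.
#' @return data.frame of class \code{fst_scores} with one row per locus:
#'   \code{locus}, \code{H_T}, \code{H_S}, \code{fst}, \code{monomorphic}.
#' @export
fst_scores <- function(genotypes, groups) {
  stopifnot(inherits(groups, "tail_groups"))
  genotypes <- .check_dosage(as.matrix(genotypes), miss_ok = TRUE)
  if (groups$n_S1 < 1 || groups$n_S2 < 1) .fail("both tails must be non-empty")
  f1 <- allele_frequencies(genotypes, groups$S1)
  f2 <- allele_frequencies(genotypes, groups$S2)
  n1 <- f1$n_called
  n2 <- f2$n_called
  callable <- n1 > 0 & n2 > 0
  pbar <- (n1 * f1$p + n2 * f2$p) / (n1 + n2)
  H_T <- 2 * pbar * (1 - pbar)
  H_S <- (n1 * f1$het + n2 * f2$het) / (n1 + n2)
  fst <- ifelse(callable & H_T > 0, (H_T - H_S) / H_T, 0)
  fst[!callable] <- NA_real_
  stopifnot(all(fst >= -1e-12 & fst <= 1 + 1e-12, na.rm = TRUE))
  fst <- pmin(pmax(fst, 0), 1)
  out <- data.frame(locus = seq_len(ncol(genotypes)),
                    name = colnames(genotypes) %||% as.character(seq_len(ncol(genotypes))),
                    H_T = H_T, H_S = H_S, fst = fst,
                    monomorphic = callable & H_T == 0)
  class(out) <- c("fst_scores", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the k loci with the largest FST scores
#'
#' Ties are broken by ascending genome order; the returned selection is
#' sorted by genome order.  Loci that could not be scored (NA) are never
#' selected.
#'
#' @param scores a \code{\link{fst_scores}} table.
#' @param k number of loci to keep.
#' @return object of class \code{marker_selection}: sorted locus indices,
#'   the method tag and \code{k}.
#' @export
select_top_k <- function(scores, k) {
  stopifnot(inherits(scores, "fst_scores"))
  k <- .check_count(k, "k")
  usable <- which(!is.na(scores$fst))
  if (k > length(usable)) .fail("k = %d exceeds the %d scored loci", k,
                                length(usable))
  ord <- usable[order(-scores$fst[usable], scores$locus[usable])]
  sel <- sort(scores$locus[ord[seq_len(k)]])
  structure(list(loci = sel, method = "fst", k = k), class = "marker_selection")
}

#' Select k loci uniformly at random
#'
#' Sampling is without replacement and reproducible by seed; the selection
#' is returned in genome order.
#'
#' @param panel number of loci in the panel, or a vector of locus indices.
#' @param k number of loci to draw.
#' @param seed integer seed.
#' @return a \code{marker_selection} with method tag \code{"random"}.
#' @export
select_random_k <- function(panel, k, seed) {
  loci <- if (length(panel) == 1L) seq_len(panel) else as.integer(panel)
  k <- .check_count(k, "k")
  if (k > length(loci)) .fail("k = %d exceeds the panel size %d", k,
                              length(loci))
  set.seed(as.integer(seed))
  sel <- sort(sample(loci, k))
  structure(list(loci = sel, method = "random", k = k, seed = as.integer(seed)),
            class = "marker_selection")
}

#' @export
print.marker_selection <- function(x, ...) {
  cat(sprintf("Marker selection: %d loci by '%s'\n", x$k, x$method))
  invisible(x)
}
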