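## ---------------------------------------------------------------------------
## Genotype quality control for user-supplied data.
## ---------------------------------------------------------------------------

#' Quality-control thresholds
#'
#' Defaults follow common SNP-array practice: individuals and SNPs must be
#' called in at least 90\% of genotypes, the minor allele frequency must
#' exceed 0.05, and the observed heterozygote frequency may deviate from its
#' Hardy-Weinberg expectation \code{2 p q} by less than 0.15 in absolute
#' value.
#'
#' @param min_call_rate minimum call rate, applied per individual and then
#'   per SNP.
#' @param min_maf minimum minor allele frequency.
#' @param max_het_deviation maximum |observed het - 2 p q|.
#' @return an object of class \code{qc_rules}.
#' @export
qc_rules <- function(min_call_rate = 0.90, min_maf = 0.05,
                     max_het_deviation = 0.15) {
  for (v in c(min_call_rate, min_maf, max_het_deviation))
    if (!is.numeric(v) || v < 0 || v > 1)
      .fail("all QC thresholds must lie in [0, 1]")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 max_het_deviation = max_het_deviation),
            class = "qc_rules")
}

#' Filter a genotype matrix by call rate, MAF and HWE heterozygosity
#'
#' Order of operations: individuals with call rate below the threshold are
#' discarded first; SNPs are then screened (on the remaining individuals)
#' for call rate, minor allele frequency, and heterozygote deviation from
#' the Hardy-Weinberg expectation.  The filter is idempotent on clean data.
#'
#' @param genotypes dosage matrix (individuals x SNPs) with NA for missing
#'   calls.
#' @param rules a \code{\link{qc_rules}} object.
#' @return list with the filtered \code{genotypes}, a \code{report}
#'   data.frame of counts removed at each step, and the kept row/column
#'   indices.
#' @export
#' @examples
#' g <- matrix(rbinom(200, 2, 0.4), 20, 10)
#' qc_filter(g)$report
qc_filter <- function(genotypes, rules = qc_rules()) {
  stopifnot(inherits(rules, "qc_rules"))
  g <- .check_dosage(as.matrix(genotypes), miss_ok = TRUE)
  ind_cr <- rowMeans(!is.na(g))
  keep_ind <- ind_cr >= rules$min_call_rate
  g1 <- g[keep_ind, , drop = FALSE]

  snp_cr <- colMeans(!is.na(g1))
  ok_cr <- snp_cr >= rules$min_call_rate
  n_called <- colSums(!is.na(g1))
  p <- ifelse(n_called > 0, colSums(g1, na.rm = TRUE) / (2 * n_called), NA)
  maf <- pmin(p, 1 - p)
  ok_maf <- !is.na(maf) & maf > rules$min_maf
  obs_het <- ifelse(n_called > 0, colMeans(g1 == 1, na.rm = TRUE), NA)
  exp_het <- 2 * p * (1 - p)
  ok_hwe <- !is.na(obs_het) & abs(obs_het - exp_het) < rules$max_het_deviation
  keep_snp <- ok_cr & ok_maf & ok_hwe

  report <- data.frame(
    step = c("individual call rate", "snp call rate", "snp maf",
             "snp het deviation"),
    removed = c(sum(!keep_ind), sum(!ok_cr), sum(ok_cr & !ok_maf),
                sum(ok_cr & ok_maf & !ok_hwe)))
  out <- g1[, keep_snp, drop = FALSE]
  if (nrow(out) == 0 || ncol(out) == 0)
    .fail("quality control removed everything; check the thresholds")
  list(genotypes = out, report = report,
       kept_individuals = which(keep_ind), kept_snps = which(keep_snp))
}
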