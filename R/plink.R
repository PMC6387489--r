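## ---------------------------------------------------------------------------
## PLINK text dialect (.ped/.map) and tab-separated cohort tables.
## ---------------------------------------------------------------------------

#' Read genotypes from PLINK text files
#'
#' Parses a .ped/.map pair of the classic PLINK text dialect.  Each locus
#' must be biallelic; the counted allele (dosage 2) is the alphabetically
#' first allele observed at that locus, so a write/read round trip through
#' \code{\link{write_plink}} is lossless.  Missing alleles are coded 0.
#'
#' @param ped,map paths to the .ped and .map files.
#' @return list with \code{genotypes} (dosage matrix, NA = missing,
#'   individual ids as rownames, SNP ids as colnames), \code{map}
#'   (chr, name, pos_cM, pos_bp), \code{fam} (family/individual ids, parents,
#'   sex, phenotype column) and \code{alleles} (counted / other allele per
#'   locus).
#' @export
read_plink <- function(ped, map) {
  mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) < 4) .fail("malformed .map: expected 4 columns")
  names(mp) <- c("chr", "name", "pos_cM", "pos_bp")[seq_len(ncol(mp))]
  m <- nrow(mp)
  lines <- readLines(ped)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0) .fail("empty .ped file")
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6 + 2 * m
  len <- lengths(toks)
  if (any(len != want))
    .fail("ragged .ped: line %d has %d fields, expected %d",
          which(len != want)[1], len[len != want][1], want)
  tok <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  fam <- data.frame(fid = tok[, 1], iid = tok[, 2], pat = tok[, 3],
                    mat = tok[, 4], sex = tok[, 5], phenotype = tok[, 6],
                    stringsAsFactors = FALSE)
  a1 <- tok[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  a2 <- tok[, 6 + 2 * seq_len(m), drop = FALSE]
  geno <- matrix(NA_real_, n, m, dimnames = list(fam$iid, mp$name))
  counted <- other <- character(m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    inv <- sort(setdiff(unique(al), "0"))
    if (length(inv) > 2)
      .fail("locus %s has %d alleles; only biallelic loci are supported",
            mp$name[j], length(inv))
    if (length(inv) == 0) next                      # fully missing locus
    counted[j] <- inv[1]
    other[j] <- if (length(inv) == 2) inv[2] else ""
    miss <- a1[, j] == "0" | a2[, j] == "0"
    geno[, j] <- (a1[, j] == inv[1]) + (a2[, j] == inv[1])
    geno[miss, j] <- NA_real_
  }
  list(genotypes = geno, map = mp, fam = fam,
       alleles = data.frame(name = mp$name, counted = counted, other = other,
                            stringsAsFactors = FALSE))
}

#' Write genotypes as PLINK text files
#'
#' Dosage 2 is written as the homozygote of allele \code{"A"}, dosage 0 as
#' the homozygote of allele \code{"B"}, missing as \code{"0 0"}; since
#' \code{"A"} sorts before \code{"B"}, \code{\link{read_plink}} recovers the
#' identical dosage matrix.
#'
#' @param genotypes dosage matrix with individual ids as rownames.
#' @param map data.frame with columns \code{chr}, \code{name}, \code{pos_cM}
#'   (one row per genotype column).  A base-pair column is synthesized as
#'   \code{round(pos_cM * 1e4)}.
#' @param prefix output path prefix; writes \code{<prefix>.ped} and
#'   \code{<prefix>.map}.
#' @param fam optional data.frame with columns fid, iid, pat, mat, sex,
#'   phenotype; sensible defaults otherwise.
#' @return invisibly, the two file paths.
#' @export
write_plink <- function(genotypes, map, prefix, fam = NULL) {
  g <- .check_dosage(as.matrix(genotypes), miss_ok = TRUE)
  if (nrow(map) != ncol(g)) .fail("map must have one row per genotype column")
  n <- nrow(g)
  ids <- rownames(g) %||% as.character(seq_len(n))
  if (is.null(fam))
    fam <- data.frame(fid = ids, iid = ids, pat = 0, mat = 0, sex = 0,
                      phenotype = -9)
  code <- c(`0` = "B B", `1` = "A B", `2` = "A A")
  gg <- matrix("0 0", n, ncol(g))
  ok <- !is.na(g)
  gg[ok] <- code[as.character(g[ok])]
  ped_lines <- paste(fam$fid, fam$iid, fam$pat, fam$mat, fam$sex,
                     fam$phenotype,
                     apply(gg, 1, paste, collapse = " "))
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  writeLines(ped_lines, ped_path)
  utils::write.table(
    data.frame(map$chr, map$name, map$pos_cM, round(map$pos_cM * 1e4)),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE,
    sep = "\t")
  invisible(c(ped = ped_path, map = map_path))
}

#' Write a simulated cohort to plain-text files
#'
#' Exports the training and validation cohorts of a
#' \code{\link{sim_population}} result: PLINK .ped/.map genotypes, a
#' tab-separated phenotype table (id, generation, sex, phenotype, tbv) and
#' the pedigree (id, sire, dam, sex, generation; 0 = unknown parent).
#'
#' @param cohort a \code{gs_cohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gs_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  smap <- cohort$map[cohort$map$type == "snp", ]
  geno <- rbind(cohort$train$geno, cohort$valid$geno)
  paths <- write_plink(geno, smap, file.path(dir, "genotypes"))
  phen <- rbind(
    data.frame(id = cohort$train$ids, generation = cohort$train$generation,
               sex = cohort$train$sex, phenotype = cohort$train$phenotype,
               tbv = cohort$train$tbv),
    data.frame(id = cohort$valid$ids, generation = cohort$valid$generation,
               sex = cohort$valid$sex, phenotype = cohort$valid$phenotype,
               tbv = cohort$valid$tbv))
  phen_path <- file.path(dir, "phenotypes.tsv")
  utils::write.table(phen, phen_path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  ped_path <- file.path(dir, "pedigree.tsv")
  utils::write.table(cohort$pedigree, ped_path, quote = FALSE,
                     row.names = FALSE, sep = "\t")
  invisible(c(paths, phenotypes = phen_path, pedigree = ped_path))
}
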