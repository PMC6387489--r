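## ---------------------------------------------------------------------------
## Relationship matrices: realized (VanRaden G), expected (pedigree A) and
## identity-by-state similarity, plus off-diagonal diagnostics.
## ---------------------------------------------------------------------------

## internal: resolve a selection argument to locus indices
.sel_loci <- function(selection, n_loci) {
  if (is.null(selection)) return(seq_len(n_loci))
  loci <- if (inherits(selection, "marker_selection")) selection$loci
          else as.integer(selection)
  if (anyDuplicated(loci)) .fail("selected loci must be unique")
  if (any(loci < 1 | loci > n_loci)) .fail("selected loci out of panel bounds")
  loci
}

#' VanRaden genomic relationship matrix
#'
#' Method-1 G: dosages at the selected loci are centered by twice the
#' observed allele frequency over the analyzed individuals and
#' \code{G = Z Z' / (2 * sum(p * (1 - p)))}.  Monomorphic loci carry no
#' information and are dropped with a message.  A small ridge is added to
#' the diagonal so the matrix stays invertible in downstream REML.
#'
#' @param genotypes dosage matrix (individuals x loci), no missing values.
#' @param selection optional \code{marker_selection} or integer vector of
#'   locus indices; default uses all loci.
#' @param ridge value added to the diagonal (default 1e-8).
#' @return symmetric matrix with the individuals' rownames, attribute
#'   \code{kind = "G"}.
#' @export
#' @examples
#' m <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2)
#' grm_vanraden(m, ridge = 0)
grm_vanraden <- function(genotypes, selection = NULL, ridge = 1e-8) {
  M <- .check_dosage(as.matrix(genotypes))
  loci <- .sel_loci(selection, ncol(M))
  M <- M[, loci, drop = FALSE]
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) .fail("all selected loci are monomorphic; G undefined")
  if (any(!poly))
    message(sprintf("grm_vanraden: dropping %d monomorphic locus/loci",
                    sum(!poly)))
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  G <- (G + t(G)) / 2
  diag(G) <- diag(G) + ridge
  dimnames(G) <- list(rownames(genotypes), rownames(genotypes))
  attr(G, "kind") <- "G"
  attr(G, "n_loci") <- ncol(M)
  G
}

#' Pedigree additive relationship matrix (tabular method)
#'
#' Recursive (tabular) numerator relationship matrix: for individual i with
#' parents s and d, \code{A[i, j] = (A[j, s] + A[j, d]) / 2} for j before i
#' and \code{A[i, i] = 1 + A[s, d] / 2}; unknown parents (coded 0 or NA)
#' contribute 0.  The pedigree is sorted internally so parents precede
#' offspring; cycles (an individual being its own ancestor) are rejected.
#'
#' @param pedigree data.frame with columns \code{id}, \code{sire},
#'   \code{dam} (0/NA = unknown).
#' @return symmetric matrix with ids as dimnames, attribute
#'   \code{kind = "A"}.
#' @export
#' @examples
#' ped <- data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
#' pedigree_a_matrix(ped)  # parent-offspring relationship 0.5
pedigree_a_matrix <- function(pedigree) {
  if (!all(c("id", "sire", "dam") %in% names(pedigree)))
    .fail("pedigree needs columns 'id', 'sire', 'dam'")
  id <- pedigree$id
  if (anyDuplicated(id)) .fail("duplicate ids in pedigree")
  n <- length(id)
  s_raw <- pedigree$sire
  d_raw <- pedigree$dam
  s_raw[!is.na(s_raw) & s_raw == 0] <- NA   # 0 codes an unknown parent
  d_raw[!is.na(d_raw) & d_raw == 0] <- NA
  sire <- match(s_raw, id)                  # NA = unknown
  dam <- match(d_raw, id)
  if (any(!is.na(s_raw) & is.na(sire)) || any(!is.na(d_raw) & is.na(dam)))
    .fail("pedigree references a parent id that has no own row")
  if (any(sire == seq_along(id), na.rm = TRUE) ||
      any(dam == seq_along(id), na.rm = TRUE))
    .fail("individual listed as its own parent")

  ## topological sort (Kahn): parents before offspring
  order_out <- integer(n)
  placed <- logical(n)
  k <- 0L
  repeat {
    ready <- which(!placed)
    ready <- ready[(is.na(sire[ready]) | placed[sire[ready]]) &
                     (is.na(dam[ready]) | placed[dam[ready]])]
    if (length(ready) == 0) {
      if (k < n) .fail("pedigree contains a cycle (individual is its own ancestor)")
      break
    }
    order_out[k + seq_along(ready)] <- ready
    placed[ready] <- TRUE
    k <- k + length(ready)
    if (k == n) break
  }

  A <- matrix(0, n, n)
  pos <- integer(n)                   # original index -> position in A
  pos[order_out] <- seq_len(n)
  ## positions of parents in sorted order, 0 = unknown
  ps <- integer(n); pd <- integer(n)
  for (i in seq_len(n)) {
    oi <- order_out[i]
    ps[i] <- if (is.na(sire[oi])) 0L else pos[sire[oi]]
    pd[i] <- if (is.na(dam[oi])) 0L else pos[dam[oi]]
  }
  for (i in seq_len(n)) {
    s <- ps[i]; d <- pd[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rs <- if (s > 0L) A[s, j] else 0
      rd <- if (d > 0L) A[d, j] else 0
      A[i, j] <- A[j, i] <- 0.5 * (rs + rd)
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  ## back to input order
  out <- A[pos, pos, drop = FALSE]
  dimnames(out) <- list(id, id)
  attr(out, "kind") <- "A"
  out
}

#' Restrict a pedigree to a set of individuals and their ancestors
#'
#' Keeps the rows for the requested individuals plus the transitive closure
#' of their parents, which is all the tabular A-matrix computation needs;
#' useful to keep \code{\link{pedigree_a_matrix}} affordable on deep
#' pedigrees when only a block of A is wanted.
#'
#' @param pedigree data.frame with columns \code{id}, \code{sire},
#'   \code{dam}.
#' @param ids individuals whose relationships are needed.
#' @return the pruned pedigree (same columns, original order).
#' @export
prune_pedigree <- function(pedigree, ids) {
  keep <- unique(ids)
  miss <- setdiff(keep, pedigree$id)
  if (length(miss)) .fail("ids not in pedigree: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  repeat {
    rows <- pedigree[pedigree$id %in% keep, ]
    parents <- setdiff(unique(c(rows$sire, rows$dam)), c(0, NA))
    new <- setdiff(parents, keep)
    if (!length(new)) break
    keep <- c(keep, new)
  }
  pedigree[pedigree$id %in% keep, ]
}

#' Identity-by-state genomic similarity matrix
#'
#' For each pair of individuals and each selected locus, the number of
#' shared alleles S is 2 for identical genotypes, 0 for opposite homozygotes
#' and 1 otherwise; similarity is the mean of S over loci divided by 2, so
#' values lie in [0, 1] with 1 on the diagonal.  Equivalently
#' \code{sim(i, j) = 1 - mean(|d_i - d_j|) / 2} for dosages d.
#'
#' @param genotypes dosage matrix (individuals x loci), no missing values.
#' @param selection optional marker selection (see
#'   \code{\link{grm_vanraden}}).
#' @return symmetric matrix in [0, 1], attribute \code{kind = "similarity"}.
#' @export
genomic_similarity <- function(genotypes, selection = NULL) {
  M <- .check_dosage(as.matrix(genotypes))
  loci <- .sel_loci(selection, ncol(M))
  if (length(loci) < 1) .fail("selection must contain at least one locus")
  M <- M[, loci, drop = FALSE]
  ## mean |d_i - d_j| via indicator cross-products (|a-b| over {0,1,2})
  I0 <- (M == 0) * 1
  I1 <- (M == 1) * 1
  I2 <- (M == 2) * 1
  D <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
    tcrossprod(I1, I2) + tcrossprod(I2, I1) +
    2 * (tcrossprod(I0, I2) + tcrossprod(I2, I0))
  S <- 1 - D / (2 * ncol(M))
  S <- (S + t(S)) / 2
  dimnames(S) <- list(rownames(genotypes), rownames(genotypes))
  attr(S, "kind") <- "similarity"
  S
}

## internal: extract the requested off-diagonal values
.offdiag_values <- function(matrix, scope = c("all", "cross"),
                            train = NULL, valid = NULL) {
  scope <- match.arg(scope)
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    .fail("a square matrix is required")
  if (scope == "all") {
    if (nrow(matrix) < 2) .fail("need at least 2 individuals")
    matrix[upper.tri(matrix)]
  } else {
    if (is.null(train) || is.null(valid))
      .fail("scope 'cross' needs 'train' and 'valid' id sets")
    ti <- if (is.character(train)) match(train, rownames(matrix)) else train
    vi <- if (is.character(valid)) match(valid, rownames(matrix)) else valid
    if (anyNA(ti) || anyNA(vi)) .fail("train/valid ids not found in matrix")
    if (length(ti) == 0 || length(vi) == 0) .fail("empty scope")
    as.vector(matrix[ti, vi, drop = FALSE])
  }
}

#' Mean off-diagonal relationship or similarity
#'
#' Mean and standard error (over pairs) of the off-diagonal entries, either
#' over all pairs or over the training x validation cross block.
#'
#' @param matrix square relationship/similarity matrix.
#' @param scope \code{"all"} or \code{"cross"}.
#' @param train,valid id vectors (or row indices) for the cross block.
#' @return list with \code{mean}, \code{se} and \code{n_pairs}.
#' @export
mean_offdiag <- function(matrix, scope = c("all", "cross"),
                         train = NULL, valid = NULL) {
  v <- .offdiag_values(matrix, scope, train, valid)
  list(mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
       n_pairs = length(v))
}

#' Histogram of off-diagonal relationship coefficients
#'
#' Bins the off-diagonal entries into the seven classes bounded by
#' -0.05, -0.03, -0.01, 0.01, 0.03 and 0.05 (half-open bins, closed on the
#' left; outermost bins open-ended) and reports the percentage per bin.
#'
#' @inheritParams mean_offdiag
#' @param edges interior bin edges.
#' @return data.frame of class \code{od_histogram} with columns \code{bin}
#'   and \code{percent} (summing to 100).
#' @export
od_histogram <- function(matrix, scope = c("all", "cross"),
                         train = NULL, valid = NULL,
                         edges = c(-0.05, -0.03, -0.01, 0.01, 0.03, 0.05)) {
  v <- .offdiag_values(matrix, scope, train, valid)
  breaks <- c(-Inf, edges, Inf)
  cnt <- graphics::hist(v, breaks = breaks, plot = FALSE, right = FALSE)$counts
  lab <- c(sprintf("OD < %g", edges[1]),
           sprintf("%g <= OD < %g", edges[-length(edges)], edges[-1]),
           sprintf("OD >= %g", edges[length(edges)]))
  out <- data.frame(bin = lab, percent = 100 * cnt / length(v))
  class(out) <- c("od_histogram", "data.frame")
  out
}
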