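#' Derive a set of stage seeds from one master seed
#'
#' All randomised stages of the package draw their seeds through this one
#' scheme so that a whole analysis is a pure function of a single master seed:
#' the master seed initialises R's RNG and \code{n} integers are drawn without
#' replacement from \code{1..(2^31 - 2)}.  The caller's RNG state is restored
#' afterwards.
#'
#' @param seed master seed (single integer).
#' @param n number of stage seeds to derive.
#' @return integer vector of length \code{n}.
#' @export
#' @examples
#' derive_seeds(1, 3)
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(n), length(n) == 1L, n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(2147483646L, as.integer(n))
}

## internal: stop() with sprintf-style formatting, no call in message
.fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## internal: check a fraction lies in (0, 1]
.check_frac <- function(x, name, open_right = FALSE) {
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || !hi_ok)
    .fail("'%s' must be a fraction in (0, 1%s], got %s", name,
          if (open_right) ")" else "", format(x))
  invisible(x)
}

## internal: positive scalar count
.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    .fail("'%s' must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

## internal: allele dosage matrix sanity (0/1/2, NA allowed when miss_ok)
.check_dosage <- function(geno, miss_ok = FALSE) {
  if (!is.matrix(geno)) .fail("genotypes must be a matrix of 0/1/2 dosages")
  v <- geno[!is.na(geno)]
  if (!miss_ok && anyNA(geno)) .fail("missing genotypes are not allowed here")
  if (length(v) && (min(v) < 0 || max(v) > 2))
    .fail("genotype dosages must lie in {0, 1, 2}")
  invisible(geno)
}
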