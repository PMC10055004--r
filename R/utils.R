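#' Derive a reproducible child seed from a master seed
#'
#' Replicate-level work units each get their own RNG seed derived
#' deterministically from a master seed, so that replicates can be run in any
#' order (or skipped) without changing the stream any other replicate sees.
#'
#' @param master Integer master seed.
#' @param index Integer index of the work unit (replicate, stage, ...).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), length(index) == 1L)
  # Lehmer-style mix kept in double precision; all intermediates < 2^53
  s <- (abs(master) %% 2147483647) + 1
  s <- (s * 48271) %% 2147483647
  s <- (s + (abs(index) %% 2147483647) * 69621) %% 2147483647
  s <- (s * 16807) %% 2147483647
  as.integer(s + 1)
}

## Draw ancestral allele frequencies from a 1/x spectrum on (lo, hi).
## The neutral site frequency spectrum for segregating derived alleles is
## proportional to 1/x; only the shape near the MAF filter boundary matters
## downstream because the F_ST and F4 ratios are a(1-a)-weighted.
rsfs <- function(n, lo = 0.005, hi = 0.995) {
  lo * (hi / lo)^stats::runif(n)
}

## One generation-block of genetic drift: Balding-Nichols (Beta) transition
## with E[p'] = p and Var[p'] = p(1-p)F, F = 1 - exp(-t/(2*Ne)).
## Exact first two moments make the compounded drift down a tree match the
## diffusion expectation 1 - exp(-t_total/(2*Ne)).
bn_drift <- function(p, fcoef) {
  if (fcoef <= 0) return(p)
  stopifnot(fcoef < 1)
  k <- (1 - fcoef) / fcoef
  out <- p
  seg <- p > 0 & p < 1
  if (any(seg)) out[seg] <- stats::rbeta(sum(seg), p[seg] * k, (1 - p[seg]) * k)
  out
}

## Population-style standardization (denominator n, not n-1).
standardize_vec <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) stop("cannot standardize a constant vector (zero variance)")
  (x - mu) / s
}

## Column-center a dosage matrix.
center_cols <- function(m) sweep(m, 2L, colMeans(m), check.margin = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
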