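## Genotype simulation under stated allele frequencies and inbreeding.

#' Simulate per-population biallelic genotype counts
#'
#' Genotype probabilities follow the inbreeding-adjusted Hardy-Weinberg
#' model `(p^2 + F p q, 2 p q (1 - F), q^2 + F p q)`, sampled multinomially;
#' `F = 0` is random mating, `F = 1` produces no heterozygotes, and
#' negative `F` (heterozygote excess) is valid down to
#' `-min(p/q, q/p)`.
#'
#' @param pops Character vector of population labels.
#' @param allele_freqs Numeric vector of allele frequencies `p`, one per
#'   population (recycled if length 1).
#' @param inbreeding_F Inbreeding coefficient (recycled).
#' @param n Diploid sample size per population (recycled).
#' @param snp_id SNP label.
#' @param seed Integer seed.
#' @return A `genotype_counts` data frame, one row per population.
#' @export
simulate_genotypes <- function(pops, allele_freqs, inbreeding_F = 0,
                               n = 100L, snp_id = "snp1", seed = 1L) {
  k <- length(pops)
  p <- rep_len(allele_freqs, k)
  F <- rep_len(inbreeding_F, k)
  n <- rep_len(as.integer(n), k)
  if (any(p < 0 | p > 1)) stop("allele frequencies must be in [0, 1]")
  q <- 1 - p
  fmin <- -pmin(ifelse(q > 0, p / q, Inf), ifelse(p > 0, q / p, Inf))
  if (any(F > 1 | F < fmin))
    stop("invalid inbreeding coefficient: F must be in [-min(p/q, q/p), 1]")
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(k), function(i) {
    probs <- c(p[i]^2 + F[i] * p[i] * q[i],
               2 * p[i] * q[i] * (1 - F[i]),
               q[i]^2 + F[i] * p[i] * q[i])
    probs <- pmax(probs, 0)
    cnt <- as.vector(rmultinom(1L, n[i], probs))
    genotype_counts(pops[i], snp_id, cnt[1L], cnt[2L], cnt[3L])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("genotype_counts", "data.frame")
  out
}
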