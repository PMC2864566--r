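## Population-genetic analysis of polymorphic pseudogenic alleles:
## Hardy-Weinberg goodness of fit, Nei-style F_ST, UPGMA population
## clustering, and a permutation test for subdivision.

allele_freq <- function(counts) {
  n <- counts$n_AA + counts$n_Aa + counts$n_aa
  (2 * counts$n_AA + counts$n_Aa) / (2 * n)
}

#' Chi-square goodness-of-fit test for Hardy-Weinberg equilibrium
#'
#' Expected genotype counts from the estimated allele frequency
#' (`n p^2, 2 n p q, n q^2`). The default degrees of freedom is 2 (the
#' convention under which the reference statistics for this analysis were
#' reported); the conventional choice — 1 d.f., since the allele frequency
#' is estimated from the data — is available as
#' `df_convention = "standard1"`.
#'
#' @param counts A single-row [genotype_counts()] (or any list with
#'   `n_AA`, `n_Aa`, `n_aa`).
#' @param df_convention `"df2"` (df = 2, default) or `"standard1"` (df = 1).
#' @return Object of class `hwe_test`: `list(chi2, df, p, p_hat, expected)`.
#' @export
hwe_chisq <- function(counts, df_convention = c("df2", "standard1")) {
  df_convention <- match.arg(df_convention)
  n <- counts$n_AA + counts$n_Aa + counts$n_aa
  if (n <= 0) stop("empty genotype sample")
  p <- (2 * counts$n_AA + counts$n_Aa) / (2 * n)
  if (p %in% c(0, 1)) stop("undefined test: sample is monomorphic")
  q <- 1 - p
  expected <- c(n * p^2, 2 * n * p * q, n * q^2)
  obs <- c(counts$n_AA, counts$n_Aa, counts$n_aa)
  chi2 <- sum((obs - expected)^2 / expected)
  df <- if (df_convention == "df2") 2L else 1L
  structure(list(chi2 = chi2, df = df,
                 p = pchisq(chi2, df, lower.tail = FALSE),
                 p_hat = p, expected = expected),
            class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("<hwe_test> chi2 = %.4g, df = %d, P = %.4g (p_hat = %.3f)\n",
              x$chi2, x$df, x$p, x$p_hat))
  invisible(x)
}

#' Pairwise F_ST between two population samples
#'
#' Nei-style estimator: `H_S` is the mean within-population expected
#' heterozygosity `2 p_i q_i`, `H_T = 2 p_bar q_bar` with the unweighted
#' mean allele frequency, and `F_ST = (H_T - H_S) / H_T`.
#'
#' @param a,b Single-row [genotype_counts()].
#' @return Object of class `fst_result`: `list(fst, h_s, h_t, defined)`;
#'   `fst` is `NA`-flagged when `H_T = 0`.
#' @export
fst_pairwise <- function(a, b) {
  p <- c(allele_freq(a), allele_freq(b))
  fst_from_freqs(p)
}

fst_from_freqs <- function(p) {
  h_s <- mean(2 * p * (1 - p))
  pb <- mean(p)
  h_t <- 2 * pb * (1 - pb)
  structure(list(fst = if (h_t > 0) (h_t - h_s) / h_t else NA_real_,
                 h_s = h_s, h_t = h_t, defined = h_t > 0),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> F_ST = %.4g (H_S = %.4g, H_T = %.4g)%s\n",
              x$fst, x$h_s, x$h_t,
              if (!is.null(x$p_perm) && !is.na(x$p_perm))
                sprintf(", permutation P = %.4g", x$p_perm) else ""))
  invisible(x)
}

#' F_ST matrix over a set of populations
#'
#' @param counts `genotype_counts` data frame, one row per population (one
#'   SNP).
#' @return Symmetric matrix of pairwise F_ST with zero diagonal.
#' @export
fst_matrix <- function(counts) {
  pops <- counts$population
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (i < j) {
      f <- fst_pairwise(counts[i, ], counts[j, ])$fst
      m[i, j] <- m[j, i] <- if (is.na(f)) 0 else f
    }
  }
  m
}

#' UPGMA clustering of populations from an F_ST distance matrix
#'
#' Average-linkage hierarchical clustering, cut at the largest gap between
#' successive merge heights to yield flat subdivisions (one subdivision if
#' all heights are equal). Ties are resolved deterministically by label
#' order.
#'
#' @param fst_matrix Symmetric non-negative matrix with zero diagonal.
#' @return `list(hclust, subdivisions, k)`; `subdivisions` is a named
#'   integer vector of cluster memberships.
#' @export
cluster_populations <- function(fst_matrix) {
  if (!isSymmetric(unname(fst_matrix)))
    stop("F_ST matrix must be symmetric")
  n <- nrow(fst_matrix)
  hc <- hclust(as.dist(fst_matrix), method = "average")
  h <- hc$height
  gaps <- diff(h)
  if (n <= 1L || max(h) == 0 || !length(gaps) || max(gaps) <= 0) {
    k <- if (max(h) > 0 && length(h) == 1L) 2L else 1L
    if (n == 1L) k <- 1L
  } else {
    k <- n - which.max(gaps)
  }
  subdivisions <- cutree(hc, k = k)
  list(hclust = hc, subdivisions = subdivisions, k = k)
}

pool_counts <- function(counts) {
  genotype_counts(population = "pooled", snp_id = counts$snp_id[1L],
                  n_AA = sum(counts$n_AA), n_Aa = sum(counts$n_Aa),
                  n_aa = sum(counts$n_aa))
}

#' Permutation test for F_ST between two population subdivisions
#'
#' The observed F_ST is computed between the two subdivisions after pooling
#' genotype counts within each; the null distribution permutes population
#' labels across subdivisions (sizes preserved). The add-one corrected
#' p-value is `(1 + #\{perm F_ST >= observed\}) / (1 + n_perm)`. When fewer
#' than 20 distinct permutations exist, all of them are enumerated exactly
#' instead, with a warning.
#'
#' @param counts `genotype_counts` data frame, one row per population.
#' @param groups Named membership vector (two groups) over
#'   `counts$population`, e.g. from [cluster_populations()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return An `fst_result` with `p_perm` and `n_perm` fields added.
#' @export
fst_subdivision_permutation <- function(counts, groups, n_perm = 1000L,
                                        seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  gl <- sort(unique(groups))
  if (length(gl) != 2L) stop("exactly two subdivisions required")
  pops <- counts$population
  if (!all(pops %in% names(groups))) stop("groups must cover all populations")
  g <- groups[pops]
  ## fast numeric path: pooled allele counts per subdivision
  m <- cbind(counts$n_AA, counts$n_Aa, counts$n_aa)
  a_cnt <- 2 * m[, 1L] + m[, 2L]   # copies of allele A per population
  n2 <- 2 * rowSums(m)             # allele copies per population
  obs_fst <- function(assign) {
    i <- assign == gl[1L]
    p <- c(sum(a_cnt[i]) / sum(n2[i]), sum(a_cnt[!i]) / sum(n2[!i]))
    h_s <- mean(2 * p * (1 - p))
    pb <- mean(p)
    h_t <- 2 * pb * (1 - pb)
    if (h_t > 0) (h_t - h_s) / h_t else NA_real_
  }
  obs <- obs_fst(g)
  n1 <- sum(g == gl[1L]); n <- length(g)
  n_distinct <- choose(n, n1)
  if (n_distinct < 20L) {
    warning("fewer than 20 distinct permutations; enumerating exactly")
    combs <- utils::combn(n, n1)
    null <- apply(combs, 2L, function(ix) {
      a <- rep(gl[2L], n); a[ix] <- gl[1L]
      obs_fst(a)
    })
    p <- (1 + sum(null >= obs)) / (1 + length(null))
    n_used <- length(null)
  } else {
    set.seed(as.integer(seed))
    null <- vapply(seq_len(n_perm), function(i) obs_fst(sample(g)), 0)
    p <- (1 + sum(null >= obs)) / (1 + n_perm)
    n_used <- n_perm
  }
  res <- fst_pairwise(pool_counts(counts[g == gl[1L], , drop = FALSE]),
                      pool_counts(counts[g == gl[2L], , drop = FALSE]))
  res$p_perm <- p
  res$n_perm <- n_used
  res$null <- null
  res
}
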