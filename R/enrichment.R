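## GO-term and protein-domain over-representation with true-path
## propagation, hypergeometric testing, and Benjamini-Hochberg FDR control.

#' Propagate gene annotations up the is_a hierarchy
#'
#' True-path propagation: a gene annotated to a term is annotated to all of
#' the term's ancestors. Idempotent; errors on a cyclic ontology (the DAG
#' constructor already rejects cycles).
#'
#' @param dag An [annotation_dag()].
#' @return The DAG with `gene2terms` closed under `is_a` ancestors.
#' @export
propagate_annotations <- function(dag) {
  stopifnot(inherits(dag, "annotation_dag"))
  anc <- term_ancestors(dag)
  g2t <- lapply(dag$gene2terms, function(ts)
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE)))))
  out <- dag
  out$gene2terms <- g2t
  out$propagated <- TRUE
  out
}

## memoized ancestor sets (term -> all is_a ancestors, excluding itself)
term_ancestors <- function(dag) {
  memo <- new.env(parent = emptyenv())
  get_anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    ps <- dag$parents[[t]]
    res <- if (!length(ps)) character() else
      sort(unique(c(ps, unlist(lapply(ps, get_anc), use.names = FALSE))))
    memo[[t]] <- res
    res
  }
  setNames(lapply(dag$terms, get_anc), dag$terms)
}

#' GO-style term over-representation test
#'
#' One-sided hypergeometric (Fisher's exact) upper-tail p-value per term on
#' the 2x2 table (study carriers, study non-carriers, other population
#' carriers, rest), with Benjamini-Hochberg FDR adjustment across all
#' tested terms. Terms with no study gene are skipped. The test universe is
#' every term carried by at least one study gene after propagation.
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population Character vector of population gene ids.
#' @param dag A propagated [annotation_dag()] (propagated automatically if
#'   not yet).
#' @param min_population_count Minimum population carriers `K` for a term
#'   to be tested.
#' @return Data frame of class `enrichment_result`: `term`, `k` (study
#'   count), `n` (study size), `K` (population count), `N` (population
#'   size), `p`, `q`, sorted by `q` then `p`.
#' @export
go_enrichment <- function(study, population, dag, min_population_count = 1L) {
  if (length(setdiff(study, population)))
    stop("study set must be a subset of the population")
  if (!isTRUE(dag$propagated)) dag <- propagate_annotations(dag)
  g2t <- dag$gene2terms
  pop_terms <- table(unlist(g2t[intersect(population, names(g2t))],
                            use.names = FALSE))
  study_terms <- table(unlist(g2t[intersect(study, names(g2t))],
                              use.names = FALSE))
  terms <- names(study_terms)  # universe: >= 1 study gene
  N <- length(population); n <- length(study)
  rows <- lapply(terms, function(t) {
    k <- as.integer(study_terms[[t]])
    K <- as.integer(pop_terms[[t]])
    if (K < min_population_count) return(NULL)
    data.frame(term = t, k = k, n = n, K = K, N = N,
               p = phyper(k - 1L, K, N - K, n, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(structure(data.frame(term = character(), k = integer(),
                                n = integer(), K = integer(), N = integer(),
                                p = numeric(), q = numeric()),
                     class = c("enrichment_result", "data.frame")))
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Protein-domain over-representation test
#'
#' Hypergeometric upper-tail test per domain from study/population carrier
#' counts, with Benjamini-Hochberg adjustment. Domains absent from the
#' study set are skipped.
#'
#' @param study_counts Named integer vector: domain -> study genes carrying
#'   it.
#' @param population_counts Named integer vector: domain -> population
#'   genes carrying it (must dominate the study counts).
#' @param n_study,n_population Set sizes.
#' @return Data frame of class `enrichment_result` (as [go_enrichment()]).
#' @export
pfam_enrichment <- function(study_counts, population_counts, n_study,
                            n_population) {
  doms <- names(study_counts)[study_counts > 0L]
  bad <- setdiff(doms, names(population_counts))
  if (length(bad)) stop("inconsistent counts: domain ", bad[1L],
                        " absent from population")
  rows <- lapply(doms, function(d) {
    k <- as.integer(study_counts[[d]])
    K <- as.integer(population_counts[[d]])
    if (k > K || k > n_study || K > n_population)
      stop("inconsistent counts for domain ", d)
    data.frame(term = d, k = k, n = n_study, K = K, N = n_population,
               p = phyper(k - 1L, K, n_population - K, n_study,
                          lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(structure(data.frame(term = character(), k = integer(),
                                n = integer(), K = integer(), N = integer(),
                                p = numeric(), q = numeric()),
                     class = c("enrichment_result", "data.frame")))
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}
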