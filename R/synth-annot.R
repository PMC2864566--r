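## Annotation-set simulation with a planted enriched term.

#' Simulate an annotation DAG with a planted enriched term
#'
#' Builds a random acyclic `is_a` hierarchy of `n_terms` terms, annotates
#' `n_genes` population genes to random leaf-ward terms, and draws a study
#' set of size `n_study` in which the planted term's carrier frequency is
#' `fold_enrichment` times its background frequency (up to rounding).
#'
#' @param n_genes Population size.
#' @param n_terms Number of ontology terms.
#' @param n_study Study-set size.
#' @param planted_term Index (1-based) of the planted term among the
#'   generated terms; defaults to the last term, and the planted term is
#'   always kept a leaf (a planted internal term would be diluted by
#'   true-path propagation of its descendants).
#' @param fold_enrichment Study-over-background frequency ratio (>= 1).
#' @param background_freq Background carrier frequency of the planted term.
#' @param terms_per_gene Mean number of direct annotations per gene.
#' @param seed Integer seed.
#' @return `list(dag, study, population, planted_term, study_carriers,
#'   background_carriers)`.
#' @export
simulate_annotations <- function(n_genes = 1000L, n_terms = 50L,
                                 n_study = 20L, planted_term = n_terms,
                                 fold_enrichment = 5, background_freq = 0.1,
                                 terms_per_gene = 3, seed = 1L) {
  if (fold_enrichment < 1) stop("fold_enrichment must be >= 1")
  study_freq <- fold_enrichment * background_freq
  if (study_freq > 1)
    stop("infeasible fold: study frequency would exceed 1")
  set.seed(as.integer(seed))
  terms <- sprintf("T:%04d", seq_len(n_terms))
  parents <- list()
  parents[[terms[1L]]] <- character()
  for (i in 2L:n_terms) {
    cand <- setdiff(seq_len(i - 1L), planted_term)  # planted term stays a leaf
    if (!length(cand)) cand <- 1L
    parents[[terms[i]]] <- terms[if (length(cand) == 1L) cand
                                 else sample(cand, 1L)]
  }
  genes <- sprintf("gene%04d", seq_len(n_genes))
  planted <- terms[planted_term]
  other <- setdiff(terms, planted)
  ## background annotations
  gene2terms <- lapply(genes, function(g) {
    k <- max(1L, rpois(1L, terms_per_gene))
    sample(other, min(k, length(other)))
  })
  names(gene2terms) <- genes
  n_bg <- round(background_freq * n_genes)
  bg_carriers <- sample(genes, n_bg)
  for (g in bg_carriers) gene2terms[[g]] <- unique(c(gene2terms[[g]], planted))
  ## study set: carriers at fold x background frequency
  n_study_carriers <- round(study_freq * n_study)
  if (n_study_carriers > length(bg_carriers))
    stop("infeasible fold: not enough carriers in the population")
  non_carriers <- setdiff(genes, bg_carriers)
  if (n_study - n_study_carriers > length(non_carriers))
    stop("infeasible fold given set sizes")
  study <- c(sample(bg_carriers, n_study_carriers),
             sample(non_carriers, n_study - n_study_carriers))
  dag <- annotation_dag(parents, gene2terms = gene2terms)
  list(dag = dag, study = sort(study), population = genes,
       planted_term = planted, study_carriers = n_study_carriers,
       background_carriers = n_bg)
}
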