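#' Construct an annotation DAG
#'
#' A GO-like ontology restricted to `is_a` edges: terms, an acyclic
#' child-to-parent mapping, a namespace per term, and direct gene-to-term
#' annotations.
#'
#' @param parents Named list: term id -> character vector of `is_a` parents
#'   (empty for roots).
#' @param gene2terms Named list: gene id -> character vector of directly
#'   annotated term ids.
#' @param namespace Optional named character vector: term id -> namespace.
#' @return Object of class `annotation_dag`.
#' @export
annotation_dag <- function(parents, gene2terms = list(), namespace = NULL) {
  terms <- sort(unique(c(names(parents), unlist(parents, use.names = FALSE))))
  parents <- lapply(setNames(terms, terms), function(t) {
    p <- parents[[t]]
    if (is.null(p)) character() else as.character(p)
  })
  ## cycle check: Kahn topological sort over child -> parent edges
  indeg <- vapply(parents, length, 0L)
  queue <- names(indeg)[indeg == 0L]
  children <- split(rep(names(parents), lengths(parents)),
                    unlist(parents, use.names = FALSE))
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(terms)) stop("annotation DAG contains a cycle")
  bad <- setdiff(unlist(gene2terms, use.names = FALSE), terms)
  if (length(bad)) stop("annotation to unknown term: ", bad[1L])
  structure(list(terms = terms, parents = parents,
                 gene2terms = gene2terms, namespace = namespace),
            class = "annotation_dag")
}

#' Read an OBO-lite ontology
#'
#' Parses only `[Term]`, `id:`, `is_a:` and `namespace:` lines — the subset
#' needed for `is_a` true-path propagation.
#'
#' @param path OBO-lite file.
#' @return An [annotation_dag()] without gene annotations (attach them with
#'   [read_gene_annotations()]).
#' @export
read_obo_lite <- function(path) {
  lines <- trimws(readLines(path))
  parents <- list(); ns <- character(); cur <- NULL
  for (line in lines) {
    if (line == "[Term]") { cur <- NULL; next }
    if (startsWith(line, "id: ")) {
      cur <- sub("^id: ", "", line)
      if (is.null(parents[[cur]])) parents[[cur]] <- character()
    } else if (startsWith(line, "is_a: ") && !is.null(cur)) {
      parents[[cur]] <- c(parents[[cur]], sub("\\s*!.*$", "", sub("^is_a: ", "", line)))
    } else if (startsWith(line, "namespace: ") && !is.null(cur)) {
      ns[[cur]] <- sub("^namespace: ", "", line)
    }
  }
  annotation_dag(parents, namespace = if (length(ns)) ns else NULL)
}

#' Write an annotation DAG as OBO-lite
#' @param dag An [annotation_dag()].
#' @param path Output path.
#' @export
write_obo_lite <- function(dag, path) {
  out <- character()
  for (t in dag$terms) {
    out <- c(out, "[Term]", paste0("id: ", t))
    if (!is.null(dag$namespace) && !is.na(dag$namespace[t]))
      out <- c(out, paste0("namespace: ", dag$namespace[[t]]))
    out <- c(out, paste0("is_a: ", dag$parents[[t]]), "")
  }
  writeLines(out, path)
  invisible(NULL)
}

#' Read direct gene-to-term annotations from TSV
#'
#' Two columns: `gene_id`, `term_id`; attaches them to a DAG.
#' @param path TSV path.
#' @param dag An [annotation_dag()].
#' @return The DAG with `gene2terms` populated.
#' @export
read_gene_annotations <- function(path, dag) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character")
  annotation_dag(dag$parents,
                 gene2terms = split(df$term_id, df$gene_id),
                 namespace = dag$namespace)
}

#' Write direct gene-to-term annotations as TSV
#' @param dag An [annotation_dag()] with gene annotations.
#' @param path Output path.
#' @export
write_gene_annotations <- function(dag, path) {
  df <- data.frame(
    gene_id = rep(names(dag$gene2terms), lengths(dag$gene2terms)),
    term_id = unlist(dag$gene2terms, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
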