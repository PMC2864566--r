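#' Construct an ortholog table
#'
#' Pairs of (reference gene, query gene) with a similarity score, plus the
#' full gene-id universes of both species so that absence of a pair is
#' meaningful (an InParanoid-style one-to-one set at toy scale).
#'
#' @param pairs Data frame with columns `ref_id`, `query_id`, `score`.
#' @param ref_universe,query_universe Character vectors of all gene ids.
#' @return Object of class `ortholog_table`.
#' @export
ortholog_table <- function(pairs, ref_universe, query_universe) {
  pairs <- as.data.frame(pairs)
  if (!nrow(pairs)) {
    pairs <- data.frame(ref_id = character(), query_id = character(),
                        score = numeric())
  }
  stopifnot(all(c("ref_id", "query_id", "score") %in% names(pairs)))
  if (anyDuplicated(pairs[c("ref_id", "query_id")]))
    stop("duplicate ortholog pair")
  if (any(pairs$score < 0)) stop("ortholog scores must be >= 0")
  bad_r <- setdiff(pairs$ref_id, ref_universe)
  bad_q <- setdiff(pairs$query_id, query_universe)
  if (length(bad_r)) stop("unknown reference id in ortholog pairs: ", bad_r[1L])
  if (length(bad_q)) stop("unknown query id in ortholog pairs: ", bad_q[1L])
  structure(list(pairs = pairs,
                 ref_universe = sort(unique(ref_universe)),
                 query_universe = sort(unique(query_universe))),
            class = "ortholog_table")
}

#' Read an ortholog table from TSV
#'
#' @param tsv_path TSV with header `ref_id`, `query_id`, `score`; `#` lines
#'   are comments.
#' @param ref_universe,query_universe Character vectors of ids, or paths to
#'   one-id-per-line files.
#' @return An [ortholog_table()].
#' @export
read_ortholog_table <- function(tsv_path, ref_universe, query_universe) {
  as_ids <- function(x) {
    if (length(x) == 1L && file.exists(x)) readLines(x) else as.character(x)
  }
  df <- read.delim(tsv_path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = c("character", "character", "numeric"))
  names(df) <- c("ref_id", "query_id", "score")
  ortholog_table(df, as_ids(ref_universe), as_ids(query_universe))
}

#' Write an ortholog table (pairs only) to TSV
#' @param tab An [ortholog_table()].
#' @param tsv_path Output path.
#' @export
write_ortholog_table <- function(tab, tsv_path) {
  write.table(tab$pairs, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

## ---------------------------------------------------------------------------

#' Construct per-population biallelic genotype counts
#'
#' @param population Population label.
#' @param snp_id SNP identifier.
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts (total > 0).
#' @return Object of class `genotype_counts` (a one-row data frame).
#' @export
genotype_counts <- function(population, snp_id, n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  if (n_AA + n_Aa + n_aa <= 0) stop("genotype counts must sum to > 0")
  structure(data.frame(population = population, snp_id = snp_id,
                       n_AA = as.integer(n_AA), n_Aa = as.integer(n_Aa),
                       n_aa = as.integer(n_aa)),
            class = c("genotype_counts", "data.frame"))
}

#' Read a genotype table from TSV
#'
#' Columns: `population`, `snp_id`, `n_AA`, `n_Aa`, `n_aa`.
#' @param path TSV path (`#` comments allowed).
#' @return A `genotype_counts` data frame (one row per population x SNP).
#' @export
read_genotype_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("population", "snp_id", "n_AA", "n_Aa", "n_aa")
  if (!all(need %in% names(df))) stop("genotype table must have columns: ",
                                      paste(need, collapse = ", "))
  if (any(df$n_AA + df$n_Aa + df$n_aa <= 0)) stop("genotype counts must sum to > 0")
  class(df) <- c("genotype_counts", "data.frame")
  df
}

#' Write a genotype table to TSV
#' @param counts `genotype_counts` data frame.
#' @param path Output path.
#' @export
write_genotype_table <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

## ---------------------------------------------------------------------------

#' Write / read a planted-truth table
#'
#' The truth table records, per reference gene, its simulated fate and any
#' planted disruptions (kind and query-genome position), so that every
#' pipeline stage can be scored against known truth.
#' @param truth Data frame with at least `gene_id` and `fate` columns.
#' @param path TSV path.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#")
}

GENE_FATES <- c("INTACT_ORTHOLOG", "UNITARY_PSEUDO", "FAMILY_PSEUDO",
                "PROCESSED_COPY", "DELETED_IN_QUERY", "GAIN_IN_REF")
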