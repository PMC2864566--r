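#' @useDynLib unipseudo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rmultinom rpois runif setNames p.adjust pchisq
#'   phyper hclust as.dist cutree
#' @importFrom utils read.delim write.table head tail
NULL

EVIDENCE_CLASSES <- c("NAMED_GENE", "SPLICED_CDNA", "UNSPLICED_CDNA", "PREDICTED")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct a gene model
#'
#' A gene model is a multi-exon protein-coding gene on a genome: an ordered
#' set of exon intervals (internal convention: 0-based, half-open, ascending
#' genomic coordinates regardless of strand), a strand, an evidence class
#' describing the annotation support, and the protein translated from the
#' spliced CDS.
#'
#' @param gene_id Gene identifier.
#' @param species Species label.
#' @param chrom Chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons Integer matrix with columns `start`, `end` (0-based,
#'   half-open), rows in ascending genomic order, non-overlapping.
#' @param protein Amino-acid string (no terminal `*`), or `NA` to fill in
#'   later from a genome.
#' @param evidence_class One of `NAMED_GENE`, `SPLICED_CDNA`,
#'   `UNSPLICED_CDNA`, `PREDICTED`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, species, chrom, strand, exons,
                       protein = NA_character_,
                       evidence_class = "NAMED_GENE") {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  strand <- match.arg(strand, c("+", "-"))
  evidence_class <- match.arg(evidence_class, EVIDENCE_CLASSES)
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("gene model must have at least one exon")
  if (any(exons[, "end"] <= exons[, "start"]))
    stop("exon intervals must be non-empty half-open [start, end)")
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons[, "start"], strictly = TRUE))
      stop("exons must be sorted by ascending start")
    if (any(exons[-1L, "start"] < exons[-nrow(exons), "end"]))
      stop("exons must be disjoint")
  }
  if (evidence_class == "UNSPLICED_CDNA" && nrow(exons) != 1L)
    stop("UNSPLICED_CDNA gene models must have exactly one exon")
  structure(list(gene_id = gene_id, species = species, chrom = chrom,
                 strand = strand, exons = exons, protein = protein,
                 evidence_class = evidence_class),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s%s:%d-%d, %d exon(s), %s\n",
              x$gene_id, x$species, x$chrom, x$strand,
              x$exons[1L, "start"], x$exons[nrow(x$exons), "end"],
              nrow(x$exons), x$evidence_class))
  invisible(x)
}

cds_length <- function(model) sum(model$exons[, "end"] - model$exons[, "start"])

#' Spliced CDS of a gene model
#'
#' Concatenates the exon sequences in biological (5'->3') order; for
#' minus-strand genes the ascending-stored exons are reverse-complemented and
#' concatenated in reverse.
#'
#' @param model A [gene_model()].
#' @param genome A [Biostrings::DNAStringSet] containing `model$chrom`.
#' @return A `DNAString` with the coding sequence.
#' @export
spliced_cds <- function(model, genome) {
  chrom <- genome[[model$chrom]]
  parts <- lapply(seq_len(nrow(model$exons)), function(i)
    Biostrings::subseq(chrom, model$exons[i, "start"] + 1L, model$exons[i, "end"]))
  cds <- do.call(Biostrings::xscat, parts)
  if (model$strand == "-") cds <- Biostrings::reverseComplement(cds)
  cds
}

#' Translate the spliced CDS of a gene model
#' @inheritParams spliced_cds
#' @return Amino-acid string (character scalar).
#' @export
translate_model <- function(model, genome) {
  cds <- spliced_cds(model, genome)
  if (length(cds) %% 3L != 0L)
    stop(sprintf("CDS length of %s (%d) is not a multiple of 3",
                 model$gene_id, length(cds)))
  as.character(Biostrings::translate(cds, no.init.codon = TRUE))
}

#' Validate a functional gene model against a genome
#'
#' Checks the functional-gene invariants: CDS length a multiple of 3 and a
#' translation free of internal stop codons.
#' @inheritParams spliced_cds
#' @return The protein string, invisibly; errors otherwise.
#' @export
validate_functional_model <- function(model, genome) {
  if (cds_length(model) %% 3L != 0L)
    stop(sprintf("validation error: CDS of functional gene %s is not a multiple of 3",
                 model$gene_id))
  aa <- translate_model(model, genome)
  body <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", body, fixed = TRUE))
    stop(sprintf("validation error: functional gene %s translates with an internal stop",
                 model$gene_id))
  invisible(aa)
}

## ---------------------------------------------------------------------------
## GFF3 (1-based, closed) <-> internal (0-based, half-open)

#' Read gene models from GFF3 + FASTA
#'
#' Parses a restricted GFF3 (gene and CDS features with `ID`, `Parent`,
#' `evidence` attributes; 1-based closed coordinates) plus the genome FASTA,
#' converts coordinates to the internal 0-based half-open convention, and
#' translates each spliced CDS with the standard genetic code.
#'
#' @param gff3_path Path to the GFF3 file.
#' @param fasta_path Path to the genome FASTA.
#' @param species Species label to attach to the models.
#' @param check Validate functional-gene invariants (default `TRUE`).
#' @return `list(models = <named list of gene_model>, genome = <DNAStringSet>)`.
#' @export
read_gene_models <- function(gff3_path, fasta_path, species = "ref", check = TRUE) {
  if (!file.exists(gff3_path)) stop("GFF3 file not found: ", gff3_path)
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  lines <- readLines(gff3_path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  recs <- vector("list", sum(keep))
  gene_meta <- list()
  cds_rows <- list()
  for (ln in which(keep)) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 9L)
      stop(sprintf("GFF3 parse error at line %d: expected 9 tab-separated fields, got %d",
                   ln, length(fields)))
    start <- suppressWarnings(as.integer(fields[4L]))
    end <- suppressWarnings(as.integer(fields[5L]))
    if (is.na(start) || is.na(end) || start < 1L || end < start)
      stop(sprintf("GFF3 parse error at line %d: bad coordinates '%s'-'%s'",
                   ln, fields[4L], fields[5L]))
    attrs <- parse_gff3_attrs(fields[9L])
    type <- fields[3L]
    if (type == "gene") {
      gene_meta[[attrs[["ID"]]]] <- list(
        evidence = if (!is.null(attrs[["evidence"]])) attrs[["evidence"]] else "NAMED_GENE")
    } else if (type == "CDS") {
      parent <- attrs[["Parent"]]
      if (is.null(parent))
        stop(sprintf("GFF3 parse error at line %d: CDS without Parent attribute", ln))
      cds_rows[[length(cds_rows) + 1L]] <- list(
        gene = parent, chrom = fields[1L], strand = fields[7L],
        start = start - 1L, end = end)
    }
  }
  if (!length(cds_rows)) return(list(models = list(), genome = genome))
  df <- do.call(rbind, lapply(cds_rows, as.data.frame))
  models <- lapply(split(df, df$gene), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    meta <- gene_meta[[g$gene[1L]]]
    ev <- if (!is.null(meta)) meta$evidence else "NAMED_GENE"
    gene_model(as.character(g$gene[1L]), species, as.character(g$chrom[1L]),
               as.character(g$strand[1L]),
               cbind(g$start, g$end), evidence_class = ev)
  })
  models <- models[order(names(models))]
  models <- lapply(models, function(m) {
    if (check) {
      m$protein <- validate_functional_model(m, genome)
    } else {
      m$protein <- tryCatch(translate_model(m, genome), error = function(e) NA_character_)
    }
    m
  })
  list(models = models, genome = genome)
}

parse_gff3_attrs <- function(s) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  vals <- lapply(kv, function(p) if (length(p) == 2L) p[2L] else NA_character_)
  names(vals) <- vapply(kv, `[`, "", 1L)
  vals
}

#' Write gene models to GFF3 + FASTA
#'
#' The inverse of [read_gene_models()]: internal 0-based half-open exon
#' coordinates are written as 1-based closed GFF3; the genome FASTA is
#' wrapped at 60 columns. Reading the written files back round-trips
#' bit-exactly.
#'
#' @param models Named list of [gene_model()]s.
#' @param genome `DNAStringSet`.
#' @param gff3_path,fasta_path Output paths.
#' @export
write_gene_models <- function(models, genome, gff3_path, fasta_path) {
  out <- c("##gff-version 3")
  for (m in models[order(names(models))]) {
    span <- range(m$exons)
    out <- c(out, sprintf("%s\tunipseudo\tgene\t%d\t%d\t.\t%s\t.\tID=%s;evidence=%s",
                          m$chrom, span[1L] + 1L, span[2L], m$strand,
                          m$gene_id, m$evidence_class))
    for (i in seq_len(nrow(m$exons)))
      out <- c(out, sprintf("%s\tunipseudo\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                            m$chrom, m$exons[i, "start"] + 1L, m$exons[i, "end"],
                            m$strand, 0L, m$gene_id))
  }
  writeLines(out, gff3_path)
  Biostrings::writeXStringSet(genome, fasta_path, width = 60L)
  invisible(NULL)
}

#' Write disruption events as BED
#'
#' 0-based half-open intervals; the `name` field is `<gene>|<kind>`.
#' @param events Data frame of disruption events (see [detect_disruptions()]).
#' @param path Output path.
#' @export
write_disruptions_bed <- function(events, path) {
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t0\t%s",
                   events$chrom, events$pos, events$pos + pmax(1L, events$width),
                   events$gene_id, events$kind, events$strand)
  writeLines(lines, path)
  invisible(NULL)
}
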