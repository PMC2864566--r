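## Synthetic genomes with planted truth.
##
## The generators are pure functions of (parameters, seed). Background
## divergence is uniform per-site substitution with no indels, and every
## simulated intron is written with canonical GT...AG ends, so that the only
## ORF-breaking signal in a simulated query genome is a planted disruption.

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

rand_dna_chars <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

#' Simulate a reference gene set
#'
#' Generates one reference chromosome carrying `n_genes` non-overlapping
#' multi-exon protein-coding genes on random strands. Exon boundaries are
#' codon-aligned (phase 0), introns carry canonical GT/AG ends, CDSs start
#' with ATG and translate without internal stops.
#'
#' @param n_genes Number of genes (>= 1).
#' @param exon_count_range Integer range `c(min, max)` of exons per gene.
#' @param exon_len_range Range of exon lengths in nt (rounded to whole
#'   codons).
#' @param intergenic_len Length of the random spacer between genes (nt).
#' @param intron_len_range Range of intron lengths in nt (>= 4).
#' @param evidence_weights Sampling weights for annotation evidence classes;
#'   `UNSPLICED_CDNA` is only ever assigned to single-exon genes.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param species,chrom Labels.
#' @return Object of class `geneset`: `list(models, genome, species)`.
#' @export
simulate_reference_geneset <- function(n_genes,
                                       exon_count_range = c(1L, 5L),
                                       exon_len_range = c(90L, 240L),
                                       intergenic_len = 300L,
                                       intron_len_range = c(60L, 200L),
                                       evidence_weights = c(
                                         NAMED_GENE = 0.7, SPLICED_CDNA = 0.15,
                                         UNSPLICED_CDNA = 0.05, PREDICTED = 0.1),
                                       seed = 1L,
                                       species = "ref", chrom = "chr1") {
  stopifnot(n_genes >= 1L)
  lo_cod <- ceiling(exon_len_range[1L] / 3)
  hi_cod <- floor(exon_len_range[2L] / 3)
  if (lo_cod > hi_cod || lo_cod < 1L)
    stop("infeasible exon_len_range: no whole-codon length inside it")
  if (exon_count_range[1L] < 1L || exon_count_range[1L] > exon_count_range[2L])
    stop("infeasible exon_count_range")
  if (intron_len_range[1L] < 4L) stop("introns must be >= 4 nt (GT...AG)")
  set.seed(as.integer(seed))
  models <- list()
  pieces <- character()
  offset <- 0L
  for (i in seq_len(n_genes)) {
    spacer <- paste(rand_dna_chars(intergenic_len), collapse = "")
    n_ex <- sample(seq(exon_count_range[1L], exon_count_range[2L]), 1L)
    exon_cod <- sample(seq(lo_cod, hi_cod), n_ex, replace = TRUE)
    intron_lens <- if (n_ex > 1L)
      sample(seq(intron_len_range[1L], intron_len_range[2L]), n_ex - 1L,
             replace = TRUE) else integer()
    strand <- sample(c("+", "-"), 1L)
    ev <- sample(names(evidence_weights), 1L, prob = evidence_weights)
    if (ev == "UNSPLICED_CDNA" && n_ex > 1L) ev <- "SPLICED_CDNA"
    gene_id <- sprintf("g%03d", i)
    layout <- list(exon_cod = exon_cod, intron_lens = intron_lens,
                   strand = strand)
    bio <- build_gene_bio_seq(layout)
    gseq <- if (strand == "-") revcomp_chars(bio) else bio
    gene_start <- offset + intergenic_len
    L <- length(bio)
    models[[gene_id]] <- gene_model(
      gene_id, species, chrom, strand,
      layout_to_exons(layout, gene_start, L),
      evidence_class = ev)
    pieces <- c(pieces, spacer, paste(gseq, collapse = ""))
    offset <- gene_start + L
  }
  pieces <- c(pieces, paste(rand_dna_chars(intergenic_len), collapse = ""))
  genome <- Biostrings::DNAStringSet(setNames(paste(pieces, collapse = ""), chrom))
  models <- lapply(models, function(m) {
    m$protein <- translate_model(m, genome)
    m
  })
  structure(list(models = models, genome = genome, species = species),
            class = "geneset")
}

#' @export
print.geneset <- function(x, ...) {
  cat(sprintf("<geneset> %s: %d gene(s) on %d sequence(s) (%s nt)\n",
              x$species, length(x$models), length(x$genome),
              format(sum(Biostrings::width(x$genome)), big.mark = ",")))
  invisible(x)
}

## -- gene layout helpers (biological 5'->3' structure) ----------------------

## layout: exon_cod (codons per exon, 5'->3'), intron_lens, strand
gene_layout <- function(model) {
  w <- model$exons[, "end"] - model$exons[, "start"]
  gaps <- if (nrow(model$exons) > 1L)
    model$exons[-1L, "start"] - model$exons[-nrow(model$exons), "end"] else integer()
  if (model$strand == "-") { w <- rev(w); gaps <- rev(gaps) }
  if (any(w %% 3L != 0L))
    stop("gene_layout assumes codon-aligned (phase-0) exons")
  list(exon_cod = as.integer(w / 3L), intron_lens = as.integer(gaps),
       strand = model$strand)
}

layout_len <- function(layout)
  sum(layout$exon_cod) * 3L + sum(layout$intron_lens)

## bio intervals of exons within the gene: matrix [start,end) 0-based
layout_exon_bio <- function(layout) {
  k <- length(layout$exon_cod)
  starts <- integer(k); pos <- 0L
  for (i in seq_len(k)) {
    starts[i] <- pos
    pos <- pos + layout$exon_cod[i] * 3L
    if (i < k) pos <- pos + layout$intron_lens[i]
  }
  cbind(start = starts, end = starts + layout$exon_cod * 3L)
}

## genomic exon coordinates (ascending) for a gene at [g0, g0+L)
layout_to_exons <- function(layout, g0, L) {
  bio <- layout_exon_bio(layout)
  if (layout$strand == "+") {
    ex <- cbind(g0 + bio[, "start"], g0 + bio[, "end"])
  } else {
    ex <- cbind(g0 + L - bio[, "end"], g0 + L - bio[, "start"])
    ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  }
  colnames(ex) <- c("start", "end")
  ex
}

## random biological gene sequence for a layout: ATG-led CDS split by
## GT..AG introns; returns character vector
build_gene_bio_seq <- function(layout) {
  n_cod <- sum(layout$exon_cod)
  cds <- c("ATG", sample(SENSE_CODONS, n_cod - 1L, replace = TRUE))
  cds <- unlist(strsplit(cds, ""))
  bio <- character()
  cpos <- 0L
  for (i in seq_along(layout$exon_cod)) {
    nt <- layout$exon_cod[i] * 3L
    bio <- c(bio, cds[(cpos + 1L):(cpos + nt)])
    cpos <- cpos + nt
    if (i < length(layout$exon_cod)) {
      il <- layout$intron_lens[i]
      bio <- c(bio, "G", "T", rand_dna_chars(il - 4L), "A", "G")
    }
  }
  bio
}

revcomp_chars <- function(x)
  rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])

## map bio position -> CDS codon index (1-based) or NA if intronic
bio_to_cds <- function(layout) {
  bio <- layout_exon_bio(layout)
  L <- layout_len(layout)
  map <- rep(NA_integer_, L)
  cpos <- 0L
  for (i in seq_len(nrow(bio))) {
    idx <- (bio[i, "start"] + 1L):bio[i, "end"]
    map[idx] <- cpos + seq_along(idx)
    cpos <- cpos + length(idx)
  }
  map  # 1-based CDS nucleotide position per bio position (NA in introns)
}

## apply purifying-safe substitutions to a bio char vector:
## never touches splice dinucleotides or `protected` positions (1-based),
## and never creates an in-frame stop codon in the CDS
mutate_bio_seq <- function(bio, layout, rate, protected = integer()) {
  if (rate <= 0) return(bio)
  L <- length(bio)
  cdsmap <- bio_to_cds(layout)
  exbio <- layout_exon_bio(layout)
  splice <- integer()
  if (nrow(exbio) > 1L) {
    for (i in seq_len(nrow(exbio) - 1L)) {
      don <- exbio[i, "end"]          # 0-based intron start
      acc <- exbio[i + 1L, "start"] - 2L
      splice <- c(splice, don + 1L, don + 2L, acc + 1L, acc + 2L)
    }
  }
  hit <- which(runif(L) < rate)
  hit <- setdiff(hit, c(splice, protected))
  bases <- c("A", "C", "G", "T")
  for (p in hit) {
    alts <- sample(setdiff(bases, bio[p]))
    cp <- cdsmap[p]
    if (is.na(cp)) { bio[p] <- alts[1L]; next }
    cod_i <- (cp - 1L) %/% 3L          # 0-based codon index
    within <- (cp - 1L) %% 3L + 1L
    cod_bio <- which(!is.na(cdsmap) & (cdsmap - 1L) %/% 3L == cod_i)
    codon <- bio[cod_bio]
    for (a in alts) {
      codon2 <- codon; codon2[within] <- a
      if (!(paste(codon2, collapse = "") %in% STOP_CODONS)) {
        bio[p] <- a
        break
      }
    }
  }
  bio
}
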