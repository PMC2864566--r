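## Exon-guided, frameshift-aware protein-to-genome alignment and CDS
## disruption detection. Each reference exon's protein segment is aligned
## near its expected position in the candidate window by the compiled
## three-frame DP; introns are inferred between exon blocks and checked for
## canonical GT/AG ends.

.unipseudo_env <- new.env(parent = emptyenv())

get_align_tables <- function() {
  if (is.null(.unipseudo_env$submat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    submat <- e$BLOSUM62
    bases <- c("A", "C", "G", "T")
    idx <- 0:63
    codons <- paste0(bases[idx %/% 16L + 1L], bases[(idx %/% 4L) %% 4L + 1L],
                     bases[idx %% 4L + 1L])
    aa <- Biostrings::GENETIC_CODE[codons]
    .unipseudo_env$submat <- submat
    .unipseudo_env$codon_aa <- ifelse(aa == "*", 0L, match(aa, rownames(submat)))
    .unipseudo_env$codon_to_aa <- aa
  }
  list(submat = .unipseudo_env$submat, codon_aa = .unipseudo_env$codon_aa,
       codon_to_aa = .unipseudo_env$codon_to_aa)
}

encode_dna <- function(chars) {
  v <- match(chars, c("A", "C", "G", "T"))
  v[is.na(v)] <- 0L
  as.integer(v - 1L)
}

encode_prot <- function(chars, submat) {
  v <- match(chars, rownames(submat))
  v[is.na(v)] <- match("X", rownames(submat))
  as.integer(v)
}

#' Frameshift-aware local alignment of a protein segment to DNA
#'
#' Thin R wrapper over the compiled DP. Exposed mainly for testing and for
#' callers that want a single-segment alignment; [align_exon_guided()] uses
#' it per exon.
#'
#' @param protein Amino-acid string.
#' @param dna DNA string.
#' @param gap_open,gap_extend Affine gap costs (> 0) for codon-sized gaps.
#' @param frameshift_penalty Cost (> 0) of each 1-2 nt frameshift slip.
#' @param stop_score Score for aligning a residue across a stop codon.
#' @return `list(score, ops)`; `ops` has one row per operation with `type`
#'   (1 codon match, 2 frameshift, 3 residue gap, 4 codon gap), 1-based
#'   `prot` and `dna_start`, and `dna_len`.
#' @export
align_protein_dna <- function(protein, dna, gap_open = 11, gap_extend = 1,
                              frameshift_penalty = 20, stop_score = -4) {
  stopifnot(gap_open > 0, gap_extend > 0, frameshift_penalty > 0)
  tb <- get_align_tables()
  fs_align_cpp(encode_prot(strsplit(protein, "")[[1L]], tb$submat),
               encode_dna(strsplit(toupper(dna), "")[[1L]]),
               tb$submat, tb$codon_aa, gap_open, gap_extend,
               frameshift_penalty, stop_score)
}

#' Exon-guided spliced alignment of a reference gene onto a candidate window
#'
#' Aligns each reference exon's protein segment against the window near its
#' expected position (using the known reference gene structure, as the
#' reference gene model is always in hand), infers introns between exon
#' blocks, and records identity, net indel length and frameshift operations
#' per exon. An exon with no positive-scoring alignment is marked missing
#' (feeding truncation calls) rather than raising an error.
#'
#' @param ref_model Reference [gene_model()] (with `protein` filled in).
#' @param window One row of [map_protein_to_genome()] output (or a list with
#'   `chrom`, `start`, `end`, `strand`).
#' @param query_genome `DNAStringSet`.
#' @param gap_open,gap_extend,frameshift_penalty,stop_score DP scoring.
#' @param margin Positional slack (nt) around each exon's expected location.
#' @return Object of class `spliced_alignment`.
#' @export
align_exon_guided <- function(ref_model, window, query_genome,
                              gap_open = 11, gap_extend = 1,
                              frameshift_penalty = 20, stop_score = -4,
                              margin = 200L) {
  stopifnot(gap_open > 0, gap_extend > 0, frameshift_penalty > 0)
  tb <- get_align_tables()
  chrom <- as.character(window$chrom)
  wstart <- as.integer(window$start); wend <- as.integer(window$end)
  strand <- as.character(window$strand)
  ws <- Biostrings::subseq(query_genome[[chrom]], wstart + 1L, wend)
  if (strand == "-") ws <- Biostrings::reverseComplement(ws)
  wchars <- strsplit(as.character(ws), "")[[1L]]
  wlen <- length(wchars)
  dna_code <- encode_dna(wchars)
  layout <- gene_layout(ref_model)
  np <- nchar(ref_model$protein)
  pchars <- strsplit(ref_model$protein, "")[[1L]]
  pcode <- encode_prot(pchars, tb$submat)
  cum <- cumsum(layout$exon_cod)
  seg_lo <- c(0L, cum[-length(cum)])   # residues before each exon

  exons <- vector("list", length(layout$exon_cod))
  prev_end <- 0L      # a coordinate just past the last aligned block
  expect_extra <- 0L  # unaligned expected nt since the last block
  for (i in seq_along(layout$exon_cod)) {
    exon_nt <- layout$exon_cod[i] * 3L
    if (i > 1L) expect_extra <- expect_extra + layout$intron_lens[i - 1L]
    lo <- prev_end
    hi <- min(wlen, prev_end + expect_extra + exon_nt + margin)
    res <- (seg_lo[i] + 1L):cum[i]
    block <- list(present = FALSE, index = i)
    if (hi - lo >= 3L) {
      al <- fs_align_cpp(pcode[res], dna_code[(lo + 1L):hi], tb$submat,
                         tb$codon_aa, gap_open, gap_extend,
                         frameshift_penalty, stop_score)
      if (al$score > 0 && nrow(al$ops)) {
        ops <- al$ops
        ops$prot <- ops$prot + seg_lo[i]          # global residue index
        ops$a <- lo + ops$dna_start - 1L          # absolute 0-based
        cons <- ops$dna_len > 0L
        a0 <- min(ops$a[cons]); a1 <- max(ops$a[cons] + ops$dna_len[cons])
        emit <- ops$type %in% c(1L, 2L)
        mt <- ops[ops$type == 1L, , drop = FALSE]
        ident <- if (nrow(mt)) {
          cod <- codon_at(wchars, mt$a + mt$dna_len - 3L, tb)
          mean(cod == pchars[mt$prot])
        } else 0
        block <- list(present = TRUE, index = i, a0 = a0, a1 = a1,
                      prot_lo = min(ops$prot[emit]), prot_hi = max(ops$prot[emit]),
                      n_aligned = sum(emit), identity = ident,
                      net_indel = sum(ops$dna_len[ops$type == 2L] - 3L) -
                        3L * sum(ops$type == 3L) + 3L * sum(ops$type == 4L),
                      score = al$score, ops = ops)
        prev_end <- a1
        expect_extra <- 0L
      }
    }
    if (!block$present) expect_extra <- expect_extra + exon_nt
    exons[[i]] <- block
  }

  present <- which(vapply(exons, `[[`, TRUE, "present"))
  introns <- data.frame(index = integer(), a_start = integer(),
                        a_end = integer(), len = integer(),
                        donor = character(), acceptor = character())
  if (length(present) > 1L) {
    for (k in seq_len(length(present) - 1L)) {
      i <- present[k]; j <- present[k + 1L]
      if (j != i + 1L) next   # an internal exon is missing; no clean intron
      a_s <- exons[[i]]$a1; a_e <- exons[[j]]$a0
      len <- a_e - a_s
      don <- if (len >= 2L) paste(wchars[(a_s + 1L):(a_s + 2L)], collapse = "") else ""
      acc <- if (len >= 2L) paste(wchars[(a_e - 1L):a_e], collapse = "") else ""
      introns <- rbind(introns, data.frame(
        index = i, a_start = a_s, a_end = a_e, len = len,
        donor = don, acceptor = acc))
    }
  }
  aligned_res <- unique(unlist(lapply(exons[present], function(b)
    b$ops$prot[b$ops$type %in% c(1L, 2L)])))
  structure(list(gene_id = ref_model$gene_id, chrom = chrom, strand = strand,
                 w_start = wstart, w_end = wend, wseq = wchars,
                 exons = exons, introns = introns,
                 coverage = length(aligned_res) / np,
                 n_ref_introns = length(layout$intron_lens),
                 ref_intron_lens = layout$intron_lens,
                 n_residues = np),
            class = "spliced_alignment")
}

codon_at <- function(wchars, a0, tb) {
  ## translate the codon at absolute 0-based position a0 (vectorized)
  c1 <- wchars[a0 + 1L]; c2 <- wchars[a0 + 2L]; c3 <- wchars[a0 + 3L]
  aa <- tb$codon_to_aa[paste0(c1, c2, c3)]
  ifelse(is.na(aa), "X", aa)
}

#' @export
print.spliced_alignment <- function(x, ...) {
  cat(sprintf("<spliced_alignment> %s on %s%s:%d-%d, coverage %.2f, %d/%d exon(s) aligned\n",
              x$gene_id, x$chrom, x$strand, x$w_start, x$w_end, x$coverage,
              sum(vapply(x$exons, `[[`, TRUE, "present")), length(x$exons)))
  invisible(x)
}

## window-local (bio-oriented) coordinate -> forward genomic position of a
## footprint of `width` nt starting at 0-based a
a2fwd <- function(aln, a, width) {
  if (aln$strand == "+") aln$w_start + a else aln$w_end - a - width
}

#' Detect CDS disruptions in a spliced alignment
#'
#' Calls premature stops (an in-frame stop codon on the optimal alignment
#' path, strictly before the final codon and outside the near-terminal
#' tolerance), frameshifts (one event per frameshift transition), splice-site
#' mutations (an inferred intron whose donor is not GT or acceptor not AG;
#' GC donors are reported with a minor-site flag), and truncations (missing
#' terminal exons). Events are reported in forward genomic coordinates,
#' sorted by position.
#'
#' @param aln A [align_exon_guided()] result.
#' @param ref_model The reference [gene_model()].
#' @param near_terminal_tol Stops within this many codons of the annotated
#'   terminus are not counted (stop-codon drift tolerance).
#' @param min_intron Minimum inferred intron length (nt) to treat a block
#'   gap as an intron with splice sites.
#' @return Data frame: `gene_id`, `kind`, `chrom`, `pos`, `width`,
#'   `detail`, `strand`.
#' @export
detect_disruptions <- function(aln, ref_model, near_terminal_tol = 10L,
                               min_intron = 20L) {
  tb <- get_align_tables()
  ev <- list()
  add <- function(kind, pos, width, detail)
    ev[[length(ev) + 1L]] <<- data.frame(
      gene_id = aln$gene_id, kind = kind, chrom = aln$chrom,
      pos = as.integer(pos), width = as.integer(width),
      detail = as.character(detail), strand = aln$strand)
  np <- aln$n_residues
  for (b in aln$exons) {
    if (!b$present) next
    ops <- b$ops
    ## stops along the path (codon-emitting ops)
    co <- ops[ops$dna_len >= 3L, , drop = FALSE]
    if (nrow(co)) {
      a0 <- co$a + co$dna_len - 3L
      aa <- codon_at(aln$wseq, a0, tb)
      st <- which(aa == "*")
      for (s in st) {
        if (co$prot[s] >= np - near_terminal_tol) next  # near-terminal drift
        cod <- paste(aln$wseq[(a0[s] + 1L):(a0[s] + 3L)], collapse = "")
        add("premature_stop", a2fwd(aln, a0[s], 3L), 3L, cod)
      }
    }
    fs <- ops[ops$type == 2L, , drop = FALSE]
    for (k in seq_len(nrow(fs)))
      add("frameshift", a2fwd(aln, fs$a[k], fs$dna_len[k]), fs$dna_len[k],
          fs$dna_len[k] - 3L)
  }
  for (k in seq_len(nrow(aln$introns))) {
    intr <- aln$introns[k, ]
    if (intr$len < min_intron) next
    if (intr$donor != "GT") {
      flag <- if (intr$donor == "GC") ";minor_site" else ""
      add("splice_site", a2fwd(aln, intr$a_start, 2L), 2L,
          paste0(intr$donor, flag))
    }
    if (intr$acceptor != "AG")
      add("splice_site", a2fwd(aln, intr$a_end - 2L, 2L), 2L, intr$acceptor)
  }
  present <- vapply(aln$exons, `[[`, TRUE, "present")
  if (any(present)) {
    lead <- which(cumsum(present) == 0L)
    trail <- which(rev(cumsum(rev(present))) == 0L)
    first_b <- aln$exons[[min(which(present))]]
    last_b <- aln$exons[[max(which(present))]]
    if (length(lead))
      add("truncation", a2fwd(aln, first_b$a0, 1L), 1L,
          sprintf("missing_5prime_exons:%d", length(lead)))
    if (length(trail))
      add("truncation", a2fwd(aln, last_b$a1 - 1L, 1L), 1L,
          sprintf("missing_3prime_exons:%d", length(trail)))
  } else {
    add("truncation", a2fwd(aln, 0L, 1L), 1L, "no_exon_aligned")
  }
  out <- if (length(ev)) do.call(rbind, ev)
    else data.frame(gene_id = character(), kind = character(),
                    chrom = character(), pos = integer(), width = integer(),
                    detail = character(), strand = character())
  out[order(out$pos), , drop = FALSE]
}

#' Gene-structure similarity of an alignment to its reference model
#'
#' `score = 0.5 x protein coverage + 0.5 x fraction of reference introns
#' recovered within +/- `intron_tol` bp of their reference length`. A gene
#' with no reference introns scores its coverage on the intron term as well
#' (term = 1) provided anything aligned at all. Intronless alignments of
#' multi-exon genes (the retrotransposition signature) fail the default
#' threshold by construction.
#'
#' @param aln A [align_exon_guided()] result.
#' @param ref_model Reference [gene_model()].
#' @param threshold Pass threshold (default 0.6).
#' @param intron_tol Intron-length recovery tolerance (bp).
#' @return `list(score, pass, coverage, intron_recovery, intronless,
#'   borderline)`.
#' @export
gene_structure_similarity <- function(aln, ref_model, threshold = 0.6,
                                      intron_tol = 10L) {
  cov <- aln$coverage
  k <- aln$n_ref_introns
  if (cov == 0) {
    return(list(score = 0, pass = FALSE, coverage = 0, intron_recovery = 0,
                intronless = FALSE, borderline = FALSE))
  }
  real_introns <- aln$introns[aln$introns$len >= 20L, , drop = FALSE]
  if (k == 0L) {
    irec <- 1
  } else {
    rec <- 0L
    for (j in seq_len(nrow(real_introns))) {
      i <- real_introns$index[j]
      if (abs(real_introns$len[j] - aln$ref_intron_lens[i]) <= intron_tol)
        rec <- rec + 1L
    }
    irec <- rec / k
  }
  score <- 0.5 * cov + 0.5 * irec
  list(score = score, pass = score >= threshold, coverage = cov,
       intron_recovery = irec,
       intronless = k > 0L && nrow(real_introns) == 0L,
       borderline = abs(score - threshold) < 0.05)
}
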