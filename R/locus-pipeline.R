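## Locus-level filter cascade: clustering of redundant candidate
## alignments, annotation-evidence filtering, tandem-family flagging,
## synteny verification, the polymorphic-locus contradiction check, and the
## end-to-end pipeline with a flowchart-style report.

#' Default pipeline configuration
#'
#' All tunable thresholds of the discovery pipeline in one place.
#' @param ... Overrides for individual entries.
#' @return Named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed_len = 5L,           # aa k-mer seed length for translated mapping
    min_coverage = 0.5,      # chained-coverage mappability threshold
    gap_bound = 50000L,      # max genomic gap between chained seeds (nt)
    gap_open = 11, gap_extend = 1,
    frameshift_penalty = 20, stop_score = -4,
    structure_threshold = 0.6,
    intron_tol = 10L,        # intron-length recovery tolerance (bp)
    near_terminal_tol = 10L, # stop-codon drift tolerance (codons)
    min_intron = 20L,        # minimum inferred intron length (nt)
    min_family_size = 3L,    # tandem-family flag: members required
    max_cluster_span = 100000L,  # tandem-family flag: clustering span (bp)
    synteny_k = 3L,          # flanking genes checked per side
    window_pad = 30L)        # window padding before alignment (nt)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Cluster candidate alignments into pseudogenic loci
#'
#' Single-linkage merge of same-chromosome, same-strand candidate intervals
#' overlapping by >= 1 bp; a locus lists every contributing reference gene,
#' removing the redundancy created by duplicated annotations and close
#' protein-family members mapping to the same region.
#'
#' @param candidates Data frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open).
#' @return Data frame of loci: `chrom`, `strand`, `start`, `end`, `genes`
#'   (comma-separated contributing gene ids), `n_members`, plus a
#'   `members` list-column of candidate row indices.
#' @export
cluster_loci <- function(candidates) {
  if (!nrow(candidates)) {
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      genes = character(), n_members = integer()))
  }
  ord <- order(candidates$chrom, candidates$strand, candidates$start)
  cc <- candidates[ord, , drop = FALSE]
  loci <- list(); cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    loci[[length(loci) + 1L]] <<- cur
  }
  for (r in seq_len(nrow(cc))) {
    row <- cc[r, ]
    if (!is.null(cur) && row$chrom == cur$chrom && row$strand == cur$strand &&
        row$start < cur$end) {
      cur$end <- max(cur$end, row$end)
      cur$gene_ids <- c(cur$gene_ids, row$gene_id)
      cur$members <- c(cur$members, ord[r])
    } else {
      flush()
      cur <- list(chrom = row$chrom, strand = row$strand, start = row$start,
                  end = row$end, gene_ids = row$gene_id, members = ord[r])
    }
  }
  flush()
  out <- data.frame(
    chrom = vapply(loci, `[[`, "", "chrom"),
    strand = vapply(loci, `[[`, "", "strand"),
    start = vapply(loci, function(l) as.integer(l$start), 0L),
    end = vapply(loci, function(l) as.integer(l$end), 0L),
    genes = vapply(loci, function(l) paste(sort(unique(l$gene_ids)),
                                           collapse = ","), ""),
    n_members = vapply(loci, function(l) length(l$members), 0L))
  out$members <- lapply(loci, `[[`, "members")
  out
}

evidence_rank <- function(cls) match(cls, EVIDENCE_CLASSES)

#' Filter loci by annotation evidence class
#'
#' A locus inherits the best evidence class among its contributing reference
#' genes (`NAMED_GENE` > `SPLICED_CDNA` > `UNSPLICED_CDNA` > `PREDICTED`);
#' loci supported only by unspliced transcribed sequences or
#' modeled/predicted genes are discarded with a logged reason, since
#' unitary pseudogenes are unlikely to be intronless and predicted models
#' cannot easily be verified.
#'
#' @param loci [cluster_loci()] output.
#' @param models Named list of reference [gene_model()]s.
#' @return `list(kept, discarded)`; `discarded` has a `reason` column.
#' @export
apply_evidence_filter <- function(loci, models) {
  cls <- vapply(seq_len(nrow(loci)), function(i) {
    ids <- strsplit(loci$genes[i], ",", fixed = TRUE)[[1L]]
    ranks <- evidence_rank(vapply(models[ids], `[[`, "", "evidence_class"))
    EVIDENCE_CLASSES[min(ranks)]
  }, "")
  loci$evidence_class <- cls
  drop <- cls %in% c("UNSPLICED_CDNA", "PREDICTED")
  discarded <- loci[drop, , drop = FALSE]
  discarded$reason <- ifelse(discarded$evidence_class == "PREDICTED",
                             "modeled/predicted", "unspliced transcribed sequence")
  list(kept = loci[!drop, , drop = FALSE], discarded = discarded)
}

#' Flag loci from tandem gene families
#'
#' Tandem families (olfactory/vomeronasal-receptor-like clusters) undergo
#' copy-number change and local rearrangement that make ortholog/paralog
#' assignment — and hence 'unitary' status — ambiguous, so their loci are
#' reported separately.
#'
#' @param locus One row of a loci data frame.
#' @param ref_models Named list of reference gene models.
#' @param paralog_families Data frame `gene_id`, `family_id`.
#' @param min_family_size Members required for a family to count (>= 1).
#' @param max_cluster_span Two members within this many bp in the reference
#'   genome make the family tandem.
#' @return `TRUE` if the locus belongs to a tandem family.
#' @export
flag_tandem_family <- function(locus, ref_models, paralog_families,
                               min_family_size = 3L, max_cluster_span = 100000L) {
  if (min_family_size < 1L) stop("min_family_size must be >= 1")
  ids <- strsplit(locus$genes, ",", fixed = TRUE)[[1L]]
  for (g in ids) {
    fam <- paralog_families$family_id[paralog_families$gene_id == g]
    if (!length(fam)) next
    members <- paralog_families$gene_id[paralog_families$family_id == fam[1L]]
    members <- intersect(members, names(ref_models))
    if (length(members) < min_family_size) next
    if (min_family_size == 1L) return(TRUE)
    starts <- sort(vapply(ref_models[members], function(m)
      m$exons[1L, "start"], 0L))
    if (length(starts) >= 2L && any(diff(starts) <= max_cluster_span))
      return(TRUE)
  }
  FALSE
}

#' Check conservation of synteny around a locus
#'
#' The positional-orthology check: on each side of the locus, at least one
#' of the `k` nearest reference genes flanking the disabled gene must have
#' its query ortholog on the same chromosome and the same relative side of
#' the locus. A locus at a contig edge passes vacuously on the empty side.
#'
#' @param locus One row of a loci data frame.
#' @param ref_gene_id The reference gene anchoring the locus.
#' @param ref_models Named list of reference gene models.
#' @param orthologs [ortholog_table()].
#' @param query_genes Data frame of query gene coordinates (`query_id`,
#'   `ref_id`, `chrom`, `start`, `end`).
#' @param k Flanking genes examined per side (>= 1).
#' @return `TRUE` if synteny is conserved.
#' @export
check_synteny <- function(locus, ref_gene_id, ref_models, orthologs,
                          query_genes, k = 3L) {
  if (k < 1L) stop("synteny check requires k >= 1 flanking genes")
  anchor <- ref_models[[ref_gene_id]]
  if (is.null(anchor)) stop("unknown reference gene: ", ref_gene_id)
  same <- Filter(function(m) m$chrom == anchor$chrom && m$gene_id != ref_gene_id,
                 ref_models)
  starts <- vapply(same, function(m) m$exons[1L, "start"], 0L)
  ## only ortholog-bearing neighbours are informative markers for synteny
  starts <- starts[names(starts) %in% orthologs$pairs$ref_id]
  a0 <- anchor$exons[1L, "start"]
  left <- names(sort(starts[starts < a0], decreasing = TRUE))
  right <- names(sort(starts[starts > a0]))
  side_ok <- function(neigh, want_left) {
    if (!length(neigh)) return(NA)   # contig edge: vacuous pass
    for (g in head(neigh, k)) {
      qid <- orthologs$pairs$query_id[orthologs$pairs$ref_id == g]
      q <- query_genes[query_genes$query_id == qid[1L], ]
      if (!nrow(q) || q$chrom != locus$chrom) next
      if (want_left && q$end <= locus$start) return(TRUE)
      if (!want_left && q$start >= locus$end) return(TRUE)
    }
    FALSE
  }
  l <- side_ok(left, TRUE); r <- side_ok(right, FALSE)
  isTRUE(l %in% c(TRUE, NA)) && isTRUE(r %in% c(TRUE, NA)) &&
    !(is.na(l) && is.na(r) && FALSE)
}

#' Detect a polymorphic (segregating) pseudogenic locus
#'
#' A locus is polymorphic when at least one transcript maps across a
#' disruption position and carries the non-disrupted, functional state at
#' every disruption it spans — the genomic DNA and the mRNA coming from
#' different individuals. Splice-site disruptions are intronic and cannot
#' be spanned by mRNA; unmappable transcripts are ignored with a warning.
#'
#' @param aln The locus's best [align_exon_guided()] result.
#' @param events Its [detect_disruptions()] table.
#' @param transcripts `DNAStringSet` of locus-associated mRNA sequences.
#' @param min_identity Minimum transcript-to-locus alignment identity.
#' @return `TRUE` (polymorphic) or `FALSE` (fixed).
#' @export
detect_polymorphic <- function(aln, events, transcripts,
                               min_identity = 0.8) {
  if (is.null(transcripts) || !length(transcripts)) return(FALSE)
  ## spliced query CDS from aligned exon blocks, with a -> spliced map
  blocks <- Filter(function(b) b$present, aln$exons)
  if (!length(blocks)) return(FALSE)
  amap <- integer(0)
  for (b in blocks) amap <- c(amap, (b$a0 + 1L):b$a1)   # 1-based a positions
  qcds <- paste(aln$wseq[amap], collapse = "")
  a2sp <- function(a) match(a + 1L, amap)               # 0-based a -> spliced pos
  ev <- events[events$kind %in% c("premature_stop", "frameshift"), , drop = FALSE]
  if (!nrow(ev)) return(FALSE)
  ## event positions back to window-local (bio) coordinates
  ev$a <- if (aln$strand == "+") ev$pos - aln$w_start
          else aln$w_end - ev$pos - ev$width
  for (t in seq_along(transcripts)) {
    tx <- as.character(transcripts[[t]])
    pa <- Biostrings::pairwiseAlignment(tx, qcds, type = "overlap",
                                        gapOpening = 10, gapExtension = 0.5)
    p <- suppressWarnings(Biostrings::pid(pa))
    if (is.na(p) || p / 100 < min_identity) {
      warning("transcript ", names(transcripts)[t],
              " does not map to the locus; ignored")
      next
    }
    ps <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    ss <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    sub_start <- Biostrings::start(Biostrings::subject(pa))
    ## subject coordinate per alignment column
    scoord <- sub_start - 1L + cumsum(ss != "-")
    spanned <- 0L; functional <- TRUE
    for (e in seq_len(nrow(ev))) {
      sp <- a2sp(ev$a[e])
      if (is.na(sp)) next
      cols <- which(scoord >= sp & scoord <= sp + max(ev$width[e] - 1L, 2L) &
                    ss != "-")
      if (!length(cols) || min(scoord[ss != "-"]) > sp - 1L ||
          max(scoord[ss != "-"]) < sp + 2L) next
      spanned <- spanned + 1L
      if (ev$kind[e] == "premature_stop") {
        codon_cols <- which(scoord %in% sp:(sp + 2L) & ss != "-")
        codon <- paste(ps[codon_cols][ps[codon_cols] != "-"], collapse = "")
        if (nchar(codon) == 3L && codon %in% STOP_CODONS) functional <- FALSE
      } else {
        shift <- as.integer(ev$detail[e])
        win <- which(scoord >= sp - 9L & scoord <= sp + 9L)
        net <- sum(ps[win] != "-") - sum(ss[win] != "-")
        if (net %% 3L != (-shift) %% 3L || net == 0L) functional <- FALSE
      }
    }
    if (spanned > 0L && functional) return(TRUE)
  }
  FALSE
}
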