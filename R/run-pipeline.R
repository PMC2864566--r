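## End-to-end unitary-pseudogene discovery: ortholog screen -> mapping ->
## exon-guided alignment and disruption detection -> locus clustering ->
## evidence / family / synteny filters -> polymorphic-vs-fixed call.

#' Run the unitary-pseudogene discovery pipeline
#'
#' Executes the full cascade on in-memory inputs and returns a report in
#' which every unmatched reference protein is accounted for in exactly one
#' bin: `unalignable` (reference-lineage gains or outright deletions),
#' `structure_fail` (mappings unlike the reference gene structure —
#' intronless retrotransposed copies fall here), `no_disruption`,
#' `evidence_removed`, `tandem_family`, `synteny_rejected`,
#' `fixed_unitary`, or `polymorphic`.
#'
#' @param ref Reference `geneset` (models + genome).
#' @param query_genome `DNAStringSet` query genome.
#' @param orthologs [ortholog_table()].
#' @param query_genes Query gene coordinates for the synteny check (data
#'   frame `query_id`, `ref_id`, `chrom`, `start`, `end`), or `NULL` to
#'   skip synteny (all loci pass vacuously, logged).
#' @param paralog_families Data frame `gene_id`, `family_id`, or `NULL`
#'   (every gene its own singleton family).
#' @param transcripts `DNAStringSet` of locus transcripts (or `NULL`).
#' @param config [pipeline_config()].
#' @param verbose Emit stage-tagged progress lines to standard error.
#' @return Object of class `pipeline_report`.
#' @export
run_pipeline <- function(ref, query_genome, orthologs, query_genes = NULL,
                         paralog_families = NULL, transcripts = NULL,
                         config = pipeline_config(), verbose = TRUE) {
  say <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  models <- ref$models
  if (is.null(paralog_families))
    paralog_families <- data.frame(gene_id = names(models),
                                   family_id = names(models))

  unmatched <- find_unmatched_reference_proteins(orthologs)
  say("screen", "%d reference proteins without query orthologs", length(unmatched))
  index <- build_translated_index(query_genome, config$seed_len)

  glen <- setNames(Biostrings::width(query_genome), names(query_genome))
  bins <- setNames(rep(NA_character_, length(unmatched)), unmatched)
  cands <- list()   # per-protein alignment payloads
  cand_rows <- list()
  for (g in unmatched) {
    m <- models[[g]]
    if (is.null(m)) stop("unmatched protein with no gene model: ", g)
    w <- map_protein_to_genome(m$protein, query_genome,
                               min_coverage = config$min_coverage,
                               gap_bound = config$gap_bound, index = index)
    if (classify_mappability(w, config$min_coverage) == "UNALIGNABLE") {
      bins[g] <- "unalignable"
      next
    }
    w1 <- w[1L, ]
    w1$start <- max(0L, w1$start - config$window_pad)
    w1$end <- min(glen[[w1$chrom]], w1$end + config$window_pad)
    aln <- align_exon_guided(m, w1, query_genome,
                             gap_open = config$gap_open,
                             gap_extend = config$gap_extend,
                             frameshift_penalty = config$frameshift_penalty,
                             stop_score = config$stop_score)
    struct <- gene_structure_similarity(aln, m,
                                        threshold = config$structure_threshold,
                                        intron_tol = config$intron_tol)
    if (!struct$pass) {
      bins[g] <- "structure_fail"
      cands[[g]] <- list(aln = aln, struct = struct, events = NULL)
      next
    }
    events <- detect_disruptions(aln, m,
                                 near_terminal_tol = config$near_terminal_tol,
                                 min_intron = config$min_intron)
    disruptive <- events[events$kind %in%
                           c("premature_stop", "frameshift", "splice_site"), ,
                         drop = FALSE]
    if (!nrow(disruptive)) {
      bins[g] <- "no_disruption"
      next
    }
    cands[[g]] <- list(aln = aln, struct = struct, events = events)
    cand_rows[[g]] <- data.frame(gene_id = g, chrom = aln$chrom,
                                 strand = aln$strand, start = aln$w_start,
                                 end = aln$w_end)
  }
  say("map", "unalignable %d, structure-fail %d, no-disruption %d, with-disruption %d",
      sum(bins == "unalignable", na.rm = TRUE),
      sum(bins == "structure_fail", na.rm = TRUE),
      sum(bins == "no_disruption", na.rm = TRUE), length(cand_rows))

  cand_df <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame(gene_id = character(), chrom = character(), strand = character(),
               start = integer(), end = integer())
  loci <- cluster_loci(cand_df)
  say("cluster", "%d candidate alignments -> %d loci", nrow(cand_df), nrow(loci))

  locus_rows <- list()
  all_events <- list()
  if (nrow(loci)) {
    evf <- apply_evidence_filter(loci, models)
    kept <- evf$kept; disc <- evf$discarded
    for (i in seq_len(nrow(disc)))
      say("evidence", "locus %s:%d-%d removed (%s)", disc$chrom[i],
          disc$start[i], disc$end[i], disc$reason[i])
    process_locus <- function(locus, status, reason = "") {
      ids <- strsplit(locus$genes, ",", fixed = TRUE)[[1L]]
      ranks <- evidence_rank(vapply(models[ids], `[[`, "", "evidence_class"))
      anchor <- ids[which.min(ranks)]
      pay <- cands[[anchor]]
      ev <- pay$events
      if (!is.null(ev) && nrow(ev))
        all_events[[length(all_events) + 1L]] <<- ev
      if (status == "pending") {
        fam <- flag_tandem_family(locus, models, paralog_families,
                                  min_family_size = config$min_family_size,
                                  max_cluster_span = config$max_cluster_span)
        if (fam) {
          status <- "tandem_family"
        } else if (!is.null(query_genes) &&
                   !check_synteny(locus, anchor, models, orthologs,
                                  query_genes, k = config$synteny_k)) {
          status <- "synteny_rejected"
        } else {
          poly <- suppressWarnings(detect_polymorphic(pay$aln, ev, transcripts))
          status <- if (poly) "polymorphic" else "fixed_unitary"
        }
      }
      for (g in ids) bins[g] <<- status
      data.frame(chrom = locus$chrom, strand = locus$strand,
                 start = locus$start, end = locus$end, genes = locus$genes,
                 anchor = anchor, evidence_class = locus$evidence_class,
                 n_disruptions = if (is.null(ev)) 0L else
                   sum(ev$kind %in% c("premature_stop", "frameshift", "splice_site")),
                 intronless = isTRUE(pay$struct$intronless),
                 structure_score = pay$struct$score,
                 borderline = isTRUE(pay$struct$borderline),
                 status = status, reason = reason)
    }
    for (i in seq_len(nrow(disc)))
      locus_rows[[length(locus_rows) + 1L]] <-
        process_locus(disc[i, ], "evidence_removed", disc$reason[i])
    for (i in seq_len(nrow(kept)))
      locus_rows[[length(locus_rows) + 1L]] <- process_locus(kept[i, ], "pending")
  }
  locus_tab <- if (length(locus_rows)) do.call(rbind, locus_rows) else
    data.frame(status = character())
  events_tab <- if (length(all_events)) do.call(rbind, all_events) else
    data.frame(gene_id = character(), kind = character(), chrom = character(),
               pos = integer(), width = integer(), detail = character(),
               strand = character())
  stage_counts <- c(
    unmatched_proteins = length(unmatched),
    unalignable = sum(bins == "unalignable", na.rm = TRUE),
    structure_fail = sum(bins == "structure_fail", na.rm = TRUE),
    no_disruption = sum(bins == "no_disruption", na.rm = TRUE),
    candidates_with_disruption = nrow(cand_df),
    loci = nrow(loci),
    evidence_removed = sum(locus_tab$status == "evidence_removed"),
    tandem_family = sum(locus_tab$status == "tandem_family"),
    synteny_rejected = sum(locus_tab$status == "synteny_rejected"),
    fixed_unitary = sum(locus_tab$status == "fixed_unitary"),
    polymorphic = sum(locus_tab$status == "polymorphic"))
  say("report", "fixed unitary %d, polymorphic %d",
      stage_counts[["fixed_unitary"]], stage_counts[["polymorphic"]])
  structure(list(counts = stage_counts, bins = bins, loci = locus_tab,
                 events = events_tab, config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (n in names(x$counts)) cat(sprintf("  %-28s %d\n", n, x$counts[[n]]))
  invisible(x)
}

#' Compare a pipeline report against a planted truth table
#'
#' Maps report bins onto planted fates (`unalignable` covers both
#' reference-lineage gains and deleted loci, which are indistinguishable by
#' construction; `structure_fail` of an intronless mapping marks a processed
#' copy; `tandem_family`, `fixed_unitary`/`polymorphic` map to their fates)
#' and computes per-fate precision and recall plus a confusion table.
#'
#' @param report A [run_pipeline()] result.
#' @param truth The `truth` element of [evolve_query_genome()] output.
#' @return `list(confusion, per_fate)`.
#' @export
score_against_truth <- function(report, truth) {
  tg <- truth$genes
  pred <- setNames(rep("intact", nrow(tg)), tg$gene_id)
  for (g in names(report$bins)) {
    b <- report$bins[[g]]
    pred[g] <- switch(b,
      unalignable = "ABSENT_FROM_QUERY",
      structure_fail = "PROCESSED_COPY",
      tandem_family = "FAMILY_PSEUDO",
      fixed_unitary = "UNITARY_PSEUDO",
      polymorphic = "UNITARY_PSEUDO",
      b)
  }
  fate <- ifelse(tg$fate %in% c("GAIN_IN_REF", "DELETED_IN_QUERY"),
                 "ABSENT_FROM_QUERY", tg$fate)
  fate[fate == "INTACT_ORTHOLOG"] <- "intact"
  confusion <- table(truth = fate, predicted = pred[tg$gene_id])
  per_fate <- do.call(rbind, lapply(
    setdiff(unique(fate), "intact"), function(f) {
      tp <- sum(fate == f & pred[tg$gene_id] == f)
      fp <- sum(fate != f & pred[tg$gene_id] == f)
      fn <- sum(fate == f & pred[tg$gene_id] != f)
      data.frame(fate = f, tp = tp, fp = fp, fn = fn,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
    }))
  list(confusion = confusion, per_fate = per_fate)
}
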