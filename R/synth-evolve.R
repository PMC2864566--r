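## Evolving a query genome from a reference gene set, planting gene fates
## with exact recorded truth.

#' Evolve a query genome with planted gene fates
#'
#' Derives a query-species genome from a reference gene set. Each reference
#' gene is assigned a fate: `INTACT_ORTHOLOG` (kept, with background
#' divergence), `UNITARY_PSEUDO` (disabled in place by planted disruptions),
#' `FAMILY_PSEUDO` (the reference gains >= 2 tandem paralogs and the focal
#' gene's query copy is disabled), `PROCESSED_COPY` (the locus is lost and an
#' intronless, disabled CDS copy is inserted elsewhere), `DELETED_IN_QUERY`
#' (locus removed), or `GAIN_IN_REF` (reference-lineage gene with no query
#' homolog; the locus is likewise absent from the query). Background
#' divergence is substitution-only and purifying-safe (it never creates an
#' in-frame stop nor touches a splice dinucleotide), so planted disruptions
#' are the only ORF-breaking events.
#'
#' Because tandem paralog families must exist in the *reference* genome for
#' the family filter to act on, the function returns a rebuilt reference
#' gene set (with paralogs inserted) alongside the query genome.
#'
#' @param ref A `geneset` from [simulate_reference_geneset()].
#' @param fates Named integer vector of requested counts for the special
#'   fates (`UNITARY_PSEUDO`, `FAMILY_PSEUDO`, `PROCESSED_COPY`,
#'   `DELETED_IN_QUERY`, `GAIN_IN_REF`); remaining genes stay intact.
#' @param neutral_sub_rate Background substitutions per site.
#' @param seed Integer seed.
#' @param n_polymorphic Number of unitary pseudogenes that also get a
#'   functional (disruption-free) transcript, emulating a segregating locus.
#' @param unitary_kinds Optional character vector of disruption kinds for the
#'   unitary genes (recycled); default cycles premature_stop / frameshift /
#'   splice_site (premature_stop substituted automatically on single-exon
#'   genes). Requesting `splice_site` explicitly for a single-exon gene is an
#'   error.
#' @param frameshift_lens Signed indel lengths for frameshift plants
#'   (negative = deletion), cycled; all must be non-multiples of 3.
#' @param paralog_divergence Per-site divergence of inserted tandem paralogs.
#' @param tandem_spacer Spacer between tandem family members (nt).
#' @param query_species Query species label.
#' @return A list of class `evolved_genomes`: `ref` (augmented geneset),
#'   `query_genome` (`DNAStringSet`), `query_genes` (coordinates of intact
#'   query genes), `orthologs` ([ortholog_table()]), `paralog_families`
#'   (data frame `gene_id`, `family_id`), `transcripts` (`DNAStringSet`),
#'   and `truth` (`list(genes, disruptions)`).
#' @export
evolve_query_genome <- function(ref,
                                fates = c(UNITARY_PSEUDO = 0L),
                                neutral_sub_rate = 0.02,
                                seed = 1L,
                                n_polymorphic = 0L,
                                unitary_kinds = NULL,
                                frameshift_lens = c(-1L, -2L, -8L, 1L),
                                paralog_divergence = 0.05,
                                tandem_spacer = 200L,
                                query_species = "query") {
  stopifnot(inherits(ref, "geneset"))
  all_fates <- setNames(rep(0L, length(GENE_FATES)), GENE_FATES)
  all_fates[names(fates)] <- as.integer(fates)
  if (any(is.na(all_fates)) || any(all_fates < 0)) stop("invalid fate counts")
  if (any(abs(frameshift_lens) %% 3L == 0L))
    stop("frameshift lengths must not be multiples of 3")
  set.seed(as.integer(seed))

  ord <- order(vapply(ref$models, function(m) m$exons[1L, "start"], 0L))
  models <- ref$models[ord]
  chrom <- models[[1L]]$chrom
  n_special <- sum(all_fates[setdiff(GENE_FATES, "INTACT_ORTHOLOG")])
  if (n_special > length(models)) stop("requested fate counts exceed n_genes")

  ## eligibility: special fates only on well-annotated genes; processed
  ## copies only of multi-exon genes (intronless exclusion is otherwise
  ## undefined)
  ev <- vapply(models, function(m) m$evidence_class, "")
  nex <- vapply(models, function(m) nrow(m$exons), 0L)
  well <- names(models)[ev %in% c("NAMED_GENE", "SPLICED_CDNA")]
  multi <- names(models)[nex > 1L]
  fate_of <- setNames(rep("INTACT_ORTHOLOG", length(models)), names(models))
  pool <- sample(well)
  take <- function(n, from = pool) {
    picked <- intersect(pool, from)[seq_len(n)]
    if (anyNA(picked)) stop("not enough eligible genes for requested fates")
    pool <<- setdiff(pool, picked)
    picked
  }
  g_unitary <- take(all_fates[["UNITARY_PSEUDO"]])
  g_family <- take(all_fates[["FAMILY_PSEUDO"]])
  g_processed <- take(all_fates[["PROCESSED_COPY"]], multi)
  g_deleted <- take(all_fates[["DELETED_IN_QUERY"]])
  g_gain <- take(all_fates[["GAIN_IN_REF"]])
  fate_of[g_unitary] <- "UNITARY_PSEUDO"
  fate_of[g_family] <- "FAMILY_PSEUDO"
  fate_of[g_processed] <- "PROCESSED_COPY"
  fate_of[g_deleted] <- "DELETED_IN_QUERY"
  fate_of[g_gain] <- "GAIN_IN_REF"

  ## disruption kinds for in-situ disabled genes (unitary + family focal)
  default_cycle <- c("premature_stop", "frameshift", "splice_site")
  kind_of <- character()
  disabled <- c(g_unitary, g_family)
  for (i in seq_along(disabled)) {
    g <- disabled[i]
    k <- if (!is.null(unitary_kinds) && i <= length(g_unitary)) {
      unitary_kinds[(i - 1L) %% length(unitary_kinds) + 1L]
    } else default_cycle[(i - 1L) %% 3L + 1L]
    if (k %in% c("splice_site", "splice_donor", "splice_acceptor") &&
        nex[[g]] == 1L) {
      if (!is.null(unitary_kinds) && i <= length(g_unitary))
        stop(sprintf("splice_site disruption requested for single-exon gene %s", g))
      k <- "premature_stop"
    }
    kind_of[g] <- k
  }
  fs_i <- 0L
  next_fs_len <- function() {
    fs_i <<- fs_i + 1L
    frameshift_lens[(fs_i - 1L) %% length(frameshift_lens) + 1L]
  }

  ## ordered construction items: spacers + genes (+ inserted paralogs)
  chrom_seq <- strsplit(as.character(ref$genome[[chrom]]), "")[[1L]]
  items <- list()
  pos <- 0L
  fam_tab <- data.frame(gene_id = character(), family_id = character())
  for (g in names(models)) {
    m <- models[[g]]
    g0 <- m$exons[1L, "start"]; g1 <- m$exons[nrow(m$exons), "end"]
    items[[length(items) + 1L]] <- list(type = "spacer",
                                        seq = chrom_seq[seq_len(g0 - pos) + pos])
    layout <- gene_layout(m)
    bio <- chrom_seq[(g0 + 1L):g1]
    if (m$strand == "-") bio <- revcomp_chars(bio)
    items[[length(items) + 1L]] <- list(type = "gene", id = g, layout = layout,
                                        bio = bio, evidence = m$evidence_class)
    fam_tab <- rbind(fam_tab, data.frame(gene_id = g, family_id = g))
    if (fate_of[[g]] == "FAMILY_PSEUDO") {
      for (p in 1:2) {
        pid <- sprintf("%s_p%d", g, p)
        pbio <- mutate_bio_seq(bio, layout, paralog_divergence)
        items[[length(items) + 1L]] <- list(type = "spacer",
                                            seq = rand_dna_chars(tandem_spacer))
        items[[length(items) + 1L]] <- list(type = "gene", id = pid,
                                            layout = layout, bio = pbio,
                                            evidence = "NAMED_GENE")
        fate_of[pid] <- "INTACT_ORTHOLOG"
        fam_tab <- rbind(fam_tab, data.frame(gene_id = pid, family_id = g))
      }
    }
    pos <- g1
  }
  items[[length(items) + 1L]] <- list(type = "spacer",
                                      seq = chrom_seq[seq_len(length(chrom_seq) - pos) + pos])

  ## rebuild reference with paralogs inserted
  ref_pieces <- character(); ref_models <- list(); roff <- 0L
  for (it in items) {
    if (it$type == "spacer") {
      ref_pieces <- c(ref_pieces, paste(it$seq, collapse = ""))
      roff <- roff + length(it$seq)
    } else {
      L <- length(it$bio)
      gseq <- if (it$layout$strand == "-") revcomp_chars(it$bio) else it$bio
      ref_pieces <- c(ref_pieces, paste(gseq, collapse = ""))
      ref_models[[it$id]] <- gene_model(it$id, ref$species, chrom,
                                        it$layout$strand,
                                        layout_to_exons(it$layout, roff, L),
                                        evidence_class = it$evidence)
      roff <- roff + L
    }
  }
  ref_genome <- Biostrings::DNAStringSet(setNames(paste(ref_pieces, collapse = ""), chrom))
  ref_models <- lapply(ref_models, function(m) {
    m$protein <- translate_model(m, ref_genome); m
  })
  new_ref <- structure(list(models = ref_models, genome = ref_genome,
                            species = ref$species), class = "geneset")

  ## choose polymorphic unitary genes and processed-copy insertion sites
  g_poly <- head(g_unitary, n_polymorphic)
  spacer_idx <- which(vapply(items, function(it) it$type == "spacer", TRUE))
  insert_at <- setNames(sample(spacer_idx, length(g_processed), replace = TRUE),
                        g_processed)
  processed_seq <- list()  # filled on first pass over gene fates

  ## build the query chromosome
  q_pieces <- character(); qoff <- 0L
  q_genes <- list(); pairs <- list(); transcripts <- list()
  dis_rows <- list(); poly_flag <- setNames(rep(FALSE, length(fate_of)), names(fate_of))
  truth_rows <- list()
  add_dis <- function(gene, events, q0, L2, strand) {
    if (!nrow(events)) return()
    qpos <- if (strand == "+") q0 + events$bio_pos
            else q0 + L2 - events$bio_pos - events$width
    dis_rows[[length(dis_rows) + 1L]] <<- data.frame(
      gene_id = gene, kind = events$kind, chrom = chrom, pos = qpos,
      width = events$width, detail = events$detail, strand = strand)
  }
  ## precompute processed-copy payloads so insertion can happen at spacers
  for (g in g_processed) {
    it <- items[[which(vapply(items, function(x)
      x$type == "gene" && x$id == g, TRUE))]]
    bio2 <- mutate_bio_seq(it$bio, it$layout, neutral_sub_rate)
    exb <- layout_exon_bio(it$layout)
    cds <- unlist(lapply(seq_len(nrow(exb)), function(i)
      bio2[(exb[i, "start"] + 1L):exb[i, "end"]]))
    pl <- plant_premature_stop(cds, intronless_layout(length(cds)))
    processed_seq[[g]] <- pl
  }

  for (ii in seq_along(items)) {
    it <- items[[ii]]
    if (it$type == "spacer") {
      sp <- it$seq
      if (neutral_sub_rate > 0 && length(sp)) {
        hit <- which(runif(length(sp)) < neutral_sub_rate)
        for (p in hit) sp[p] <- sample(setdiff(c("A", "C", "G", "T"), sp[p]), 1L)
      }
      q_pieces <- c(q_pieces, paste(sp, collapse = ""))
      qoff <- qoff + length(sp)
      for (g in names(insert_at)[insert_at == ii]) {
        pl <- processed_seq[[g]]
        strand <- sample(c("+", "-"), 1L)
        seq <- if (strand == "-") revcomp_chars(pl$bio) else pl$bio
        add_dis(g, pl$events, qoff, length(pl$bio), strand)
        q_pieces <- c(q_pieces, paste(seq, collapse = ""))
        qoff <- qoff + length(pl$bio)
      }
      next
    }
    g <- it$id; fate <- fate_of[[g]]
    truth_rows[[length(truth_rows) + 1L]] <-
      data.frame(gene_id = g, fate = fate, n_exons = length(it$layout$exon_cod))
    if (fate %in% c("DELETED_IN_QUERY", "GAIN_IN_REF", "PROCESSED_COPY")) next
    bio2 <- mutate_bio_seq(it$bio, it$layout, neutral_sub_rate)
    if (fate %in% c("UNITARY_PSEUDO", "FAMILY_PSEUDO")) {
      if (g %in% g_poly) {
        exb <- layout_exon_bio(it$layout)
        tx <- unlist(lapply(seq_len(nrow(exb)), function(i)
          bio2[(exb[i, "start"] + 1L):exb[i, "end"]]))
        transcripts[[paste0("tx_", g)]] <- paste(tx, collapse = "")
        poly_flag[g] <- TRUE
      }
      pl <- plant_disruption(bio2, it$layout, kind_of[[g]], next_fs_len,
                             ref_bio = it$bio)
      bio2 <- pl$bio
      add_dis(g, pl$events, qoff, length(bio2), it$layout$strand)
    }
    seq <- if (it$layout$strand == "-") revcomp_chars(bio2) else bio2
    if (fate == "INTACT_ORTHOLOG") {
      qid <- paste0("q_", g)
      q_genes[[qid]] <- data.frame(query_id = qid, ref_id = g, chrom = chrom,
                                   start = qoff, end = qoff + length(bio2),
                                   strand = it$layout$strand)
      pairs[[qid]] <- data.frame(ref_id = g, query_id = qid, score = 1)
    }
    q_pieces <- c(q_pieces, paste(seq, collapse = ""))
    qoff <- qoff + length(bio2)
  }

  query_genome <- Biostrings::DNAStringSet(
    setNames(paste(q_pieces, collapse = ""), chrom))
  truth_genes <- do.call(rbind, truth_rows)
  truth_genes$polymorphic <- unname(poly_flag[truth_genes$gene_id])
  disruptions <- if (length(dis_rows)) do.call(rbind, dis_rows)
    else data.frame(gene_id = character(), kind = character(),
                    chrom = character(), pos = integer(), width = integer(),
                    detail = character(), strand = character())
  orth <- ortholog_table(do.call(rbind, c(pairs, list(NULL))),
                         ref_universe = names(ref_models),
                         query_universe = names(q_genes))
  structure(list(
    ref = new_ref,
    query_genome = query_genome,
    query_species = query_species,
    query_genes = if (length(q_genes)) do.call(rbind, q_genes)
                  else data.frame(),
    orthologs = orth,
    paralog_families = fam_tab,
    transcripts = Biostrings::DNAStringSet(unlist(transcripts)),
    truth = list(genes = truth_genes, disruptions = disruptions)
  ), class = "evolved_genomes")
}

#' @export
print.evolved_genomes <- function(x, ...) {
  cat("<evolved_genomes>\n")
  print(table(x$truth$genes$fate))
  invisible(x)
}

intronless_layout <- function(cds_len)
  list(exon_cod = as.integer(cds_len / 3L), intron_lens = integer(),
       strand = "+")

## ---- disruption planting --------------------------------------------------

plant_premature_stop <- function(bio, layout) {
  n_cod <- sum(layout$exon_cod)
  lo <- 6L; hi <- n_cod - 12L
  if (hi < lo) stop("gene too short to plant an interior premature stop")
  ## keep the stop >= 3 codons inside its exon: a terminal stop codon on an
  ## exon block edge can be clipped by the local aligner
  ends <- cumsum(layout$exon_cod)
  starts <- c(1L, head(ends, -1L) + 1L)
  interior <- unlist(lapply(seq_along(ends), function(e) {
    a <- starts[e] + 3L; b <- ends[e] - 3L
    if (a <= b) a:b else integer()
  }))
  cand <- intersect(lo:hi, interior)
  if (!length(cand)) stop("gene too short to plant an interior premature stop")
  ci <- if (length(cand) == 1L) cand else sample(cand, 1L)
  cdsmap <- bio_to_cds(layout)
  cod_bio <- which(!is.na(cdsmap) & (cdsmap - 1L) %/% 3L == ci - 1L)
  codon <- bio[cod_bio]
  tgt <- c("TAA", "TAG", "TGA")
  dist <- vapply(tgt, function(s) sum(strsplit(s, "")[[1L]] != codon), 0L)
  stop_cod <- strsplit(tgt[which.min(dist)], "")[[1L]]
  bio[cod_bio] <- stop_cod
  list(bio = bio,
       events = data.frame(kind = "premature_stop", bio_pos = cod_bio[1L] - 1L,
                           width = 3L, detail = paste(stop_cod, collapse = "")))
}

plant_frameshift <- function(bio, layout, len, ref_bio = bio, max_tries = 25L) {
  stopifnot(abs(len) %% 3L != 0L)
  exb <- layout_exon_bio(layout)
  need <- abs(len) + 9L
  ok <- which(exb[, "end"] - exb[, "start"] >= need + 18L)
  if (!length(ok)) stop("no exon long enough for the requested frameshift")
  width <- if (len < 0L) 3L - ((-len) %% 3L) else 3L + len
  for (try in seq_len(max_tries)) {
    e <- if (length(ok) == 1L) ok else sample(ok, 1L)
    n_cod_e <- (exb[e, "end"] - exb[e, "start"]) / 3L
    slots <- 4L:(n_cod_e - ceiling(need / 3) - 3L)
    ci <- if (length(slots) == 1L) slots else sample(slots, 1L)
    d <- exb[e, "start"] + (ci - 1L) * 3L        # 0-based codon start
    if (len < 0L) {
      cand <- bio[-((d + 1L):(d - len))]
    } else {
      cand <- append(bio, rand_dna_chars(len), after = d)
    }
    ## a small indel can admit an equally scoring alignment with the
    ## frameshift shifted by whole codons; only keep plants whose optimal
    ## placement is unique, so planted truth and detected events coincide
    s <- exb[e, "start"]; en <- exb[e, "end"] + len
    seg_aa <- as.character(Biostrings::translate(Biostrings::DNAString(
      paste(ref_bio[(s + 1L):exb[e, "end"]], collapse = ""))))
    al <- align_protein_dna(seg_aa, paste(cand[(s + 1L):en], collapse = ""))
    fs <- al$ops[al$ops$type == 2L, , drop = FALSE]
    if (nrow(fs) == 1L && fs$dna_start - 1L == d - s && fs$dna_len == width) {
      return(list(bio = cand,
                  events = data.frame(kind = "frameshift", bio_pos = d,
                                      width = width,
                                      detail = as.character(len))))
    }
  }
  stop("could not place an alignment-unambiguous frameshift")
}

plant_splice_site <- function(bio, layout, donor = NA) {
  k <- length(layout$intron_lens)
  if (k < 1L) stop("splice_site disruption requires a multi-exon gene")
  i <- if (k == 1L) 1L else sample(k, 1L)
  exb <- layout_exon_bio(layout)
  if (is.na(donor)) donor <- sample(c(TRUE, FALSE), 1L)
  if (donor) {
    s <- exb[i, "end"]                           # 0-based intron start
    bio[s + 1L] <- "A"                           # GT -> AT
    detail <- "AT"
  } else {
    s <- exb[i + 1L, "start"] - 2L               # 0-based acceptor dinuc start
    bio[s + 2L] <- "C"                           # AG -> AC
    detail <- "AC"
  }
  list(bio = bio,
       events = data.frame(kind = "splice_site", bio_pos = s, width = 2L,
                           detail = detail))
}

plant_disruption <- function(bio, layout, kind, next_fs_len, ref_bio = bio) {
  switch(kind,
         premature_stop = plant_premature_stop(bio, layout),
         frameshift = plant_frameshift(bio, layout, next_fs_len(), ref_bio),
         splice_site = plant_splice_site(bio, layout),
         splice_donor = plant_splice_site(bio, layout, donor = TRUE),
         splice_acceptor = plant_splice_site(bio, layout, donor = FALSE),
         stop("unknown disruption kind: ", kind))
}
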