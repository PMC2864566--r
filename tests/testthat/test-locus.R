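test_that("locus clustering is single-linkage on overlapping same-strand intervals", {
  cand <- data.frame(gene_id = c("a", "b"), chrom = "chr1", strand = "+",
                     start = c(100L, 150L), end = c(200L, 250L))
  loci <- cluster_loci(cand)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, 100L)
  expect_equal(loci$end, 250L)
  expect_equal(loci$genes, "a,b")

  disjoint <- data.frame(gene_id = c("a", "b"), chrom = "chr1", strand = "+",
                         start = c(100L, 300L), end = c(200L, 400L))
  expect_equal(nrow(cluster_loci(disjoint)), 2L)

  ## A-B overlap, B-C overlap, A-C disjoint -> one locus
  chain <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1", strand = "+",
                      start = c(0L, 80L, 160L), end = c(100L, 180L, 260L))
  expect_equal(nrow(cluster_loci(chain)), 1L)

  ## opposite strands never merge
  ss <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                   strand = c("+", "-"), start = c(0L, 50L), end = c(100L, 150L))
  expect_equal(nrow(cluster_loci(ss)), 2L)
})

test_that("cluster counts equal the union-find oracle on random interval sets", {
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(2:15, 1L)
    df <- data.frame(gene_id = sprintf("g%d", seq_len(n)),
                     chrom = sample(c("c1", "c2"), n, TRUE),
                     strand = sample(c("+", "-"), n, TRUE),
                     start = sample(0:500, n, TRUE))
    df$end <- df$start + sample(20:150, n, TRUE)
    expect_equal(nrow(cluster_loci(df)), oracle_interval_clusters(df))
  }
})

make_locus_models <- function() {
  list(
    gN = gene_model("gN", "ref", "chrR", "+", rbind(c(0L, 30L)),
                    evidence_class = "NAMED_GENE"),
    gS = gene_model("gS", "ref", "chrR", "+", rbind(c(100L, 130L)),
                    evidence_class = "SPLICED_CDNA"),
    gU = gene_model("gU", "ref", "chrR", "+", rbind(c(200L, 230L)),
                    evidence_class = "UNSPLICED_CDNA"),
    gP = gene_model("gP", "ref", "chrR", "+", rbind(c(300L, 330L)),
                    evidence_class = "PREDICTED"))
}

test_that("evidence filtering keeps named/spliced loci and logs removal reasons", {
  models <- make_locus_models()
  loci <- data.frame(chrom = "chr1", strand = "+",
                     start = c(0L, 100L, 200L, 300L),
                     end = c(50L, 150L, 250L, 350L),
                     genes = c("gN", "gS", "gU", "gP"),
                     n_members = 1L)
  out <- apply_evidence_filter(loci, models)
  expect_equal(out$kept$genes, c("gN", "gS"))
  expect_equal(out$discarded$reason,
               c("unspliced transcribed sequence", "modeled/predicted"))
  ## best class wins for a multi-gene locus
  multi <- data.frame(chrom = "chr1", strand = "+", start = 0L, end = 50L,
                      genes = "gN,gP", n_members = 2L)
  expect_equal(nrow(apply_evidence_filter(multi, models)$kept), 1L)
})

test_that("tandem family flagging distinguishes planted families from singletons", {
  gs <- simulate_reference_geneset(15, seed = 91)
  ev <- evolve_query_genome(gs, fates = c(FAMILY_PSEUDO = 2L,
                                          UNITARY_PSEUDO = 2L),
                            neutral_sub_rate = 0, seed = 92)
  models <- ev$ref$models
  fams <- ev$paralog_families
  for (g in ev$truth$genes$gene_id[ev$truth$genes$fate == "FAMILY_PSEUDO"]) {
    locus <- data.frame(genes = g)
    expect_true(flag_tandem_family(locus, models, fams))
  }
  ## singleton-family pseudogenes (the GULO-like case) are not flagged
  for (g in ev$truth$genes$gene_id[ev$truth$genes$fate == "UNITARY_PSEUDO"]) {
    expect_false(flag_tandem_family(data.frame(genes = g), models, fams))
    ## degenerate threshold: every locus flags
    expect_true(flag_tandem_family(data.frame(genes = g), models, fams,
                                   min_family_size = 1L))
  }
})

test_that("synteny passes planted neighborhoods, fails shuffled ones, errors at k = 0", {
  gs <- simulate_reference_geneset(20, seed = 93)
  ev <- evolve_query_genome(gs, fates = c(UNITARY_PSEUDO = 2L),
                            neutral_sub_rate = 0, seed = 94)
  idx <- build_translated_index(ev$query_genome)
  for (g in ev$truth$genes$gene_id[ev$truth$genes$fate == "UNITARY_PSEUDO"]) {
    m <- ev$ref$models[[g]]
    w <- map_protein_to_genome(m$protein, ev$query_genome, index = idx)[1L, ]
    locus <- data.frame(chrom = w$chrom, start = w$start, end = w$end,
                        genes = g)
    expect_true(check_synteny(locus, g, ev$ref$models, ev$orthologs,
                              ev$query_genes))
    expect_error(check_synteny(locus, g, ev$ref$models, ev$orthologs,
                               ev$query_genes, k = 0L), "k >= 1")
  }
})

test_that("a relocated locus fails the synteny check", {
  gs <- simulate_reference_geneset(20, seed = 95)
  ev <- evolve_query_genome(gs, fates = c(UNITARY_PSEUDO = 1L),
                            neutral_sub_rate = 0, seed = 96)
  g <- ev$truth$genes$gene_id[ev$truth$genes$fate == "UNITARY_PSEUDO"]
  ## pretend the locus sits at the far end of the chromosome: flanking
  ## orthologs are then all on one side
  L <- Biostrings::width(ev$query_genome)[1L]
  locus <- data.frame(chrom = "chr1", start = L - 50L, end = L - 10L,
                      genes = g)
  expect_false(check_synteny(locus, g, ev$ref$models, ev$orthologs,
                             ev$query_genes))
})

test_that("polymorphic loci are called from functional transcripts only", {
  gs <- simulate_reference_geneset(10, seed = 97)
  ev <- evolve_query_genome(gs, fates = c(UNITARY_PSEUDO = 2L),
                            neutral_sub_rate = 0, seed = 98,
                            n_polymorphic = 2L,
                            unitary_kinds = c("premature_stop", "frameshift"))
  idx <- build_translated_index(ev$query_genome)
  for (g in ev$truth$genes$gene_id[ev$truth$genes$fate == "UNITARY_PSEUDO"]) {
    m <- ev$ref$models[[g]]
    w <- map_protein_to_genome(m$protein, ev$query_genome, index = idx)[1L, ]
    aln <- align_exon_guided(m, w, ev$query_genome)
    evts <- detect_disruptions(aln, m)
    tx_fun <- ev$transcripts[paste0("tx_", g)]
    ## functional-allele transcript over the disruption -> polymorphic
    expect_true(detect_polymorphic(aln, evts, tx_fun))
    ## a transcript carrying the disrupted state -> fixed
    blocks <- Filter(function(b) b$present, aln$exons)
    amap <- unlist(lapply(blocks, function(b) (b$a0 + 1L):b$a1))
    tx_pseudo <- Biostrings::DNAStringSet(setNames(
      paste(aln$wseq[amap], collapse = ""), "tx_pseudo"))
    expect_false(detect_polymorphic(aln, evts, tx_pseudo))
    ## no transcripts -> fixed by default
    expect_false(detect_polymorphic(aln, evts, NULL))
  }
})

test_that("the pipeline report accounts for every unmatched protein exactly once", {
  gs <- simulate_reference_geneset(40, seed = 101)
  ev <- evolve_query_genome(gs, fates = c(UNITARY_PSEUDO = 5L,
                                          FAMILY_PSEUDO = 1L,
                                          PROCESSED_COPY = 1L,
                                          DELETED_IN_QUERY = 2L,
                                          GAIN_IN_REF = 1L),
                            neutral_sub_rate = 0, seed = 102)
  rep <- run_pipeline(ev$ref, ev$query_genome, ev$orthologs, ev$query_genes,
                      ev$paralog_families, verbose = FALSE)
  expect_false(anyNA(rep$bins))
  expect_equal(length(rep$bins), rep$counts[["unmatched_proteins"]])
  terminal <- c("unalignable", "structure_fail", "no_disruption",
                "evidence_removed", "tandem_family", "synteny_rejected",
                "fixed_unitary", "polymorphic")
  expect_true(all(rep$bins %in% terminal))
  ## bin totals partition the unmatched set
  expect_equal(sum(table(factor(rep$bins, levels = terminal))),
               rep$counts[["unmatched_proteins"]])
  ## determinism: same inputs give an identical report
  rep2 <- run_pipeline(ev$ref, ev$query_genome, ev$orthologs, ev$query_genes,
                       ev$paralog_families, verbose = FALSE)
  expect_identical(rep$counts, rep2$counts)
  expect_identical(rep$bins, rep2$bins)
})

test_that("zero planted events yield zero reported loci", {
  gs <- simulate_reference_geneset(10, seed = 103)
  ev <- evolve_query_genome(gs, fates = c(UNITARY_PSEUDO = 0L),
                            neutral_sub_rate = 0, seed = 104)
  rep <- run_pipeline(ev$ref, ev$query_genome, ev$orthologs, ev$query_genes,
                      ev$paralog_families, verbose = FALSE)
  expect_equal(rep$counts[["loci"]], 0L)
  expect_equal(rep$counts[["unmatched_proteins"]], 0L)
})
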