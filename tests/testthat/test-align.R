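test_that("an exact locus aligns with full identity, coverage and no frameshifts", {
  fx <- make_two_exon_fixture("+")
  win <- list(chrom = "chr1", start = 80L, end = 290L, strand = "+")
  aln <- align_exon_guided(fx$model, win, fx$genome)
  expect_equal(aln$coverage, 1.0)
  for (b in aln$exons) {
    expect_true(b$present)
    expect_equal(b$identity, 1.0)
    expect_equal(b$net_indel, 0L)
    expect_equal(sum(b$ops$type == 2L), 0L)
  }
  expect_equal(nrow(detect_disruptions(aln, fx$model)), 0L)
  ss <- gene_structure_similarity(aln, fx$model)
  expect_equal(ss$score, 1.0)
  expect_true(ss$pass)
})

test_that("exon-block scores match the exhaustive DP oracle on small inputs", {
  set.seed(5)
  aas <- setdiff(rownames(blosum62)[1:20], character())
  for (rep in 1:12) {
    np <- sample(4:8, 1L)
    prot <- paste(sample(aas, np, TRUE), collapse = "")
    nd <- sample((3 * np - 4):(3 * np + 6), 1L)
    dna <- paste(sample(c("A", "C", "G", "T"), nd, TRUE), collapse = "")
    got <- align_protein_dna(prot, dna)$score
    want <- oracle_fs_align_score(prot, dna)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("a planted 1-bp deletion yields exactly one frameshift transition at the planted offset", {
  set.seed(6)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  cds <- c("ATG", sample(sense, 29, TRUE))
  dna <- unlist(strsplit(cds, ""))
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(dna, collapse = "")), no.init.codon = TRUE))
  del_codon <- 15L
  d <- (del_codon - 1L) * 3L            # 0-based codon start
  mut <- dna[-(d + 1L)]
  al <- align_protein_dna(prot, paste(mut, collapse = ""))
  fs <- al$ops[al$ops$type == 2L, ]
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$dna_start - 1L, d)
  expect_equal(fs$dna_len, 2L)
})

test_that("alignment score is monotone in the frameshift penalty", {
  set.seed(7)
  cds <- unlist(strsplit(c("ATG", sample(setdiff(
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"], ""),
    19, TRUE)), ""))
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(cds, collapse = "")), no.init.codon = TRUE))
  mut <- cds[-16L]   # 1-bp deletion
  scores <- vapply(c(5, 10, 20, 40), function(fp)
    align_protein_dna(prot, paste(mut, collapse = ""),
                      frameshift_penalty = fp)$score, 0)
  expect_true(all(diff(scores) <= 1e-9))
})

test_that("strand symmetry: mirrored windows give identical events at mirrored coordinates", {
  gs <- simulate_reference_geneset(8, seed = 71)
  ev <- evolve_query_genome(gs, fates = c(UNITARY_PSEUDO = 3L),
                            neutral_sub_rate = 0, seed = 72)
  idx <- build_translated_index(ev$query_genome)
  L <- Biostrings::width(ev$query_genome)[1L]
  rcg <- Biostrings::DNAStringSet(setNames(as.character(
    Biostrings::reverseComplement(ev$query_genome[[1L]])), "chr1"))
  for (g in ev$truth$genes$gene_id[ev$truth$genes$fate == "UNITARY_PSEUDO"]) {
    m <- ev$ref$models[[g]]
    w <- map_protein_to_genome(m$protein, ev$query_genome, index = idx)[1L, ]
    aln <- align_exon_guided(m, w, ev$query_genome)
    evts <- detect_disruptions(aln, m)
    ## reverse-complement the query chromosome and flip the window strand:
    ## the aligner must see the same biological sequence
    w2 <- w
    w2$start <- L - w$end; w2$end <- L - w$start
    w2$strand <- if (w$strand == "+") "-" else "+"
    aln2 <- align_exon_guided(m, w2, rcg)
    evts2 <- detect_disruptions(aln2, m)
    expect_equal(nrow(evts2), nrow(evts))
    expect_equal(evts2$kind, evts$kind)
    expect_equal(sort(L - evts2$pos - evts2$width), sort(evts$pos))
  }
})

test_that("donor GT->AT and an 8-bp deletion are classified as in the published cases", {
  gs <- simulate_reference_geneset(10, exon_count_range = c(2L, 4L), seed = 81)
  ev <- evolve_query_genome(gs, fates = c(UNITARY_PSEUDO = 2L),
                            neutral_sub_rate = 0, seed = 82,
                            unitary_kinds = c("splice_site", "frameshift"),
                            frameshift_lens = -8L)
  idx <- build_translated_index(ev$query_genome)
  tr <- ev$truth$disruptions
  for (g in unique(tr$gene_id)) {
    m <- ev$ref$models[[g]]
    w <- map_protein_to_genome(m$protein, ev$query_genome, index = idx)[1L, ]
    aln <- align_exon_guided(m, w, ev$query_genome)
    evts <- detect_disruptions(aln, m)
    want <- tr[tr$gene_id == g, ]
    expect_equal(nrow(evts), nrow(want))
    expect_equal(evts$kind, want$kind)
    expect_equal(evts$pos, want$pos)
    if (want$kind[1L] == "frameshift")
      expect_equal(abs(as.integer(want$detail)) %% 3L, 2L)  # 8 mod 3 = 2
  }
})

test_that("a 3-bp in-frame deletion is not a disruption", {
  fx <- make_two_exon_fixture("+")
  chrom <- as.character(fx$genome[[1L]])
  ## delete one whole codon inside exon 1 (codons 5..: positions 112-114)
  mut <- paste0(substr(chrom, 1, 112), substr(chrom, 116, nchar(chrom)))
  genome <- Biostrings::DNAStringSet(c(chr1 = mut))
  win <- list(chrom = "chr1", start = 80L, end = 287L, strand = "+")
  aln <- align_exon_guided(fx$model, win, genome)
  evts <- detect_disruptions(aln, fx$model)
  expect_equal(nrow(evts), 0L)
})

test_that("gene structure similarity follows its definition", {
  ## intronless processed copy of a multi-exon gene: full coverage, no
  ## introns recovered -> score 0.5, fail at the default threshold
  fx <- make_two_exon_fixture("+")
  cdna <- fx$cds
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    paste(rep("ACGT", 25), collapse = ""), cdna,
    paste(rep("TGCA", 25), collapse = ""))))
  win <- list(chrom = "chr1", start = 70L, end = 100L + nchar(cdna) + 30L,
              strand = "+")
  aln <- align_exon_guided(fx$model, win, genome)
  ss <- gene_structure_similarity(aln, fx$model)
  expect_equal(ss$coverage, 1.0)
  expect_equal(ss$intron_recovery, 0)
  expect_equal(ss$score, 0.5)
  expect_false(ss$pass)
  expect_true(ss$intronless)
  ## zero coverage (nothing alignable) -> score 0
  aln0 <- align_exon_guided(fx$model, list(chrom = "chr1", start = 0L,
                                           end = 2L, strand = "+"),
                            fx$genome)
  ss0 <- gene_structure_similarity(aln0, fx$model)
  expect_equal(ss0$coverage, 0)
  expect_equal(ss0$score, 0)
  expect_false(ss0$pass)
})
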