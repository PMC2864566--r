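test_that("the reference generator is a pure function of its seed", {
  a <- simulate_reference_geneset(10, seed = 7)
  b <- simulate_reference_geneset(10, seed = 7)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(lapply(a$models, `[[`, "exons"),
                   lapply(b$models, `[[`, "exons"))
  c <- simulate_reference_geneset(10, seed = 8)
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
})

test_that("exon count range (1,1) yields single-exon genes only", {
  gs <- simulate_reference_geneset(8, exon_count_range = c(1L, 1L), seed = 3)
  expect_true(all(vapply(gs$models, function(m) nrow(m$exons), 0L) == 1L))
  expect_error(simulate_reference_geneset(5, exon_len_range = c(1, 2)),
               "infeasible")
})

test_that("simulated proteins contain no internal stops (100 genes)", {
  gs <- simulate_reference_geneset(100, seed = 13)
  for (m in gs$models) {
    expect_false(grepl("*", m$protein, fixed = TRUE))
    expect_equal(sum(m$exons[, "end"] - m$exons[, "start"]) %% 3L, 0L)
  }
  ## introns written with canonical splice dinucleotides
  chrom <- as.character(gs$genome[[1L]])
  for (m in gs$models[1:10]) {
    if (nrow(m$exons) < 2L) next
    for (i in seq_len(nrow(m$exons) - 1L)) {
      don <- substr(chrom, m$exons[i, "end"] + 1L, m$exons[i, "end"] + 2L)
      acc <- substr(chrom, m$exons[i + 1L, "start"] - 1L, m$exons[i + 1L, "start"])
      if (m$strand == "+") {
        expect_equal(don, "GT"); expect_equal(acc, "AG")
      } else {
        expect_equal(don, "CT"); expect_equal(acc, "AC")
      }
    }
  }
})

test_that("fate counts in the truth table equal the requested counts exactly", {
  gs <- simulate_reference_geneset(40, seed = 21)
  req <- c(UNITARY_PSEUDO = 5L, FAMILY_PSEUDO = 2L, PROCESSED_COPY = 2L,
           DELETED_IN_QUERY = 3L, GAIN_IN_REF = 1L)
  ev <- evolve_query_genome(gs, fates = req, neutral_sub_rate = 0, seed = 22)
  tab <- table(ev$truth$genes$fate)
  for (f in names(req)) expect_equal(unname(tab[[f]]), unname(req[[f]]))
  ## disruptions recorded only for pseudogenic fates
  dis_fates <- ev$truth$genes$fate[match(ev$truth$disruptions$gene_id,
                                         ev$truth$genes$gene_id)]
  expect_true(all(dis_fates %in%
                    c("UNITARY_PSEUDO", "FAMILY_PSEUDO", "PROCESSED_COPY")))
})

test_that("with zero divergence and all-intact fates the query carries identical CDS", {
  gs <- simulate_reference_geneset(6, seed = 31)
  ev <- evolve_query_genome(gs, fates = c(UNITARY_PSEUDO = 0L),
                            neutral_sub_rate = 0, seed = 32)
  for (i in seq_len(nrow(ev$query_genes))) {
    q <- ev$query_genes[i, ]
    m <- ev$ref$models[[q$ref_id]]
    qm <- gene_model(q$ref_id, "query", q$chrom, q$strand,
                     m$exons - m$exons[1L, "start"] + q$start)
    expect_equal(translate_model(qm, ev$query_genome), m$protein)
  }
})

test_that("planted 8-bp deletions and donor GT->AT mutations are recorded as such", {
  gs <- simulate_reference_geneset(12, exon_count_range = c(2L, 4L), seed = 41)
  ev <- evolve_query_genome(gs, fates = c(UNITARY_PSEUDO = 2L),
                            neutral_sub_rate = 0, seed = 42,
                            unitary_kinds = c("frameshift", "splice_site"),
                            frameshift_lens = -8L)
  dd <- ev$truth$disruptions
  fs <- dd[dd$kind == "frameshift", ]
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$detail, "-8")
  expect_equal(abs(as.integer(fs$detail)) %% 3L, 2L)
  sp <- dd[dd$kind == "splice_site", ]
  expect_equal(nrow(sp), 1L)
  expect_true(sp$detail %in% c("AT", "AC"))
})

test_that("an explicit splice-site request on a single-exon gene errors", {
  gs <- simulate_reference_geneset(6, exon_count_range = c(1L, 1L), seed = 51)
  expect_error(
    evolve_query_genome(gs, fates = c(UNITARY_PSEUDO = 1L),
                        neutral_sub_rate = 0, seed = 52,
                        unitary_kinds = "splice_site"),
    "single-exon")
})

test_that("genotype simulation honours HWE limits and inbreeding", {
  g <- simulate_genotypes("p1", 0.5, inbreeding_F = 0, n = 200000L, seed = 1)
  frac <- c(g$n_AA, g$n_Aa, g$n_aa) / 200000
  expect_equal(frac, c(0.25, 0.5, 0.25), tolerance = 0.02)
  g1 <- simulate_genotypes(c("a", "b"), 0.3, inbreeding_F = 1, n = 500L, seed = 2)
  expect_true(all(g1$n_Aa == 0L))
  expect_error(simulate_genotypes("p", 0.5, inbreeding_F = -1.5), "invalid")
})

test_that("the observed allele-frequency estimator is unbiased (Monte Carlo)", {
  p <- 0.3; n <- 100L; reps <- 1000L
  g <- simulate_genotypes(sprintf("p%04d", seq_len(reps)), p, 0, n, seed = 77)
  phat <- (2 * g$n_AA + g$n_Aa) / (2 * n)
  se <- sqrt(p * (1 - p) / (2 * n)) / sqrt(reps)
  expect_lt(abs(mean(phat) - p), 3 * se)
})

test_that("annotation simulation plants the stated enrichment and reproduces under seed", {
  ann <- simulate_annotations(n_genes = 1000L, n_study = 20L,
                              fold_enrichment = 5, background_freq = 0.1,
                              seed = 5)
  expect_equal(ann$background_carriers, 100L)
  expect_equal(ann$study_carriers, 10L)   # 5 x 0.1 x 20
  ann2 <- simulate_annotations(n_genes = 1000L, n_study = 20L,
                               fold_enrichment = 5, background_freq = 0.1,
                               seed = 5)
  expect_identical(ann$study, ann2$study)
  ## fold = 1: study frequency equals background by construction
  flat <- simulate_annotations(n_genes = 500L, n_study = 100L,
                               fold_enrichment = 1, background_freq = 0.1,
                               seed = 6)
  expect_equal(flat$study_carriers / 100, 0.1)
  expect_error(simulate_annotations(fold_enrichment = 20,
                                    background_freq = 0.1), "infeasible")
})
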