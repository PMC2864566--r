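test_that("Fitch reconstruction: identical leaves give identical ancestors", {
  tr <- primate_tree()
  aln <- setNames(rep("ATGCATGCA", 4), tr$tree$tip.label)
  out <- fitch_ancestral_reconstruction(aln, tr)
  expect_equal(out$parsimony, 0L)
  expect_true(all(out$sequences == "ATGCATGCA"))
})

test_that("a single divergent leaf implies exactly one change", {
  tr <- primate_tree()
  aln <- c(human = "ATGCAT", chimp = "ATGCAT", rhesus = "ATGCAT",
           marmoset = "ATGCAC")
  out <- fitch_ancestral_reconstruction(aln, tr)
  expect_equal(out$parsimony, 1L)
  ## the root's state set is {C, T}: the tie breaks alphabetically at the
  ## root, and children then prefer their own sets over the parent state
  expect_equal(substr(out$sequences[["node5"]], 6, 6), "C")
  expect_equal(substr(out$sequences[["node6"]], 6, 6), "T")
  expect_equal(substr(out$sequences[["node7"]], 6, 6), "T")
})

test_that("parsimony counts match the brute-force minimum over labelings", {
  set.seed(19)
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,(d:1,e:1):0.5):1);")
  for (rep in 1:5) {
    L <- sample(4:8, 1L)
    aln <- setNames(vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""), ""),
      c("a", "b", "c", "d", "e"))
    out <- fitch_ancestral_reconstruction(aln, tr)
    expect_equal(out$parsimony, oracle_parsimony(aln, tr))
  }
  expect_error(fitch_ancestral_reconstruction(c(zz = "AAAA"), tr), "missing")
})

test_that("NG86 matches the hand-computed oracle and is symmetric", {
  r <- nei_gojobori_kaks("GGGGGG", "GGAGGG")
  expect_equal(r$s_sites, 2)
  expect_equal(r$p_s, 0.5)
  expect_equal(r$ks, -0.75 * log(1 / 3), tolerance = 1e-12)
  expect_equal(r$ka, 0)
  ident <- nei_gojobori_kaks("ATGAAA", "ATGAAA")
  expect_equal(c(ident$ka, ident$ks), c(0, 0))
  ## symmetry on random sense-codon pairs
  set.seed(23)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (rep in 1:100) {
    a <- paste(sample(sense, 10, TRUE), collapse = "")
    b <- paste(sample(sense, 10, TRUE), collapse = "")
    r1 <- nei_gojobori_kaks(a, b); r2 <- nei_gojobori_kaks(b, a)
    expect_equal(r1$sd, r2$sd); expect_equal(r1$nd, r2$nd)
    expect_equal(r1$s_sites, r2$s_sites)
  }
  expect_error(nei_gojobori_kaks("ATG", "ATGAAA"), "equal length")
  expect_error(nei_gojobori_kaks("ATGTAAAAA", "ATGCAAAAA"), "stop")
})

test_that("saturation is flagged, not silent", {
  ## maximally diverged third positions: p_s > 3/4 is impossible per codon
  ## pair here, so force it with many synonymous differences vs few sites
  a <- paste(rep("GGG", 30), collapse = "")
  b <- paste(rep("GGA", 30), collapse = "")
  r <- nei_gojobori_kaks(a, b)
  expect_true(r$saturated)
  expect_true(is.na(r$ks))
})

test_that("zero-length branches give K_A = K_S = 0 with omega flagged undefined", {
  tr <- dated_tree(ape::read.tree(text = "((a:0.0,b:0.0):1,c:1);"))
  sim <- simulate_codon_phylogeny(tr, omega_constrained = 0.5,
                                  codon_count = 200L, seed = 3)
  rates <- lineage_omega(sim$alignment, tr)
  ab <- rates[rates$branch %in% c("a", "b"), ]
  expect_true(all(ab$ka == 0 & ab$ks == 0))
  expect_true(all(!ab$omega_defined))
})

test_that("Dollo placement maps sharing patterns to the minimal clade stem", {
  tr <- primate_tree()
  ## human-specific disruption -> human terminal branch
  p1 <- place_disruption(c(human = "present", chimp = "absent",
                           rhesus = "absent", marmoset = "absent"), tr)
  expect_equal(p1$stem_label, "human")
  ## shared by human/chimp/rhesus, absent in marmoset -> catarrhine stem
  p2 <- place_disruption(c(human = "present", chimp = "present",
                           rhesus = "present", marmoset = "absent"), tr)
  expect_equal(sort(p2$clade_tips), c("chimp", "human", "rhesus"))
  expect_equal(node_age(tr, p2$node), 30)
  ## marmoset missing data is uninformative, not conflicting
  p3 <- place_disruption(c(human = "present", chimp = "present",
                           rhesus = "present", marmoset = "missing"), tr)
  expect_false(p3$homoplasic)
  ## all leaves -> root stem
  p4 <- place_disruption(setNames(rep("present", 4), tr$tree$tip.label), tr)
  expect_equal(p4$node, length(tr$tree$tip.label) + 1L)
  ## an absent species inside the clade is homoplasic
  expect_warning(
    p5 <- place_disruption(c(human = "present", rhesus = "present",
                             chimp = "absent", marmoset = "absent"), tr),
    "homoplasic")
  expect_true(p5$homoplasic)
  expect_error(place_disruption(c(human = "absent"), tr), "no species")
})

test_that("T_N estimator: algebraic limits, worked value, monotonicity, errors", {
  T <- 6.6
  expect_equal(estimate_tn(1, 0.12, T)$t_n, T)
  expect_equal(estimate_tn(0.12, 0.12, T)$t_n, 0)
  expect_equal(estimate_tn(0.56, 0.12, T)$t_n, 6.6 * 0.44 / 0.88,
               tolerance = 1e-12)
  ## monotone increasing in omega1
  tns <- vapply(seq(0.12, 1, by = 0.05), function(w)
    estimate_tn(w, 0.12, T)$t_n, 0)
  expect_true(all(diff(tns) > 0))
  ## clamping flags out-of-range values
  expect_true(estimate_tn(1.4, 0.12, T)$clamped)
  expect_equal(estimate_tn(1.4, 0.12, T)$t_n, T)
  expect_error(estimate_tn(0.5, 1.0, T), "omega_bar")
})

test_that("codon simulation is deterministic and respects the neutral limit", {
  tr <- primate_tree()
  s1 <- simulate_codon_phylogeny(tr, 0.12, codon_count = 300L, seed = 9)
  s2 <- simulate_codon_phylogeny(tr, 0.12, codon_count = 300L, seed = 9)
  expect_identical(s1$alignment, s2$alignment)
  ## omega = 1 everywhere -> lineage omega estimates near 1 at 10,000 codons
  sim <- simulate_codon_phylogeny(tr, omega_constrained = 1,
                                  codon_count = 10000L, seed = 10)
  rates <- lineage_omega(sim$alignment, tr)
  long <- rates[rates$ks > 0.01, ]
  expect_true(all(abs(long$omega - 1) < 0.15))
})

test_that("disruptions planted on an internal branch propagate to exactly its descendants", {
  tr <- primate_tree()
  ## catarrhine ancestor branch: stem of human/chimp/rhesus
  node_lab <- paste0("node", ape::getMRCA(tr$tree, c("human", "rhesus")))
  sim <- simulate_codon_phylogeny(tr, 0.12, codon_count = 500L,
                                  switch_tip = node_lab, t_n = 35,
                                  n_disruptions = 2L, seed = 11)
  expect_equal(sim$truth$pattern[c("human", "chimp", "rhesus")],
               setNames(rep("present", 3), c("human", "chimp", "rhesus")))
  expect_equal(unname(sim$truth$pattern[["marmoset"]]), "absent")
  ## the planted stop codons are visible in all carriers
  for (ci in sim$truth$disruption_codons) {
    for (sp in c("human", "chimp", "rhesus")) {
      cod <- substr(sim$alignment[[sp]], 3 * ci - 2, 3 * ci)
      expect_true(cod %in% c("TAA", "TAG", "TGA"))
    }
  }
  ## placement recovers the planted branch
  pl <- place_disruption(sim$truth$pattern, tr)
  expect_equal(paste0("node", pl$node), node_lab)
  ## t_n outside the branch errors
  expect_error(simulate_codon_phylogeny(tr, 0.12, codon_count = 10L,
                                        switch_tip = "human", t_n = 10,
                                        seed = 1), "outside")
})
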