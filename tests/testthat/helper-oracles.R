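## Independent oracles used across the suite: each reimplements the checked
## quantity by direct enumeration or a textbook algorithm, separate from
## the package's own code path.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

## memoized top-down scorer for the frameshift-aware local alignment,
## written independently of the compiled DP (explicit three-state affine
## recursion over all admissible operation sequences)
oracle_fs_align_score <- function(protein, dna, gap_open = 11, gap_extend = 1,
                                  fs = 20, stop_score = -4) {
  p <- strsplit(protein, "")[[1L]]
  d <- strsplit(dna, "")[[1L]]
  m <- length(p); n <- length(d)
  gc <- Biostrings::GENETIC_CODE
  emit <- function(i, j, c) {
    if (c <= 2L) return(-fs)
    cod <- paste(d[(j - 2L):j], collapse = "")
    aa <- gc[[cod]]
    s <- if (is.null(aa)) -1 else if (aa == "*") stop_score else blosum62[p[i], aa]
    if (c > 3L) s - fs else s
  }
  M <- array(NA_real_, c(m + 1L, n + 1L, 3L))
  sc <- function(i, j, q) {
    if (i == 0L) return(if (q == 1L) 0 else -Inf)
    if (!is.na(M[i + 1L, j + 1L, q])) return(M[i + 1L, j + 1L, q])
    v <- -Inf
    if (q == 1L) {          # state M: emit residue i with c nt
      for (c in 1:5) {
        if (j - c < 0L) next
        pre <- max(0, sc(i - 1L, j - c, 1L), sc(i - 1L, j - c, 2L),
                   sc(i - 1L, j - c, 3L))
        v <- max(v, pre + emit(i, j, c))
      }
    } else if (q == 2L) {   # state Ix: residue i gapped
      v <- max(sc(i - 1L, j, 1L) - gap_open, sc(i - 1L, j, 2L) - gap_extend)
    } else {                # state Iy: codon gapped in DNA
      if (j >= 3L)
        v <- max(sc(i, j - 3L, 1L) - gap_open, sc(i, j - 3L, 3L) - gap_extend)
    }
    M[i + 1L, j + 1L, q] <<- v
    v
  }
  best <- 0
  for (i in 0:m) for (j in 0:n) best <- max(best, sc(i, j, 1L))
  best
}

## textbook UPGMA: iterative nearest-pair merging with size-weighted
## average linkage; returns sorted merge heights
oracle_upgma_heights <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  sizes <- rep(1L, length(labs))
  dm <- d
  heights <- numeric()
  while (nrow(dm) > 1L) {
    dm2 <- dm; diag(dm2) <- Inf
    ij <- which(dm2 == min(dm2), arr.ind = TRUE)[1L, ]
    i <- min(ij); j <- max(ij)
    heights <- c(heights, dm[i, j])
    new_d <- (dm[i, ] * sizes[i] + dm[j, ] * sizes[j]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(nrow(dm)), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], new_d[keep]),
                c(new_d[keep], 0))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  sort(heights)
}

## brute-force Fitch parsimony: minimum change count over all internal
## labelings (tiny trees only)
oracle_parsimony <- function(aln, tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  L <- nchar(aln[[1L]])
  tipmat <- do.call(rbind, lapply(tree$tip.label, function(x)
    strsplit(aln[[x]], "")[[1L]]))
  bases <- c("A", "C", "G", "T")
  total <- 0L
  for (s in seq_len(L)) {
    combos <- expand.grid(rep(list(bases), nnode), stringsAsFactors = FALSE)
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      lab <- c(tipmat[, s], unlist(combos[r, ]))
      ch <- sum(lab[tree$edge[, 1L]] != lab[tree$edge[, 2L]])
      best <- min(best, ch)
    }
    total <- total + best
  }
  total
}

## union-find single-linkage clustering of intervals (same chrom+strand)
oracle_interval_clusters <- function(df) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && df$chrom[i] == df$chrom[j] && df$strand[i] == df$strand[j] &&
        df$start[i] < df$end[j] && df$start[j] < df$end[i]) {
      parent[find(i)] <- find(j)
    }
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}

## transitive closure of a parent mapping by iterated expansion
oracle_ancestors <- function(parents) {
  anc <- parents
  repeat {
    changed <- FALSE
    for (t in names(anc)) {
      more <- unique(c(anc[[t]], unlist(anc[anc[[t]]], use.names = FALSE)))
      if (length(more) > length(anc[[t]])) { anc[[t]] <- more; changed <- TRUE }
    }
    if (!changed) break
  }
  lapply(anc, sort)
}

## small two-exon gene fixture on a hand-built genome
make_two_exon_fixture <- function(strand = "+") {
  ## exon1: 60 nt (20 codons, starts ATG), intron 40 nt GT..AG, exon2 60 nt
  set.seed(99)
  cds <- c("ATG", sample(setdiff(names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"], "ATG"), 39, replace = TRUE))
  cds <- unlist(strsplit(cds, ""))
  intron <- c("G", "T", sample(c("A", "C", "G", "T"), 36, replace = TRUE), "A", "G")
  bio <- c(cds[1:60], intron, cds[61:120])
  pad <- sample(c("A", "C", "G", "T"), 100, replace = TRUE)
  gene <- if (strand == "-") rev(c(A = "T", C = "G", G = "C", T = "A")[bio]) else bio
  chrom <- paste(c(pad, gene, pad), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  exons <- if (strand == "+") {
    rbind(c(100L, 160L), c(200L, 260L))
  } else {
    rbind(c(100L, 160L), c(200L, 260L))  # mirrored layout is symmetric here
  }
  m <- gene_model("gx", "ref", "chr1", strand, exons)
  m$protein <- translate_model(m, genome)
  list(model = m, genome = genome,
       cds = paste(cds, collapse = ""))
}
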