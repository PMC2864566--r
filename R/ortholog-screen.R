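## Ortholog-absence screen: unmatched reference proteins, translated-seed
## mapping of proteins onto the query genome, and the mappability split
## between reference-lineage gains and pseudogene candidates.

#' Reference proteins without query orthologs
#'
#' @param orthologs An [ortholog_table()].
#' @return Sorted character vector of reference gene ids that appear in the
#'   reference universe but in no ortholog pair.
#' @export
find_unmatched_reference_proteins <- function(orthologs) {
  stopifnot(inherits(orthologs, "ortholog_table"))
  sort(setdiff(orthologs$ref_universe, orthologs$pairs$ref_id))
}

#' Build a six-frame translated k-mer index of a genome
#'
#' Amino-acid `seed_len`-mers of all six translation frames, hashed to their
#' strand-local nucleotide start positions. Plus-strand positions are
#' forward 0-based codon starts; minus-strand positions are 0-based codon
#' starts on the reverse complement (converted back to forward coordinates
#' when windows are reported).
#'
#' @param genome `DNAStringSet`.
#' @param seed_len Amino-acid seed length (default 5).
#' @return An object of class `translated_index`.
#' @export
build_translated_index <- function(genome, seed_len = 5L) {
  if (!length(genome) || sum(Biostrings::width(genome)) == 0L)
    stop("empty genome")
  kmer <- character(); chrom <- character(); strand <- character(); spos <- integer()
  for (ch in names(genome)) {
    fwd <- genome[[ch]]
    for (st in c("+", "-")) {
      s <- if (st == "+") fwd else Biostrings::reverseComplement(fwd)
      L <- length(s)
      for (f in 0:2) {
        n_cod <- (L - f) %/% 3L
        if (n_cod < seed_len) next
        aa <- as.character(suppressWarnings(Biostrings::translate(
          Biostrings::subseq(s, f + 1L, f + 3L * n_cod),
          if.fuzzy.codon = "solve")))
        n_k <- nchar(aa) - seed_len + 1L
        if (n_k < 1L) next
        i <- seq_len(n_k)
        kmer <- c(kmer, substring(aa, i, i + seed_len - 1L))
        chrom <- c(chrom, rep(ch, n_k))
        strand <- c(strand, rep(st, n_k))
        spos <- c(spos, f + 3L * (i - 1L))
      }
    }
  }
  keep <- !grepl("*", kmer, fixed = TRUE)
  df <- data.frame(chrom = chrom[keep], strand = strand[keep],
                   spos = spos[keep])
  idx <- list2env(split(seq_len(nrow(df)), kmer[keep]), hash = TRUE)
  structure(list(hits = df, index = idx, seed_len = seed_len,
                 seq_len = setNames(Biostrings::width(genome), names(genome))),
            class = "translated_index")
}

#' Map a protein onto a genome by translated seed chaining
#'
#' Exact amino-acid k-mer seeds against a six-frame translation, chained when
#' colinear on the same strand within a genomic gap bound (a toy-scale
#' stand-in for translated BLAT with the same contract). Windows are ranked
#' by chained protein coverage, then leftmost coordinate.
#'
#' @param protein Amino-acid string (length >= `seed_len`).
#' @param genome `DNAStringSet`, or a prebuilt [build_translated_index()]
#'   passed via `index` to amortize indexing over many proteins.
#' @param seed_len Seed length in residues.
#' @param min_coverage Minimum chained coverage for a window to be reported
#'   by [classify_mappability()]; windows below it are still returned here.
#' @param gap_bound Maximum genomic gap between chained seeds (nt).
#' @param index Optional prebuilt `translated_index`.
#' @param max_windows Cap on reported windows.
#' @return Data frame: `chrom`, `strand`, `start`, `end` (forward, 0-based
#'   half-open), `coverage`, `n_seeds`, best first.
#' @export
map_protein_to_genome <- function(protein, genome, seed_len = 5L,
                                  min_coverage = 0.5, gap_bound = 50000L,
                                  index = NULL, max_windows = 20L) {
  if (is.null(index)) index <- build_translated_index(genome, seed_len)
  stopifnot(inherits(index, "translated_index"))
  seed_len <- index$seed_len
  np <- nchar(protein)
  if (np < seed_len) stop("protein shorter than seed_len")
  i <- seq_len(np - seed_len + 1L)
  kmers <- substring(protein, i, i + seed_len - 1L)
  rows <- integer(); ppos <- integer()
  for (j in seq_along(kmers)) {
    h <- index$index[[kmers[j]]]
    if (!is.null(h)) { rows <- c(rows, h); ppos <- c(ppos, rep(j, length(h))) }
  }
  empty <- data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      coverage = numeric(), score = numeric(),
                      n_seeds = integer())
  if (!length(rows)) return(empty)
  seeds <- cbind(index$hits[rows, , drop = FALSE], prot = ppos)
  out <- list()
  for (key in unique(paste(seeds$chrom, seeds$strand))) {
    part <- strsplit(key, " ", fixed = TRUE)[[1L]]
    ss <- seeds[seeds$chrom == part[1L] & seeds$strand == part[2L], , drop = FALSE]
    ss <- ss[order(ss$spos, ss$prot), , drop = FALSE]
    alive <- rep(TRUE, nrow(ss))
    repeat {
      ch <- best_seed_chain(ss[alive, , drop = FALSE], seed_len, gap_bound)
      if (is.null(ch)) break
      cov <- ch$covered / np
      s0 <- ch$spos_min; s1 <- ch$spos_max + 3L * seed_len
      if (part[2L] == "+") {
        win <- c(s0, s1)
      } else {
        L <- index$seq_len[[part[1L]]]
        win <- c(L - s1, L - s0)
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = part[1L], strand = part[2L], start = win[1L], end = win[2L],
        coverage = cov, score = ch$score, n_seeds = ch$n)
      alive[which(alive)[ss$spos[alive] >= s0 & ss$spos[alive] < s1]] <- FALSE
      if (!any(alive) || length(out) >= max_windows) break
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(-res$score, res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## best colinear chain among seeds of one chrom+strand (already sorted by
## spos); a span penalty (1e-3 residues per nt of genomic gap) makes a
## compact single-locus chain beat an equally covering chain stitched
## across tandem copies
best_seed_chain <- function(ss, seed_len, gap_bound, span_cost = 1e-3) {
  n <- nrow(ss)
  if (!n) return(NULL)
  best <- numeric(n); covered <- numeric(n); prev <- integer(n)
  for (j in seq_len(n)) {
    best[j] <- seed_len; covered[j] <- seed_len; prev[j] <- 0L
    if (j > 1L) {
      i <- seq_len(j - 1L)
      ok <- ss$spos[i] < ss$spos[j] & ss$prot[i] < ss$prot[j] &
        ss$spos[j] - (ss$spos[i] + 3L * seed_len) <= gap_bound
      if (any(ok)) {
        i <- i[ok]
        add <- pmin(seed_len, ss$prot[j] - ss$prot[i])
        gap <- pmax(0L, ss$spos[j] - ss$spos[i] - 3L * add)
        cand <- best[i] + add - span_cost * gap
        w <- which.max(cand)
        if (cand[w] > best[j]) {
          best[j] <- cand[w]
          covered[j] <- covered[i[w]] + add[w]
          prev[j] <- i[w]
        }
      }
    }
  }
  j <- which.max(best)
  ## walk back for extent
  s_min <- ss$spos[j]; s_max <- ss$spos[j]; n_ch <- 0L; jj <- j
  while (jj > 0L) {
    s_min <- min(s_min, ss$spos[jj]); s_max <- max(s_max, ss$spos[jj])
    n_ch <- n_ch + 1L
    jj <- prev[jj]
  }
  list(covered = covered[j], score = best[j], spos_min = s_min,
       spos_max = s_max, n = n_ch)
}

#' Classify protein mappability
#'
#' A protein with no candidate window at or above `min_coverage` cannot be
#' aligned to the query genome and is classified `UNALIGNABLE` — the
#' signature of a reference-lineage gene gain (or a locus deleted outright
#' in the query); all others are `ALIGNABLE` pseudogene candidates.
#'
#' @param windows Result of [map_protein_to_genome()] for one protein.
#' @param min_coverage Coverage threshold (default 0.5).
#' @return `"ALIGNABLE"` or `"UNALIGNABLE"`.
#' @export
classify_mappability <- function(windows, min_coverage = 0.5) {
  if (nrow(windows) && any(windows$coverage >= min_coverage))
    "ALIGNABLE" else "UNALIGNABLE"
}
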