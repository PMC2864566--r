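## Dating pseudogenization: parsimony ancestral reconstruction, NG86
## lineage Ka/Ks, Dollo placement of shared disruptions, and the
## nonfunctionalization-time estimator.

low_bit <- function(x) bitwAnd(x, bitwAnd(bitwNot(x - 1L), 15L))
BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)
BIT_BASE <- c(`1` = "A", `2` = "C", `4` = "G", `8` = "T")

as_phylo <- function(tree) if (inherits(tree, "dated_tree")) tree$tree else tree

#' Fitch parsimony ancestral sequence reconstruction
#'
#' Per-site Fitch parsimony on nucleotides: the bottom-up pass computes
#' state sets and the parsimony count; the top-down pass assigns states,
#' breaking ties by preferring the parent's state, then alphabetical order.
#' Gaps and ambiguous bases are treated as missing (any state).
#'
#' @param aln Named character vector (or `DNAStringSet`) of equal-length
#'   sequences, one per tree tip.
#' @param tree An `ape::phylo` (or [dated_tree()]).
#' @return `list(sequences, parsimony)`: sequences for every node (tips and
#'   internal nodes, internal nodes named `node<N>`), and the total implied
#'   change count.
#' @export
fitch_ancestral_reconstruction <- function(aln, tree) {
  tree <- as_phylo(tree)
  aln <- vapply(aln, as.character, "")
  miss <- setdiff(names(aln), tree$tip.label)
  if (length(miss))
    stop("species in alignment missing from tree: ", miss[1L])
  miss2 <- setdiff(tree$tip.label, names(aln))
  if (length(miss2)) stop("tree tip without sequence: ", miss2[1L])
  L <- unique(nchar(aln))
  if (length(L) != 1L) stop("aligned sequences must have equal length")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- matrix(0L, ntip + nnode, L)
  for (i in seq_len(ntip)) {
    b <- BASE_BITS[strsplit(aln[[tree$tip.label[i]]], "")[[1L]]]
    b[is.na(b)] <- 15L
    sets[i, ] <- b
  }
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  changes <- 0L
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1L]; ch <- edges[e, 2L]
    if (all(sets[p, ] == 0L)) {
      sets[p, ] <- sets[ch, ]
    } else {
      inter <- bitwAnd(sets[p, ], sets[ch, ])
      un <- bitwOr(sets[p, ], sets[ch, ])
      zero <- inter == 0L
      changes <- changes + sum(zero)
      sets[p, ] <- ifelse(zero, un, inter)
    }
  }
  ## top-down assignment
  states <- matrix(0L, ntip + nnode, L)
  root <- ntip + 1L
  states[root, ] <- low_bit(sets[root, ])
  for (e in rev(seq_len(nrow(edges)))) {
    p <- edges[e, 1L]; ch <- edges[e, 2L]
    keep <- bitwAnd(states[p, ], sets[ch, ]) > 0L
    states[ch, ] <- ifelse(keep, states[p, ], low_bit(sets[ch, ]))
  }
  labs <- c(tree$tip.label, paste0("node", root:(ntip + nnode)))
  seqs <- setNames(vapply(seq_len(ntip + nnode), function(i)
    paste(BIT_BASE[as.character(states[i, ])], collapse = ""), ""), labs)
  list(sequences = seqs, parsimony = changes)
}

## ---------------------------------------------------------------------------
## NG86 Ka/Ks

ng86_tables <- function() {
  if (!is.null(.unipseudo_env$ng86)) return(.unipseudo_env$ng86)
  tb <- get_align_tables()
  bases <- c("A", "C", "G", "T")
  idx <- 0:63
  codons <- paste0(bases[idx %/% 16L + 1L], bases[(idx %/% 4L) %% 4L + 1L],
                   bases[idx %% 4L + 1L])
  aa <- tb$codon_to_aa[codons]
  ## fractional synonymous sites per codon (one-step changes; changes to a
  ## stop codon count as nonsynonymous)
  syn_sites <- setNames(numeric(64), codons)
  for (c0 in codons) {
    if (aa[[c0]] == "*") { syn_sites[c0] <- NA_real_; next }
    s <- 0
    for (p in 1:3) for (b in setdiff(bases, substr(c0, p, p))) {
      c1 <- c0; substr(c1, p, p) <- b
      if (aa[[c1]] != "*" && aa[[c1]] == aa[[c0]]) s <- s + 1 / 3
    }
    syn_sites[c0] <- s
  }
  ## pathway-averaged (syn, nonsyn) difference counts per codon pair;
  ## paths through stop codons are excluded unless all are blocked
  perms <- list(`1` = matrix(1L, 1L), `2` = rbind(c(1L, 2L), c(2L, 1L)),
                `3` = do.call(rbind, lapply(seq_len(6), function(i)
                  as.integer(arrangements_3()[i, ]))))
  sd_tab <- matrix(0, 64, 64, dimnames = list(codons, codons))
  nd_tab <- matrix(0, 64, 64, dimnames = list(codons, codons))
  for (i in seq_len(64)) for (j in seq_len(64)) {
    c1 <- codons[i]; c2 <- codons[j]
    if (c1 == c2) next
    pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
    P <- perms[[as.character(length(pos))]]
    res <- matrix(NA_real_, nrow(P), 2L)
    for (r in seq_len(nrow(P))) {
      cur <- c1; s <- 0; n <- 0; blocked <- FALSE
      for (p in pos[P[r, ]]) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (aa[[nxt]] == "*" && nxt != c2) blocked <- TRUE
        if (aa[[nxt]] != "*" && aa[[cur]] != "*" && aa[[nxt]] == aa[[cur]])
          s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      res[r, ] <- c(s, n)
      if (blocked) res[r, ] <- c(NA, NA)  # mark blocked path
    }
    keep <- !is.na(res[, 1L])
    if (!any(keep)) keep <- rep(TRUE, nrow(P))  # all blocked: use all
    res2 <- matrix(res[keep, ], ncol = 2L)
    if (anyNA(res2)) {   # recompute blocked paths when forced to use them
      for (r in which(is.na(res2[, 1L]))) {
        cur <- c1; s <- 0; n <- 0
        for (p in pos[P[which(keep)[r], ]]) {
          nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
          if (aa[[nxt]] != "*" && aa[[cur]] != "*" && aa[[nxt]] == aa[[cur]])
            s <- s + 1 else n <- n + 1
          cur <- nxt
        }
        res2[r, ] <- c(s, n)
      }
    }
    sd_tab[i, j] <- mean(res2[, 1L]); nd_tab[i, j] <- mean(res2[, 2L])
  }
  .unipseudo_env$ng86 <- list(codons = codons, syn_sites = syn_sites,
                              sd = sd_tab, nd = nd_tab)
  .unipseudo_env$ng86
}

arrangements_3 <- function() {
  rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
}

split_codons <- function(s) {
  n <- nchar(s) %/% 3L
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Nei-Gojobori (1986) Ka and Ks between two coding sequences
#'
#' Fractional synonymous-site counting per codon position, pathway-averaged
#' difference counting for multi-hit codons (paths through stop codons
#' excluded unless all are), and the Jukes-Cantor correction
#' d = -(3/4) ln(1 - (4/3) p). Codon columns containing a gap or ambiguity
#' in either sequence are skipped.
#'
#' @param cds1,cds2 Equal-length coding sequences (length a multiple of 3,
#'   no internal stop codons).
#' @return `list(ka, ks, omega, s_sites, n_sites, sd, nd, p_s, p_n,
#'   saturated)`; `omega` is `NA` (flagged) when `ks` is 0 or undefined,
#'   and `saturated` is set when a proportion exceeds 3/4 (the corrected
#'   distance is then `NA`, never silent).
#' @export
nei_gojobori_kaks <- function(cds1, cds2) {
  cds1 <- toupper(as.character(cds1)); cds2 <- toupper(as.character(cds2))
  if (nchar(cds1) != nchar(cds2)) stop("sequences must have equal length")
  if (nchar(cds1) %% 3L != 0L) stop("length must be a multiple of 3")
  tb <- ng86_tables()
  co1 <- split_codons(cds1); co2 <- split_codons(cds2)
  n <- length(co1)
  if (n > 1L && co1[n] %in% STOP_CODONS && co2[n] %in% STOP_CODONS) {
    co1 <- co1[-n]; co2 <- co2[-n]   # shared terminal stop codon
  }
  ok <- co1 %in% tb$codons & co2 %in% tb$codons   # skip gap/ambiguous columns
  co1 <- co1[ok]; co2 <- co2[ok]
  if (any(co1 %in% STOP_CODONS) || any(co2 %in% STOP_CODONS))
    stop("internal stop codon in input")
  if (!length(co1)) stop("no comparable codon columns")
  S <- (sum(tb$syn_sites[co1]) + sum(tb$syn_sites[co2])) / 2
  N <- 3 * length(co1) - S
  ii <- cbind(match(co1, tb$codons), match(co2, tb$codons))
  Sd <- sum(tb$sd[ii]); Nd <- sum(tb$nd[ii])
  p_s <- if (S > 0) Sd / S else 0
  p_n <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(p_s); ka <- jc(p_n)
  list(ka = ka, ks = ks,
       omega = if (!is.na(ks) && !is.na(ka) && ks > 0) ka / ks else NA_real_,
       s_sites = S, n_sites = N, sd = Sd, nd = Nd, p_s = p_s, p_n = p_n,
       saturated = p_s >= 0.75 || p_n >= 0.75)
}

#' Per-branch Ka/Ks on a tree
#'
#' Reconstructs ancestral sequences by Fitch parsimony and computes NG86
#' Ka/Ks between every parent-child pair. Codon columns containing a stop
#' codon in any node sequence can be masked (`mask_stops = TRUE`, the
#' default), since rate estimation must use sites away from disruptions.
#'
#' @param aln Named character vector of aligned CDS per tip.
#' @param tree `ape::phylo` or [dated_tree()].
#' @param mask_stops Drop codon columns containing a stop in any sequence.
#' @return Data frame with one row per branch: `branch` (child label),
#'   `parent`, `ka`, `ks`, `omega`, `omega_defined`.
#' @export
lineage_omega <- function(aln, tree, mask_stops = TRUE) {
  phy <- as_phylo(tree)
  anc <- fitch_ancestral_reconstruction(aln, phy)
  seqs <- anc$sequences
  if (mask_stops) {
    mats <- lapply(seqs, split_codons)
    is_stop <- Reduce(`|`, lapply(mats, function(x) x %in% STOP_CODONS))
    seqs <- vapply(mats, function(x) paste(x[!is_stop], collapse = ""), "")
  }
  ntip <- length(phy$tip.label)
  labs <- c(phy$tip.label, paste0("node", (ntip + 1L):(ntip + phy$Nnode)))
  rows <- lapply(seq_len(nrow(phy$edge)), function(e) {
    p <- labs[phy$edge[e, 1L]]; ch <- labs[phy$edge[e, 2L]]
    r <- nei_gojobori_kaks(seqs[[p]], seqs[[ch]])
    data.frame(branch = ch, parent = p, ka = r$ka, ks = r$ks,
               omega = r$omega, omega_defined = !is.na(r$omega))
  })
  do.call(rbind, rows)
}

#' Dollo placement of a shared disruptive mutation
#'
#' Under Dollo parsimony a disruption arises once and never reverts, so a
#' disruption shared by a set of species maps to the stem branch of the
#' minimal clade containing every species carrying it. Species with missing
#' data are uninformative; a disruption-free species inside the minimal
#' clade makes the pattern homoplasic and is flagged as a conflict.
#'
#' @param pattern Named character vector over tip labels with values
#'   `"present"`, `"absent"` or `"missing"`.
#' @param tree `ape::phylo` or [dated_tree()].
#' @return `list(node, clade_tips, stem_label, homoplasic)`: `node` is the
#'   crown node of the minimal clade (a tip number for single-species
#'   patterns) whose stem branch carries the event.
#' @export
place_disruption <- function(pattern, tree) {
  phy <- as_phylo(tree)
  if (!length(pattern)) stop("empty sharing pattern")
  present <- names(pattern)[pattern == "present"]
  if (!length(present)) stop("no species carries the disruption")
  bad <- setdiff(names(pattern), phy$tip.label)
  if (length(bad)) stop("unknown species in pattern: ", bad[1L])
  if (length(present) == 1L) {
    node <- match(present, phy$tip.label)
    clade <- present
  } else {
    node <- ape::getMRCA(phy, present)
    clade <- ape::extract.clade(phy, node)$tip.label
  }
  absent_in <- intersect(names(pattern)[pattern == "absent"], clade)
  if (length(absent_in))
    warning("homoplasic pattern: ", paste(absent_in, collapse = ","),
            " lack the disruption inside the minimal clade")
  list(node = node, clade_tips = clade,
       stem_label = if (length(present) == 1L) present
                    else paste0("node", node),
       homoplasic = length(absent_in) > 0L)
}

#' Nonfunctionalization-time estimate
#'
#' Under the standard two-phase model, nonsynonymous mutations are removed
#' by selection while the gene is functional (rate `omega_bar * r_S`) and
#' accumulate neutrally after inactivation, while synonymous mutations are
#' always neutral. Over a focal terminal branch of length `T` this gives
#' `K_A1 = r_S1 * (omega_bar * (T - T_N) + T_N)` and hence the closed form
#' `T_N = T * (omega1 - omega_bar) / (1 - omega_bar)`.
#'
#' @param omega1 Ka/Ks on the focal (e.g. human) terminal branch.
#' @param omega_bar Mean Ka/Ks over the non-focal branches (must be < 1);
#'   the constrained background.
#' @param T Focal branch length in MY (default 6.6, the human-chimpanzee
#'   split).
#' @param ka1,ks1 Optional focal-branch per-site rates, recorded in the
#'   result together with `r_S1 = ks1 / T`.
#' @param few_species Set the caution flag (estimates from few species
#'   should be viewed with caution).
#' @return Object of class `tn_estimate`: `list(T, t_n, omega1, omega_bar,
#'   ka1, ks1, r_s1, clamped, caution)`. `t_n` is clamped to `[0, T]` with
#'   `clamped = TRUE` when the raw value fell outside.
#' @export
estimate_tn <- function(omega1, omega_bar, T = 6.6, ka1 = NA_real_,
                        ks1 = NA_real_, few_species = FALSE) {
  if (!is.finite(omega_bar) || omega_bar >= 1)
    stop("undefined estimate: omega_bar must be < 1")
  if (T <= 0) stop("T must be > 0")
  raw <- T * (omega1 - omega_bar) / (1 - omega_bar)
  t_n <- min(max(raw, 0), T)
  structure(list(T = T, t_n = t_n, t_n_raw = raw, omega1 = omega1,
                 omega_bar = omega_bar, ka1 = ka1, ks1 = ks1,
                 r_s1 = if (is.na(ks1)) NA_real_ else ks1 / T,
                 clamped = raw < 0 || raw > T, caution = few_species),
            class = "tn_estimate")
}

#' @export
print.tn_estimate <- function(x, ...) {
  cat(sprintf("<tn_estimate> T_N = %.3f MY (T = %.2f, omega1 = %.3f, omega_bar = %.3f)%s%s\n",
              x$t_n, x$T, x$omega1, x$omega_bar,
              if (x$clamped) " [clamped]" else "",
              if (x$caution) " [few species: view with caution]" else ""))
  invisible(x)
}

#' Date a focal-lineage pseudogene from a codon alignment
#'
#' Convenience wrapper: reconstructs ancestors, computes per-branch Ka/Ks,
#' takes `omega1` from the focal terminal branch and `omega_bar` as the
#' unweighted mean of defined omega values over all other branches (or a
#' fixed constrained background such as 0.12), and returns the T_N
#' estimate.
#'
#' @param aln Named character vector of aligned CDS per species.
#' @param tree [dated_tree()] (branch lengths in MY).
#' @param focal Focal tip label (default `"human"`).
#' @param T Focal branch length in MY; defaults to the focal tip's parent
#'   node age.
#' @param omega_bar Fixed background omega, or `NULL` to average the
#'   non-focal branches.
#' @return `list(estimate, rates)` with the [estimate_tn()] object and the
#'   [lineage_omega()] table.
#' @export
date_pseudogene <- function(aln, tree, focal = "human", T = NULL,
                            omega_bar = NULL) {
  phy <- as_phylo(tree)
  rates <- lineage_omega(aln, tree)
  if (is.null(T)) {
    if (!inherits(tree, "dated_tree"))
      stop("T not given and tree carries no node ages")
    tip <- match(focal, phy$tip.label)
    parent <- phy$edge[phy$edge[, 2L] == tip, 1L]
    T <- tree$ages[parent]
  }
  f <- rates[rates$branch == focal, ]
  if (!nrow(f)) stop("focal species not in tree: ", focal)
  if (is.null(omega_bar)) {
    others <- rates[rates$branch != focal & rates$omega_defined, ]
    omega_bar <- mean(others$omega)
  }
  est <- estimate_tn(f$omega, omega_bar, T = T, ka1 = f$ka, ks1 = f$ks,
                     few_species = length(phy$tip.label) < 4L)
  list(estimate = est, rates = rates)
}
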