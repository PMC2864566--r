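## Codon-level sequence simulation on a dated species tree with a planted
## selection switch: purifying selection (Ka/Ks = omega_constrained) while
## the gene is functional, full neutrality (omega = 1, stop codons allowed)
## after inactivation at T_N on the focal branch, and planted disruptive
## mutations that propagate to every descendant of the switch branch.

#' Default dated primate tree used by the dating simulations
#'
#' Human-chimpanzee split at 6.6 MY, catarrhine crown at 30 MY, split from
#' the New World monkeys at 42.9 MY.
#' @return A [dated_tree()] with tips human, chimp, rhesus, marmoset.
#' @export
primate_tree <- function() {
  dated_tree(ape::read.tree(text =
    "(((human:6.6,chimp:6.6):23.4,rhesus:30):12.9,marmoset:42.9);"))
}

#' Simulate coding sequences on a dated tree with a selection switch
#'
#' Sequences evolve by per-site nucleotide proposals at the neutral rate;
#' synonymous proposals are always accepted, nonsynonymous proposals with
#' probability omega, so the realized Ka/Ks equals omega. While constrained
#' (functional), proposals creating stop codons are rejected; after the
#' planted switch everything is neutral and stops may appear. On the branch
#' leading to `switch_tip`, the switch occurs at age `t_n` (MYA); planted
#' disruptive stop mutations are introduced at the switch and inherited by
#' all descendant leaves.
#'
#' @param tree A [dated_tree()] (branch lengths in MY).
#' @param omega_constrained Ka/Ks under purifying selection (0 < omega < 1,
#'   or 1 for a fully neutral control).
#' @param codon_count Number of codons.
#' @param neutral_rate Neutral substitutions per site per MY.
#' @param switch_tip Tip label, or internal node label `"node<N>"`, naming
#'   the branch carrying the inactivation; `NULL` for no switch.
#' @param t_n Age (MYA) of the inactivation on that branch; must lie within
#'   the branch's age span.
#' @param n_disruptions Premature-stop mutations planted at the switch.
#' @param seed Integer seed.
#' @return `list(alignment, tree, truth)`; `alignment` is a named character
#'   vector of leaf CDS, `truth` records the switch branch and ages and the
#'   sharing pattern of the planted disruptions.
#' @export
simulate_codon_phylogeny <- function(tree, omega_constrained = 0.12,
                                     codon_count = 500L,
                                     neutral_rate = 0.002,
                                     switch_tip = NULL, t_n = 0,
                                     n_disruptions = 0L, seed = 1L) {
  stopifnot(inherits(tree, "dated_tree"))
  if (omega_constrained <= 0 || omega_constrained > 1)
    stop("omega_constrained must be in (0, 1]")
  set.seed(as.integer(seed))
  phy <- tree$tree
  ntip <- length(phy$tip.label)
  labs <- c(phy$tip.label, paste0("node", (ntip + 1L):(ntip + phy$Nnode)))
  switch_node <- if (is.null(switch_tip)) NA_integer_ else match(switch_tip, labs)
  if (!is.null(switch_tip) && is.na(switch_node))
    stop("unknown switch branch: ", switch_tip)
  if (!is.null(switch_tip)) {
    edge <- which(phy$edge[, 2L] == switch_node)
    top <- tree$ages[phy$edge[edge, 1L]]; bot <- tree$ages[switch_node]
    if (t_n > top || t_n < bot)
      stop(sprintf("t_n = %g outside the switch branch age span [%g, %g]",
                   t_n, bot, top))
  }
  root_seq <- unlist(strsplit(c("ATG", sample(SENSE_CODONS, codon_count - 1L,
                                              replace = TRUE)), ""))
  tb <- get_align_tables()
  translate1 <- function(cod) tb$codon_to_aa[[paste(cod, collapse = "")]]
  evolve <- function(seq, t, omega, allow_stops) {
    L <- length(seq)
    n_prop <- rpois(1L, neutral_rate * L * t)
    if (n_prop == 0L) return(seq)
    sites <- sample.int(L, n_prop, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    for (s in sites) {
      new <- sample(setdiff(bases, seq[s]), 1L)
      ci <- (s - 1L) %/% 3L
      cod <- seq[(3L * ci + 1L):(3L * ci + 3L)]
      cod2 <- cod; cod2[(s - 1L) %% 3L + 1L] <- new
      aa1 <- translate1(cod); aa2 <- translate1(cod2)
      if (aa2 == "*" && !allow_stops) next
      if (identical(aa1, aa2)) { seq[s] <- new; next }
      if (runif(1L) < omega) seq[s] <- new
    }
    seq
  }
  ## depth-first simulation from the root
  seqs <- vector("list", ntip + phy$Nnode)
  root <- ntip + 1L
  seqs[[root]] <- root_seq
  neutral_below <- logical(ntip + phy$Nnode)
  disruption_codons <- integer()
  order_edges <- ape::reorder.phylo(phy, "cladewise")$edge
  for (e in seq_len(nrow(order_edges))) {
    p <- order_edges[e, 1L]; ch <- order_edges[e, 2L]
    t_top <- tree$ages[p]; t_bot <- tree$ages[ch]
    s <- seqs[[p]]
    if (neutral_below[p]) {
      s <- evolve(s, t_top - t_bot, 1, TRUE)
      neutral_below[ch] <- TRUE
    } else if (!is.na(switch_node) && ch == switch_node) {
      s <- evolve(s, t_top - t_n, omega_constrained, FALSE)
      if (n_disruptions > 0L) {
        cand <- setdiff(seq_len(length(s) %/% 3L), 1L)
        disruption_codons <- sort(sample(cand, n_disruptions))
        for (ci in disruption_codons) {
          stop_cod <- strsplit(sample(c("TAA", "TAG", "TGA"), 1L), "")[[1L]]
          s[(3L * ci - 2L):(3L * ci)] <- stop_cod
        }
      }
      s <- evolve(s, t_n - t_bot, 1, TRUE)
      neutral_below[ch] <- TRUE
    } else {
      s <- evolve(s, t_top - t_bot, omega_constrained, FALSE)
    }
    seqs[[ch]] <- s
  }
  aln <- setNames(vapply(seq_len(ntip), function(i)
    paste(seqs[[i]], collapse = ""), ""), phy$tip.label)
  desc <- if (is.na(switch_node)) character() else {
    if (switch_node <= ntip) labs[switch_node]
    else ape::extract.clade(phy, switch_node)$tip.label
  }
  pattern <- setNames(ifelse(phy$tip.label %in% desc, "present", "absent"),
                      phy$tip.label)
  list(alignment = aln, tree = tree,
       truth = list(switch_branch = switch_tip, t_n = t_n,
                    omega_constrained = omega_constrained,
                    disruption_codons = disruption_codons,
                    pattern = if (is.null(switch_tip)) NULL else pattern))
}
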