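# shared fixture builders; everything is generated in code under fixed seeds

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

mutate_fraction <- function(seq, frac) {
  s <- strsplit(seq, "")[[1]]
  k <- round(frac * length(s))
  idx <- sample(length(s), k)
  s[idx] <- vapply(s[idx], function(a) sample(setdiff(AA, a), 1L), character(1))
  paste(s, collapse = "")
}

# additive distance matrix from a random binary tree with positive lengths
random_additive <- function(ntaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, br = function(n) runif(n, 0.2, 2))
  D <- cophenetic(tr)
  D <- D[sort(rownames(D)), sort(colnames(D))]
  list(tree = tr, D = D)
}

# independent Dollo oracle: exhaustive search over internal-state
# assignments with exactly one gain (0->1 transition, counting a present
# root as a gain at the root edge)
dollo_oracle <- function(presence, tree) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  parents <- po$edge[, 1]; children <- po$edge[, 2]
  states <- matrix(0L, nrow = 2^nint, ncol = ntip + nint)
  for (j in seq_len(nint)) {
    states[, ntip + j] <- rep(rep(0:1, each = 2^(j - 1)), length.out = 2^nint)
  }
  states[, seq_len(ntip)] <- matrix(rep(as.integer(presence), each = 2^nint),
                                    nrow = 2^nint)
  changes <- matrix(0L, nrow = 2^nint, ncol = length(parents))
  gains <- integer(2^nint)
  for (e in seq_along(parents)) {
    d <- states[, children[e]] - states[, parents[e]]
    changes[, e] <- abs(d)
    gains <- gains + as.integer(d == 1L)
  }
  root <- ntip + 1L
  gains <- gains + states[, root]
  events <- rowSums(changes) + states[, root]
  feasible <- gains == 1L
  if (!any(feasible)) return(NA_integer_)
  min(events[feasible])
}

scan_seed_queries <- function() {
  p <- default_root_profiles()
  tibble::tibble(query_id = c("seed_nonTALE", "seed_TALE"),
                 seq = c(p$nonTALE, p$TALE))
}

# truth-vs-hits recovery summary used by search and acceptance tests
recovery_summary <- function(sim, result, codon_tol = 2L) {
  tr <- sim$truth
  hits <- result$hits
  nt_tol <- 3L * codon_tol
  intact_tr <- tr[tr$intact == "intact", ]
  recovered <- vapply(seq_len(nrow(intact_tr)), function(i) {
    r <- intact_tr[i, ]
    any(hits$source_id == r$scaffold_id & hits$strand == r$strand &
          hits$frame == r$frame & hits$intactness == "intact" &
          abs(hits$nt_start - r$hd_start_nt) <= nt_tol &
          abs(hits$nt_end - r$hd_end_nt) <= nt_tol)
  }, logical(1))
  ih <- hits[hits$intactness == "intact", ]
  false_pos <- vapply(seq_len(nrow(ih)), function(i) {
    h <- ih[i, ]
    !any(tr$scaffold_id == h$source_id & tr$strand == h$strand &
           tr$frame == h$frame & abs(tr$hd_start_nt - h$nt_start) <= nt_tol)
  }, logical(1))
  genes <- unique(tr$gene_id)
  arch_truth <- vapply(genes, function(g) {
    rows <- tr[tr$gene_id == g, ]
    if (nrow(rows) == 2L && all(rows$intact == "intact")) "double"
    else if (nrow(rows) == 2L) "double_with_degraded" else "single"
  }, character(1))
  arch_call <- vapply(genes, function(g) {
    h <- hits[hits$source_id == paste0("scf_", g), ]
    if (nrow(h) == 0L) NA_character_ else detect_architecture(h)
  }, character(1))
  list(recovery = mean(recovered), n_intact = length(recovered),
       n_false_pos = sum(false_pos),
       arch_agreement = mean(arch_call == arch_truth, na.rm = TRUE),
       arch_exact = all(!is.na(arch_call)) && all(arch_call == arch_truth))
}
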