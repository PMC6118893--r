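#' Pairwise amino-acid distances from an alignment
#'
#' Pairwise deletion: for each pair of rows only columns where neither row
#' has a gap are compared (manually edited homeodomain alignments retain
#' gappy rows, so complete-column deletion would discard most sites).
#' `p` is the proportion of mismatches; `poisson` applies the multiple-hit
#' correction `-ln(1 - p)`.
#'
#' @param alignment Tibble (`id`, `seq`) of equal-length aligned rows.
#' @param model `"p"` or `"poisson"`.
#' @param saturation For `poisson` with `p >= 1`: `"error"` (default) or
#'   `"cap"` (replace by the largest resolvable distance,
#'   `-ln(1 / (sites + 1))`; used internally by bootstrap resampling).
#' @return Symmetric numeric matrix with an attached `model` attribute.
#' @export
aa_distance <- function(alignment, model = c("p", "poisson"),
                        saturation = c("error", "cap")) {
  model <- match.arg(model)
  saturation <- match.arg(saturation)
  if (nrow(alignment) < 2L) abort("alignment needs >= 2 rows")
  if (anyDuplicated(alignment$id)) abort("duplicate alignment ids")
  if (length(unique(nchar(alignment$seq))) != 1L)
    abort("alignment rows differ in length")
  M <- do.call(rbind, strsplit(toupper(alignment$seq), ""))
  rownames(M) <- alignment$id
  nongap <- M != "-" & M != "."
  compared <- tcrossprod(nongap * 1L)
  letters_seen <- setdiff(unique(as.vector(M)), c("-", "."))
  matches <- matrix(0L, nrow(M), nrow(M))
  for (a in letters_seen) {
    ind <- (M == a) * 1L
    matches <- matches + tcrossprod(ind)
  }
  zero <- which(compared == 0 & upper.tri(compared), arr.ind = TRUE)
  if (nrow(zero) > 0) {
    abort(paste0("no comparable columns for pair: ",
                 alignment$id[zero[1, 1]], " / ", alignment$id[zero[1, 2]]))
  }
  p <- (compared - matches) / compared
  if (model == "poisson") {
    sat <- p >= 1
    if (any(sat)) {
      if (saturation == "error") {
        w <- which(sat & upper.tri(sat), arr.ind = TRUE)
        abort(paste0("saturated distance (p >= 1) for pair: ",
                     alignment$id[w[1, 1]], " / ", alignment$id[w[1, 2]]))
      }
      p[sat] <- 1 - 1 / (ncol(M) + 1)
    }
    d <- -log(1 - p)
  } else d <- p
  diag(d) <- 0
  dimnames(d) <- list(alignment$id, alignment$id)
  attr(d, "model") <- model
  d
}

# recursive cluster structure -> ape phylo
cluster_to_phylo <- function(root) {
  tips <- character(0)
  count_tips <- function(n) {
    if (is.null(n$children)) tips <<- c(tips, n$label)
    else for (c in n$children) count_tips(c)
  }
  count_tips(root)
  ntip <- length(tips)
  n_internal <- 0L
  count_int <- function(n) {
    if (!is.null(n$children)) {
      n_internal <<- n_internal + 1L
      for (c in n$children) count_int(c)
    }
  }
  count_int(root)
  edge <- matrix(0L, 0, 2)
  edge_len <- numeric(0)
  next_internal <- ntip + 1L
  assign_ids <- function(n) {
    if (is.null(n$children)) return(match(n$label, tips))
    my_id <- next_internal
    next_internal <<- next_internal + 1L
    for (i in seq_along(n$children)) {
      cid <- assign_ids(n$children[[i]])
      edge <<- rbind(edge, c(my_id, cid))
      edge_len <<- c(edge_len, n$lens[i])
    }
    my_id
  }
  assign_ids(root)
  tr <- list(edge = edge, edge.length = edge_len, tip.label = tips,
             Nnode = n_internal)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration with deterministic tie-breaking:
#' equal Q values are resolved toward the pair whose clusters contain the
#' lexicographically smallest leaf ids. Negative branch lengths are clamped
#' to zero with the deficit moved to the sister edge, preserving the path
#' length between the joined clusters.
#'
#' @param D Symmetric distance matrix with row/column names (>= 3 taxa).
#' @return Unrooted `ape::phylo` with branch lengths.
#' @export
neighbor_joining <- function(D) {
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    abort("distance matrix is not symmetric")
  n <- nrow(D)
  if (n < 3L) abort("neighbor joining needs >= 3 taxa")
  labels <- rownames(D)
  clusters <- purrr::map(labels, function(l) list(label = l))
  ids <- labels  # lexicographic representative per cluster (min leaf label)
  Dm <- D
  while (length(clusters) > 3L) {
    r <- nrow(Dm)
    Rs <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(Rs, Rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    keys <- apply(cand, 1L, function(ij) {
      pair <- sort(c(ids[ij[1]], ids[ij[2]]))
      paste(pair, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- Dm[i, j]
    li <- dij / 2 + (Rs[i] - Rs[j]) / (2 * (r - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_cluster <- list(children = list(clusters[[i]], clusters[[j]]),
                        lens = c(li, lj))
    dnew <- (Dm[i, ] + Dm[j, ] - dij) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    Dm2 <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                 c(dnew[keep], 0))
    clusters <- c(clusters[keep], list(new_cluster))
    ids <- c(ids[keep], min(ids[c(i, j)]))
    Dm <- Dm2
  }
  # final three clusters: three-point formulas
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  lens <- pmax(c(l1, l2, l3), 0)
  root <- list(children = clusters, lens = lens)
  cluster_to_phylo(root)
}

#' Canonical bipartitions (splits) of a tree
#'
#' One bipartition per internal edge; rooted trees are treated as unrooted.
#' The canonical key of a split is the sorted leaf set of the side *not*
#' containing the globally smallest leaf id, so identical splits hash
#' identically regardless of rotation or root placement.
#'
#' @param tree An `ape::phylo` with >= 4 leaves.
#' @param dedupe Drop duplicate keys (the two root-adjacent edges of a
#'   rooted binary tree describe one unrooted split). Internal callers that
#'   need every node keep duplicates and resolve them by label.
#' @return Tibble: `key` (leaf ids joined by `;`), `size` (leaves on the
#'   key side), and `node` (child node of the edge in the input tree).
#' @export
bipartitions <- function(tree, dedupe = TRUE) {
  if (anyDuplicated(tree$tip.label))
    abort(paste0("duplicate leaf ids: ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  ntip <- length(tree$tip.label)
  if (ntip < 4L) abort("bipartitions need >= 4 leaves")
  anchor <- min(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  tr <- tree
  # descendants per internal node via postorder accumulation
  po <- ape::reorder.phylo(tr, "postorder")
  below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; c <- po$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  root <- ntip + 1L
  out <- list()
  for (node in (ntip + 1L):(ntip + tr$Nnode)) {
    if (node == root) next
    side <- sort(below[[node]])
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (anchor %in% side) side <- setdiff(all_tips, side)
    out[[length(out) + 1L]] <- tibble(key = paste(side, collapse = ";"),
                                      size = length(side), node = node)
  }
  if (length(out) == 0L)
    return(tibble(key = character(0), size = integer(0), node = integer(0)))
  out <- bind_rows(out)
  if (dedupe) out <- distinct(out, .data$key, .keep_all = TRUE)
  out
}

#' Bootstrap support for bipartitions of a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement; a tree is built per
#' replicate and every nontrivial bipartition's occurrences counted.
#' Saturated Poisson distances within a replicate are capped rather than
#' raising an error, so all replicates complete.
#'
#' @param alignment Tibble (`id`, `seq`), >= 4 rows.
#' @param model Distance model passed to [aa_distance()].
#' @param replicates Number of bootstrap replicates (survey convention
#'   1000).
#' @param seed Integer seed; identical seeds give identical counts.
#' @return List: `tree` (NJ tree on the original alignment), `support`
#'   (tibble `key`, `count`), `replicates`.
#' @export
bootstrap_support <- function(alignment, model = "poisson",
                              replicates = 1000L, seed = 1L) {
  if (nrow(alignment) < 4L) abort("bootstrap needs >= 4 rows")
  if (replicates < 1L) abort("replicates must be >= 1")
  L <- nchar(alignment$seq[1])
  base_tree <- neighbor_joining(aa_distance(alignment, model,
                                            saturation = "cap"))
  counts <- new.env(parent = emptyenv())
  with_seed(seed, {
    chars <- strsplit(alignment$seq, "")
    M <- do.call(rbind, chars)
    for (b in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      res <- alignment
      res$seq <- apply(M[, cols, drop = FALSE], 1L, paste, collapse = "")
      tr <- neighbor_joining(aa_distance(res, model, saturation = "cap"))
      for (k in bipartitions(tr)$key) {
        counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
      }
    }
  })
  keys <- ls(counts)
  support <- tibble(key = keys,
                    count = unname(vapply(keys, function(k) counts[[k]],
                                          integer(1))))
  list(tree = base_tree, support = arrange(support, dplyr::desc(.data$count)),
       replicates = as.integer(replicates))
}

#' Root a tree on an outgroup leaf
#'
#' The root is placed at the midpoint of the outgroup's pendant edge;
#' ingroup topology (and the unrooted bipartition set) is unchanged.
#'
#' @param tree Unrooted `ape::phylo`.
#' @param outgroup_id A leaf label.
#' @return Rooted `ape::phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup_id) {
  if (!outgroup_id %in% tree$tip.label)
    abort(paste0("unknown outgroup id: ", outgroup_id))
  tip <- match(outgroup_id, tree$tip.label)
  pend <- which(tree$edge[, 2] == tip)
  plen <- tree$edge.length[pend]
  rooted <- ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE)
  ntip <- length(rooted$tip.label)
  root <- ntip + 1L
  tip2 <- match(outgroup_id, rooted$tip.label)
  e_out <- which(rooted$edge[, 1] == root & rooted$edge[, 2] == tip2)
  e_in <- which(rooted$edge[, 1] == root & rooted$edge[, 2] != tip2)
  if (length(e_out) == 1L && length(e_in) == 1L) {
    rooted$edge.length[e_out] <- plen / 2
    rooted$edge.length[e_in] <- rooted$edge.length[e_in] + plen / 2
  }
  rooted
}
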