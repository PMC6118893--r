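ABSENT <- NA_real_

#' Format / parse a support triplet
#'
#' The figure-annotation dialect: neighbor-joining bootstrap count,
#' maximum-likelihood bootstrap percentage and Bayesian posterior
#' probability, in that order, separated by vertical bars; a dash marks a
#' slot whose node is not present in the corresponding tree.
#'
#' @param nj Bootstrap count (integer) or `NA`.
#' @param ml Bootstrap percentage (integer) or `NA`.
#' @param bayes Posterior probability in `[0, 1]` or `NA`.
#' @return `format_support()`: a string like `"886|72|0.99"` or
#'   `"-|-|-"`. `parse_support()`: a list with `nj`, `ml`, `bayes`.
#' @export
format_support <- function(nj, ml, bayes) {
  f <- function(x, fmt) if (is.na(x)) "-" else sprintf(fmt, x)
  paste(f(nj, "%d"), f(ml, "%d"), f(bayes, "%.2f"), sep = "|")
}

#' @rdname format_support
#' @param x A triplet string.
#' @export
parse_support <- function(x) {
  parts <- strsplit(x, "|", fixed = TRUE)[[1]]
  if (length(parts) != 3L) abort(paste0("malformed support triplet: ", x))
  num <- function(s) if (s == "-") NA_real_ else as.numeric(s)
  list(nj = if (parts[1] == "-") NA_integer_ else as.integer(parts[1]),
       ml = if (parts[2] == "-") NA_integer_ else as.integer(parts[2]),
       bayes = num(parts[3]))
}

# one support value per unrooted split; where the two root-adjacent edges
# duplicate a split, the labelled copy wins
source_support_map <- function(tree) {
  bp <- bipartitions(tree, dedupe = FALSE)
  if (is.null(tree$node.label)) {
    bp$value <- NA_real_
  } else {
    ntip <- length(tree$tip.label)
    labs <- tree$node.label[bp$node - ntip]
    bp$value <- suppressWarnings(as.numeric(labs))
  }
  bp <- bp[order(is.na(bp$value)), ]
  distinct(bp, .data$key, .keep_all = TRUE)
}

#' Map support values from several phylogenies onto a target tree
#'
#' For every internal edge of the target, each source analysis contributes
#' its native support when the source tree contains the same canonical
#' (unrooted) bipartition; otherwise the slot is marked absent. Node
#' equivalence by unrooted bipartition makes the mapping robust to the
#' sources' differing root conventions. A source polytomy matches no
#' resolved target edge inside it.
#'
#' @param target Rooted target tree (`ape::phylo`); its own node labels are
#'   used for `target_slot` unless that source is supplied explicitly.
#' @param nj,ml,bayes Source trees whose node labels carry, respectively,
#'   bootstrap counts, bootstrap percentages and posterior probabilities.
#'   Any may be `NULL`.
#' @param target_slot Which slot the target's own labels fill
#'   (conventionally the target is the Bayesian tree).
#' @param nj_replicates Bootstrap replicates behind the NJ counts (for
#'   normalisation to percent).
#' @param prune_to_common Prune all trees to their common leaf set instead
#'   of erroring on a mismatch (logged via `message()`).
#' @return An `hb_annotated_tree`: list with `tree` (target, node labels
#'   rewritten as formatted triplets), `supports` (tibble: `node`, `key`,
#'   `nj`, `ml`, `bayes`), `nj_replicates`.
#' @export
transfer_support <- function(target, nj = NULL, ml = NULL, bayes = NULL,
                             target_slot = c("bayes", "nj", "ml"),
                             nj_replicates = 1000L,
                             prune_to_common = FALSE) {
  target_slot <- match.arg(target_slot)
  sources <- list(nj = nj, ml = ml, bayes = bayes)
  supplied <- names(sources)[!vapply(sources, is.null, logical(1))]
  tgt_leaves <- sort(target$tip.label)
  for (s in supplied) {
    src_leaves <- sort(sources[[s]]$tip.label)
    if (!identical(tgt_leaves, src_leaves)) {
      diff <- c(setdiff(tgt_leaves, src_leaves),
                setdiff(src_leaves, tgt_leaves))
      if (!prune_to_common)
        abort(paste0("leaf sets of target and ", s, " tree differ: ",
                     paste(diff, collapse = ", ")))
      common <- intersect(tgt_leaves, src_leaves)
      message("pruning to ", length(common), " common leaves (",
              paste(diff, collapse = ", "), " dropped)")
      target <- ape::keep.tip(target, intersect(target$tip.label, common))
      sources[supplied] <- purrr::map(sources[supplied], function(tr)
        ape::keep.tip(tr, intersect(tr$tip.label, common)))
      tgt_leaves <- sort(target$tip.label)
    }
  }
  maps <- purrr::map(sources[supplied], source_support_map)
  tbp <- bipartitions(target, dedupe = FALSE)
  ntip <- length(target$tip.label)
  own_all <- if (!is.null(target$node.label)) {
    suppressWarnings(as.numeric(target$node.label[tbp$node - ntip]))
  } else rep(NA_real_, nrow(tbp))
  tbp$own <- own_all
  tbp <- distinct(tbp[order(is.na(tbp$own)), ], .data$key, .keep_all = TRUE)
  tbp <- arrange(tbp, .data$node)
  own <- tbp$own
  slot_value <- function(slot, key) {
    if (!is.null(maps[[slot]])) {
      v <- maps[[slot]]$value[match(key, maps[[slot]]$key)]
      return(ifelse(is.na(v), ABSENT, v))
    }
    if (slot == target_slot) return(own[match(key, tbp$key)])
    rep(ABSENT, length(key))
  }
  supports <- tibble(node = tbp$node, key = tbp$key,
                     nj = slot_value("nj", tbp$key),
                     ml = slot_value("ml", tbp$key),
                     bayes = slot_value("bayes", tbp$key))
  out <- structure(list(tree = target, supports = supports,
                        nj_replicates = as.integer(nj_replicates)),
                   class = "hb_annotated_tree")
  out$tree$node.label <- annotated_labels(out)
  out
}

annotated_labels <- function(atree) {
  ntip <- length(atree$tree$tip.label)
  labs <- rep("", atree$tree$Nnode)
  for (i in seq_len(nrow(atree$supports))) {
    s <- atree$supports[i, ]
    labs[s$node - ntip] <- format_support(
      if (is.na(s$nj)) NA else as.integer(round(s$nj)),
      if (is.na(s$ml)) NA else as.integer(round(s$ml)),
      s$bayes)
  }
  labs
}

#' Normalised (percent-scale) supports of an annotated tree
#'
#' NJ counts are divided by `nj_replicates / 100`, ML percentages kept,
#' posteriors multiplied by 100. Values are stored unnormalised and only
#' converted here, at comparison time.
#'
#' @param atree An `hb_annotated_tree`.
#' @return Tibble: `node`, `key`, `nj_pct`, `ml_pct`, `bayes_pct`.
#' @export
normalized_supports <- function(atree) {
  atree$supports %>%
    mutate(nj_pct = .data$nj / (atree$nj_replicates / 100),
           ml_pct = .data$ml,
           bayes_pct = .data$bayes * 100) %>%
    select("node", "key", "nj_pct", "ml_pct", "bayes_pct")
}

#' Write / read an annotated tree as Newick with triplet node labels
#'
#' The triplet string is stored as a quoted internal-node label, so the
#' file round-trips through any Newick-aware tool.
#'
#' @param atree An `hb_annotated_tree`.
#' @param path File path.
#' @export
write_annotated_newick <- function(atree, path) {
  write_newick(atree$tree, path)
  invisible(path)
}

#' @rdname write_annotated_newick
#' @param nj_replicates Bootstrap replicate count behind the NJ slot.
#' @export
read_annotated_newick <- function(path, nj_replicates = 1000L) {
  tr <- read_newick(path)
  ntip <- length(tr$tip.label)
  bp <- bipartitions(tr)
  labs <- tr$node.label[bp$node - ntip]
  parsed <- purrr::map(labs, function(l) {
    if (is.na(l) || l == "" ) list(nj = NA_integer_, ml = NA_integer_,
                                   bayes = NA_real_)
    else parse_support(l)
  })
  supports <- tibble(node = bp$node, key = bp$key,
                     nj = as.numeric(purrr::map_dbl(parsed, function(p)
                       as.numeric(p$nj))),
                     ml = as.numeric(purrr::map_dbl(parsed, function(p)
                       as.numeric(p$ml))),
                     bayes = purrr::map_dbl(parsed, "bayes"))
  structure(list(tree = tr, supports = supports,
                 nj_replicates = as.integer(nj_replicates)),
            class = "hb_annotated_tree")
}

#' @export
print.hb_annotated_tree <- function(x, ...) {
  cat("<hb_annotated_tree>", length(x$tree$tip.label), "leaves,",
      nrow(x$supports), "annotated splits\n")
  n_abs <- colSums(is.na(x$supports[, c("nj", "ml", "bayes")]))
  cat("  absent slots: nj", n_abs[["nj"]], "| ml", n_abs[["ml"]],
      "| bayes", n_abs[["bayes"]], "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hb_annotated_tree <- function(x, ...) normalized_supports(x)
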