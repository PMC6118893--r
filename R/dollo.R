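#' Collapse a presence/absence matrix to taxon groups
#'
#' Group presence is the OR over member taxa: a gain is marked for a group
#' if the family has been found in any of its species, a loss only if it
#' has been identified in none.
#'
#' @param matrix_ Wide presence tibble: `family` plus one logical/0-1
#'   column per taxon.
#' @param grouping Tibble (`taxon`, `group`) covering all matrix taxa.
#' @return Group-level presence tibble.
#' @export
collapse_taxa <- function(matrix_, grouping) {
  taxa <- setdiff(names(matrix_), "family")
  missing_taxa <- setdiff(taxa, grouping$taxon)
  if (length(missing_taxa) > 0)
    abort(paste0("grouping does not cover: ",
                 paste(missing_taxa, collapse = ", ")))
  if (any(!grouping$group %in% grouping$group[grouping$taxon %in% taxa])) {
    empty <- setdiff(unique(grouping$group),
                     grouping$group[grouping$taxon %in% taxa])
    if (length(empty) > 0)
      abort(paste0("group with zero members: ", paste(empty, collapse = ", ")))
  }
  groups <- unique(grouping$group[grouping$taxon %in% taxa])
  out <- tibble(family = matrix_$family)
  for (g in groups) {
    members <- grouping$taxon[grouping$group == g & grouping$taxon %in% taxa]
    out[[g]] <- rowSums(as.matrix(matrix_[members])) > 0L
  }
  out
}

#' Minimum gain/loss events under Dollo parsimony
#'
#' Each family is constrained to a single gain; losses may follow anywhere
#' below it. The minimum-event reconstruction places the gain at the most
#' recent common ancestor of the taxa carrying the family (ties in total
#' events are broken toward the root, i.e. the earliest origin) and one
#' loss on the edge to every maximal subtree below the gain containing no
#' carrier.
#'
#' @param matrix_ Wide presence tibble (`family` + taxon columns); no
#'   all-absent rows.
#' @param cladogram `ape::phylo` whose leaves are exactly the matrix taxa;
#'   internal nodes may be labelled.
#' @return An `hb_dollo`: list with `events` (tibble: `family`, `node`,
#'   `node_label`, `type`), `per_family` summary and the cladogram.
#' @export
dollo_events <- function(matrix_, cladogram) {
  taxa <- setdiff(names(matrix_), "family")
  if (!setequal(taxa, cladogram$tip.label))
    abort(paste0("matrix taxa and cladogram leaves differ: ",
                 paste(c(setdiff(taxa, cladogram$tip.label),
                         setdiff(cladogram$tip.label, taxa)), collapse = ", ")))
  pres_mat <- as.matrix(matrix_[taxa]) > 0
  if (any(rowSums(pres_mat) == 0L))
    abort(paste0("family absent everywhere: ",
                 paste(matrix_$family[rowSums(pres_mat) == 0L], collapse = ", ")))
  ntip <- length(cladogram$tip.label)
  nnode <- cladogram$Nnode
  root <- ntip + 1L
  po <- ape::reorder.phylo(cladogram, "postorder")
  parent_of <- integer(ntip + nnode)
  for (e in seq_len(nrow(po$edge))) parent_of[po$edge[e, 2]] <- po$edge[e, 1]
  kids <- split(po$edge[, 2], po$edge[, 1])
  node_name <- function(n) {
    if (n <= ntip) return(cladogram$tip.label[n])
    lab <- cladogram$node.label[n - ntip]
    if (is.null(lab) || is.na(lab) || lab == "") paste0("node", n) else lab
  }
  events <- list()
  for (f in seq_len(nrow(matrix_))) {
    present_tips <- match(taxa[pres_mat[f, ]], cladogram$tip.label)
    # carriers below each node (postorder), MRCA = shallowest node whose
    # subtree holds all carriers
    n_below <- integer(ntip + nnode)
    n_below[seq_len(ntip)] <- as.integer(seq_len(ntip) %in% present_tips)
    for (e in seq_len(nrow(po$edge)))
      n_below[po$edge[e, 1]] <- n_below[po$edge[e, 1]] + n_below[po$edge[e, 2]]
    k <- length(present_tips)
    gain <- if (k == 1L) present_tips else {
      v <- present_tips[1]
      while (n_below[v] < k) v <- parent_of[v]
      v
    }
    events[[length(events) + 1L]] <- tibble(
      family = matrix_$family[f], node = gain,
      node_label = node_name(gain), type = "gain")
    if (gain > ntip) {
      # losses: maximal carrier-free subtrees below the gain
      stack <- kids[[as.character(gain)]]
      while (length(stack) > 0) {
        v <- stack[1]; stack <- stack[-1]
        if (n_below[v] == 0L) {
          events[[length(events) + 1L]] <- tibble(
            family = matrix_$family[f], node = v,
            node_label = node_name(v), type = "loss")
        } else if (v > ntip) {
          stack <- c(stack, kids[[as.character(v)]])
        }
      }
    }
  }
  events <- bind_rows(events)
  per_family <- events %>%
    group_by(.data$family) %>%
    summarise(n_gain = sum(.data$type == "gain"),
              n_loss = sum(.data$type == "loss"),
              total = n(), .groups = "drop")
  structure(list(events = events, per_family = per_family,
                 cladogram = cladogram),
            class = "hb_dollo")
}

#' Per-edge summary of gain/loss events
#'
#' @param dollo An `hb_dollo` (see [dollo_events()]) or its `events`
#'   tibble.
#' @return Tibble: `node`, `node_label`, `gains` and `losses` (list
#'   columns of family ids), `n_gain`, `n_loss`.
#' @export
summarize_by_node <- function(dollo) {
  events <- if (inherits(dollo, "hb_dollo")) dollo$events else dollo
  if (nrow(events) == 0L)
    return(tibble(node = integer(0), node_label = character(0),
                  gains = list(), losses = list(),
                  n_gain = integer(0), n_loss = integer(0)))
  events %>%
    group_by(.data$node, .data$node_label) %>%
    summarise(gains = list(sort(.data$family[.data$type == "gain"])),
              losses = list(sort(.data$family[.data$type == "loss"])),
              n_gain = sum(.data$type == "gain"),
              n_loss = sum(.data$type == "loss"),
              .groups = "drop") %>%
    arrange(.data$node)
}

#' @export
print.hb_dollo <- function(x, ...) {
  cat("<hb_dollo>", nrow(x$per_family), "families;",
      sum(x$events$type == "gain"), "gains,",
      sum(x$events$type == "loss"), "losses\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hb_dollo <- function(x, ...) x$events

#' @exportS3Method generics::glance
glance.hb_dollo <- function(x, ...) {
  tibble(n_families = nrow(x$per_family),
         n_gains = sum(x$events$type == "gain"),
         n_losses = sum(x$events$type == "loss"),
         total_events = nrow(x$events))
}

#' @exportS3Method ggplot2::autoplot
autoplot.hb_dollo <- function(object, ...) {
  s <- summarize_by_node(object)
  long <- tidyr::pivot_longer(s[, c("node_label", "n_gain", "n_loss")],
                              c("n_gain", "n_loss"),
                              names_to = "type", values_to = "n")
  long$type <- ifelse(long$type == "n_gain", "gain", "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$node_label, y = .data$n,
                                     fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "cladogram edge (child node)",
                  y = "gene-family events", fill = NULL) +
    ggplot2::theme_minimal()
}
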