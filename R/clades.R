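#' Criteria for calling clades on an annotated tree
#'
#' A node becomes a named clade if any of its normalised support values
#' exceeds the threshold, or if the node was reconstructed in all three
#' analyses (no absent slot), or if it carries structural evidence (e.g.
#' a shared two-homeodomain architecture). Justification records the first
#' satisfied criterion in that order.
#'
#' @param support_threshold Percent threshold (survey convention 70).
#' @param require_strict `TRUE`: strictly greater than the threshold.
#' @param structure_evidence Named character vector: node id (as character)
#'   -> free-text evidence tag.
#' @export
clade_criteria <- function(support_threshold = 70, require_strict = TRUE,
                           structure_evidence = character(0)) {
  if (support_threshold <= 0 || support_threshold >= 100)
    abort("support_threshold must be in (0, 100)")
  structure(list(support_threshold = support_threshold,
                 require_strict = require_strict,
                 structure_evidence = structure_evidence),
            class = "clade_criteria")
}

clade_members <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  sort(tree$tip.label[unlist(phangorn_free_descendants(tree, node))])
}

# tip indices below a node (no phangorn dependency)
phangorn_free_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; c <- po$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  below[node]
}

#' Call clades on an annotated tree
#'
#' @param atree An `hb_annotated_tree` (see [transfer_support()]).
#' @param criteria A [clade_criteria()].
#' @return An `hb_clade_calls` tibble: `node`, `members` (list column),
#'   `n_members`, `justification` (`support`, `all-three` or `structure`),
#'   and the normalised supports. Nested calls are allowed.
#' @export
call_clades <- function(atree, criteria = clade_criteria()) {
  ns <- normalized_supports(atree)
  thr <- criteria$support_threshold
  ev <- criteria$structure_evidence
  rows <- purrr::map(seq_len(nrow(ns)), function(i) {
    s <- ns[i, ]
    vals <- c(s$nj_pct, s$ml_pct, s$bayes_pct)
    over <- if (criteria$require_strict) any(vals > thr, na.rm = TRUE)
            else any(vals >= thr, na.rm = TRUE)
    just <- if (over) "support"
            else if (!anyNA(vals)) "all-three"
            else if (as.character(s$node) %in% names(ev)) "structure"
            else NA_character_
    if (is.na(just)) return(NULL)
    members <- clade_members(atree$tree, s$node)
    n_mem <- length(members)
    tibble(node = s$node, members = list(members),
           n_members = n_mem, justification = just,
           nj_pct = s$nj_pct, ml_pct = s$ml_pct, bayes_pct = s$bayes_pct)
  })
  rows <- purrr::keep(rows, Negate(is.null))
  empty <- tibble(node = integer(0), members = list(),
                  n_members = integer(0), justification = character(0),
                  nj_pct = numeric(0), ml_pct = numeric(0),
                  bayes_pct = numeric(0))
  out <- if (length(rows) == 0L) empty else
    bind_rows(rows[order(purrr::map_int(rows, function(r) r$node))])
  class(out) <- c("hb_clade_calls", class(out))
  out
}

roman_index <- function(clade, prefix) {
  x <- sub(paste0("^", prefix, "-"), "", clade)
  suppressWarnings(as.integer(utils::as.roman(x)))
}

#' Reconcile clade calls against a prior nomenclature registry
#'
#' Each called clade is matched to at most one prior clade by Jaccard
#' overlap (> `match_threshold`) over previously classified members.
#' Member outcomes: `unchanged` (already in the matched clade),
#' `reclassified` (previously classified elsewhere; the prior name is
#' recorded), `added` (never classified; origin `N`). Calls matching no
#' prior clade erect a new clade named with the next unused Roman numeral
#' of the series; retired numerals are never reused.
#'
#' @param calls An `hb_clade_calls` tibble (or any tibble with a `members`
#'   list column).
#' @param prior Prior registry tibble (`clade`, `species`, `sequence`,
#'   `letter`, `origin`, `prior`).
#' @param member_species Optional tibble (`sequence`, `species`) naming the
#'   species of sequences absent from the prior registry.
#' @param series_prefix Clade-name prefix, e.g. `"TALE"`.
#' @param match_threshold Jaccard threshold for prior-clade matching.
#' @return An `hb_revision`: list with `registry` (updated), `report`
#'   (per-sequence outcomes) and `tallies`.
#' @export
reconcile_registry <- function(calls, prior, member_species = NULL,
                               series_prefix = "TALE",
                               match_threshold = 0.5) {
  prior_clades <- split(prior$sequence, prior$clade)
  classified <- unique(prior$sequence)
  species_of <- setNames(prior$species, prior$sequence)
  if (!is.null(member_species))
    species_of <- c(species_of,
                    setNames(member_species$species, member_species$sequence))
  used_idx <- roman_index(unique(prior$clade), series_prefix)
  next_idx <- if (all(is.na(used_idx))) 1L else max(used_idx, na.rm = TRUE) + 1L

  registry <- prior
  report <- list()
  for (i in seq_len(nrow(calls))) {
    members <- calls$members[[i]]
    cm <- intersect(members, classified)
    jac <- purrr::map_dbl(prior_clades, function(pc) {
      u <- union(cm, pc)
      if (length(u) == 0L) return(0)
      length(intersect(cm, pc)) / length(u)
    })
    hit <- names(jac)[jac > match_threshold]
    if (length(hit) > 1L)
      abort(paste0("called clade matches several prior clades: ",
                   paste(hit, collapse = ", ")))
    if (length(hit) == 1L) {
      clade_name <- hit
      is_new_clade <- FALSE
    } else {
      clade_name <- paste0(series_prefix, "-",
                           as.character(utils::as.roman(next_idx)))
      next_idx <- next_idx + 1L
      is_new_clade <- TRUE
    }
    for (m in members) {
      old <- registry$clade[registry$sequence == m]
      if (length(old) == 1L && old == clade_name) {
        outcome <- "unchanged"
      } else if (length(old) == 1L) {
        outcome <- "reclassified"
        registry$prior[registry$sequence == m] <- old
        registry$clade[registry$sequence == m] <- clade_name
        registry$letter[registry$sequence == m] <- ""
      } else {
        outcome <- "added"
        registry <- bind_rows(registry, tibble(
          clade = clade_name,
          species = if (m %in% names(species_of)) species_of[[m]]
                    else "unknown",
          sequence = m, letter = "", origin = "N", prior = "NONE"))
      }
      report[[length(report) + 1L]] <- tibble(
        sequence = m, clade = clade_name, outcome = outcome,
        new_clade = is_new_clade,
        prior_clade = if (length(old) == 1L) old else NA_character_)
    }
  }
  report <- if (length(report)) bind_rows(report) else
    tibble(sequence = character(0), clade = character(0),
           outcome = character(0), new_clade = logical(0),
           prior_clade = character(0))
  gained <- report %>%
    filter(!.data$new_clade,
           .data$outcome %in% c("added", "reclassified"),
           is.na(.data$prior_clade) | .data$prior_clade != .data$clade) %>%
    pull(.data$clade) %>% unique()
  lost <- report %>%
    filter(.data$outcome == "reclassified") %>%
    pull(.data$prior_clade) %>% unique()
  lost <- setdiff(lost, NA)
  tallies <- list(
    new_clades = length(unique(report$clade[report$new_clade])),
    clades_with_additions = length(gained),
    clades_losing_members = length(lost))
  structure(list(registry = registry, report = report, tallies = tallies),
            class = "hb_revision")
}

#' @export
print.hb_revision <- function(x, ...) {
  cat("<hb_revision>\n")
  cat("  new clades:            ", x$tallies$new_clades, "\n")
  cat("  clades with additions: ", x$tallies$clades_with_additions, "\n")
  cat("  clades losing members: ", x$tallies$clades_losing_members, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hb_revision <- function(x, ...) x$report

#' @exportS3Method generics::glance
glance.hb_revision <- function(x, ...) {
  tibble(new_clades = x$tallies$new_clades,
         clades_with_additions = x$tallies$clades_with_additions,
         clades_losing_members = x$tallies$clades_losing_members,
         sequences_added = sum(x$report$outcome == "added"),
         sequences_reclassified = sum(x$report$outcome == "reclassified"))
}

letter_series <- function(n) {
  single <- LETTERS
  if (n <= 26L) return(single[seq_len(n)])
  double <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(single, double)[seq_len(n)]
}

#' Assign paralogue letters within each clade and species
#'
#' Members sharing a (clade, species) pair are lettered A, B, C, ... in
#' lexicographic order of sequence name; letters carry no orthology claim,
#' so any stable rule suffices and this one is deterministic across runs.
#' Pre-existing letters are preserved and new members continue the series
#' after the highest letter in use. A sequence alone in its (clade,
#' species) group receives no letter. Beyond Z the series continues AA,
#' AB, ...
#'
#' @param registry Registry tibble.
#' @return Registry with the `letter` column filled.
#' @export
assign_letters <- function(registry) {
  registry %>%
    group_by(.data$clade, .data$species) %>%
    mutate(letter = assign_letters_group(.data$sequence, .data$letter)) %>%
    ungroup()
}

assign_letters_group <- function(sequence, letter) {
  letter[is.na(letter)] <- ""
  if (length(sequence) == 1L && letter[1] == "") return("")
  pool <- letter_series(length(sequence) + 26L)
  used <- letter[letter != ""]
  avail <- setdiff(pool, used)
  last <- suppressWarnings(max(match(used, pool), na.rm = TRUE))
  if (is.finite(last)) avail <- avail[match(avail, pool) > last]
  todo <- order(sequence[letter == ""])
  letter[letter == ""][todo] <- avail[seq_len(sum(letter == ""))]
  letter
}

#' Collapse called clades to single labelled tips
#'
#' Each selected clade is replaced by one tip carrying the clade's name;
#' supports of internal collapsed nodes are discarded. Used to condense
#' large clades for reporting.
#'
#' @param tree An `ape::phylo`.
#' @param clades Named list: clade name -> character vector of member
#'   leaf ids. Must be non-overlapping.
#' @return The condensed tree.
#' @export
collapse_clades <- function(tree, clades) {
  if (length(clades) == 0L) return(tree)
  all_members <- unlist(clades)
  if (anyDuplicated(all_members))
    abort("collapse targets overlap")
  out <- tree
  for (nm in names(clades)) {
    members <- clades[[nm]]
    stopifnot(all(members %in% out$tip.label))
    keep_one <- members[1]
    if (length(members) > 1L)
      out <- ape::drop.tip(out, setdiff(members, keep_one))
    out$tip.label[out$tip.label == keep_one] <- nm
  }
  out
}
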