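#' The revised spiralian TALE-class clade registry
#'
#' The package ships the published revision of the spiralian TALE-class
#' homeobox nomenclature as a registry fixture: clades I-XIX plus the
#' unclassified sequences (`TALE-?`), with each sequence's species, origin
#' flag (`N` newly discovered, `P` part of the prior nine-clade system,
#' `M` described in the SPILE literature) and, where a sequence was
#' reclassified, its prior clade.
#'
#' @return A registry tibble (see [read_registry()]).
#' @export
spiralian_tale_registry <- function() {
  read_registry(system.file("extdata", "spiralian_tale_registry.tsv",
                            package = "homeoclass", mustWork = TRUE))
}

#' Reconstruct the prior (pre-revision) registry from a revised one
#'
#' Rows that were part of the prior classification (`origin == "P"`) are
#' returned under their original clade (the `prior` column where recorded).
#' Sequences that were previously unclassified (`prior == "TALE-?"`) are
#' dropped: they carried no prior clade assignment.
#'
#' @param revised A revised registry tibble.
#' @return The prior registry tibble.
#' @export
prior_registry <- function(revised) {
  revised %>%
    filter(.data$origin == "P") %>%
    mutate(clade = ifelse(.data$prior != "NONE", .data$prior, .data$clade)) %>%
    filter(.data$clade != "TALE-?") %>%
    mutate(letter = "", prior = "NONE")
}

#' Clade membership calls implied by a registry
#'
#' One call per named clade (unclassified `TALE-?` sequences form no
#' clade), in registry order, suitable for [reconcile_registry()].
#'
#' @param registry A registry tibble.
#' @return A tibble with `clade` and a `members` list column.
#' @export
registry_calls <- function(registry) {
  named <- filter(registry, .data$clade != "TALE-?")
  clades <- unique(named$clade)
  tibble(clade = clades,
         members = purrr::map(clades, function(cl)
           named$sequence[named$clade == cl]))
}

#' Presence/absence matrix of clades across species, from a registry
#'
#' @param registry A registry tibble.
#' @param species Optional character vector fixing the taxon set (and
#'   column order); defaults to the species present in the registry.
#' @return Wide presence tibble (`family` = clade).
#' @export
registry_presence <- function(registry, species = NULL) {
  named <- filter(registry, .data$clade != "TALE-?")
  if (is.null(species)) species <- sort(unique(named$species))
  clades <- unique(named$clade)
  out <- tibble(family = clades)
  for (sp in species) {
    out[[sp]] <- vapply(clades, function(cl)
      any(named$species == sp & named$clade == cl), logical(1))
  }
  out
}
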