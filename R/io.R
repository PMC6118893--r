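#' Read and write the file formats used across the pipeline
#'
#' `parse_formats()` is a strict dispatcher over the formats every stage
#' exchanges: plain and aligned FASTA, Newick (including node labels holding
#' quoted support triplets), the clade registry TSV and presence/absence
#' matrix TSV. Writers are round-trip stable: `write` followed by `read`
#' reproduces the object exactly.
#'
#' @param path File path.
#' @param kind One of `"fasta"`, `"aligned_fasta"`, `"newick"`,
#'   `"annotated_newick"`, `"tsv_registry"`, `"tsv_matrix"`.
#' @return A tibble of sequences (`id`, `seq`), an `ape::phylo`, a registry
#'   tibble, or a presence-matrix tibble, depending on `kind`.
#' @export
parse_formats <- function(path, kind = c("fasta", "aligned_fasta", "newick",
                                         "annotated_newick", "tsv_registry",
                                         "tsv_matrix")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  switch(kind,
    fasta = read_fasta(path),
    aligned_fasta = read_fasta(path, aligned = TRUE),
    newick = read_newick(path),
    annotated_newick = read_newick(path),
    tsv_registry = read_registry(path),
    tsv_matrix = read_presence_matrix(path)
  )
}

#' @rdname parse_formats
#' @param aligned If `TRUE`, require all sequences to share one length.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  lines <- readr::read_lines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort(paste0("empty FASTA file: ", path))
  hdr <- startsWith(lines, ">")
  if (!hdr[1]) abort(paste0(path, ": line 1: expected '>' header"))
  grp <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  if (length(seqs) != length(ids)) abort(paste0(path, ": record without sequence"))
  if (anyDuplicated(ids)) abort(paste0(path, ": duplicate ids: ",
                                       paste(ids[duplicated(ids)], collapse = ", ")))
  out <- tibble(id = ids, seq = unname(toupper(seqs)))
  if (aligned && length(unique(nchar(out$seq))) > 1L)
    abort(paste0(path, ": aligned FASTA rows differ in length"))
  out
}

#' @rdname parse_formats
#' @param x Object to write (sequences tibble, `phylo`, registry or matrix).
#' @param width Line-wrap width for FASTA output.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  chunks <- purrr::map2(x$id, x$seq, function(id, s) {
    body <- substring(s, seq(1L, nchar(s), by = width),
                      pmin(seq(1L, nchar(s), by = width) + width - 1L, nchar(s)))
    c(paste0(">", id), body)
  })
  readr::write_lines(unlist(chunks), path)
  invisible(path)
}

# Newick with support for single-quoted labels (which may contain '|', '-'
# and other characters ape's reader would otherwise choke on): quoted tokens
# are swapped for placeholders before parsing and restored afterwards.
#' @rdname parse_formats
#' @export
read_newick <- function(path) {
  txt <- paste(sub("\r$", "", readr::read_lines(path)), collapse = "")
  parse_newick_string(txt)
}

#' @rdname parse_formats
#' @param text A Newick string.
#' @export
parse_newick_string <- function(text) {
  m <- gregexpr("'[^']*'", text)[[1]]
  labels <- character(0)
  if (m[1] != -1) {
    labels <- regmatches(text, gregexpr("'[^']*'", text))[[1]]
    for (i in seq_along(labels)) {
      text <- sub(labels[i], paste0("HCQUOTE", i, "HC"), text, fixed = TRUE)
    }
    labels <- substr(labels, 2L, nchar(labels) - 1L)
  }
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                 error = function(e) abort(paste0("malformed Newick: ",
                                                  conditionMessage(e))))
  if (is.null(tr)) abort("malformed Newick: parser returned no tree")
  restore <- function(lab) {
    hit <- regmatches(lab, regexec("^HCQUOTE([0-9]+)HC$", lab))
    vapply(seq_along(lab), function(i) {
      g <- hit[[i]]
      if (length(g) == 2L) labels[as.integer(g[2])] else lab[i]
    }, character(1))
  }
  if (!is.null(tr$tip.label)) tr$tip.label <- restore(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- restore(tr$node.label)
  if (anyDuplicated(tr$tip.label))
    abort(paste0("duplicate leaf ids: ",
                 paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                       collapse = ", ")))
  tr
}

#' @rdname parse_formats
#' @export
write_newick <- function(x, path) {
  quote_if <- function(lab) {
    need <- grepl("[][ |():,;']", lab)
    lab[need] <- paste0("'", gsub("'", "''", lab[need]), "'")
    lab
  }
  tr <- x
  tr$tip.label <- quote_if(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- quote_if(tr$node.label)
  readr::write_lines(ape::write.tree(tr), path)
  invisible(path)
}

#' @rdname parse_formats
#' @export
read_registry <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("clade", "species", "sequence", "letter", "origin", "prior")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols) > 0)
    abort(paste0(path, ": registry missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  out <- out %>% mutate(letter = dplyr::coalesce(.data$letter, ""),
                        prior = dplyr::coalesce(.data$prior, "NONE"))
  dup <- out %>% dplyr::count(.data$species, .data$sequence) %>% filter(n > 1L)
  if (nrow(dup) > 0)
    abort(paste0(path, ": duplicate (species, sequence): ",
                 paste(dup$sequence, collapse = ", ")))
  out
}

#' @rdname parse_formats
#' @export
write_registry <- function(x, path) {
  y <- x
  y$letter[is.na(y$letter)] <- ""
  readr::write_tsv(y, path)
  invisible(path)
}

#' @rdname parse_formats
#' @export
read_presence_matrix <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (names(out)[1] != "family") abort(paste0(path, ": first column must be 'family'"))
  taxa <- names(out)[-1]
  out <- out %>% mutate(dplyr::across(dplyr::all_of(taxa), ~ as.logical(as.integer(.x))))
  all_absent <- rowSums(as.matrix(out[taxa])) == 0L
  if (any(all_absent))
    abort(paste0(path, ": families absent from every taxon: ",
                 paste(out$family[all_absent], collapse = ", ")))
  out
}

#' @rdname parse_formats
#' @export
write_presence_matrix <- function(x, path) {
  y <- x
  taxa <- names(y)[-1]
  y <- y %>% mutate(dplyr::across(dplyr::all_of(taxa), as.integer))
  readr::write_tsv(y, path)
  invisible(path)
}
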