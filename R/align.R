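#' Configuration for homeodomain scanning
#'
#' @param scoring_matrix Name of an amino-acid scoring matrix shipped with
#'   Biostrings (`"BLOSUM62"`, `"BLOSUM45"`, `"PAM120"`, ...).
#' @param gap_open,gap_extend Affine gap penalties; a gap of length L costs
#'   `gap_open + gap_extend * L`.
#' @param accept_score Minimum Smith-Waterman score for an accepted hit.
#'   The default (160, BLOSUM62 units) stands in for the expert's manual
#'   inspection of search results: well above the maximum score random
#'   sequence reaches against a 60-aa query at desk-scale corpus sizes,
#'   while comfortably below the score of a true homeodomain at moderate
#'   divergence.
#' @param degraded_floor Scores in `[degraded_floor, accept_score)` mark
#'   degraded homeodomain remnants. Default 0.4 of the acceptance score.
#' @param tale_margin Minimum score difference between the TALE and
#'   non-TALE profile alignments for a confident class call; smaller
#'   differences are `unresolved`.
#' @param max_iterations Cap on recursive search rounds.
#' @param flank_residues Residues excised either side of the homeodomain
#'   (5 for Hox/ParaHox work, 0 otherwise).
#' @param seed Integer seed (reserved; the scan itself is deterministic).
#' @return A validated `scan_config` list.
#' @export
scan_config <- function(scoring_matrix = "BLOSUM62",
                        gap_open = 10,
                        gap_extend = 1,
                        accept_score = 160,
                        degraded_floor = 0.4 * accept_score,
                        tale_margin = 5,
                        max_iterations = 10L,
                        flank_residues = 0L,
                        seed = 1L) {
  if (accept_score <= 0) abort("accept_score must be > 0")
  if (max_iterations < 1L) abort("max_iterations must be >= 1")
  structure(list(scoring_matrix = scoring_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 accept_score = accept_score, degraded_floor = degraded_floor,
                 tale_margin = tale_margin,
                 max_iterations = as.integer(max_iterations),
                 flank_residues = as.integer(flank_residues),
                 seed = as.integer(seed)),
            class = "scan_config")
}

matrix_cache <- new.env(parent = emptyenv())

get_scoring_matrix <- function(name) {
  if (!is.null(matrix_cache[[name]])) return(matrix_cache[[name]])
  ok <- tryCatch({
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    get(name, envir = e)
  }, warning = function(w) NULL, error = function(e) NULL)
  if (is.null(ok) || !is.matrix(ok))
    abort(paste0("unknown scoring matrix: ", name))
  matrix_cache[[name]] <- ok
  ok
}

encode_aa <- function(seq, S) {
  alpha <- rownames(S)
  idx <- match(strsplit(seq, "")[[1]], alpha)
  x <- match("X", alpha)
  if (anyNA(idx)) {
    if (is.na(x)) abort("sequence contains residues absent from the matrix")
    idx[is.na(idx)] <- x
  }
  idx - 1L
}

#' Optimal local alignment of two protein sequences
#'
#' Exact Smith-Waterman alignment under an affine gap model, with
#' deterministic tie-breaking: within a cell, diagonal is preferred over a
#' gap in the target over a gap in the query; among equal-score maxima the
#' alignment with the smallest (target start, query start) wins.
#'
#' @param query,target Protein sequences (strings).
#' @param config A [scan_config()].
#' @return List: `score`, 0-based half-open `q_start`/`q_end`,
#'   `t_start`/`t_end`, and the two `aligned` strings (with `-` gaps).
#' @export
local_align <- function(query, target, config = scan_config()) {
  if (nchar(query) == 0L || nchar(target) == 0L)
    abort("query and target must be non-empty")
  S <- get_scoring_matrix(config$scoring_matrix)
  q <- encode_aa(query, S)
  t <- encode_aa(target, S)
  r <- sw_align_cpp(q, t, S, config$gap_open, config$gap_extend)
  qs <- strsplit(query, "")[[1]]
  ts <- strsplit(target, "")[[1]]
  qa <- rep("-", length(r$q_path))
  qa[r$q_path >= 0] <- qs[r$q_path[r$q_path >= 0] + 1L]
  ta <- rep("-", length(r$t_path))
  ta[r$t_path >= 0] <- ts[r$t_path[r$t_path >= 0] + 1L]
  list(score = r$score,
       q_start = r$q_start, q_end = r$q_end,
       t_start = r$t_start, t_end = r$t_end,
       q_aligned = paste(qa, collapse = ""),
       t_aligned = paste(ta, collapse = ""))
}

#' Recompute an alignment score from its aligned strings
#'
#' Self-consistency check: the score of any reported alignment equals the
#' sum of matrix values over aligned pairs minus affine gap costs.
#'
#' @param q_aligned,t_aligned Gapped aligned strings of equal length.
#' @param config A [scan_config()].
#' @return The alignment score.
#' @export
score_alignment <- function(q_aligned, t_aligned, config = scan_config()) {
  S <- get_scoring_matrix(config$scoring_matrix)
  qa <- strsplit(q_aligned, "")[[1]]
  ta <- strsplit(t_aligned, "")[[1]]
  stopifnot(length(qa) == length(ta))
  score <- 0
  gap_side <- ""   # a gap switching sides opens a new gap
  for (i in seq_along(qa)) {
    if (qa[i] == "-" || ta[i] == "-") {
      side <- if (qa[i] == "-") "q" else "t"
      if (gap_side != side) score <- score - config$gap_open
      score <- score - config$gap_extend
      gap_side <- side
    } else {
      score <- score + S[qa[i], ta[i]]
      gap_side <- ""
    }
  }
  score
}

sw_score <- function(query, target, config) {
  S <- get_scoring_matrix(config$scoring_matrix)
  sw_score_cpp(encode_aa(query, S), encode_aa(target, S), S,
               config$gap_open, config$gap_extend)
}
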