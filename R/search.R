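IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +0, +1, +2 read the forward strand at offsets 0-2; frames -0, -1,
#' -2 read the reverse complement likewise. Stop codons are emitted as `*`;
#' codons containing ambiguity codes translate to `X`.
#'
#' @param seq Nucleotide sequence (IUPAC).
#' @param id Optional source id carried through to the output.
#' @return Tibble: `source_id`, `strand` (`+`/`-`), `frame` (0-2), `aa`.
#' @export
translate_six_frames <- function(seq, id = NA_character_) {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!chars %in% IUPAC_NT)
  if (length(bad) > 0)
    abort(paste0("non-IUPAC nucleotide characters at positions: ",
                 paste(head(bad, 10L), collapse = ", ")))
  fwd <- gsub("U", "T", paste(chars, collapse = ""))
  rev <- revcomp(fwd)
  gc_tab <- Biostrings::GENETIC_CODE
  one <- function(s, offset) {
    L <- nchar(s) - offset
    L <- L - (L %% 3L)
    if (L <= 0L) return("")
    starts <- seq(offset + 1L, offset + L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    aa <- unname(gc_tab[codons])
    aa[is.na(aa)] <- "X"   # ambiguity codes
    paste(aa, collapse = "")
  }
  tidyr::expand_grid(strand = c("+", "-"), frame = 0:2) %>%
    mutate(source_id = id,
           aa = purrr::map2_chr(.data$strand, .data$frame, function(st, f) {
             one(if (st == "+") fwd else rev, f)
           })) %>%
    select("source_id", "strand", "frame", "aa")
}

#' Type a candidate homeodomain as TALE or non-TALE
#'
#' The candidate is aligned (gapped, local) against a 60-aa non-TALE and a
#' 63-aa TALE reference profile; the higher score decides the class. Score
#' differences smaller than `config$tale_margin` are `unresolved`.
#'
#' @param candidate Protein sequence of the candidate domain.
#' @param profiles List with `nonTALE` and `TALE` profile sequences.
#' @param config A [scan_config()].
#' @return List: `hd_type` (`"TALE"`, `"nonTALE"` or `"unresolved"`),
#'   `score_tale`, `score_nontale`.
#' @export
classify_tale <- function(candidate, profiles = default_root_profiles(),
                          config = scan_config()) {
  if (nchar(candidate) < 50L)
    warn("candidate shorter than 50 aa; classification may be unreliable")
  s_t <- sw_score(candidate, profiles$TALE, config)
  s_n <- sw_score(candidate, profiles$nonTALE, config)
  type <- if (abs(s_t - s_n) < config$tale_margin) "unresolved"
          else if (s_t > s_n) "TALE" else "nonTALE"
  list(hd_type = type, score_tale = s_t, score_nontale = s_n)
}

#' Excise a domain window with optional flanking residues
#'
#' Returns the interval `[aa_start - flank, aa_end + flank)` of the source
#' protein, clamped to the sequence bounds; clamping is recorded.
#'
#' @param source_aa Source protein sequence.
#' @param aa_start,aa_end 0-based half-open domain interval.
#' @param flank_residues Residues to add either side (5 for Hox/ParaHox).
#' @return List: `seq`, realised `aa_start`/`aa_end`, `clamped`.
#' @export
excise_domain <- function(source_aa, aa_start, aa_end, flank_residues = 0L) {
  if (aa_end < aa_start) abort("inverted interval")
  L <- nchar(source_aa)
  s <- aa_start - flank_residues
  e <- aa_end + flank_residues
  clamped <- s < 0L || e > L
  s <- max(0L, s); e <- min(L, e)
  list(seq = substr(source_aa, s + 1L, e), aa_start = s, aa_end = e,
       clamped = clamped)
}

# all local hits of one query in one frame, by recursive segment splitting:
# take the best hit, then search the flanking segments independently
find_frame_hits <- function(query, frame_aa, config, floor) {
  out <- list()
  recurse <- function(offset, seg) {
    if (nchar(seg) < 15L) return()
    S <- get_scoring_matrix(config$scoring_matrix)
    r <- sw_align_cpp(encode_aa(query, S), encode_aa(seg, S), S,
                      config$gap_open, config$gap_extend)
    if (r$score < floor || r$t_end <= r$t_start) return()
    out[[length(out) + 1L]] <<- list(
      score = r$score,
      q_start = r$q_start, q_end = r$q_end,
      t_start = offset + r$t_start, t_end = offset + r$t_end)
    recurse(offset, substr(seg, 1L, r$t_start))
    recurse(offset + r$t_end, substr(seg, r$t_end + 1L, nchar(seg)))
  }
  recurse(0L, frame_aa)
  out
}

looks_nt <- function(seq) {
  chars <- strsplit(toupper(substr(seq, 1L, 500L)), "")[[1]]
  mean(chars %in% c("A", "C", "G", "T", "N", "U")) > 0.9
}

#' Recursive homeodomain search run to saturation
#'
#' Every query in the pool is aligned against every target frame; hits
#' scoring at least `accept_score` are accepted (greedily by descending
#' score; a candidate overlapping an already-accepted hit by more than 30
#' aa on the same frame is discarded), excised, typed, and added to the
#' query pool. Rounds repeat until an iteration adds no new accepted hit
#' (search saturation) or `max_iterations` is reached, in which case the
#' result is flagged unsaturated. Scores in
#' `[degraded_floor, accept_score)` at accepted-hit-free positions are
#' reported as degraded homeodomain remnants.
#'
#' @param targets Tibble of sequences (`id`, `seq`); nucleotide targets are
#'   six-frame translated, protein targets searched directly.
#' @param seed_pool Tibble (`query_id`, `seq`) of seed queries.
#' @param config A [scan_config()].
#' @param profiles Reference profiles for TALE typing.
#' @return An `hb_scan_result`: list with `hits` (tibble of homeodomain
#'   hits: `source_id`, `strand`, `frame`, `nt_start`, `nt_end`,
#'   `aa_start`, `aa_end`, `score`, `best_query_id`, `hd_type`,
#'   `intactness`, `hd_seq`), `pool` (final query pool), `iterations`,
#'   `saturated`.
#' @export
recursive_scan <- function(targets, seed_pool, config = scan_config(),
                           profiles = default_root_profiles()) {
  if (nrow(seed_pool) == 0L) abort("seed pool must be non-empty")
  # frame table
  frames <- if (nrow(targets) == 0L) {
    tibble(source_id = character(0), strand = character(0),
           frame = integer(0), aa = character(0))
  } else {
    bind_rows(purrr::map(seq_len(nrow(targets)), function(i) {
      if (looks_nt(targets$seq[i])) {
        translate_six_frames(targets$seq[i], targets$id[i])
      } else {
        tibble(source_id = targets$id[i], strand = "+", frame = 0L,
               aa = targets$seq[i])
      }
    }))
  }
  frames <- filter(frames, nchar(.data$aa) >= 15L)
  target_nt <- setNames(nchar(targets$seq), targets$id)
  is_nt <- setNames(vapply(targets$seq, looks_nt, logical(1)), targets$id)

  pool <- tibble(query_id = seed_pool$query_id, seq = seed_pool$seq,
                 provenance = "seed")
  pool <- distinct(pool, .data$seq, .keep_all = TRUE)
  scanned <- character(0)
  cand <- list()
  n_accept_prev <- -1L
  iter <- 0L
  saturated <- FALSE
  accepted <- NULL

  # overlap resolution works on full domain windows (alignment interval
  # extended by the query overhang), not the raw local-alignment interval:
  # a ragged partial alignment of an already-claimed domain must not
  # survive as a phantom second domain
  resolve <- function(cand_df) {
    if (nrow(cand_df) == 0L) return(cand_df)
    w_start <- cand_df$t_start - cand_df$q_start
    w_end <- cand_df$t_end + (cand_df$q_len - cand_df$q_end)
    o <- order(-cand_df$score, cand_df$source_id, cand_df$strand,
               cand_df$frame, cand_df$t_start, cand_df$query_id)
    cand_df <- cand_df[o, ]
    w_start <- w_start[o]; w_end <- w_end[o]
    frame_key <- paste(cand_df$source_id, cand_df$strand, cand_df$frame)
    kept_start <- split(numeric(0), character(0))
    kept_end <- split(numeric(0), character(0))
    take <- logical(nrow(cand_df))
    for (i in seq_len(nrow(cand_df))) {
      k <- frame_key[i]
      ks <- kept_start[[k]]; ke <- kept_end[[k]]
      if (!is.null(ks) && length(ks) > 0) {
        ov <- pmin(ke, w_end[i]) - pmax(ks, w_start[i])
        if (any(ov > 30L)) next
      }
      take[i] <- TRUE
      kept_start[[k]] <- c(ks, w_start[i])
      kept_end[[k]] <- c(ke, w_end[i])
    }
    cand_df[take, ]
  }

  # locus a discovered query was excised from: "src|start-end|strand frame"
  parse_locus <- function(qid) {
    m <- regexec("^(.*)\\|([0-9]+)-([0-9]+)\\|([+-])([0-9])$", qid)[[1]]
    if (m[1] == -1L) return(NULL)
    g <- regmatches(qid, regexec("^(.*)\\|([0-9]+)-([0-9]+)\\|([+-])([0-9])$",
                                 qid))[[1]]
    list(source_id = g[2], start = as.integer(g[3]), end = as.integer(g[4]),
         strand = g[5], frame = as.integer(g[6]))
  }

  repeat {
    iter <- iter + 1L
    new_q <- filter(pool, !.data$query_id %in% scanned)
    for (qi in seq_len(nrow(new_q))) {
      q <- new_q$seq[qi]
      qid <- new_q$query_id[qi]
      locus <- parse_locus(qid)
      for (fi in seq_len(nrow(frames))) {
        hs <- find_frame_hits(q, frames$aa[fi], config, config$degraded_floor)
        # a query never scores the locus it was excised from (self-match)
        if (!is.null(locus) && locus$source_id == frames$source_id[fi] &&
            locus$strand == frames$strand[fi] &&
            locus$frame == frames$frame[fi]) {
          hs <- purrr::keep(hs, function(h)
            min(h$t_end, locus$end) - max(h$t_start, locus$start) <= 30L)
        }
        if (length(hs) == 0L) next
        cand[[length(cand) + 1L]] <- tibble(
          source_id = frames$source_id[fi], strand = frames$strand[fi],
          frame = frames$frame[fi],
          t_start = vapply(hs, function(h) h$t_start, numeric(1)),
          t_end = vapply(hs, function(h) h$t_end, numeric(1)),
          q_start = vapply(hs, function(h) h$q_start, numeric(1)),
          q_end = vapply(hs, function(h) h$q_end, numeric(1)),
          q_len = nchar(q),
          score = vapply(hs, function(h) h$score, numeric(1)),
          query_id = qid)
      }
      scanned <- c(scanned, qid)
    }
    all_cand <- if (length(cand)) bind_rows(cand) else
      tibble(source_id = character(0), strand = character(0),
             frame = integer(0), t_start = integer(0), t_end = integer(0),
             q_start = integer(0), q_end = integer(0), q_len = integer(0),
             score = numeric(0), query_id = character(0))
    resolved <- resolve(all_cand)
    accepted <- filter(resolved, .data$score >= config$accept_score)

    # excise newly accepted domains into the pool
    if (nrow(accepted) > 0) {
      for (i in seq_len(nrow(accepted))) {
        h <- accepted[i, ]
        faa <- frames$aa[frames$source_id == h$source_id &
                         frames$strand == h$strand & frames$frame == h$frame]
        ws <- max(0L, h$t_start - h$q_start)
        we <- min(nchar(faa), h$t_end + (h$q_len - h$q_end))
        dom <- substr(faa, ws + 1L, we)
        if (nchar(dom) >= 50L && !dom %in% pool$seq) {
          pool <- bind_rows(pool, tibble(
            query_id = sprintf("%s|%d-%d|%s%d", h$source_id, ws, we,
                               h$strand, h$frame),
            seq = dom,
            provenance = paste0("discovered-iteration-", iter)))
        }
      }
    }
    if (nrow(accepted) == n_accept_prev) { saturated <- TRUE; break }
    n_accept_prev <- nrow(accepted)
    if (iter >= config$max_iterations) break
    if (nrow(filter(pool, !.data$query_id %in% scanned)) == 0L &&
        nrow(accepted) == 0L) { saturated <- TRUE; break }
  }

  resolved <- resolve(if (length(cand)) bind_rows(cand) else accepted)
  hits <- finalize_hits(resolved, frames, target_nt, is_nt, config, profiles)
  structure(list(hits = hits, pool = pool, iterations = iter,
                 saturated = saturated),
            class = "hb_scan_result")
}

# window extension, typing and coordinate conversion for resolved candidates
finalize_hits <- function(resolved, frames, target_nt, is_nt, config,
                          profiles) {
  if (nrow(resolved) == 0L) {
    return(tibble(source_id = character(0), strand = character(0),
                  frame = integer(0), nt_start = integer(0),
                  nt_end = integer(0), aa_start = integer(0),
                  aa_end = integer(0), score = numeric(0),
                  best_query_id = character(0), hd_type = character(0),
                  intactness = character(0), hd_seq = character(0)))
  }
  rows <- purrr::map(seq_len(nrow(resolved)), function(i) {
    h <- resolved[i, ]
    faa <- frames$aa[frames$source_id == h$source_id &
                     frames$strand == h$strand & frames$frame == h$frame]
    flen <- nchar(faa)
    ws <- h$t_start - h$q_start
    we <- h$t_end + (h$q_len - h$q_end)
    clamped <- ws < 0L || we > flen
    ws <- max(0L, ws); we <- min(flen, we)
    cand_seq <- substr(faa, ws + 1L, we)
    cls <- classify_tale(cand_seq, profiles, config)
    want <- if (cls$score_tale >= cls$score_nontale) 63L else 60L
    if (!clamped && we - ws != want) {
      we2 <- ws + want
      if (we2 <= flen) we <- we2 else clamped <- TRUE
      we <- min(we, flen)
      cand_seq <- substr(faa, ws + 1L, we)
    }
    intact <- if (clamped) "truncated"
              else if (h$score >= config$accept_score) "intact"
              else "degraded"
    nt <- is_nt[[h$source_id]]
    if (isTRUE(nt)) {
      L <- target_nt[[h$source_id]]
      if (h$strand == "+") {
        s0 <- h$frame + 3L * ws; e0 <- h$frame + 3L * we
      } else {
        s0 <- L - (h$frame + 3L * we); e0 <- L - (h$frame + 3L * ws)
      }
    } else { s0 <- NA_integer_; e0 <- NA_integer_ }
    tibble(source_id = h$source_id, strand = h$strand, frame = h$frame,
           nt_start = s0, nt_end = e0, aa_start = ws, aa_end = we,
           score = h$score, best_query_id = h$query_id,
           hd_type = cls$hd_type, intactness = intact, hd_seq = cand_seq)
  })
  arrange(bind_rows(rows), .data$source_id, .data$strand, .data$frame,
          .data$aa_start)
}

#' @export
print.hb_scan_result <- function(x, ...) {
  cat("<hb_scan_result>\n")
  cat("  hits:", nrow(x$hits),
      sprintf("(%d intact, %d degraded, %d truncated)",
              sum(x$hits$intactness == "intact"),
              sum(x$hits$intactness == "degraded"),
              sum(x$hits$intactness == "truncated")), "\n")
  cat("  pool:", nrow(x$pool), "queries; iterations:", x$iterations,
      if (x$saturated) "(saturated)" else "(UNSATURATED)", "\n")
  invisible(x)
}

#' Call gene architecture from the homeodomain hits of one gene
#'
#' @param hits Tibble of hits sharing one `source_id`.
#' @return One of `"single"`, `"double"`, `"double_with_degraded"`,
#'   `"fragment"`: two intact domains give `double`; one intact plus a
#'   degraded remnant gives `double_with_degraded`; a lone intact domain
#'   gives `single`; anything truncated by the sequence end (or only
#'   degraded remnants) gives `fragment`.
#' @export
detect_architecture <- function(hits) {
  if (nrow(hits) == 0L) abort("no hits: call on hit-bearing genes only")
  if (length(unique(hits$source_id)) > 1L)
    abort("hits must share one source_id")
  n_int <- sum(hits$intactness == "intact")
  n_deg <- sum(hits$intactness == "degraded")
  if (n_int >= 2L) "double"
  else if (n_int == 1L && n_deg >= 1L) "double_with_degraded"
  else if (n_int == 1L && all(hits$intactness %in% c("intact"))) "single"
  else if (n_int == 1L) "single"
  else "fragment"
}

#' Read-quantification configuration
#'
#' @param identity_cutoff Minimum alignment identity for a read to count
#'   (inclusive; the survey convention is 0.95).
#' @param library_total Total read count of the library, used for
#'   normalisation.
#' @param scale_per_million Report normalised counts per million reads.
#' @export
quant_config <- function(identity_cutoff = 0.95, library_total = 1e6,
                         scale_per_million = TRUE) {
  if (identity_cutoff <= 0 || identity_cutoff > 1)
    abort("identity_cutoff must be in (0, 1]")
  if (library_total <= 0) abort("library_total must be > 0")
  structure(list(identity_cutoff = identity_cutoff,
                 library_total = library_total,
                 scale_per_million = scale_per_million),
            class = "quant_config")
}

nt_matrix <- function(match = 2, mismatch = -3) {
  a <- c("A", "C", "G", "T", "N")
  S <- matrix(mismatch, 5, 5, dimnames = list(a, a))
  diag(S) <- match
  S["N", ] <- 0; S[, "N"] <- 0
  S
}

#' Count reads supporting a transcript
#'
#' A read counts when its best local alignment to the transcript covers at
#' least 90% of the read at an identity of at least
#' `config$identity_cutoff` (identity = matches / aligned columns, the
#' boundary inclusive). The normalised count is raw / library total,
#' scaled per million if requested.
#'
#' @param reads Tibble of nucleotide reads (`id`, `seq`).
#' @param transcript Transcript nucleotide sequence.
#' @param config A [quant_config()].
#' @return List: `raw_count`, `normalized_count`, `per_read` tibble.
#' @export
quantify_reads <- function(reads, transcript, config = quant_config()) {
  if (nrow(reads) == 0L)
    return(list(raw_count = 0L, normalized_count = 0,
                per_read = tibble(id = character(0), identity = numeric(0),
                                  coverage = numeric(0), counted = logical(0))))
  S <- nt_matrix()
  enc <- function(s) {
    idx <- match(strsplit(toupper(s), "")[[1]], rownames(S))
    idx[is.na(idx)] <- match("N", rownames(S))
    idx - 1L
  }
  tgt <- enc(transcript)
  per <- purrr::map(seq_len(nrow(reads)), function(i) {
    q <- enc(reads$seq[i])
    r <- sw_align_cpp(q, tgt, S, 5, 2)
    if (r$score <= 0)
      return(tibble(id = reads$id[i], identity = 0, coverage = 0,
                    counted = FALSE))
    qp <- r$q_path; tp <- r$t_path
    both <- which(qp >= 0 & tp >= 0)
    matches <- sum(q[qp[both] + 1L] == tgt[tp[both] + 1L])
    identity <- matches / length(qp)
    coverage <- (r$q_end - r$q_start) / length(q)
    tibble(id = reads$id[i], identity = identity, coverage = coverage,
           counted = coverage >= 0.9 && identity >= config$identity_cutoff)
  })
  per <- bind_rows(per)
  raw <- sum(per$counted)
  norm <- raw / config$library_total *
    (if (config$scale_per_million) 1e6 else 1)
  list(raw_count = raw, normalized_count = norm, per_read = per)
}
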