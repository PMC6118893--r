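#' Synthetic medial-Hox homeodomain alignment with a divergent focal gene
#'
#' A constructed (synthetic) stand-in for the kind of medial-Hox
#' homeodomain alignment used to characterise a highly divergent Antp
#' orthologue: thirteen background sequences derived from a canonical
#' Antennapedia-type homeodomain by scattered substitutions, plus one
#' divergent focal sequence that is the sole variant at exactly six
#' otherwise-invariant positions (the published analysis of the divergent
#' annelid Antp reports six such residues). Deterministic; built in code,
#' not from any real alignment.
#'
#' @param n_background Number of background (non-focal) rows.
#' @param n_unique_variants Number of planted focal-only variant columns.
#' @param seed Seed fixing the construction.
#' @return Alignment tibble (`id`, `seq`) with the focal row `divergent_Antp`.
#' @export
synthetic_medial_hox_alignment <- function(n_background = 13L,
                                           n_unique_variants = 6L,
                                           seed = 2018L) {
  profile <- default_root_profiles()$nonTALE
  L <- nchar(profile)
  with_seed(seed, {
    planted <- sort(sample(L, n_unique_variants))
    mutable <- setdiff(seq_len(L), planted)
    bg <- vapply(seq_len(n_background), function(i) {
      s <- strsplit(profile, "")[[1]]
      k <- sample(3:6, 1)
      idx <- sample(mutable, k)
      s[idx] <- vapply(s[idx], function(a) sample(setdiff(AA20, a), 1L),
                       character(1))
      paste(s, collapse = "")
    }, character(1))
    f <- strsplit(profile, "")[[1]]
    f[planted] <- vapply(f[planted], function(a) sample(setdiff(AA20, a), 1L),
                         character(1))
    tibble(id = c("divergent_Antp", sprintf("medialHox_%02d",
                                            seq_len(n_background))),
           seq = c(paste(f, collapse = ""), bg))
  })
}
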