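#' Configure the gene-family simulator
#'
#' The simulator emulates the data a homeobox survey works from: gene
#' families born on a species tree with duplication and loss, homeodomains
#' of 60 aa (non-TALE) or 63 aa (TALE class, carrying the three-residue
#' loop extension between helices 1 and 2), optional second homeodomains
#' (intact or degraded), conserved C-terminal motifs, and nucleotide
#' scaffolds with random flanks on either strand. Every output is fixed
#' bit-for-bit by `seed`.
#'
#' @param species_tree Newick string (with branch lengths) or `ape::phylo`.
#' @param duplication_rate,loss_rate Expected duplications/losses per gene
#'   per unit branch length.
#' @param substitution_rate Expected substitutions per site per unit branch
#'   length along the gene tree.
#' @param n_families Number of gene families to simulate.
#' @param tale_fraction Fraction of families given the 63-aa TALE
#'   architecture (deterministic count, `round(tale_fraction * n_families)`).
#' @param double_hd_fraction Fraction of TALE families given a second
#'   homeodomain.
#' @param degrade_fraction Fraction of second domains degraded (substitution
#'   rate multiplied by 5 plus 10% of positions replaced uniformly).
#' @param scaffold_flank_length Nucleotides of random flank each side of the
#'   embedded coding sequence.
#' @param family_divergence Expected substitutions per site separating each
#'   family's ancestral homeodomain from the shared root profile; this is
#'   what makes families distinct, recoverable clades.
#' @param motif_fraction Fraction of TALE families carrying a conserved
#'   15-aa C-terminal motif (evolved at one fifth of the family rate).
#' @param seed Integer seed fixing all outputs.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(species_tree = default_species_tree(),
                       duplication_rate = 0.3,
                       loss_rate = 0.2,
                       substitution_rate = 0.5,
                       n_families = 20L,
                       tale_fraction = 0.5,
                       double_hd_fraction = 0.5,
                       degrade_fraction = 0.5,
                       scaffold_flank_length = 300L,
                       family_divergence = 0.2,
                       motif_fraction = 0.5,
                       seed = 1L) {
  if (is.character(species_tree)) species_tree <- parse_newick_string(species_tree)
  stopifnot(inherits(species_tree, "phylo"), !is.null(species_tree$edge.length))
  rates <- c(duplication_rate, loss_rate, substitution_rate, family_divergence)
  if (any(rates < 0)) abort("all rates must be >= 0")
  fr <- c(tale_fraction, double_hd_fraction, degrade_fraction, motif_fraction)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (n_families < 1L) abort("n_families must be >= 1")
  structure(list(
    species_tree = species_tree,
    duplication_rate = duplication_rate,
    loss_rate = loss_rate,
    substitution_rate = substitution_rate,
    n_families = as.integer(n_families),
    tale_fraction = tale_fraction,
    double_hd_fraction = double_hd_fraction,
    degrade_fraction = degrade_fraction,
    scaffold_flank_length = as.integer(scaffold_flank_length),
    family_divergence = family_divergence,
    motif_fraction = motif_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_species_tree <- function() {
  paste0("((Slam:0.15,Ctel:0.15):0.10,",
         "(Lana:0.20,(Lgig:0.10,Pvul:0.10):0.10):0.05);")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Ancestral homeodomain profiles used to root the simulation
#'
#' The non-TALE profile is a canonical 60-aa Antennapedia-type homeodomain;
#' the TALE profile is the same domain with a three-residue loop extension
#' inserted between positions 24 and 25 (the loop between helices 1 and 2),
#' giving the diagnostic 63-aa TALE architecture.
#'
#' @return List with elements `nonTALE` (60 aa) and `TALE` (63 aa).
#' @export
default_root_profiles <- function() {
  hd60 <- "RKRGRQTYTRYQTLELEKEFHFNRYLTRRRRIEIAHALGLTERQIKIWFQNRRMKWKKEN"
  list(nonTALE = hd60, TALE = tale_insert(hd60))
}

# insert the 3-aa loop extension between positions 24 and 25 of a 60-aa frame
tale_insert <- function(hd60, insert = "LGL") {
  paste0(substr(hd60, 1L, 24L), insert, substr(hd60, 25L, nchar(hd60)))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# per-branch substitution: each site hit with prob 1 - exp(-r * t); a hit
# site is redrawn uniformly from the 19 other residues, so the realised
# per-branch difference probability is exactly 1 - exp(-r * t)
mutate_seq <- function(seq, dist) {
  if (dist <= 0) return(seq)
  s <- strsplit(seq, "")[[1]]
  p <- 1 - exp(-dist)
  hit <- which(runif(length(s)) < p)
  if (length(hit) > 0) {
    s[hit] <- vapply(s[hit], function(a) sample(setdiff(AA20, a), 1L), character(1))
  }
  paste(s, collapse = "")
}

# degrade a domain: 5x the family substitution rate has already been applied
# by the caller; here 10% of positions are additionally replaced uniformly
degrade_seq <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  k <- max(1L, round(0.1 * length(s)))
  idx <- sample(length(s), k)
  s[idx] <- sample(AA20, k, replace = TRUE)
  paste(s, collapse = "")
}

# ---- gene-tree birth-death simulation -------------------------------------

# one gene lineage evolving along one species-tree edge of length t.
# Returns NULL (extinct) or list(bl = ..., node = leaf placeholder /
# duplication structure). Leaf placeholders are completed at the species node.
evolve_on_edge <- function(t_remaining, dup, loss, counter) {
  repeat {
    t_dup <- if (dup > 0) rexp(1L, dup) else Inf
    t_loss <- if (loss > 0) rexp(1L, loss) else Inf
    t_event <- min(t_dup, t_loss)
    if (t_event >= t_remaining) {
      return(list(type = "end", bl = t_remaining))
    }
    if (t_loss <= t_dup) return(NULL)
    counter$dups <- counter$dups + 1L
    left <- evolve_on_edge(t_remaining - t_event, dup, loss, counter)
    right <- evolve_on_edge(t_remaining - t_event, dup, loss, counter)
    if (is.null(left) && is.null(right)) return(NULL)
    if (is.null(left)) { right$bl <- right$bl + t_event; return(right) }
    if (is.null(right)) { left$bl <- left$bl + t_event; return(left) }
    return(list(type = "dup", bl = t_event, children = list(left, right)))
  }
}

# continue every open lineage end of an on-edge subtree into the subtree of
# the species node at the edge's bottom
graft_ends <- function(node, continue_fn) {
  if (node$type == "end") {
    sub <- continue_fn()
    if (is.null(sub)) return(NULL)
    sub$bl <- sub$bl + node$bl
    return(sub)
  }
  kids <- purrr::map(node$children, graft_ends, continue_fn = continue_fn)
  kids <- kids[!vapply(kids, is.null, logical(1))]
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) {
    k <- kids[[1]]
    k$bl <- k$bl + node$bl
    return(k)
  }
  list(type = "dup", bl = node$bl, children = kids)
}

# one gene lineage arriving at a species-tree node (phylo node id)
evolve_at_node <- function(tr, node, dup, loss, counter, state) {
  ntip <- length(tr$tip.label)
  if (node <= ntip) {
    sp <- tr$tip.label[node]
    state$n <- state$n + 1L
    gid <- sprintf("%s_%s_g%02d", state$fam, sp, state$n)
    return(list(type = "leaf", bl = 0, gene_id = gid, species = sp))
  }
  kid_rows <- which(tr$edge[, 1] == node)
  kids <- list()
  for (r in kid_rows) {
    child <- tr$edge[r, 2]
    len <- tr$edge.length[r]
    onedge <- evolve_on_edge(len, dup, loss, counter)
    if (is.null(onedge)) next
    sub <- graft_ends(onedge, function()
      evolve_at_node(tr, child, dup, loss, counter, state))
    if (!is.null(sub)) kids[[length(kids) + 1L]] <- sub
  }
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) return(kids[[1]])
  list(type = "spec", bl = 0, children = kids)
}

tree_leaves <- function(node) {
  if (node$type == "leaf")
    return(tibble(species = node$species, gene_id = node$gene_id))
  bind_rows(purrr::map(node$children, tree_leaves))
}

tree_newick <- function(node) {
  rec <- function(n) {
    if (n$type == "leaf") return(sprintf("%s:%g", n$gene_id, n$bl))
    inner <- paste(vapply(n$children, rec, character(1)), collapse = ",")
    sprintf("(%s):%g", inner, n$bl)
  }
  paste0(rec(node), ";")
}

#' Simulate gene families on a species tree
#'
#' Each family starts as a single gene at the species-tree root and evolves
#' by a birth-death process: duplications bifurcate the gene lineage within
#' a species-tree edge, losses prune it. Families losing every lineage are
#' retained with an all-`FALSE` presence row (and no gene tree) so that loss
#' statistics remain observable.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per family: `family_id`, `hd_type`,
#'   `double_hd`, `degraded_second`, `has_motif`, `n_genes`,
#'   `n_duplications`, `gene_tree` (Newick, `NA` if extinct), `members`
#'   (list of tibbles `species`, `gene_id`) and `presence` (list of named
#'   logicals over species).
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tr <- config$species_tree
  species <- tr$tip.label
  n <- config$n_families
  n_tale <- round(config$tale_fraction * n)
  n_double <- round(config$double_hd_fraction * n_tale)
  n_degr <- round(config$degrade_fraction * n_double)
  n_motif <- round(config$motif_fraction * n_tale)
  with_seed(config$seed, {
    rows <- purrr::map(seq_len(n), function(i) {
      fam <- sprintf("fam%03d", i)
      counter <- new.env(); counter$dups <- 0L
      state <- new.env(); state$n <- 0L; state$fam <- fam
      root <- ape::Ntip(tr) + 1L
      gt <- evolve_at_node(tr, root, config$duplication_rate,
                           config$loss_rate, counter, state)
      if (is.null(gt)) {
        members <- tibble(species = character(0), gene_id = character(0))
        nwk <- NA_character_
      } else {
        members <- tree_leaves(gt)
        nwk <- tree_newick(gt)
      }
      presence <- setNames(species %in% members$species, species)
      tibble(family_id = fam,
             hd_type = if (i <= n_tale) "TALE" else "nonTALE",
             double_hd = i <= n_double,
             degraded_second = i <= n_degr,
             has_motif = i <= n_motif,
             n_genes = nrow(members),
             n_duplications = counter$dups,
             gene_tree = nwk,
             tree_struct = list(gt),
             members = list(members),
             presence = list(presence))
    })
    bind_rows(rows)
  })
}

# ---- sequence evolution ----------------------------------------------------

# root-to-tip path length per leaf of a gene-tree structure
tree_depths <- function(node, acc = 0) {
  d <- acc + node$bl
  if (node$type == "leaf") return(setNames(d, node$gene_id))
  do.call(c, purrr::map(node$children, tree_depths, acc = d))
}

# Degraded-remnant score band, in BLOSUM62 units against the ancestral
# profiles: remnants are "detectable but unalignable" by construction --
# recognizably homeodomain-derived (above the band floor, which sits above
# anything random sequence reaches) yet too decayed to pass for an intact
# domain. Draws are rejection-sampled into the band, adapting the
# degradation depth when a tip's path length alone cannot reach it.
REMNANT_BAND <- c(75, 140)

sample_remnant <- function(root2, dist, profiles,
                           band = REMNANT_BAND, max_tries = 60L) {
  cfg <- scan_config()
  score_of <- function(s)
    max(sw_score(s, profiles$TALE, cfg), sw_score(s, profiles$nonTALE, cfg))
  best <- NULL; best_gap <- Inf
  d <- dist
  for (i in seq_len(max_tries)) {
    cand <- degrade_seq(mutate_seq(root2, d))
    sc <- score_of(cand)
    if (sc >= band[1] && sc <= band[2]) return(cand)
    gap <- if (sc < band[1]) band[1] - sc else sc - band[2]
    if (gap < best_gap) { best <- cand; best_gap <- gap }
    if (sc > band[2]) d <- d * 1.2 else d <- d / 1.2
  }
  best
}

evolve_tree_seqs <- function(node, seq, rate) {
  seq2 <- mutate_seq(seq, rate * node$bl)
  if (node$type == "leaf") {
    return(tibble(gene_id = node$gene_id, species = node$species, hd = seq2))
  }
  bind_rows(purrr::map(node$children, evolve_tree_seqs, seq = seq2, rate = rate))
}

#' Evolve protein sequences for simulated families
#'
#' Sequences evolve by independent-site substitution along each family's
#' gene tree, starting from a family-specific ancestral homeodomain derived
#' from the shared root profiles (`family_divergence` expected substitutions
#' per site away). TALE families carry the 3-residue loop extension; genes in
#' two-homeodomain families receive a second domain descended from an
#' internal tandem duplication of the family's ancestral domain. In
#' "degraded" families the second domain decays independently per gene at
#' five times the substitution rate plus a 10% uniform scramble,
#' constrained to the detectable-but-unalignable score band relative to
#' the ancestral profiles. Each protein is leader + HD1 + linker (+ HD2)
#' + tail (+ conserved C-terminal motif).
#'
#' @param families Output of [simulate_families()].
#' @param config The same [sim_config()].
#' @param root_profiles List with 60-aa `nonTALE` and 63-aa `TALE` ancestral
#'   homeodomains; see [default_root_profiles()].
#' @return List with `proteins` (tibble: `gene_id`, `species`, `family_id`,
#'   `hd_type`, `seq`), `domains` (tibble of per-gene domain annotations with
#'   0-based half-open `aa_start`/`aa_end`, `hd_type`, `intact`,
#'   `motif_start`), `alignment` (the true cross-family homeodomain alignment,
#'   63 columns, gaps at the loop-extension columns for non-TALE rows) and
#'   `family_alignments` (per-family ungapped true alignments).
#' @export
evolve_sequences <- function(families, config,
                             root_profiles = default_root_profiles()) {
  stopifnot(inherits(config, "sim_config"))
  if (nchar(root_profiles$nonTALE) != 60L || nchar(root_profiles$TALE) != 63L)
    abort("root profiles must be 60 aa (nonTALE) and 63 aa (TALE)")
  motif_root <- "WLDPNSFRKEWTEQM"
  leader_len <- 15L; linker_len <- 20L; tail_len <- 10L
  with_seed(config$seed + 1L, {
    prot_rows <- list(); dom_rows <- list(); fam_alns <- list()
    for (i in seq_len(nrow(families))) {
      fam <- families$family_id[i]
      gt <- families$tree_struct[[i]]
      if (is.null(gt)) next
      type <- families$hd_type[i]
      profile <- root_profiles[[type]]
      fam_root <- mutate_seq(profile, config$family_divergence)
      hd1 <- evolve_tree_seqs(gt, fam_root, config$substitution_rate)
      hd_len <- nchar(profile)
      double_hd <- families$double_hd[i]
      degraded <- families$degraded_second[i]
      has_motif <- families$has_motif[i]
      if (double_hd) {
        # the second domain arises by internal tandem duplication of the
        # family's ancestral domain, then diverges (0.15 subs/site before
        # the family radiates)
        fam_root2 <- mutate_seq(fam_root, 0.15)
        if (degraded) {
          # degraded remnants: five-fold rate along each tip's own path
          # plus a 10% uniform scramble, drawn independently per tip
          # (remnants decay independently once the domain is dead) and
          # constrained to stay recognizable-but-degraded relative to the
          # ancestral profiles (see remnant_window below)
          depths <- tree_depths(gt)
          hd2 <- hd1[, c("gene_id", "species")]
          hd2$hd <- vapply(hd1$gene_id, function(gid) {
            sample_remnant(fam_root2,
                           5 * config$substitution_rate * depths[[gid]],
                           root_profiles)
          }, character(1))
        } else {
          hd2 <- evolve_tree_seqs(gt, fam_root2, config$substitution_rate)
        }
        hd2 <- rename(hd2, hd2 = "hd")
        hd1 <- left_join(hd1, hd2[, c("gene_id", "hd2")], by = "gene_id")
      }
      fam_motif <- if (has_motif) mutate_seq(motif_root, 0.1) else NA_character_
      for (g in seq_len(nrow(hd1))) {
        leader <- rand_aa(leader_len)
        linker <- rand_aa(linker_len)
        tail_ <- rand_aa(tail_len)
        parts <- c(leader, hd1$hd[g])
        dom <- tibble(gene_id = hd1$gene_id[g], hd_index = 1L,
                      aa_start = leader_len, aa_end = leader_len + hd_len,
                      hd_type = type, intact = "intact")
        pos <- leader_len + hd_len
        if (double_hd) {
          parts <- c(parts, linker, hd1$hd2[g])
          dom <- bind_rows(dom, tibble(
            gene_id = hd1$gene_id[g], hd_index = 2L,
            aa_start = pos + linker_len, aa_end = pos + linker_len + hd_len,
            hd_type = type,
            intact = if (degraded) "degraded" else "intact"))
          pos <- pos + linker_len + hd_len
        }
        parts <- c(parts, tail_)
        pos <- pos + tail_len
        motif_start <- NA_integer_
        if (has_motif) {
          gm <- mutate_seq(fam_motif, config$substitution_rate * 0.2)
          parts <- c(parts, gm)
          motif_start <- pos
        }
        dom$motif_start <- motif_start
        prot_rows[[length(prot_rows) + 1L]] <- tibble(
          gene_id = hd1$gene_id[g], species = hd1$species[g],
          family_id = fam, hd_type = type, seq = paste(parts, collapse = ""))
        dom_rows[[length(dom_rows) + 1L]] <- dom
      }
      fam_alns[[fam]] <- tibble(id = hd1$gene_id, seq = hd1$hd)
    }
    proteins <- bind_rows(prot_rows)
    domains <- bind_rows(dom_rows)
    aln <- bind_rows(purrr::imap(fam_alns, function(a, fam) {
      if (nchar(a$seq[1]) == 60L) {
        a$seq <- paste0(substr(a$seq, 1L, 24L), "---",
                        substr(a$seq, 25L, 60L))
      }
      a
    }))
    list(proteins = proteins, domains = domains,
         alignment = aln, family_alignments = fam_alns)
  })
}

# ---- scaffold embedding ----------------------------------------------------

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

reverse_translate <- function(aa, codons) {
  s <- strsplit(aa, "")[[1]]
  paste(vapply(s, function(a) {
    cs <- codons[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1)), collapse = "")
}

revcomp <- function(nt) {
  comp <- chartr("ACGTURYSWKMBDHVNacgturyswkmbdhvn",
                 "TGCAAYRSWMKVHDBNtgcaayrswmkvhdbn", nt)
  vapply(comp, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
}

#' Embed simulated proteins in nucleotide scaffolds
#'
#' Each gene is reverse-translated (uniform codon choice under the seed) and
#' embedded between random-nucleotide flanks; alternate scaffolds are placed
#' on the reverse strand. The truth table records every homeodomain's exact
#' 0-based half-open forward-strand nucleotide interval, strand and frame.
#'
#' @param seqres Output of [evolve_sequences()].
#' @param config The same [sim_config()].
#' @return List with `scaffolds` (tibble `id`, `seq`) and `truth` (tibble:
#'   `gene_id`, `scaffold_id`, `hd_index`, `hd_start_nt`, `hd_end_nt`,
#'   `strand`, `frame`, `hd_type`, `intact`, `family_id`).
#' @export
embed_in_scaffolds <- function(seqres, config) {
  stopifnot(inherits(config, "sim_config"))
  codons <- codon_table()
  flank <- config$scaffold_flank_length
  with_seed(config$seed + 2L, {
    scf_rows <- list(); truth_rows <- list()
    for (g in seq_len(nrow(seqres$proteins))) {
      p <- seqres$proteins[g, ]
      cds <- reverse_translate(p$seq, codons)
      fwd <- paste0(if (flank > 0) rand_nt(flank) else "",
                    cds,
                    if (flank > 0) rand_nt(flank) else "")
      strand <- if (g %% 2L == 1L) "+" else "-"
      scf <- if (strand == "+") fwd else revcomp(fwd)
      scf_id <- paste0("scf_", p$gene_id)
      L <- nchar(scf)
      dom <- filter(seqres$domains, .data$gene_id == p$gene_id)
      for (d in seq_len(nrow(dom))) {
        cs <- flank + 3L * dom$aa_start[d]   # coding-strand offset
        ce <- flank + 3L * dom$aa_end[d]
        if (strand == "+") { s0 <- cs; e0 <- ce } else { s0 <- L - ce; e0 <- L - cs }
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          gene_id = p$gene_id, scaffold_id = scf_id, hd_index = dom$hd_index[d],
          hd_start_nt = s0, hd_end_nt = e0, strand = strand,
          frame = cs %% 3L, hd_type = dom$hd_type[d],
          intact = dom$intact[d], family_id = p$family_id)
      }
      scf_rows[[length(scf_rows) + 1L]] <- tibble(id = scf_id, seq = scf)
    }
    list(scaffolds = bind_rows(scf_rows), truth = bind_rows(truth_rows))
  })
}

#' Excise and translate a truth-table interval (round-trip check helper)
#'
#' @param scaffolds Scaffold tibble (`id`, `seq`).
#' @param truth_row One row of the truth table.
#' @return The translated protein sequence of the recorded interval.
#' @export
excise_truth_domain <- function(scaffolds, truth_row) {
  scf <- scaffolds$seq[scaffolds$id == truth_row$scaffold_id]
  nt <- substr(scf, truth_row$hd_start_nt + 1L, truth_row$hd_end_nt)
  if (truth_row$strand == "-") nt <- revcomp(nt)
  as.character(Biostrings::translate(Biostrings::DNAString(nt)))
}

#' Build the family-by-species presence/absence matrix from simulated truth
#'
#' @param families Output of [simulate_families()].
#' @param drop_extinct Drop all-absent families (required by downstream
#'   gain/loss analysis).
#' @return Wide tibble: `family` plus one logical column per species.
#' @export
presence_matrix <- function(families, drop_extinct = TRUE) {
  rows <- purrr::map2(families$family_id, families$presence,
                      function(f, p) tibble(family = f, !!!as.list(p)))
  out <- bind_rows(rows)
  if (drop_extinct) {
    keep <- rowSums(as.matrix(out[, -1])) > 0L
    out <- out[keep, ]
  }
  out
}

#' Run the full simulator
#'
#' Convenience wrapper chaining [simulate_families()], [evolve_sequences()]
#' and [embed_in_scaffolds()].
#'
#' @param config A [sim_config()].
#' @param root_profiles See [default_root_profiles()].
#' @return An object of class `hb_simulation`: list with `config`,
#'   `families`, `proteins`, `domains`, `alignment`, `family_alignments`,
#'   `scaffolds`, `truth`, `presence`.
#' @export
simulate_homeobox_data <- function(config = sim_config(),
                                   root_profiles = default_root_profiles()) {
  fams <- simulate_families(config)
  seqs <- evolve_sequences(fams, config, root_profiles)
  emb <- embed_in_scaffolds(seqs, config)
  structure(list(config = config, families = fams,
                 proteins = seqs$proteins, domains = seqs$domains,
                 alignment = seqs$alignment,
                 family_alignments = seqs$family_alignments,
                 scaffolds = emb$scaffolds, truth = emb$truth,
                 presence = presence_matrix(fams)),
            class = "hb_simulation")
}

#' @export
print.hb_simulation <- function(x, ...) {
  cat("<hb_simulation>\n")
  cat("  families:", nrow(x$families),
      sprintf("(%d extinct)", sum(x$families$n_genes == 0L)), "\n")
  cat("  genes:   ", nrow(x$proteins), "\n")
  cat("  domains: ", nrow(x$truth), "planted on", nrow(x$scaffolds),
      "scaffolds\n")
  invisible(x)
}
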