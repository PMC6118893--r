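#' Configure an end-to-end pipeline run
#'
#' One global seed deterministically derives a seed per stage (a stable
#' hash of the seed and the stage name), so stages are individually
#' reproducible and mutually uncorrelated.
#'
#' @param out_dir Output directory (one run directory per run).
#' @param sim A [sim_config()] for the simulate stage.
#' @param scan A [scan_config()] for the search stage.
#' @param bootstrap_replicates NJ bootstrap replicates.
#' @param support_threshold Clade-calling support threshold (percent).
#' @param stages Which stages to execute, in order.
#' @param ml_tree,bayes_tree Optional externally built source trees
#'   (Newick paths) whose supports are mapped onto the NJ tree.
#' @param prior_registry Optional prior registry tibble for nomenclature
#'   reconciliation; defaults to an empty registry.
#' @param series_prefix Clade-name prefix for newly erected clades.
#' @param seed Global seed.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            scan = scan_config(),
                            bootstrap_replicates = 1000L,
                            support_threshold = 70,
                            stages = c("simulate", "scan", "buildtree",
                                       "reconcile", "callclades", "gainloss"),
                            ml_tree = NULL, bayes_tree = NULL,
                            prior_registry = NULL,
                            series_prefix = "FAM",
                            seed = 1L) {
  if (is.null(prior_registry))
    prior_registry <- tibble(clade = character(0), species = character(0),
                             sequence = character(0), letter = character(0),
                             origin = character(0), prior = character(0))
  structure(list(out_dir = out_dir, sim = sim, scan = scan,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 support_threshold = support_threshold, stages = stages,
                 ml_tree = ml_tree, bayes_tree = bayes_tree,
                 prior_registry = prior_registry,
                 series_prefix = series_prefix, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (seed * 7919L + h) %% 2147483647L
}

#' Run the homeobox survey pipeline end-to-end
#'
#' Stages, in order: `simulate` (generate scaffolds plus ground truth),
#' `scan` (recursive homeodomain search of the scaffolds), `buildtree`
#' (NJ with bootstrap on the homeodomain alignment; alignment construction
#' itself is an explicit external hand-off, and the simulator's true
#' alignment fills that slot), `reconcile` (map supports from any supplied
#' external trees onto the NJ tree), `callclades` (criterion-based clade
#' calls plus registry reconciliation) and `gainloss` (Dollo events on the
#' species tree). Each stage writes its outputs before the next starts;
#' failures abort with the stage named.
#'
#' @param config A [pipeline_config()].
#' @return An `hb_pipeline_run`: list with `manifest` (tibble of per-file
#'   checksums), `sim`, `scan`, `tree`, `annotated`, `calls`, `revision`,
#'   `dollo` (stages not run are `NULL`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(sim = NULL, scan = NULL, tree = NULL, annotated = NULL,
              calls = NULL, revision = NULL, dollo = NULL)
  outfiles <- character(0)
  emit <- function(writer, x, name) {
    path <- file.path(config$out_dir, name)
    writer(x, path)
    outfiles <<- c(outfiles, path)
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e))))
  }

  if ("simulate" %in% config$stages) run_stage("simulate", function() {
    sc <- config$sim
    sc$seed <- stage_seed(config$seed, "simulate")
    res$sim <<- simulate_homeobox_data(sc)
    emit(write_fasta, res$sim$scaffolds %>% rename(id = "id"), "scaffolds.fasta")
    emit(write_fasta, res$sim$proteins %>% select(id = "gene_id", "seq"),
         "proteins.fasta")
    emit(write_fasta, res$sim$alignment, "true_alignment.fasta")
    emit(function(x, p) readr::write_tsv(x, p), res$sim$truth, "truth.tsv")
    emit(write_presence_matrix, res$sim$presence, "presence.tsv")
  })

  if ("scan" %in% config$stages) run_stage("scan", function() {
    if (is.null(res$sim)) abort("scan requires the simulate stage")
    profiles <- default_root_profiles()
    seeds <- tibble(query_id = c("seed_nonTALE", "seed_TALE"),
                    seq = c(profiles$nonTALE, profiles$TALE))
    res$scan <<- recursive_scan(res$sim$scaffolds, seeds, config$scan)
    emit(function(x, p) readr::write_tsv(x, p), res$scan$hits, "hits.tsv")
    emit(write_fasta, res$scan$pool %>% select(id = "query_id", "seq"),
         "pool.fasta")
  })

  if ("buildtree" %in% config$stages) run_stage("buildtree", function() {
    if (is.null(res$sim)) abort("buildtree requires the simulate stage")
    bs <- bootstrap_support(res$sim$alignment, model = "poisson",
                            replicates = config$bootstrap_replicates,
                            seed = stage_seed(config$seed, "buildtree"))
    res$tree <<- bs
    emit(write_newick, bs$tree, "nj_tree.nwk")
    emit(function(x, p) readr::write_tsv(x, p), bs$support, "nj_support.tsv")
  })

  if ("reconcile" %in% config$stages) run_stage("reconcile", function() {
    if (is.null(res$tree)) abort("reconcile requires the buildtree stage")
    nj_tree <- res$tree$tree
    ntip <- length(nj_tree$tip.label)
    bp <- bipartitions(nj_tree)
    counts <- res$tree$support$count[match(bp$key, res$tree$support$key)]
    labs <- rep("", nj_tree$Nnode)
    labs[bp$node - ntip] <- ifelse(is.na(counts), "", counts)
    nj_tree$node.label <- labs
    ml <- if (!is.null(config$ml_tree)) read_newick(config$ml_tree) else NULL
    bayes <- if (!is.null(config$bayes_tree)) read_newick(config$bayes_tree)
             else NULL
    res$annotated <<- transfer_support(nj_tree, ml = ml, bayes = bayes,
                                       target_slot = "nj",
                                       nj_replicates = res$tree$replicates)
    emit(write_annotated_newick, res$annotated, "annotated.nwk")
  })

  if ("callclades" %in% config$stages) run_stage("callclades", function() {
    if (is.null(res$annotated)) abort("callclades requires the reconcile stage")
    crit <- clade_criteria(support_threshold = config$support_threshold)
    res$calls <<- call_clades(res$annotated, crit)
    member_species <- res$sim$proteins %>%
      select(sequence = "gene_id", "species")
    res$revision <<- reconcile_registry(res$calls, config$prior_registry,
                                        member_species = member_species,
                                        series_prefix = config$series_prefix)
    res$revision$registry <<- assign_letters(res$revision$registry)
    calls_flat <- res$calls %>%
      mutate(members = purrr::map_chr(.data$members, paste, collapse = ","))
    emit(function(x, p) readr::write_tsv(x, p), calls_flat, "calls.tsv")
    emit(write_registry, res$revision$registry, "registry.tsv")
    emit(function(x, p) readr::write_tsv(x, p), res$revision$report,
         "revision_report.tsv")
  })

  if ("gainloss" %in% config$stages) run_stage("gainloss", function() {
    if (is.null(res$sim)) abort("gainloss requires the simulate stage")
    res$dollo <<- dollo_events(res$sim$presence, config$sim$species_tree)
    emit(function(x, p) readr::write_tsv(x, p), res$dollo$events, "events.tsv")
    emit(function(x, p) readr::write_tsv(x, p),
         summarize_by_node(res$dollo) %>%
           mutate(gains = purrr::map_chr(.data$gains, paste, collapse = ","),
                  losses = purrr::map_chr(.data$losses, paste, collapse = ",")),
         "events_by_node.tsv")
  })

  manifest <- tibble(file = basename(outfiles),
                     md5 = unname(tools::md5sum(outfiles)))
  structure(c(list(manifest = manifest, config = config), res),
            class = "hb_pipeline_run")
}

#' @export
print.hb_pipeline_run <- function(x, ...) {
  cat("<hb_pipeline_run>", nrow(x$manifest), "output files in",
      x$config$out_dir, "\n")
  print(x$manifest, n = Inf)
  invisible(x)
}

#' Fraction of planted families recovered as exact-membership clade calls
#'
#' A family counts as recovered when some called clade's leaf membership
#' equals the family's gene set exactly (either side of the called split,
#' since the NJ tree is unrooted). Families with fewer than two genes
#' cannot form an internal edge and are excluded from the denominator.
#'
#' @param calls An `hb_clade_calls` tibble.
#' @param sim An `hb_simulation`.
#' @return List: `rate`, `n_recovered`, `n_eligible`.
#' @export
family_recovery <- function(calls, sim) {
  all_genes <- sort(sim$proteins$gene_id)
  call_sets <- purrr::map(calls$members, sort)
  call_keys <- purrr::map_chr(call_sets, paste, collapse = ";")
  comp_keys <- purrr::map_chr(call_sets, function(m)
    paste(setdiff(all_genes, m), collapse = ";"))
  fams <- split(sim$proteins$gene_id, sim$proteins$family_id)
  fams <- fams[purrr::map_int(fams, length) >= 2L]
  fams <- fams[purrr::map_int(fams, length) <= length(all_genes) - 2L]
  hit <- purrr::map_lgl(fams, function(g) {
    key <- paste(sort(g), collapse = ";")
    key %in% call_keys || key %in% comp_keys
  })
  list(rate = mean(hit), n_recovered = sum(hit), n_eligible = length(fams))
}
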