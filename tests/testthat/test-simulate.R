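test_that("no-event limit gives one gene per species and an all-true matrix", {
  cfg <- sim_config(duplication_rate = 0, loss_rate = 0, n_families = 5,
                    seed = 3)
  fams <- simulate_families(cfg)
  nsp <- length(cfg$species_tree$tip.label)
  expect_true(all(fams$n_genes == nsp))
  expect_true(all(fams$n_duplications == 0L))
  pm <- presence_matrix(fams)
  expect_true(all(as.matrix(pm[, -1])))
})

test_that("per-edge loss probability matches the binomial expectation", {
  # star tree of 5 species, edge length t: loss probability 1 - exp(-l t)
  star <- paste0("(", paste(sprintf("s%d:0.5", 1:5), collapse = ","), ");")
  l <- 0.6
  p_expect <- 1 - exp(-l * 0.5)
  n_fam <- 4000L
  cfg <- sim_config(species_tree = star, duplication_rate = 0, loss_rate = l,
                    n_families = n_fam, seed = 11)
  fams <- simulate_families(cfg)
  absent <- vapply(fams$presence, function(p) sum(!p), integer(1))
  p_hat <- sum(absent) / (5 * n_fam)
  se <- sqrt(p_expect * (1 - p_expect) / (5 * n_fam))
  expect_lt(abs(p_hat - p_expect), 3 * se)
})

test_that("duplication counts follow the pure-birth expectation", {
  # pure birth on one edge of length t: E[duplications] = e^(d t) - 1
  star <- "(s1:0.4,s2:0.4,s3:0.4);"
  d <- 0.5
  n_fam <- 3000L
  cfg <- sim_config(species_tree = star, duplication_rate = d, loss_rate = 0,
                    n_families = n_fam, seed = 13)
  fams <- simulate_families(cfg)
  mu <- 3 * (exp(d * 0.4) - 1)
  m_hat <- mean(fams$n_duplications)
  se <- sd(fams$n_duplications) / sqrt(n_fam)
  expect_lt(abs(m_hat - mu), 3 * se)
})

test_that("a high-duplication terminal edge yields single-species expansions", {
  # one long terminal edge with all the duplication opportunity
  sp <- "((burst:2.0,quiet:0.0001):0.0001,out:0.0001);"
  cfg <- sim_config(species_tree = sp, duplication_rate = 1.5, loss_rate = 0,
                    n_families = 30, seed = 17)
  fams <- simulate_families(cfg)
  extra <- dplyr::bind_rows(fams$members) %>%
    dplyr::count(.data$species)
  n_burst <- extra$n[extra$species == "burst"]
  expect_gt(n_burst, 30)                       # expanded
  expect_true(all(extra$n[extra$species != "burst"] == 30))  # not expanded
})

test_that("rate-zero sequences equal the root profile exactly", {
  cfg <- sim_config(duplication_rate = 0, loss_rate = 0,
                    substitution_rate = 0, family_divergence = 0,
                    n_families = 2, tale_fraction = 0.5,
                    double_hd_fraction = 0, seed = 5)
  fams <- simulate_families(cfg)
  seqs <- evolve_sequences(fams, cfg)
  profiles <- default_root_profiles()
  for (i in seq_len(nrow(seqs$proteins))) {
    p <- seqs$proteins[i, ]
    dom <- seqs$domains[seqs$domains$gene_id == p$gene_id &
                          seqs$domains$hd_index == 1L, ]
    hd <- substr(p$seq, dom$aa_start + 1L, dom$aa_end)
    expect_identical(hd, profiles[[p$hd_type]])
  }
  # zero variant columns within each family's true alignment
  for (a in seqs$family_alignments) {
    expect_length(unique(a$seq), 1L)
  }
})

test_that("per-site divergence over one branch follows 1 - exp(-r t)", {
  # one ancestor-descendant branch, 10,000 sites
  set.seed(23)
  L <- 10000L
  root <- random_aa(L)
  r_t <- 0.35
  derived <- homeoclass:::mutate_seq(root, r_t)
  p_hat <- mean(strsplit(root, "")[[1]] != strsplit(derived, "")[[1]])
  p_expect <- 1 - exp(-r_t)
  se <- sqrt(p_expect * (1 - p_expect) / L)
  expect_lt(abs(p_hat - p_expect), 3 * se)
})

test_that("TALE proteins carry 63-aa domains and non-TALE 60-aa", {
  sim <- simulate_homeobox_data(sim_config(n_families = 4, seed = 7))
  lens <- with(sim$truth, hd_end_nt - hd_start_nt)
  expect_true(all(lens[sim$truth$hd_type == "TALE"] == 3 * 63))
  expect_true(all(lens[sim$truth$hd_type == "nonTALE"] == 3 * 60))
})

test_that("truth-table coordinates round trip through the scaffolds", {
  sim <- simulate_homeobox_data(sim_config(n_families = 5, seed = 19))
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    prot <- sim$proteins$seq[sim$proteins$gene_id == tr$gene_id]
    dom <- sim$domains[sim$domains$gene_id == tr$gene_id &
                         sim$domains$hd_index == tr$hd_index, ]
    expect_identical(excise_truth_domain(sim$scaffolds, tr),
                     substr(prot, dom$aa_start + 1L, dom$aa_end))
  }
  expect_setequal(unique(sim$truth$strand), c("+", "-"))
})

test_that("flank-free scaffolds are exactly 3x the protein length", {
  sim <- simulate_homeobox_data(sim_config(n_families = 2,
                                           scaffold_flank_length = 0,
                                           seed = 3))
  lens <- setNames(nchar(sim$proteins$seq), sim$proteins$gene_id)
  for (i in seq_len(nrow(sim$scaffolds))) {
    gid <- sub("^scf_", "", sim$scaffolds$id[i])
    expect_identical(nchar(sim$scaffolds$seq[i]), 3L * lens[[gid]])
  }
})

test_that("all-double all-degraded config marks every TALE gene accordingly", {
  cfg <- sim_config(n_families = 4, tale_fraction = 1,
                    double_hd_fraction = 1, degrade_fraction = 1, seed = 29)
  sim <- simulate_homeobox_data(cfg)
  per_gene <- split(sim$truth$intact, sim$truth$gene_id)
  for (g in per_gene) {
    expect_setequal(g, c("intact", "degraded"))
  }
})

test_that("identical seeds give byte-identical FASTA and TSV outputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    sim <- simulate_homeobox_data(sim_config(n_families = 3, seed = 31))
    write_fasta(sim$scaffolds, file.path(d, "scf.fasta"))
    readr::write_tsv(sim$truth, file.path(d, "truth.tsv"))
  }
  expect_identical(readLines(file.path(d1, "scf.fasta")),
                   readLines(file.path(d2, "scf.fasta")))
  expect_identical(readLines(file.path(d1, "truth.tsv")),
                   readLines(file.path(d2, "truth.tsv")))
})

test_that("presence matrix derived from the truth table matches family truth", {
  sim <- simulate_homeobox_data(sim_config(n_families = 6, seed = 37))
  from_truth <- sim$truth %>%
    dplyr::distinct(.data$family_id, species = sub("^fam[0-9]+_([A-Za-z]+)_.*$",
                                                   "\\1", .data$gene_id))
  pm <- sim$presence
  for (i in seq_len(nrow(pm))) {
    fam <- pm$family[i]
    expected <- from_truth$species[from_truth$family_id == fam]
    observed <- names(pm)[-1][unlist(pm[i, -1])]
    expect_setequal(observed, expected)
  }
})

test_that("a malformed species tree names the problem", {
  expect_error(sim_config(species_tree = "((a:1,b:1):1,c:1"), "malformed")
})
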