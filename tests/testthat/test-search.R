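test_that("six-frame translation covers both strands and all offsets", {
  expect_equal(translate_six_frames("ATG")$aa[1], "M")
  rev0 <- translate_six_frames("CAT") %>%
    dplyr::filter(strand == "-", frame == 0)
  expect_equal(rev0$aa, "M")
  fr <- translate_six_frames("ATGAAACCC")
  expect_equal(nrow(fr), 6L)
  expect_equal(nchar(fr$aa[fr$strand == "+" & fr$frame == 0]), 3L)
  expect_equal(nchar(fr$aa[fr$strand == "+" & fr$frame == 1]), 2L)
  expect_error(translate_six_frames("ATGZZZ"), "positions")
  expect_match(translate_six_frames("ATGNNA")$aa[1], "X")
})

test_that("planted domains appear verbatim in their recorded frame", {
  sim <- simulate_homeobox_data(sim_config(n_families = 3, seed = 43))
  for (i in seq_len(nrow(sim$truth))) {
    r <- sim$truth[i, ]
    scf <- sim$scaffolds$seq[sim$scaffolds$id == r$scaffold_id]
    fr <- translate_six_frames(scf, r$scaffold_id)
    faa <- fr$aa[fr$strand == r$strand & fr$frame == r$frame]
    expect_true(grepl(excise_truth_domain(sim$scaffolds, r), faa, fixed = TRUE))
  }
})

test_that("TALE typing discriminates the loop extension", {
  profiles <- default_root_profiles()
  expect_equal(classify_tale(profiles$nonTALE)$hd_type, "nonTALE")
  expect_equal(classify_tale(profiles$TALE)$hd_type, "TALE")
  # inserting any 3 residues between positions 24 and 25 flips the class
  made_tale <- homeoclass:::tale_insert(profiles$nonTALE, "QQQ")
  expect_equal(classify_tale(made_tale)$hd_type, "TALE")
})

test_that("domain excision honours flanks and records clamping", {
  src <- paste(rep("A", 200), collapse = "")
  e0 <- excise_domain(src, 100, 160, 0)
  expect_equal(c(e0$aa_start, e0$aa_end), c(100, 160))
  expect_false(e0$clamped)
  e5 <- excise_domain(src, 100, 160, 5)
  expect_equal(c(e5$aa_start, e5$aa_end), c(95, 165))
  expect_equal(nchar(e5$seq), 70L)
  ec <- excise_domain(src, 2, 62, 5)
  expect_equal(ec$aa_start, 0)
  expect_true(ec$clamped)
  expect_error(excise_domain(src, 50, 40), "inverted")
})

test_that("empty target sets saturate immediately with zero hits", {
  res <- recursive_scan(tibble::tibble(id = character(0), seq = character(0)),
                        scan_seed_queries(), scan_config())
  expect_equal(nrow(res$hits), 0L)
  expect_equal(res$iterations, 1L)
  expect_true(res$saturated)
})

test_that("a two-step homology chain is only completed at iteration 2", {
  profiles <- default_root_profiles()
  cfg <- scan_config()
  set.seed(47)
  tries <- 0L
  repeat {
    tries <- tries + 1L
    near <- mutate_fraction(profiles$nonTALE, 0.30)
    distant <- mutate_fraction(near, 0.30)
    s_seed_near <- homeoclass:::sw_score(profiles$nonTALE, near, cfg)
    s_seed_far <- homeoclass:::sw_score(profiles$nonTALE, distant, cfg)
    s_near_far <- homeoclass:::sw_score(near, distant, cfg)
    if (s_seed_near >= cfg$accept_score && s_near_far >= cfg$accept_score &&
          s_seed_far < cfg$accept_score) break
    if (tries > 500L) stop("could not construct the homology chain")
  }
  targets <- tibble::tibble(
    id = c("t_near", "t_far"),
    seq = c(paste0(random_aa(40), near, random_aa(40)),
            paste0(random_aa(40), distant, random_aa(40))))
  seeds <- tibble::tibble(query_id = "seed", seq = profiles$nonTALE)
  res <- recursive_scan(targets, seeds, cfg)
  expect_true(res$saturated)
  expect_gte(res$iterations, 2L)
  far_hit <- res$hits[res$hits$source_id == "t_far" &
                        res$hits$intactness == "intact", ]
  expect_equal(nrow(far_hit), 1L)
  expect_match(far_hit$best_query_id, "t_near")
  iters <- res$pool$provenance[grepl("t_far", res$pool$query_id)]
  expect_true(all(iters == "discovered-iteration-2"))
})

test_that("scan results are deterministic and re-scoring confirms hits", {
  sim <- simulate_homeobox_data(sim_config(n_families = 4, seed = 53))
  cfg <- scan_config()
  r1 <- recursive_scan(sim$scaffolds, scan_seed_queries(), cfg)
  r2 <- recursive_scan(sim$scaffolds, scan_seed_queries(), cfg)
  expect_identical(r1$hits, r2$hits)
  # every intact hit re-scores at least the acceptance threshold against
  # its best query
  pool_seq <- setNames(r1$pool$seq, r1$pool$query_id)
  for (i in which(r1$hits$intactness == "intact")) {
    h <- r1$hits[i, ]
    q <- pool_seq[[h$best_query_id]]
    expect_gte(homeoclass:::sw_score(q, h$hd_seq, cfg), cfg$accept_score)
  }
})

test_that("moderate-divergence recovery finds planted domains precisely", {
  sim <- simulate_homeobox_data(sim_config(n_families = 6, seed = 59))
  res <- recursive_scan(sim$scaffolds, scan_seed_queries(), scan_config())
  s <- recovery_summary(sim, res)
  expect_gte(s$recovery, 0.95)
  expect_equal(s$n_false_pos, 0L)
})

test_that("architecture calls follow the intact/degraded hit pattern", {
  one <- tibble::tibble(source_id = "g", intactness = "intact")
  expect_equal(detect_architecture(one), "single")
  expect_equal(detect_architecture(
    tibble::tibble(source_id = "g", intactness = c("intact", "intact"))),
    "double")
  expect_equal(detect_architecture(
    tibble::tibble(source_id = "g", intactness = c("intact", "degraded"))),
    "double_with_degraded")
  expect_equal(detect_architecture(
    tibble::tibble(source_id = "g", intactness = "truncated")),
    "fragment")
  expect_error(detect_architecture(one[0, ]), "hit-bearing")
  expect_error(detect_architecture(
    tibble::tibble(source_id = c("a", "b"), intactness = "intact")),
    "one source")
})

test_that("read quantification applies inclusive identity and coverage rules", {
  set.seed(61)
  transcript <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  mutate_read <- function(s, positions) {
    x <- strsplit(s, "")[[1]]
    for (p in positions) x[p] <- setdiff(c("A", "C", "G", "T"), x[p])[1]
    paste(x, collapse = "")
  }
  copies <- vapply(c(1, 101, 201), function(o) {
    mutate_read(substr(transcript, o, o + 99), c(20, 40, 60, 80))
  }, character(1))
  randoms <- vapply(1:2, function(i)
    paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""),
    character(1))
  reads <- tibble::tibble(id = paste0("r", 1:5), seq = c(copies, randoms))
  q <- quantify_reads(reads, transcript, quant_config(library_total = 1e6))
  expect_equal(q$raw_count, 3L)
  expect_equal(q$normalized_count, 3)
  # a read at exactly 95.0% identity counts (boundary inclusive)
  boundary <- mutate_read(substr(transcript, 301, 400),
                          seq(10, 95, length.out = 5))
  qb <- quantify_reads(tibble::tibble(id = "b", seq = boundary), transcript,
                       quant_config())
  expect_equal(qb$per_read$identity, 0.95)
  expect_equal(qb$raw_count, 1L)
  # empty read set
  q0 <- quantify_reads(reads[0, ], transcript, quant_config())
  expect_equal(q0$raw_count, 0L)
  expect_equal(q0$normalized_count, 0)
})
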