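make_annotated <- function(nj = NA, ml = NA, bayes = NA) {
  tgt <- parse_newick_string("((A,B),(C,(D,E)));")
  supports <- bipartitions(tgt) %>%
    dplyr::transmute(node = .data$node, key = .data$key,
                     nj = NA_real_, ml = NA_real_, bayes = NA_real_)
  focal <- supports$key == "D;E"
  supports$nj[focal] <- nj
  supports$ml[focal] <- ml
  supports$bayes[focal] <- bayes
  structure(list(tree = tgt, supports = supports, nj_replicates = 1000L),
            class = "hb_annotated_tree")
}

test_that("clade criteria combine support, all-three and structure evidence", {
  # (ABSENT, 65%, pp 0.60): max 65 <= 70 and an absent slot -> no clade
  at <- make_annotated(ml = 65, bayes = 0.60)
  calls <- call_clades(at)
  expect_equal(nrow(dplyr::filter(calls, .data$node ==
    at$supports$node[at$supports$key == "D;E"])), 0L)

  # (500/1000, 60%, 0.65): nothing above 70 but present in all three
  at2 <- make_annotated(nj = 500, ml = 60, bayes = 0.65)
  calls2 <- call_clades(at2)
  row2 <- dplyr::filter(calls2, .data$node ==
    at2$supports$node[at2$supports$key == "D;E"])
  expect_equal(row2$justification, "all-three")
  expect_setequal(row2$members[[1]], c("D", "E"))

  # (ABSENT, 40%, 0.50) + structure tag -> structure call
  at3 <- make_annotated(ml = 40, bayes = 0.50)
  node3 <- at3$supports$node[at3$supports$key == "D;E"]
  crit3 <- clade_criteria(structure_evidence =
    setNames("two-homeodomain architecture", as.character(node3)))
  calls3 <- call_clades(at3, crit3)
  row3 <- dplyr::filter(calls3, .data$node == node3)
  expect_equal(row3$justification, "structure")

  # support beats all-three in the justification order
  at4 <- make_annotated(nj = 900, ml = 60, bayes = 0.65)
  row4 <- dplyr::filter(call_clades(at4), .data$node ==
    at4$supports$node[at4$supports$key == "D;E"])
  expect_equal(row4$justification, "support")

  # the 70% boundary is strict by default, configurable otherwise
  at5 <- make_annotated(nj = 700, ml = 70, bayes = 0.70)
  expect_equal(dplyr::filter(call_clades(at5), .data$node ==
    at5$supports$node[at5$supports$key == "D;E"])$justification, "all-three")
  lax <- clade_criteria(require_strict = FALSE)
  expect_equal(dplyr::filter(call_clades(at5, lax), .data$node ==
    at5$supports$node[at5$supports$key == "D;E"])$justification, "support")
})

test_that("reconciliation against an identical prior is a fixed point", {
  prior <- tibble::tibble(
    clade = c("TALE-I", "TALE-I", "TALE-II"),
    species = c("sp1", "sp2", "sp1"),
    sequence = c("q1", "q2", "q3"),
    letter = "", origin = "P", prior = "NONE")
  calls <- tibble::tibble(clade = c("TALE-I", "TALE-II"),
                          members = list(c("q1", "q2"), "q3"))
  rev <- reconcile_registry(calls, prior)
  expect_equal(rev$tallies$new_clades, 0L)
  expect_equal(rev$tallies$clades_with_additions, 0L)
  expect_equal(rev$tallies$clades_losing_members, 0L)
  expect_identical(rev$registry, prior)
})

test_that("unclassified members join a matched prior clade as origin N", {
  prior <- tibble::tibble(
    clade = "TALE-VI", species = c("sp1", "sp1", "sp2"),
    sequence = c("v1", "v2", "v3"), letter = "", origin = "P",
    prior = "NONE")
  calls <- tibble::tibble(clade = "c1",
                          members = list(c("v1", "v2", "v3", "new1", "new2")))
  rev <- reconcile_registry(calls, prior,
                            member_species = tibble::tibble(
                              sequence = c("new1", "new2"),
                              species = c("sp3", "sp3")))
  added <- rev$registry[rev$registry$sequence %in% c("new1", "new2"), ]
  expect_equal(added$clade, c("TALE-VI", "TALE-VI"))
  expect_equal(added$origin, c("N", "N"))
  expect_equal(rev$tallies$clades_with_additions, 1L)
})

test_that("wholly unclassified calls erect the next Roman numeral", {
  prior <- tibble::tibble(
    clade = paste0("TALE-", as.character(utils::as.roman(1:19))),
    species = "sp", sequence = paste0("s", 1:19), letter = "",
    origin = "P", prior = "NONE")
  calls <- tibble::tibble(clade = "x", members = list(c("a1", "a2")))
  rev <- reconcile_registry(calls, prior)
  expect_true(all(rev$report$clade == "TALE-XX"))
  expect_equal(rev$tallies$new_clades, 1L)
})

test_that("reclassification is recorded with the prior clade name", {
  prior <- tibble::tibble(
    clade = c("TALE-IV", "TALE-IV", "TALE-VI"),
    species = "sp", sequence = c("a1", "a2", "b1"), letter = "",
    origin = "P", prior = "NONE")
  calls <- tibble::tibble(clade = "c",
                          members = list(c("a1", "a2", "b1")))
  rev <- reconcile_registry(calls, prior)
  row <- rev$registry[rev$registry$sequence == "b1", ]
  expect_equal(row$clade, "TALE-IV")
  expect_equal(row$prior, "TALE-VI")
  expect_equal(rev$tallies$clades_losing_members, 1L)
})

test_that("paralogue letters follow the stable per-species series", {
  reg <- tibble::tibble(
    clade = "TALE-VIII", species = "S_lamarcki",
    sequence = paste0("s", 8:1),   # deliberately unsorted
    letter = "", origin = "N", prior = "NONE")
  out <- assign_letters(reg)
  expect_equal(out$letter[order(out$sequence)], LETTERS[1:8])

  solo <- tibble::tibble(clade = "TALE-XIV", species = c("sp1", "sp2"),
                         sequence = c("x", "y"), letter = "",
                         origin = "N", prior = "NONE")
  expect_true(all(assign_letters(solo)$letter == ""))

  # 15 unlettered members with A occupied letter from B onward
  reg2 <- tibble::tibble(
    clade = "TALE-XIX", species = "H_robusta",
    sequence = c("a0", paste0("m", sprintf("%02d", 1:15))),
    letter = c("A", rep("", 15)), origin = "N", prior = "NONE")
  out2 <- assign_letters(reg2)
  expect_equal(out2$letter, c("A", LETTERS[2:16]))

  # beyond Z the series goes AA, AB, ...
  reg3 <- tibble::tibble(
    clade = "c", species = "sp",
    sequence = sprintf("s%02d", 1:28), letter = "",
    origin = "N", prior = "NONE")
  out3 <- assign_letters(reg3)
  expect_equal(tail(out3$letter, 2), c("AA", "AB"))

  # letters are stable across re-runs
  expect_identical(assign_letters(out2), out2)
})

test_that("collapsing clades shrinks the tree by members minus one", {
  tr <- ape::rtree(10)
  tr$tip.label <- paste0("t", 1:10)
  expect_identical(collapse_clades(tr, list()), tr)
  # use a genuine clade: the tips of one internal node
  node <- ape::Ntip(tr) + 2L
  members <- homeoclass:::clade_members(tr, node)
  out <- collapse_clades(tr, setNames(list(members), "CladeA"))
  expect_equal(ape::Ntip(out), 10L - length(members) + 1L)
  expect_true("CladeA" %in% out$tip.label)
  expect_error(collapse_clades(tr, list(a = c("t1", "t2"), b = c("t2", "t3"))),
               "overlap")
})

test_that("registry reconciliation applied twice changes nothing", {
  reg <- spiralian_tale_registry()
  prior <- prior_registry(reg)
  calls <- registry_calls(reg)
  rev1 <- reconcile_registry(calls, prior,
                             member_species = reg[, c("sequence", "species")])
  calls2 <- registry_calls(rev1$registry)
  rev2 <- reconcile_registry(calls2, rev1$registry)
  expect_equal(rev2$tallies$new_clades, 0L)
  expect_equal(rev2$tallies$clades_with_additions, 0L)
  expect_equal(rev2$tallies$clades_losing_members, 0L)
  expect_true(all(rev2$report$outcome == "unchanged"))
})
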