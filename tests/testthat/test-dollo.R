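test_that("taxon-group collapse applies the any-gain / all-loss rule", {
  m <- tibble::tibble(family = c("f1", "f2"),
                      L_gigantea = c(TRUE, FALSE),
                      P_vulgata = c(FALSE, FALSE),
                      C_teleta = c(TRUE, TRUE))
  g <- tibble::tibble(taxon = c("L_gigantea", "P_vulgata", "C_teleta"),
                      group = c("Gastropoda", "Gastropoda", "C_teleta"))
  out <- collapse_taxa(m, g)
  expect_true(out$Gastropoda[out$family == "f1"])    # present in any member
  expect_false(out$Gastropoda[out$family == "f2"])   # absent from all
  # singleton groups leave the matrix unchanged
  ident <- tibble::tibble(taxon = names(m)[-1], group = names(m)[-1])
  expect_equal(collapse_taxa(m, ident), m)
  expect_error(collapse_taxa(m, g[1:2, ]), "does not cover")
})

test_that("textbook Dollo reconstructions are reproduced", {
  clad <- parse_newick_string("((A,B)ab,(C,D)cd)root;")
  # present everywhere: one gain at the root
  m1 <- tibble::tibble(family = "f", A = 1, B = 1, C = 1, D = 1)
  d1 <- dollo_events(m1, clad)
  expect_equal(d1$events$type, "gain")
  expect_equal(d1$events$node_label, "root")
  # A=1 B=0 C=0 D=1: gain at root plus losses on B and C
  m2 <- tibble::tibble(family = "f", A = 1, B = 0, C = 0, D = 1)
  d2 <- dollo_events(m2, clad)
  expect_equal(sum(d2$events$type == "gain"), 1L)
  expect_equal(d2$events$node_label[d2$events$type == "gain"], "root")
  expect_setequal(d2$events$node_label[d2$events$type == "loss"], c("B", "C"))
  expect_equal(dollo_oracle(c(A = 1, B = 0, C = 0, D = 1), clad), 3L)
  # single-species family: terminal gain, no losses
  m3 <- tibble::tibble(family = "f", A = 1, B = 0, C = 0, D = 0)
  d3 <- dollo_events(m3, clad)
  expect_equal(d3$events$type, "gain")
  expect_equal(d3$events$node_label, "A")
  expect_error(dollo_events(tibble::tibble(family = "f", A = 0, B = 0,
                                           C = 0, D = 0), clad),
               "absent everywhere")
})

test_that("Dollo reconstruction invariants hold on random inputs", {
  set.seed(71)
  for (i in 1:40) {
    n <- sample(5:9, 1)
    tree <- ape::rtree(n)
    tree$tip.label <- paste0("t", seq_len(n))
    pres <- as.logical(rbinom(n, 1, 0.5))
    if (!any(pres)) pres[sample(n, 1)] <- TRUE
    m <- tibble::tibble(family = "f", !!!setNames(as.list(pres), tree$tip.label))
    d <- dollo_events(m, tree)
    # exactly one gain
    expect_equal(sum(d$events$type == "gain"), 1L)
    gain <- d$events$node[d$events$type == "gain"]
    # every loss lies strictly below the gain
    below <- unlist(homeoclass:::phangorn_free_descendants(tree, gain))
    losses <- d$events$node[d$events$type == "loss"]
    for (l in losses) {
      lt <- if (l <= n) l else unlist(
        homeoclass:::phangorn_free_descendants(tree, l))
      expect_true(all(lt %in% below))
    }
    # implied leaf states reproduce the input row
    lost_tips <- unique(unlist(lapply(losses, function(l)
      if (l <= n) l else unlist(
        homeoclass:::phangorn_free_descendants(tree, l)))))
    gained_tips <- if (gain <= n) gain else below
    implied <- seq_len(n) %in% setdiff(gained_tips, lost_tips)
    expect_identical(implied, unname(pres))
  }
})

test_that("event counts match the exhaustive single-gain oracle", {
  set.seed(73)
  checked <- 0L
  for (rep in 1:50) {
    n <- sample(5:10, 1)
    tree <- ape::rtree(n)
    tree$tip.label <- paste0("t", seq_len(n))
    pres_mat <- matrix(rbinom(10 * n, 1, runif(1, 0.3, 0.7)) > 0, nrow = 10)
    keep <- rowSums(pres_mat) > 0
    pres_mat <- pres_mat[keep, , drop = FALSE]
    if (nrow(pres_mat) == 0) next
    m <- tibble::tibble(family = paste0("f", seq_len(nrow(pres_mat))))
    for (j in seq_len(n)) m[[tree$tip.label[j]]] <- pres_mat[, j]
    d <- dollo_events(m, tree)
    for (f in seq_len(nrow(pres_mat))) {
      ours <- sum(d$events$family == paste0("f", f))
      oracle <- dollo_oracle(pres_mat[f, ], tree)
      expect_equal(ours, oracle)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 400L)
})

test_that("adding a present taxon cannot drop the event count by more than 1", {
  set.seed(79)
  for (rep in 1:20) {
    n <- 8L
    tree <- ape::rtree(n)
    tree$tip.label <- paste0("t", seq_len(n))
    pres <- as.logical(rbinom(n, 1, 0.4))
    if (!any(pres)) pres[1] <- TRUE
    absent <- which(!pres)
    if (length(absent) == 0) next
    m1 <- tibble::tibble(family = "f", !!!setNames(as.list(pres),
                                                   tree$tip.label))
    pres2 <- pres; pres2[sample(absent, 1)] <- TRUE
    m2 <- tibble::tibble(family = "f", !!!setNames(as.list(pres2),
                                                   tree$tip.label))
    e1 <- nrow(dollo_events(m1, tree)$events)
    e2 <- nrow(dollo_events(m2, tree)$events)
    expect_gte(e2, e1 - 1L)
  }
})

test_that("per-node summaries conserve event totals", {
  expect_equal(nrow(summarize_by_node(tibble::tibble(
    family = character(0), node = integer(0), node_label = character(0),
    type = character(0)))), 0L)
  clad <- parse_newick_string("((A,B)ab,(C,D)cd)root;")
  m <- tibble::tibble(family = paste0("f", 1:6),
                      A = c(1, 1, 1, 0, 1, 1), B = c(1, 0, 1, 0, 1, 0),
                      C = c(1, 0, 0, 1, 1, 0), D = c(1, 1, 0, 1, 0, 0))
  d <- dollo_events(m, clad)
  s <- summarize_by_node(d)
  expect_equal(sum(s$n_gain), 6L)           # one gain per family
  expect_equal(sum(s$n_gain) + sum(s$n_loss), nrow(d$events))
  expect_equal(sort(unlist(s$gains)), sort(d$events$family[
    d$events$type == "gain"]))
})

test_that("registry presence on the shipped cladogram places deep gains deep", {
  reg <- spiralian_tale_registry()
  clad <- read_newick(system.file("extdata", "spiralian_cladogram.nwk",
                                  package = "homeoclass"))
  m <- registry_presence(reg, species = clad$tip.label)
  grouping <- tibble::tibble(
    taxon = clad$tip.label,
    group = dplyr::case_when(
      clad$tip.label %in% c("C_gigas", "P_fucata") ~ "Bivalvia",
      clad$tip.label %in% c("L_gigantea", "N_fuscoviridis",
                            "P_vulgata") ~ "Gastropoda",
      TRUE ~ clad$tip.label))
  mg <- collapse_taxa(m, grouping)
  gclad <- collapse_clades(clad, list(
    Bivalvia = c("C_gigas", "P_fucata"),
    Gastropoda = c("L_gigantea", "N_fuscoviridis", "P_vulgata")))
  d <- dollo_events(mg, gclad)
  gains <- d$events[d$events$type == "gain", ]
  # clades spanning annelids, molluscs and the brachiopod arise at the
  # deepest (lophotrochozoan) node
  expect_equal(gains$node_label[gains$family == "TALE-I"], "Lophotrochozoa")
  expect_equal(gains$node_label[gains$family == "TALE-XIII"],
               "Lophotrochozoa")
  # genus- or group-restricted clades arise on their own branches
  expect_equal(gains$node_label[gains$family == "TALE-XVI"], "H_robusta")
  expect_equal(gains$node_label[gains$family == "TALE-XIX"], "H_robusta")
  expect_equal(gains$node_label[gains$family == "TALE-XV"], "Gastropoda")
  # the biggest cluster of gains sits at the deepest sampled node
  s <- summarize_by_node(d)
  expect_equal(s$node_label[which.max(s$n_gain)], "Lophotrochozoa")
})
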