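graft_table <- function() {
  load_taxon_table(data.frame(
    species = c("A", "B", "C", "D", "E", "F", "Z"),
    genus = c("G1", "G1", "G2", "G2", "G1", "G3", "G9"),
    family = c("FamX", "FamX", "FamY", "FamY", "FamX", "FamY", "FamZ"),
    element = "PT", r1 = 1L, stringsAsFactors = FALSE))
}

test_that("S1 grafts congeners as crown polytomies and preserves ages", {
  tab <- graft_table()[1:5, ]  # add E in genus G1
  attr(tab, "regions") <- "r1"
  g <- graft_taxa(t4(), tab, "S1")
  tr <- g$tree
  expect_setequal(tr$tip.label, c("A", "B", "C", "D", "E"))
  expect_true(attr(tr, "ultrametric"))
  expect_equal(max(ape::node.depth.edgelength(tr)), 2)
  dm <- oracle_patristic(tr)
  expect_equal(dm["E", "A"], 2)  # joined at the G1 crown (age 1)
  expect_equal(dm["E", "C"], 4)
  expect_equal(g$report$polytomy, "E")
  # pre-existing pairwise distances unchanged
  d0 <- oracle_patristic(t4())
  expect_equal(dm[rownames(d0), colnames(d0)], d0, tolerance = 1e-9)
})

test_that("a species joining a monotypic genus splits the pendant edge", {
  tab <- load_taxon_table(data.frame(
    species = c("A", "B", "C", "D", "F"),
    genus = c("G1", "G1", "G2", "G3", "G3"),
    family = c("FamX", "FamX", "FamY", "FamY", "FamY"),
    element = "PT", r1 = 1L))
  g <- graft_taxa(t4(), tab, "S1")  # F joins D, D's genus is monotypic
  tr <- g$tree
  expect_true(attr(tr, "ultrametric"))
  dm <- oracle_patristic(tr)
  expect_equal(dm["F", "D"], 1)   # attachment node at age 0.5
  expect_equal(dm["F", "C"], 2)
  d0 <- oracle_patristic(t4())
  expect_equal(dm[rownames(d0), colnames(d0)], d0, tolerance = 1e-9)
})

test_that("taxa with no containing clade on the tree are left unplaced", {
  tab <- graft_table()
  g <- graft_taxa(t4(), tab, "S1")
  expect_equal(g$report$unplaced, "Z")  # family FamZ absent
  expect_setequal(g$report$polytomy, c("E", "F"))
  # report lists partition the added taxa
  expect_equal(length(g$report$polytomy) + length(g$report$random) +
                 length(g$report$scenario3) + length(g$report$unplaced), 3L)
})

test_that("grafting requires an ultrametric backbone for S1/S3 and a seed for S2/S3", {
  tab <- graft_table()
  nonultra <- read_newick(text = "((A:1,B:3):1,(C:1,D:1):1);")
  expect_error(graft_taxa(nonultra, tab, "S1"), "ultrametric")
  expect_error(graft_taxa(t4(), tab, "S2"), "seed")
  expect_error(graft_taxa(t4(), tab, "S3"), "seed")
})

test_that("S2 attaches within the clade, reproducibly under a seed", {
  tab <- graft_table()
  g1 <- graft_taxa(t4(), tab, "S2", seed = 42)
  g2 <- graft_taxa(t4(), tab, "S2", seed = 42)
  expect_identical(write_newick(g1$tree), write_newick(g2$tree))
  expect_true(attr(g1$tree, "ultrametric"))
  dm <- oracle_patristic(g1$tree)
  # E stays within genus G1 = {A,B}: closer to them than to the other clade
  expect_lt(min(dm["E", c("A", "B")]), min(dm["E", c("C", "D")]))
  expect_setequal(g1$report$random, c("E", "F"))
})

test_that("S3 grafting re-dates new nodes but keeps backbone ages", {
  tab <- graft_table()
  g <- graft_taxa(t4(), tab, "S3", seed = 1)
  tr <- g$tree
  expect_true(attr(tr, "ultrametric"))
  d0 <- oracle_patristic(t4())
  dm <- oracle_patristic(tr)
  expect_equal(dm[rownames(d0), colnames(d0)], d0, tolerance = 1e-9)
  expect_setequal(g$report$scenario3, c("E", "F"))
})

test_that("prune-then-regraft restores patristic distances", {
  n_done <- 0L; seed <- 0L
  while (n_done < 8L && seed < 40L) {
    seed <- seed + 1L
    tr <- simulate_tree(12, "yule", seed = seed)
    tax <- tryCatch(simulate_taxonomy(tr, 2, 2), error = function(e) NULL)
    if (is.null(tax)) next
    # need a tip with >= 2 congeners so S1 reattaches at the genus crown
    counts <- table(tax$genus)
    g_ok <- names(counts)[counts >= 3]
    if (!length(g_ok)) next
    tab <- load_taxon_table(cbind(tax, element = "PT", r1 = 1L))
    tip <- sort(tab$species[tab$genus == g_ok[1]])[1]
    pruned <- ape::drop.tip(tr, tip)
    regrafted <- graft_taxa(pruned, tab, "S1")$tree
    keep <- setdiff(tr$tip.label, tip)
    d0 <- oracle_patristic(tr)[keep, keep]
    d1 <- oracle_patristic(regrafted)[keep, keep]
    expect_equal(d1, d0, tolerance = 1e-9)
    expect_true(attr(regrafted, "ultrametric"))
    n_done <- n_done + 1L
  }
  expect_gte(n_done, 8L)
})

test_that("bladj interpolation spaces undated nodes evenly", {
  # single undated node on a root(10) -> x -> tip chain: x gets age 5
  r1 <- bladj_smooth(chain_tree(1), data.frame(clade = "r", age_myr = 10))
  expect_equal(r1$edge.length, c(5, 5))
  # two undated nodes under root(9): ages 6 and 3
  r2 <- bladj_smooth(chain_tree(2), data.frame(clade = "r", age_myr = 9))
  expect_equal(r2$edge.length, c(3, 3, 3))
})

test_that("bladj leaves fully dated trees unchanged and rejects conflicts", {
  tr <- ape::read.tree(text = "((A:1,B:1)n1:1,(C:1,D:1)n2:1)r;")
  out <- bladj_smooth(tr, data.frame(clade = c("r", "n1", "n2"),
                                     age_myr = c(2, 1, 1)))
  expect_equal(out$edge.length, tr$edge.length)
  expect_error(bladj_smooth(tr, data.frame(clade = c("r", "n1"),
                                           age_myr = c(2, 5))),
               "conflict")
  expect_error(bladj_smooth(tr, data.frame(clade = "n1", age_myr = 1)),
               "root")
})

test_that("after bladj, ages are monotone and path sums equal the root age", {
  for (seed in 1:5) {
    tr <- withr::with_seed(seed, ape::rtree(12))
    # date the root and the MRCA of a random non-root-spanning tip pair
    tips <- withr::with_seed(seed, sample(tr$tip.label, 2))
    cal <- if (ape::getMRCA(tr, tips) == ape::Ntip(tr) + 1L)
      data.frame(clade = "root", age_myr = 20)
    else
      data.frame(clade = c("root", paste(tips, collapse = ";")),
                 age_myr = c(20, 5))
    out <- bladj_smooth(tr, cal)
    expect_true(all(out$edge.length >= 0))
    depths <- ape::node.depth.edgelength(out)[seq_len(ape::Ntip(out))]
    expect_equal(unname(depths), rep(20, ape::Ntip(out)), tolerance = 1e-9)
  }
})

test_that("collapse_to_rank keeps one relabelled exemplar per group", {
  tab <- t4_table()
  g <- collapse_to_rank(t4(), tab, "genus")
  expect_setequal(g$tip.label, c("G1", "G2"))
  dm <- oracle_patristic(g)
  expect_equal(dm["G1", "G2"], 4)  # exemplars A and C, pruned lengths 2+2
  # species rank is the identity
  expect_identical(collapse_to_rank(t4(), tab, "species"), t4())
  # single-species family: relabel only, lengths unchanged
  f <- collapse_to_rank(t4(), tab, "family")
  expect_setequal(f$tip.label, c("FamX", "FamY"))
  expect_equal(oracle_patristic(f)["FamX", "FamY"], 4)
  # rank taxa with no tips on the tree are omitted with a warning
  tr3 <- ape::keep.tip(t4(), c("A", "B", "C"))
  tab2 <- tab; tab2$family[4] <- "FamGone"
  tab2 <- load_taxon_table(as.data.frame(tab2)[c("species", "genus",
                                                 "family", "element",
                                                 "r1", "r2")])
  expect_warning(collapse_to_rank(ape::keep.tip(tr3, c("A", "B", "C")),
                                  tab2, "family"), "omitted")
})
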