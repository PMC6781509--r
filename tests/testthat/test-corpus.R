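test_that("interaction reading collapses duplicates and filters by score", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("d1\tg1", "d1\tg1", "d2\tg2"), f)
  corpus <- read_interactions(f, format = "simple_tsv")
  expect_equal(n_interactions(corpus), 2L)

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("chemical\tprotein\tcombined_score", "d1\tg1\t900", "d2\tg2\t100"), f2)
  expect_equal(n_interactions(read_interactions(f2, format = "stitch_tsv")), 2L)
  filtered <- read_interactions(f2, format = "stitch_tsv", min_score = 400)
  expect_equal(corpus_drugs(filtered), "d1")
  expect_equal(corpus_genes(filtered), "g1")
})

test_that("corpus maps are exact inverses and edge count matches brute force", {
  set.seed(7)
  drugs <- sprintf("d%d", sample(5, 100, replace = TRUE))
  genes <- sprintf("g%02d", sample(40, 100, replace = TRUE))
  corpus <- corpus_from_edges(drugs, genes)
  n_unique <- length(unique(paste(drugs, genes)))
  expect_equal(n_interactions(corpus), n_unique)
  # inverse-map invariant both ways
  for (d in corpus_drugs(corpus)) {
    for (g in corpus$drug_to_genes[[d]]) {
      expect_true(d %in% corpus$gene_to_drugs[[g]])
    }
  }
  for (g in corpus_genes(corpus)) {
    for (d in corpus$gene_to_drugs[[g]]) {
      expect_true(g %in% corpus$drug_to_genes[[d]])
    }
  }
})

test_that("corpus round-trips through the simple TSV dialect", {
  set.seed(11)
  corpus <- corpus_from_edges(sprintf("d%d", sample(4, 60, replace = TRUE)),
                              sprintf("g%02d", sample(25, 60, replace = TRUE)))
  f <- tempfile(fileext = ".tsv")
  write_interactions(corpus, f, format = "simple_tsv")
  expect_identical(read_interactions(f, format = "simple_tsv"), corpus)
  f2 <- tempfile(fileext = ".tsv")
  write_interactions(corpus, f2, format = "stitch_tsv")
  expect_identical(read_interactions(f2, format = "stitch_tsv"), corpus)
})

test_that("malformed and empty interaction files are reported", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("d1\tg1", "only-one-column"), f)
  expect_error(read_interactions(f, format = "simple_tsv"), "line 2")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(character(0), f2)
  expect_warning(corpus <- read_interactions(f2, format = "simple_tsv"), "no interactions")
  expect_equal(n_interactions(corpus), 0L)
})

test_that("well-studied filter applies the root-term rule per aspect", {
  corpus <- corpus_from_edges(c("d1", "d1", "d1", "d1"), c("gRoot", "gBP", "gCC", "gMF"))
  ann <- ann_from_table(
    gene = c("gRoot", "gBP", "gCC", "gCC", "gMF"),
    term = c("GO:0003674", "GO:0007049", "GO:0005634", "GO:0005575", "GO:0016301"),
    aspect = c("MF", "BP", "CC", "CC", "MF"))
  kept <- filter_well_studied(corpus, ann)
  # only the root MF term -> removed; one BP term -> retained;
  # CC-only annotation -> removed; non-root MF -> retained
  expect_setequal(corpus_genes(kept), c("gBP", "gMF"))
  # gene absent from annotations entirely is also removed
  corpus2 <- corpus_from_edges("d1", "gUnknown")
  expect_equal(n_interactions(filter_well_studied(corpus2, ann)), 0L)
})

test_that("label space selects drugs by strict target-count cutoff", {
  nA <- 401; nB <- 400; nC <- 10
  drugs <- c(rep("A", nA), rep("B", nB), rep("C", nC))
  genes <- c(sprintf("a%03d", 1:nA), sprintf("b%03d", 1:nB), sprintf("c%03d", 1:nC))
  corpus <- corpus_from_edges(drugs, genes)
  ls <- build_label_space(corpus, min_targets = 400, others_size = 5,
                          nontarget_size = 0, seed = 1)
  expect_equal(ls$labels, c("A", "others", "non-target"))
  expect_equal(ls$N, 3L)
  expect_equal(ls$others_index, 2L)
  expect_equal(ls$nontarget_index, 3L)
})

test_that("drug classes are numbered in descending size with lexicographic ties", {
  corpus <- corpus_from_edges(
    c(rep("B", 7), rep("A", 10), rep("C", 5), rep("Z", 10)),
    c(sprintf("gb%d", 1:7), sprintf("ga%d", 1:10), sprintf("gc%d", 1:5),
      sprintf("gz%d", 1:10)))
  ls <- build_label_space(corpus, min_targets = 0, others_size = 0,
                          nontarget_size = 0, seed = 1)
  expect_equal(ls$labels, c("A", "Z", "B", "C", "others", "non-target"))
})

test_that("sentinel gene sets are sampled from the admissible pools only", {
  # two selected drugs share 3 genes; one unselected drug has 5
  # exclusive genes plus an overlap with a selected drug
  drugs <- c(rep("big1", 7), rep("big2", 7), rep("small", 6))
  genes <- c("s1", "s2", "s3", sprintf("x%d", 1:4),
             "s1", "s2", "s3", sprintf("x%d", 5:8),
             sprintf("e%d", 1:5), "s1")
  corpus <- corpus_from_edges(drugs, genes)
  universe <- c(unique(genes), sprintf("u%d", 1:4))
  ls <- build_label_space(corpus, min_targets = 6, others_size = 2,
                          nontarget_size = 3, gene_universe = universe, seed = 5)
  others <- ls$gene_sets[[ls$others_index]]
  expect_length(others, 2L)
  expect_true(all(others %in% sprintf("e%d", 1:5)))
  nont <- ls$gene_sets[[ls$nontarget_index]]
  expect_length(nont, 3L)
  drug_genes <- unique(unlist(ls$gene_sets[1:2]))
  expect_length(intersect(nont, c(drug_genes, others)), 0L)
  # disjointness invariants
  expect_length(intersect(others, drug_genes), 0L)
})

test_that("label space construction is deterministic and seed affects only sentinels", {
  corpus <- corpus_from_edges(
    sprintf("d%d", rep(1:3, each = 8)),
    sprintf("g%02d", c(1:8, 7:14, 13:20)))
  universe <- c(sprintf("g%02d", 1:20), sprintf("h%02d", 1:10))
  ls1 <- build_label_space(corpus, min_targets = 0, others_size = 0,
                           nontarget_size = 4, gene_universe = universe, seed = 1)
  ls1b <- build_label_space(corpus, min_targets = 0, others_size = 0,
                            nontarget_size = 4, gene_universe = universe, seed = 1)
  ls2 <- build_label_space(corpus, min_targets = 0, others_size = 0,
                           nontarget_size = 4, gene_universe = universe, seed = 2)
  expect_identical(ls1, ls1b)
  expect_identical(ls1$labels, ls2$labels)
  expect_identical(ls1$gene_sets[1:3], ls2$gene_sets[1:3])
  expect_false(identical(ls1$gene_sets[[ls1$nontarget_index]],
                         ls2$gene_sets[[ls2$nontarget_index]]))
})

test_that("oversized sentinel requests report the available pool", {
  corpus <- corpus_from_edges(rep("d1", 5), sprintf("g%d", 1:5))
  expect_error(
    build_label_space(corpus, min_targets = 0, others_size = 3,
                      nontarget_size = 0, seed = 1),
    "pool of 0")
  expect_error(
    build_label_space(corpus, min_targets = 0, others_size = 0, nontarget_size = 2,
                      gene_universe = c(sprintf("g%d", 1:5), "u1"), seed = 1),
    "pool of 1")
})
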