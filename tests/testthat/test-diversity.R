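toy_table <- function() {
  m <- matrix(c(100, 0, 20, 5,
                50, 200, 0, 10,
                0, 30, 40, 0,
                600, 300, 10, 25,
                10, 0, 0, 90), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("ASV", 1:5), paste0("S", 1:4)))
  storage.mode(m) <- "integer"
  m
}

test_that("probiotic-ASV removal drops rows and reports removed reads", {
  tab <- toy_table()
  same <- remove_probiotic_asvs(tab)
  expect_identical(same$counts, tab)
  expect_true(all(same$removed_reads == 0))
  res <- remove_probiotic_asvs(tab, "ASV1")
  expect_equal(nrow(res$counts), 4)
  expect_equal(unname(res$removed_reads["S1"]), 100)
  expect_equal(colSums(res$counts), colSums(tab) - c(100, 0, 20, 5),
               ignore_attr = TRUE)
  expect_warning(remove_probiotic_asvs(tab, "NOPE"), "unknown ASV")
  # lineage-based matching
  taxonomy <- c(ASV1 = "k__Bacteria; g__Lacticaseibacillus",
                ASV2 = "k__Bacteria; g__Blautia")
  res2 <- remove_probiotic_asvs(tab, taxonomy = taxonomy,
                                lineage_pattern = "g__Lacticaseibacillus")
  expect_equal(res2$removed, "ASV1")
  # removing everything leaves a degenerate table diversity rejects
  all_gone <- remove_probiotic_asvs(tab, rownames(tab))
  expect_equal(nrow(all_gone$counts), 0)
  expect_error(alpha_diversity(all_gone$counts), "no ASVs")
})

test_that("Shannon index matches direct evaluation and its bounds", {
  expect_equal(shannon(c(0, 42, 0)), 0)
  expect_equal(shannon(rep(7, 4)), log(4))
  expect_equal(shannon(c(3, 1)), 0.5623351, tolerance = 1e-6)
  expect_error(shannon(c(0, 0)), "undefined diversity")
  set.seed(21)
  for (i in 1:20) {
    x <- rpois(12, 5)
    if (sum(x) == 0) x[1] <- 1
    h <- shannon(x)
    expect_equal(h, oracle_shannon(x), tolerance = 1e-12)
    expect_gte(h, 0)
    expect_lte(h, log(max(richness(x), 1)) + 1e-12)
    expect_equal(shannon(sample(x)), h, tolerance = 1e-12)
  }
})

test_that("richness counts strictly positive entries", {
  expect_equal(richness(c(0, 0, 0)), 0)
  expect_equal(richness(c(5, 0, 2, 1)), 3)
  tab <- toy_table()
  res <- remove_probiotic_asvs(tab, "ASV4")  # present in every sample
  for (j in 1:4) {
    expect_equal(richness(res$counts[, j]), richness(tab[, j]) - 1)
  }
})

test_that("Faith's PD equals hand path enumeration on the worked tree", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(faith_pd(tree, c("A", "B", "C", "D")), 6.0)
  expect_equal(faith_pd(tree, "A"), 2.0)
  expect_equal(faith_pd(tree, c("A", "B")), 3.0)
  expect_warning(pd0 <- faith_pd(tree, character()), "empty")
  expect_equal(pd0, 0)
  expect_error(faith_pd(tree, "Z"), "not in tree")
})

test_that("Faith's PD matches the path-enumeration oracle and is monotone", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    tree <- gen_tree(paste0("t", 1:n), seed = i)
    tips <- sample(tree$tip.label, sample(1:n, 1))
    expect_equal(faith_pd(tree, tips), oracle_faith_pd(tree, tips),
                 tolerance = 1e-12)
    # adding a tip never decreases PD
    extra <- setdiff(tree$tip.label, tips)
    if (length(extra) > 0) {
      expect_gte(faith_pd(tree, c(tips, extra[1])), faith_pd(tree, tips))
    }
    expect_equal(faith_pd(tree, tree$tip.label), sum(tree$edge.length),
                 tolerance = 1e-12)
  }
})

test_that("alpha_diversity tabulates all metrics per sample", {
  tab <- toy_table()
  tree <- gen_tree(rownames(tab), seed = 2)
  a <- alpha_diversity(tab, tree)
  expect_named(a, c("sample", "depth", "shannon", "richness", "faith_pd"))
  expect_equal(a$depth, unname(colSums(tab)))
  expect_equal(a$richness[1], 4)
  expect_equal(a$faith_pd[2], oracle_faith_pd(tree, c("ASV2", "ASV3", "ASV4")),
               tolerance = 1e-12)
  bad <- cbind(tab, EMPTY = 0L)
  expect_error(alpha_diversity(bad), "zero total")
})

test_that("group ANOVA reproduces hand sums of squares and Tukey output", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- alpha_group_test(vals, grp)
  expect_equal(res$f, 3.0)
  expect_equal(unname(res$df), c(2, 6))
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p_adj >= 0 & res$pairwise$p_adj <= 1))
  # identical groups carry no between-group signal
  res0 <- suppressWarnings(
    alpha_group_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3)))
  expect_equal(res0$f, 0)
  expect_equal(res0$p, 1)
  expect_warning(alpha_group_test(c(1, 2, 3, 4, 5), c("a", "a", "b", "b", "c")),
                 "excluding")
  expect_error(alpha_group_test(c(1, 1, 1, 1), c("a", "a", "b", "b")),
               "degenerate")
})

test_that("rank aggregation normalizes and conserves reads", {
  tab <- toy_table()
  taxonomy <- c(ASV1 = "k__Bacteria; p__Firmicutes; g__Blautia",
                ASV2 = "k__Bacteria; p__Firmicutes; g__Roseburia",
                ASV3 = "k__Bacteria; p__Bacteroidetes; g__Bacteroides",
                ASV4 = "k__Bacteria; p__Bacteroidetes; g__Prevotella",
                ASV5 = "k__Bacteria; p__Proteobacteria; g__")
  rel <- aggregate_by_rank(tab, taxonomy, "phylum")
  expect_equal(unname(colSums(rel)), rep(1, 4), tolerance = 1e-12)
  raw <- aggregate_by_rank(tab, taxonomy, "phylum", relative = FALSE)
  expect_equal(unname(colSums(raw)), unname(colSums(tab)))
  # single-phylum table collapses to a unit row
  one <- aggregate_by_rank(tab, setNames(rep("p__X", 5), rownames(tab)),
                           "phylum")
  expect_equal(nrow(one), 1)
  expect_true(all(one == 1))
  # hand proportions: S1 Firmicutes 150, Bacteroidetes 600, Proteobacteria 10
  expect_equal(rel["Firmicutes", "S1"], 150 / 760)
  # empty genus rank pools as unclassified
  gen <- aggregate_by_rank(tab, taxonomy, "genus")
  expect_true("unclassified" %in% rownames(gen))
})

test_that("F/B ratio is the ratio of phylum proportions, depth-invariant", {
  tab <- matrix(c(600, 300, 100), ncol = 1,
                dimnames = list(c("a", "b", "c"), "S1"))
  taxonomy <- c(a = "p__Firmicutes", b = "p__Bacteroidetes",
                c = "p__Proteobacteria")
  fb <- fb_ratio(tab, taxonomy)
  expect_equal(fb$fb_ratio, 2.0)
  fb10 <- fb_ratio(tab * 10L, taxonomy)
  expect_equal(fb10$fb_ratio, 2.0)
  tab_eq <- matrix(c(300, 300), ncol = 1,
                   dimnames = list(c("a", "b"), "S1"))
  expect_equal(fb_ratio(tab_eq, taxonomy[1:2])$fb_ratio, 1.0)
  # absent Bacteroidetes flags the ratio
  tab_nf <- matrix(c(300, 5), ncol = 1, dimnames = list(c("a", "c"), "S1"))
  expect_warning(fb0 <- fb_ratio(tab_nf, taxonomy[c(1, 3)]), "absent")
  expect_true(is.infinite(fb0$fb_ratio))
})

test_that("lineage parsing tolerates empty and missing ranks", {
  p <- parse_lineage(c("k__Bacteria; p__Firmicutes; c__; g__Blautia",
                       "p__Bacteroidetes",
                       ""))
  expect_equal(p$phylum, c("Firmicutes", "Bacteroidetes", NA))
  expect_equal(p$genus, c("Blautia", NA, NA))
  expect_true(is.na(p$class[1]))
})
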