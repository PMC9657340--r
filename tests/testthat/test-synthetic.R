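test_that("qPCR generator is deterministic and noise-free equals truth", {
  cfg0 <- synth_config(seed = 5, qpcr_noise_sd = 0)
  a <- gen_qpcr_trajectory(cfg0)
  b <- gen_qpcr_trajectory(cfg0)
  expect_identical(a, b)
  s <- a[["BR1.AC"]]
  expect_equal(s$series$cells_per_ml, s$truth)
  # truth = growth model + constant baseline; pre-dose at baseline level
  pre <- s$series$cycles < 0
  expect_true(all(s$truth[pre] == s$baseline))
  tr <- simulate_with_growth(reactor_chain(cfg0$volumes),
                             feeding_schedule(cfg0$transfer_volume),
                             dose_event(cfg0$dose_compartment, cfg0$dose_cells),
                             cfg0$growth, cfg0$n_cycles)
  expect_equal(s$truth[!pre],
               unname(tr$concentrations["AC", ]) + s$baseline)
})

test_that("generated baselines honor the endogenous range", {
  cfg <- synth_config(seed = 11)
  qp <- gen_qpcr_trajectory(cfg)
  bl <- vapply(qp, `[[`, numeric(1), "baseline")
  expect_true(all(bl >= 1.3e3 & bl <= 8e4))
  # pre-dose truth sits at those levels
  for (x in qp) {
    expect_true(all(x$truth[x$series$cycles < 0] >= 1.3e3))
    expect_true(all(x$truth[x$series$cycles < 0] <= 8e4))
  }
})

test_that("feature-table generator has the configured shape and spike", {
  cfg <- small_synth_config()
  ft <- gen_feature_table(cfg)
  expect_identical(ft, gen_feature_table(cfg))
  expect_equal(unname(colSums(ft$counts)), rep(cfg$depth, ncol(ft$counts)))
  expect_equal(nrow(ft$counts), cfg$n_taxa + 1)
  expect_equal(nrow(ft$metadata), 2 * 3 * 3 * 3)
  # probiotic ASV appears only in post-dose AC samples
  spike <- ft$counts[ft$probiotic_asv, ]
  meta <- ft$metadata
  off_target <- meta$region != "AC" | meta$period == "pre"
  expect_true(all(spike[meta$sample[off_target]] == 0))
  expect_gt(mean(spike[meta$sample[!off_target]] > 0), 0.9)
  # zero spike weight removes it everywhere
  ft0 <- gen_feature_table(small_synth_config())
  cfg0 <- small_synth_config(); cfg0$spike_weight <- 0
  expect_true(all(gen_feature_table(cfg0)$counts[ft0$probiotic_asv, ] == 0))
  # lineages parse and are Firmicutes/Bacteroidetes-dominated
  ph <- parse_lineage(ft$taxonomy)$phylum
  expect_gt(mean(ph %in% c("Firmicutes", "Bacteroidetes")), 0.5)
})

test_that("tree generator yields seeded rooted binary trees", {
  taxa <- paste0("ASV", 1:17)
  tr <- gen_tree(taxa, seed = 4)
  expect_s3_class(tr, "phylo")
  expect_true(ape::is.rooted(tr))
  expect_equal(ape::Ntip(tr), 17)
  expect_equal(tr$Nnode, 16)  # rooted binary: n - 1 internal nodes
  expect_setequal(tr$tip.label, taxa)
  expect_true(all(tr$edge.length >= 0))
  expect_identical(ape::write.tree(tr), ape::write.tree(gen_tree(taxa, seed = 4)))
  expect_false(identical(ape::write.tree(tr),
                         ape::write.tree(gen_tree(taxa, seed = 5))))
  expect_error(gen_tree("one"), ">= 2 taxa")
})

test_that("exponential branch lengths have the expected total", {
  taxa <- paste0("t", 1:10)
  totals <- vapply(1:100, function(s) {
    sum(gen_tree(taxa, seed = s, mean_branch = 0.1)$edge.length)
  }, numeric(1))
  # rooted binary tree on n tips has 2n - 2 edges of mean 0.1
  expect_equal(mean(totals), (2 * 10 - 2) * 0.1, tolerance = 0.1)
})

test_that("SCFA generator is seeded, mean-faithful and region-ordered", {
  cfg <- small_synth_config()
  sc <- gen_scfa(cfg)
  expect_identical(sc, gen_scfa(cfg))
  expect_equal(dim(sc$concentrations),
               c(nrow(sc$metadata), length(cfg$scfa_base_means)))
  cfg0 <- small_synth_config(); cfg0$scfa_noise_sd <- 0
  sc0 <- gen_scfa(cfg0)
  ac_rows <- sc0$metadata$period != "early-post" & sc0$metadata$region == "AC"
  expect_equal(unname(sc0$concentrations[which(ac_rows)[1], ]),
               unname(cfg0$scfa_base_means * cfg0$scfa_region_factor["AC"]))
  # region means ordered AC < TC < DC for every acid
  for (acid in colnames(sc$concentrations)) {
    m <- tapply(sc$concentrations[, acid], sc$metadata$region, mean)
    expect_true(m["AC"] < m["TC"] && m["TC"] < m["DC"])
  }
  bad <- small_synth_config()
  bad$scfa_region_factor <- c(AC = 2, TC = 1, DC = 1)
  expect_error(gen_scfa(bad), "non-decreasing")
})
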