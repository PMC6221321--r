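test_that("config invariants are enforced with the offending field named", {
  expect_error(simulation_config(time_grid_hours = c(1, 2, 4)), "time_grid_hours")
  expect_error(simulation_config(time_grid_hours = c(0, 2, 1)), "time_grid_hours")
  expect_error(simulation_config(n_replicates = 1), "n_replicates")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  expect_error(simulation_config(de_fraction = 1), "de_fraction")
  expect_error(simulation_config(opioids = "fentanyl"), "opioids")
})

test_that("zero DE fraction produces flat truth and no planted genes", {
  sim <- simulate_expression(simulation_config(n_genes = 50, de_fraction = 0,
                                               seed = 1))
  expect_equal(nrow(sim$truth$de_genes), 0)
  expect_true(all(sim$truth$amplitudes == 0))
})

test_that("planted DE counts follow the configured fraction exactly", {
  sim <- simulate_expression(simulation_config(n_genes = 100,
                                               de_fraction = 0.1, seed = 1))
  per_drug <- table(sim$truth$de_genes$drug)
  expect_equal(unname(per_drug[["morphine"]]), 10)
  expect_equal(unname(per_drug[["heroin"]]), 10)
  # one pattern per gene per drug
  expect_false(any(duplicated(sim$truth$de_genes[, c("gene", "drug")])))
})

test_that("identical seeds reproduce; seeds change noise but not structure", {
  cfg1 <- simulation_config(n_genes = 80, seed = 5)
  a <- simulate_expression(cfg1)
  b <- simulate_expression(cfg1)
  expect_identical(a$dataset$values, b$dataset$values)
  cfg2 <- simulation_config(n_genes = 80, seed = 6)
  c <- simulate_expression(cfg2)
  expect_false(identical(a$dataset$values, c$dataset$values))
  expect_identical(a$truth$de_genes, c$truth$de_genes)
  expect_identical(a$truth$amplitudes, c$truth$amplitudes)
})

test_that("time-0 control is shared across drugs and noise looks Gaussian", {
  sim <- tiny_sim(seed = 7, n_genes = 200)
  s <- sim$dataset$samples
  ctrl <- s$time_hours == 0
  expect_true(all(s$drug[ctrl] == "control"))
  m1 <- drug_matrix(sim$dataset, "morphine")
  m2 <- drug_matrix(sim$dataset, "nicotine")
  expect_identical(m1$values[, m1$times == 0], m2$values[, m2$times == 0])
  nulls <- setdiff(sim$dataset$gene_ids, unique(sim$truth$de_genes$gene))
  resid <- sweep(sim$dataset$values[nulls, ], 1,
                 rowMeans(sim$dataset$values[nulls, ]))
  expect_gt(shapiro.test(sample(as.vector(resid), 3000))$p.value, 0.001)
})

test_that("planted template refits near the configured fold change", {
  # noise well below signal: the refitted maximum fold change recovers the
  # planted linear value up to local-quadratic smoothing bias
  cfg <- simulation_config(n_genes = 60, noise_sd = 0.01, fc_planted = 2,
                           seed = 3)
  sim <- simulate_expression(cfg)
  fits <- fit_all_drugs(sim$dataset)
  td <- sim$truth$de_genes[sim$truth$de_genes$drug == "morphine", ]
  ie_up <- td$gene[td$pattern == "up-IE"]
  fc <- abs(fits$morphine$signed_fc[match(ie_up, fits$morphine$genes)])
  # the sharply peaked immediate-early template carries the largest
  # smoothing bias (~5-6% at the peak); slower templates refit within 1%
  expect_true(all(abs(fc - 2) / 2 < 0.08))
  slow <- td$gene[td$pattern %in% c("up-L", "down-L", "up-M", "down-M")]
  fc_slow <- abs(fits$morphine$signed_fc[match(slow, fits$morphine$genes)])
  expect_true(all(abs(fc_slow - 2) / 2 < 0.02))
})

test_that("harm scores are affine in planted amplitudes and ignore unplanted", {
  cfg <- simulation_config(n_genes = 60, seed = 2)
  sim <- simulate_expression(cfg)
  planted <- sim$truth$effect_associated_genes
  harm <- simulate_harm_scores(cfg$drugs, planted = planted,
                               truth = sim$truth, seed = 4,
                               score_noise_sd = 0)
  e <- names(planted)[1]
  g <- planted[[e]][1]
  amp <- abs(sim$truth$amplitudes[g, cfg$drugs])
  sc <- as.numeric(harm[harm$effect == e, cfg$drugs])
  expect_equal(abs(cor(amp, sc)), 1, tolerance = 1e-12)
  # unplanted effects do not depend on the expression structure at all
  h1 <- simulate_harm_scores(cfg$drugs, planted = list(), truth = sim$truth,
                             seed = 9)
  sim2 <- simulate_expression(simulation_config(n_genes = 60, seed = 11,
                                                de_fraction = 0.2))
  h2 <- simulate_harm_scores(cfg$drugs, planted = list(), truth = sim2$truth,
                             seed = 9)
  expect_identical(h1, h2)
  expect_error(simulate_harm_scores(cfg$drugs, effects = character(),
                                    truth = sim$truth), "empty")
  expect_error(simulate_harm_scores(cfg$drugs[1:3], truth = sim$truth),
               ">= 4 drugs")
})

test_that("peaks land inside planted targets' windows and nowhere else", {
  cfg <- simulation_config(n_genes = 80, seed = 6)
  sim <- simulate_expression(cfg)
  rc <- simulate_regulators_and_compounds(sim$truth, cfg, n_regulators = 6,
                                          n_compounds = 10, seed = 2)
  sets <- regulator_sets_from_peaks(rc$peaks, rc$annotation, 1000)
  for (r in names(rc$truth$regulator_target_map)) {
    expect_setequal(sets[[r]], rc$truth$regulator_target_map[[r]])
  }
})

test_that("the bundle writes valid files that read back consistently", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_genes = 60, seed = 3)
  b <- write_synthetic_bundle(dir, cfg, n_regulators = 5, n_compounds = 8)
  ds <- read_expression(file.path(dir, "expression.tsv"),
                        file.path(dir, "samples.csv"))
  expect_equal(ds$values, b$dataset$values, tolerance = 1e-10,
               ignore_attr = TRUE)
  sets <- read_gmt(file.path(dir, "genesets.gmt"))
  expect_true(all(unlist(sets) %in% ds$gene_ids))
  ann <- read_annotation(file.path(dir, "annotation.gff3"))
  expect_equal(ann$start, b$annotation$start)
  expect_equal(ann$strand, b$annotation$strand)
  pk <- read_peaks(file.path(dir, "peaks.bed"))
  expect_equal(nrow(pk), nrow(b$peaks))
  expect_equal(pk$start, b$peaks$start)
  lib <- read_compound_library(file.path(dir, "compounds.tsv"))
  expect_true(b$ground_truth$reversal_compound_ids %in% names(lib))
  expect_true(all(abs(unlist(lib)) > 1.2))
})
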