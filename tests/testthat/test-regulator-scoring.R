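make_scoring_fixture <- function(seed = 1, n_genes = 60) {
  sim <- tiny_sim(seed = seed, n_genes = n_genes)
  fits <- fit_all_drugs(sim$dataset)$morphine
  degs <- call_degs(fits = fits)
  list(sim = sim, fits = fits, degs = degs)
}

test_that("phase fold changes come from the fitted curve and are >= 1", {
  fx <- make_scoring_fixture()
  genes <- fx$fits$genes[1:10]
  for (ph in c("IE", "M", "L")) {
    fc <- max_abs_fc_in_phase(fx$fits, genes, ph)
    expect_true(all(fc >= 1))
    # independent recomputation straight from the fitted matrix
    w <- switch(ph, IE = c(0, 2), M = c(2, 4), L = c(4, 8))
    j <- which(fx$fits$grid > w[1] & fx$fits$grid <= w[2])
    i0 <- which(fx$fits$grid == 0)
    ii <- match(genes, fx$fits$genes)
    oracle <- 2^apply(abs(fx$fits$fitted[ii, j] - fx$fits$fitted[ii, i0]),
                      1, max)
    expect_equal(unname(fc), unname(oracle), tolerance = 1e-12)
  }
  expect_error(max_abs_fc_in_phase(fx$fits, "NOT_A_GENE", "IE"), "missing")
})

test_that("a planted mid-phase peak yields the expected fold change", {
  # one gene whose log2 ratio peaks at +1 inside the M window
  tt <- rep(c(0, 1, 2, 4, 8), each = 3)
  vals <- matrix(8 + sin(pi * tt / 6), 1, dimnames = list("GPK", NULL))
  # use a synthetic curve evaluated exactly: replace with direct fit
  samples <- data.frame(sample = paste0("s", seq_along(tt)),
                        drug = ifelse(tt == 0, "control", "d1"),
                        time_hours = tt,
                        replicate = rep(1:3, times = 5))
  ds <- expression_dataset(rbind(GPK = 8 + tt * (8 - tt) / 16,
                                 GFLAT = rep(8, 15)), samples)
  fits <- fit_timecourse(ds, "d1")
  fc_flat <- max_abs_fc_in_phase(fits, "GFLAT", "M")
  expect_equal(unname(fc_flat), 1, tolerance = 1e-6)
  fc_pk <- max_abs_fc_in_phase(fits, "GPK", "M")
  expect_gt(fc_pk, 1.8)   # parabola peaks at t = 4, log2 ratio 1 -> FC ~ 2
  expect_lt(abs(fc_pk - 2), 0.2)
})

test_that("dependence score is the exact sum with additivity and direction", {
  fx <- make_scoring_fixture(seed = 2)
  de <- fx$degs[fx$degs$is_de, ]
  skip_if(nrow(de) < 4)
  ph <- names(sort(table(de$phase), decreasing = TRUE))[1]
  in_ph <- de[de$phase == ph, ]
  targets <- in_ph$gene[seq_len(min(3, nrow(in_ph)))]
  ds <- dependence_score(targets, de, fx$fits, ph)
  fc <- max_abs_fc_in_phase(fx$fits, targets, ph)
  expect_equal(ds$N, length(targets))
  expect_equal(ds$dependence_score, sum(fc))
  expect_gte(ds$dependence_score, max(fc))
  # additivity: adding one more regulated DEG adds exactly its FC
  if (nrow(in_ph) > length(targets)) {
    extra <- in_ph$gene[length(targets) + 1]
    ds2 <- dependence_score(c(targets, extra), de, fx$fits, ph)
    expect_equal(ds2$dependence_score,
                 ds$dependence_score +
                   unname(max_abs_fc_in_phase(fx$fits, extra, ph)))
  }
  # empty intersection
  empty <- dependence_score("NOPE", de, fx$fits, ph)
  expect_equal(empty$N, 0L)
  expect_equal(empty$dependence_score, 0)
})

test_that("scores are permutation invariant and monotone in the target set", {
  fx <- make_scoring_fixture(seed = 4)
  de <- fx$degs[fx$degs$is_de, ]
  skip_if(nrow(de) < 5)
  ph <- de$phase[1]
  tg <- de$gene[de$phase == ph]
  skip_if(length(tg) < 2)
  a <- dependence_score(tg, de, fx$fits, ph)
  b <- dependence_score(rev(tg), de, fx$fits, ph)
  expect_equal(a$dependence_score, b$dependence_score)
  sub <- dependence_score(tg[-1], de, fx$fits, ph)
  expect_lte(sub$dependence_score, a$dependence_score)
})

test_that("association scores sum the fold changes of effect-linked targets", {
  fx <- make_scoring_fixture(seed = 5)
  de <- fx$degs[fx$degs$is_de, ]
  skip_if(nrow(de) < 3)
  ph <- de$phase[1]
  tg <- de$gene[de$phase == ph]
  assoc <- data.frame(gene = rep(tg, each = 2),
                      effect = rep(c("dependence", "pleasure"), length(tg)),
                      significant = TRUE)
  es <- association_scores(tg, assoc, fx$degs, fx$fits, ph)
  expect_equal(es[["dependence"]], es[["pleasure"]])
  expect_equal(es[["cpp"]], 0)
  expect_equal(es[["dependence"]],
               sum(max_abs_fc_in_phase(fx$fits, tg, ph)))
})

test_that("the regulator report ranks planted regulators by dependence score", {
  fx <- make_scoring_fixture(seed = 6, n_genes = 100)
  de <- fx$degs[fx$degs$is_de, ]
  skip_if(nrow(de) < 6)
  ph <- names(sort(table(de$phase), decreasing = TRUE))[1]
  tg <- de$gene[de$phase == ph]
  skip_if(length(tg) < 3)
  assoc <- data.frame(gene = tg, effect = "dependence", significant = TRUE)
  sets <- list(big = tg, small = tg[1], none = "XXXX")
  rep <- score_regulators(sets, fx$degs, assoc, fx$fits)
  expect_equal(rep$regulator[1], "big")
  expect_false("none" %in% rep$regulator)
  expect_true(all(rep$dependence_score[rep$N >= 1] >= 1.2))
  expect_equal(rep$signed_score,
               ifelse(rep$direction == "down", -1, 1) * rep$dependence_score)
})
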