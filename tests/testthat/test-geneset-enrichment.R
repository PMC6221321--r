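test_that("hypergeometric upper tail matches combinatorial oracles", {
  expect_equal(hypergeom_upper_tail(3, 4, 5, 10), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(3, 4, 5, 10), enum_hyper_draws(3, 4, 5, 10),
               tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeom_upper_tail(5, 5, 5, 5), 1)
  set.seed(1)
  for (i in 1:50) {
    N <- sample(2:12, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_upper_tail(k, K, n, N), brute_hyper(k, K, n, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_upper_tail(5, 4, 5, 10), "require")
  expect_error(hypergeom_upper_tail(1, 4, 5, 4), "require")
})

test_that("enrichment ranks a fully recovered set first and adds BH in regulator mode", {
  universe <- sprintf("G%03d", 1:100)
  sets <- list(hit = universe[1:10], other = universe[51:60],
               third = universe[61:80])
  res <- enrich(universe[1:10], sets, universe, mode = "functional")
  expect_equal(res$set[1], "hit")
  expect_equal(res$k[res$set == "other"], 0)
  expect_equal(res$p[res$set == "other"], 1)
  expect_true(res$significant[res$set == "hit"])
  reg <- enrich(universe[1:10], sets, universe, mode = "regulator")
  expect_true(all(reg$fdr_p >= reg$p))
  expect_equal(reg$fdr_p, p.adjust(reg$p, "BH")[order(order(reg$p, reg$set))],
               tolerance = 1e-12)
})

test_that("Benjamini-Hochberg step-up matches the hand-computed example", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.8), "BH"),
               c(0.04, 0.04, 0.04, 0.8))
})

test_that("symbols are uppercased and out-of-universe queries handled", {
  universe <- c("Abc", "Def", "Ghi", "Jkl")
  sets <- list(s1 = c("ABC", "DEF"))
  expect_message(res <- enrich(c("abc", "zzz"), sets, universe), "dropped")
  expect_equal(res$n[1], 1)
  expect_warning(res2 <- enrich("zzz", sets, universe), "empty query")
  expect_equal(nrow(res2), 0)
})

test_that("null queries give approximately uniform enrichment p-values", {
  set.seed(7)
  universe <- sprintf("G%04d", 1:200)
  sets <- list(s = universe[1:40])
  ps <- replicate(500, enrich(sample(universe, 30), sets, universe)$p)
  # discrete p-values are valid (stochastically >= uniform): the empirical
  # CDF never rises far above the diagonal
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / 500))
  }
  expect_gte(mean(ps), 0.45)
})

test_that("window target assignment honors the 1000-bp flanks on both strands", {
  ann <- data.frame(gene = c("gplus", "gminus"),
                    chrom = "chr1",
                    start = c(5000, 20000), end = c(7000, 22000),
                    strand = c("+", "-"))
  # 800 bp upstream of the + TSS: inside the window
  expect_true("GPLUS" %in% assign_targets(
    data.frame(chrom = "chr1", start = 4200, end = 4300), ann)$targets)
  # 1100 bp upstream: outside
  expect_false("GPLUS" %in% assign_targets(
    data.frame(chrom = "chr1", start = 3500, end = 3900), ann)$targets)
  # boundary: peak ending exactly at the window start does not overlap
  expect_false("GPLUS" %in% assign_targets(
    data.frame(chrom = "chr1", start = 3900, end = 4000), ann)$targets)
  expect_true("GPLUS" %in% assign_targets(
    data.frame(chrom = "chr1", start = 3900, end = 4001), ann)$targets)
  # minus-strand gene: TSS at the interval end; 800 bp beyond the genomic
  # start (3' of the gene, downstream of its TTS) is inside the window
  expect_true("GMINUS" %in% assign_targets(
    data.frame(chrom = "chr1", start = 19100, end = 19300), ann)$targets)
  # unknown chromosome peaks are skipped with a message
  expect_message(
    res <- assign_targets(data.frame(chrom = "chrX", start = 1, end = 50),
                          ann), "unknown")
  expect_equal(length(res$targets), 0)
})

test_that("target assignment matches brute-force overlap on random genomes", {
  set.seed(3)
  for (i in 1:25) {
    ng <- sample(2:5, 1)
    starts <- sort(sample(seq(1000, 30000, by = 100), ng))
    ann <- data.frame(gene = sprintf("g%d", seq_len(ng)), chrom = "c1",
                      start = starts, end = starts + sample(500:2000, ng, TRUE),
                      strand = sample(c("+", "-"), ng, TRUE))
    np <- sample(1:6, 1)
    ps <- sample(seq(0, 33000, by = 50), np)
    peaks <- data.frame(chrom = sample(c("c1", "c2"), np, TRUE),
                        start = ps, end = ps + sample(50:500, np, TRUE))
    got <- suppressMessages(assign_targets(peaks, ann, window_bp = 1000))
    expect_setequal(got$targets, brute_targets(peaks, ann, 1000))
  }
})
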