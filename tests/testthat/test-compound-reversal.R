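make_query <- function(w) structure(w, class = "query_signature")

test_that("copy scores positive, negation scores its exact mirror", {
  q <- make_query(c(A = 1.5, B = -2, C = 1.3, D = -1.7, E = 2.2))
  copy <- c(A = 1.5, B = -2, C = 1.3, D = -1.7, E = 2.2)
  s_copy <- connectivity_score(q, copy)
  s_neg <- connectivity_score(q, -copy)
  expect_gt(s_copy$score, 0)
  expect_lt(s_neg$score, 0)
  expect_equal(s_copy$score, -s_neg$score, tolerance = 1e-12)
  expect_equal(length(s_neg$opposite), 5)
  expect_equal(length(s_copy$opposite), 0)
  # negation is the extreme reversal on this universe: no decoy beats it
  set.seed(1)
  worst <- min(replicate(200, {
    decoy <- setNames(sample(c(-1, 1), 5, TRUE) * runif(5, 1.3, 3),
                      names(copy))
    connectivity_score(q, decoy)$score
  }))
  expect_gte(worst, s_neg$score)
})

test_that("score is antisymmetric under negating either signature", {
  set.seed(2)
  for (i in 1:20) {
    genes <- sprintf("g%02d", 1:12)
    q <- make_query(setNames(sample(c(-1, 1), 6, TRUE) * runif(6, 1.3, 4),
                             sample(genes, 6)))
    comp <- setNames(sample(c(-1, 1), 12, TRUE) * runif(12, 1.21, 5), genes)
    s <- connectivity_score(q, comp)$score
    expect_equal(connectivity_score(q, -comp)$score, -s, tolerance = 1e-12)
    qn <- make_query(-unclass(q))
    expect_equal(connectivity_score(qn, comp)$score, -s, tolerance = 1e-12)
    # positive rescaling of the query changes nothing
    q2 <- make_query(unclass(q) * 3.7)
    expect_equal(connectivity_score(q2, comp)$score, s, tolerance = 1e-12)
  }
})

test_that("random signatures score near zero on average", {
  set.seed(3)
  genes <- sprintf("g%02d", 1:50)
  q <- make_query(setNames(sample(c(-1, 1), 20, TRUE) * runif(20, 1.3, 3),
                           sample(genes, 20)))
  scores <- replicate(2000, {
    comp <- setNames(sample(c(-1, 1), 50, TRUE) * runif(50, 1.21, 4), genes)
    connectivity_score(q, comp)$score
  })
  expect_lt(abs(mean(scores)), 0.05)
})

test_that("compounds sharing no genes are flagged and excluded from ranking", {
  q <- make_query(c(A = 2, B = -2))
  res <- connectivity_score(q, c(X = 1.5, Y = -1.4))
  expect_false(res$comparable)
  lib <- list(good = c(A = -2, B = 2), stranger = c(X = 1.5, Y = -1.4))
  expect_message(rk <- rank_compounds(q, lib, n_perm = 0), "excluded")
  expect_equal(rk$compound, "good")
  expect_error(rank_compounds(q, list()), "empty")
})

test_that("permutation p is deterministic, valid, and matches enumeration", {
  set.seed(4)
  genes <- sprintf("g%d", 1:6)
  comp <- setNames(c(2.5, -1.9, 1.6, -1.4, 2.1, -2.8), genes)
  q <- make_query(setNames(c(2, -2, 1.5), c("g1", "g2", "g5")))
  p1 <- permutation_p(q, comp, n_perm = 99, seed = 7)$perm_p
  p2 <- permutation_p(q, comp, n_perm = 99, seed = 7)$perm_p
  expect_identical(p1, p2)
  expect_gt(p1, 0)
  expect_lte(p1, 1)
  # exact null by enumerating all 6! label permutations
  obs <- connectivity_score(q, comp)$score
  ord <- order(-comp, names(comp))
  w <- abs(comp[ord]); gsort <- names(comp)[ord]
  null <- vapply(all_perms(6), function(pm) {
    relab <- setNames(names(comp)[pm], names(comp))  # permuted gene labels
    hu <- relab[gsort] %in% c("g1", "g5")
    hd <- relab[gsort] %in% "g2"
    es <- function(h) {
      if (!any(h)) return(0)
      dev <- cumsum(w * h) / sum(w[h]) - cumsum(!h) / sum(!h)
      max(dev, 0) + min(dev, 0)
    }
    max(min((es(hu) - es(hd)) / 2, 1), -1)
  }, numeric(1))
  p_exact <- mean(null <= obs)
  p_hat <- permutation_p(q, comp, n_perm = 999, seed = 11)$perm_p
  expect_lt(abs(p_hat - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 999) + 2e-3)
})

test_that("an exact-negation compound achieves an extreme permutation p", {
  set.seed(5)
  genes <- sprintf("g%02d", 1:20)
  q <- make_query(setNames(sample(c(-1, 1), 20, TRUE) * runif(20, 1.3, 3),
                           genes))
  neg <- -unclass(q)
  res <- permutation_p(q, neg, n_perm = 999, seed = 3)
  expect_lte(res$perm_p, 2 / 1000)
})

test_that("ranking orders negation first and copy last", {
  set.seed(6)
  genes <- sprintf("g%02d", 1:15)
  q <- make_query(setNames(sample(c(-1, 1), 15, TRUE) * runif(15, 1.3, 3),
                           genes))
  lib <- list(neg = -unclass(q), copy = unclass(q),
              rand = setNames(sample(c(-1, 1), 15, TRUE) * runif(15, 1.3, 3),
                              genes))
  rk <- rank_compounds(q, lib, n_perm = 99, seed = 1)
  expect_equal(rk$compound[1], "neg")
  expect_equal(rk$compound[3], "copy")
  expect_setequal(attr(rk, "opposite_genes")$neg, toupper(names(q)))
})

test_that("the library loader applies the compound DEG filters", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(compound_id = c("c1", "c1", "c1", "c2"),
                   gene = c("a", "b", "c", "a"),
                   signed_fc = c(2, 1.1, -3, -1.5),
                   p = c(0.01, 0.01, 0.2, 0.04))
  write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  lib <- read_compound_library(tf)
  expect_equal(names(lib$c1), "A")     # |fc| 1.1 and p 0.2 entries dropped
  expect_equal(unname(lib$c2), -1.5)
})
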