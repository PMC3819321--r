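test_that("adjust_factors divides by the geometric mean, idempotently", {
  expect_equal(factors_of(adjust_factors(c(a = 2, b = 0.5))), c(a = 2, b = 0.5))
  expect_equal(factors_of(adjust_factors(c(a = 4, b = 1))), c(a = 2, b = 0.5))
  f <- c(x = 0.3, y = 7, z = 2.2)
  once <- adjust_factors(f)
  expect_equal(prod(once$factor), 1, tolerance = 1e-12)
  expect_equal(factors_of(adjust_factors(once)), factors_of(once))
  # scale invariance: c * f adjusts to the same set
  expect_equal(factors_of(adjust_factors(13.7 * f)), factors_of(once))
  expect_error(adjust_factors(c(a = -1, b = 2)), "positive")
})

test_that("CPM scales every column to one million; Total to the mean total", {
  m <- toy_expression(cbind(s1 = c(4, 6), s2 = c(15, 5)))  # totals 10, 20
  cpm <- normalize_cpm(m)
  expect_equal(factors_of(cpm), c(s1 = 1e5, s2 = 5e4))
  expect_equal(unname(colSums(expr_mat(cpm$data))), c(1e6, 1e6))

  r <- random_expression(60, 4, seed = 11)
  expect_equal(unname(colSums(expr_mat(normalize_cpm(r)$data))),
               rep(1e6, 4), tolerance = 1e-9)

  tot <- normalize_total(toy_expression(cbind(s1 = c(4, 6), s2 = c(25, 5))))
  expect_equal(factors_of(tot), c(s1 = 2, s2 = 2 / 3))
  expect_equal(unname(colSums(expr_mat(tot$data))), c(20, 20))
  # grand total conserved
  expect_equal(sum(expr_mat(tot$data)), 40)
})

test_that("percentile scaling equalizes the nearest-rank quantile", {
  # 4 genes; 75th percentile = 3rd ascending value
  m <- toy_expression(cbind(s1 = c(1, 2, 4, 8), s2 = c(2, 4, 8, 16)))
  uq <- normalize_percentile(m, q = 0.75)
  expect_equal(factors_of(uq), c(s1 = 1.5, s2 = 0.75))  # values 4, 8 -> mean 6
  m2 <- expr_mat(uq$data)
  expect_equal(sort(m2[, 1])[3], sort(m2[, 2])[3])

  same <- toy_expression(cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3)))
  expect_equal(factors_of(normalize_percentile(same, 0.75)), c(s1 = 1, s2 = 1))

  sparse <- toy_expression(cbind(s1 = c(0, 0, 0, 5), s2 = c(1, 2, 3, 4)))
  expect_error(normalize_percentile(sparse, q = 0.5), "nonzero_only")
  ok <- normalize_percentile(sparse, q = 0.5, nonzero_only = TRUE)
  expect_true(all(ok$factors$factor > 0))
})

test_that("guide scaling equalizes the weighted geometric mean of guides", {
  m <- toy_expression(rbind(hk = c(10, 20), other = c(5, 100)),
                      genes = c("hk", "other"))
  g <- normalize_guide(m, "hk")
  expect_equal(factors_of(g), c(s1 = sqrt(2), s2 = 1 / sqrt(2)))
  scaled <- expr_mat(g$data)
  expect_equal(scaled["hk", 1], scaled["hk", 2])

  # identical guides across samples: factors all 1
  ident <- toy_expression(rbind(a = c(3, 3, 3), b = c(9, 9, 9), c = c(1, 5, 7)),
                          genes = c("a", "b", "c"))
  expect_equal(unname(factors_of(normalize_guide(ident, c("a", "b")))), rep(1, 3))

  # weight-scale invariance
  w1 <- normalize_guide(m, tibble::tibble(gene = c("hk", "other"), weight = c(2, 1)))
  w2 <- normalize_guide(m, tibble::tibble(gene = c("hk", "other"), weight = c(4, 2)))
  expect_equal(factors_of(w1), factors_of(w2))

  # zero-valued guide is rejected by name
  z <- toy_expression(rbind(a = c(1, 0), b = c(2, 2)), genes = c("a", "b"))
  expect_error(normalize_guide(z, "a"), "a")
})

test_that("guide scaling recovers planted factors exactly when guides are proportional", {
  base <- c(a = 2, b = 40, c = 7, d = 900)
  phi <- c(s1 = 1.3, s2 = 0.6, s3 = 1.9)
  m <- toy_expression(outer(base, phi), genes = names(base))
  rec <- factors_of(normalize_guide(m, names(base)))
  truth <- factors_of(adjust_factors(1 / phi))
  expect_equal(rec, truth, tolerance = 1e-12)
})

test_that("geNorm stability measure flags the scrambled candidate first", {
  withr::with_seed(42, {
    prof <- 2^rnorm(6, 4, 1)
    m <- toy_expression(rbind(
      a = prof * 2,      # proportional to b
      b = prof,
      c = 2^rnorm(6, 4, 1),  # scrambled
      x = 2^rnorm(6, 2, 2) + 1
    ), genes = c("a", "b", "c", "x"), samples = paste0("s", 1:6))
  })
  sel <- genorm_select(m, c("a", "b", "c"), k = 3)  # k = n: ranking only
  expect_setequal(sel$selected, c("a", "b", "c"))
  # brute-force M: proportional pair contributes sd 0 to each other
  mm <- log2(expr_mat(m))
  m_of <- function(j, others) mean(sapply(others, function(h) sd(mm[j, ] - mm[h, ])))
  expect_equal(sel$ranking$m_value[sel$ranking$gene == "c"],
               m_of("c", c("a", "b")))
  expect_gt(m_of("c", c("a", "b")), m_of("a", c("b", "c")))

  sel2 <- genorm_select(m, c("a", "b", "c", "x"), k = 3)
  first_removed <- sel2$ranking$gene[!sel2$ranking$selected][
    length(sel2$ranking$gene[!sel2$ranking$selected])]
  # the least stable of the four is dropped first; with the brute-force M
  # that is whichever of c/x maximizes the initial M
  mv0 <- sapply(c("a", "b", "c", "x"), function(j)
    m_of(j, setdiff(c("a", "b", "c", "x"), j)))
  expect_equal(first_removed, names(which.max(mv0)))
})

test_that("stability_select finds the planted proportional clique", {
  # 5 genes exactly proportional to the shared profile; 50 genes follow the
  # same profile under per-gene multiplicative noise, so the clique's zero
  # mutual log-ratio spread is the only distinction
  withr::with_seed(5, {
    prof <- 2^rnorm(16, 5, 1.5)
    clique <- t(sapply(2^seq(-2, 2), function(cst) prof * cst))
    sds <- runif(50, 0.5, 1.5)
    noisy <- t(sapply(1:50, function(i) prof * 2^rnorm(16, 0, sds[i])))
    m <- toy_expression(rbind(clique, noisy),
                        genes = c(paste0("clique", 1:5), paste0("n", 1:50)),
                        samples = paste0("s", 1:16))
  })
  picked <- stability_select(m, m$gene, n = 5, seed = 9)
  expect_setequal(picked$gene, paste0("clique", 1:5))
  # determinism under the seed
  again <- stability_select(m, m$gene, n = 5, seed = 9)
  expect_identical(picked, again)
  expect_warning(stability_select(m, paste0("clique", 1:5), n = 10), "pool")
})

test_that("random-ubiquitous draws are seeded and exhaustive draws equal all-ubiquitous", {
  m <- random_expression(80, 4, seed = 21)
  pool <- ubiquitous_genes(m, 0.05, 0.95)
  a <- normalize_random_ubiquitous(m, pool, n = 10, seed = 3)
  b <- normalize_random_ubiquitous(m, pool, n = 10, seed = 3)
  expect_equal(factors_of(a), factors_of(b))
  full <- normalize_random_ubiquitous(m, pool, n = nrow(pool), seed = 3)
  allu <- normalize_guide(m, pool$gene, method_name = "all_ubiquitous")
  expect_equal(factors_of(full), factors_of(allu))
  expect_error(normalize_random_ubiquitous(m, pool, n = nrow(pool) + 1), "pool")
})

test_that("total-ubiquitous equalizes pool totals and ignores non-pool genes", {
  m <- toy_expression(rbind(p1 = c(4, 10), p2 = c(6, 20), out = c(100, 2)),
                      genes = c("p1", "p2", "out"))
  tu <- normalize_total_ubiquitous(m, pool = c("p1", "p2"))
  expect_equal(factors_of(tu), c(s1 = 2, s2 = 2 / 3))  # totals 10, 30 -> 20
  after <- expr_mat(tu$data)
  expect_equal(sum(after[c("p1", "p2"), 1]), sum(after[c("p1", "p2"), 2]))

  # pool locality: adding an unrelated gene changes nothing
  m2 <- dplyr::bind_rows(m, toy_expression(rbind(extra = c(7, 7)), genes = "extra"))
  expect_equal(factors_of(normalize_total_ubiquitous(m2, pool = c("p1", "p2"))),
               factors_of(tu))
})

test_that("mock random factors stay in [2^-0.5, 2^0.5) with zero-mean log2", {
  m <- random_expression(10, 500, seed = 2)
  r <- normalize_random(m, seed = 7)
  f <- factors_of(r)
  expect_true(all(f >= 2^-0.5 & f < 2^0.5))
  expect_equal(factors_of(normalize_random(m, seed = 7)), f)
  # uniform-distribution oracle: mean log2 factor ~ 0 within 3 SE
  se <- sqrt(1 / 12) / sqrt(length(f))
  expect_lt(abs(mean(log2(f))), 3 * se)
})

test_that("TMM is 1 for self-comparison and depth-only differences", {
  m <- random_expression(200, 3, seed = 4)
  mm <- expr_mat(m)
  doubled <- toy_expression(cbind(s1 = mm[, 1], s2 = 2 * mm[, 1], s3 = mm[, 3]))
  res <- normalize_tmm(doubled, reference = "s1")
  tmm <- res$details$tmm
  expect_equal(unname(tmm["s2"]), 1, tolerance = 1e-9)  # fractions cancel
  # identical sample: all M = 0
  same <- toy_expression(cbind(s1 = mm[, 1], s2 = mm[, 1], s3 = mm[, 3]))
  expect_equal(unname(normalize_tmm(same, reference = "s1")$details$tmm["s2"]), 1)
})

test_that("TMM trimming absorbs a block of inflated genes", {
  withr::with_seed(8, {
    base <- 2^rnorm(400, 6, 1.5)
    s2 <- base
    s2[1:40] <- s2[1:40] * 100  # 10% of genes wildly inflated
    m <- toy_expression(cbind(s1 = base, s2 = s2, s3 = base * 1.1))
  })
  res <- normalize_tmm(m, reference = "s1")
  # after trimming removes the inflated block, the non-inflated majority
  # must end up on equal footing in s1 and s2: scaled ratio ~ 1 within 5%
  sm <- expr_mat(res$data)
  ratio <- median(sm[41:400, "s2"] / sm[41:400, "s1"])
  expect_equal(unname(ratio), 1, tolerance = 0.05)
})

test_that("factor methods preserve within-sample ratios exactly", {
  m <- random_expression(50, 4, seed = 13)
  pool <- ubiquitous_genes(m, 0.05, 0.95)
  results <- list(
    normalize_cpm(m), normalize_total(m), normalize_percentile(m, 0.75),
    normalize_guide(m, pool$gene[1:5]), normalize_total_ubiquitous(m, pool),
    normalize_random(m, 1), normalize_tmm(m)
  )
  mm <- expr_mat(m)
  ratios <- mm[1:25, ] / mm[26:50, ]
  for (res in results) {
    sm <- expr_mat(res$data)
    expect_equal(sm[1:25, ] / sm[26:50, ], ratios, tolerance = 1e-12)
    f <- factors_of(res)
    expect_equal(sm, sweep(mm, 2, f[colnames(mm)], `*`), tolerance = 1e-12)
  }
})

test_that("guide-based methods converge to the same truth as noise vanishes", {
  truth <- c(1.4, 0.8, 0.9, 1.05)
  err_at <- function(sigma) {
    sim <- simulate_expression(n_samples = 4, n_core = 120, n_specific = 0,
                               n_noise = 0, true_factors = truth,
                               sigma = sigma, seed = 31)
    target <- 1 / factors_of(sim$truth$adjusted_factors)
    pool <- ubiquitous_genes(sim$data, 0.05, 0.95)
    sapply(list(
      guide = normalize_guide(sim$data, pool$gene),
      tu = normalize_total_ubiquitous(sim$data, pool)
    ), function(r) max_rel_error(factors_of(adjust_factors(r$factors)), target))
  }
  e_hi <- err_at(0.2); e_lo <- err_at(0.01)
  expect_true(all(e_lo < e_hi))
  expect_true(all(e_lo < 0.01))
})
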