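test_that("pair_dispersal matches the log2 ratio range and is symmetric", {
  expect_equal(pair_dispersal(c(2, 4, 8), c(1, 2, 4))$dispersal, 0)
  expect_equal(pair_dispersal(c(2, 4), c(1, 4))$dispersal, 1)
  a <- c(3.2, 0.7, 11, 2.5); b <- c(1.1, 9, 0.4, 2.2)
  expect_equal(pair_dispersal(a, b)$dispersal, pair_dispersal(b, a)$dispersal)
  expect_gte(pair_dispersal(a, b)$dispersal, 0)
  expect_error(pair_dispersal(c(1, 0), c(1, 2)), "positive")
})

test_that("the similarity network admits pairs up to the dispersal cutoff", {
  # three genes: i ~ 2j (D = 0), k dispersed vs both
  m <- toy_expression(rbind(
    i = c(2, 4, 8), j = c(1, 2, 4), k = c(1, 8, 4)
  ), genes = c("i", "j", "k"))
  net <- build_similarity_network(m, c("i", "j", "k"), d_cutoff = 1)
  ij <- dplyr::filter(net$edges, from == "i", to == "j")
  expect_equal(ij$sim, 1)  # perfectly proportional pair
  # k vs i: ratios (0.5, 2, 0.5) -> D = 2: discarded
  expect_false(any(net$edges$from == "k" | net$edges$to == "k"))
  expect_equal(length(net$nodes), 3)  # isolated gene stays a node

  # a pair exactly at the cutoff keeps an edge of weight 0.5
  m2 <- toy_expression(rbind(a = c(2, 4), b = c(1, 4), c = c(1, 1)),
                       genes = c("a", "b", "c"))
  net2 <- build_similarity_network(m2, c("a", "b"), d_cutoff = 1)
  expect_equal(net2$edges$sim, 0.5)
  # all edge weights in (1/(1+cutoff), 1]
  r <- random_expression(40, 6, seed = 23)
  net3 <- build_similarity_network(r, r$gene, d_cutoff = 1)
  expect_true(all(net3$edges$sim > 0.5 & net3$edges$sim <= 1))
})

test_that("the network is invariant under per-sample rescaling", {
  m <- random_expression(30, 5, seed = 19)
  f <- c(s1 = 0.2, s2 = 5, s3 = 1.7, s4 = 0.9, s5 = 3)
  net_a <- build_similarity_network(m, m$gene)
  net_b <- build_similarity_network(distort_expression(m, f), m$gene)
  expect_equal(net_a$edges, net_b$edges)
})

test_that("PageRank centrality: star center wins, symmetric graphs tie", {
  # star: center c0 linked to 3 leaves with equal weight.
  star <- structure(list(
    nodes = c("c0", "l1", "l2", "l3"),
    edges = tibble::tibble(from = "c0", to = c("l1", "l2", "l3"),
                           dispersal = 0.5, sim = 1 / 1.5),
    d_cutoff = 1
  ), class = "tx_network")
  cw <- centrality_weights(star)
  all_w <- attr(cw, "all")
  expect_equal(sum(all_w$pagerank), 1, tolerance = 1e-9)
  expect_equal(sum(all_w$weight), 0, tolerance = 1e-7)  # sum(PR*G - 1) = 0
  expect_equal(cw$gene, "c0")  # only the center exceeds uniform centrality
  # oracle: dense linear solve on the 4x4 transition matrix
  w <- matrix(0, 4, 4); w[1, 2:4] <- w[2:4, 1] <- 1 / 1.5
  expect_equal(all_w$pagerank, solve_pagerank(w), tolerance = 1e-7)

  # two disconnected proportional pairs of equal weight: symmetry, all W = 0
  pairs <- structure(list(
    nodes = c("a", "b", "c", "d"),
    edges = tibble::tibble(from = c("a", "c"), to = c("b", "d"),
                           dispersal = 0, sim = 1),
    d_cutoff = 1
  ), class = "tx_network")
  cw2 <- centrality_weights(pairs)
  expect_equal(nrow(cw2), 0)
  expect_equal(attr(cw2, "all")$pagerank, rep(0.25, 4), tolerance = 1e-9)
})

test_that("power iteration agrees with the dense solve oracle on random graphs", {
  for (seed in 1:60) {
    g <- withr::with_seed(seed, sample(2:6, 1))
    w <- withr::with_seed(seed + 1000, {
      w <- matrix(0, g, g)
      upper <- which(upper.tri(w))
      on <- upper[runif(length(upper)) < 0.6]
      w[on] <- runif(length(on), 0.5, 1)
      w + t(w)
    })
    nodes <- paste0("n", seq_len(g))
    idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    net <- structure(list(
      nodes = nodes,
      edges = tibble::tibble(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                             dispersal = 0, sim = w[idx]),
      d_cutoff = 1
    ), class = "tx_network")
    pr <- attr(centrality_weights(net, tol = 1e-12), "all")$pagerank
    expect_equal(pr, solve_pagerank(w), tolerance = 1e-8)
  }
})

test_that("power iteration matches igraph's PageRank on a weighted graph", {
  skip_if_not_installed("igraph")
  m <- random_expression(25, 6, seed = 29)
  net <- build_similarity_network(m, m$gene, d_cutoff = 2)
  pr <- attr(centrality_weights(net, tol = 1e-12), "all")
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = net$nodes)
  ig <- igraph::page_rank(g, weights = net$edges$sim, damping = 0.85)$vector
  expect_equal(pr$pagerank, unname(ig[pr$gene]), tolerance = 1e-6)
})

test_that("ncs_factors equalizes the weighted geometric mean of guides", {
  m <- toy_expression(rbind(g1 = c(2, 4), g2 = c(6, 12), other = c(5, 5)),
                      genes = c("g1", "g2", "other"))
  w <- tibble::tibble(gene = c("g1", "g2"), weight = c(0.7, 0.3))
  f <- factors_of(ncs_factors(m, w))
  expect_equal(f, c(s1 = sqrt(2), s2 = 1 / sqrt(2)))  # guides 2x higher in s2
  # identical guides: unit factors
  ident <- toy_expression(rbind(g1 = c(3, 3), g2 = c(7, 7), o = c(1, 9)),
                          genes = c("g1", "g2", "o"))
  expect_equal(unname(factors_of(ncs_factors(ident, w))), c(1, 1))
  # invariance under global weight rescaling
  w10 <- dplyr::mutate(w, weight = weight * 10)
  expect_equal(factors_of(ncs_factors(m, w10)), f)
  expect_error(ncs_factors(m, dplyr::mutate(w, weight = 0)), "zero")
})

test_that("NCS recovers planted factors and is idempotent at the fixed point", {
  truth <- c(1.35, 0.7, 1.1, 0.96, 0.8, 1.25)
  sim <- simulate_expression(n_samples = 6, n_core = 150, n_specific = 0,
                             n_noise = 0, true_factors = truth, sigma = 0,
                             seed = 41)
  res <- normalize_ncs(sim$data, pool_cap = 100)
  target <- factors_of(sim$truth$adjusted_factors)
  expect_equal(factors_of(res), 1 / target, tolerance = 1e-6)
  # fixed point: renormalizing the normalized matrix gives unit factors
  again <- normalize_ncs(res$data, pool_cap = 100)
  expect_equal(unname(factors_of(again)), rep(1, 6), tolerance = 1e-6)
})

test_that("sample-specific spikes barely move the recovered NCS factors", {
  truth <- 2^seq(-0.4, 0.4, length.out = 6)
  clean <- simulate_expression(n_samples = 6, n_core = 300, n_specific = 0,
                               n_noise = 0, true_factors = truth,
                               sigma = 0.05, seed = 43)
  spiked <- simulate_expression(n_samples = 6, n_core = 300, n_specific = 15,
                                n_noise = 0, true_factors = truth,
                                sigma = 0.05, seed = 43)
  f_clean <- factors_of(normalize_ncs(clean$data, pool_cap = 200))
  f_spiked <- factors_of(normalize_ncs(spiked$data, pool_cap = 200))
  expect_lt(max(abs(f_spiked / f_clean - 1)), 0.02)
})

test_that("factor recovery error shrinks with the noise level", {
  truth <- c(1.2, 0.85, 1.05, 0.95)
  err <- sapply(c(0.3, 0.1, 0.02), function(sg) {
    sim <- simulate_expression(n_samples = 4, n_core = 150, n_specific = 0,
                               n_noise = 0, true_factors = truth, sigma = sg,
                               seed = 47)
    f <- factors_of(normalize_ncs(sim$data, pool_cap = 120))
    max_rel_error(f, 1 / factors_of(sim$truth$adjusted_factors))
  })
  expect_true(all(diff(err) < 0))
})
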