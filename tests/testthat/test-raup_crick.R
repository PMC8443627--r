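test_that("closed-form rescaled index reproduces the anchor cases", {
  expect_equal(exact_src_unweighted(1, 1, 10, 1), 0.9)
  expect_equal(exact_src_unweighted(1, 1, 10, 0), -0.1)
  # full-pool communities share everything by necessity: exactly 0
  expect_equal(exact_src_unweighted(7, 7, 7, 7), 0)
  expect_error(exact_src_unweighted(3, 3, 10, 4), "incompatible")
  expect_error(exact_src_unweighted(0, 3, 10, 0), "richness")
})

test_that("s_rc is monotone in observed sharing and bounded in [-1, 1]", {
  for (na in c(2, 4, 6)) for (nb in c(3, 5)) {
    lo <- max(0, na + nb - 12)
    vals <- vapply(lo:min(na, nb), function(s)
      exact_src_unweighted(na, nb, 12, s), numeric(1))
    expect_true(all(diff(vals) > 0))
    expect_true(all(vals >= -1 & vals <= 1))
  }
})

test_that("Monte-Carlo estimator converges to the hypergeometric oracle", {
  n_rand <- 10000
  tol <- 3 * sqrt(0.25 / n_rand) * 2  # 3 MC standard errors of the score
  pool <- letters[1:12]
  grid <- list(list(na = 1, nb = 1, sh = 1), list(na = 1, nb = 1, sh = 0),
               list(na = 3, nb = 4, sh = 2), list(na = 5, nb = 5, sh = 0),
               list(na = 6, nb = 3, sh = 3), list(na = 4, nb = 4, sh = 1))
  for (g in grid) {
    a <- pool[seq_len(g$na)]
    b <- c(pool[seq_len(g$sh)],
           rev(pool)[seq_len(g$nb - g$sh)])
    stopifnot(length(intersect(a, b)) == g$sh)
    est <- raup_crick_pair(a, b, pool, weights = NULL, n_rand = n_rand,
                           seed = 100 + g$na * 10 + g$sh)
    exact <- exact_src_unweighted(g$na, g$nb, 12, g$sh)
    expect_lt(abs(as.numeric(est) - exact), tol)
  }
})

test_that("pair statistic is symmetric and seed-reproducible", {
  pool <- paste0("t", 1:20)
  a <- pool[1:6]; b <- pool[4:12]
  w <- rep(c(1, 3), 10)
  e1 <- raup_crick_pair(a, b, pool, w, n_rand = 500, seed = 7)
  e2 <- raup_crick_pair(a, b, pool, w, n_rand = 500, seed = 7)
  expect_identical(e1, e2)
  # symmetry in expectation: both orders within MC error of each other
  e3 <- raup_crick_pair(b, a, pool, w, n_rand = 4000, seed = 8)
  e4 <- raup_crick_pair(a, b, pool, w, n_rand = 4000, seed = 9)
  expect_lt(abs(as.numeric(e3) - as.numeric(e4)), 6 * sqrt(0.25 / 4000) * 2)
  expect_error(raup_crick_pair(character(0), b, pool), "empty")
  expect_error(raup_crick_pair(c("nope"), b, pool), "subsets")
})

test_that("vegan's Raup-Crick null agrees with the closed form", {
  # vegan::raupcrick with null model r0 (fixed richness, equiprobable
  # species) reports P(null >= obs) with chase = FALSE and P(null > obs)
  # with chase = TRUE; averaging the two gives the half-tie convention, so
  # 1 - (d_ge + d_gt) is the rescaled similarity this package computes.
  m <- matrix(0, 2, 10, dimnames = list(NULL, letters[1:10]))
  m[1, 1:3] <- 1; m[2, 3:5] <- 1
  set.seed(1)
  d_ge <- as.numeric(vegan::raupcrick(m, null = "r0", nsimul = 6000,
                                      chase = FALSE))
  d_gt <- as.numeric(vegan::raupcrick(m, null = "r0", nsimul = 6000,
                                      chase = TRUE))
  exact <- exact_src_unweighted(3, 3, 10, 1)
  expect_lt(abs((1 - (d_ge + d_gt)) - exact), 0.05)
})

test_that("island-level results cover all pairs deterministically", {
  arch <- small_archipelago()
  ts <- arch$islands[[2]]
  n <- ncol(ts$presence)
  r1 <- raup_crick_island(ts, arch, n_rand = 300, seed = 21)
  r2 <- raup_crick_island(ts, arch, n_rand = 300, seed = 21)
  expect_equal(nrow(r1$pairs), n * (n - 1) / 2)
  expect_identical(r1$pairs$s_rc, r2$pairs$s_rc)
  expect_true(all(r1$pairs$s_rc >= -1 & r1$pairs$s_rc <= 1))
  expect_true(all(r1$pairs$census_i < r1$pairs$census_j))
  # observed sharing recorded per pair matches the presence matrix
  i <- r1$pairs$census_i[5]; j <- r1$pairs$census_j[5]
  expect_equal(r1$pairs$obs_shared[5],
               sum(ts$presence[, i] & ts$presence[, j]))
  expect_error(raup_crick_island(worked_ts(), arch), "not part")
})

test_that("identical censuses far below pool size read as homogenized", {
  # an island whose censuses are all the same 10 taxa, inside a 60-taxon
  # archipelago: sharing 10 of 10 is far beyond chance
  taxa <- sprintf("t%02d", 1:60)
  m_same <- matrix(1, 10, 4, dimnames = list(taxa[1:10], NULL))
  isl1 <- community_ts("same", m_same, c(0, 10, 20, 30))
  m_rest <- matrix(rbinom(60 * 5, 1, 0.4), 60, 5,
                   dimnames = list(taxa, NULL))
  m_rest[1:3, ] <- 1
  isl2 <- community_ts("bg", m_rest, seq(0, 40, 10))
  arch <- archipelago(list(isl1, isl2),
                      data.frame(island_id = c("same", "bg"),
                                 area_cm2 = c(10, 20),
                                 volume_ml = c(100, 200)))
  exact <- exact_src_unweighted(10, 10, length(arch$regional_pool), 10)
  expect_gt(exact, 0.95)
  r <- raup_crick_island(isl1, arch, n_rand = 1000, seed = 3,
                         null_weighting = "equiprobable")
  expect_true(all(r$pairs$s_rc >= 0.95))
})

test_that("process classification bookkeeping is exact", {
  pf <- classify_processes(c(0.99, 0.99, 0.5, -0.99), island_id = "X")
  expect_equal(pf$pct_HD, 50)
  expect_equal(pf$pct_drift, 25)
  expect_equal(pf$pct_DL, 25)
  expect_equal(pf$pct_HD + pf$pct_DL + pf$pct_drift, 100)
  expect_equal(classify_processes(rep(0, 7))$pct_drift, 100)
  # boundary values are counted as deterministic, not drift
  bd <- classify_processes(c(0.95, -0.95, 0.9499))
  expect_equal(bd$pct_HD, 100 / 3)
  expect_equal(bd$pct_DL, 100 / 3)
  expect_error(classify_processes(numeric(0)), "no census pairs")
  # percentages invariant to pair ordering
  set.seed(1)
  v <- runif(30, -1, 1)
  expect_equal(classify_processes(sample(v))[, -1],
               classify_processes(v)[, -1])
})
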