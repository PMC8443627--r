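# Independent oracles, deliberately implemented with plain set operations
# and longhand sums so they share no code with the package internals.

# communities as a list of character vectors, one per census
as_sets <- function(ts) {
  lapply(seq_len(ncol(ts$presence)),
         function(t) rownames(ts$presence)[ts$presence[, t]])
}

oracle_mw <- function(sets) {
  S <- numeric(length(sets))
  S[1] <- length(sets[[1]])
  for (t in seq_along(sets)[-1])
    S[t] <- S[t - 1] + length(setdiff(sets[[t]], sets[[t - 1]]))
  S
}

oracle_cmw <- function(sets) {
  vapply(seq_along(sets), function(t)
    length(unique(unlist(sets[1:t]))), numeric(1))
}

oracle_epw <- function(sets) {
  n <- length(sets)
  vapply(seq_len(n), function(k) {
    vals <- vapply(1:(n - k + 1), function(a)
      length(unique(unlist(sets[a:(a + k - 1)]))), numeric(1))
    mean(vals)
  }, numeric(1))
}

# longhand simple OLS with F statistic, no lm()
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  ssres <- sum((y - yhat)^2)
  sstot <- sum((y - mean(y))^2)
  f <- ((sstot - ssres) / 1) / (ssres / (n - 2))
  list(slope = slope, intercept = intercept, r2 = 1 - ssres / sstot,
       f = f, p = pf(f, 1, n - 2, lower.tail = FALSE))
}

# longhand one-way ANOVA from sums of squares
oracle_anova <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(all_v) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = pf(f, df1, df2, lower.tail = FALSE))
}

# random presence matrix guaranteed valid (no empty censuses, no empty taxa)
random_presence <- function(n_taxa, n_census, p = 0.5) {
  repeat {
    m <- matrix(runif(n_taxa * n_census) < p, n_taxa, n_census,
                dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
    if (all(colSums(m) > 0) && all(rowSums(m) > 0)) return(m)
  }
}

# 4-census worked example used across the STR tests
worked_ts <- function() {
  m <- matrix(c(1, 1, 0, 0,
                0, 1, 1, 0,
                1, 0, 0, 1,
                0, 1, 0, 0), nrow = 4,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  community_ts("TH1", m, census_days = c(0, 30, 60, 90))
}

small_archipelago <- function(seed = 11) {
  generate_archipelago(
    sim_config(n_islands = 4, pool_size = 250, n_censuses = 8),
    seed = seed)
}
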