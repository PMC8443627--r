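#' Exact rescaled Raup-Crick similarity under the equiprobable null
#'
#' With equiprobable draws at fixed richness, the null shared-taxon count
#' between two communities of richness `n_a` and `n_b` drawn from a pool of
#' `pool_size` taxa is hypergeometric:
#' `P(shared = s) = C(n_a, s) C(pool - n_a, n_b - s) / C(pool, n_b)`.
#' The rescaled similarity is
#' `s_rc = 2 * (P(shared < obs) + 0.5 * P(shared = obs)) - 1`,
#' oriented so +1 means more similar than expected by chance. This closed
#' form is the test oracle for the Monte-Carlo estimator.
#'
#' @param richness_a,richness_b Observed richness of the two communities.
#' @param pool_size Regional pool size.
#' @param obs_shared Observed number of shared taxa.
#' @return The exact `s_rc` value in `[-1, 1]`.
#' @export
#' @examples
#' exact_src_unweighted(1, 1, 10, 1)   #  0.9
#' exact_src_unweighted(1, 1, 10, 0)   # -0.1
exact_src_unweighted <- function(richness_a, richness_b, pool_size,
                                 obs_shared) {
  if (richness_a < 1 || richness_b < 1 || richness_a > pool_size ||
      richness_b > pool_size)
    stop("richness must be in [1, pool_size]")
  if (obs_shared > min(richness_a, richness_b) ||
      obs_shared < max(0, richness_a + richness_b - pool_size))
    stop("obs_shared incompatible with richnesses and pool size")
  p_less <- stats::phyper(obs_shared - 1, richness_a,
                          pool_size - richness_a, richness_b)
  p_tie <- stats::dhyper(obs_shared, richness_a,
                         pool_size - richness_a, richness_b)
  2 * (p_less + 0.5 * p_tie) - 1
}

#' Monte-Carlo rescaled Raup-Crick similarity for one community pair
#'
#' For each randomization a null counterpart of each community is drawn
#' from the regional pool without replacement at the community's observed
#' richness, with taxon inclusion probability proportional to `weights`
#' (dataset-wide occurrence frequency by default) or equiprobable when
#' `weights` is NULL. The rescaled statistic
#' `s_rc = 2 * ((n_less + 0.5 * n_tie) / n_rand) - 1`
#' compares the observed shared-taxon count against the null draws; ties
#' get half-weight so the degenerate full-pool case lands exactly at 0.
#'
#' @param comm_a,comm_b Character vectors of taxon identifiers (presence
#'   sets), both subsets of `pool`.
#' @param pool Character vector: the regional taxon pool.
#' @param weights Positive numeric vector over `pool` (occurrence
#'   frequencies), or NULL for equiprobable draws.
#' @param n_rand Number of randomizations (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return The `s_rc` estimate, with attributes `obs_shared` and `n_rand`.
#' @export
raup_crick_pair <- function(comm_a, comm_b, pool, weights = NULL,
                            n_rand = 1000L, seed = NULL) {
  P <- length(pool)
  if (!length(comm_a) || !length(comm_b))
    stop("empty community: Raup-Crick is undefined")
  if (!all(comm_a %in% pool) || !all(comm_b %in% pool))
    stop("communities must be subsets of the pool")
  na <- length(unique(comm_a)); nb <- length(unique(comm_b))
  if (na > P || nb > P) stop("richness exceeds pool size")
  if (n_rand < 1L) stop("n_rand must be >= 1")
  if (!is.null(weights)) {
    if (length(weights) != P || any(weights <= 0))
      stop("weights must be positive, one per pool taxon")
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- length(intersect(unique(comm_a), unique(comm_b)))
  less <- 0L; tie <- 0L
  memb <- logical(P)
  for (r in seq_len(n_rand)) {
    ia <- sample.int(P, na, prob = weights)
    ib <- sample.int(P, nb, prob = weights)
    memb[ia] <- TRUE
    s <- sum(memb[ib])
    memb[ia] <- FALSE
    if (s < obs) less <- less + 1L else if (s == obs) tie <- tie + 1L
  }
  structure(2 * ((less + 0.5 * tie) / n_rand) - 1,
            obs_shared = obs, n_rand = n_rand)
}

#' Raup-Crick similarities for all census pairs within one island
#'
#' Computes the rescaled Monte-Carlo similarity for every unordered pair of
#' censuses of one island, using the archipelago-wide regional pool (all
#' taxa observed anywhere over the whole survey) and, by default, null
#' draws weighted by dataset-wide occurrence frequency. Each randomization
#' draws one null community per census at that census's richness; shared
#' counts for all pairs come from the same draw, as in Chase-style
#' implementations. Deterministic given `seed`.
#'
#' @param ts A [community_ts()]; must be one of `dataset`'s islands.
#' @param dataset The [archipelago()] the island belongs to.
#' @param n_rand Number of randomizations (default 1000).
#' @param seed Optional integer seed.
#' @param null_weighting `"occurrence"` (inclusion probability proportional
#'   to dataset-wide occurrence frequency) or `"equiprobable"`.
#' @return Object of class `raup_crick_result`: `island_id`, `pairs` (data
#'   frame `census_i`, `census_j`, `day_i`, `day_j`, `obs_shared`, `s_rc`),
#'   `n_rand`, `null_weighting`, `seed`.
#' @export
raup_crick_island <- function(ts, dataset, n_rand = 1000L, seed = NULL,
                              null_weighting = c("occurrence",
                                                 "equiprobable")) {
  null_weighting <- match.arg(null_weighting)
  stopifnot(inherits(ts, "community_ts"), inherits(dataset, "archipelago"))
  if (!ts$island_id %in% names(dataset$islands))
    stop("island '", ts$island_id, "' is not part of the dataset")
  pool <- dataset$regional_pool
  P <- length(pool)
  w <- if (null_weighting == "occurrence")
    as.numeric(dataset$occurrence_freq) else NULL
  n <- ncol(ts$presence)
  # island presence embedded in pool coordinates, censuses in rows
  pres <- matrix(0L, n, P)
  pres[, match(ts$taxon_ids, pool)] <- t(ts$presence * 1L)
  rich <- rowSums(pres)
  obs <- tcrossprod(pres)
  if (!is.null(seed)) set.seed(seed)
  less <- matrix(0L, n, n)
  tie <- matrix(0L, n, n)
  nullm <- matrix(0L, n, P)
  for (r in seq_len(n_rand)) {
    nullm[] <- 0L
    for (i in seq_len(n))
      nullm[i, sample.int(P, rich[i], prob = w)] <- 1L
    ns <- tcrossprod(nullm)
    less <- less + (ns < obs)
    tie <- tie + (ns == obs)
  }
  srcm <- 2 * ((less + 0.5 * tie) / n_rand) - 1
  idx <- which(upper.tri(srcm), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  pairs <- data.frame(
    census_i = idx[, 1L], census_j = idx[, 2L],
    day_i = ts$census_days[idx[, 1L]], day_j = ts$census_days[idx[, 2L]],
    obs_shared = obs[idx], s_rc = srcm[idx])
  structure(
    list(island_id = ts$island_id, pairs = pairs, n_rand = n_rand,
         null_weighting = null_weighting, seed = seed),
    class = "raup_crick_result")
}

#' @export
print.raup_crick_result <- function(x, ...) {
  cat("Raup-Crick result: island", x$island_id, "-", nrow(x$pairs),
      "census pairs,", x$n_rand, "randomizations (",
      x$null_weighting, "null )\n")
  cat(sprintf("  s_rc: min %.3f, median %.3f, max %.3f\n",
              min(x$pairs$s_rc), stats::median(x$pairs$s_rc),
              max(x$pairs$s_rc)))
  invisible(x)
}

#' Raup-Crick similarities for every island of an archipelago
#'
#' One independent random stream per island, derived from `seed` as
#' `seed + island index`, recorded in each result.
#'
#' @inheritParams raup_crick_island
#' @param dataset An [archipelago()] object.
#' @return Named list of `raup_crick_result`, one per island.
#' @export
raup_crick_archipelago <- function(dataset, n_rand = 1000L, seed = NULL,
                                   null_weighting = c("occurrence",
                                                      "equiprobable")) {
  null_weighting <- match.arg(null_weighting)
  res <- vector("list", length(dataset$islands))
  names(res) <- names(dataset$islands)
  for (j in seq_along(dataset$islands)) {
    s_j <- if (is.null(seed)) NULL else seed + j
    res[[j]] <- raup_crick_island(dataset$islands[[j]], dataset,
                                  n_rand = n_rand, seed = s_j,
                                  null_weighting = null_weighting)
  }
  res
}

#' Classify census pairs into ecological processes
#'
#' Pairs more similar than expected by chance (`s_rc >= threshold`,
#' boundary inclusive) indicate homogenizing dispersal; pairs more
#' dissimilar than chance (`s_rc <= -threshold`) indicate dispersal
#' limitation (selection); the remainder indicate ecological drift.
#' Frequencies are returned as percentages of the island's pair count.
#'
#' @param result A `raup_crick_result` (or a numeric vector of s_rc
#'   values, in which case `island_id` is taken from the argument).
#' @param threshold Classification cutoff (default 0.95).
#' @param island_id Island label used when `result` is a bare vector.
#' @return Object of class `process_frequencies`: data frame with
#'   `island_id`, `pct_HD`, `pct_DL`, `pct_drift`, `n_pairs`.
#' @export
#' @examples
#' classify_processes(c(0.99, 0.99, 0.5, -0.99), island_id = "TH1")
classify_processes <- function(result, threshold = 0.95,
                               island_id = NA_character_) {
  if (inherits(result, "raup_crick_result")) {
    src <- result$pairs$s_rc
    island_id <- result$island_id
  } else {
    src <- as.numeric(result)
  }
  if (!length(src)) stop("no census pairs to classify")
  stopifnot(threshold > 0, threshold <= 1)
  hd <- sum(src >= threshold)
  dl <- sum(src <= -threshold)
  drift <- length(src) - hd - dl
  out <- data.frame(island_id = island_id,
                    pct_HD = 100 * hd / length(src),
                    pct_DL = 100 * dl / length(src),
                    pct_drift = 100 * drift / length(src),
                    n_pairs = length(src))
  class(out) <- c("process_frequencies", "data.frame")
  out
}
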