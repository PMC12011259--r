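# Independent oracles used to freeze expected values. Each one deliberately
# avoids the code path it checks.

# Eq-by-eq arithmetic on the stratified sample-size formula, written out
# directly (no package calls).
oracle_plot_count <- function(A, Ap, t, E, W, S) {
  N <- A / Ap
  wss <- sum(W * S^2)
  N * t^2 * wss / (N * E^2 + t^2 * wss)
}

# Grid-search minimizer of log-space squared error for M = a D^b.
oracle_allometric_grid <- function(dbh, mass,
                                   a_grid = exp(seq(log(0.01), log(1),
                                                    length.out = 201)),
                                   b_grid = seq(1.5, 3.5, length.out = 401)) {
  best <- c(a = NA, b = NA); best_sse <- Inf
  lm_ <- log(mass); ld <- log(dbh)
  for (b in b_grid) {
    # profile out a: for fixed b the optimal log(a) is the mean residual
    la <- mean(lm_ - b * ld)
    sse <- sum((lm_ - la - b * ld)^2)
    if (sse < best_sse) { best_sse <- sse; best <- c(a = exp(la), b = b) }
  }
  best
}

# Plain accumulation of per-species sums with a loop.
oracle_subtotals <- function(groups) {
  out <- list()
  for (r in seq_len(nrow(groups))) {
    sp <- groups$species[r]
    if (is.null(out[[sp]])) out[[sp]] <- c(volume = 0, count = 0)
    out[[sp]]["volume"] <- out[[sp]]["volume"] + groups$volume[r]
    out[[sp]]["count"] <- out[[sp]]["count"] + groups$count[r]
  }
  out
}

# Random stratum table with weights summing exactly to 1.
random_strata <- function(k) {
  w <- stats::runif(k)
  w <- w / sum(w)
  w[k] <- 1 - sum(w[-k])  # force the exact-sum invariant
  stratum_table(paste0("s", seq_len(k)), w, stats::runif(k, 0, 50))
}

# Small synthetic inventory for biomass/MLP tests: noiseless unless asked.
make_power_law_trees <- function(n, a = 0.1, b = 2.4, sigma = 0, seed = 1) {
  withr::with_seed(seed, {
    dbh <- stats::runif(n, 5, 30)
    height <- 1.3 + 0.8 * dbh + stats::rnorm(n, 0, 0.2)
    data.frame(tree_id = sprintf("t%03d", seq_len(n)),
               species = "Cunninghamia lanceolata",
               dbh = dbh, height = height,
               age = sample(5:22, n, replace = TRUE),
               region = sample(0:5, n, replace = TRUE),
               biomass = a * dbh^b * exp(stats::rnorm(n, 0, sigma)),
               stringsAsFactors = FALSE)
  })
}
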