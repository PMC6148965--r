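# Independent oracles used to validate the package's own implementations.
# These deliberately use different code paths (stats:: pmf functions, grid
# search, explicit enumeration) from the compiled routines they check.

# NB log-likelihood via stats::dnbinom / stats::dpois
oracle_nb_ll <- function(y, mu, phi) {
  if (phi < 1e-12) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

# Joint (mu, phi) MLE by coarse grid search refined with Nelder-Mead
oracle_nb_mle <- function(y, mu_range = c(0.5, 20), phi_range = c(0, 3)) {
  nll <- function(par) {
    if (par[1] <= 0 || par[2] < 0) return(1e10)
    -oracle_nb_ll(y, par[1], par[2])
  }
  mus <- seq(mu_range[1], mu_range[2], by = 0.1)
  phis <- seq(phi_range[1], phi_range[2], by = 0.01)
  grid <- expand.grid(mu = mus, phi = phis)
  vals <- mapply(function(m, p) oracle_nb_ll(y, m, p), grid$mu, grid$phi)
  best <- as.numeric(grid[which.max(vals), ])
  opt <- stats::optim(best, nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 5000))
  list(mu = opt$par[1], phi = opt$par[2], loglik = -opt$value)
}

# Literal transcription of the published TMM definition (reference by upper
# quartile, 30%/5% two-sided trims, inverse-variance weights, geometric-mean
# centering), written with explicit per-sample loops.
oracle_tmm_factors <- function(m) {
  lib <- colSums(m)
  uq <- vapply(seq_len(ncol(m)),
               function(j) stats::quantile(m[, j], 0.75), numeric(1)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    o <- m[, j]; r <- m[, ref]
    keep <- o > 0 & r > 0
    o <- o[keep]; r <- r[keep]
    M <- log2((o / lib[j]) / (r / lib[ref]))
    A <- 0.5 * log2((o / lib[j]) * (r / lib[ref]))
    w <- (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r)
    if (length(M) == 0 || max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f[j] <- 2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
  }
  f / exp(mean(log(f)))
}

# Step-by-step transcription of Storey's q-value formula
oracle_storey <- function(p, lambda = 0.5) {
  G <- length(p)
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * G))
  o <- order(p)
  q_sorted <- numeric(G)
  for (i in seq_len(G)) {
    cand <- sapply(i:G, function(j) pi0 * G * p[o[j]] / j)
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(G)
  q[o] <- q_sorted
  q
}

# Equal-tailed Poisson interval by explicit pmf summation
oracle_pois_interval <- function(mu, alpha) {
  a2 <- alpha / 2
  k <- 0
  while (ppois(k, mu) < 1 - a2 - 1e-12) k <- k + 1
  hi <- k
  lo <- 0
  while (ppois(lo, mu) <= a2 + 1e-12) lo <- lo + 1
  c(lo = lo, hi = hi)
}

# ROC/AUC by brute-force threshold enumeration
oracle_auc <- function(scores, de) {
  s <- ifelse(is.na(scores), Inf, scores)
  thr <- sort(unique(s))
  fpr <- c(0, vapply(thr, function(t) mean(s[!de] <= t), numeric(1)))
  tpr <- c(0, vapply(thr, function(t) mean(s[de] <= t), numeric(1)))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
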