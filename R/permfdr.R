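#' Select null-like genes
#'
#' Genes whose chi-square LRT p-value is at least the cutoff (default 0.1)
#' show no strong evidence against the null and are pooled to estimate the
#' permutation null distribution of the shrunken statistic.
#'
#' @param p_chi2 Per-gene chi-square p-values in `[0, 1]` (NA allowed).
#' @param cutoff Inclusion threshold; the boundary value is included
#'   (`p >= cutoff`).
#' @return Integer vector of gene indices.
#' @export
select_null_like <- function(p_chi2, cutoff = 0.1) {
  if (any(p_chi2 < 0 | p_chi2 > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  idx <- which(!is.na(p_chi2) & p_chi2 >= cutoff)
  if (length(idx) == 0L)
    stop("no null-like genes at cutoff ", cutoff,
         "; increase the cutoff to build a null pool", call. = FALSE)
  idx
}

#' Enumerate group-label permutations
#'
#' Lists the distinct unordered partitions of the `n = n1 + n2` samples into
#' pseudo-groups of sizes `(n1, n2)`, excluding the observed labeling. When
#' `n1 = n2` a partition and its label swap give the same value of the
#' label-symmetric statistic and are counted once. If the count exceeds
#' `max_permutations`, a seeded uniform subsample is returned.
#'
#' @param n1,n2 Group sizes, both at least 2.
#' @param max_permutations Cap on the number of partitions returned.
#' @param seed Seed for the subsample draw (only used when capping applies).
#' @param observed Indices of the samples observed in group 1 (default
#'   `1:n1`).
#' @return Object of class `desyn_perms`: list with `perms` (list of group-1
#'   index vectors), `M`, `n1`, `n2`, `exhaustive`.
#' @export
enumerate_permutations <- function(n1, n2, max_permutations = 200,
                                   seed = NULL, observed = seq_len(n1)) {
  if (n1 < 2 || n2 < 2)
    stop("need at least 2 replicates per group to permute", call. = FALSE)
  n <- n1 + n2
  stopifnot(length(observed) == n1, all(observed %in% seq_len(n)))
  combos <- utils::combn(n, n1, simplify = FALSE)
  obs <- sort(observed)
  if (n1 == n2) {
    # canonical representative of each {partition, label swap} pair: the
    # half containing sample 1
    combos <- Filter(function(s) 1L %in% s, combos)
    if (!(1L %in% obs)) obs <- sort(setdiff(seq_len(n), obs))
  }
  combos <- Filter(function(s) !identical(as.integer(s), as.integer(obs)),
                   combos)
  if (length(combos) == 0L)
    stop("no permutations distinct from the observed labeling", call. = FALSE)
  if (length(combos) > max_permutations) {
    pick <- with_local_seed(seed,
      sample.int(length(combos), max_permutations))
    combos <- combos[sort(pick)]
    exhaustive <- FALSE
  } else exhaustive <- TRUE
  structure(list(perms = combos, M = length(combos), n1 = n1, n2 = n2,
                 exhaustive = exhaustive),
            class = "desyn_perms")
}

#' Build the pooled permutation null distribution
#'
#' For each permutation of the group labels, every gene is refit under the
#' relabeled groups, the group-context dispersion hyperpriors are
#' re-estimated from all genes, dispersions are shrunken, and the
#' shrunken-statistic values of the null-like genes are pooled. The pooled
#' context (all samples together) does not depend on the labeling and is
#' computed once. Genes whose fit fails under a relabeling (an all-zero
#' pseudo-group) are skipped and counted.
#'
#' @param cm Normalized [desyn_counts] object (values are rounded to
#'   integers before likelihood evaluation).
#' @param null_like Integer indices of the null-like genes (from
#'   [select_null_like()]).
#' @param perms A `desyn_perms` object from [enumerate_permutations()].
#' @param cutoff The null-like p-value cutoff used (recorded for reporting).
#' @return Object of class `perm_null`: list with `values` (pooled
#'   statistics), `M`, `n_null_like`, `cutoff`, `n_failed`.
#' @export
build_null <- function(cm, null_like, perms, cutoff = 0.1) {
  stopifnot(inherits(cm, "desyn_counts"), inherits(perms, "desyn_perms"))
  if (length(null_like) == 0L) stop("null_like is empty", call. = FALSE)
  m <- round(cm$counts)
  G <- nrow(m)
  n <- ncol(m)
  stopifnot(perms$n1 + perms$n2 == n)
  # label-invariant pooled piece
  pooled <- fit_context(m)
  hp0 <- estimate_hyperprior(pooled$phi, pooled$tau2, "pooled")
  phiB0 <- shrink_dispersion(pooled$phi, pooled$tau2, hp0)
  llp <- cpp_ll_rows_at(m, pooled$mu, phiB0)
  values <- vector("list", perms$M)
  n_failed <- 0L
  for (i in seq_len(perms$M)) {
    cols1 <- perms$perms[[i]]
    cols2 <- setdiff(seq_len(n), cols1)
    f1 <- fit_context(m[, cols1, drop = FALSE])
    f2 <- fit_context(m[, cols2, drop = FALSE])
    fail <- !(f1$ok & f2$ok)
    if (mean(fail) > 0.5)
      stop("more than 50% of genes failed to fit in permutation ", i,
           call. = FALSE)
    hp1 <- estimate_hyperprior(f1$phi, f1$tau2, "group1")
    hp2 <- estimate_hyperprior(f2$phi, f2$tau2, "group2")
    phiB1 <- shrink_dispersion(f1$phi, f1$tau2, hp1)
    phiB2 <- shrink_dispersion(f2$phi, f2$tau2, hp2)
    ll1 <- cpp_ll_rows_at(m[, cols1, drop = FALSE], f1$mu, phiB1)
    ll2 <- cpp_ll_rows_at(m[, cols2, drop = FALSE], f2$mu, phiB2)
    lr <- 2 * (ll1 + ll2 - llp)
    v <- lr[null_like]
    n_failed <- n_failed + sum(is.na(v))
    values[[i]] <- v[!is.na(v)]
  }
  structure(list(values = unlist(values, use.names = FALSE), M = perms$M,
                 n_null_like = length(null_like), cutoff = cutoff,
                 n_failed = n_failed),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("pooled permutation null: %d values (%d permutations x %d null-like genes, %d fit failures skipped)\n",
              length(x$values), x$M, x$n_null_like, x$n_failed))
  invisible(x)
}

#' Empirical permutation p-value
#'
#' Upper-tail p-value of a statistic against the pooled null, with the
#' add-one convention `p = (1 + #\{null >= stat\}) / (#null + 1)`, which
#' guarantees a strictly positive, valid permutation p-value.
#'
#' @param lr_eb Statistic value(s); vectorized, `NA` propagates.
#' @param null A `perm_null` object.
#' @return p-value(s) in `(0, 1]`.
#' @export
empirical_pvalue <- function(lr_eb, null) {
  stopifnot(inherits(null, "perm_null"))
  v <- null$values
  if (length(v) == 0L) stop("empty permutation null", call. = FALSE)
  sv <- sort(v)
  L <- length(sv)
  # #\{v >= x\} = L - #\{v < x\}
  n_lt <- findInterval(lr_eb, sv, left.open = TRUE)
  p <- (1 + (L - n_lt)) / (L + 1)
  p[is.na(lr_eb)] <- NA_real_
  p
}

#' Storey q-values
#'
#' Converts p-values to FDR-adjusted q-values using Storey's estimator of
#' the null proportion at a single lambda:
#' `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) * G))`, then
#' `q_(i) = min_\{j >= i\} pi0 * G * p_(j) / j` on the sorted scale, mapped
#' back to the input order and capped at 1. `NA` p-values are excluded from
#' the calculation (and from `G`) and returned as `NA`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param lambda Tuning parameter of the null-proportion estimate.
#' @return q-values aligned with `p`.
#' @export
storey_qvalues <- function(p, lambda = 0.5) {
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (length(ok) == 0L) return(out)
  pv <- p[ok]
  G <- length(pv)
  pi0 <- min(1, sum(pv > lambda) / ((1 - lambda) * G))
  o <- order(pv)
  q <- pi0 * G * pv[o] / seq_len(G)
  q <- rev(cummin(rev(q)))
  q <- pmin(1, q)
  out[ok[o]] <- q
  out
}
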