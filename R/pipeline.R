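#' Core mean-and-dispersion testing engine
#'
#' Runs the testing stages on a normalized count matrix: per-gene NB fits in
#' the pooled and two group contexts, the chi-square screening LRT,
#' empirical-Bayes dispersion shrinkage, the shrunken LRT statistic, the
#' pooled permutation null, empirical p-values and Storey q-values. Genes
#' whose fit fails in any context (e.g. an all-zero group) are reported with
#' `NA` statistics, a reason flag, and are excluded from the
#' multiple-testing denominator.
#'
#' @param cm A [desyn_counts] object; values are rounded to integers for
#'   likelihood evaluation.
#' @param null_cutoff Chi-square p-value threshold defining null-like genes.
#' @param max_perms Cap on the number of label permutations.
#' @param seed Seed (used only if the permutation set is subsampled).
#' @param verbose Emit one progress line per stage.
#' @return List with `results` (data frame: `gene_id`, `lr`, `p_chi2`,
#'   `lr_eb`, `p_perm`, `q_value`, `flag`), `hyperpriors`, `null` (the
#'   `perm_null`), `fits_g1` (per-gene normal-group `mu` and shrunken
#'   `phiB`, for replicate classification), `M`.
#' @export
desyn_core <- function(cm, null_cutoff = 0.1, max_perms = 200, seed = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(cm, "desyn_counts"))
  say <- function(...) if (verbose) message(sprintf(...))
  m <- round(cm$counts)
  g1 <- which(cm$group == 1L); g2 <- which(cm$group == 2L)
  say("fitting %d genes in 3 contexts", nrow(m))
  fp <- fit_context(m)
  f1 <- fit_context(m[, g1, drop = FALSE])
  f2 <- fit_context(m[, g2, drop = FALSE])
  ok <- fp$ok & f1$ok & f2$ok
  lr <- pmax(0, 2 * (f1$loglik + f2$loglik - fp$loglik))
  p_chi2 <- exp(-lr / 2)
  say("estimating hyperpriors and shrinking dispersions")
  hp0 <- estimate_hyperprior(fp$phi, fp$tau2, "pooled")
  hp1 <- estimate_hyperprior(f1$phi, f1$tau2, "group1")
  hp2 <- estimate_hyperprior(f2$phi, f2$tau2, "group2")
  phiB0 <- shrink_dispersion(fp$phi, fp$tau2, hp0)
  phiB1 <- shrink_dispersion(f1$phi, f1$tau2, hp1)
  phiB2 <- shrink_dispersion(f2$phi, f2$tau2, hp2)
  llB0 <- cpp_ll_rows_at(m, fp$mu, phiB0)
  llB1 <- cpp_ll_rows_at(m[, g1, drop = FALSE], f1$mu, phiB1)
  llB2 <- cpp_ll_rows_at(m[, g2, drop = FALSE], f2$mu, phiB2)
  lr_eb <- 2 * (llB1 + llB2 - llB0)
  null_like <- select_null_like(ifelse(ok, p_chi2, NA_real_), null_cutoff)
  perms <- enumerate_permutations(cm$n1, cm$n2, max_perms, seed,
                                  observed = g1)
  say("building pooled null: %d permutations x %d null-like genes",
      perms$M, length(null_like))
  null <- build_null(cm, null_like, perms, null_cutoff)
  p_perm <- empirical_pvalue(ifelse(ok, lr_eb, NA_real_), null)
  q <- storey_qvalues(p_perm)
  say("done: %d genes scored, %d untestable", sum(ok), sum(!ok))
  results <- data.frame(
    gene_id = cm$gene_ids,
    lr = ifelse(ok, lr, NA_real_),
    p_chi2 = ifelse(ok, p_chi2, NA_real_),
    lr_eb = ifelse(ok, lr_eb, NA_real_),
    p_perm = p_perm,
    q_value = q,
    flag = ifelse(ok, "ok", "fit_failed"))
  list(results = results,
       hyperpriors = list(pooled = hp0, group1 = hp1, group2 = hp2),
       null = null,
       fits_g1 = data.frame(gene_id = cm$gene_ids, mu = f1$mu, phiB = phiB1),
       M = perms$M)
}

#' Run the full analysis pipeline
#'
#' End-to-end analysis of a raw two-group count matrix: low-count filtering,
#' TMM normalization, the chi-square screening LRT, empirical-Bayes
#' dispersion shrinkage, the pooled permutation test, Storey FDR control,
#' and NB prediction-interval classification of each declared DE gene's
#' disease replicates.
#'
#' @param cm A raw [desyn_counts] object (see [read_counts()]).
#' @param fdr Nominal FDR level defining the DE list.
#' @param null_cutoff Null-like chi-square p-value cutoff.
#' @param fwer Family-wise error level for replicate classification.
#' @param max_perms Cap on label permutations.
#' @param seed Seed for permutation subsampling.
#' @param filter_threshold Total-count filter threshold.
#' @param skip_tmm Treat the input as already normalized (equal library
#'   sizes); used for simulated data.
#' @param global_bonferroni Bonferroni across genes x replicates instead of
#'   within-gene (see [classify_replicates()]).
#' @param verbose Emit stage progress.
#' @return Object of class `desyn_result`: list with `results`, `de_genes`,
#'   `calls` (a `replicate_calls` or `NULL` if no DE genes), `factors`,
#'   `manifest`, `core` (the [desyn_core()] internals).
#' @export
run_desyn <- function(cm, fdr = 0.05, null_cutoff = 0.1, fwer = 0.05,
                      max_perms = 200, seed = NULL, filter_threshold = 10,
                      skip_tmm = FALSE, global_bonferroni = FALSE,
                      verbose = FALSE) {
  stopifnot(inherits(cm, "desyn_counts"))
  n_input <- nrow(cm$counts)
  factors <- NULL
  if (!cm$normalized) {
    cmf <- filter_low_counts(cm, filter_threshold)
    if (skip_tmm) {
      norm <- desyn_counts(cmf$counts, cmf$group, normalized = TRUE)
    } else {
      tn <- tmm_normalize(cmf)
      factors <- tn$factors
      norm <- tn$normalized
    }
    discarded <- cmf$discarded
  } else {
    norm <- cm
    discarded <- character(0)
  }
  core <- desyn_core(norm, null_cutoff = null_cutoff, max_perms = max_perms,
                     seed = seed, verbose = verbose)
  res <- core$results
  de_genes <- res$gene_id[!is.na(res$q_value) & res$q_value <= fdr]
  calls <- NULL
  if (length(de_genes)) {
    disease_obs <- norm$counts[, norm$group == 2L, drop = FALSE]
    calls <- classify_replicates(de_genes, core$fits_g1, disease_obs,
                                 fwer = fwer,
                                 global_family = global_bonferroni)
  }
  manifest <- list(
    package = "DESyn",
    version = as.character(utils::packageVersion("DESyn")),
    seed = seed,
    config = list(fdr = fdr, null_cutoff = null_cutoff, fwer = fwer,
                  max_perms = max_perms, filter_threshold = filter_threshold,
                  skip_tmm = skip_tmm, global_bonferroni = global_bonferroni),
    M = core$M,
    hyperpriors = lapply(core$hyperpriors, function(h)
      list(phi0 = h$phi0, tau20 = h$tau20, n_genes_used = h$n_genes_used)),
    gene_counts = list(n_input = n_input,
                       n_filtered_out = length(discarded),
                       n_tested = sum(res$flag == "ok"),
                       n_na = sum(res$flag != "ok"),
                       n_de = length(de_genes)))
  structure(list(results = res, de_genes = de_genes, calls = calls,
                 factors = factors, manifest = manifest, core = core),
            class = "desyn_result")
}

#' @export
print.desyn_result <- function(x, ...) {
  gc <- x$manifest$gene_counts
  cat(sprintf("DESyn run: %d genes in, %d filtered out, %d tested (%d untestable)\n",
              gc$n_input, gc$n_filtered_out, gc$n_tested, gc$n_na))
  cat(sprintf("  permutations: %d; DE genes at q <= %.3g: %d\n",
              x$manifest$M, x$manifest$config$fdr, gc$n_de))
  if (!is.null(x$calls)) print(x$calls)
  invisible(x)
}

#' Write the pipeline outputs to a directory
#'
#' Writes `results.tsv`, `de_genes.txt`, optional `factors.tsv`,
#' `calls.tsv`, `subset_summary.tsv`, and `manifest.json` (the latter only
#' if the jsonlite package is available).
#'
#' @param x A `desyn_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_desyn_result <- function(x, dir) {
  stopifnot(inherits(x, "desyn_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x$results, file.path(dir, "results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(x$de_genes, file.path(dir, "de_genes.txt"))
  if (!is.null(x$factors))
    utils::write.table(x$factors, file.path(dir, "factors.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(x$calls)) {
    cl <- x$calls
    long <- data.frame(
      gene_id = rep(rownames(cl$calls), ncol(cl$calls)),
      replicate_id = rep(colnames(cl$calls), each = nrow(cl$calls)),
      call = as.vector(cl$calls),
      lo = rep(cl$lo, ncol(cl$calls)), hi = rep(cl$hi, ncol(cl$calls)),
      observed = as.vector(cl$observed))
    utils::write.table(long, file.path(dir, "calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sm <- share_summary(cl)
    utils::write.table(
      data.frame(subset = names(sm$subset_counts),
                 n_genes = as.integer(sm$subset_counts)),
      file.path(dir, "subset_summary.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Deterministic small test datasets
#'
#' Builds small count matrices with a truth ledger for tests and examples:
#' `"null"` is all-EE; `"planted"` adds 4 genes whose counts are shifted
#' about 16-fold in a random non-empty subset of disease replicates;
#' `"fig1-like"` plants 4 genes with fixed aberrant-replicate patterns
#' (`{3}`, `{1,2}`, `{3,4}`, all) emulating syndrome-style heterogeneity
#' where each disease replicate carries a different aberration.
#'
#' @param kind One of `"null"`, `"planted"`, `"fig1-like"`.
#' @param n_genes Total genes including planted ones.
#' @param seed Seed; each kind uses a disjoint stream at a given seed.
#' @param n_per_group Replicates per group.
#' @param dir Optional directory; if given, `counts.tsv`, `groups.tsv`, and
#'   `truth.tsv` are written there.
#' @return List with `counts` (raw [desyn_counts]) and `truth` (data frame:
#'   `gene_id`, `is_de`, `aberrant_set`).
#' @export
make_fixture <- function(kind = c("null", "planted", "fig1-like"),
                         n_genes = 500, seed = 1, n_per_group = 4,
                         dir = NULL) {
  kind <- match.arg(kind)
  n2 <- n_per_group
  out <- with_local_seed(seed + 7919L * match(kind, c("null", "planted", "fig1-like")), {
    mu <- 10^stats::runif(n_genes, 0.8, 2.8)
    phi <- stats::rgamma(n_genes, shape = 2, scale = 0.075)
    counts <- matrix(rnb(n_genes * (n_per_group + n2),
                         rep(mu, n_per_group + n2),
                         rep(phi, n_per_group + n2)),
                     n_genes, n_per_group + n2)
    truth <- data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)),
                        is_de = FALSE, aberrant_set = "")
    if (kind != "null") {
      planted <- seq_len(4L)
      sets <- if (kind == "fig1-like") {
        list(3L, c(1L, 2L), c(3L, 4L), seq_len(n2))
      } else {
        lapply(planted, function(i) sort(sample.int(n2, sample.int(min(4L, n2), 1))))
      }
      for (i in planted) {
        mu_i <- stats::runif(1, 20, 80)
        counts[i, seq_len(n_per_group)] <- rnb(n_per_group, mu_i, 0.05)
        dis <- rnb(n2, mu_i, 0.05)
        dis[sets[[i]]] <- rnb(length(sets[[i]]), 16 * mu_i, 0.05)
        counts[i, n_per_group + seq_len(n2)] <- dis
        truth$is_de[i] <- TRUE
        truth$aberrant_set[i] <- paste(sets[[i]], collapse = "+")
      }
    }
    rownames(counts) <- truth$gene_id
    colnames(counts) <- c(paste0("normal", seq_len(n_per_group)),
                          paste0("disease", seq_len(n2)))
    list(counts = desyn_counts(counts, rep(c(1L, 2L), c(n_per_group, n2))),
         truth = truth)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_counts(out$counts, file.path(dir, "counts.tsv"))
    utils::write.table(
      data.frame(sample_id = out$counts$sample_ids,
                 group = c("normal", "disease")[out$counts$group]),
      file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    utils::write.table(out$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
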