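#' Construct a two-group count matrix object
#'
#' Container for a genes x samples count matrix with a normal/disease group
#' assignment. Raw matrices must be integer-valued and non-negative;
#' normalized matrices may hold non-negative reals.
#'
#' @param counts Numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs).
#' @param group Per-sample group: integers 1 (normal) / 2 (disease), or the
#'   labels `"normal"` / `"disease"`.
#' @param normalized Logical; `FALSE` for raw integer counts.
#' @return An object of class `desyn_counts`: list with `counts`, `gene_ids`,
#'   `sample_ids`, `group`, `n1`, `n2`, `normalized`.
#' @export
desyn_counts <- function(counts, group, normalized = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  if (anyNA(counts)) stop("count matrix contains missing values", call. = FALSE)
  if (!is.numeric(counts) || any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (!normalized && any(abs(counts - round(counts)) > 1e-8))
    stop("raw counts must be integers", call. = FALSE)
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup))
    stop("duplicate gene IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  group <- normalize_group(group, ncol(counts))
  structure(
    list(counts = counts, gene_ids = rownames(counts),
         sample_ids = colnames(counts), group = group,
         n1 = sum(group == 1L), n2 = sum(group == 2L),
         normalized = normalized),
    class = "desyn_counts")
}

normalize_group <- function(group, n) {
  if (length(group) != n)
    stop("`group` must have one entry per sample", call. = FALSE)
  if (is.character(group) || is.factor(group)) {
    g <- match(tolower(as.character(group)), c("normal", "disease"))
    if (anyNA(g))
      stop("group labels must be 'normal' or 'disease' (or 1/2)", call. = FALSE)
    group <- g
  }
  group <- as.integer(group)
  if (!all(group %in% c(1L, 2L)))
    stop("group codes must be 1 (normal) or 2 (disease)", call. = FALSE)
  if (!any(group == 1L) || !any(group == 2L))
    stop("both groups must be non-empty", call. = FALSE)
  group
}

#' @export
print.desyn_counts <- function(x, ...) {
  cat(sprintf("desyn_counts: %d genes x %d samples (%d normal, %d disease), %s\n",
              nrow(x$counts), ncol(x$counts), x$n1, x$n2,
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Read a count matrix with group assignments
#'
#' Reads a delimited (TSV or CSV, chosen by file extension) genes x samples
#' table with a header row of sample IDs and gene IDs in the first column,
#' attaches the group assignment, and validates the result. Samples not
#' listed in `group_spec` are dropped; input gene order is preserved.
#'
#' @param path Path to the count file.
#' @param group_spec Named vector mapping sample ID to group (`"normal"` /
#'   `"disease"` or 1/2), or a two-column data frame `(sample_id, group)` as
#'   returned by [read_group_file()].
#' @return A [desyn_counts] object holding raw counts.
#' @export
read_counts <- function(path, group_spec) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(tab) < 2L) stop("count file needs a gene-ID column and at least one sample",
                           call. = FALSE)
  gene_ids <- tab[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene IDs in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (is.data.frame(group_spec)) {
    gs <- group_spec[[2L]]
    names(gs) <- group_spec[[1L]]
    group_spec <- gs
  }
  samples <- colnames(tab)[-1L]
  missing <- setdiff(names(group_spec), samples)
  if (length(missing))
    stop("samples in group_spec missing from header: ",
         paste(missing, collapse = ", "), call. = FALSE)
  keep <- samples[samples %in% names(group_spec)]
  mat <- matrix(NA_real_, nrow(tab), length(keep),
                dimnames = list(gene_ids, keep))
  for (s in keep) {
    v <- suppressWarnings(as.numeric(tab[[s]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad))
      stop(sprintf("non-numeric or negative count at gene '%s', sample '%s'",
                   gene_ids[bad[1L]], s), call. = FALSE)
    mat[, s] <- v
  }
  desyn_counts(mat, unname(group_spec[keep]))
}

#' Read a two-column sample/group file
#'
#' @param path TSV with columns `sample_id` and `group` (values `normal` or
#'   `disease`); a header row is detected automatically.
#' @return Data frame with columns `sample_id`, `group`.
#' @export
read_group_file <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) != 2L) stop("group file must have exactly two columns", call. = FALSE)
  if (tolower(tab[1, 2]) %in% c("group", "condition")) tab <- tab[-1, , drop = FALSE]
  data.frame(sample_id = tab[[1]], group = tolower(tab[[2]]))
}

#' Write a count matrix to TSV
#' @param cm A [desyn_counts] object or numeric matrix.
#' @param path Output path.
#' @export
write_counts <- function(cm, path) {
  m <- if (inherits(cm, "desyn_counts")) cm$counts else cm
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Discard genes with low total counts
#'
#' Keeps exactly the genes whose total count across all samples (both groups)
#' is strictly greater than `threshold`; genes with sum counts no greater
#' than the threshold are discarded before normalization and testing.
#'
#' @param cm A [desyn_counts] object holding raw counts.
#' @param threshold Total-count threshold (default 10).
#' @return A [desyn_counts] object with the retained genes in their original
#'   order; the discarded gene IDs are in the `discarded` element.
#' @export
filter_low_counts <- function(cm, threshold = 10) {
  stopifnot(inherits(cm, "desyn_counts"))
  if (cm$normalized) stop("filter applies to raw counts", call. = FALSE)
  sums <- rowSums(cm$counts)
  keep <- sums > threshold
  if (!any(keep))
    stop("zero genes remain after filtering at threshold ", threshold,
         call. = FALSE)
  out <- desyn_counts(cm$counts[keep, , drop = FALSE], cm$group)
  out$discarded <- cm$gene_ids[!keep]
  out
}

# Weighted trimmed-mean-of-M-values factor for one sample against the
# reference: genes zero in either column are excluded, M-values are trimmed
# by 30% each tail and A-values by 5% each tail, and the surviving M-values
# are averaged with inverse (delta-method) variance weights.
tmm_factor_pair <- function(obs, ref, lib_obs, lib_ref) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / lib_obs) / (ref / lib_ref))
  A <- 0.5 * log2((obs / lib_obs) * (ref / lib_ref))
  w <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  if (length(M) == 0L) return(1)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
  loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' TMM normalization
#'
#' Computes trimmed-mean-of-M-values scaling factors and the normalized
#' matrix. The reference sample is the one whose upper-quartile count (scaled
#' by library size) is closest to the mean upper quartile across samples.
#' Per-pair factors use the published TMM defaults: genes zero in either
#' column excluded, 30% two-sided trim on M-values, 5% on A-values, inverse-
#' variance weighting. Factors are centered to geometric mean 1 and the
#' normalized matrix is `counts[g, j] / (library_size[j] * factor[j]) * mean
#' library size`, keeping values on a count-like scale.
#'
#' @param cm A [desyn_counts] object holding raw counts.
#' @return List with `factors` (data frame `sample_id`, `library_size`,
#'   `tmm_factor`) and `normalized` (a [desyn_counts] with
#'   `normalized = TRUE`).
#' @export
tmm_normalize <- function(cm) {
  stopifnot(inherits(cm, "desyn_counts"))
  m <- cm$counts
  lib <- colSums(m)
  zero <- which(lib == 0)
  if (length(zero))
    stop("sample(s) with all-zero counts: ",
         paste(cm$sample_ids[zero], collapse = ", "), call. = FALSE)
  q75 <- apply(m, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(m)), function(j)
    tmm_factor_pair(m[, j], m[, ref], lib[j], lib[ref]), numeric(1))
  f <- f / exp(mean(log(f)))
  norm <- sweep(m, 2, lib * f, "/") * mean(lib)
  list(factors = data.frame(sample_id = cm$sample_ids, library_size = lib,
                            tmm_factor = f, row.names = NULL),
       normalized = desyn_counts(norm, cm$group, normalized = TRUE))
}
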