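# Decomposition: mean-centering, SVD/PCA, per-condition score trajectories,
# component diagnostics, and eigengene ranking.
#
# Analysis orientation is samples x genes, so eigengenes are right singular
# vectors: X = U S V' with V's columns holding per-gene loadings.

#' Mean-center an expression matrix across samples
#'
#' @param m a `log_expr` matrix (genes x samples) or plain numeric matrix with
#'   dimnames.
#' @return A `centered_expr` object: list with `matrix` (samples x genes,
#'   gene means removed), `gene_means`, `gene_ids`, `sample_ids`, and the
#'   normalization `pseudocount`/`provenance` carried over for projection
#'   checks.
#' @export
center_expression <- function(m) {
  x <- t(unclass(as.matrix(m)))   # samples x genes
  if (nrow(x) < 2)
    stop_ft("centering requires at least 2 samples")
  gene_means <- colMeans(x)
  centered <- sweep(x, 2, gene_means, "-")
  structure(list(matrix = centered,
                 gene_means = gene_means,
                 gene_ids = colnames(centered),
                 sample_ids = rownames(centered),
                 pseudocount = attr(m, "pseudocount"),
                 provenance = attr(m, "provenance")),
            class = "centered_expr")
}

#' Singular value decomposition of a centered expression matrix
#'
#' Computes `X = U S V'` on the samples x genes centered matrix and returns
#' loadings (V, genes x components), sample scores (`U S`), singular values
#' and variance fractions. The sign of each component is fixed
#' deterministically: the loading of largest absolute value is made positive
#' (first index wins exact ties), so repeated runs and sample permutations
#' yield identical orientations.
#'
#' @param centered a `centered_expr` from [center_expression()].
#' @return A `pca_decomp` object with fields `gene_ids`, `sample_ids`,
#'   `gene_means`, `loadings`, `scores`, `singular_values`,
#'   `variance_fraction`, `sign_convention`, `pseudocount`, `provenance`.
#' @export
svd_pca <- function(centered) {
  if (!inherits(centered, "centered_expr"))
    stop_ft("svd_pca expects the output of center_expression()")
  x <- centered$matrix
  if (any(!is.finite(x))) stop_ft("centered matrix contains non-finite values")
  k <- min(dim(x))
  sv <- svd(x, nu = k, nv = k)
  # deterministic sign: largest-|loading| entry of each component positive
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    v[which.max(abs(v))] < 0
  }, logical(1))
  sgn <- ifelse(flip, -1, 1)
  v <- sweep(sv$v, 2, sgn, "*")
  u <- sweep(sv$u, 2, sgn, "*")
  scores <- sweep(u, 2, sv$d, "*")
  dimnames(v) <- list(centered$gene_ids, paste0("PC", seq_len(k)))
  dimnames(scores) <- list(centered$sample_ids, paste0("PC", seq_len(k)))
  structure(list(gene_ids = centered$gene_ids,
                 sample_ids = centered$sample_ids,
                 gene_means = centered$gene_means,
                 loadings = v,
                 scores = scores,
                 singular_values = sv$d,
                 variance_fraction = sv$d^2 / sum(sv$d^2),
                 sign_convention = "largest-|loading| positive per component",
                 pseudocount = centered$pseudocount,
                 provenance = centered$provenance),
            class = "pca_decomp")
}

#' Fit the trajectory PCA in one call
#'
#' Convenience wrapper: [center_expression()] then [svd_pca()].
#'
#' @param m a `log_expr` matrix.
#' @return A `pca_decomp`.
#' @export
fit_trajectory_pca <- function(m) svd_pca(center_expression(m))

#' @export
print.pca_decomp <- function(x, ...) {
  cat("PCA decomposition:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples,", ncol(x$loadings), "components\n")
  vf <- utils::head(round(100 * x$variance_fraction, 1), 5)
  cat("variance explained (%):", paste(vf, collapse = ", "), "...\n")
  invisible(x)
}

# Match design rows to decomposition samples, erroring on gaps.
align_design <- function(d, design) {
  idx <- match(d$sample_ids, design$sample_id)
  if (anyNA(idx))
    stop_ft("sample(s) missing from design: ",
            paste(d$sample_ids[is.na(idx)], collapse = ", "))
  design[idx, , drop = FALSE]
}

#' Component score trajectories over time
#'
#' Builds one (condition, replicate) score-vs-time curve per replicate series
#' and per-condition mean curves across replicates.
#'
#' @param d a `pca_decomp`.
#' @param design a `sample_design` covering all samples of `d`.
#' @param component 1-based component index.
#' @return A `trajectory_set`: list with `component`, `curves` (data.frame
#'   `condition`, `replicate`, `time_h`, `score`, `sample_id`, times strictly
#'   increasing within a curve) and `condition_means` (data.frame `condition`,
#'   `time_h`, `mean_score`, `n`).
#' @export
trajectory_curves <- function(d, design, component) {
  stopifnot(length(component) == 1, component >= 1,
            component <= ncol(d$scores))
  des <- align_design(d, design)
  curves <- data.frame(condition = des$condition,
                       replicate = des$replicate,
                       time_h = des$time_h,
                       score = d$scores[, component],
                       sample_id = des$sample_id,
                       stringsAsFactors = FALSE, row.names = NULL)
  curves <- curves[order_radix(curves$condition, curves$replicate,
                               curves$time_h), , drop = FALSE]
  dup <- duplicated(curves[c("condition", "replicate", "time_h")])
  if (any(dup))
    stop_ft("duplicate (condition, replicate, time) sample(s): ",
            paste(curves$sample_id[dup], collapse = ", "))
  agg <- stats::aggregate(score ~ condition + time_h, data = curves,
                          FUN = mean)
  n <- stats::aggregate(score ~ condition + time_h, data = curves,
                        FUN = length)
  cm <- data.frame(condition = agg$condition, time_h = agg$time_h,
                   mean_score = agg$score, n = n$score,
                   stringsAsFactors = FALSE)
  cm <- cm[order_radix(cm$condition, cm$time_h), , drop = FALSE]
  rownames(curves) <- rownames(cm) <- NULL
  structure(list(component = component, curves = curves,
                 condition_means = cm),
            class = "trajectory_set")
}

#' Per-component diagnostics against a two-condition design
#'
#' For every component, computes the variance fraction, the Spearman
#' correlation of scores with time pooled over the two conditions, a
#' between-condition divergence score, and an excess-kurtosis spike score.
#'
#' The divergence score of component k is the mean over timepoints of
#' `|mean_A(t) - mean_B(t)| / s_k`, where `s_k` is the pooled
#' within-(condition, time) standard deviation of the scores (n-1 denominator
#' across replicates). If `s_k` is 0 the score is 0 when the numerator is 0
#' and `Inf` otherwise.
#'
#' @param d a `pca_decomp`.
#' @param design a `sample_design`.
#' @param conditions exactly two condition labels to contrast.
#' @return A `component_diag` data.frame: `component`, `variance_fraction`,
#'   `time_correlation`, `divergence_score`, `spike_score`.
#' @export
component_diagnostics <- function(d, design, conditions) {
  if (length(conditions) != 2 || anyDuplicated(conditions))
    stop_ft("exactly two distinct condition labels are required")
  des <- align_design(d, design)
  use <- des$condition %in% conditions
  if (!all(conditions %in% des$condition))
    stop_ft("condition(s) absent from design: ",
            paste(setdiff(conditions, des$condition), collapse = ", "))
  des <- des[use, , drop = FALSE]
  scores <- d$scores[use, , drop = FALSE]
  a <- des$condition == conditions[1]
  times <- sort(unique(des$time_h))
  common <- times[vapply(times, function(t)
    any(a & des$time_h == t) && any(!a & des$time_h == t), logical(1))]
  k <- ncol(scores)
  out <- data.frame(component = seq_len(k),
                    variance_fraction = d$variance_fraction[seq_len(k)],
                    time_correlation = NA_real_,
                    divergence_score = NA_real_,
                    spike_score = NA_real_)
  cell <- interaction(des$condition, des$time_h, drop = TRUE)
  for (j in seq_len(k)) {
    s <- scores[, j]
    out$time_correlation[j] <-
      suppressWarnings(stats::cor(s, des$time_h, method = "spearman"))
    # pooled within-(condition, time) SD
    ss <- 0; df <- 0
    for (g in levels(cell)) {
      v <- s[cell == g]
      if (length(v) >= 2) {
        ss <- ss + sum((v - mean(v))^2)
        df <- df + length(v) - 1
      }
    }
    s_k <- if (df > 0) sqrt(ss / df) else 0
    gaps <- vapply(common, function(t)
      abs(mean(s[a & des$time_h == t]) - mean(s[!a & des$time_h == t])),
      numeric(1))
    num <- mean(gaps)
    out$divergence_score[j] <- if (s_k > 0) num / s_k
      else if (num == 0) 0 else Inf
    m <- mean(s); v2 <- mean((s - m)^2)
    out$spike_score[j] <- if (v2 > 0) mean((s - m)^4) / v2^2 - 3 else 0
  }
  # a constant score vector has no rank correlation; report 0
  out$time_correlation[is.na(out$time_correlation)] <- 0
  class(out) <- c("component_diag", "data.frame")
  out
}

#' Select the divergence-carrying component
#'
#' Returns the component with the highest divergence score among those whose
#' absolute time correlation does not exceed `max_time_corr` (the gate removes
#' the time-drift axis). Exact ties go to the smaller index.
#'
#' @param diag a `component_diag` from [component_diagnostics()].
#' @param max_time_corr gate on `|time_correlation|` (default 0.8).
#' @return 1-based component index.
#' @export
select_divergent_component <- function(diag, max_time_corr = 0.8) {
  pass <- abs(diag$time_correlation) <= max_time_corr
  if (!any(pass))
    stop_ft("no component passes the time-correlation gate ",
            "(|rho| <= ", max_time_corr, "); consider raising max_time_corr")
  cand <- diag[pass, , drop = FALSE]
  cand$component[which.max(cand$divergence_score)]
}

#' Rank eigengenes by absolute loading
#'
#' Genes are ordered by decreasing absolute loading on the chosen component;
#' exact ties are broken by gene id (ascending, C locale).
#'
#' @param d a `pca_decomp`.
#' @param component 1-based component index.
#' @return An `eigengene_ranking` data.frame: `rank`, `gene_id`, `component`,
#'   `loading`, `abs_loading`.
#' @export
rank_eigengenes <- function(d, component) {
  stopifnot(length(component) == 1, component >= 1,
            component <= ncol(d$loadings))
  loading <- d$loadings[, component]
  ord <- order_radix(-abs(loading), names(loading))
  out <- data.frame(rank = seq_along(ord),
                    gene_id = names(loading)[ord],
                    component = component,
                    loading = unname(loading[ord]),
                    abs_loading = unname(abs(loading[ord])),
                    stringsAsFactors = FALSE)
  class(out) <- c("eigengene_ranking", "data.frame")
  out
}

#' Write an eigengene or MI ranking as TSV
#'
#' @param ranking a ranking data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
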