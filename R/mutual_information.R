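# Nearest-neighbour mutual information between a continuous variable and a
# discrete label (Ross-style estimator for mixed data), and gene ranking by it.

#' Mutual information between a continuous variable and a discrete label
#'
#' Nearest-neighbour estimator for mixed discrete/continuous data. For each
#' point i with label l_i, let d_i be the distance to its k-th nearest
#' neighbour among points sharing l_i, and m_i the number of points of any
#' label (point i included) lying strictly within d_i. The estimate is
#'
#'   MI = psi(n) - <psi(n_l)> + psi(k) - <psi(m)>     (psi = digamma),
#'
#' clamped at 0. Exact ties in the values (common in log2 CPM data, e.g.
#' zeros) are broken by a deterministic jitter of magnitude 1e-10 of the value
#' range, drawn under `jitter_seed` without touching the global RNG stream.
#'
#' @param values numeric vector.
#' @param labels vector of discrete labels, same length.
#' @param k neighbour count (default 3); every label class must contain more
#'   than `k` points.
#' @param jitter_seed seed of the tie-breaking jitter (default 0).
#' @param units `"nats"` (default) or `"bits"`.
#' @return Non-negative scalar MI estimate.
#' @export
mi_mixed <- function(values, labels, k = 3, jitter_seed = 0L,
                     units = c("nats", "bits")) {
  units <- match.arg(units)
  stopifnot(length(values) == length(labels), k >= 1)
  if (any(!is.finite(values))) stop_ft("values must be finite")
  n <- length(values)
  labels <- as.character(labels)
  cls <- table(labels)
  small <- names(cls)[cls < k + 1]
  if (length(small) > 0)
    stop_ft("label class(es) smaller than k + 1 = ", k + 1, ": ",
            paste(small, collapse = ", "))
  rng <- diff(range(values))
  if (rng == 0) return(0)   # constant values carry no information
  x <- values + with_seed(jitter_seed, stats::runif(n, -1, 1)) * 1e-10 * rng
  # 1-D distances; n is at most a few thousand here, dense is fine
  D <- abs(outer(x, x, "-"))
  diag(D) <- Inf
  d_k <- numeric(n)
  for (l in names(cls)) {
    idx <- which(labels == l)
    sub <- D[idx, idx, drop = FALSE]
    d_k[idx] <- apply(sub, 1, function(r) sort.int(r, partial = k)[k])
  }
  # m_i: points (self included) strictly inside the same-label k-NN radius
  m <- rowSums(D < d_k) + 1
  n_l <- as.numeric(cls[labels])
  mi <- digamma(n) - mean(digamma(n_l)) + digamma(k) - mean(digamma(m))
  mi <- max(0, mi)
  if (units == "bits") mi / log(2) else mi
}

#' Rank genes by mutual information with a condition label
#'
#' Computes [mi_mixed()] for every gene over the samples belonging to the
#' designated conditions and ranks genes by decreasing MI, ties broken by gene
#' id (ascending).
#'
#' @param m a `log_expr` matrix (genes x samples).
#' @param design a `sample_design`.
#' @param conditions condition labels defining the discrete variable (samples
#'   of other conditions are excluded).
#' @param k neighbour count (default 3).
#' @param times optional numeric vector restricting to specific timepoints
#'   (default: all samples of the chosen conditions).
#' @param jitter_seed seed for the tie-breaking jitter (default 0).
#' @return An `mi_ranking` data.frame: `rank`, `gene_id`, `mi_nats`,
#'   `n_samples`, `k_neighbors`.
#' @export
rank_by_mi <- function(m, design, conditions, k = 3, times = NULL,
                       jitter_seed = 0L) {
  idx <- match(colnames(m), design$sample_id)
  if (anyNA(idx))
    stop_ft("sample(s) missing from design: ",
            paste(colnames(m)[is.na(idx)], collapse = ", "))
  des <- design[idx, , drop = FALSE]
  use <- des$condition %in% conditions
  if (!is.null(times)) use <- use & des$time_h %in% times
  if (sum(use) == 0) stop_ft("no samples match the requested conditions/times")
  vals <- unclass(m)[, use, drop = FALSE]
  labs <- des$condition[use]
  mi <- vapply(seq_len(nrow(vals)), function(i)
    mi_mixed(vals[i, ], labs, k = k,
             jitter_seed = child_seed(jitter_seed, i)),
    numeric(1))
  ord <- order_radix(-mi, rownames(vals))
  out <- data.frame(rank = seq_along(ord),
                    gene_id = rownames(vals)[ord],
                    mi_nats = mi[ord],
                    n_samples = sum(use),
                    k_neighbors = k,
                    stringsAsFactors = FALSE)
  class(out) <- c("mi_ranking", "data.frame")
  out
}
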