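# Projection of external expression data into a fitted component space, and
# placement of projected samples relative to the two condition trajectories.

#' Project external expression data into a fitted component space
#'
#' External samples are aligned to the decomposition's gene order, centered by
#' the *training* gene means (never the external matrix's own means), and
#' multiplied by the stored loadings: `scores = (X' - mean) V`. Genes absent
#' from the external matrix contribute the centered value 0, i.e. they are
#' assumed at the training mean; the fraction of training genes found is
#' reported as `gene_coverage`.
#'
#' @param d a `pca_decomp`.
#' @param external a `log_expr` matrix normalized with the same pseudocount as
#'   the training data (checked through provenance unless
#'   `check_provenance = FALSE`).
#' @param min_coverage hard floor on `gene_coverage` (default 0.8).
#' @param check_provenance compare normalization provenance (default TRUE).
#' @return A `projection_result`: list with `sample_ids`, `scores` (samples x
#'   components), `gene_coverage`, and `placement` (NULL until
#'   [place_on_trajectory()] fills it).
#' @export
project_expression <- function(d, external, min_coverage = 0.8,
                               check_provenance = TRUE) {
  if (check_provenance && !is.null(d$pseudocount)) {
    pc_ext <- attr(external, "pseudocount")
    if (is.null(pc_ext) || !isTRUE(all.equal(pc_ext, d$pseudocount)))
      stop_ft("normalization provenance mismatch: training pseudocount ",
              d$pseudocount, ", external ",
              if (is.null(pc_ext)) "unknown" else pc_ext)
  }
  ext <- unclass(as.matrix(external))       # genes x samples
  shared <- intersect(d$gene_ids, rownames(ext))
  coverage <- length(shared) / length(d$gene_ids)
  if (coverage < min_coverage)
    stop_ft(sprintf(
      "gene coverage %.3f below the required %.3f (%d of %d training genes)",
      coverage, min_coverage, length(shared), length(d$gene_ids)))
  n_ext <- ncol(ext)
  centered <- matrix(0, nrow = n_ext, ncol = length(d$gene_ids),
                     dimnames = list(colnames(ext), d$gene_ids))
  centered[, shared] <- t(ext[shared, , drop = FALSE]) -
    rep(d$gene_means[shared], each = n_ext)
  scores <- centered %*% d$loadings
  structure(list(sample_ids = colnames(ext),
                 scores = scores,
                 gene_coverage = coverage,
                 placement = NULL),
            class = "projection_result")
}

#' Place projected samples relative to two condition trajectories
#'
#' Each projected sample is compared, on the trajectory component, with the
#' final-timepoint mean score of each condition (the trajectory termini). The
#' signed proximity is `(d_B - d_A) / (d_A + d_B)`, so +1 means the sample
#' sits exactly at condition A's terminus and -1 at condition B's; the label
#' is the nearer condition, or `"equidistant"` on an exact tie (including the
#' degenerate case of coincident termini).
#'
#' @param p a `projection_result`.
#' @param t a `trajectory_set` built from the same decomposition and the
#'   component of interest.
#' @param conditions length-2 character vector naming conditions A and B;
#'   defaults to their order of appearance in `t`.
#' @return `p` with `placement` filled: data.frame `sample_id`, `score`,
#'   `proximity`, `label`, plus the component index and termini as attributes.
#' @export
place_on_trajectory <- function(p, t, conditions = NULL) {
  cm <- t$condition_means
  if (is.null(conditions)) conditions <- unique(cm$condition)
  if (length(conditions) != 2)
    stop_ft("exactly two conditions are required for placement")
  if (!all(conditions %in% cm$condition))
    stop_ft("condition(s) absent from trajectory: ",
            paste(setdiff(conditions, cm$condition), collapse = ", "))
  t_end <- max(cm$time_h)
  term <- vapply(conditions, function(cc) {
    v <- cm$mean_score[cm$condition == cc & cm$time_h == t_end]
    if (length(v) != 1)
      stop_ft("condition ", cc, " has no unique final-timepoint mean")
    v
  }, numeric(1))
  s <- p$scores[, t$component]
  d_a <- abs(s - term[1])
  d_b <- abs(s - term[2])
  tot <- d_a + d_b
  proximity <- ifelse(tot == 0, 0, (d_b - d_a) / tot)
  label <- ifelse(d_a < d_b, conditions[1],
                  ifelse(d_b < d_a, conditions[2], "equidistant"))
  placement <- data.frame(sample_id = p$sample_ids,
                          score = unname(s),
                          proximity = unname(proximity),
                          label = unname(label),
                          stringsAsFactors = FALSE)
  attr(placement, "component") <- t$component
  attr(placement, "termini") <- term
  p$placement <- placement
  p
}
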