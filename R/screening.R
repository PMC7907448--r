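# Screening: contrast log2 fold changes, the sign-concordance candidate
# screen, and gene-pair co-expression correlation.

#' Per-gene contrast log2 fold change
#'
#' The fold change is the difference of mean log2 expression between two
#' sample groups (values are already on the log2 scale). For time courses the
#' `timepoint_policy` selects which samples enter: `"endpoint"` (default) uses
#' only samples at the latest shared timepoint, `"all"` pools every sample,
#' and `"per-timepoint"` returns one fold change per timepoint.
#'
#' @param m a `log_expr` matrix.
#' @param design a `sample_design`.
#' @param group_a,group_b condition labels (numerator and reference).
#' @param timepoint_policy `"endpoint"`, `"all"` or `"per-timepoint"`.
#' @return A `contrast_fc` data.frame: `gene_id`, `log2fc`, `n_a`, `n_b`
#'   (plus `time_h` under `"per-timepoint"`), with a `label` attribute
#'   `"A/B"`.
#' @export
contrast_log2fc <- function(m, design, group_a, group_b,
                            timepoint_policy = c("endpoint", "all",
                                                 "per-timepoint")) {
  timepoint_policy <- match.arg(timepoint_policy)
  idx <- match(colnames(m), design$sample_id)
  if (anyNA(idx))
    stop_ft("sample(s) missing from design: ",
            paste(colnames(m)[is.na(idx)], collapse = ", "))
  des <- design[idx, , drop = FALSE]
  in_a <- des$condition == group_a
  in_b <- des$condition == group_b
  if (!any(in_a)) stop_ft("group '", group_a, "' is empty")
  if (!any(in_b)) stop_ft("group '", group_b, "' is empty")
  vals <- unclass(m)
  fc_at <- function(sel_a, sel_b) {
    rowMeans(vals[, sel_a, drop = FALSE]) -
      rowMeans(vals[, sel_b, drop = FALSE])
  }
  label <- paste0(group_a, "/", group_b)
  if (timepoint_policy == "per-timepoint") {
    times <- sort(intersect(des$time_h[in_a], des$time_h[in_b]))
    if (length(times) == 0) stop_ft("groups share no timepoint")
    out <- do.call(rbind, lapply(times, function(t) {
      sa <- in_a & des$time_h == t
      sb <- in_b & des$time_h == t
      data.frame(gene_id = rownames(vals), time_h = t,
                 log2fc = unname(fc_at(sa, sb)),
                 n_a = sum(sa), n_b = sum(sb), stringsAsFactors = FALSE)
    }))
  } else {
    if (timepoint_policy == "endpoint") {
      t_end <- max(intersect(des$time_h[in_a], des$time_h[in_b]))
      in_a <- in_a & des$time_h == t_end
      in_b <- in_b & des$time_h == t_end
    }
    out <- data.frame(gene_id = rownames(vals),
                      log2fc = unname(fc_at(in_a, in_b)),
                      n_a = sum(in_a), n_b = sum(in_b),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "label") <- label
  class(out) <- c("contrast_fc", "data.frame")
  out
}

# Pull a named gene -> log2fc vector out of a contrast_fc.
fc_vector <- function(fc) stats::setNames(fc$log2fc, fc$gene_id)

#' Sign-concordance screen for candidate regulators
#'
#' Applies the cross-stimulus screen to the `top_n` genes of an eigengene
#' ranking: a candidate must change in the same direction under the
#' shear contrast and the protective-stimulus contrast
#' (`sign(fc_ps_os) == sign(fc_atv)`) and in the opposite direction under the
#' inflammatory contrast (`sign(fc_ps_os) == -sign(fc_tnfa)`). Sign tests are
#' strict: a zero fold change fails. An optional magnitude floor
#' `min_abs_fc` additionally requires `|fc| >= min_abs_fc` in all three
#' contrasts.
#'
#' @param ranking an `eigengene_ranking`.
#' @param fc_ps_os,fc_atv,fc_tnfa `contrast_fc` tables (or named numeric
#'   vectors) for the shear, protective and inflammatory contrasts.
#' @param top_n number of top-ranked genes screened (default 50).
#' @param min_abs_fc magnitude floor applied to all three contrasts
#'   (default 0, i.e. sign-only).
#' @return A `candidate_table` data.frame over the screened genes, ordered by
#'   eigengene rank: `gene_id`, `eigengene_rank`, `fc_ps_os`, `fc_atv`,
#'   `fc_tnfa`, `concordant_atv`, `discordant_tnfa`, `pass`.
#' @export
concordance_screen <- function(ranking, fc_ps_os, fc_atv, fc_tnfa,
                               top_n = 50, min_abs_fc = 0) {
  for (nm in c("fc_ps_os", "fc_atv", "fc_tnfa")) {
    v <- get(nm)
    if (is.null(v)) stop_ft("missing contrast: ", nm)
  }
  as_vec <- function(fc) if (is.data.frame(fc)) fc_vector(fc) else fc
  v_ps <- as_vec(fc_ps_os); v_atv <- as_vec(fc_atv); v_tnfa <- as_vec(fc_tnfa)
  top <- utils::head(as.data.frame(ranking), top_n)
  genes <- top$gene_id
  miss <- genes[!(genes %in% names(v_ps) & genes %in% names(v_atv) &
                    genes %in% names(v_tnfa))]
  if (length(miss) > 0)
    stop_ft("gene(s) absent from a contrast table: ",
            paste(utils::head(miss, 5), collapse = ", "))
  f1 <- unname(v_ps[genes]); f2 <- unname(v_atv[genes]); f3 <- unname(v_tnfa[genes])
  big <- abs(f1) >= min_abs_fc & abs(f2) >= min_abs_fc & abs(f3) >= min_abs_fc
  concordant_atv <- ((f1 > 0 & f2 > 0) | (f1 < 0 & f2 < 0)) & big
  discordant_tnfa <- ((f1 > 0 & f3 < 0) | (f1 < 0 & f3 > 0)) & big
  out <- data.frame(gene_id = genes,
                    eigengene_rank = top$rank,
                    fc_ps_os = f1, fc_atv = f2, fc_tnfa = f3,
                    concordant_atv = concordant_atv,
                    discordant_tnfa = discordant_tnfa,
                    pass = concordant_atv & discordant_tnfa,
                    stringsAsFactors = FALSE)
  out <- out[order(out$eigengene_rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Candidates passing the screen
#'
#' @param ct a `candidate_table`.
#' @return The passing subset, ordered by eigengene rank.
#' @export
candidates <- function(ct) {
  out <- ct[ct$pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Co-expression correlation of a gene pair
#'
#' Correlates two genes' expression across paired samples, pooling several
#' matrices if a list is given (each contributes its samples).
#'
#' @param m a `log_expr` matrix, a plain matrix, or a list of such.
#' @param gene_a,gene_b gene ids present in every matrix.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `estimate`, `p_value`, `n`, `method`.
#' @export
coexpression_correlation <- function(m, gene_a, gene_b,
                                     method = c("spearman", "pearson")) {
  method <- match.arg(method)
  mats <- if (is.list(m) && !is.data.frame(m)) m else list(m)
  pull <- function(mm, g) {
    mm <- unclass(as.matrix(mm))
    if (!g %in% rownames(mm)) stop_ft("gene not found: ", g)
    mm[g, ]
  }
  x <- unlist(lapply(mats, pull, g = gene_a), use.names = FALSE)
  y <- unlist(lapply(mats, pull, g = gene_b), use.names = FALSE)
  if (length(x) < 3) stop_ft("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_ft("correlation undefined for a constant expression vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = length(x), method = method)
}
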