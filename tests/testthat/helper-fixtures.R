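# Shared fixtures: everything is built in code at test time.

# A 3-gene x 2-sample toy count matrix.
toy_counts <- function() {
  counts_matrix(matrix(c(10, 0, 1, 0, 5, 1), nrow = 3,
                       dimnames = list(c("G1", "G2", "G3"), c("S1", "S2"))))
}

# Small simulation config so property loops stay fast; same structure as the
# default study-sized configuration.
small_config <- function(n_genes = 400, n_time_drift = 30, n_mito_spike = 15,
                         n_divergent = 20, ...) {
  sim_config(n_genes = n_genes, n_time_drift = n_time_drift,
             n_mito_spike = n_mito_spike, n_divergent = n_divergent, ...)
}

# A log_expr built directly from a value matrix (pseudocount 1).
toy_log_expr <- function(values) {
  log_expr(values, pseudocount = 1)
}

# Identify the component that actually carries the planted divergent program:
# the one on which the planted genes hold the largest share of loading energy.
truth_component <- function(d, truth) {
  planted <- truth$genes$gene_id[truth$genes$program == "divergent"]
  energy <- colSums(d$loadings[rownames(d$loadings) %in% planted, ,
                               drop = FALSE]^2)
  unname(which.max(energy))
}

# Run normalization + filtering + PCA on a simulated time course.
fit_sim <- function(sim) {
  fit_trajectory_pca(filter_low_expression(cpm_log2(sim$counts)))
}

# Placement table of the treated samples of a stimulus dataset.
place_treated <- function(d, tr, stim) {
  p <- place_on_trajectory(project_expression(d, cpm_log2(stim$counts)),
                           tr, conditions = c("PS", "OS"))
  p$placement[grepl("_trt_", p$placement$sample_id), , drop = FALSE]
}
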