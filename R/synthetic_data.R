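# Synthetic data: negative-binomial time-course and stimulus datasets with
# planted expression programs and full ground truth.
#
# The generator emulates the structure the trajectory analysis assumes: a
# 2-condition x 10-timepoint x 2-replicate count matrix containing (a) a
# shared monotone time-drift program, (b) a program spiking at a sparse set
# of timepoints in both conditions (mitochondrial-like), (c) a program whose
# between-condition separation grows linearly with time, and (d) background
# negative-binomial noise; plus small single-timepoint stimulus datasets
# whose effects on the divergent program are signed concordantly.

#' Simulation configuration
#'
#' @param n_genes total genes (default 5000).
#' @param n_time_drift,n_mito_spike,n_divergent planted program sizes
#'   (defaults 200, 100, 100).
#' @param timepoints hours sampled (default 0, 1, 2, 3, 4, 6, 9, 12, 16, 24).
#' @param replicates biological replicates per condition x time (default 2).
#' @param conditions two condition labels (default `c("PS", "OS")`).
#' @param lib_size,lib_sdlog library sizes are log-normal with this median and
#'   sdlog (defaults 1e7 and 0.2), so CPM normalization is exercised
#'   non-trivially.
#' @param baseline_median,baseline_sdlog per-gene baseline means are
#'   log-normal (defaults 200 and 1.5).
#' @param dispersion_range gene-wise NB dispersion, uniform (default
#'   0.05-0.3).
#' @param drift_range log2 amplitude of the time-drift program at the final
#'   timepoint, uniform (default 1-2), random sign per gene.
#' @param spike_amp_range log2 spike amplitude, uniform (default 2-4).
#' @param n_spike_times number of spiking timepoints, shared across the
#'   program (default 2).
#' @param divergent_range log2 half-separation of the divergent program at
#'   the final timepoint, uniform (default 1-2), random sign per gene.
#' @param pcg_fraction fraction of genes labelled protein_coding; the rest
#'   split 2:1 between lincRNA and antisense so every program spans coding
#'   and non-coding biotypes (default 0.7).
#' @param stimulus_reps treated and control replicates per stimulus dataset
#'   (default 3).
#' @param stimulus_shift_scale multiplier on the divergent effect applied by
#'   atv-like / tnfa-like stimuli (default 1).
#' @param background_perturb_frac,background_perturb_range fraction of
#'   background genes randomly shifted in any stimulus dataset and the log2
#'   magnitude range of that shift (defaults 0.05 and 0.5-1.5).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000,
                       n_time_drift = 200,
                       n_mito_spike = 100,
                       n_divergent = 100,
                       timepoints = c(0, 1, 2, 3, 4, 6, 9, 12, 16, 24),
                       replicates = 2,
                       conditions = c("PS", "OS"),
                       lib_size = 1e7,
                       lib_sdlog = 0.2,
                       baseline_median = 200,
                       baseline_sdlog = 1.5,
                       dispersion_range = c(0.05, 0.3),
                       drift_range = c(1, 2),
                       spike_amp_range = c(2, 4),
                       n_spike_times = 2,
                       divergent_range = c(1, 2),
                       pcg_fraction = 0.7,
                       stimulus_reps = 3,
                       stimulus_shift_scale = 1,
                       background_perturb_frac = 0.05,
                       background_perturb_range = c(0.5, 1.5)) {
  cfg <- as.list(environment())
  if (n_time_drift + n_mito_spike + n_divergent > n_genes)
    stop_ft("planted program sizes exceed n_genes")
  if (length(conditions) != 2) stop_ft("exactly two conditions are required")
  if (n_spike_times >= length(timepoints))
    stop_ft("n_spike_times must be smaller than the number of timepoints")
  class(cfg) <- "sim_config"
  cfg
}

# Draw gene-level parameters and program assignments.
sim_gene_params <- function(cfg, seed) {
  with_seed(seed, {
    n <- cfg$n_genes
    program <- rep("background", n)
    planted <- sample.int(n, cfg$n_time_drift + cfg$n_mito_spike +
                            cfg$n_divergent)
    program[planted[seq_len(cfg$n_time_drift)]] <- "time_drift"
    program[planted[cfg$n_time_drift + seq_len(cfg$n_mito_spike)]] <- "mito_spike"
    program[planted[cfg$n_time_drift + cfg$n_mito_spike +
                      seq_len(cfg$n_divergent)]] <- "divergent"
    effect <- numeric(n)
    direction <- integer(n)
    effect[program == "time_drift"] <-
      stats::runif(cfg$n_time_drift, cfg$drift_range[1], cfg$drift_range[2])
    effect[program == "mito_spike"] <-
      stats::runif(cfg$n_mito_spike, cfg$spike_amp_range[1],
                   cfg$spike_amp_range[2])
    effect[program == "divergent"] <-
      stats::runif(cfg$n_divergent, cfg$divergent_range[1],
                   cfg$divergent_range[2])
    direction[program %in% c("time_drift", "divergent")] <-
      sample(c(-1L, 1L), sum(program %in% c("time_drift", "divergent")),
             replace = TRUE)
    direction[program == "mito_spike"] <- 1L
    spike_times <- sort(sample(cfg$timepoints[-1], cfg$n_spike_times))
    n_ncg <- n - round(cfg$pcg_fraction * n)
    biotype <- rep("protein_coding", n)
    ncg_idx <- sample.int(n, n_ncg)
    biotype[ncg_idx] <- rep_len(c("lincRNA", "lincRNA", "antisense"),
                                n_ncg)
    data_frame <- data.frame(
      gene_id = sprintf("G%05d", seq_len(n)),
      program = program,
      baseline = stats::rlnorm(n, log(cfg$baseline_median),
                               cfg$baseline_sdlog),
      dispersion = stats::runif(n, cfg$dispersion_range[1],
                                cfg$dispersion_range[2]),
      effect = effect,
      direction = direction,
      biotype = biotype,
      stringsAsFactors = FALSE)
    list(genes = data_frame, spike_times = spike_times)
  })
}

# Log2 signal of every gene in one (condition, time) cell of the time course.
timecourse_signal <- function(genes, spike_times, condition, conditions,
                              time_h, t_max) {
  sig <- numeric(nrow(genes))
  td <- genes$program == "time_drift"
  sig[td] <- genes$direction[td] * genes$effect[td] * time_h / t_max
  ms <- genes$program == "mito_spike"
  if (time_h %in% spike_times) sig[ms] <- genes$effect[ms]
  dv <- genes$program == "divergent"
  cond_sign <- if (condition == conditions[1]) 1 else -1
  sig[dv] <- cond_sign * genes$direction[dv] * genes$effect[dv] * time_h / t_max
  sig
}

# NB draw of one sample column given per-gene means.
draw_counts <- function(mu, dispersion) {
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate the two-condition shear time course
#'
#' Counts are negative-binomial with mean
#' `mu_g(condition, t) = lib_factor * baseline_g * 2^signal_g(condition, t)`;
#' see [sim_config()] for the planted signal programs. Identical
#' (config, seed) pairs reproduce the output exactly.
#'
#' @param config a [sim_config()].
#' @param seed master seed; per-stage child seeds are derived
#'   deterministically and recorded in the truth object.
#' @return A `sim_timecourse` list: `counts` ([counts_matrix()]), `design`
#'   ([sample_design()]), `biotypes` ([biotype_map()]), `truth`
#'   (a `sim_truth`: seed, config, per-gene program table, spike times,
#'   child seeds).
#' @export
simulate_timecourse <- function(config = sim_config(), seed = 1L) {
  cfg <- config
  seeds <- c(params = child_seed(seed, 1), counts = child_seed(seed, 2))
  gp <- sim_gene_params(cfg, seeds[["params"]])
  genes <- gp$genes
  t_max <- max(cfg$timepoints)
  grid <- expand.grid(replicate = paste0("r", seq_len(cfg$replicates)),
                      time_h = cfg$timepoints,
                      condition = cfg$conditions,
                      stringsAsFactors = FALSE)
  grid <- grid[order_radix(grid$condition, grid$time_h, grid$replicate), ,
               drop = FALSE]
  sample_id <- sprintf("%s_t%g_%s", grid$condition, grid$time_h,
                       grid$replicate)
  design <- sample_design(data.frame(sample_id = sample_id,
                                     condition = grid$condition,
                                     time_h = grid$time_h,
                                     replicate = grid$replicate,
                                     dataset = "timecourse",
                                     stringsAsFactors = FALSE))
  scale <- sum(genes$baseline)
  counts <- with_seed(seeds[["counts"]], {
    lib <- stats::rlnorm(nrow(design), log(cfg$lib_size), cfg$lib_sdlog)
    m <- matrix(0L, nrow = nrow(genes), ncol = nrow(design))
    for (j in seq_len(nrow(design))) {
      sig <- timecourse_signal(genes, gp$spike_times, design$condition[j],
                               cfg$conditions, design$time_h[j], t_max)
      mu <- lib[j] / scale * genes$baseline * 2^sig
      m[, j] <- draw_counts(mu, genes$dispersion)
    }
    m
  })
  dimnames(counts) <- list(genes$gene_id, design$sample_id)
  truth <- structure(list(seed = seed, config = cfg, genes = genes,
                          spike_times = gp$spike_times, child_seeds = seeds),
                     class = "sim_truth")
  structure(list(counts = counts_matrix(counts),
                 design = design,
                 biotypes = biotype_map(genes$gene_id, genes$biotype),
                 truth = truth),
            class = "sim_timecourse")
}

#' Simulate a single-timepoint stimulus dataset
#'
#' Generates treated and control samples at the final timepoint of the parent
#' time course, reusing its gene baselines and dispersions. `"atv_like"`
#' shifts each planted divergent gene in its first-condition (PS) direction,
#' `"tnfa_like"` in its second-condition (OS) direction, and
#' `"hypoxia_like"` leaves the divergent program untouched. Every stimulus
#' additionally perturbs a random subset of background genes in the treated
#' samples (see [sim_config()]), so no dataset is a pure replicate of its
#' controls.
#'
#' @param truth a `sim_truth` from [simulate_timecourse()].
#' @param stimulus one of `"atv_like"`, `"tnfa_like"`, `"hypoxia_like"`.
#' @param seed master seed for this dataset.
#' @return A `sim_stimulus` list: `counts`, `design` (conditions `<TAG>` and
#'   `CTRL`), `stimulus`, and `perturbed` (background gene ids shifted in the
#'   treated samples).
#' @export
simulate_stimulus_dataset <- function(truth, stimulus, seed = 1L) {
  tags <- c(atv_like = "ATV", tnfa_like = "TNFA", hypoxia_like = "HYPOXIA")
  if (!stimulus %in% names(tags))
    stop_ft("unknown stimulus '", stimulus, "'; expected one of: ",
            paste(names(tags), collapse = ", "))
  cfg <- truth$config
  genes <- truth$genes
  tag <- tags[[stimulus]]
  n_reps <- cfg$stimulus_reps
  design <- sample_design(data.frame(
    sample_id = c(sprintf("%s_trt_r%d", tag, seq_len(n_reps)),
                  sprintf("%s_ctl_r%d", tag, seq_len(n_reps))),
    condition = rep(c(tag, "CTRL"), each = n_reps),
    time_h = max(cfg$timepoints),
    replicate = rep(paste0("r", seq_len(n_reps)), 2),
    dataset = stimulus,
    stringsAsFactors = FALSE))
  dv <- genes$program == "divergent"
  shift <- numeric(nrow(genes))
  if (stimulus == "atv_like")
    shift[dv] <- genes$direction[dv] * genes$effect[dv] *
      cfg$stimulus_shift_scale
  if (stimulus == "tnfa_like")
    shift[dv] <- -genes$direction[dv] * genes$effect[dv] *
      cfg$stimulus_shift_scale
  seeds <- c(perturb = child_seed(seed, 11), counts = child_seed(seed, 12))
  bg <- which(genes$program == "background")
  perturbed <- with_seed(seeds[["perturb"]], {
    idx <- sample(bg, round(cfg$background_perturb_frac * length(bg)))
    amp <- stats::runif(length(idx), cfg$background_perturb_range[1],
                        cfg$background_perturb_range[2]) *
      sample(c(-1, 1), length(idx), replace = TRUE)
    list(idx = idx, amp = amp)
  })
  shift_trt <- shift
  shift_trt[perturbed$idx] <- shift_trt[perturbed$idx] + perturbed$amp
  scale <- sum(genes$baseline)
  counts <- with_seed(seeds[["counts"]], {
    lib <- stats::rlnorm(nrow(design), log(cfg$lib_size), cfg$lib_sdlog)
    m <- matrix(0L, nrow = nrow(genes), ncol = nrow(design))
    for (j in seq_len(nrow(design))) {
      s <- if (design$condition[j] == "CTRL") numeric(nrow(genes)) else shift_trt
      mu <- lib[j] / scale * genes$baseline * 2^s
      m[, j] <- draw_counts(mu, genes$dispersion)
    }
    m
  })
  dimnames(counts) <- list(genes$gene_id, design$sample_id)
  structure(list(counts = counts_matrix(counts),
                 design = design,
                 stimulus = stimulus,
                 perturbed = genes$gene_id[perturbed$idx]),
            class = "sim_stimulus")
}

#' Write a simulated dataset to disk
#'
#' Emits the formats the ingest module reads: `counts.tsv` (or `counts.mtx`
#' with label sidecars), `design.tsv`, and for time courses `biotypes.tsv`
#' and `truth.tsv` (per-gene program table).
#'
#' @param sim a `sim_timecourse` or `sim_stimulus`.
#' @param dir output directory (created if needed).
#' @param format `"tsv"` or `"mtx"` for the count matrix.
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "tsv") {
    write_counts(sim$counts, file.path(dir, "counts.tsv"))
  } else {
    Matrix::writeMM(Matrix::Matrix(unclass(sim$counts), sparse = TRUE),
                    file.path(dir, "counts.mtx"))
    writeLines(rownames(sim$counts), file.path(dir, "counts.genes.tsv"))
    writeLines(colnames(sim$counts), file.path(dir, "counts.samples.tsv"))
  }
  utils::write.table(as.data.frame(sim$design), file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (inherits(sim, "sim_timecourse")) {
    bt <- data.frame(gene_id = names(sim$biotypes),
                     biotype = unname(unclass(sim$biotypes)))
    utils::write.table(bt, file.path(dir, "biotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(sim$truth$genes, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
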