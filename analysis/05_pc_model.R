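#!/usr/bin/env Rscript

# Purkinje-cell attribution model on synthetic PCs generated as known
# nonnegative mixtures of the granule-cell and inferior-olive cluster
# regressors: kernel matching, per-cell lambda cross-validation, shared
# (geometric-mean) lambda refit, shuffle null, GC/ION index, and the
# index-vs-reliability correlation.
# Outputs: results/pc_weights.csv, results/pc_summary.csv

suppressPackageStartupMessages(library(lumicell))
dir.create("results", showWarnings = FALSE)

fp <- 0.24888
stim <- sample_protocol(build_steps_protocol(n_repetitions = 1), fp)
kf <- make_kernel("GCaMP6fEF05", fp)
ks <- make_kernel("GCaMP6s", fp)
recipe <- default_population_recipe()
n_fr <- length(stim$luminance)
gc_m <- t(vapply(recipe$gc, template_response, numeric(n_fr),
                 stimulus = stim, kernel = kf))
ion_m <- t(vapply(recipe$ion, template_response, numeric(n_fr),
                  stimulus = stim, kernel = kf))
regs <- build_cluster_regressors(gc_m, ion_m, kf, ks, fp)

set.seed(111)
n_pc <- 50
W <- matrix(0, n_pc, 14)
for (i in seq_len(n_pc)) W[i, sample(14, 3)] <- runif(3, 10, 50)
g <- gen_pc_traces(regs, W, offsets = runif(n_pc, -1, 1), n_trials = 6,
                   noise_sd = 0.3, seed = 112)
zscore <- function(tr) t(apply(tr, 1, function(x) (x - mean(x)) / sd(x)))
preps <- lapply(g$trials, function(tr) {
  structure(list(values = zscore(tr), fit_trials = 1:4, test_trials = 5:6,
                 frame_period = fp), class = "pc_prep")
})

grid <- 10^seq(-7, -2, length.out = 11)
lams <- vapply(preps, function(p) crossval_lambda(p, regs, grid)$lambda,
               numeric(1))
lam <- average_lambda(lams)
cat(sprintf("lambda: per-cell CV range [%.1e, %.1e], shared value %.2e\n",
            min(lams), max(lams), lam))

fits <- lapply(preps, fit_pc, regs = regs, lambda = lam)
costs <- vapply(seq_len(n_pc), function(i) {
  evaluate_test_cost(fits[[i]], preps[[i]], regs)
}, numeric(1))
sn <- shuffle_null(fits, preps, regs, n_shuffles = 200, seed = 113)
cat(sprintf("shuffle null: threshold %.3f; %.0f%% of cells better than chance\n",
            sn$threshold, 100 * mean(sn$better_than_chance)))

idx <- vapply(fits, gc_ion_index, numeric(1))
cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
cosines <- vapply(seq_len(n_pc), function(i) {
  cosine(c(fits[[i]]$gc_coeffs, fits[[i]]$ion_coeffs), W[i, ])
}, numeric(1))
cat(sprintf("weight recovery: median cosine similarity %.3f\n",
            median(cosines)))

# reliability of each synthetic PC, correlated against its GC/ION index
tensors <- lapply(g$trials, function(tr) {
  structure(list(values = array(tr, c(1, nrow(tr), ncol(tr))),
                 frame_period = fp, trial_stimulus = stim$luminance),
            class = "trial_tensor")
})
rel <- vapply(tensors, reliability_index, numeric(1))
rv <- reliability_vs_index(idx, rel)
cat(sprintf("reliability vs GC/ION index: Spearman rho %.3f (p = %.2g, n = %d)\n",
            rv$rho, rv$p, n_pc))

wm <- t(vapply(fits, function(f) c(f$gc_coeffs, f$ion_coeffs), numeric(14)))
colnames(wm) <- regs$names
write.csv(round(wm, 4), "results/pc_weights.csv", row.names = FALSE)
write.csv(data.frame(
  cell = seq_len(n_pc),
  offset = round(vapply(fits, `[[`, numeric(1), "offset"), 4),
  test_cost = round(costs, 5),
  better_than_chance = sn$better_than_chance,
  gc_ion_index = round(idx, 4),
  reliability = round(rel, 4),
  weight_cosine_vs_truth = round(cosines, 4)
), "results/pc_summary.csv", row.names = FALSE)
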