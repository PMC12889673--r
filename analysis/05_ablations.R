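#!/usr/bin/env Rscript

# Stage 5: ablation fits.
#
# Refits the synthetic observations under three ablations — no recurrent
# connections, no projections from L2/3 E neurons, and a rectified-linear
# (instead of rectified-quadratic) transfer function — and compares the
# fitted size-tuning of the centered E unit against the full model's fit.
# The signature of interest: without E projections the model cannot
# amplify weak inputs, so it underestimates responses to small stimuli.

suppressMessages(library(ssnspace))

ds <- default_fixture(1)
variants <- c("full", "no_recurrent", "no_E_projections", "linear_nl")
fits <- list()
for (v in variants) {
  cfg <- fit_config(seed = 8, n_restarts = 3, top_k = 1, maxit = 120,
                    variant = v)
  t0 <- Sys.time()
  rk <- fit_multistart(ds$truth, ds$observed, ds$drive, cfg)
  fits[[v]] <- rk$fits[[1]]
  cat(sprintf("%-17s loss %.4f  (%s)\n", v, rk$ranking$loss[1],
              format(Sys.time() - t0)))
}

tune <- sapply(fits, function(f) size_tuning(predict(f$model, ds$drive), "E"))
rownames(tune) <- ds$drive$sizes
dir.create("results", showWarnings = FALSE)
write.csv(cbind(size = ds$drive$sizes, tune), "results/ablation_E_tuning.csv",
          row.names = FALSE)
cat("\ncentered-E size tuning by variant:\n")
print(round(tune, 3))

pk <- apply(tune, 2, function(v) ds$drive$sizes[which.max(v)])
cat(sprintf(paste0(
  "\nsignatures:\n",
  " - rectified-linear fit at 5 deg: %.3f vs full %.3f (the expansive\n",
  "   nonlinearity is needed for small-stimulus responses);\n",
  " - no-recurrence fit peaks at %d deg vs full %d deg (without recurrence\n",
  "   the size tuning inherits the external-input tuning);\n",
  " - no-E-projections fit is an order of magnitude worse overall, though\n",
  "   its centered 5-deg value (%.3f) is not itself diagnostic at such a\n",
  "   misfit optimum.\n"),
  tune[1, "linear_nl"], tune[1, "full"],
  pk[["no_recurrent"]], pk[["full"]], tune[1, "no_E_projections"]))
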