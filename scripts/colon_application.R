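#!/usr/bin/env Rscript
# Optional real-data application: dependence-aware reanalysis of a colon
# cancer survival dataset.  The data are NOT shipped here; export them from
# the 'dirttee' R package yourself, e.g.
#
#   data(colcancer, package = "dirttee")
#   df <- data.frame(y = colcancer$followup, delta = colcancer$death,
#                    model.matrix(~ . - followup - death, colcancer)[, -1])
#   write.csv(df, "colcancer.csv", row.names = FALSE)
#
# then run
#
#   Rscript scripts/colon_application.R --data colcancer.csv --out-dir colon_out
#
# The script ranks all margin x copula combinations by 10-fold
# cross-validated predictive log-likelihood, refits the winner on the full
# data with a validation split for m_stop, and writes the ranked scores,
# the fitted model and its coefficient table.  Expect a runtime of hours at
# the default budgets; shrink --mstop for a quick look.

suppressPackageStartupMessages({
  library(optparse)
  library(copboost)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--data", type = "character"),
  make_option("--folds", type = "integer", default = 10),
  make_option("--nu", type = "double", default = 0.01),
  make_option("--mstop", type = "integer", default = 5000),
  make_option("--seed", type = "integer", default = 1),
  make_option("--out-dir", dest = "out_dir", default = "colon_out"))))
if (is.null(opts$data)) stop("--data <exported csv> is required")
dir.create(opts$out_dir, recursive = TRUE, showWarnings = FALSE)

data <- read_survival_table(opts$data)
cfg <- boost_config(nu = opts$nu, mstop_max = opts$mstop)

specs <- list()
for (m in c("weibull", "lognormal"))
  for (cp in c("clayton", "gaussian", "gumbel"))
    specs[[paste(m, cp, sep = "+")]] <-
      model_spec(margin_spec(m), margin_spec(m), copula_spec(cp))

message("ranking ", length(specs), " candidate models by ", opts$folds,
        "-fold predictive log-likelihood")
scores <- cv_predictive_loglik(specs, data, cfg, folds = opts$folds,
                               seed = opts$seed)
write.csv(scores, file.path(opts$out_dir, "model-scores.csv"),
          row.names = FALSE)
print(scores)

best <- specs[[scores$model[1]]]
message("refitting ", scores$model[1], " with a 25% validation split")
set.seed(opts$seed)
n <- length(data$y)
val_idx <- sample.int(n, round(0.25 * n))
fit <- fit_boost(best, copboost:::.subset_data(data, setdiff(seq_len(n), val_idx)),
                 cfg, data_val = copboost:::.subset_data(data, val_idx))
write_fit(fit, file.path(opts$out_dir, "fit.json"))
write_coef_table(fit, file.path(opts$out_dir, "coefficients.csv"))
message("m_stop = ", fit$mstop, "; outputs in ", opts$out_dir)
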