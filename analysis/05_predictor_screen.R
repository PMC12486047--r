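#!/usr/bin/env Rscript
# Stage 5: screen the user-specific factors against signal strength.
#
# Assembles the 16-factor predictor matrix (clinical covariates, fMRI
# activation summaries, implant geometry), screens each factor with a
# Spearman correlation against the measured d-prime (uncorrected p, the
# screen is exploratory), and runs Lasso feature selection with
# leave-one-out cross-validation.

suppressMessages(library(vascbci))

seed <- 20260929L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

co <- generate_cohort(10, seed = seed)
ft <- assemble_factor_table(co)
screen <- screen_factors(ft$X, ft$y)
lasso <- lasso_select(ft$X, ft$y)

write.csv(ft$table, file.path(out_dir, "factor_table.csv"),
          row.names = FALSE)
write.csv(as.data.frame(screen), file.path(out_dir, "screen.csv"),
          row.names = FALSE)
write.csv(as.data.frame(lasso), file.path(out_dir, "lasso.csv"),
          row.names = FALSE)

cat("ranked factor screen (Spearman vs signal strength):\n")
print(head(as.data.frame(screen)[, c("factor", "rho", "p.value", "rank")],
           8), row.names = FALSE, digits = 3)
cat("\nLasso-selected factors (nonzero standardised coefficients):\n")
sel <- as.data.frame(lasso)[as.data.frame(lasso)$selected, ]
print(sel[, c("factor", "coefficient")], row.names = FALSE, digits = 3)
cat(sprintf("\ntop screen factor: %s (rho = %.2f, p = %.3f)\n",
            screen$factor[1], screen$rho[1], screen$p.value[1]))
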