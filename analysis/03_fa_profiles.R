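#!/usr/bin/env Rscript
# Fatty-acid composition comparison between sexes across three contrasting
# tissues (liver, vastus muscle, BAT) and two lipid fractions (PL, TG):
# simulate per-sample FA amounts with planted sex shifts (n = 8 per group,
# mirroring a chow-fed mouse study), normalize to mol% and produce the
# grouped summary with error bars and significance tiers.
# Writes results/fa_profiles/.

suppressMessages(library(lipidtraffic))

out <- file.path("results", "fa_profiles")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
set.seed(30)

species <- c("FA(16:0)", "FA(16:1)", "FA(18:0)", "FA(18:1)", "FA(18:2)",
             "FA(20:4)")
base_prof <- c(30, 5, 15, 25, 18, 7)  # typical tissue mol% profile
names(base_prof) <- species

# planted female shifts (mol points), emulating longer/more unsaturated FAs
# in female phospholipids: less 16:0/16:1 and 18:2, more 18:0 and 20:4
shift_f <- c("FA(16:0)" = -4, "FA(16:1)" = -1.5, "FA(18:0)" = +4,
             "FA(18:1)" = 0, "FA(18:2)" = -2, "FA(20:4)" = +3.5)

simulate_tissue <- function(tissue, fraction, n = 8, sd = 1.5) {
  rows <- lapply(c("F", "M"), function(sex) {
    prof <- base_prof + if (sex == "F" && fraction == "PL") shift_f else 0
    m <- pmax(matrix(stats::rnorm(n * length(species), rep(prof, each = n),
                                  sd), n), 0.1)
    colnames(m) <- species
    rownames(m) <- sprintf("%s_%s_%s_%d", tissue, fraction, sex, seq_len(n))
    m
  })
  amounts <- do.call(rbind, rows)
  molp <- normalize_mol_percent(amounts)
  s <- group_fa_summary(molp, rep(c("F", "M"), each = n))
  s$tissue <- tissue
  s$fraction <- fraction
  s
}

summaries <- do.call(rbind, lapply(c("liver", "vastus muscle", "BAT"),
  function(ti) rbind(simulate_tissue(ti, "PL"), simulate_tissue(ti, "TG"))))
utils::write.csv(summaries, file.path(out, "fa_summary.csv"),
                 row.names = FALSE)

cat("FA mol% comparison, PL fraction (planted female shifts):\n")
pl <- summaries[summaries$fraction == "PL" & summaries$tissue == "liver", ]
print(pl[, c("species", "mean_F", "err_F", "mean_M", "err_M", "p_value",
             "tier")], digits = 3, row.names = FALSE)
tg <- summaries[summaries$fraction == "TG", ]
cat(sprintf("TG fraction (no planted shift): %d of %d species below p = 0.05\n",
            sum(tg$p_value < 0.05, na.rm = TRUE), nrow(tg)))
cat("Summary table written to", file.path(out, "fa_summary.csv"), "\n")
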