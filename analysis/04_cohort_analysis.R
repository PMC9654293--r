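#!/usr/bin/env Rscript
# Stage 4 — the statistical battery on the quantified cohort:
# survivor/non-survivor comparisons routed by Shapiro-Wilk, the Spearman
# correlation matrix, the median-dichotomized coincidence network with
# Haberman residuals, and confounder-adjusted odds ratios for baseline
# measures and follow-up changes (overall and tumor-cause mortality).
# Writes group_tests.csv, spearman_rho.csv, network_edges.csv /
# network.graphml, adjusted_odds_ratios.csv and a forest plot.

suppressPackageStartupMessages({
  library(l3compo)
  library(ggplot2)
})
stopifnot(file.exists("results/analysis_table.csv"))  # run 03 first

analysis <- read.csv("results/analysis_table.csv", na.strings = "")
gate <- read.csv("results/gate_report.csv")
retained <- gate$measure[gate$retained]

## survivor vs non-survivor comparisons --------------------------------------
vars <- c("age", "sex", "bmi", "weight_kg", "ecog", "grade", "metastasis",
          "albumin", "ldh", "urea", "glucose", "fibrinogen", retained)
tab2 <- suppressWarnings(
  group_compare_table(analysis, intersect(vars, names(analysis)),
                      group = "deceased"))
write.csv(tab2, "results/group_tests.csv", row.names = FALSE)
sig <- tab2$variable[!is.na(tab2$p_value) & tab2$p_value < 0.05]
cat(sprintf("group tests: %d/%d variables differ between survivors and non-survivors (p < 0.05): %s\n",
            length(sig), nrow(tab2), paste(sig, collapse = ", ")))

## Spearman matrix -------------------------------------------------------------
cont <- intersect(c("age", "bmi", "albumin", "ldh", "urea", "glucose",
                    "fibrinogen", retained), names(analysis))
sm <- spearman_matrix(analysis[, cont])
write.csv(sm$rho, "results/spearman_rho.csv")
write.csv(sm$p, "results/spearman_p.csv")

## coincidence network ---------------------------------------------------------
dich <- dichotomize(analysis[, intersect(c("age", "bmi", "albumin", "ldh",
                                           "urea", retained),
                                         names(analysis))])
ind <- dich$indicators
ind$deceased <- analysis$deceased == 1
ind$survivor <- analysis$deceased == 0
net <- build_coincidence_network(ind)
write.csv(net$edges, "results/network_edges.csv", row.names = FALSE)
igraph::write_graph(net$graph, "results/network.graphml", format = "graphml")
cat(sprintf("coincidence network: %d nodes, %d significant edges (Haberman d > %.3f)\n",
            nrow(net$nodes), nrow(net$edges), net$threshold))
mort_edges <- net$edges[net$edges$from == "deceased" |
                          net$edges$to == "deceased", ]
if (nrow(mort_edges))
  cat("  mortality co-occurs with:",
      paste(setdiff(unlist(mort_edges[, 1:2]), "deceased"), collapse = ", "),
      "\n")

## adjusted odds ratios --------------------------------------------------------
ors <- list()
for (oc in c("overall", "tumor")) {
  for (m in intersect(retained, names(analysis)))
    ors[[paste(oc, m)]] <- suppressWarnings(adjusted_logistic(analysis, m, oc))
  for (m in paste0("delta_", retained))
    if (m %in% names(analysis))
      ors[[paste(oc, m)]] <- suppressWarnings(adjusted_logistic(analysis, m, oc))
}
or_tab <- do.call(rbind, c(ors, make.row.names = FALSE))
write.csv(or_tab, "results/adjusted_odds_ratios.csv", row.names = FALSE)

deltas <- or_tab[grepl("^delta_", or_tab$measure) &
                   or_tab$outcome == "overall", ]
cat("adjusted odds ratios per cm2/m2 of follow-up change (overall mortality):\n")
for (i in seq_len(nrow(deltas)))
  cat(sprintf("  %-16s OR %.3f [%.3f, %.3f] p = %.3f\n",
              deltas$measure[i], deltas$odds_ratio[i], deltas$ci_low[i],
              deltas$ci_high[i], deltas$p_value[i]))

forest <- or_tab[grepl("^delta_", or_tab$measure), ]
forest$measure <- sub("^delta_", "Δ", forest$measure)
gp <- ggplot(forest, aes(x = odds_ratio, y = measure)) +
  geom_vline(xintercept = 1, linetype = 2) +
  geom_errorbarh(aes(xmin = ci_low, xmax = ci_high), height = 0.25) +
  geom_point(aes(shape = p_value < 0.05), size = 2.5) +
  scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                     name = "p < 0.05") +
  scale_x_log10() +
  facet_wrap(~outcome) +
  labs(x = "adjusted OR per cm²/m² of change (log scale)",
       y = NULL,
       title = "Follow-up body-composition change and mortality") +
  theme_bw()
ggsave("results/or_forest.pdf", gp, width = 8, height = 4.5)
cat("wrote results/group_tests.csv, spearman_rho.csv, network_edges.csv, adjusted_odds_ratios.csv, or_forest.pdf\n")
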