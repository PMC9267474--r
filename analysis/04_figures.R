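#!/usr/bin/env Rscript

# Step 4 (optional): figures.
#
# Renders one section's pseudo-color segmentation overlay, the per-group
# scatter of recovered ratios, and the ROC curves, into scratch/figures/.

suppressPackageStartupMessages(library(msipath))

fig_dir <- file.path("scratch", "figures")
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

summaries <- read.csv(file.path("results", "summaries.csv"))
roc_pts <- read.csv(file.path("results", "roc_points.csv"))

# pseudo-color overlay of one freshly simulated cSCC section
sc <- make_scene(tissue_preset("cscc"), seed = 11L)
r <- render_cube(sc, imaging_model(), seed = 12L)
res <- process_section(r$stacks, r$cal, section_id = "example",
                       label = "cscc", keep_images = TRUE)
overlay <- compose_pseudocolor(res$masks, get_band(res$cube, 660L))
png::writePNG(overlay, file.path(fig_dir, "pseudocolor_cscc.png"))

png(file.path(fig_dir, "group_scatter.png"), 600, 500)
set.seed(1)
x <- as.integer(factor(summaries$label, c("normal", "cscc")))
plot(jitter(x, 0.2), summaries$mean_pct, xaxt = "n", xlim = c(0.5, 2.5),
     xlab = "", ylab = "mean nucleocytoplasmic ratio (%)",
     pch = 19, col = c("steelblue", "firebrick")[x],
     main = "Recovered per-section ratios")
axis(1, 1:2, c("normal", "cSCC"))
dev.off()

png(file.path(fig_dir, "roc_curves.png"), 600, 500)
plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "false positive rate",
     ylab = "true positive rate", main = "ROC by summary statistic")
abline(0, 1, lty = 3, col = "grey")
cols <- c(mean = "firebrick", max = "steelblue", min = "darkgreen")
for (st in names(cols)) {
  p <- roc_pts[roc_pts$statistic == st, ]
  lines(p$fpr, p$tpr, type = "s", lwd = 2, col = cols[[st]])
}
legend("bottomright", names(cols), col = cols, lwd = 2, bty = "n")
dev.off()

message("Figures written under ", fig_dir)
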