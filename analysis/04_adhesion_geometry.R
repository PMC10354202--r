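#!/usr/bin/env Rscript
# Focal-adhesion geometry on segmented cells.
#
# Generates synthetic cells with adhesions planted at known normalized
# distances from the cell edge, segments the cell body by Otsu thresholding,
# applies the 0.3 um^2 size filter, classifies adhesions central vs
# peripheral by the 0.3 r rule, and measures background-subtracted adhesion
# intensities. Reports the central fraction both pooled and per cell.
# Writes tables under results/.

suppressPackageStartupMessages(library(vinkin))
dir.create("results", showWarnings = FALSE)

cells <- data.frame(cell_id = 1:6,
                    shape = rep(c("disk", "ellipse"), 3),
                    central_fraction = c(0.25, 0.5, 0.5, 0.75, 0.375, 0.625))

records <- list()
for (i in seq_len(nrow(cells))) {
  fx <- synthetic_cell_fixture(shape = cells$shape[i], n_adhesions = 8,
                               central_fraction = cells$central_fraction[i],
                               seed = 400 + i, noise_sd = 3)
  cell <- segment_cell(fx$actin_image, fx$pixel_size_um)
  fl <- filter_adhesions(fx$label_mask, fx$pixel_size_um, min_area_um2 = 0.3)
  rec <- classify_adhesions(fl$labels, cell, fx$intensity_image)
  ai <- adhesion_intensity(fl$labels, fx$intensity_image, cell)
  rec$intensity_bgsub <- ai$intensity_bgsub[match(rec$fa_id, ai$fa_id)]
  rec$cell_id <- cells$cell_id[i]
  rec$planted_class <- fx$truth$class[match(rec$fa_id, fx$truth$fa_id)]
  records[[i]] <- rec
}
all_rec <- do.call(rbind, records)
write.table(all_rec[, c("cell_id", "fa_id", "area_um2", "dist_um",
                        "dist_norm", "class", "intensity_bgsub",
                        "planted_class")],
            "results/adhesion_records.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

per_cell <- aggregate(class ~ cell_id, all_rec,
                      function(cl) mean(cl == "central"))
names(per_cell)[2] <- "central_fraction_measured"
per_cell$central_fraction_planted <- cells$central_fraction
write.table(per_cell, "results/central_fraction_per_cell.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Per-cell central fractions (measured vs planted):\n")
print(per_cell, row.names = FALSE)
cat(sprintf("\nPooled central fraction: %.3f (planted %.3f)\n",
            mean(all_rec$class == "central"),
            mean(all_rec$planted_class == "central")))
cat(sprintf("Classification agreement with planted truth: %.1f%%\n",
            100 * mean(all_rec$class == all_rec$planted_class)))
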