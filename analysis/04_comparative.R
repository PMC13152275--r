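#!/usr/bin/env Rscript
# Stage 4: comparative inference on the species conductance table.
#
# Log-transform, residualize log G on log egg mass (residuals used only if
# the allometric slope is significant), estimate phylogenetic signal
# (Pagel's lambda + LRT), rank the four trait-evolution models by AICc,
# run the simulation-based phylogenetic ANOVA and the Levene-type variance
# test across elevation bands, fit the elevation PGLS under the best-AICc
# covariance, and repeat the PGLS within families. This is the run_pipeline()
# sequence, driven from the persisted stage outputs.

library(ovocond)

inp <- "results/inputs"
out <- "results/comparative"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

bundle <- list(
  tree = read_newick(file = file.path(inp, "tree.nwk")),
  mass_df = read.csv(file.path(inp, "mass_series.csv")),
  morph_df = read.csv(file.path(inp, "morphometry.csv")),
  species_meta = read.csv(file.path(inp, "species_meta.csv")))

pipe <- run_pipeline(bundle, nsim = 1000, seed = 20260925, output_dir = out)
print(pipe)

write.csv(pipe$model_selection, file.path(out, "model_selection.csv"),
          row.names = FALSE)

# per-family PGLS of log conductance on elevation
sp <- merge(pipe$species, bundle$species_meta[, c("species", "family")],
            by = "species")
sp_fam <- data.frame(species = sp$species, family = sp$family,
                     elevation_m = sp$elevation_m, trait = sp$log_g)
fam_fits <- family_subset_analysis(sp_fam, bundle$tree, "trait")
fam_tab <- do.call(rbind, lapply(names(fam_fits), function(f) {
  co <- fam_fits[[f]]$coefficients["elevation_km", ]
  data.frame(family = f, n = fam_fits[[f]]$n, slope = co$estimate,
             p = co$p, r_squared = fam_fits[[f]]$r_squared)
}))
if (!is.null(fam_tab)) {
  write.csv(fam_tab, file.path(out, "family_pgls.csv"), row.names = FALSE)
  cat("\nPer-family PGLS (trait = log G, predictor = elevation km):\n")
  print(fam_tab, digits = 3)
}

# GLM model selection over predictor sets, as for the field data
tab <- pipe$species
tab$band <- as.character(elevation_category(tab$elevation_m))
sel <- glm_model_selection(tab, "log_g",
                           list(character(0), "log_mass", "band",
                                c("log_mass", "band")))
print(sel)
write.csv(sel$table, file.path(out, "glm_selection.csv"), row.names = FALSE)
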