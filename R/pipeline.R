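# End-to-end workflow: per-egg conductance with QC -> species means -> log
# transform -> allometric residualization -> trait-evolution model selection
# -> phylogenetic ANOVA / variance test across elevation bands -> PGLS of
# residual conductance on elevation, plus per-family subsets. Each stage's
# table can be persisted as CSV for provenance.

#' Run the full conductance-and-comparative analysis pipeline
#'
#' Takes a study bundle (as produced by [simulate_egg_study()], or
#' assembled from CSVs with the same columns) and executes the analysis
#' sequence: egg QC and conductance, species aggregation (max 3 eggs),
#' log transform, residualization of log G on log egg mass (residuals used
#' when the allometric slope is significant, absolute values otherwise),
#' phylogenetic-signal estimation and four-model AICc selection, covariance
#' choice by best AICc, phylogenetic ANOVA and Levene-type variance test
#' across elevation bands, and PGLS of the residual trait on elevation.
#'
#' @param bundle List with `tree`, `mass_df`, `morph_df`, `species_meta`
#'   (see [simulate_egg_study()]).
#' @param delta_p_mode "temperature" or "standard" (see
#'   [conductance_table()]).
#' @param standard_delta_p dP (torr) for standard mode.
#' @param bands Elevation bands for categorization.
#' @param nsim Null simulations for the ANOVA stage.
#' @param models Trait-evolution models for selection.
#' @param seed Optional RNG seed (ANOVA nulls).
#' @param output_dir Optional directory; when given, stage tables are
#'   written as CSVs.
#' @return Object of class `egg_pipeline`: per-egg and species tables,
#'   allometry, `signal` (Pagel's lambda + LRT), `model_selection` table,
#'   `anova`, `variance_test`, `pgls` (residual trait ~ elevation in km),
#'   `covariance_model`.
#' @export
run_pipeline <- function(bundle,
                         delta_p_mode = c("temperature", "standard"),
                         standard_delta_p = 23.77,
                         bands = default_elevation_bands(),
                         nsim = 500,
                         models = c("BM", "lambda", "OU", "EB"),
                         seed = NULL, output_dir = NULL) {
  delta_p_mode <- match.arg(delta_p_mode)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("tree", "mass_df", "morph_df") %in% names(bundle)))

  eggs <- conductance_table(bundle$mass_df, delta_p_mode = delta_p_mode,
                            standard_delta_p = standard_delta_p)
  sp <- species_conductance(eggs)
  if (nrow(sp) < 3) stop("stage species_conductance: fewer than 3 species passed QC")
  sp <- merge(sp, bundle$morph_df[, c("species", "mass_g")], by = "species")
  sp$log_g <- log(sp$g_h2o)
  sp$log_mass <- log(sp$mass_g)
  sp$band <- elevation_category(sp$elevation_m, bands)

  log_g <- stats::setNames(sp$log_g, sp$species)
  log_mass <- stats::setNames(sp$log_mass, sp$species)
  allo <- allometric_residuals(log_g, log_mass)
  trait <- if (allo$significant) allo$residuals else log_g

  md <- match_tree_data(bundle$tree, trait)
  sel <- fit_all_models(md$tree, md$x, models = models)
  best <- sel$table$model[1]
  best_fit <- sel$fits[[best]]
  signal <- phylo_signal_lambda(md$tree, md$x)

  h <- tree_height(md$tree)
  C <- transform_covariance(
    tree_vcv(md$tree), best,
    params = switch(best,
      BM = list(),
      lambda = list(lambda = unname(best_fit$shape["lambda"])),
      OU = list(alpha = unname(best_fit$shape["alpha"]) * h),
      EB = list(a = unname(best_fit$shape["a"]) * h)))

  groups <- stats::setNames(as.character(sp$band), sp$species)
  anv <- phylo_anova(md$tree, md$x, groups, nsim = nsim)
  vtest <- group_variance_test(md$tree, md$x, groups, nsim = nsim)

  elev_km <- data.frame(elevation_km = sp$elevation_m / 1000,
                        row.names = sp$species)
  fit_pgls <- pgls(md$x, elev_km[names(md$x), , drop = FALSE], C)

  out <- structure(list(
    eggs = eggs, species = sp, allometry = allo,
    trait_used = if (allo$significant) "residual_log_g" else "log_g",
    signal = signal, model_selection = sel$table,
    covariance_model = list(model = best, shape = best_fit$shape),
    anova = anv, variance_test = vtest, pgls = fit_pgls,
    n_species = nrow(sp)), class = "egg_pipeline")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(eggs, file.path(output_dir, "per_egg_conductance.csv"),
                     row.names = FALSE)
    utils::write.csv(sp, file.path(output_dir, "species_conductance.csv"),
                     row.names = FALSE)
    utils::write.csv(out$model_selection,
                     file.path(output_dir, "model_selection.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(term = rownames(fit_pgls$coefficients),
                           fit_pgls$coefficients),
                     file.path(output_dir, "pgls_elevation.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.egg_pipeline <- function(x, ...) {
  cat("Egg conductance pipeline:", x$n_species, "species\n")
  cat(sprintf("  allometric slope (log G ~ log mass): %.3f (R^2 = %.3f, p = %.3g)\n",
              x$allometry$slope, x$allometry$r_squared, x$allometry$p_value))
  cat(sprintf("  trait analyzed: %s; Pagel's lambda = %.3f (LRT p = %.3g)\n",
              x$trait_used, x$signal$lambda, x$signal$p_value))
  cat("  best covariance model:", x$covariance_model$model, "\n")
  cat(sprintf("  phylo ANOVA across bands: F_%d,%d = %.2f, simulation p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$f, x$anova$p_simulation))
  elev <- x$pgls$coefficients["elevation_km", ]
  cat(sprintf("  PGLS elevation slope: %.3f (p = %.3g, R^2 = %.3f)\n",
              elev$estimate, elev$p, x$pgls$r_squared))
  invisible(x)
}

#' Per-family PGLS of a trait on elevation
#'
#' Runs the elevation PGLS separately within each family having at least
#' `min_species` species spanning more than one distinct elevation;
#' families below the threshold are skipped (reported via message).
#'
#' @param species_df data.frame with `species`, a family column,
#'   `elevation_m`, and the trait column.
#' @param tree A `phylo` covering the species.
#' @param trait_col Trait column name.
#' @param family_col Family column name.
#' @param min_species Minimum species per family (default 3, i.e. the
#'   "more than 2 species" rule).
#' @param model Covariance model for the within-family PGLS (BM default;
#'   single-family subsets rarely support shape estimation).
#' @return Named list of `pgls_fit` objects, one per analyzed family.
#' @export
family_subset_analysis <- function(species_df, tree, trait_col,
                                   family_col = "family", min_species = 3,
                                   model = "BM") {
  stopifnot(all(c("species", family_col, "elevation_m", trait_col)
                %in% colnames(species_df)))
  out <- list()
  for (fam in unique(species_df[[family_col]])) {
    d <- species_df[species_df[[family_col]] == fam, ]
    if (nrow(d) < min_species || length(unique(d$elevation_m)) < 2) {
      message("family ", fam, " skipped (needs >= ", min_species,
              " species at different elevations)")
      next
    }
    y <- stats::setNames(d[[trait_col]], d$species)
    md <- match_tree_data(tree, y)
    if (ape::Ntip(md$tree) < min_species) {
      message("family ", fam, " skipped (too few species in tree)")
      next
    }
    C <- tree_vcv(md$tree)
    X <- data.frame(elevation_km = d$elevation_m[match(names(md$x), d$species)] / 1000,
                    row.names = names(md$x))
    out[[fam]] <- pgls(md$x, X, C)
  }
  out
}

#' Ordinary within-species regression of a trait on elevation
#'
#' For nests of a single species spanning an elevational range no phylogeny
#' applies; this is a plain OLS of the trait on elevation (km).
#'
#' @param elevation_m Elevations (m) per nest/sample.
#' @param value Trait values.
#' @return List: `slope` (per km), `r_squared`, `p_value`, `n`.
#' @export
within_species_regression <- function(elevation_m, value) {
  ok <- is.finite(elevation_m) & is.finite(value)
  if (sum(ok) < 3) stop("need >= 3 observations")
  fit <- stats::lm(value[ok] ~ I(elevation_m[ok] / 1000))
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]), r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4], n = sum(ok))
}
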