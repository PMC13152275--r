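# Synthetic-data generators with known ground truth: pure-birth trees,
# traits evolved under BM/lambda/OU/EB with an additive elevation effect,
# egg mass-loss series with balance noise (and optional fracture events),
# egg morphometry, and SEM-like pore fields. Every generator is a pure
# function of its arguments and seed.

#' Simulate a pure-birth (Yule) tree rescaled to unit height
#'
#' @param n Number of tips (>= 2).
#' @param seed Optional RNG seed.
#' @return Ultrametric `phylo` of height 1 with tips `s1..sn`.
#' @export
simulate_tree <- function(n, seed = NULL) {
  if (n < 2) stop("need >= 2 tips")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length / tree_height(tr)
  tr$tip.label <- paste0("s", seq_len(n))
  tr
}

#' Assign species elevations by band sampling
#'
#' Each species draws a band label (lowland / mid / highland), then a
#' uniform elevation within the band; this reproduces the clumped-with-gaps
#' elevation distribution of a three-station design. With
#' `clustered = TRUE` band membership follows a thresholded Brownian
#' trait on the tree, giving phylogenetically clustered elevations.
#'
#' @param tree A `phylo` object (tips name the output).
#' @param bands Band bounds as in [default_elevation_bands()].
#' @param probs Band sampling probabilities.
#' @param clustered Phylogenetically clustered band membership?
#' @param seed Optional RNG seed.
#' @return Named numeric vector of elevations (m).
#' @export
assign_elevations <- function(tree, bands = default_elevation_bands(),
                              probs = NULL, clustered = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  if (is.null(probs)) probs <- rep(1 / length(bands), length(bands))
  if (clustered) {
    z <- simulate_trait(tree, model = "BM",
                        params = list(sigma2 = 1, z0 = 0))
    qs <- stats::quantile(z, cumsum(probs)[-length(probs)])
    band_idx <- findInterval(z, qs) + 1
  } else {
    band_idx <- sample(length(bands), n, replace = TRUE, prob = probs)
  }
  elev <- vapply(band_idx, function(i)
    stats::runif(1, bands[[i]][1], bands[[i]][2]), numeric(1))
  names(elev) <- tree$tip.label
  elev
}

#' Simulate a continuous trait on a tree under a named evolutionary model
#'
#' Draws from the multivariate normal with mean
#' `z0 + beta * elevation_m / 1000` and covariance `sigma2 * C_model`, where
#' `C_model` comes from the same [transform_covariance()] code path used by
#' the fitting routines.
#'
#' @param tree A `phylo` object.
#' @param model One of "BM", "lambda", "OU", "EB".
#' @param params List with `sigma2` (> 0), `z0`, and the model's shape
#'   parameter (`lambda`, `alpha`, or `a`).
#' @param elevation Optional named elevations (m) for the additive effect.
#' @param beta Elevation effect in trait units per km (default 0).
#' @param seed Optional RNG seed.
#' @return Named trait vector in `tree$tip.label` order.
#' @export
simulate_trait <- function(tree, model = "BM",
                           params = list(sigma2 = 1, z0 = 0),
                           elevation = NULL, beta = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sigma2 <- params$sigma2 %||% 1
  z0 <- params$z0 %||% 0
  stopifnot(sigma2 >= 0)
  C <- transform_covariance(tree_vcv(tree), model, params)
  mu <- rep(z0, ape::Ntip(tree))
  names(mu) <- tree$tip.label
  if (!is.null(elevation)) mu <- mu + beta * elevation[tree$tip.label] / 1000
  if (sigma2 == 0) return(mu)
  L <- chol_safe(sigma2 * C)
  x <- mu + drop(crossprod(L, stats::rnorm(length(mu))))
  names(x) <- tree$tip.label
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an egg mass-loss series with balance noise
#'
#' Deterministic loss `mass(d) = M0 - G * dP * d / 1000` (grams) plus
#' iid balance noise, over days `0 .. days-1`. An optional fracture injects
#' an extra step drop of `fracture_drop_g` from `fracture_day` onward, for
#' QC-detector testing.
#'
#' @param true_g True conductance (mg day^-1 torr^-1, > 0).
#' @param delta_p Vapor-pressure difference (torr).
#' @param m0 Initial mass (g).
#' @param days Number of daily weighings (4..30).
#' @param noise_sd Balance noise sd in grams.
#' @param fracture_day Optional day index (1..days-1) at which a fracture
#'   step occurs.
#' @param fracture_drop_g Size of the fracture step (g); default 10x the
#'   deterministic daily loss.
#' @param seed Optional RNG seed.
#' @return data.frame with columns `day`, `mass_g`.
#' @export
simulate_mass_series <- function(true_g, delta_p = 23.77, m0 = 5, days = 8,
                                 noise_sd = 0.005, fracture_day = NULL,
                                 fracture_drop_g = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(true_g > 0, days >= 4, days <= 30, delta_p > 0, m0 > 0)
  d <- 0:(days - 1)
  daily_loss_g <- true_g * delta_p / 1000
  mass <- m0 - daily_loss_g * d
  if (!is.null(fracture_day)) {
    if (fracture_day < 1 || fracture_day > days - 1)
      stop("fracture_day must be in 1..days-1")
    if (is.null(fracture_drop_g)) fracture_drop_g <- 10 * daily_loss_g
    mass <- mass - fracture_drop_g * (d >= fracture_day)
  }
  if (any(mass <= 0)) stop("egg mass would reach zero within the window")
  mass <- mass + stats::rnorm(days, 0, noise_sd)
  if (any(mass <= 0)) stop("egg mass would reach zero within the window")
  data.frame(day = d, mass_g = mass)
}

# Rasterize a filled disk into matrix `px` (value `val`).
fill_disk <- function(px, row, col, radius, val) {
  rr <- max(1, floor(row - radius)):min(nrow(px), ceiling(row + radius))
  cc <- max(1, floor(col - radius)):min(ncol(px), ceiling(col + radius))
  for (r in rr) for (c in cc)
    if ((r - row)^2 + (c - col)^2 <= radius^2) px[r, c] <- val
  px
}

#' Generate an SEM-like eggshell surface field with known pores
#'
#' Textured bright background (mean ~0.8, speckle sd ~0.05) carrying dark
#' disks (functional pores, intensity ~0.05) and lighter gray disks
#' (occluded holes, ~0.35). Disk centers are rejection-sampled to respect a
#' minimum separation and a border margin, so ground truth maps 1:1 onto
#' detectable components.
#'
#' @param n_functional,n_occluded Pore counts by class.
#' @param radius_px Range (min, max) of disk radii in pixels.
#' @param size_px Field edge length in pixels (square field).
#' @param scale_um_per_px Physical scale (um per pixel).
#' @param min_sep_px Minimum edge-to-edge separation between disks.
#' @param seed Optional RNG seed.
#' @param max_attempts Placement attempts before giving up.
#' @return List: `image` (an `sem_image`), `truth` (data.frame with 0-based
#'   `center_row`, `center_col`, `radius_px`, `area_um2`, `class`).
#' @export
generate_sem_image <- function(n_functional, n_occluded = 0,
                               radius_px = c(3, 6), size_px = 256,
                               scale_um_per_px = 0.2, min_sep_px = 5,
                               seed = NULL, max_attempts = 1e4) {
  if (!is.null(seed)) set.seed(seed)
  px <- matrix(pmin(pmax(stats::rnorm(size_px^2, 0.8, 0.05), 0), 1),
               size_px, size_px)
  ntot <- n_functional + n_occluded
  centers <- matrix(numeric(0), 0, 3)  # row, col, radius
  attempts <- 0
  while (nrow(centers) < ntot) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("could not place requested pores in ", max_attempts, " attempts")
    r <- stats::runif(1, radius_px[1], radius_px[2])
    margin <- r + 2
    row <- stats::runif(1, 1 + margin, size_px - margin)
    col <- stats::runif(1, 1 + margin, size_px - margin)
    if (nrow(centers)) {
      dd <- sqrt((centers[, 1] - row)^2 + (centers[, 2] - col)^2)
      if (any(dd < centers[, 3] + r + min_sep_px)) next
    }
    centers <- rbind(centers, c(row, col, r))
  }
  cls <- rep(c("functional", "occluded"), c(n_functional, n_occluded))
  vals <- ifelse(cls == "functional", 0.05, 0.35)
  if (ntot > 0)
    for (i in seq_len(ntot))
      px <- fill_disk(px, centers[i, 1], centers[i, 2], centers[i, 3], vals[i])
  truth <- data.frame(
    center_row = if (ntot) centers[, 1] - 1 else numeric(0),
    center_col = if (ntot) centers[, 2] - 1 else numeric(0),
    radius_px = if (ntot) centers[, 3] else numeric(0),
    area_um2 = if (ntot) pi * (centers[, 3] * scale_um_per_px)^2 else numeric(0),
    class = cls, stringsAsFactors = FALSE)
  list(image = sem_image(px, scale_um_per_px, normalized = TRUE),
       truth = truth)
}

#' Mean desiccator temperatures (C) by elevation band
#' @export
default_station_temps <- function() c(lowland = 22.9, mid = 17.7, highland = 12.6)

#' Generate a full synthetic egg study with ground truth
#'
#' Builds everything the analysis pipeline consumes: a unit-height
#' pure-birth tree, band-sampled elevations, species-level log conductance
#' evolved under a low-signal lambda model with an additive elevation
#' effect, per-egg mass-loss series at station temperature, and egg
#' morphometry consistent with egg mass. Defaults emulate the Andean study
#' design: three elevation bands, balance noise 0.005 g, 8 daily
#' weighings, at most 3 eggs per species.
#'
#' @param n_species Number of species.
#' @param beta_per_km Elevation effect on log conductance (per km).
#' @param model,params Trait-evolution model and parameters for log G.
#' @param eggs_per_species Range (min, max) of eggs sampled per species.
#' @param days Daily weighings per egg.
#' @param noise_sd Balance noise sd (g).
#' @param bands Elevation bands.
#' @param station_temps Named band temperatures (C).
#' @param clustered_elevation Phylogenetically clustered elevations?
#' @param seed Optional RNG seed.
#' @return List: `tree`, `mass_df` (long format), `morph_df`, `species_meta`
#'   (species, family, station, elevation_m), `truth` (true log G, beta,
#'   model, params, per-species true G).
#' @export
simulate_egg_study <- function(n_species = 32, beta_per_km = -0.4,
                               model = "lambda",
                               params = list(sigma2 = 0.25, z0 = 0.65, lambda = 0.4),
                               eggs_per_species = c(1, 3), days = 8,
                               noise_sd = 0.005,
                               bands = default_elevation_bands(),
                               station_temps = default_station_temps(),
                               clustered_elevation = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_tree(n_species)
  elev <- assign_elevations(tree, bands = bands, clustered = clustered_elevation)
  band <- elevation_category(elev, bands)
  log_g <- simulate_trait(tree, model, params, elevation = elev,
                          beta = beta_per_km)
  true_g <- exp(log_g)
  temp_c <- unname(station_temps[as.character(band)])
  # egg mass ~ lognormal around 5 g; morphometry consistent with volume
  mass0 <- exp(stats::rnorm(n_species, log(5), 0.4))
  vol <- mass0 / 1.03                        # cm^3, density ~1.03 g/cm^3
  width <- (vol / (0.51 * 1.4))^(1 / 3)      # aspect ratio L/W = 1.4
  length_cm <- 1.4 * width
  # fake family labels: contiguous clades of ~4 species for subset analyses
  fam <- paste0("fam", ceiling(match(tree$tip.label, tree$tip.label) / 4))
  n_eggs <- sample(eggs_per_species[1]:eggs_per_species[2], n_species,
                   replace = TRUE)
  mass_rows <- vector("list", sum(n_eggs))
  k <- 0
  for (i in seq_len(n_species)) {
    dp <- saturation_vapor_pressure(temp_c[i])
    for (e in seq_len(n_eggs[i])) {
      k <- k + 1
      ser <- simulate_mass_series(true_g[i], delta_p = dp, m0 = mass0[i],
                                  days = days, noise_sd = noise_sd)
      mass_rows[[k]] <- data.frame(
        egg_id = sprintf("%s_e%d", tree$tip.label[i], e),
        species = tree$tip.label[i],
        station = as.character(band[i]), elevation_m = unname(elev[i]),
        temp_c = temp_c[i], day = ser$day, mass_g = ser$mass_g,
        stringsAsFactors = FALSE)
    }
  }
  list(
    tree = tree,
    mass_df = do.call(rbind, mass_rows),
    morph_df = data.frame(species = tree$tip.label, length_cm = length_cm,
                          width_cm = width, mass_g = mass0,
                          stringsAsFactors = FALSE),
    species_meta = data.frame(species = tree$tip.label, family = fam,
                              station = as.character(band),
                              elevation_m = unname(elev),
                              stringsAsFactors = FALSE),
    truth = list(log_g = log_g, true_g = true_g, beta_per_km = beta_per_km,
                 model = model, params = params, elevation = elev))
}
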