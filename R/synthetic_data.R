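#' Logistic recovery curve
#'
#' Fraction of recovery toward the natural-reference state at a given
#' restoration age, on the same logistic family that the succession module
#' fits: \eqn{1 / (1 + e^{-rate (age - midpoint)})}.
#'
#' @param age restoration age in years (vectorised).
#' @param rate logistic rate, 1/years; must be > 0.
#' @param midpoint age of half-recovery, years.
#' @return recovery fraction in (0, 1), strictly increasing in `age`.
#' @examples
#' recovery_curve(5, rate = 0.8, midpoint = 3)  # 1 / (1 + exp(-1.6))
#' @export
recovery_curve <- function(age, rate, midpoint) {
  stopifnot(rate > 0)
  stats::plogis(rate * (age - midpoint))
}

#' Default soil-indicator parameters for the chronosequence generator
#'
#' Reference and freshly disturbed means for the nine soil properties of a
#' semi-arid mine-dump chronosequence, with per-indicator logistic recovery
#' rates and plot-level Gaussian noise SDs. Units: SMC %, BD g/cm3, pH
#' (unitless), TS g/kg, OM g/kg, TN g/kg, AN/AP/AK mg/kg. pH and bulk
#' density decrease during recovery (disturbance compacts soil and raises
#' alkalinity); everything else increases.
#'
#' @return data.frame with columns `indicator`, `reference_mean`,
#'   `disturbed_mean`, `recovery_rate`, `midpoint`, `noise_sd`.
#' @export
default_soil_params <- function() {
  data.frame(
    indicator      = c("SMC", "BD", "pH", "TS", "OM", "TN", "AN", "AP", "AK"),
    reference_mean = c(14,    1.25, 8.05, 0.60, 20,   1.0,  60,   6,    150),
    disturbed_mean = c(7,     1.55, 8.31, 0.30, 6,    0.30, 10,   3,    60),
    recovery_rate  = rep(0.8, 9),
    midpoint       = rep(2.5, 9),
    noise_sd       = c(0.8,  0.05, 0.06, 0.04, 1.2,  0.07, 4.5,  0.4,  8),
    stringsAsFactors = FALSE
  )
}

#' Default vegetation parameters for the chronosequence generator
#'
#' @return list with reference/disturbed species richness and total
#'   abundance, logistic recovery rate and midpoint, and the
#'   Dirichlet-multinomial dispersion of plot-level abundances.
#' @export
default_veg_params <- function() {
  list(reference_richness = 18, disturbed_richness = 4,
       reference_abundance = 150, disturbed_abundance = 25,
       recovery_rate = 0.8, midpoint = 2.5,
       abundance_dispersion = 30)
}

#' Build and validate a chronosequence simulation configuration
#'
#' The configuration fixes the design of the synthetic study: a set of mines,
#' each with restoration sites of different ages plus one natural reference
#' site, replicated plots per site, and latent logistic recovery of soil
#' properties and vegetation toward reference values.
#'
#' @param n_mines number of mines.
#' @param ages restoration ages in years for the restoration sites of each
#'   mine (the natural reference is added automatically).
#' @param plots_per_site replicate plots per site (>= 2).
#' @param species_pool_size size of the ranked regional species pool.
#' @param soil_params data.frame as [default_soil_params()].
#' @param veg_params list as [default_veg_params()].
#' @param seed integer RNG seed.
#' @return validated list of class `"sim_config"`.
#' @export
simulation_config <- function(n_mines = 3,
                              ages = c(0.5, 1, 2, 3, 4),
                              plots_per_site = 3,
                              species_pool_size = 30,
                              soil_params = default_soil_params(),
                              veg_params = default_veg_params(),
                              seed = 1L) {
  stopifnot(n_mines >= 1, length(ages) >= 1, all(ages >= 0),
            plots_per_site >= 2, species_pool_size >= 1)
  if (any(soil_params$noise_sd < 0))
    stop("noise_sd must be >= 0", call. = FALSE)
  if (any(soil_params$recovery_rate <= 0) || veg_params$recovery_rate <= 0)
    stop("recovery rates must be > 0", call. = FALSE)
  if (all(soil_params$reference_mean == soil_params$disturbed_mean))
    stop("at least one soil indicator must have a disturbed/reference trend",
         call. = FALSE)
  if (max(veg_params$reference_richness, veg_params$disturbed_richness) >
      species_pool_size)
    stop("richness exceeds species_pool_size", call. = FALSE)
  structure(list(n_mines = n_mines, ages = sort(ages),
                 plots_per_site = plots_per_site,
                 species_pool_size = species_pool_size,
                 soil_params = soil_params, veg_params = veg_params,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Dirichlet draw via normalised gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a mine-dump restoration chronosequence
#'
#' Generates the three study tables (sites, long-format vegetation census,
#' wide-format soil properties) under a latent logistic recovery trajectory.
#' Soil indicator means at age t interpolate between the disturbed and
#' reference means along [recovery_curve()]; plot values add Gaussian noise
#' (truncated at zero for physically non-negative indicators, with the
#' truncation rate recorded). Species richness interpolates along the same
#' latent curve over a ranked species pool (common species enter first) and
#' abundances are Dirichlet-multinomial with configurable dispersion.
#' Natural-reference sites sample the reference state itself.
#'
#' @param config a [simulation_config()].
#' @return list of class `"chronosequence"`: `sites` (site_id, mine_id, age,
#'   is_reference), `vegetation` (plot_id, site_id, species, count), `soil`
#'   (plot_id, site_id + one column per indicator), `latent` (site_id, age,
#'   recovery — the true trajectory, retained for parameter-recovery tests),
#'   `truncation_rate`, and the `config`.
#' @export
simulate_chronosequence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sp <- config$soil_params
  vp <- config$veg_params
  pool <- sprintf("sp%02d", seq_len(config$species_pool_size))
  # ranked geometric relative-abundance profile over the pool
  base_p <- 0.75^(seq_len(config$species_pool_size) - 1)

  sites <- list(); soil <- list(); veg <- list(); latent <- list()
  n_trunc <- 0L; n_draw <- 0L
  for (m in seq_len(config$n_mines)) {
    mine_id <- sprintf("M%d", m)
    age_vec <- c(config$ages, NA_real_)  # NA = natural reference
    for (k in seq_along(age_vec)) {
      age <- age_vec[k]
      is_ref <- is.na(age)
      site_id <- if (is_ref) sprintf("%s-NA", mine_id) else
        sprintf("%s-RA%04.1f", mine_id, age)
      rec_soil <- if (is_ref) rep(1, nrow(sp)) else
        recovery_curve(age, sp$recovery_rate, sp$midpoint)
      rec_veg <- if (is_ref) 1 else
        recovery_curve(age, vp$recovery_rate, vp$midpoint)
      sites[[length(sites) + 1L]] <- data.frame(
        site_id = site_id, mine_id = mine_id, age = age,
        is_reference = is_ref)
      latent[[length(latent) + 1L]] <- data.frame(
        site_id = site_id, mine_id = mine_id, age = age, recovery = rec_veg)

      soil_mean <- sp$disturbed_mean +
        (sp$reference_mean - sp$disturbed_mean) * rec_soil
      richness <- as.integer(round(vp$disturbed_richness +
        (vp$reference_richness - vp$disturbed_richness) * rec_veg))
      richness <- max(1L, min(richness, config$species_pool_size))
      abund <- max(richness, as.integer(round(vp$disturbed_abundance +
        (vp$reference_abundance - vp$disturbed_abundance) * rec_veg)))

      for (pl in seq_len(config$plots_per_site)) {
        plot_id <- sprintf("%s-P%d", site_id, pl)
        vals <- stats::rnorm(nrow(sp), soil_mean, sp$noise_sd)
        n_draw <- n_draw + length(vals)
        n_trunc <- n_trunc + sum(vals < 0)
        vals <- pmax(vals, 0)
        row <- as.data.frame(as.list(stats::setNames(vals, sp$indicator)))
        soil[[length(soil) + 1L]] <- cbind(
          data.frame(plot_id = plot_id, site_id = site_id), row)

        p <- base_p[seq_len(richness)]
        p <- p / sum(p)
        w <- rdirichlet1(vp$abundance_dispersion * p)
        counts <- as.vector(stats::rmultinom(1, size = abund, prob = w))
        keep <- counts > 0
        veg[[length(veg) + 1L]] <- data.frame(
          plot_id = plot_id, site_id = site_id,
          species = pool[seq_len(richness)][keep], count = counts[keep])
      }
    }
  }
  structure(list(
    sites = do.call(rbind, sites),
    vegetation = do.call(rbind, veg),
    soil = do.call(rbind, soil),
    latent = do.call(rbind, latent),
    truncation_rate = n_trunc / n_draw,
    config = config), class = "chronosequence")
}

#' Write a chronosequence dataset as three CSV tables
#'
#' Writes `sites.csv`, `vegetation.csv` (long format) and `soil.csv` (wide
#' format) in a plain UTF-8/comma/'.'-decimal dialect.
#'
#' @param dataset a `"chronosequence"` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_chronosequence <- function(dataset, dir) {
  stopifnot(inherits(dataset, "chronosequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("sites.csv", "vegetation.csv", "soil.csv"))
  utils::write.csv(dataset$sites, paths[1], row.names = FALSE)
  utils::write.csv(dataset$vegetation, paths[2], row.names = FALSE)
  utils::write.csv(dataset$soil, paths[3], row.names = FALSE)
  invisible(paths)
}
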