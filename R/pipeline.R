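#' Validate the three chronosequence input tables
#'
#' Schema and referential-integrity checks on the sites, vegetation and
#' soil tables: required columns, positive counts, numeric soil values, and
#' plot/site cross-references. Report-only — never throws.
#'
#' @param sites,vegetation,soil data.frames (or paths to their CSV files).
#' @return data.frame of violations (`table`, `message`); zero rows when
#'   everything checks out.
#' @export
validate_inputs <- function(sites, vegetation, soil) {
  read_maybe <- function(x) {
    if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  }
  sites <- read_maybe(sites); vegetation <- read_maybe(vegetation)
  soil <- read_maybe(soil)
  v <- list()
  add <- function(tab, msg) v[[length(v) + 1L]] <<- data.frame(
    table = tab, message = msg)

  for (col in c("site_id", "mine_id", "age", "is_reference"))
    if (!col %in% names(sites)) add("sites", paste("missing column", col))
  for (col in c("plot_id", "site_id", "species", "count"))
    if (!col %in% names(vegetation))
      add("vegetation", paste("missing column", col))
  for (col in c("plot_id", "site_id"))
    if (!col %in% names(soil)) add("soil", paste("missing column", col))

  if ("count" %in% names(vegetation)) {
    if (!is.numeric(vegetation$count)) {
      add("vegetation", "counts must be numeric")
    } else if (any(vegetation$count <= 0, na.rm = TRUE)) {
      add("vegetation", "counts must be positive")
    }
  }
  soil_cols <- setdiff(names(soil), c("plot_id", "site_id"))
  if (length(soil_cols) == 0L) add("soil", "no indicator columns")
  for (col in soil_cols)
    if (!is.numeric(soil[[col]]))
      add("soil", paste("indicator column", col, "must be numeric"))

  if (all(c("site_id") %in% names(sites))) {
    if ("site_id" %in% names(vegetation)) {
      bad <- setdiff(vegetation$site_id, sites$site_id)
      if (length(bad))
        add("vegetation", paste("site_id not in sites table:",
                                paste(sort(bad), collapse = ", ")))
    }
    if ("site_id" %in% names(soil)) {
      bad <- setdiff(soil$site_id, sites$site_id)
      if (length(bad))
        add("soil", paste("site_id not in sites table:",
                          paste(sort(bad), collapse = ", ")))
    }
  }
  if (all(c("plot_id", "site_id") %in% names(vegetation))) {
    multi <- unique(vegetation[c("plot_id", "site_id")])
    dup <- multi$plot_id[duplicated(multi$plot_id)]
    if (length(dup))
      add("vegetation", paste("plot assigned to multiple sites:",
                              paste(sort(unique(dup)), collapse = ", ")))
  }
  if (length(v) == 0L)
    return(data.frame(table = character(), message = character()))
  do.call(rbind, v)
}

#' Run the full restoration-assessment pipeline
#'
#' Orchestrates simulate (or load) -> diversity -> group letters ->
#' redundancy analysis -> stability -> succession as one reproducible run.
#' Every stage's table is written as CSV under `outdir`, together with a
#' JSON manifest that records the full configuration, seed, package
#' version and the decision settings actually exercised (entropy epsilon,
#' coordination variant, polarities, truncation rate), so a run can be
#' reconstructed exactly.
#'
#' @param config either a `"sim_config"` (data are simulated) or a list
#'   with `sites`, `vegetation`, `soil` paths to CSV inputs.
#' @param outdir output directory.
#' @param seed integer seed (overrides the config's for simulation and is
#'   used for the permutation tests).
#' @param n_permutations Monte Carlo permutations for the RDA test
#'   (>= 99; default 499).
#' @param alpha significance level for the letter displays.
#' @param variant coordination-degree variant.
#' @return invisibly, the manifest list.
#' @export
run_all <- function(config = simulation_config(), outdir, seed = 1L,
                    n_permutations = 499, alpha = 0.05,
                    variant = c("sqrt", "product")) {
  variant <- match.arg(variant)
  if (n_permutations < 99) stop("n_permutations must be >= 99", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()

  if (inherits(config, "sim_config")) {
    config$seed <- as.integer(seed)
    dataset <- simulate_chronosequence(config)
    write_chronosequence(dataset, outdir)
    if (dataset$truncation_rate > 0)
      warnings_log <- c(warnings_log, sprintf(
        "soil noise truncated at 0 in %.2f%% of draws",
        100 * dataset$truncation_rate))
  } else {
    for (p in unlist(config[c("sites", "vegetation", "soil")]))
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    report <- validate_inputs(config$sites, config$vegetation, config$soil)
    if (nrow(report) > 0L)
      stop("input validation failed:\n",
           paste(report$table, report$message, sep = ": ", collapse = "\n"),
           call. = FALSE)
    dataset <- list(
      sites = utils::read.csv(config$sites, stringsAsFactors = FALSE),
      vegetation = utils::read.csv(config$vegetation,
                                   stringsAsFactors = FALSE),
      soil = utils::read.csv(config$soil, stringsAsFactors = FALSE))
    dataset$sites$is_reference <- as.logical(dataset$sites$is_reference)
  }

  # diversity, per plot and per site
  div_plot <- diversity_table(dataset$vegetation, level = "plot")
  div_site <- diversity_table(dataset$vegetation, level = "site")
  utils::write.csv(div_plot, file.path(outdir, "diversity.csv"),
                   row.names = FALSE)

  # significance letters per mine and variable (diversity + soil)
  soil_cols <- setdiff(names(dataset$soil), c("plot_id", "site_id"))
  idx_cols <- c("SP", "NP", "shannon", "simpson", "pielou", "margalef")
  site2mine <- dataset$sites$mine_id[match(div_plot$site_id,
                                           dataset$sites$site_id)]
  letters_out <- list()
  for (mine in unique(dataset$sites$mine_id)) {
    dsub <- div_plot[site2mine == mine, ]
    ssub <- dataset$soil[dataset$soil$site_id %in%
                           dataset$sites$site_id[
                             dataset$sites$mine_id == mine], ]
    for (v in idx_cols) {
      gl <- group_letters(dsub[[v]], dsub$site_id, alpha = alpha)
      letters_out[[length(letters_out) + 1L]] <-
        cbind(mine_id = mine, variable = v, gl)
    }
    for (v in soil_cols) {
      gl <- group_letters(ssub[[v]], ssub$site_id, alpha = alpha)
      letters_out[[length(letters_out) + 1L]] <-
        cbind(mine_id = mine, variable = v, gl)
    }
  }
  letters_df <- do.call(rbind, letters_out)
  utils::write.csv(letters_df, file.path(outdir, "letters.csv"),
                   row.names = FALSE)

  # RDA per mine on plot rows
  ord_rows <- list(); score_rows <- list()
  for (mine in unique(dataset$sites$mine_id)) {
    keep <- site2mine == mine
    dsub <- div_plot[keep, ]
    ssub <- dataset$soil[match(dsub$plot_id, dataset$soil$plot_id), ]
    Y <- as.matrix(dsub[idx_cols])
    X <- as.matrix(ssub[soil_cols])
    rownames(Y) <- rownames(X) <- dsub$plot_id
    fit <- rda_fit(Y, X)
    pt <- permutation_test(Y, X, n_permutations = n_permutations,
                           seed = seed)
    ref_site <- dataset$sites$site_id[dataset$sites$mine_id == mine &
                                        dataset$sites$is_reference]
    dists <- reference_distance(fit, dsub$site_id, ref_site)
    ord_rows[[mine]] <- data.frame(
      mine_id = mine, variance_explained = fit$variance_explained,
      pseudo_F = pt$F, p = pt$p, n_permutations = n_permutations)
    score_rows[[mine]] <- data.frame(
      mine_id = mine, site_id = names(dists), ref_distance = unname(dists))
  }
  utils::write.csv(do.call(rbind, ord_rows),
                   file.path(outdir, "ordination_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, score_rows),
                   file.path(outdir, "ordination_scores.csv"),
                   row.names = FALSE)

  # stability and succession
  stab <- stability_pipeline(dataset, variant = variant)
  utils::write.csv(stab, file.path(outdir, "stability.csv"),
                   row.names = FALSE)
  succ <- succession_table(stab)
  utils::write.csv(succ, file.path(outdir, "succession_fit.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ecostab")),
    seed = seed,
    n_permutations = n_permutations,
    alpha = alpha,
    coordination_variant = variant,
    entropy_eps = 1e-6,
    soil_cost_indicators = c("pH", "BD"),
    config = if (inherits(config, "sim_config"))
      unclass(config) else config,
    outputs = c("sites.csv", "vegetation.csv", "soil.csv", "diversity.csv",
                "letters.csv", "ordination_tests.csv",
                "ordination_scores.csv", "stability.csv",
                "succession_fit.csv"),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
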