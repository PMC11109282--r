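# End-to-end orchestration: simulate -> covariables -> envirotyping ->
# ANOVA -> per-year GGE -> consensus, with CSV outputs and a JSON
# manifest recording seeds, configuration and output hashes.

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param n_years,start_year Weather simulation span.
#' @param trial_years Calendar years with trials; each gets its own GGE
#'   analysis (defaults to the last three simulated years).
#' @param n_genotypes Genotype count per trial year (recycled).
#' @param n_reps Replicates per trial.
#' @param k Number of mega-environments for every clustering stage.
#' @param svp SVP mode for the which-won-where view.
#' @param sites Site table (default [default_sites()]).
#' @param windows Crop-cycle [window_spec()].
#' @param make_plots Write figure files alongside their coordinate CSVs.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, n_years = 20, start_year = 2002,
                       trial_years = NULL, n_genotypes = c(41, 30, 48),
                       n_reps = 3, k = 4, svp = "symmetric",
                       sites = default_sites(),
                       windows = default_windows(), make_plots = FALSE) {
  if (is.null(trial_years)) {
    trial_years <- (start_year + n_years - 3):(start_year + n_years - 1)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_years = n_years, start_year = start_year,
                 trial_years = trial_years,
                 n_genotypes = rep_len(n_genotypes, length(trial_years)),
                 n_reps = n_reps, k = k, svp = svp, sites = sites,
                 windows = windows, make_plots = make_plots),
            class = "run_config")
}

write_stage_csv <- function(x, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# megaenv output; seed=%d", seed), con)
  utils::write.csv(x, con, row.names = FALSE)
  path
}

#' Run the full mega-environment delineation pipeline
#'
#' Simulates the study inputs (19 sites, daily weather, per-year trials),
#' derives the 19 covariables, builds W and the enviromic kernel, clusters
#' sites into envirotype MEs, runs the joint RCBD ANOVA and a GGE analysis
#' per trial year, and merges all partitions into consensus MEs. All
#' tables are written as CSV under `config$out_dir`; a JSON manifest
#' records the configuration, seeds and MD5 hashes of every output.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`partitions`,
#'   `consensus`, `anova`, `kernel`, `w`, `pca`, ...) and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  sites <- config$sites
  message("simulate: ", nrow(sites), " sites, ", config$n_years,
          " years of daily weather")
  wx <- gen_daily_weather(sites, weather_config(
    n_years = config$n_years, start_year = config$start_year, seed = seed))
  message("covariables: deriving 19-covariable panels")
  stats_all <- dplyr::bind_rows(lapply(seq_len(nrow(sites)), function(i) {
    panel <- compute_panel(wx[wx$SITE == sites$code[i], ],
                           lat = sites$lat[i])
    window_means(panel, config$windows)
  }))
  message("envirotyping: W matrix, kernel, clustering")
  w <- build_w(stats_all)
  kernel <- enviromic_kernel(w)
  dist <- kernel_to_distance(kernel)
  env_part <- cluster_environments(dist, k = config$k,
                                   method = "envirotype")
  env_sum <- env_covariable_summary(stats_all)
  trials <- list(); anovas <- list(); gge_parts <- list()
  dr <- list(); www_list <- list()
  env_mean_yield <- NULL
  for (i in seq_along(config$trial_years)) {
    yr <- config$trial_years[i]
    cfg <- trial_config(n_genotypes = config$n_genotypes[i],
                        n_envs = nrow(sites), n_reps = config$n_reps,
                        me_assignment = stats::setNames(
                          sites |> merge_archetype_ids(), sites$code),
                        winner_bonus = 1500,
                        env_codes = sites$code,
                        seed = (seed + i) %% .Machine$integer.max)
    trial <- gen_trial_yields(cfg)
    message("trial ", yr, ": ", config$n_genotypes[i], " genotypes; ANOVA + GGE")
    anovas[[as.character(yr)]] <- anova_joint(trial)
    model <- fit_gge(ge_means(trial), svp = config$svp)
    www_list[[as.character(yr)]] <- which_won_where(model)
    dr[[as.character(yr)]] <- discrim_vs_repres(model)
    gge_parts[[as.character(yr)]] <-
      env_similarity_groups(model, k = config$k,
                            method = paste0("gge-", yr))
    trials[[as.character(yr)]] <- trial
    m <- colMeans(ge_means(trial))
    env_mean_yield <- if (is.null(env_mean_yield)) m else env_mean_yield + m
  }
  env_mean_yield <- env_mean_yield / length(config$trial_years)
  pca <- pca_covariables(env_sum, yield = env_mean_yield)
  message("consensus: merging ", 1 + length(gge_parts), " partitions")
  consensus <- propose_mes(c(list(env_part), unname(gge_parts)),
                           k = config$k, anchor = env_part)
  # ---- outputs -------------------------------------------------------
  files <- character(0)
  add <- function(x, name) {
    p <- file.path(config$out_dir, name)
    files[[name]] <<- write_stage_csv(x, p, seed)
    p
  }
  wm <- as.data.frame(w$W); wm <- cbind(SITE = rownames(w$W), wm)
  add(wm, "w_matrix.csv")
  km <- as.data.frame(kernel$K); km <- cbind(SITE = kernel$env_codes, km)
  add(km, "kernel.csv")
  add(partition_df(env_part), "partition_envirotype.csv")
  for (yr in names(gge_parts)) {
    add(partition_df(gge_parts[[yr]]), paste0("partition_gge_", yr, ".csv"))
    add(as.data.frame(anovas[[yr]]), paste0("anova_", yr, ".csv"))
    add(as.data.frame(dr[[yr]]), paste0("discrim_repres_", yr, ".csv"))
  }
  add(partition_df(consensus$proposed), "partition_consensus.csv")
  co <- as.data.frame(consensus$co_membership)
  add(cbind(SITE = rownames(consensus$co_membership), co),
      "co_membership.csv")
  contrib <- data.frame(COVARIABLE = rownames(pca$contributions),
                        PC1 = pca$contributions[, 1],
                        PC2 = pca$contributions[, 2],
                        PC12 = pca$contrib_pc12)
  add(contrib, "pca_contributions.csv")
  if (config$make_plots) {
    ggplot2::ggsave(file.path(config$out_dir, "kernel_heatmap.pdf"),
                    plot_kernel_heatmap(kernel, env_part),
                    width = 7, height = 6)
    for (yr in names(www_list)) {
      ggplot2::ggsave(file.path(config$out_dir,
                                paste0("gge_biplot_", yr, ".pdf")),
                      plot_gge_biplot(www_list[[yr]],
                                      fit_gge(ge_means(trials[[yr]]),
                                              svp = config$svp)),
                      width = 7, height = 6)
    }
  }
  manifest <- list(
    package = "megaenv",
    version = as.character(utils::packageVersion("megaenv")),
    seed = seed, k = config$k, svp = config$svp,
    n_years = config$n_years, start_year = config$start_year,
    trial_years = config$trial_years, n_genotypes = config$n_genotypes,
    outputs = lapply(files, function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(w = w, kernel = kernel, envirotype = env_part,
                 gge = gge_parts, www = www_list, anova = anovas,
                 dr = dr, pca = pca, consensus = consensus,
                 trials = trials, manifest = manifest))
}

merge_archetype_ids <- function(sites) {
  as.integer(factor(sites$archetype, levels = unique(sites$archetype)))
}

partition_df <- function(p) {
  data.frame(SITE = names(p$assignment), ME = unname(p$assignment))
}

#' Validate pipeline input files
#'
#' Schema and coverage checks for the three CSV dialects: daily weather
#' (NASA-POWER columns), site metadata, and long trial yields. Returns a
#' report rather than erroring, so all problems surface at once.
#'
#' @param weather,sites,trial Optional paths to CSV files.
#' @param windows [window_spec()] used for coverage checks.
#' @return Tibble with columns `input`, `check`, `ok`, `detail`; an empty
#'   `ok == FALSE` subset means the bundle is valid.
#' @export
validate_inputs <- function(weather = NULL, sites = NULL, trial = NULL,
                            windows = default_windows()) {
  rep_rows <- list()
  note <- function(input, check, ok, detail = "") {
    rep_rows[[length(rep_rows) + 1]] <<-
      tibble::tibble(input = input, check = check, ok = ok, detail = detail)
  }
  read1 <- function(p) utils::read.csv(p, comment.char = "#",
                                       check.names = FALSE)
  if (!is.null(sites)) {
    if (!file.exists(sites)) note("sites", "exists", FALSE, sites)
    else {
      s <- read1(sites)
      need <- c("code", "lon", "lat", "alt")
      miss <- setdiff(need, names(s))
      note("sites", "schema", length(miss) == 0,
           paste(miss, collapse = ", "))
      if (length(miss) == 0) {
        note("sites", "unique codes", !anyDuplicated(s$code), "")
        note("sites", "lat range", all(abs(s$lat) <= 90), "")
        note("sites", "lon range", all(abs(s$lon) <= 180), "")
      }
    }
  }
  if (!is.null(weather)) {
    if (!file.exists(weather)) note("weather", "exists", FALSE, weather)
    else {
      wx <- read1(weather)
      need <- c("SITE", "DATE", "T2M", "T2M_MAX", "T2M_MIN", "PRECTOTCORR",
                "WS2M", "RH2M", "T2MDEW", "ALLSKY_SFC_LW_DWN",
                "ALLSKY_SFC_SW_DWN")
      miss <- setdiff(need, names(wx))
      note("weather", "schema", length(miss) == 0,
           paste(miss, collapse = ", "))
      if (length(miss) == 0) {
        wx$DATE <- as.Date(wx$DATE)
        md <- format(wx$DATE, "%m-%d")
        yr <- as.integer(format(wx$DATE, "%Y"))
        for (site in unique(wx$SITE)) {
          for (y in unique(yr[wx$SITE == site])) {
            for (i in seq_len(nrow(windows))) {
              sel <- wx$SITE == site & yr == y &
                md >= windows$start[i] & md <= windows$end[i]
              if (!any(sel)) {
                note("weather", "window coverage", FALSE,
                     sprintf("site %s, year %d, window %s", site, y,
                             windows$label[i]))
              }
            }
          }
        }
        note("weather", "Tmax >= Tmin", all(wx$T2M_MAX >= wx$T2M_MIN), "")
      }
    }
  }
  if (!is.null(trial)) {
    if (!file.exists(trial)) note("trial", "exists", FALSE, trial)
    else {
      tr <- read1(trial)
      need <- c("GEN", "ENV", "REP", "GY_KG_HA")
      miss <- setdiff(need, names(tr))
      note("trial", "schema", length(miss) == 0,
           paste(miss, collapse = ", "))
      if (length(miss) == 0) {
        bal <- tryCatch({check_balanced(tr); TRUE},
                        error = function(e) conditionMessage(e))
        note("trial", "balanced", isTRUE(bal),
             if (isTRUE(bal)) "" else bal)
        note("trial", "finite yields", all(is.finite(tr$GY_KG_HA)), "")
      }
    }
  }
  if (length(rep_rows) == 0) {
    return(tibble::tibble(input = character(), check = character(),
                          ok = logical(), detail = character()))
  }
  dplyr::bind_rows(rep_rows)
}
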