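# Seeded generators for the study's three inputs: site metadata, daily
# weather in the NASA-POWER agroclimatology dialect, and balanced RCBD
# multi-environment trial yields.

#' Reference site table for the 19-location soybean trial network
#'
#' Site metadata (code, longitude, latitude, altitude, ecosystem) for the
#' nineteen AICRP soybean test locations, with each site assigned to one of
#' four climate archetypes sized 4/8/2/5. The archetypes drive the synthetic
#' weather generator and act as planted truth for clustering checks.
#'
#' @return A tibble with columns `code`, `location`, `lon`, `lat`, `alt`,
#'   `ecosystem`, `archetype`.
#' @export
#' @examples
#' default_sites()
default_sites <- function() {
  tibble::tribble(
    ~code, ~location,       ~lon,   ~lat,    ~alt, ~ecosystem,  ~archetype,
    "ALM", "Almora",        79.646, 29.589, 1642, "Sub humid", "humid_highland",
    "AML", "Amreli",        71.220, 21.602,  128, "Semiarid",  "semiarid_plains",
    "AND", "Anand",         72.928, 22.564,   39, "Semiarid",  "semiarid_plains",
    "BDR", "Bidar",         77.519, 17.910,  710, "Semiarid",  "semiarid_plains",
    "BNG", "Bengaluru",     77.569, 13.081,  919, "Semiarid",  "semiarid_south",
    "BPN", "Bhawanipatna",  83.164, 19.907,  248, "Sub humid", "semiarid_plains",
    "DWD", "Dharwad",       75.007, 15.458,  750, "Semiarid",  "semiarid_south",
    "IMP", "Imphal",        94.052, 24.764,  821, "Humid",     "humid_highland",
    "KDR", "Kasbedigraj",   74.514, 16.907,  554, "Semiarid",  "semiarid_south",
    "KTA", "Kota",          75.864, 25.213,  271, "Semiarid",  "arid_north",
    "LKB", "Lokbharti",     71.764, 21.721,   67, "Semiarid",  "semiarid_plains",
    "MJH", "Mojhera",       79.474, 29.507,  888, "Humid",     "humid_highland",
    "MRN", "Morena",        77.994, 26.494,  177, "Semiarid",  "arid_north",
    "PBN", "Parbhani",      76.785, 19.240,  390, "Semiarid",  "semiarid_plains",
    "PLM", "Palampur",      76.545, 32.096, 1244, "Humid",     "humid_highland",
    "PUN", "Pune",          74.306, 18.119,  556, "Semiarid",  "semiarid_south",
    "RNC", "Ranchi",        85.309, 23.344,  651, "Humid",     "semiarid_plains",
    "RPR", "Raipur",        81.717, 21.228,  293, "Sub humid", "semiarid_plains",
    "UMM", "Umiam",         91.545, 25.418, 1520, "Humid",     "humid_highland"
  )
}

#' Default climate-archetype parameters for the weather generator
#'
#' Four archetypes spanning the trial network's climates. Per raw variable
#' each archetype holds a mean, an annual-sinusoid amplitude and a noise
#' standard deviation; rainfall uses a two-part model (wet-day probability
#' with a monsoon bump, gamma amounts). Means are chosen so June-October
#' window means separate the archetypes well beyond within-archetype noise.
#'
#' @return Named list of archetype parameter lists, each with elements
#'   `vars` (named list of `c(mean, amp, sd)` per raw variable) and
#'   `precip` (`wet_p`, `monsoon_boost`, `gamma_shape`, `gamma_mean`).
#' @export
default_archetypes <- function() {
  v <- function(mean, amp, sd) c(mean = mean, amp = amp, sd = sd)
  list(
    semiarid_south = list(
      vars = list(
        T2M = v(24, 3, 1.2), T2M_MAX = v(29, 4, 1.5), T2M_MIN = v(19, 3, 1.2),
        WS2M = v(3.5, 0.8, 0.5), RH2M = v(70, 10, 5), T2MDEW = v(18, 3, 1.2),
        ALLSKY_SFC_LW_DWN = v(38, 2, 1.5), ALLSKY_SFC_SW_DWN = v(18, 3, 2)
      ),
      precip = list(wet_p = 0.25, monsoon_boost = 0.35,
                    gamma_shape = 0.9, gamma_mean = 8)
    ),
    semiarid_plains = list(
      vars = list(
        T2M = v(27, 5, 1.4), T2M_MAX = v(33, 5, 1.6), T2M_MIN = v(22, 5, 1.3),
        WS2M = v(3.0, 0.8, 0.5), RH2M = v(62, 12, 5), T2MDEW = v(20, 4, 1.3),
        ALLSKY_SFC_LW_DWN = v(40, 2, 1.5), ALLSKY_SFC_SW_DWN = v(19, 3, 2)
      ),
      precip = list(wet_p = 0.15, monsoon_boost = 0.40,
                    gamma_shape = 0.8, gamma_mean = 10)
    ),
    arid_north = list(
      vars = list(
        T2M = v(28, 9, 1.6), T2M_MAX = v(36, 9, 1.8), T2M_MIN = v(21, 9, 1.5),
        WS2M = v(2.5, 0.7, 0.5), RH2M = v(45, 15, 6), T2MDEW = v(14, 5, 1.5),
        ALLSKY_SFC_LW_DWN = v(41, 3, 1.5), ALLSKY_SFC_SW_DWN = v(22, 4, 2)
      ),
      precip = list(wet_p = 0.08, monsoon_boost = 0.30,
                    gamma_shape = 0.8, gamma_mean = 9)
    ),
    humid_highland = list(
      vars = list(
        T2M = v(20, 7, 1.3), T2M_MAX = v(25, 7, 1.5), T2M_MIN = v(15, 7, 1.2),
        WS2M = v(1.8, 0.5, 0.4), RH2M = v(85, 8, 4), T2MDEW = v(17, 6, 1.2),
        ALLSKY_SFC_LW_DWN = v(35, 3, 1.5), ALLSKY_SFC_SW_DWN = v(14, 3, 2)
      ),
      precip = list(wet_p = 0.35, monsoon_boost = 0.40,
                    gamma_shape = 1.0, gamma_mean = 12)
    )
  )
}

raw_weather_vars <- function() {
  c("T2M", "T2M_MAX", "T2M_MIN", "WS2M", "RH2M", "T2MDEW",
    "ALLSKY_SFC_LW_DWN", "ALLSKY_SFC_SW_DWN")
}

#' Weather generator configuration
#'
#' @param n_years Number of calendar years to simulate.
#' @param start_year First calendar year.
#' @param archetypes Archetype parameter list as in [default_archetypes()].
#' @param ar1_rho Day-to-day AR(1) autocorrelation of the continuous
#'   variables, in `[0, 1)`.
#' @param seed Integer seed; all draws flow from it.
#' @return A validated `weather_config` list.
#' @export
weather_config <- function(n_years = 20, start_year = 2002,
                           archetypes = default_archetypes(),
                           ar1_rho = 0.6, seed = 1L) {
  stopifnot(n_years >= 1, ar1_rho >= 0, ar1_rho < 1)
  for (a in names(archetypes)) {
    pars <- archetypes[[a]]
    missing_vars <- setdiff(raw_weather_vars(), names(pars$vars))
    if (length(missing_vars) > 0) {
      stop("archetype '", a, "' lacks parameters for: ",
           paste(missing_vars, collapse = ", "), call. = FALSE)
    }
    if (pars$vars$T2M_MAX[["mean"]] < pars$vars$T2M_MIN[["mean"]]) {
      stop("archetype '", a, "': Tmax mean must be >= Tmin mean",
           call. = FALSE)
    }
    if (is.null(pars$precip)) {
      stop("archetype '", a, "' lacks precipitation parameters",
           call. = FALSE)
    }
  }
  structure(list(n_years = as.integer(n_years),
                 start_year = as.integer(start_year),
                 archetypes = archetypes, ar1_rho = ar1_rho,
                 seed = as.integer(seed)),
            class = "weather_config")
}

#' Generate trial sites assigned to climate archetypes
#'
#' With no `archetype_map` and `n_sites = 19` the study layout is returned
#' ([default_sites()]: 4 archetypes sized 4/8/2/5). Otherwise sites get
#' generated codes and coordinates, with archetype labels recycled from
#' `archetype_map` (or from the archetype names).
#'
#' @param n_sites Number of sites (>= 2).
#' @param archetype_map Optional character vector of archetype labels, one
#'   per site (recycled); names, if present, are used as site codes.
#' @param seed Integer seed for generated coordinates.
#' @param archetypes Archetype definitions the labels must belong to.
#' @return Tibble of site records (`code`, `lon`, `lat`, `alt`,
#'   `archetype`, ...).
#' @export
#' @examples
#' gen_sites(4, archetype_map = c("arid_north", "humid_highland"), seed = 1)
gen_sites <- function(n_sites = 19, archetype_map = NULL, seed = 1L,
                      archetypes = default_archetypes()) {
  stopifnot(n_sites >= 2)
  if (is.null(archetype_map)) {
    if (n_sites == 19) {
      sites <- default_sites()
      bad <- setdiff(unique(sites$archetype), names(archetypes))
      if (length(bad) > 0) {
        stop("unknown archetype label(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      return(sites)
    }
    archetype_map <- names(archetypes)
  }
  bad <- setdiff(unique(archetype_map), names(archetypes))
  if (length(bad) > 0) {
    stop("unknown archetype label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  labels <- rep_len(archetype_map, n_sites)
  codes <- if (!is.null(names(archetype_map)) &&
               length(archetype_map) == n_sites) {
    names(archetype_map)
  } else {
    sprintf("S%02d", seq_len(n_sites))
  }
  if (anyDuplicated(codes)) stop("site codes must be unique", call. = FALSE)
  withr::with_seed(seed, {
    tibble::tibble(
      code = codes,
      location = codes,
      lon = runif(n_sites, 68, 95),
      lat = runif(n_sites, 9, 33),
      alt = round(ifelse(labels == "humid_highland",
                         runif(n_sites, 800, 1700),
                         runif(n_sites, 30, 950))),
      ecosystem = NA_character_,
      archetype = labels
    )
  })
}

ar1_series <- function(n, sd, rho) {
  if (sd == 0) return(rep(0, n))
  innov <- rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

# Smooth monsoon weight peaking around early-mid July through September.
monsoon_weight <- function(doy) exp(-((doy - 200) / 55)^2)

#' Generate daily weather series for a set of sites
#'
#' Continuous variables follow an annual sinusoid (archetype mean and
#' amplitude, peak near the pre-monsoon maximum) plus AR(1) Gaussian noise;
#' rainfall is a two-part model (wet-day Bernoulli with a monsoon bump,
#' gamma amounts). Physical clamps: RH in `[0, 100]`, shortwave >= 0,
#' rainfall >= 0, and Tmax >= Tmin enforced by swapping.
#'
#' @param sites Site tibble from [gen_sites()] (needs `code`, `archetype`).
#' @param config A [weather_config()].
#' @return Tibble in the NASA-POWER daily dialect: `SITE`, `DATE`, `YEAR`,
#'   `DOY`, `YYYYMMDD`, `T2M`, `T2M_MAX`, `T2M_MIN`, `PRECTOTCORR`,
#'   `WS2M`, `RH2M`, `T2MDEW`, `ALLSKY_SFC_LW_DWN`, `ALLSKY_SFC_SW_DWN`.
#' @export
#' @examples
#' sites <- gen_sites(2, archetype_map = c("arid_north", "humid_highland"))
#' wx <- gen_daily_weather(sites, weather_config(n_years = 1, seed = 7))
#' range(wx$RH2M)
gen_daily_weather <- function(sites, config = weather_config()) {
  stopifnot(inherits(config, "weather_config"))
  bad <- setdiff(unique(sites$archetype), names(config$archetypes))
  if (length(bad) > 0) {
    stop("unknown archetype label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dates <- seq(as.Date(sprintf("%d-01-01", config$start_year)),
               as.Date(sprintf("%d-12-31",
                               config$start_year + config$n_years - 1)),
               by = "day")
  doy <- as.integer(strftime(dates, "%j"))
  year <- as.integer(strftime(dates, "%Y"))
  n <- length(dates)
  # Annual temperature cycle peaks pre-monsoon (~mid May) at these latitudes.
  seasonal <- cos(2 * pi * (doy - 135) / 365)
  withr::with_seed(config$seed, {
    out <- lapply(seq_len(nrow(sites)), function(i) {
      pars <- config$archetypes[[sites$archetype[i]]]
      cols <- lapply(raw_weather_vars(), function(vn) {
        p <- pars$vars[[vn]]
        p[["mean"]] + p[["amp"]] * seasonal +
          ar1_series(n, p[["sd"]], config$ar1_rho)
      })
      names(cols) <- raw_weather_vars()
      # enforce Tmax >= Tmin by swapping the offending days
      swap <- cols$T2M_MAX < cols$T2M_MIN
      if (any(swap)) {
        tmp <- cols$T2M_MAX[swap]
        cols$T2M_MAX[swap] <- cols$T2M_MIN[swap]
        cols$T2M_MIN[swap] <- tmp
      }
      cols$RH2M <- pmin(100, pmax(0, cols$RH2M))
      cols$ALLSKY_SFC_SW_DWN <- pmax(0, cols$ALLSKY_SFC_SW_DWN)
      cols$ALLSKY_SFC_LW_DWN <- pmax(0, cols$ALLSKY_SFC_LW_DWN)
      cols$WS2M <- pmax(0, cols$WS2M)
      pp <- pars$precip
      p_wet <- pmin(0.95, pmax(0, pp$wet_p + pp$monsoon_boost *
                                 monsoon_weight(doy)))
      wet <- rbinom(n, 1, p_wet)
      amount <- rgamma(n, shape = pp$gamma_shape,
                       scale = pp$gamma_mean / pp$gamma_shape)
      tibble::tibble(
        SITE = sites$code[i], DATE = dates, YEAR = year, DOY = doy,
        YYYYMMDD = format(dates, "%Y%m%d"),
        T2M = cols$T2M, T2M_MAX = cols$T2M_MAX, T2M_MIN = cols$T2M_MIN,
        PRECTOTCORR = wet * amount, WS2M = cols$WS2M, RH2M = cols$RH2M,
        T2MDEW = cols$T2MDEW,
        ALLSKY_SFC_LW_DWN = cols$ALLSKY_SFC_LW_DWN,
        ALLSKY_SFC_SW_DWN = cols$ALLSKY_SFC_SW_DWN
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Trial generator configuration
#'
#' Variance components are on the yield scale (kg/ha)^2. Block effects are
#' nested within environments with variance `var_B` (default
#' `0.01 * var_eps`, i.e. negligible blocks).
#'
#' @param n_genotypes,n_envs,n_reps Design dimensions (`n_reps >= 2`).
#' @param mu Grand mean yield, kg/ha.
#' @param var_G,var_E,var_GE,var_eps Variance components, (kg/ha)^2.
#'   Defaults mirror the variance shares typical of rain-fed soybean MET
#'   networks (environment ~55%, GEI ~30%, genotype ~7% of total SS).
#' @param var_B Block-within-environment variance.
#' @param me_assignment Optional named vector mapping env code to ME id;
#'   when given (with `winner_bonus > 0`), a rank-2 GE structure is
#'   planted: each ME occupies a direction at an equally spaced angle in
#'   the latent GE plane, its environments sit on that direction (small
#'   angular jitter) and genotype `G<m>` — the designated winner of ME
#'   `m` — points exactly along it, leading its ME by about
#'   `winner_bonus` kg/ha in the GE surface. Rank 2 is what the biplot's
#'   retained PC1-PC2 plane can represent, so the planted
#'   which-won-where truth is geometrically recoverable.
#' @param winner_bonus kg/ha lead of the planted per-ME winners (0 = no
#'   planted structure).
#' @param env_codes Optional env codes (default `E01`, `E02`, ...).
#' @param empirical If `TRUE`, each drawn effect vector is centered and
#'   rescaled to its exact target sample variance (as in
#'   `MASS::mvrnorm(empirical = TRUE)`), giving tight control of realized
#'   variance shares in small designs.
#' @param seed Integer seed.
#' @return A validated `trial_config` list.
#' @export
trial_config <- function(n_genotypes, n_envs, n_reps = 3, mu = 1500,
                         var_G = 2.8e4, var_E = 2.2e5, var_GE = 1.2e5,
                         var_eps = 2.4e4, var_B = 0.01 * var_eps,
                         me_assignment = NULL, winner_bonus = 0,
                         env_codes = NULL, empirical = FALSE, seed = 1L) {
  if (any(c(var_G, var_E, var_GE, var_eps, var_B) < 0)) {
    stop("variance components must be >= 0", call. = FALSE)
  }
  stopifnot(n_genotypes >= 2, n_envs >= 2, n_reps >= 2)
  if (is.null(env_codes)) env_codes <- sprintf("E%02d", seq_len(n_envs))
  stopifnot(length(env_codes) == n_envs, !anyDuplicated(env_codes))
  if (!is.null(me_assignment)) {
    if (!setequal(names(me_assignment), env_codes)) {
      stop("me_assignment must name every environment code", call. = FALSE)
    }
  }
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_envs = as.integer(n_envs), n_reps = as.integer(n_reps),
                 mu = mu, var_G = var_G, var_E = var_E, var_GE = var_GE,
                 var_eps = var_eps, var_B = var_B,
                 me_assignment = me_assignment,
                 winner_bonus = winner_bonus, env_codes = env_codes,
                 empirical = empirical, seed = as.integer(seed)),
            class = "trial_config")
}

scale_to_var <- function(x, target) {
  if (length(x) < 2 || target == 0) return(if (target == 0) x * 0 else x)
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(x)
  x * sqrt(target) / s
}

#' Generate a balanced multi-environment trial yield table
#'
#' Yields follow the RCBD model
#' `y_ijk = mu + G_i + E_j + B_k(j) + GE_ij + eps_ijk`
#' with all effects drawn from centered normals at the configured
#' variances. When `me_assignment` is set, genotype `g` designated as the
#' winner of ME `m` (genotypes `G01`, `G02`, ... map to MEs `1`, `2`, ...)
#' gains `winner_bonus` on GE in every environment of that ME.
#'
#' @param config A [trial_config()].
#' @return Long tibble with columns `GEN`, `ENV`, `REP`, `GY_KG_HA`,
#'   one row per genotype x environment x replicate.
#' @export
#' @examples
#' cfg <- trial_config(n_genotypes = 5, n_envs = 4, n_reps = 3, seed = 3)
#' nrow(gen_trial_yields(cfg))  # 60
gen_trial_yields <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  g <- config$n_genotypes; e <- config$n_envs; r <- config$n_reps
  gen_codes <- sprintf("G%02d", seq_len(g))
  env_codes <- config$env_codes
  withr::with_seed(config$seed, {
    G <- rnorm(g, 0, sqrt(config$var_G))
    E <- rnorm(e, 0, sqrt(config$var_E))
    B <- matrix(rnorm(e * r, 0, sqrt(config$var_B)), nrow = e)
    GE <- matrix(rnorm(g * e, 0, sqrt(config$var_GE)), nrow = g)
    eps <- rnorm(g * e * r, 0, sqrt(config$var_eps))
    if (config$empirical) {
      G <- scale_to_var(G, config$var_G)
      E <- scale_to_var(E, config$var_E)
      B <- matrix(scale_to_var(as.numeric(B), config$var_B), nrow = e)
      GE <- matrix(scale_to_var(as.numeric(GE), config$var_GE), nrow = g)
      eps <- scale_to_var(eps, config$var_eps)
    }
    if (!is.null(config$me_assignment) && config$winner_bonus > 0) {
      # Plant the which-won-where truth in the rank-2 plane the biplot
      # retains: each ME gets a direction at an equally spaced angle,
      # environments sit on their ME's direction (small angular jitter),
      # and genotype m (the winner of ME m) points exactly along it while
      # rivals get shorter random directions. The winner thus leads its
      # own ME by ~winner_bonus in the modeled GE surface.
      mes <- sort(unique(config$me_assignment))
      M <- length(mes)
      theta_me <- 2 * pi * (seq_len(M) - 1) / M
      env_me <- match(config$me_assignment[env_codes], mes)
      th_env <- theta_me[env_me] + rnorm(e, 0, 0.08)
      U <- cbind(cos(th_env), sin(th_env))
      V <- matrix(0, g, 2)
      V[seq_len(min(M, g)), ] <- cbind(cos(theta_me), sin(theta_me))[
        seq_len(min(M, g)), , drop = FALSE]
      if (g > M) {
        th_rival <- runif(g - M, 0, 2 * pi)
        V[(M + 1):g, ] <- 0.5 * cbind(cos(th_rival), sin(th_rival))
      }
      GE <- GE + config$winner_bonus * tcrossprod(V, U)
    }
    idx <- expand.grid(gen = seq_len(g), env = seq_len(e), rep = seq_len(r))
    y <- config$mu + G[idx$gen] + E[idx$env] +
      B[cbind(idx$env, idx$rep)] + GE[cbind(idx$gen, idx$env)] + eps
    tibble::tibble(GEN = gen_codes[idx$gen], ENV = env_codes[idx$env],
                   REP = idx$rep, GY_KG_HA = y)
  })
}

#' Variance components targeting given %TSS shares
#'
#' Inverts the expected balanced-ANOVA sums of squares to find variance
#' components under which a generated trial's percent-of-TSS partition
#' hits the requested shares for genotype, environment and GEI (the
#' remainder going to blocks and residual). Intended for
#' [gen_trial_yields()] with `empirical = TRUE`, where drawn effects have
#' their exact target sample variance. Expected SS per term is the
#' effect-scaling term plus the residual leakage `df * var_eps`.
#'
#' @param g,e,r Design dimensions.
#' @param shares Named vector with entries `G`, `E`, `GE` in (0, 1),
#'   summing to less than 1.
#' @param var_eps Residual variance, (kg/ha)^2.
#' @param var_B Block-within-environment variance.
#' @return List with `var_G`, `var_E`, `var_GE`, `var_eps`, `var_B`.
#' @export
#' @examples
#' components_for_shares(40, 19, 3)
components_for_shares <- function(g, e, r,
                                  shares = c(G = 0.07, E = 0.55, GE = 0.30),
                                  var_eps = 2.4e4,
                                  var_B = 0.01 * var_eps) {
  stopifnot(all(c("G", "E", "GE") %in% names(shares)),
            all(shares > 0), sum(shares) < 1)
  ss_res <- e * (g - 1) * (r - 1) * var_eps
  ss_b <- g * e * (r - 1) * var_B + e * (r - 1) * var_eps
  total <- (ss_res + ss_b) / (1 - sum(shares[c("G", "E", "GE")]))
  var_G <- (shares[["G"]] * total - (g - 1) * var_eps) / (e * r * (g - 1))
  var_E <- (shares[["E"]] * total - (e - 1) * var_eps) / (g * r * (e - 1))
  var_GE <- (shares[["GE"]] * total - (g - 1) * (e - 1) * var_eps) /
    (r * (g - 1) * (e - 1))
  if (any(c(var_G, var_E, var_GE) <= 0)) {
    stop("requested shares are unattainable at this design size ",
         "(residual leakage exceeds a target share)", call. = FALSE)
  }
  list(var_G = var_G, var_E = var_E, var_GE = var_GE,
       var_eps = var_eps, var_B = var_B)
}
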