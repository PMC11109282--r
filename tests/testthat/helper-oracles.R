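# Independently coded scalar oracles for the agroclimatic closed forms.
# Deliberately written step by step (scalar, intermediate named
# quantities) so they share no code path with the vectorized package
# implementations they check.

oracle_es <- function(tc) {
  exponent <- (17.27 * tc) / (tc + 237.3)
  0.6108 * exp(exponent)
}

oracle_vpd <- function(tmax, tmin, tdew) {
  es_mean <- (oracle_es(tmax) + oracle_es(tmin)) / 2
  ea <- oracle_es(tdew)
  max(0, es_mean - ea)
}

oracle_slope <- function(tc) {
  4098 * oracle_es(tc) / (tc + 237.3)^2
}

oracle_gdd <- function(tmax, tmin, tb) {
  tmean <- (tmax + tmin) / 2
  if (tmean > tb) tmean - tb else 0
}

oracle_frue <- function(tc, tb, to1, to2, tcl) {
  if (tc <= tb || tc >= tcl) return(0)
  if (tc < to1) return((tc - tb) / (to1 - tb))
  if (tc <= to2) return(1)
  (tcl - tc) / (tcl - to2)
}

oracle_daylight <- function(lat_deg, doy) {
  delta <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  phi <- pi / 180 * lat_deg
  x <- -tan(phi) * tan(delta)
  x <- min(1, max(-1, x))
  omega_s <- acos(x)
  24 / pi * omega_s
}

oracle_rta <- function(lat_deg, doy) {
  gsc <- 0.0820
  delta <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  phi <- pi / 180 * lat_deg
  dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  x <- min(1, max(-1, -tan(phi) * tan(delta)))
  omega_s <- acos(x)
  ra <- (24 * 60 / pi) * gsc * dr *
    (omega_s * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(omega_s))
  max(0, ra)
}

oracle_sunshine <- function(sw, ra, nmax, as_ = 0.25, bs_ = 0.50) {
  frac <- sw / ra
  nn <- nmax * (frac - as_) / bs_
  min(nmax, max(0, nn))
}

oracle_etp <- function(t2m, sw, alpha = 1.26, gam = 0.0665,
                       lam = 2.45, alb = 0.23) {
  delta <- oracle_slope(t2m)
  rn <- (1 - alb) * sw
  max(0, alpha * (delta / (delta + gam)) * rn / lam)
}

# planted archetype truth for the default 19-site network
archetype_truth <- function(sites = default_sites()) {
  stats::setNames(as.integer(factor(sites$archetype,
                                    levels = unique(sites$archetype))),
                  sites$code)
}

# window-mean stats for a set of sites (small wrapper used across tests)
site_window_stats <- function(sites, n_years = 2, seed = 1,
                              spec = default_windows()) {
  wx <- gen_daily_weather(sites, weather_config(n_years = n_years,
                                                seed = seed))
  dplyr::bind_rows(lapply(seq_len(nrow(sites)), function(i) {
    panel <- compute_panel(wx[wx$SITE == sites$code[i], ],
                           lat = sites$lat[i])
    window_means(panel, spec)
  }))
}

# small random balanced trial for oracle comparisons
random_trial <- function(g, e, r, seed) {
  withr::with_seed(seed, {
    idx <- expand.grid(GEN = sprintf("G%02d", 1:g),
                       ENV = sprintf("E%02d", 1:e), REP = 1:r,
                       stringsAsFactors = FALSE)
    idx$GY_KG_HA <- rnorm(nrow(idx), 1500, 300)
    tibble::as_tibble(idx)
  })
}
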