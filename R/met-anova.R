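# Joint RCBD ANOVA across environments with %TSS variance partitioning.
# Fixed-effects decomposition via closed-form sums of squares:
#   y_ijk = mu + E_j + B_k(j) + G_i + GE_ij + eps_ijk

std_trial_names <- function(trial) {
  nm <- toupper(names(trial))
  map <- c(GEN = "GEN", GENOTYPE = "GEN", ENV = "ENV", ENVIRONMENT = "ENV",
           REP = "REP", REPLICATION = "REP", BLOCK = "REP",
           GY_KG_HA = "GY_KG_HA", YIELD = "GY_KG_HA", GY = "GY_KG_HA")
  hit <- map[nm]
  names(trial)[!is.na(hit)] <- hit[!is.na(hit)]
  need <- c("GEN", "ENV", "REP", "GY_KG_HA")
  if (!all(need %in% names(trial))) {
    stop("trial table lacks column(s): ",
         paste(setdiff(need, names(trial)), collapse = ", "), call. = FALSE)
  }
  trial
}

check_balanced <- function(trial) {
  cells <- table(trial$GEN, trial$ENV, trial$REP)
  if (any(cells != 1)) {
    idx <- which(cells != 1, arr.ind = TRUE)
    miss <- apply(utils::head(idx, 10), 1, function(r) {
      paste0("(", dimnames(cells)[[1]][r[1]], ", ",
             dimnames(cells)[[2]][r[2]], ", rep ",
             dimnames(cells)[[3]][r[3]], ")")
    })
    stop("trial table is not balanced; offending genotype x environment x ",
         "rep cells include: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(trial)
}

#' Joint RCBD analysis of variance for a multi-environment trial
#'
#' Fixed-effects partition of grain yield into genotype (G), environment
#' (E), blocks within environments, genotype x environment interaction
#' (GEI) and residual, computed from closed-form sums of squared means on
#' a balanced table. F tests use the pooled residual mean square. The
#' percent of total (corrected) sum of squares is reported per term.
#'
#' Degrees of freedom: G = g-1, E = e-1, B(E) = e(r-1),
#' GEI = (g-1)(e-1), residual = N-1 minus all others = e(g-1)(r-1).
#'
#' @param trial Long trial tibble with columns `GEN`, `ENV`, `REP`,
#'   `GY_KG_HA` (case-insensitive synonyms accepted). Must be balanced.
#' @return A `met_anova` object: tibble with columns `term`, `df`, `ss`,
#'   `ms`, `f_value`, `p_value`, `pct_tss`; attributes `ss_total`
#'   (corrected total SS) and `n`.
#' @export
#' @examples
#' tr <- gen_trial_yields(trial_config(6, 4, 3, seed = 2))
#' anova_joint(tr)
anova_joint <- function(trial) {
  trial <- std_trial_names(trial)
  stopifnot(all(is.finite(trial$GY_KG_HA)))
  check_balanced(trial)
  y <- trial$GY_KG_HA
  g <- length(unique(trial$GEN))
  e <- length(unique(trial$ENV))
  r <- length(unique(trial$REP))
  n <- length(y)
  C <- sum(y)^2 / n
  ss_tot <- sum(y^2) - C
  tg <- tapply(y, trial$GEN, sum)
  te <- tapply(y, trial$ENV, sum)
  teb <- tapply(y, list(trial$ENV, trial$REP), sum)
  tge <- tapply(y, list(trial$GEN, trial$ENV), sum)
  ss_g <- sum(tg^2) / (e * r) - C
  ss_e <- sum(te^2) / (g * r) - C
  ss_b <- sum(teb^2) / g - sum(te^2) / (g * r)
  ss_ge <- sum(tge^2) / r - C - ss_g - ss_e
  ss_res <- ss_tot - ss_g - ss_e - ss_b - ss_ge
  df <- c(G = g - 1, E = e - 1, B = e * (r - 1),
          GE = (g - 1) * (e - 1), RES = e * (g - 1) * (r - 1))
  stopifnot(sum(df) == n - 1)
  ss <- c(ss_g, ss_e, ss_b, ss_ge, ss_res)
  ms <- ss / df
  ms_res <- ms[5]
  f <- c(ms[1:4] / ms_res, NA_real_)
  p <- c(stats::pf(f[1:4], df[1:4], df[5], lower.tail = FALSE), NA_real_)
  if (!is.finite(ms_res) || ms_res == 0) {
    f[] <- NA_real_; p[] <- NA_real_
  }
  pct <- if (ss_tot > 0) 100 * ss / ss_tot else rep(NA_real_, 5)
  res <- tibble::tibble(
    term = c("Genotype (G)", "Environment (E)", "Block(Environment)",
             "G x E interaction (GEI)", "Residual"),
    df = as.integer(df), ss = ss, ms = ms, f_value = f, p_value = p,
    pct_tss = pct
  )
  # SS additivity is structural; guard against numerical loss
  if (ss_tot > 0) {
    stopifnot(abs(sum(ss) - ss_tot) <= 1e-6 * ss_tot)
  }
  structure(res, ss_total = ss_tot, n = n,
            class = c("met_anova", class(res)))
}

#' Percent of total sum of squares per ANOVA term
#'
#' `100 * SS_term / SS_total(corrected)`, including the
#' blocks-within-environments term.
#'
#' @param result A `met_anova` from [anova_joint()].
#' @return Named numeric vector of percentages (sums to 100).
#' @export
percent_tss <- function(result) {
  stopifnot(inherits(result, "met_anova"))
  if (!isTRUE(attr(result, "ss_total") > 0)) {
    stop("percent of TSS is undefined: total corrected SS is zero",
         call. = FALSE)
  }
  stats::setNames(result$pct_tss, result$term)
}
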