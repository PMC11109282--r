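# Envirotype track: crop-cycle window means, the W matrix, the enviromic
# kernel K_E = WW'/(trace(WW')/nrow(W)), average-linkage clustering into
# mega-environments, and the covariable PCA.

#' Default crop-cycle windows
#'
#' Four monthly periods spanning the soybean crop cycle (second fortnight
#' of June to second fortnight of October): 15 Jun-15 Jul, 16 Jul-15 Aug,
#' 16 Aug-15 Sep, 16 Sep-15 Oct. Both end dates are included.
#'
#' @return Tibble with columns `label`, `start` (`"mm-dd"`), `end`.
#' @export
default_windows <- function() {
  window_spec(tibble::tibble(
    label = c("W1", "W2", "W3", "W4"),
    start = c("06-15", "07-16", "08-16", "09-16"),
    end   = c("07-15", "08-15", "09-15", "10-15")
  ))
}

#' Validate a crop-cycle window specification
#'
#' @param windows Tibble with `label`, `start`, `end` month-day strings;
#'   windows must be ordered, non-overlapping and not cross the year end.
#' @return The validated tibble, classed `window_spec`.
#' @export
window_spec <- function(windows) {
  stopifnot(all(c("label", "start", "end") %in% names(windows)),
            nrow(windows) >= 1)
  if (any(windows$start > windows$end)) {
    stop("windows must not cross the year boundary", call. = FALSE)
  }
  if (nrow(windows) > 1) {
    for (i in 2:nrow(windows)) {
      if (windows$start[i] <= windows$end[i - 1]) {
        stop("windows must be ordered and non-overlapping", call. = FALSE)
      }
    }
  }
  class(windows) <- c("window_spec", class(windows))
  windows
}

#' Window means of the covariable panel
#'
#' Averages each covariable over each crop-cycle window of each year.
#' Windows are closed intervals on both end dates.
#'
#' @param panel Covariable panel from [compute_panel()] (single site).
#' @param spec A [window_spec()]; default [default_windows()].
#' @param years Optional integer vector restricting the years used;
#'   default: all years present in the panel.
#' @return Long tibble `SITE`, `YEAR`, `WINDOW`, `COVARIABLE`, `VALUE`.
#' @export
window_means <- function(panel, spec = default_windows(), years = NULL) {
  stopifnot(inherits(spec, "window_spec"))
  if (is.null(years)) years <- sort(unique(panel$YEAR))
  panel <- panel[panel$YEAR %in% years, , drop = FALSE]
  md <- format(panel$DATE, "%m-%d")
  win <- rep(NA_character_, nrow(panel))
  for (i in seq_len(nrow(spec))) {
    sel <- md >= spec$start[i] & md <= spec$end[i]
    win[sel] <- spec$label[i]
  }
  keep <- !is.na(win)
  covs <- intersect(covariable_names(), names(panel))
  dat <- panel[keep, c("SITE", "YEAR", covs)]
  dat$WINDOW <- win[keep]
  # every (year, window) must be covered
  got <- unique(dat[c("YEAR", "WINDOW")])
  want <- expand.grid(YEAR = years, WINDOW = spec$label,
                      stringsAsFactors = FALSE)
  miss <- dplyr::anti_join(want, got, by = c("YEAR", "WINDOW"))
  if (nrow(miss) > 0) {
    site <- unique(panel$SITE)[1]
    stop("no daily records for site ", site, ", year ", miss$YEAR[1],
         ", window ", miss$WINDOW[1], call. = FALSE)
  }
  long <- tidyr::pivot_longer(dat, dplyr::all_of(covs),
                              names_to = "COVARIABLE", values_to = "VALUE")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$SITE, .data$YEAR, .data$WINDOW,
                    .data$COVARIABLE),
    VALUE = mean(.data$VALUE), .groups = "drop")
  dplyr::arrange(out, .data$YEAR, .data$COVARIABLE, .data$WINDOW)
}

#' Build the envirotype covariable matrix W
#'
#' Rows are environments (sites); columns are (year, covariable, window)
#' triples — e.g. 20 years x 19 covariables x 4 windows = 1520 columns.
#' By default each column is centered and scaled to unit variance;
#' zero-variance columns are dropped with a warning and recorded.
#'
#' @param stats Long tibble of window means for all sites, as produced by
#'   row-binding [window_means()] outputs.
#' @param scale Center and scale columns (default `TRUE`).
#' @return A `w_matrix` object: list with `W` (numeric matrix, rownames =
#'   site codes), `env_codes`, `col_meta` (tibble: `YEAR`, `COVARIABLE`,
#'   `WINDOW`, `center`, `scale`, `dropped`), `scaled`, `n_cols_full`.
#' @export
build_w <- function(stats, scale = TRUE) {
  need <- c("SITE", "YEAR", "WINDOW", "COVARIABLE", "VALUE")
  if (!all(need %in% names(stats))) {
    stop("window-mean input lacks column(s): ",
         paste(setdiff(need, names(stats)), collapse = ", "), call. = FALSE)
  }
  stats$.col <- paste(stats$YEAR, stats$COVARIABLE, stats$WINDOW, sep = "|")
  wide <- tidyr::pivot_wider(stats[c("SITE", ".col", "VALUE")],
                             names_from = ".col", values_from = "VALUE")
  if (anyNA(wide)) {
    stop("ragged input: some sites lack some (year, covariable, window) cells",
         call. = FALSE)
  }
  # column order: year, then covariable, then window
  meta <- unique(stats[c("YEAR", "COVARIABLE", "WINDOW", ".col")])
  meta <- meta[order(meta$YEAR, meta$COVARIABLE, meta$WINDOW), ]
  env_codes <- sort(wide$SITE)
  W <- as.matrix(wide[match(env_codes, wide$SITE), meta$.col])
  rownames(W) <- env_codes
  n_full <- ncol(W)
  ctr <- rep(0, n_full); scl <- rep(1, n_full)
  dropped <- rep(FALSE, n_full)
  if (scale) {
    ctr <- colMeans(W)
    scl <- apply(W, 2, stats::sd)
    dropped <- !is.finite(scl) | scl == 0
    if (any(dropped)) {
      warning(sum(dropped), " zero-variance column(s) dropped from W")
    }
    W <- sweep(W, 2, ctr, "-")
    W[, !dropped] <- sweep(W[, !dropped, drop = FALSE], 2,
                           scl[!dropped], "/")
    W <- W[, !dropped, drop = FALSE]
  }
  structure(list(
    W = W, env_codes = env_codes,
    col_meta = tibble::tibble(YEAR = meta$YEAR, COVARIABLE = meta$COVARIABLE,
                              WINDOW = meta$WINDOW, center = ctr,
                              scale = scl, dropped = dropped),
    scaled = scale, n_cols_full = n_full
  ), class = "w_matrix")
}

#' @export
print.w_matrix <- function(x, ...) {
  cat("Envirotype covariable matrix W: ", nrow(x$W), " environments x ",
      ncol(x$W), " columns", if (x$scaled) " (scaled)", "\n", sep = "")
  invisible(x)
}

#' Enviromic kernel
#'
#' `K_E = WW' / (trace(WW') / nrow(W))`, so that `trace(K_E)` equals the
#' number of environments. Symmetric and positive semi-definite by
#' construction.
#'
#' @param w A `w_matrix` from [build_w()] or a plain numeric matrix with
#'   environments in rows.
#' @return An `enviromic_kernel` object: list with `K` (named symmetric
#'   matrix) and `env_codes`.
#' @export
enviromic_kernel <- function(w) {
  W <- if (inherits(w, "w_matrix")) w$W else as.matrix(w)
  stopifnot(nrow(W) >= 2, ncol(W) >= 1)
  G <- tcrossprod(W)
  tr <- sum(diag(G))
  if (tr <= 0) {
    stop("degenerate kernel: trace(WW') = 0 (all-zero W)", call. = FALSE)
  }
  K <- G / (tr / nrow(W))
  structure(list(K = K, env_codes = rownames(W)),
            class = "enviromic_kernel")
}

#' Kernel-induced distance between environments
#'
#' `d_ij = sqrt(K_ii + K_jj - 2 K_ij)`, clipped at 0 — the canonical
#' feature-space metric of the kernel; on scaled W rows it reduces to the
#' Euclidean distance between envirotype profiles (up to the kernel's
#' trace normalization).
#'
#' @param kernel An [enviromic_kernel()] or symmetric PSD matrix.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
kernel_to_distance <- function(kernel) {
  K <- if (inherits(kernel, "enviromic_kernel")) kernel$K else as.matrix(kernel)
  d2 <- outer(diag(K), diag(K), "+") - 2 * K
  D <- sqrt(pmax(d2, 0))
  diag(D) <- 0
  D
}

#' Construct a mega-environment partition
#'
#' @param method Label of the producing method (e.g. `"envirotype"`,
#'   `"gge-2019"`, `"consensus"`).
#' @param assignment Named integer vector, site code -> ME id; ids are
#'   relabelled to be contiguous from 1 in order of first appearance.
#' @param hclust Optional `hclust` object the partition was cut from.
#' @return An `me_partition` object with fields `method`, `assignment`,
#'   `k`, and optionally `hclust`.
#' @export
me_partition <- function(method, assignment, hclust = NULL) {
  stopifnot(!is.null(names(assignment)), !anyDuplicated(names(assignment)))
  ids <- as.integer(factor(assignment, levels = unique(assignment)))
  names(ids) <- names(assignment)
  structure(list(method = method, assignment = ids,
                 k = length(unique(ids)), hclust = hclust),
            class = "me_partition")
}

#' @export
print.me_partition <- function(x, ...) {
  cat("ME partition (", x$method, "): ", length(x$assignment),
      " sites in ", x$k, " MEs\n", sep = "")
  for (m in sort(unique(x$assignment))) {
    cat("  ME", m, ": ",
        paste(names(x$assignment)[x$assignment == m], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Cluster environments into mega-environments
#'
#' Average-linkage (UPGMA) hierarchical clustering of the kernel-induced
#' distance, cut to exactly `k` groups. Sites are ordered by code before
#' agglomeration so results do not depend on input order.
#'
#' @param d Distance matrix (e.g. from [kernel_to_distance()]) with site
#'   codes as dimnames, or a `dist` object.
#' @param k Number of mega-environments, between 2 and `n - 1`.
#' @param method Label recorded on the partition (default `"envirotype"`).
#' @return An [me_partition()] carrying the `hclust` tree (merge heights
#'   available as `result$hclust$height`).
#' @export
cluster_environments <- function(d, k = 4, method = "envirotype") {
  D <- as.matrix(d)
  n <- nrow(D)
  if (!(k >= 2 && k <= n - 1)) {
    stop("k must be between 2 and n_envs - 1 (= ", n - 1, ")", call. = FALSE)
  }
  ord <- order(rownames(D))
  D <- D[ord, ord]
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  cut <- stats::cutree(hc, k = k)
  me_partition(method, cut, hclust = hc)
}

#' PCA of environment-level covariable summaries
#'
#' Correlation-matrix PCA (columns standardized) of an environments x
#' covariables table, reporting per-component explained variance shares,
#' per-covariable contributions (percent, summing to 100 per component)
#' and, when an environment mean-yield vector is supplied, the sign of the
#' association between yield and each covariable.
#'
#' @param env_summary Numeric matrix or data frame, environments in rows
#'   (rownames = codes), covariables in columns.
#' @param yield Optional named numeric vector of environment mean yields.
#' @return A `covariable_pca` object: `scores`, `loadings`, `explained`,
#'   `contributions` (per PC1/PC2 and combined), and `yield_assoc`
#'   (tibble `COVARIABLE`, `cor`, `sign`) when yield is given.
#' @export
pca_covariables <- function(env_summary, yield = NULL) {
  X <- as.matrix(env_summary)
  if (nrow(X) < 3) stop("PCA needs at least 3 environments", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant covariable column(s) excluded from PCA")
    X <- X[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  explained <- ev / sum(ev)
  contrib <- 100 * sweep(pc$rotation^2, 2, colSums(pc$rotation^2), "/")
  w12 <- ev[1:2] / sum(ev[1:2])
  contrib12 <- contrib[, 1] * w12[1] + contrib[, 2] * w12[2]
  yield_assoc <- NULL
  if (!is.null(yield)) {
    y <- yield[rownames(X)]
    if (anyNA(y)) stop("yield vector must name every environment",
                       call. = FALSE)
    cors <- apply(X, 2, function(col) stats::cor(y, col))
    yield_assoc <- tibble::tibble(COVARIABLE = colnames(X), cor = cors,
                                  sign = ifelse(cors >= 0, "positive",
                                                "negative"))
  }
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained = explained, contributions = contrib,
                 contrib_pc12 = contrib12, yield_assoc = yield_assoc),
            class = "covariable_pca")
}

#' Mean covariable values per environment over the crop-cycle windows
#'
#' Convenience summary feeding [pca_covariables()]: averages the window
#' means over years and windows, one row per site, one column per
#' covariable.
#'
#' @param stats Long window-mean tibble (see [build_w()]).
#' @return Numeric matrix, sites x covariables.
#' @export
env_covariable_summary <- function(stats) {
  agg <- dplyr::summarise(
    dplyr::group_by(stats, .data$SITE, .data$COVARIABLE),
    VALUE = mean(.data$VALUE), .groups = "drop")
  wide <- tidyr::pivot_wider(agg, names_from = "COVARIABLE",
                             values_from = "VALUE")
  M <- as.matrix(wide[, -1])
  rownames(M) <- wide$SITE
  covs <- intersect(covariable_names(), colnames(M))
  M[, covs, drop = FALSE]
}
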