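# GGE biplot engine: environment-centered genotype x environment means
# decomposed by SVD, with singular-value partitioning, which-won-where
# sector geometry and discriminativeness vs representativeness.

#' Genotype x environment means from a balanced trial table
#'
#' @param trial Long trial tibble (`GEN`, `ENV`, `REP`, `GY_KG_HA`).
#' @return Numeric matrix, genotypes x environments, cell = mean yield
#'   over replicates.
#' @export
ge_means <- function(trial) {
  trial <- std_trial_names(trial)
  check_balanced(trial)
  M <- tapply(trial$GY_KG_HA, list(trial$GEN, trial$ENV), mean)
  M[order(rownames(M)), order(colnames(M)), drop = FALSE]
}

svp_scores <- function(u, v, d, svp) {
  switch(svp,
         symmetric = list(g = u %*% diag(sqrt(d), length(d)),
                          e = v %*% diag(sqrt(d), length(d))),
         environment = list(g = u, e = v %*% diag(d, length(d))),
         genotype = list(g = u %*% diag(d, length(d)), e = v),
         stop("unknown svp mode: ", svp, call. = FALSE))
}

#' Fit a GGE model to a genotype x environment means matrix
#'
#' Centers each column by its environment mean — removing the grand mean
#' and environment main effect, retaining genotype main effect plus GEI —
#' then decomposes the centered matrix by SVD:
#' `Ybar_ij - mu - beta_j = sum_n lambda_n alpha_in eta_jn`.
#' Scores are scaled by the singular-value partitioning (SVP) mode:
#' `symmetric` splits `sqrt(lambda)` between sides; `environment` puts
#' `lambda` on environment scores (for environment evaluation);
#' `genotype` puts it on genotype scores.
#'
#' @param M Genotype x environment means matrix (>= 3 x 3, complete).
#' @param svp One of `"symmetric"`, `"environment"`, `"genotype"`.
#' @return A `gge_model`: list with `centered`, `d` (singular values),
#'   `u`, `v`, `genotype_scores`, `env_scores`, `svp`, `explained`
#'   (per-PC share of the G+GE sum of squares), `genotypes`, `envs`.
#' @export
fit_gge <- function(M, svp = c("symmetric", "environment", "genotype")) {
  svp <- match.arg(svp)
  M <- as.matrix(M)
  if (anyNA(M)) stop("means matrix must be complete", call. = FALSE)
  if (nrow(M) < 3 || ncol(M) < 3) {
    stop("biplot geometry needs at least 3 genotypes and 3 environments",
         call. = FALSE)
  }
  centered <- sweep(M, 2, colMeans(M))
  if (all(abs(centered) < 1e-12)) {
    stop("zero-variance matrix: no genotypic or GEI signal to decompose",
         call. = FALSE)
  }
  sv <- svd(centered)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  k <- max(k, 2L)
  d <- sv$d[seq_len(k)]
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  sc <- svp_scores(u, v, d, svp)
  dimnames(sc$g) <- list(rownames(M), paste0("PC", seq_len(k)))
  dimnames(sc$e) <- list(colnames(M), paste0("PC", seq_len(k)))
  structure(list(centered = centered, d = d, u = u, v = v,
                 genotype_scores = sc$g, env_scores = sc$e, svp = svp,
                 explained = sv$d^2 / sum(sv$d^2),
                 genotypes = rownames(M), envs = colnames(M)),
            class = "gge_model")
}

#' @export
print.gge_model <- function(x, ...) {
  cat("GGE model: ", length(x$genotypes), " genotypes x ",
      length(x$envs), " environments (svp = ", x$svp, ")\n",
      "PC1 + PC2 explain ",
      sprintf("%.1f%%", 100 * sum(x$explained[1:2])),
      " of G + GE\n", sep = "")
  invisible(x)
}

#' Re-scale a fitted GGE model under a different SVP mode
#'
#' @param model A `gge_model`.
#' @param svp Target SVP mode.
#' @return The model with scores rescaled (SVD untouched).
#' @export
set_svp <- function(model, svp = c("symmetric", "environment", "genotype")) {
  svp <- match.arg(svp)
  sc <- svp_scores(model$u, model$v, model$d, svp)
  dimnames(sc$g) <- dimnames(model$genotype_scores)
  dimnames(sc$e) <- dimnames(model$env_scores)
  model$genotype_scores <- sc$g
  model$env_scores <- sc$e
  model$svp <- svp
  model
}

vec_angle <- function(xy) atan2(xy[, 2], xy[, 1])

#' Which-won-where sector analysis
#'
#' Builds the convex hull of genotype scores in the PC1-PC2 plane; rays
#' from the origin perpendicular to the hull edges partition the plane
#' into sectors, each "owned" by a hull-vertex genotype. Every environment
#' falls in the sector of the hull genotype maximizing the inner product
#' with its score vector — the rank-2 predicted winner in that
#' environment. Environments sharing a sector form a candidate
#' mega-environment.
#'
#' @param model A `gge_model`; symmetric SVP is the conventional scaling
#'   for this view (a warning is issued otherwise).
#' @return A `which_won_where` object: `hull_vertices` (genotype codes,
#'   counter-clockwise), `sector_of_env` (named integer), `winner_of_env`
#'   (named character), `winner_of_sector`, `me_groups` (list of env code
#'   vectors per occupied sector), `boundaries` (tibble of sector boundary
#'   angles).
#' @export
which_won_where <- function(model) {
  stopifnot(inherits(model, "gge_model"))
  if (model$svp != "symmetric") {
    warning("which-won-where is conventionally read under symmetric SVP; ",
            "got '", model$svp, "'")
  }
  if (length(model$d) < 2 || model$d[2] <= 1e-8 * model$d[1]) {
    stop("degenerate hull: genotype scores are collinear in PC1-PC2 ",
         "(the fitted G + GE structure has rank < 2)", call. = FALSE)
  }
  gs <- model$genotype_scores[, 1:2, drop = FALSE]
  es <- model$env_scores[, 1:2, drop = FALSE]
  hull_idx <- grDevices::chull(gs)      # clockwise order
  hull_idx <- rev(hull_idx)             # counter-clockwise
  hv <- gs[hull_idx, , drop = FALSE]
  scale_ref <- max(sqrt(rowSums(hv^2)))
  hull_area <- if (length(hull_idx) >= 3) {
    nx <- c(2:nrow(hv), 1)
    abs(sum(hv[, 1] * hv[nx, 2] - hv[nx, 1] * hv[, 2])) / 2
  } else 0
  if (length(hull_idx) < 3 || hull_area <= 1e-9 * scale_ref^2) {
    stop("degenerate hull: genotype scores are collinear in PC1-PC2",
         call. = FALSE)
  }
  # winner per environment: hull vertex maximizing the inner product;
  # near-ties resolved counter-clockwise of the environment direction
  win_pos <- vapply(seq_len(nrow(es)), function(j) {
    ip <- as.numeric(hv %*% es[j, ])
    cand <- which(ip >= max(ip) - 1e-9 * scale_ref * max(1, sqrt(sum(es[j, ]^2))))
    if (length(cand) == 1) return(cand[1])
    rel <- (vec_angle(hv[cand, , drop = FALSE]) -
              atan2(es[j, 2], es[j, 1])) %% (2 * pi)
    cand[which.min(rel)]
  }, integer(1))
  # sector boundaries: perpendicular to each hull edge
  m <- nrow(hv)
  nxt <- c(2:m, 1)
  edge <- hv[nxt, , drop = FALSE] - hv
  boundaries <- tibble::tibble(
    from_vertex = rownames(hv),
    to_vertex = rownames(hv)[nxt],
    boundary_angle = atan2(edge[, 1], -edge[, 2])  # perpendicular to edge
  )
  winner_of_env <- stats::setNames(rownames(hv)[win_pos], rownames(es))
  occupied <- sort(unique(win_pos))
  sector_ids <- stats::setNames(seq_along(occupied), occupied)
  sector_of_env <- stats::setNames(
    as.integer(sector_ids[as.character(win_pos)]), rownames(es))
  me_groups <- split(rownames(es), sector_of_env)
  winner_of_sector <- stats::setNames(rownames(hv)[occupied],
                                      names(me_groups))
  structure(list(hull_vertices = rownames(hv),
                 sector_of_env = sector_of_env,
                 winner_of_env = winner_of_env,
                 winner_of_sector = winner_of_sector,
                 me_groups = me_groups, boundaries = boundaries),
            class = "which_won_where")
}

#' @export
print.which_won_where <- function(x, ...) {
  cat("Which-won-where: ", length(x$hull_vertices), " hull genotypes, ",
      length(x$me_groups), " occupied sector(s)\n", sep = "")
  for (s in names(x$me_groups)) {
    cat("  sector ", s, " (winner ", x$winner_of_sector[[s]], "): ",
        paste(x$me_groups[[s]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Convert which-won-where sectors to a mega-environment partition
#'
#' @param www A [which_won_where()] result.
#' @param method Partition label.
#' @return An [me_partition()] of environments by occupied sector.
#' @export
www_partition <- function(www, method = "gge") {
  stopifnot(inherits(www, "which_won_where"))
  me_partition(method, www$sector_of_env)
}

#' Discriminativeness vs representativeness of environments
#'
#' Under environment-focused SVP (applied automatically), an environment's
#' vector length in PC1-PC2 is proportional to its ability to discriminate
#' genotypes (its standard deviation in the rank-2 model), and the cosine
#' of its angle with the Average-Environment Axis (AEA — direction of the
#' mean environment vector) measures how representative it is of the
#' whole network. Environments above the median on both measures are
#' classed `"both"`.
#'
#' @param model A `gge_model` (any SVP; environment-focused applied).
#' @return Tibble `env`, `vector_length`, `cos_aea`, `class` (one of
#'   `discriminative`, `representative`, `both`, `neither`), with the AEA
#'   direction in attribute `aea`.
#' @export
discrim_vs_repres <- function(model) {
  stopifnot(inherits(model, "gge_model"))
  model <- set_svp(model, "environment")
  ev <- model$env_scores[, 1:2, drop = FALSE]
  len <- sqrt(rowSums(ev^2))
  if (any(len == 0)) {
    warning("environment(s) with zero-length score vector excluded: ",
            paste(rownames(ev)[len == 0], collapse = ", "))
    ev <- ev[len > 0, , drop = FALSE]
    len <- len[len > 0]
  }
  aea <- colMeans(ev)
  aea_norm <- sqrt(sum(aea^2))
  if (aea_norm < 1e-12) {
    stop("degenerate average-environment axis (zero mean vector)",
         call. = FALSE)
  }
  cos_aea <- as.numeric(ev %*% aea) / (len * aea_norm)
  disc <- len > stats::median(len)
  repr <- cos_aea > stats::median(cos_aea)
  cls <- dplyr::case_when(disc & repr ~ "both",
                          disc ~ "discriminative",
                          repr ~ "representative",
                          TRUE ~ "neither")
  out <- tibble::tibble(env = rownames(ev), vector_length = len,
                        cos_aea = cos_aea, class = cls)
  attr(out, "aea") <- aea / aea_norm
  out
}

#' Group environments by angular similarity of their GGE score vectors
#'
#' Average-linkage clustering of environments on the angular distance
#' (arc cosine of the cosine similarity) between their PC1-PC2 score
#' vectors, cut at `k` — the per-year GGE grouping fed to the consensus.
#'
#' @param model A `gge_model`.
#' @param k Number of groups (2 to n_envs - 1).
#' @param method Partition label (e.g. `"gge-2019"`).
#' @return An [me_partition()].
#' @export
env_similarity_groups <- function(model, k = 4, method = "gge") {
  stopifnot(inherits(model, "gge_model"))
  ev <- model$env_scores[, 1:2, drop = FALSE]
  len <- sqrt(rowSums(ev^2))
  if (any(len == 0)) {
    stop("environment(s) with zero-length score vector: ",
         paste(rownames(ev)[len == 0], collapse = ", "), call. = FALSE)
  }
  unit <- ev / len
  cosim <- pmin(pmax(tcrossprod(unit), -1), 1)
  D <- acos(cosim)
  diag(D) <- 0
  dimnames(D) <- list(rownames(ev), rownames(ev))
  cluster_environments(D, k = k, method = method)
}
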