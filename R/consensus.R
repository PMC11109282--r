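# Consensus mega-environments: merge the envirotype partition with the
# per-year GGE partitions via co-membership clustering, anchored on the
# envirotype grouping.

partition_assignment <- function(p) {
  if (inherits(p, "me_partition")) p$assignment else p
}

check_same_sites <- function(partitions) {
  sites <- sort(names(partition_assignment(partitions[[1]])))
  for (i in seq_along(partitions)) {
    si <- sort(names(partition_assignment(partitions[[i]])))
    if (!identical(si, sites)) {
      only_a <- setdiff(sites, si); only_b <- setdiff(si, sites)
      stop("partitions cover different site sets; difference: ",
           paste(c(only_a, only_b), collapse = ", "), call. = FALSE)
    }
  }
  sites
}

#' Co-membership matrix of a set of partitions
#'
#' Entry (i, j) is the fraction of input partitions in which sites i and j
#' fall in the same mega-environment. Symmetric, unit diagonal.
#'
#' @param partitions List of [me_partition()] objects (or named
#'   assignment vectors) over the same site set.
#' @return Symmetric numeric matrix with site codes as dimnames.
#' @export
co_membership <- function(partitions) {
  stopifnot(length(partitions) >= 1)
  sites <- check_same_sites(partitions)
  acc <- matrix(0, length(sites), length(sites),
                dimnames = list(sites, sites))
  for (p in partitions) {
    a <- partition_assignment(p)[sites]
    acc <- acc + outer(a, a, "==")
  }
  acc / length(partitions)
}

#' Adjusted Rand index between two mega-environment partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions
#' (up to label permutation), expected 0 for independent ones.
#'
#' @param p1,p2 [me_partition()] objects or named assignment vectors over
#'   the same sites.
#' @return ARI score (<= 1).
#' @export
adjusted_rand <- function(p1, p2) {
  sites <- check_same_sites(list(p1, p2))
  a <- partition_assignment(p1)[sites]
  b <- partition_assignment(p2)[sites]
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  ar <- sum_comb(rowSums(tab))
  bc <- sum_comb(colSums(tab))
  expected <- ar * bc / choose(n, 2)
  max_idx <- (ar + bc) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (idx - expected) / (max_idx - expected)
}

#' Propose consensus mega-environments from several partitions
#'
#' Clusters sites by average linkage on `1 - co_membership`, cut at `k`.
#' Exact ties in the distance are broken toward the anchor partition
#' (by an infinitesimal discount on pairs the anchor co-clusters), and
#' the proposal's ME labels are aligned to the anchor's by greatest
#' overlap.
#'
#' @param partitions List of input [me_partition()]s (envirotype plus the
#'   per-year GGE groupings).
#' @param k Number of consensus MEs.
#' @param anchor Partition guiding tie-breaks and label alignment;
#'   default the first input (conventionally the envirotype partition).
#' @return A `consensus_result`: list with `co_membership`, `proposed`
#'   ([me_partition()], method `"consensus"`), `per_input_ari` (named by
#'   each input's method label).
#' @export
propose_mes <- function(partitions, k = 4, anchor = partitions[[1]]) {
  stopifnot(length(partitions) >= 1)
  sites <- check_same_sites(c(partitions, list(anchor)))
  co <- co_membership(partitions)
  anchor_co <- outer(partition_assignment(anchor)[sites],
                     partition_assignment(anchor)[sites], "==")
  D <- (1 - co) - 1e-9 * anchor_co
  D <- pmax(D, 0)
  diag(D) <- 0
  if (k == 1) {
    prop <- me_partition("consensus",
                         stats::setNames(rep(1L, length(sites)), sites))
  } else {
    prop <- cluster_environments(D, k = k, method = "consensus")
    prop$assignment <- align_labels(prop$assignment,
                                    partition_assignment(anchor)[sites])
    prop$k <- length(unique(prop$assignment))
  }
  ari <- vapply(partitions, function(p) adjusted_rand(p, prop), numeric(1))
  labels <- vapply(seq_along(partitions), function(i) {
    p <- partitions[[i]]
    if (inherits(p, "me_partition") && !is.null(p$method)) p$method
    else paste0("input", i)
  }, character(1))
  structure(list(co_membership = co, proposed = prop,
                 per_input_ari = stats::setNames(ari, labels)),
            class = "consensus_result")
}

# Greedy relabelling of `x` cluster ids to maximize overlap with `ref`.
align_labels <- function(x, ref) {
  tab <- table(x, ref)
  new <- rep(NA_integer_, nrow(tab))
  used <- integer(0)
  ord <- order(apply(tab, 1, max), decreasing = TRUE)
  for (i in ord) {
    pref <- order(tab[i, ], decreasing = TRUE)
    pick <- setdiff(as.integer(colnames(tab))[pref], used)
    new[i] <- if (length(pick) > 0) pick[1] else max(c(used, 0L)) + 1L
    used <- c(used, new[i])
  }
  out <- new[match(x, as.integer(rownames(tab)))]
  names(out) <- names(x)
  out
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus over ", length(x$per_input_ari), " partition(s)\n",
      sep = "")
  print(x$proposed)
  cat("Agreement (ARI) of each input with the proposal:\n")
  print(round(x$per_input_ari, 3))
  invisible(x)
}
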