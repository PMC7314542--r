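# Group-level inference: cluster-based permutation tests, rank and circular
# correlation families, percentile bootstrap for dependent correlations,
# effect sizes, and behavioral scoring.

#' Word-pair recall score
#'
#' Percentage of recalled word pairs, with semantically correct answers
#' weighted by 0.5.
#'
#' @param n_correct number of correctly recalled pairs.
#' @param n_semantic number of semantically correct pairs.
#' @param n_total total number of pairs.
#' @return recall percentage in \[0, 100\]; vectorized.
#' @export
score_recall <- function(n_correct, n_semantic, n_total) {
  if (any(n_total == 0)) stop("n_total must be positive")
  if (any(n_correct < 0 | n_semantic < 0)) stop("counts must be >= 0")
  if (any(n_correct + n_semantic > n_total)) stop("counts exceed n_total")
  100 * (n_correct + 0.5 * n_semantic) / n_total
}

# connected components over an adjacency list; nodes: integer ids
graph_components <- function(nodes, adj_list) {
  comp <- integer(0)
  label <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cur <- 0L
  for (v in nodes) {
    if (!is.na(label[as.character(v)])) next
    cur <- cur + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(label[as.character(u)])) next
      label[as.character(u)] <- cur
      nb <- adj_list[[u]]
      nb <- nb[nb %in% nodes]
      queue <- c(queue, nb[is.na(label[as.character(nb)])])
    }
  }
  split(nodes, label[as.character(nodes)])
}

# cluster sizes of supra-threshold points for one sign
# t: statistic vector; crit: threshold; adj_list: NULL for 1-D chains
signed_clusters <- function(t, crit, sign, adj_list = NULL) {
  supra <- if (sign > 0) t > crit else t < -crit
  if (!any(supra)) return(list())
  if (is.null(adj_list)) {
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    lapply(which(r$values), function(i) starts[i]:ends[i])
  } else {
    graph_components(which(supra), adj_list)
  }
}

max_cluster_size <- function(t, crit, adj_list = NULL) {
  cl <- c(signed_clusters(t, crit, 1, adj_list),
          signed_clusters(t, crit, -1, adj_list))
  if (length(cl) == 0L) 0L else max(lengths(cl))
}

#' Cluster-based permutation test for paired data
#'
#' Pointwise paired t-statistics over a grid (frequency bins, time points,
#' or channels); points exceeding the two-sided `cluster_alpha` threshold
#' are grouped into clusters by adjacency, the cluster statistic is the
#' cluster SIZE (max-size criterion), and the null distribution of the
#' maximum cluster size is built by randomly sign-flipping subjects.
#' Monte-Carlo p-values are two-sided through the shared max-size null over
#' both signs.
#'
#' @param data_a,data_b numeric matrices, subjects x grid points (paired).
#' @param adjacency `NULL` for a 1-D chain grid (neighbors = adjacent
#'   columns), or an adjacency list (one integer vector of neighbor indices
#'   per grid point) for channel grids.
#' @param n_perm permutation count.
#' @param cluster_alpha pointwise two-sided threshold forming clusters.
#' @param alpha cluster-level significance level.
#' @param seed integer seed.
#' @return object of class `cluster_result`: data.frame `clusters` with
#'   `size`, `sign`, `p`, `d` (mean pointwise Cohen's d over the cluster)
#'   and a list-column `members`; plus the pointwise `t` values.
#' @export
cluster_permutation_paired <- function(data_a, data_b, adjacency = NULL,
                                       n_perm = 1000, cluster_alpha = 0.05,
                                       alpha = 0.05, seed = 1L) {
  if (!all(dim(data_a) == dim(data_b))) stop("grid mismatch between conditions")
  n <- nrow(data_a)
  if (n < 5L) stop("need at least 5 paired subjects")
  d <- data_a - data_b
  p_grid <- ncol(d)
  crit <- stats::qt(1 - cluster_alpha / 2, n - 1)
  tstat <- function(m) {
    mu <- colMeans(m)
    s <- sqrt((colSums(m^2) - n * mu^2) / (n - 1))
    mu / (s / sqrt(n))
  }
  t_obs <- tstat(d)
  clusters <- c(lapply(signed_clusters(t_obs, crit, 1, adjacency),
                       function(m) list(members = m, sign = 1L)),
                lapply(signed_clusters(t_obs, crit, -1, adjacency),
                       function(m) list(members = m, sign = -1L)))
  set.seed(seed)
  # sign-flip null of the max cluster size; colSums(d^2) is flip-invariant,
  # so the permuted t-statistics come from the flipped means alone
  ss <- colSums(d^2)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  mu_perm <- (signs %*% d) / n
  sd_perm <- sqrt(sweep(-n * mu_perm^2, 2, ss, "+") / (n - 1))
  t_perm <- mu_perm / (sd_perm / sqrt(n))
  null_max <- vapply(seq_len(n_perm), function(b) {
    max_cluster_size(t_perm[b, ], crit, adjacency)
  }, 0L)
  res <- data.frame(size = integer(0), sign = integer(0), p = numeric(0),
                    d = numeric(0))
  members <- list()
  for (cl in clusters) {
    sz <- length(cl$members)
    p <- (1 + sum(null_max >= sz)) / (n_perm + 1)
    dd <- d[, cl$members, drop = FALSE]
    d_point <- colMeans(dd) / apply(dd, 2, stats::sd)
    res <- rbind(res, data.frame(size = sz, sign = cl$sign, p = p,
                                 d = mean(d_point)))
    members[[length(members) + 1L]] <- cl$members
  }
  res$significant <- res$p <= alpha
  structure(list(clusters = res, members = members, t = t_obs,
                 crit = crit, alpha = alpha, n_perm = n_perm),
            class = "cluster_result")
}

#' Cluster-corrected correlation test
#'
#' Pointwise Spearman correlations between a per-subject grid of predictors
#' (e.g. per-channel coupling-strength change) and one outcome (e.g. recall
#' change); rho is transformed to a t-value (p < `cluster_alpha` two-sided
#' threshold), supra-threshold points are clustered by adjacency (max-size
#' criterion) and compared against a permutation null built by shuffling
#' the outcome across subjects.
#'
#' @param x numeric matrix, subjects x grid points.
#' @param y outcome vector, one value per subject.
#' @inheritParams cluster_permutation_paired
#' @return a `cluster_result`; pointwise `rho` values included.
#' @export
cluster_permutation_corr <- function(x, y, adjacency = NULL, n_perm = 1000,
                                     cluster_alpha = 0.05, alpha = 0.05,
                                     seed = 1L) {
  n <- nrow(x)
  if (length(y) != n) stop("grid mismatch: y must have one value per subject")
  if (n < 5L) stop("need at least 5 subjects")
  rx <- apply(x, 2, rank)
  rho_of <- function(ry) {
    suppressWarnings(as.vector(stats::cor(ry, rx)))
  }
  rho_to_t <- function(rho) rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  crit <- stats::qt(1 - cluster_alpha / 2, n - 2)
  ry <- rank(y)
  rho_obs <- rho_of(ry)
  t_obs <- rho_to_t(rho_obs)
  clusters <- c(lapply(signed_clusters(t_obs, crit, 1, adjacency),
                       function(m) list(members = m, sign = 1L)),
                lapply(signed_clusters(t_obs, crit, -1, adjacency),
                       function(m) list(members = m, sign = -1L)))
  set.seed(seed)
  null_max <- vapply(seq_len(n_perm), function(b) {
    tb <- rho_to_t(rho_of(sample(ry)))
    max_cluster_size(tb, crit, adjacency)
  }, 0L)
  res <- data.frame(size = integer(0), sign = integer(0), p = numeric(0),
                    rho = numeric(0))
  members <- list()
  for (cl in clusters) {
    sz <- length(cl$members)
    p <- (1 + sum(null_max >= sz)) / (n_perm + 1)
    res <- rbind(res, data.frame(size = sz, sign = cl$sign, p = p,
                                 rho = mean(rho_obs[cl$members])))
    members[[length(members) + 1L]] <- cl$members
  }
  res$significant <- res$p <= alpha
  structure(list(clusters = res, members = members, t = t_obs,
                 rho = rho_obs, crit = crit, alpha = alpha, n_perm = n_perm),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cluster(s), max-size criterion, %d permutations\n",
              nrow(x$clusters), x$n_perm))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Spearman rank correlation
#'
#' @param x,y numeric vectors.
#' @return rho in \[-1, 1\]; `NA` for constant input.
#' @export
spearman <- function(x, y) {
  if (length(x) < 4L) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Partial Spearman correlation
#'
#' Rank-residual method: both variables are ranked, the covariate's ranks
#' are regressed out of each, and the residuals are correlated.
#'
#' @param x,y numeric vectors.
#' @param z single covariate to partial out.
#' @return partial rho; `NA` for constant input.
#' @export
partial_spearman <- function(x, y, z) {
  if (length(x) < 4L) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0) return(NA_real_)
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- stats::resid(stats::lm(rx ~ rz))
  ey <- stats::resid(stats::lm(ry ~ rz))
  # covariate explains a variable completely -> nothing left to correlate
  if (stats::sd(ex) < 1e-10 || stats::sd(ey) < 1e-10) return(0)
  stats::cor(ex, ey)
}

#' Circular-linear correlation
#'
#' Multiple correlation of a linear variable with the sine and cosine of a
#' circular one (the conventional circular-linear coefficient, in \[0, 1\]).
#'
#' @param phases circular variable (radians).
#' @param y linear variable.
#' @return rho in \[0, 1\]; `NA` for degenerate input.
#' @export
circ_linear_corr <- function(phases, y) {
  if (length(phases) < 5L) stop("need at least 5 observations")
  s <- sin(phases); c <- cos(phases)
  if (stats::sd(s) == 0 && stats::sd(c) == 0) return(NA_real_)
  if (stats::sd(y) == 0) return(NA_real_)
  rxs <- stats::cor(y, s); rxc <- stats::cor(y, c); rcs <- stats::cor(s, c)
  num <- rxc^2 + rxs^2 - 2 * rxc * rxs * rcs
  den <- 1 - rcs^2
  sqrt(pmin(pmax(num / den, 0), 1))
}

#' Circular-circular correlation
#'
#' Jammalamadaka-SenGupta correlation of paired angles.
#'
#' @param phases_a,phases_b paired circular variables (radians).
#' @return rho in \[-1, 1\]; `NA` for zero angular dispersion.
#' @export
circ_circ_corr <- function(phases_a, phases_b) {
  if (length(phases_a) < 5L) stop("need at least 5 observations")
  sa <- sin(phases_a - preferred_phase(phases_a))
  sb <- sin(phases_b - preferred_phase(phases_b))
  # zero angular dispersion in either sample: coefficient undefined
  if (sum(sa^2) < 1e-12 || sum(sb^2) < 1e-12) return(NA_real_)
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}

#' Percentile bootstrap for two dependent (overlapping) correlations
#'
#' Compares `cor(x1, y)` with `cor(x2, y)` (Spearman) when both share the
#' outcome `y`: subjects are resampled with replacement keeping the row
#' dependency, the difference of the two correlations is recomputed per
#' resample, and the percentile CI95 and p-value of the difference are
#' reported.  p = 2*min(P(diff <= 0), P(diff >= 0)) with add-one smoothing;
#' Z is the bootstrap mean over SD of the difference.
#'
#' @param x1,x2 predictor vectors.
#' @param y shared outcome.
#' @param n_boot bootstrap iterations.
#' @param seed integer seed.
#' @return list with `delta_rho` (observed), `Z`, `p`, `ci95`, `draws`.
#' @export
bootstrap_compare_dependent_corrs <- function(x1, y, x2, n_boot = 1000,
                                              seed = 1L) {
  n <- length(y)
  if (n < 10L) stop("need at least 10 subjects")
  set.seed(seed)
  draws <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    r1 <- suppressWarnings(stats::cor(x1[i], y[i], method = "spearman"))
    r2 <- suppressWarnings(stats::cor(x2[i], y[i], method = "spearman"))
    draws[b] <- r1 - r2
  }
  draws <- draws[is.finite(draws)]
  ci <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
  p <- 2 * min((1 + sum(draws <= 0)) / (length(draws) + 1),
               (1 + sum(draws >= 0)) / (length(draws) + 1))
  sdd <- stats::sd(draws)
  list(delta_rho = spearman(x1, y) - spearman(x2, y),
       Z = if (sdd > 0) mean(draws) / sdd else 0,
       p = min(p, 1), ci95 = ci, draws = draws)
}

#' Paired Cohen's d
#'
#' Mean of the paired differences over their standard deviation.
#'
#' @param a,b paired samples; the difference is `a - b`.
#' @return d; `NA` when the differences have zero variance.
#' @export
cohens_d_paired <- function(a, b) {
  d <- a - b
  s <- stats::sd(d)
  # guard numerically constant differences (e.g. b = a + c)
  if (is.na(s) || s < 1e-10 * max(1, abs(mean(d)))) return(NA_real_)
  mean(d) / s
}

#' Cluster effect size
#'
#' Mean of pointwise paired Cohen's d over the member points of a cluster.
#'
#' @param data_a,data_b subjects x grid matrices.
#' @param cluster integer vector of member grid indices.
#' @return mean d over the cluster.
#' @export
cluster_effect_size <- function(data_a, data_b, cluster) {
  d <- vapply(cluster, function(j) cohens_d_paired(data_a[, j], data_b[, j]),
              0)
  mean(d)
}

#' Channel adjacency for the 11-channel 10-20 montage
#'
#' Reads the shipped neighbor table and returns an adjacency list for the
#' requested montage (subset of F3, Fz, F4, C3, Cz, C4, P3, Pz, P4, O1, O2),
#' in the format [cluster_permutation_paired()] expects.
#'
#' @param channels channel labels, in grid order.
#' @return list of integer neighbor-index vectors, one per channel.
#' @export
channel_adjacency <- function(channels) {
  path <- system.file("extdata", "adjacency_1020.txt", package = "socoupling")
  tab <- utils::read.table(path, header = FALSE, col.names = c("a", "b"),
                           stringsAsFactors = FALSE)
  lapply(seq_along(channels), function(i) {
    nb <- c(tab$b[tab$a == channels[i]], tab$a[tab$b == channels[i]])
    which(channels %in% nb)
  })
}
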