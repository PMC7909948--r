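#' Hierarchical bootstrap test
#'
#' Units recorded on one array are not independent; the hierarchical
#' bootstrap respects this by resampling recording sites with replacement
#' and then units within each sampled site with replacement, before
#' applying the statistic. The two-sided p-value for a location test
#' against 0 is `2 * min(frac <= 0, frac >= 0)` over the bootstrap
#' distribution, floored at `1/n_iter` (reported as `"< 1/n_iter"` when no
#' crossing occurs — the printed floor of the resampling resolution).
#'
#' @param values Numeric per-unit values (e.g. per-unit MI differences for
#'   a paired test).
#' @param groups Recording-site id per unit. A single site falls back to a
#'   flat bootstrap with a warning.
#' @param statistic `"mean"` or `"median"`.
#' @param n_iter Bootstrap iterations (default 10000).
#' @param seed Integer seed; results are deterministic given it.
#' @return List: `estimate` (statistic on the full data), `ci` (2.5/97.5
#'   percentile), `p`, `p_label`, `n_iter`, `seed`.
#' @export
hierarchical_bootstrap <- function(values, groups,
                                   statistic = c("mean", "median"),
                                   n_iter = 10000, seed = 1) {
  statistic <- match.arg(statistic)
  stat_fn <- if (statistic == "mean") mean else stats::median
  stopifnot(length(values) == length(groups))
  idx <- split(seq_along(values), groups)
  if (length(idx) < 2) {
    warning("single recording site: falling back to flat bootstrap")
    idx <- as.list(seq_along(values))
  }
  n_sites <- length(idx)
  boot <- with_seed(seed, vapply(seq_len(n_iter), function(i) {
    sites <- sample.int(n_sites, n_sites, replace = TRUE)
    v <- unlist(lapply(idx[sites], function(u)
      values[u[sample.int(length(u), length(u), replace = TRUE)]]),
      use.names = FALSE)
    stat_fn(v)
  }, numeric(1)))
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  p <- min(p, 1)
  floored <- p == 0
  if (floored) p <- 1 / n_iter
  list(estimate = stat_fn(values),
       ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
       p = p,
       p_label = if (floored) paste0("< ", format(1 / n_iter)) else
         format(p),
       n_iter = n_iter, seed = seed)
}

#' Hierarchical bootstrap test of a correlation
#'
#' Point estimate is the Pearson correlation over all pairs; the p-value
#' comes from the hierarchical bootstrap distribution of r (sites, then
#' units within sites) tested against 0, two-sided.
#'
#' @param x,y Paired per-unit values.
#' @param groups Recording-site id per unit.
#' @param n_iter,seed As in [hierarchical_bootstrap()].
#' @return List: `r`, `ci`, `p`, `p_label`, `n_iter`, `seed`.
#' @export
bootstrap_correlation <- function(x, y, groups, n_iter = 10000, seed = 1) {
  stopifnot(length(x) == length(y), length(x) == length(groups))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant input")
  }
  idx <- split(seq_along(x), groups)
  if (length(idx) < 2) {
    warning("single recording site: falling back to flat bootstrap")
    idx <- as.list(seq_along(x))
  }
  n_sites <- length(idx)
  boot <- with_seed(seed, vapply(seq_len(n_iter), function(i) {
    sites <- sample.int(n_sites, n_sites, replace = TRUE)
    sel <- unlist(lapply(idx[sites], function(u)
      u[sample.int(length(u), length(u), replace = TRUE)]),
      use.names = FALSE)
    if (stats::sd(x[sel]) == 0 || stats::sd(y[sel]) == 0) return(NA_real_)
    stats::cor(x[sel], y[sel])
  }, numeric(1)))
  boot <- boot[is.finite(boot)]
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  p <- min(p, 1)
  floored <- p == 0
  if (floored) p <- 1 / n_iter
  list(r = stats::cor(x, y),
       ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
       p = p,
       p_label = if (floored) paste0("< ", format(1 / n_iter)) else format(p),
       n_iter = n_iter, seed = seed)
}

# all permutations of 1..n (n small), one per column
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (j in seq_len(ncol(sub))) {
      col <- col + 1
      out[, col] <- c(k, rest[sub[, j]])
    }
  }
  out
}

#' Permutation test for independence of task and pupil effects
#'
#' Asks whether units showing both task- and pupil-unique effects are more
#' common than expected if the two effects occurred independently: one flag
#' vector is permuted across units and the joint count re-tallied. The
#' one-sided (enrichment) p is the fraction of permutations whose joint
#' count is at least the observed one. For small populations
#' (`n! <= 40320`, i.e. n <= 8) the test enumerates all permutations
#' exactly; otherwise it samples `n_iter` random permutations.
#'
#' @param sig_task,sig_pupil Logical per-unit significance flags.
#' @param n_iter Random permutations when enumeration is infeasible.
#' @param seed Seed for the sampled variant.
#' @param exact `"auto"` (enumerate when n <= 8), `TRUE`, or `FALSE`.
#' @return List: `p`, `observed` joint count, `expected` (null mean),
#'   `exact` flag, `n_iter` used.
#' @export
independence_permutation_test <- function(sig_task, sig_pupil,
                                          n_iter = 10000, seed = 1,
                                          exact = "auto") {
  stopifnot(length(sig_task) == length(sig_pupil))
  a <- as.logical(sig_task)
  b <- as.logical(sig_pupil)
  n <- length(a)
  obs <- sum(a & b)
  use_exact <- isTRUE(exact) || (identical(exact, "auto") && n <= 8)
  if (use_exact) {
    pm <- all_perms(n)
    counts <- vapply(seq_len(ncol(pm)), function(j) sum(a & b[pm[, j]]),
                     integer(1))
    list(p = mean(counts >= obs), observed = obs, expected = mean(counts),
         exact = TRUE, n_iter = ncol(pm))
  } else {
    counts <- with_seed(seed, vapply(seq_len(n_iter), function(i)
      sum(a & b[sample.int(n)]), integer(1)))
    list(p = mean(counts >= obs), observed = obs, expected = mean(counts),
         exact = FALSE, n_iter = n_iter)
  }
}
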