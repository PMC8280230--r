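# compositional beta diversity: dissimilarity, nested variance partitioning,
# distance decay, Mantel inference and power, ordination

#' Bray-Curtis dissimilarity among samples
#'
#' Read counts are square-root transformed first; biomass is used as
#' observed. A pair in which both samples are entirely empty is defined as
#' dissimilarity 0 (with a warning).
#'
#' @param x a `community_matrix`.
#' @return symmetric dissimilarity matrix in `[0, 1]` with a `"transform"`
#'   attribute (`"sqrt-reads"` or `"raw-biomass"`).
#' @export
bray_curtis <- function(x) {
  m <- unclass(x)
  transform <- if (abundance_mode(x) == "reads") {
    m <- sqrt(m)
    "sqrt-reads"
  } else "raw-biomass"
  D <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  empty <- rowSums(m) == 0
  if (any(empty)) {
    # a pair of entirely empty samples carries no compositional signal
    warning("pair(s) of all-zero samples: dissimilarity set to 0")
    D[empty, empty] <- 0
  }
  D[is.na(D)] <- 0
  attr(D, "transform") <- transform
  D
}

# pooled within-group sum of squared distances: sum_g (1/n_g) sum_{i<j in g} d^2
.ss_within <- function(D2, groups) {
  sum(vapply(split(seq_len(nrow(D2)), groups), function(i)
    sum(D2[i, i, drop = FALSE]) / (2 * length(i)), numeric(1)))
}

#' Hierarchical variance partitioning of compositional dissimilarity
#'
#' Decomposes the total variation in a dissimilarity matrix across a fully
#' nested sampling hierarchy using distance-based sums of squares (the
#' McArdle-Anderson identity `SS = sum d^2 / n` within groups) and
#' method-of-moments (expected-mean-squares) variance components for the
#' unbalanced nested random model. Components are expressed as percentages
#' of the total variance; intermediate components may be negative and are
#' reported as computed. The finest stratum (variation among samples within
#' the finest grouping) is the residual mean square.
#'
#' @param D dissimilarity matrix (e.g. [bray_curtis()]).
#' @param design a [sample_design()].
#' @param levels design columns, coarsest first (e.g.
#'   `c("site_id", "transect_id")` for bottle samples; the residual is then
#'   among-bottle variation).
#' @return data frame with one row per component (each level plus
#'   `"residual"`): variance estimate and `percent`; percentages sum to 100.
#'   A level with a single group gets `NA` (undefined component).
#' @export
hierarchical_varpart <- function(D, design, levels = c("site_id",
                                                       "transect_id")) {
  ids <- rownames(D)
  idx <- match(ids, design$sample_id)
  if (anyNA(idx)) stop("sample(s) missing from design: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  des <- design[idx, , drop = FALSE]
  n <- nrow(D)
  D2 <- D^2
  groupings <- lapply(levels, function(lv) as.character(des[[lv]]))
  a <- vapply(groupings, function(g) length(unique(g)), integer(1))
  if (any(diff(a) < 0)) stop("levels must be ordered coarsest first")
  L <- length(levels)

  ss_tot <- sum(D2) / (2 * n)
  ss_w <- vapply(groupings, function(g) .ss_within(D2, g), numeric(1))
  # among-stratum SS and df (stratum l = among groups of level l)
  ss_among <- diff(c(ss_tot - ss_tot, ss_tot - ss_w))     # = c(ss_tot-ss_w[1], ...)
  df_among <- diff(c(1L, a))
  ss_res <- ss_w[L]
  df_res <- n - a[L]
  if (df_res <= 0) stop("no replication below the finest level")

  # EMS coefficients: S[l, m] = sum over groups g of level l of
  # (sum of n_h^2 over level-m subgroups h of g) / n_g; level 0 = grand group
  sizes <- lapply(groupings, function(g) table(g)[unique(g)])
  S_lm <- function(l, m) {
    gl <- if (l == 0) rep("all", n) else groupings[[l]]
    gm <- groupings[[m]]
    sum(vapply(split(seq_len(n), gl), function(i)
      sum(table(gm[i])^2) / length(i), numeric(1)))
  }
  ms_res <- ss_res / df_res
  sigma2 <- numeric(L)
  # solve from the finest stratum upward
  for (l in rev(seq_len(L))) {
    if (df_among[l] <= 0) { sigma2[l] <- NA_real_; next }
    ms_l <- ss_among[l] / df_among[l]
    rhs <- ms_l - ms_res
    if (l < L) {
      for (m in seq(l + 1, L)) {
        c_lm <- (S_lm(l, m) - S_lm(l - 1, m)) / df_among[l]
        rhs <- rhs - c_lm * sigma2[m]
      }
    }
    c_ll <- (n - S_lm(l - 1, l)) / df_among[l]
    sigma2[l] <- rhs / c_ll
  }
  comp <- c(sigma2, ms_res)
  total <- sum(comp, na.rm = TRUE)
  data.frame(component = c(levels, "residual"),
             variance = comp,
             percent = 100 * comp / total,
             stringsAsFactors = FALSE)
}

# --- fast Mantel machinery -------------------------------------------------

# precompute a permutation gather-index: entry [p, k] is the linear index of
# the upper-triangle entry p of a symmetric n x n matrix after relabelling
# samples by permutation k
.mantel_perm_index <- function(n, n_perm) {
  ut <- which(upper.tri(matrix(0, n, n)))
  ri <- ((ut - 1) %% n) + 1
  ci <- ((ut - 1) %/% n) + 1
  idx <- matrix(0L, length(ut), n_perm)
  for (k in seq_len(n_perm)) {
    pm <- sample.int(n)
    idx[, k] <- (pm[ci] - 1L) * n + pm[ri]
  }
  idx
}

# correlation of D's upper triangle with zg (standardized), plus the
# permutation null via a precomputed gather index; the multiset of
# upper-triangle values is invariant under joint row/column permutation, so
# only one centering/scaling of D is needed
.mantel_fast <- function(D, zg, ut, idx) {
  np <- length(ut)
  dv <- D[ut]
  sD <- stats::sd(dv)
  if (sD == 0) stop("constant dissimilarity vector: Mantel statistic undefined")
  robs <- sum(zg * (dv - mean(dv))) / (sD * (np - 1))
  rp <- as.numeric(crossprod(matrix(D[idx], nrow = np), zg)) / (sD * (np - 1))
  list(r = robs, perm = rp)
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the upper triangles, with significance from
#' permuting the sample labels of the first matrix. One-tailed by default
#' (positive association, the distance-decay alternative).
#'
#' @param D,G symmetric matrices over the same samples in the same order.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`.
#' @return list with `statistic`, `p_value`, `n_perm`, and the null vector
#'   `perm`.
#' @export
mantel_test <- function(D, G, n_perm = 999, seed = NULL,
                        alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- nrow(D)
  if (!all(dim(G) == dim(D))) stop("matrices must share dimensions")
  ut <- which(upper.tri(D))
  gv <- G[ut]
  if (stats::sd(gv) == 0) stop("constant distance vector: test undefined")
  zg <- (gv - mean(gv)) / stats::sd(gv)
  res <- with_seed(seed, {
    idx <- .mantel_perm_index(n, n_perm)
    .mantel_fast(D, zg, ut, idx)
  })
  p <- switch(alternative,
              greater = (1 + sum(res$perm >= res$r)) / (n_perm + 1),
              less = (1 + sum(res$perm <= res$r)) / (n_perm + 1),
              two.sided = (1 + sum(abs(res$perm) >= abs(res$r))) /
                (n_perm + 1))
  list(statistic = res$r, p_value = p, n_perm = n_perm, perm = res$perm)
}

#' Distance decay of ecological similarity
#'
#' Regresses pairwise ecological similarity `1 - D` on geographic distance
#' (ordinary least squares over all unordered pairs) and tests the spatial
#' association of the two matrices with a Mantel permutation test, one-tailed
#' toward the sign of the observed statistic.
#'
#' @param D dissimilarity matrix.
#' @param geo geographic distance matrix (km), same sample order.
#' @param n_perm Mantel permutations.
#' @param seed integer seed.
#' @return a `distance_decay` list: `intercept` (similarity at distance 0),
#'   `slope` (per km), `mantel_r`, `mantel_p`, `n_perm`.
#' @export
distance_decay <- function(D, geo, n_perm = 999, seed = NULL) {
  ut <- which(upper.tri(D))
  g <- geo[ut]
  if (stats::sd(g) == 0) stop("constant distance vector: fit undefined")
  sim <- 1 - D[ut]
  fit <- stats::lm(sim ~ g)
  mt0 <- mantel_test(D, geo, n_perm = 1, seed = seed)
  side <- if (mt0$statistic >= 0) "greater" else "less"
  mt <- mantel_test(D, geo, n_perm = n_perm, seed = seed, alternative = side)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 mantel_r = mt$statistic, mantel_p = mt$p_value,
                 n_perm = n_perm), class = "distance_decay")
}

#' @export
print.distance_decay <- function(x, ...) {
  cat("distance decay: similarity =", signif(x$intercept, 4), "+",
      signif(x$slope, 4), "* km\n")
  cat("Mantel r =", signif(x$mantel_r, 4), ", p =", signif(x$mantel_p, 4),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}

# one simulated survey on a fixed geometry; returns its dissimilarity matrix
.simulate_survey_D <- function(method, config, theta) {
  cfg <- config
  cfg$sorting_strength <- theta
  ls <- simulate_landscape(cfg)
  x <- if (method == "eDNA") simulate_edna_reads(ls, cfg) else
    simulate_uvc_survey(ls, cfg)
  # empty transects can occur under sparse detection; their zero pairs are
  # defined as 0 and carry no signal
  suppressWarnings(bray_curtis(x))
}

#' Power of the Mantel test under the study sampling geometry
#'
#' Simulation-based power analysis conditioned on the hierarchical sampling
#' geometry: communities are generated by the landscape generator on the
#' fixed site/transect/replicate layout, observed through the chosen survey
#' process (multinomial reads or visual census), and their Bray-Curtis
#' matrices tested against the fixed geographic distance matrix with a
#' one-tailed Mantel permutation test. For each target effect size the
#' generator's sorting strength is calibrated by bisection (common random
#' numbers) so the mean realized Mantel correlation matches the target; power
#' is the rejection fraction over `n_sim` independent surveys.
#'
#' The null variance of the Mantel statistic depends strongly on the
#' structure of both matrices, so power is only meaningful conditioned on a
#' concrete geometry; an simulation with independent pair-level noise badly
#' overstates power.
#'
#' @param method `"eDNA"` (49 bottles) or `"UVC"` (27 transects) under the
#'   default design.
#' @param r_grid effect sizes (target Mantel correlations) in `[0, 0.5]`.
#' @param config a [simulation_config()]; defaults are the study design.
#' @param alpha significance level.
#' @param n_sim simulated surveys per effect size.
#' @param n_perm Mantel permutations per test.
#' @param n_cal simulations per bisection step during calibration.
#' @param cal_tol calibration tolerance on the mean Mantel correlation.
#' @param seed integer seed.
#' @return a `mantel_power_curve` data frame: `r`, `theta`, `mean_r`
#'   (realized), `power`, plus attributes recording the settings.
#' @export
mantel_power <- function(method = c("eDNA", "UVC"),
                         r_grid = seq(0, 0.5, by = 0.1),
                         config = simulation_config(),
                         alpha = 0.05, n_sim = 1000, n_perm = 999,
                         n_cal = 400, cal_tol = 0.005, seed = NULL) {
  method <- match.arg(method)
  if (any(r_grid < 0)) stop("effect sizes must be non-negative")
  with_seed(seed, {
    geom <- simulate_landscape(config)
    des <- if (method == "eDNA") geom$design_edna else geom$design_uvc
    geo <- geo_distances(des)
    n <- nrow(geo)
    ut <- which(upper.tri(geo))
    gv <- geo[ut]
    zg <- (gv - mean(gv)) / stats::sd(gv)
    idx <- .mantel_perm_index(n, n_perm)
    cal_seeds <- sample.int(.Machine$integer.max %/% 2, n_cal)
    sim_seeds <- sample.int(.Machine$integer.max %/% 2, n_sim)

    mean_r_at <- function(theta) {
      mean(vapply(cal_seeds, function(s) with_seed(s, {
        D <- .simulate_survey_D(method, config, theta)
        dv <- D[ut]
        sum(zg * (dv - mean(dv))) / (stats::sd(dv) * (length(ut) - 1))
      }), numeric(1)))
    }
    calibrate <- function(target) {
      if (target == 0) return(list(theta = 0, mean_r = mean_r_at(0)))
      lo <- 0; hi <- 1
      m_hi <- mean_r_at(hi)
      if (m_hi < target) {
        stop("target Mantel correlation ", target,
             " unreachable: maximum attainable mean r is ",
             signif(m_hi, 3))
      }
      for (it in 1:25) {
        mid <- (lo + hi) / 2
        m <- mean_r_at(mid)
        if (abs(m - target) < cal_tol) return(list(theta = mid, mean_r = m))
        if (m > target) hi <- mid else lo <- mid
      }
      list(theta = mid, mean_r = m)
    }

    rows <- lapply(r_grid, function(r) {
      cal <- calibrate(r)
      rej <- 0; rsum <- 0
      for (s in sim_seeds) {
        D <- with_seed(s, .simulate_survey_D(method, config, cal$theta))
        mt <- .mantel_fast(D, zg, ut, idx)
        p <- (1 + sum(mt$perm >= mt$r)) / (n_perm + 1)
        if (p <= alpha) rej <- rej + 1
        rsum <- rsum + mt$r
      }
      data.frame(r = r, theta = cal$theta, mean_r = rsum / n_sim,
                 power = rej / n_sim)
    })
    out <- do.call(rbind, rows)
    attr(out, "method") <- method
    attr(out, "n_samples") <- n
    attr(out, "alpha") <- alpha
    attr(out, "n_sim") <- n_sim
    attr(out, "n_perm") <- n_perm
    class(out) <- c("mantel_power_curve", "data.frame")
    out
  })
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS with random restarts (vegan's engine); the best
#' configuration over restarts is returned, deterministic under a seed.
#'
#' @param D dissimilarity matrix.
#' @param k embedding dimension.
#' @param n_restarts random restarts.
#' @param seed integer seed.
#' @return list with `points` (n x k), `stress`, and `converged`.
#' @export
nmds_embed <- function(D, k = 2, n_restarts = 20, seed = NULL) {
  fit <- with_seed(seed, suppressWarnings(
    vegan::metaMDS(stats::as.dist(D), k = k, trymax = n_restarts,
                   trace = 0)))
  if (!fit$converged) {
    warning("NMDS did not converge in ", n_restarts,
            " restarts; best attempt returned")
  }
  list(points = fit$points, stress = fit$stress,
       converged = isTRUE(fit$converged) || is.numeric(fit$converged))
}
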