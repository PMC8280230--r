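# spatially ordered taxa-area relationships and competing model fits

#' Build a spatially ordered taxa-area curve
#'
#' Starting from every sample in turn, grows the selected set by repeatedly
#' adding the unselected sample closest to *any* already-selected sample
#' (single-linkage growth, so the growing set stays spatially contiguous),
#' recording cumulative richness. Curve statistics are taken across the N
#' resulting orderings: the mean and the 2.5/97.5 percentile band.
#'
#' @param x a `community_matrix`.
#' @param geo distance matrix from [geo_distances()], matching rows of `x`.
#' @return a `tar_curve`: data frame `S`, `mean_richness`, `ci_low`,
#'   `ci_high`, with the per-ordering richness matrix in attribute
#'   `"orderings"`.
#' @export
build_tar <- function(x, geo) {
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples")
  ids <- rownames(x)
  if (!identical(ids, rownames(geo))) geo <- geo[ids, ids]
  pres <- unclass(x) > 0
  rich <- matrix(0L, n, n)  # orderings in rows
  for (s in seq_len(n)) {
    sel <- s
    acc <- pres[s, ]
    rich[s, 1] <- sum(acc)
    for (k in 2:n) {
      rest <- setdiff(seq_len(n), sel)
      d <- if (length(sel) == 1) geo[rest, sel] else
        apply(geo[rest, sel, drop = FALSE], 1, min)
      cand <- rest[d == min(d)]
      nxt <- cand[order(ids[cand])][1]  # distance ties: lexicographic id
      sel <- c(sel, nxt)
      acc <- acc | pres[nxt, ]
      rich[s, k] <- sum(acc)
    }
  }
  out <- data.frame(S = seq_len(n),
                    mean_richness = colMeans(rich),
                    ci_low = apply(rich, 2, stats::quantile, 0.025),
                    ci_high = apply(rich, 2, stats::quantile, 0.975))
  attr(out, "orderings") <- rich
  attr(out, "n_focal") <- n
  class(out) <- c("tar_curve", "data.frame")
  out
}

.aic_gauss <- function(rss, n, k) {
  # gaussian profile-likelihood AIC; k counts mean-function parameters
  n * log(max(rss, 1e-300) / n) + 2 * (k + 1)
}

#' Fit competing richness-accumulation models
#'
#' Least-squares fits of four forms to the mean accumulation curve: linear
#' `y = a + b S`, exponential `y = a e^(bS)`, power `y = a S^b`, and a
#' continuous one-breakpoint piecewise-linear model fitted by iterative
#' breakpoint linearization (gap-variable updates from a median start until
#' `|delta psi| < 1e-6` or 50 iterations), with a delta-method 95% CI on the
#' breakpoint. Nonlinear fits are initialized by log-linearization and
#' refined by `nls`. Models are ranked by AIC.
#'
#' @param curve a [build_tar()] curve (or any data frame with `S` and
#'   `mean_richness`).
#' @param forms subset of `c("linear", "exponential", "power", "piecewise")`.
#' @return list of `tar_fit` objects, ordered by increasing AIC.
#' @export
fit_tar_models <- function(curve,
                           forms = c("linear", "exponential", "power",
                                     "piecewise")) {
  S <- curve$S
  y <- curve$mean_richness
  if (length(S) < 5) stop("need at least 5 curve points")
  fits <- list()

  if ("linear" %in% forms) {
    fm <- stats::lm(y ~ S)
    fits$linear <- list(form = "linear",
                        params = c(a = unname(stats::coef(fm)[1]),
                                   b = unname(stats::coef(fm)[2])),
                        rss = sum(stats::resid(fm)^2),
                        aic = .aic_gauss(sum(stats::resid(fm)^2),
                                         length(S), 2),
                        converged = TRUE)
  }
  nls_fit <- function(formula, start, k, form) {
    fm <- tryCatch(suppressWarnings(
      stats::nls(formula, data.frame(S = S, y = y), start = start,
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fm)) return(NULL)
    rss <- sum(stats::resid(fm)^2)
    list(form = form, params = stats::coef(fm), rss = rss,
         aic = .aic_gauss(rss, length(S), k), converged = fm$convInfo$isConv)
  }
  if ("exponential" %in% forms && all(y > 0)) {
    init <- stats::lm(log(y) ~ S)
    fits$exponential <- nls_fit(y ~ a * exp(b * S),
                                list(a = exp(stats::coef(init)[1]),
                                     b = stats::coef(init)[2]),
                                2, "exponential")
  }
  if ("power" %in% forms && all(y > 0)) {
    init <- stats::lm(log(y) ~ log(S))
    fits$power <- nls_fit(y ~ a * S^b,
                          list(a = exp(stats::coef(init)[1]),
                               b = stats::coef(init)[2]),
                          2, "power")
  }
  if ("piecewise" %in% forms) {
    fits$piecewise <- .fit_piecewise(S, y)
  }
  fits <- Filter(Negate(is.null), fits)
  fits <- fits[order(vapply(fits, `[[`, numeric(1), "aic"))]
  lapply(fits, function(f) structure(f, class = "tar_fit"))
}

# continuous one-breakpoint piecewise linear fit (iterative linearization)
.fit_piecewise <- function(S, y, psi = NULL, tol = 1e-6, max_iter = 50) {
  psi <- psi %||% stats::median(S)
  lo <- min(S) + 1e-8
  hi <- max(S) - 1e-8
  converged <- FALSE
  fm <- NULL
  for (it in seq_len(max_iter)) {
    U <- pmax(S - psi, 0)
    V <- -(S > psi)
    fm <- stats::lm(y ~ S + U + V)
    cf <- stats::coef(fm)
    if (!is.finite(cf["U"]) || abs(cf["U"]) < 1e-10) break  # no slope change
    step <- unname(cf["V"] / cf["U"])
    if (!is.finite(step)) break
    psi_new <- min(max(psi + step, lo), hi)
    if (abs(psi_new - psi) < tol) {
      psi <- psi_new
      converged <- TRUE
      break
    }
    psi <- psi_new
  }
  U <- pmax(S - psi, 0)
  V <- -(S > psi)
  fm <- stats::lm(y ~ S + U + V)
  cf <- stats::coef(fm)
  # delta-method SE of the breakpoint from the gap coefficient
  vc <- suppressWarnings(stats::vcov(fm))
  se_psi <- if (is.finite(cf["U"]) && abs(cf["U"]) > 1e-10 &&
                all(is.finite(vc))) {
    sqrt(vc["V", "V"]) / abs(cf["U"])
  } else NA_real_
  tq <- stats::qt(0.975, length(S) - 4L)
  final <- stats::lm(y ~ S + U)
  rss <- sum(stats::resid(final)^2)
  b1 <- unname(stats::coef(final)["S"])
  list(form = "piecewise",
       params = c(a = unname(stats::coef(final)[1]),
                  slope1 = b1,
                  slope2 = b1 + unname(stats::coef(final)["U"])),
       breakpoint = unname(psi),
       breakpoint_ci = unname(psi + c(-1, 1) * tq * se_psi),
       rss = rss,
       # 4 mean parameters: intercept, slope, slope change, breakpoint
       aic = .aic_gauss(rss, length(S), 4),
       converged = converged)
}

#' @export
print.tar_fit <- function(x, ...) {
  cat(x$form, "fit:",
      paste(names(x$params), signif(unlist(x$params), 4), sep = "=",
            collapse = ", "), "\n")
  if (!is.null(x$breakpoint)) {
    cat("  breakpoint:", signif(x$breakpoint, 5), " 95% CI [",
        paste(signif(x$breakpoint_ci, 5), collapse = ", "), "]\n")
  }
  cat("  RSS:", signif(x$rss, 4), " AIC:", signif(x$aic, 5), "\n")
  invisible(x)
}

#' Extend a taxa-area curve with a historical sample pool
#'
#' Bootstraps the continuation of the accumulation curve beyond the focal
#' samples: each bootstrap appends randomly ordered pool samples and
#' continues cumulative richness from the full focal set; mean and 2.5/97.5
#' percentile CI are taken over bootstraps.
#'
#' @param curve focal [build_tar()] curve.
#' @param x focal `community_matrix` (the one `curve` was built from).
#' @param pool historical `community_matrix`; taxa are aligned with `x` by
#'   name (new taxa extend the union).
#' @param n_boot number of bootstraps (default 499).
#' @param n_extra how many pool samples to append (default all; truncated
#'   with a warning when the pool is smaller).
#' @param replace draw pool samples with replacement within a bootstrap.
#' @param seed integer seed.
#' @return a `tar_curve` covering `S = 1 .. N + n_extra`; rows beyond the
#'   focal N carry the bootstrap statistics (attribute `"n_focal"` marks the
#'   boundary).
#' @export
extend_tar_with_pool <- function(curve, x, pool, n_boot = 499,
                                 n_extra = NULL, replace = FALSE,
                                 seed = NULL) {
  n <- attr(curve, "n_focal")
  n_extra <- n_extra %||% nrow(pool)
  if (!replace && n_extra > nrow(pool)) {
    warning("pool smaller than requested extension; truncating to ",
            nrow(pool), " samples")
    n_extra <- nrow(pool)
  }
  taxa <- union(colnames(x), colnames(pool))
  focal_acc <- logical(length(taxa))
  names(focal_acc) <- taxa
  focal_acc[colnames(x)] <- colSums(unclass(x) > 0) > 0
  pool_pres <- matrix(FALSE, nrow(pool), length(taxa),
                      dimnames = list(rownames(pool), taxa))
  pool_pres[, colnames(pool)] <- unclass(pool) > 0
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ord <- sample(nrow(pool), n_extra, replace = replace)
      acc <- focal_acc
      out <- integer(n_extra)
      for (k in seq_len(n_extra)) {
        acc <- acc | pool_pres[ord[k], ]
        out[k] <- sum(acc)
      }
      out
    }, integer(n_extra))
  })
  boot <- matrix(boot, nrow = n_extra)
  ext <- data.frame(S = n + seq_len(n_extra),
                    mean_richness = rowMeans(boot),
                    ci_low = apply(boot, 1, stats::quantile, 0.025),
                    ci_high = apply(boot, 1, stats::quantile, 0.975))
  out <- rbind(as.data.frame(curve)[, names(ext)], ext)
  attr(out, "n_focal") <- n
  attr(out, "n_boot") <- n_boot
  class(out) <- c("tar_curve", "data.frame")
  out
}

#' Sampling effort needed to reach a target richness
#'
#' Inverts the (possibly extended) mean accumulation curve by linear
#' interpolation: the smallest effort at which mean richness reaches
#' `target`.
#'
#' @param curve a `tar_curve`.
#' @param target richness to reach.
#' @return effort (number of samples, interpolated); `Inf` when the curve
#'   never reaches the target.
#' @export
samples_to_reach <- function(curve, target) {
  y <- curve$mean_richness
  S <- curve$S
  if (target <= y[1]) return(S[1])
  i <- which(y >= target)[1]
  if (is.na(i)) return(Inf)
  S[i - 1] + (target - y[i - 1]) / (y[i] - y[i - 1]) * (S[i] - S[i - 1])
}
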