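# additive partitioning of regional richness over a nested sampling hierarchy

.pooled_richness <- function(pres, groups) {
  pooled <- rowsum(pres + 0, groups) > 0
  rowSums(pooled)
}

#' Additive partition of regional taxonomic richness
#'
#' Decomposes regional richness (gamma) into the mean richness of the lowest
#' sampling units (alpha) plus one beta component per hierarchy level:
#' `beta_sample` is the gain from pooling samples within the first grouping
#' level, each further `beta_<level>` the gain from pooling one level up, and
#' the top beta the gain from pooling groups into the region. Components
#' telescope, so `alpha + sum(beta) == gamma` exactly.
#'
#' @param x a `community_matrix`; presence is abundance > 0.
#' @param design a [sample_design()] covering every row of `x`.
#' @param levels design columns to pool by, finest first (e.g.
#'   `c("transect_id", "site_id")` for bottle samples).
#' @return a `partition_result` with observed components only.
#' @export
additive_partition <- function(x, design,
                               levels = c("transect_id", "site_id")) {
  idx <- match(rownames(x), design$sample_id)
  if (anyNA(idx)) {
    stop("sample(s) missing from design: ",
         paste(rownames(x)[is.na(idx)], collapse = ", "))
  }
  des <- design[idx, , drop = FALSE]
  for (lv in levels) {
    if (!lv %in% names(des)) stop("level '", lv, "' not a design column")
    if (any(is.na(des[[lv]]) | !nzchar(des[[lv]]))) {
      stop("sample(s) without a '", lv, "' assignment")
    }
  }
  pres <- unclass(x) > 0
  alpha_bar <- c(mean(rowSums(pres)),
                 vapply(levels, function(lv)
                   mean(.pooled_richness(pres, des[[lv]])), numeric(1)))
  gamma <- sum(colSums(pres) > 0)
  comp <- diff(c(alpha_bar, gamma))
  names(comp) <- paste0("beta_", c("sample", levels))
  out <- list(gamma = gamma,
              alpha = unname(alpha_bar[1]),
              components = c(alpha = unname(alpha_bar[1]), comp),
              levels = levels,
              n_samples = nrow(x))
  class(out) <- "partition_result"
  out
}

#' Significance of partition components by matrix randomization
#'
#' Compares each observed component with its distribution under an
#' individual-based null in which every read (individual) is reshuffled
#' across the sample-by-taxon matrix conditional on both margins, so each
#' randomized matrix keeps every sample's total count and every taxon's total
#' count (Patefield two-margin algorithm, `stats::r2dtable`). An
#' occurrence-based alternative (`scheme = "occurrence"`) randomizes the
#' presence matrix preserving occupancy margins (curveball algorithm).
#'
#' One-sided p-values use the add-one rule
#' `p_high = (1 + #\{null >= obs\}) / (n_iter + 1)` (and symmetrically for
#' `p_low`); a component is flagged `"+"` when `p_high <= alpha`, `"-"` when
#' `p_low <= alpha`, else `"NS"`.
#'
#' @inheritParams additive_partition
#' @param scheme `"individual"` (two-margin read reshuffle; integer counts
#'   required) or `"occurrence"`.
#' @param n_iter number of randomizations (default 999).
#' @param seed integer seed.
#' @param alpha flag threshold.
#' @param check_margins assert the margins of every null matrix (slow; used
#'   in tests).
#' @return a `partition_result` whose `table` holds observed value, null mean
#'   and sd, `p_low`, `p_high` and flag per component.
#' @export
partition_significance <- function(x, design,
                                   levels = c("transect_id", "site_id"),
                                   scheme = c("individual", "occurrence"),
                                   n_iter = 999, seed = NULL, alpha = 0.05,
                                   check_margins = FALSE) {
  scheme <- match.arg(scheme)
  if (n_iter < 1) stop("n_iter must be >= 1")
  obs <- additive_partition(x, design, levels)
  m <- unclass(x)
  if (scheme == "individual" && any(m != round(m))) {
    stop("individual-based randomization needs integer counts; ",
         "use scheme = 'occurrence' for continuous abundances")
  }
  idx <- match(rownames(x), design$sample_id)
  des <- design[idx, , drop = FALSE]
  groups <- lapply(levels, function(lv) des[[lv]])
  k <- length(obs$components)

  null_one <- function(mm) {
    pres <- mm > 0
    a <- c(mean(rowSums(pres)),
           vapply(groups, function(g)
             mean(.pooled_richness(pres, g)), numeric(1)))
    g <- sum(colSums(pres) > 0)
    c(a[1], diff(c(a, g)))
  }

  nulls <- with_seed(seed, {
    if (scheme == "individual") {
      rs <- rowSums(m); cs <- colSums(m)
      vapply(seq_len(n_iter), function(i) {
        nm <- stats::r2dtable(1, rs, cs)[[1]]
        if (check_margins &&
            (any(rowSums(nm) != rs) || any(colSums(nm) != cs))) {
          stop("null matrix margins differ from the original")
        }
        null_one(nm)
      }, numeric(k))
    } else {
      nm <- vegan::nullmodel(1 * (m > 0), "curveball")
      sims <- stats::simulate(nm, nsim = n_iter)
      vapply(seq_len(n_iter), function(i) null_one(sims[, , i]), numeric(k))
    }
  })

  obs_v <- obs$components
  ge <- rowSums(nulls >= obs_v)
  le <- rowSums(nulls <= obs_v)
  p_high <- (1 + ge) / (n_iter + 1)
  p_low <- (1 + le) / (n_iter + 1)
  flag <- ifelse(p_high <= alpha, "+", ifelse(p_low <= alpha, "-", "NS"))
  obs$table <- data.frame(component = names(obs_v),
                          observed = unname(obs_v),
                          null_mean = rowMeans(nulls),
                          null_sd = apply(nulls, 1, stats::sd),
                          p_low = unname(p_low), p_high = unname(p_high),
                          flag = unname(flag),
                          row.names = NULL, stringsAsFactors = FALSE)
  obs$n_iter <- n_iter
  obs$scheme <- scheme
  obs
}

#' Assemble a partition summary from component values
#'
#' Reporting layer used when components are already known (e.g. tabulated
#' results): checks non-negativity and returns the components together with
#' the regional richness they sum to.
#'
#' @param alpha mean richness of the lowest sampling unit.
#' @param betas named numeric vector of beta components, finest first.
#' @return a `partition_result` with `gamma = alpha + sum(betas)`.
#' @export
partition_summary <- function(alpha, betas) {
  if (alpha < 0 || any(betas < 0)) {
    stop("richness components must be non-negative")
  }
  out <- list(gamma = alpha + sum(betas), alpha = alpha,
              components = c(alpha = unname(alpha), betas),
              levels = names(betas))
  class(out) <- "partition_result"
  out
}

#' @export
print.partition_result <- function(x, ...) {
  cat("additive partition: gamma =", format(x$gamma), "\n")
  if (!is.null(x$table)) {
    print(x$table, digits = 4)
    cat("(", x$n_iter, "randomizations,", x$scheme, "scheme )\n")
  } else {
    print(round(x$components, 4))
  }
  invisible(x)
}
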