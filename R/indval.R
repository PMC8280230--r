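# Dufrene-Legendre indicator taxa, cross-method taxon harmonization, and the
# joint reads-biomass relationship

#' Indicator-taxon analysis across site groups
#'
#' For taxon `j` and site `g`, specificity `A` is the mean abundance of `j`
#' in `g` divided by the sum of its per-site mean abundances, fidelity `B`
#' is the fraction of `g`'s samples containing `j`, and the indicator value
#' is `A * B`; each taxon's statistic is its maximum over sites. Significance
#' is by permuting site labels of samples (add-one p-values), adjusted across
#' taxa (Holm by default).
#'
#' @param x a `community_matrix`.
#' @param groups site label per row of `x` (character or factor).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param adjust p-adjustment method: `"holm"`, `"BH"`, or `"none"`.
#' @return data frame, one row per taxon: `taxon`, `best_site`, `indval`
#'   (in `[0, 1]`), `p_value`, `p_adjusted`, `n_perm`; sorted by adjusted p.
#' @export
indval <- function(x, groups, n_perm = 1000, seed = NULL,
                   adjust = c("holm", "BH", "none")) {
  adjust <- match.arg(adjust)
  m <- unclass(x)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) stop("one group label per sample required")
  tab <- table(groups)
  if (any(tab == 0) || length(tab) < 2) stop("need >= 2 non-empty sites")

  stat <- function(gr) {
    mean_ab <- rowsum(m, gr) / as.vector(table(gr)[sort(unique(gr))])
    A <- sweep(mean_ab, 2, colSums(mean_ab), "/")
    A[!is.finite(A)] <- 0
    B <- rowsum((m > 0) + 0, gr) / as.vector(table(gr)[sort(unique(gr))])
    iv <- A * B
    list(max = apply(iv, 2, max),
         best = rownames(iv)[apply(iv, 2, which.max)])
  }
  obs <- stat(groups)
  exceed <- with_seed(seed, {
    ex <- integer(ncol(m))
    for (k in seq_len(n_perm)) {
      pm <- stat(sample(groups))
      ex <- ex + (pm$max >= obs$max)
    }
    ex
  })
  p <- (1 + exceed) / (n_perm + 1)
  out <- data.frame(taxon = colnames(m), best_site = obs$best,
                    indval = unname(obs$max), p_value = unname(p),
                    p_adjusted = unname(stats::p.adjust(p, method = adjust)),
                    n_perm = n_perm, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$p_adjusted, -out$indval), ]
}

#' Harmonize visually detected taxa with eDNA taxa
#'
#' Matches each UVC taxon to an eDNA taxon at the finest shared rank: species
#' when both carry the species; otherwise UVC species are lumped into a
#' genus-rank eDNA taxon of the same genus; otherwise into a family-rank
#' eDNA taxon of the same family. Collapse is many-to-one toward coarser
#' ranks only.
#'
#' @param uvc_taxa character vector of UVC taxon ids (resolvable in `tax`).
#' @param edna_taxa character vector of eDNA taxon ids (any rank, resolvable
#'   in `tax`).
#' @param tax a [taxonomy_tree()].
#' @return list with `matches` (data frame `uvc_taxon`, `edna_taxon`,
#'   `match_rank`), `edges` (Sankey-style UVC taxon -> merged taxon list) and
#'   `overlap` (per-rank joint detection counts: for each of species, genus,
#'   family, the number of taxa at that rank detected by both methods).
#' @export
harmonize_taxa <- function(uvc_taxa, edna_taxa, tax) {
  unknown <- setdiff(uvc_taxa, names(tax$rank))
  resolvable <- setdiff(uvc_taxa, unknown)
  if (length(unknown) > 0) {
    warning("UVC taxa not in taxonomy, reported unmatched: ",
            paste(unknown, collapse = ", "))
  }
  edna_rank <- tax$rank[edna_taxa]
  match_one <- function(u) {
    for (r in c("species", "genus", "family")) {
      anc <- ancestor_at_rank(tax, u, r)
      if (is.na(anc)) next
      cand <- edna_taxa[edna_rank == r & edna_taxa == anc]
      if (length(cand) > 0) {
        return(data.frame(uvc_taxon = u, edna_taxon = cand[1], match_rank = r,
                          stringsAsFactors = FALSE))
      }
    }
    data.frame(uvc_taxon = u, edna_taxon = NA_character_, match_rank = "none",
               stringsAsFactors = FALSE)
  }
  matches <- do.call(rbind, c(lapply(resolvable, match_one),
                              if (length(unknown) > 0) list(
                                data.frame(uvc_taxon = unknown,
                                           edna_taxon = NA_character_,
                                           match_rank = "none",
                                           stringsAsFactors = FALSE))))
  at_rank <- function(taxa, r) {
    unique(stats::na.omit(vapply(taxa, function(t)
      ancestor_at_rank(tax, t, r), character(1))))
  }
  overlap <- vapply(c("species", "genus", "family"), function(r)
    length(intersect(at_rank(resolvable, r), at_rank(edna_taxa, r))),
    integer(1))
  list(matches = matches,
       edges = matches[!is.na(matches$edna_taxon),
                       c("uvc_taxon", "edna_taxon")],
       overlap = overlap)
}

#' Relationship between sequence reads and observed biomass
#'
#' Ordinary least squares of per-taxon total reads on log-transformed total
#' biomass, over taxa detected by both methods.
#'
#' @param reads numeric vector of total reads per jointly detected taxon.
#' @param biomass numeric vector of total biomass (same taxa, positive).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
reads_biomass_regression <- function(reads, biomass) {
  if (length(reads) != length(biomass)) stop("vectors must match")
  if (length(reads) < 3) stop("need at least 3 jointly detected taxa")
  if (any(biomass <= 0)) stop("biomass must be positive for the log transform")
  lb <- log(biomass)
  if (stats::sd(lb) == 0) stop("zero variance in log biomass")
  fm <- stats::lm(reads ~ lb)
  sm <- suppressWarnings(summary(fm))  # tolerate exact fits
  list(slope = unname(stats::coef(fm)[2]),
       intercept = unname(stats::coef(fm)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = length(reads))
}
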