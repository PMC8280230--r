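# shared fixtures and independent brute-force oracles

# small fish-like taxonomy: two families, three genera, four species
fixture_taxonomy <- function() {
  taxonomy_tree(data.frame(
    taxon_id = c("root", "Actinopteri",
                 "Labridae", "Oxyjulis", "Oxyjulis_californica",
                 "Semicossyphus", "Semicossyphus_pulcher",
                 "Sebastidae", "Sebastes", "Sebastes_auriculatus",
                 "Sebastes_mystinus"),
    parent_id = c(NA, "root",
                  "Actinopteri", "Labridae", "Oxyjulis",
                  "Labridae", "Semicossyphus",
                  "Actinopteri", "Sebastidae", "Sebastes",
                  "Sebastes"),
    rank = c("root", "class",
             "family", "genus", "species",
             "genus", "species",
             "family", "genus", "species",
             "species"),
    stringsAsFactors = FALSE))
}

# a nested design: ns sites x nt transects x nb bottles, co-located bottles
fixture_design <- function(ns = 2, nt = 2, nb = 2, spacing_km = 10) {
  n <- ns * nt * nb
  km <- rep(seq(0, by = spacing_km, length.out = ns), each = nt * nb) +
    rep(rep(seq(0, by = 0.05, length.out = nt), each = nb), ns)
  sample_design(data.frame(
    sample_id = sprintf("b%02d", seq_len(n)),
    method = "eDNA",
    site_id = rep(sprintf("s%d", seq_len(ns)), each = nt * nb),
    transect_id = rep(sprintf("t%02d", seq_len(ns * nt)), each = nb),
    replicate_id = rep(sprintf("r%d", seq_len(nb)), ns * nt),
    lat = 34, lon = km / (pi / 180 * 6371 * cos(34 * pi / 180)),
    stringsAsFactors = FALSE))
}

random_counts <- function(n, p, lambda = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n * p, lambda), n, p,
              dimnames = list(sprintf("b%02d", seq_len(n)),
                              sprintf("x%02d", seq_len(p))))
  community_matrix(m, "reads")
}

# --- independent oracles ---------------------------------------------------

# Bray-Curtis by the per-pair formula, applied to an already-transformed matrix
oracle_bray <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- sum(m[i, ] + m[j, ])
    D[i, j] <- D[j, i] <- if (tot == 0) 0 else sum(abs(m[i, ] - m[j, ])) / tot
  }
  D
}

# additive partition by explicit pooling
oracle_partition <- function(m, groups_list) {
  pres <- m > 0
  pool_rich <- function(g) {
    mean(vapply(split(seq_len(nrow(m)), g), function(i)
      sum(colSums(pres[i, , drop = FALSE]) > 0), numeric(1)))
  }
  a <- c(mean(rowSums(pres)), vapply(groups_list, pool_rich, numeric(1)))
  gamma <- sum(colSums(pres) > 0)
  c(a[1], diff(c(a, gamma)), gamma)
}

# IndVal by the double loop over taxa and sites
oracle_indval <- function(m, groups) {
  sites <- sort(unique(groups))
  out <- numeric(ncol(m))
  best <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    A_num <- vapply(sites, function(g) mean(m[groups == g, j]), numeric(1))
    A <- if (sum(A_num) == 0) rep(0, length(sites)) else A_num / sum(A_num)
    B <- vapply(sites, function(g) mean(m[groups == g, j] > 0), numeric(1))
    iv <- A * B
    out[j] <- max(iv)
    best[j] <- sites[which.max(iv)]
  }
  list(indval = out, best = best)
}

# majority-LCA by scoring every tree node
oracle_lca <- function(hit_taxa, tax, majority = 0.85) {
  nodes <- names(tax$rank)
  frac <- vapply(nodes, function(nd) {
    mean(vapply(hit_taxa, function(h) nd %in% kelpbeta:::lineage(tax, h),
                logical(1)))
  }, numeric(1))
  elig <- nodes[frac >= majority]
  elig[order(-tax$depth[elig], elig)][1]
}

# random nested taxonomy of bounded size for oracle testing
random_taxonomy <- function(max_fam = 3, max_gen = 3, max_sp = 3) {
  rows <- data.frame(taxon_id = "root", parent_id = NA, rank = "root",
                     stringsAsFactors = FALSE)
  for (f in seq_len(sample(max_fam, 1))) {
    fid <- sprintf("F%d", f)
    rows <- rbind(rows, data.frame(taxon_id = fid, parent_id = "root",
                                   rank = "family"))
    for (g in seq_len(sample(max_gen, 1))) {
      gid <- sprintf("%s.G%d", fid, g)
      rows <- rbind(rows, data.frame(taxon_id = gid, parent_id = fid,
                                     rank = "genus"))
      for (s in seq_len(sample(max_sp, 1))) {
        rows <- rbind(rows, data.frame(taxon_id = sprintf("%s.S%d", gid, s),
                                       parent_id = gid, rank = "species"))
      }
    }
  }
  taxonomy_tree(rows)
}
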