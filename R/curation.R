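#' Read BLAST tabular hits (outfmt-6 dialect)
#'
#' Reads the standard 12-column tabular output (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`) and keeps the
#' columns the curation rules use. `sseqid` is taken as the subject taxon
#' identifier, resolvable in the taxonomy table.
#'
#' @param path file path (TSV, no header).
#' @return data frame with `otu_id`, `subject_taxon`, `pct_identity`,
#'   `bitscore`.
#' @export
read_blast_hits <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 12) stop("expected >= 12 tab-separated columns (outfmt 6)")
  out <- data.frame(otu_id = as.character(df[[1]]),
                    subject_taxon = as.character(df[[2]]),
                    pct_identity = as.numeric(df[[3]]),
                    bitscore = as.numeric(df[[12]]),
                    stringsAsFactors = FALSE)
  blast_hits(out)
}

#' Validate a table of BLAST hits
#' @param df data frame with `otu_id`, `subject_taxon`, `pct_identity`,
#'   `bitscore`.
#' @return the validated data frame.
#' @export
blast_hits <- function(df) {
  req <- c("otu_id", "subject_taxon", "pct_identity", "bitscore")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("hits missing columns: ",
                             paste(miss, collapse = ", "))
  if (any(df$pct_identity < 0 | df$pct_identity > 100)) {
    stop("pct_identity outside [0, 100]")
  }
  if (any(df$bitscore < 0)) stop("negative bitscore")
  df
}

#' Build a taxonomy tree from a lineage table
#'
#' @param df data frame with columns `taxon_id`, `parent_id` (empty or `NA`
#'   for the root), `rank` (one of species, genus, family, order, class,
#'   phylum, kingdom, root) and optionally `name`.
#' @return a `taxonomy_tree`: list with named `parent` and `rank` vectors and
#'   a precomputed `depth` (root = 0).
#' @export
taxonomy_tree <- function(df) {
  req <- c("taxon_id", "parent_id", "rank")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("taxonomy missing columns: ",
                             paste(miss, collapse = ", "))
  id <- as.character(df$taxon_id)
  if (anyDuplicated(id)) stop("duplicate taxon_id in taxonomy")
  parent <- as.character(df$parent_id)
  parent[is.na(parent) | parent == ""] <- NA_character_
  rank <- as.character(df$rank)
  rank_index(rank)  # validates
  names(parent) <- names(rank) <- id
  roots <- id[is.na(parent)]
  if (length(roots) != 1) stop("taxonomy must have exactly one root, found ",
                               length(roots))
  dangling <- setdiff(stats::na.omit(parent), id)
  if (length(dangling) > 0) stop("parent(s) not in taxonomy: ",
                                 paste(dangling, collapse = ", "))
  depth <- integer(length(id)); names(depth) <- id
  for (t in id) {
    d <- 0L; cur <- t
    while (!is.na(parent[[cur]])) {
      cur <- parent[[cur]]; d <- d + 1L
      if (d > length(id)) stop("cycle in taxonomy at ", t)
    }
    depth[[t]] <- d
  }
  # ranks must get coarser (or stay) toward the root
  for (t in id) {
    p <- parent[[t]]
    if (!is.na(p) && rank_index(rank[[p]]) < rank_index(rank[[t]])) {
      stop("rank of '", p, "' is finer than its child '", t, "'")
    }
  }
  structure(list(parent = parent, rank = rank, depth = depth,
                 root = roots,
                 name = if ("name" %in% names(df)) {
                   stats::setNames(as.character(df$name), id)
                 } else stats::setNames(id, id)),
            class = "taxonomy_tree")
}

#' Read a taxonomy lineage table (TSV)
#' @param path file with header columns `taxon_id`, `parent_id`, `rank`,
#'   optionally `name`.
#' @return a [taxonomy_tree()].
#' @export
read_taxonomy <- function(path) {
  taxonomy_tree(utils::read.table(path, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE, quote = "",
                                  colClasses = "character"))
}

# self-to-root lineage of a taxon
lineage <- function(tax, taxon) {
  if (!taxon %in% names(tax$parent)) stop("taxon '", taxon,
                                          "' not in taxonomy")
  out <- taxon
  while (!is.na(tax$parent[[taxon]])) {
    taxon <- tax$parent[[taxon]]
    out <- c(out, taxon)
  }
  out
}

# nearest ancestor (or self) whose rank is exactly `rank`, NA if none
ancestor_at_rank <- function(tax, taxon, rank) {
  lin <- lineage(tax, taxon)
  hit <- lin[tax$rank[lin] == rank]
  if (length(hit) == 0) NA_character_ else hit[[1]]
}

# nearest ancestor (or self) at rank `rank` or coarser
ancestor_at_or_above <- function(tax, taxon, rank) {
  lin <- lineage(tax, taxon)
  hit <- lin[rank_index(tax$rank[lin]) >= rank_index(rank)]
  hit[[1]]  # root always qualifies
}

#' Filter BLAST hits per OTU
#'
#' Retains, within each OTU, hits with percent identity at or above
#' `min_identity`, bitscore at or above `min_bitscore`, and bitscore within
#' the top `top_frac` fraction of the OTU's best qualifying bitscore
#' (`bitscore >= (1 - top_frac) * max`, inclusive).
#'
#' @param hits a [blast_hits()] table (any number of OTUs).
#' @param min_identity identity floor (percent).
#' @param min_bitscore bitscore floor.
#' @param top_frac top-percent window as a fraction (0.02 = top 2 percent).
#' @return the retained hits; OTUs with no surviving hit are absent from the
#'   result (and thereby unassigned).
#' @export
filter_hits <- function(hits, min_identity = 85, min_bitscore = 100,
                        top_frac = 0.02) {
  hits <- blast_hits(hits)
  ok <- hits$pct_identity >= min_identity & hits$bitscore >= min_bitscore
  hits <- hits[ok, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$otu_id), function(i) {
    i[hits$bitscore[i] >= (1 - top_frac) * max(hits$bitscore[i])]
  }), use.names = FALSE)
  hits[sort(keep), , drop = FALSE]
}

#' Majority lowest-common-ancestor assignment
#'
#' Returns the deepest taxonomy node whose subtree contains at least a
#' `majority` fraction of the retained hits. Ties at equal covered fraction
#' are broken toward the deeper node (and lexicographically at equal depth).
#' The root covers every hit, so an assignment always exists.
#'
#' @param hits retained hits for a single OTU (see [filter_hits()]).
#' @param tax a [taxonomy_tree()].
#' @param majority required covered fraction (default 0.85).
#' @return the assigned taxon id.
#' @export
weighted_lca <- function(hits, tax, majority = 0.85) {
  if (nrow(hits) == 0) stop("weighted_lca needs at least one retained hit")
  n <- nrow(hits)
  counts <- new.env(parent = emptyenv())
  for (t in hits$subject_taxon) {
    for (a in lineage(tax, t)) {
      assign(a, (get0(a, envir = counts) %||% 0L) + 1L, envir = counts)
    }
  }
  nodes <- ls(counts)
  cov <- vapply(nodes, function(a) get(a, envir = counts), integer(1)) / n
  elig <- nodes[cov >= majority]
  d <- tax$depth[elig]
  elig <- elig[order(-d, elig)]
  elig[[1]]
}

#' Rank-threshold gates with elevation
#'
#' A species-rank assignment is kept only if the OTU's best retained hit has
#' identity >= 97 and bitscore >= 300; a genus-rank assignment requires
#' >= 95 and >= 200. Failed assignments are elevated rank by rank (species ->
#' genus -> family) until the gate at that rank passes; family and coarser
#' ranks require only the 85 / 100 floor already enforced by hit filtering.
#'
#' @param lca_taxon taxon assigned by [weighted_lca()].
#' @param best_identity,best_bitscore identity and bitscore of the OTU's best
#'   retained hit.
#' @param tax a [taxonomy_tree()].
#' @param species_gate,genus_gate numeric `c(identity, bitscore)` gates.
#' @return list with `taxon`, `rank`, and `provenance` (`"lca"`,
#'   `"species-threshold"`, `"genus-threshold"`, or `"elevated"`).
#' @export
apply_rank_thresholds <- function(lca_taxon, best_identity, best_bitscore,
                                  tax, species_gate = c(97, 300),
                                  genus_gate = c(95, 200)) {
  rank <- tax$rank[[lca_taxon]]
  passes <- function(gate) best_identity >= gate[1] && best_bitscore >= gate[2]
  if (rank == "species") {
    if (passes(species_gate)) {
      return(list(taxon = lca_taxon, rank = "species",
                  provenance = "species-threshold"))
    }
    lca_taxon <- ancestor_at_or_above(tax, lca_taxon, "genus")
    rank <- tax$rank[[lca_taxon]]
  }
  if (rank == "genus") {
    if (passes(genus_gate)) {
      return(list(taxon = lca_taxon, rank = "genus",
                  provenance = "genus-threshold"))
    }
    lca_taxon <- ancestor_at_or_above(tax, lca_taxon, "family")
    rank <- tax$rank[[lca_taxon]]
  }
  # family and coarser: the 85/100 floor was already enforced upstream
  list(taxon = lca_taxon, rank = rank, provenance = "lca")
}

#' Annotate OTUs from filtered hits
#'
#' Runs [filter_hits()], [weighted_lca()] and [apply_rank_thresholds()] per
#' OTU.
#'
#' @param hits a [blast_hits()] table covering all OTUs.
#' @param tax a [taxonomy_tree()].
#' @param majority LCA majority fraction.
#' @param ... gates passed to [apply_rank_thresholds()].
#' @return data frame with one row per OTU appearing in `hits`: `otu_id`,
#'   `taxon_id` (`NA` when unassigned), `rank`, `provenance`.
#' @export
annotate_otus <- function(hits, tax, majority = 0.85, ...) {
  all_otus <- unique(hits$otu_id)
  kept <- filter_hits(hits)
  rows <- lapply(all_otus, function(o) {
    h <- kept[kept$otu_id == o, , drop = FALSE]
    if (nrow(h) == 0) {
      return(data.frame(otu_id = o, taxon_id = NA_character_,
                        rank = NA_character_, provenance = "unassigned",
                        stringsAsFactors = FALSE))
    }
    lca <- weighted_lca(h, tax, majority)
    best <- h[which.max(h$bitscore), ]
    a <- apply_rank_thresholds(lca, best$pct_identity, best$bitscore, tax, ...)
    prov <- if (a$taxon != lca) "elevated" else a$provenance
    data.frame(otu_id = o, taxon_id = a$taxon, rank = a$rank,
               provenance = prov, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.log_entry <- function(otu_id, action, reason, reads) {
  data.frame(otu_id = otu_id, action = action, reason = reason,
             reads = reads, stringsAsFactors = FALSE)
}

#' Remove contaminant taxa using no-template controls and a blacklist
#'
#' Drops every OTU annotated to (or below) a blacklisted terrestrial taxon,
#' and every OTU whose reads in any single no-template control exceed
#' `ntc_threshold`; minor NTC carry-over below the threshold is tolerated.
#' NTC rows are removed from the returned matrix. Every removal is logged
#' with its read total.
#'
#' @param x `community_matrix` (mode `"reads"`) whose columns are OTUs and
#'   whose rows include the NTC samples.
#' @param ntc_samples row names of the no-template controls.
#' @param annot OTU annotation table from [annotate_otus()].
#' @param tax a [taxonomy_tree()].
#' @param blacklist taxon ids (any rank) to remove wherever detected.
#' @param ntc_threshold reads in any one NTC above which an OTU is treated as
#'   a major contaminant (default 100).
#' @return list with `counts` (NTC rows and dropped OTUs removed) and `log`.
#' @export
remove_contaminants <- function(x, ntc_samples, annot, tax,
                                blacklist = character(),
                                ntc_threshold = 100) {
  miss <- setdiff(ntc_samples, rownames(x))
  if (length(miss) > 0) stop("NTC sample(s) not in matrix: ",
                             paste(miss, collapse = ", "))
  log <- list()
  drop <- character()
  for (o in colnames(x)) {
    tx <- annot$taxon_id[match(o, annot$otu_id)]
    if (!is.na(tx) && length(blacklist) > 0 &&
        any(lineage(tax, tx) %in% blacklist)) {
      drop <- c(drop, o)
      log[[length(log) + 1]] <- .log_entry(o, "dropped", "blacklisted taxon",
                                           sum(x[, o]))
      next
    }
    ntc_reads <- x[ntc_samples, o, drop = TRUE]
    if (length(ntc_samples) > 0 && max(ntc_reads) > ntc_threshold) {
      drop <- c(drop, o)
      log[[length(log) + 1]] <- .log_entry(o, "dropped",
                                           sprintf("NTC reads %d > %d",
                                                   max(ntc_reads),
                                                   ntc_threshold),
                                           sum(x[, o]))
    }
  }
  keep_rows <- setdiff(rownames(x), ntc_samples)
  keep_cols <- setdiff(colnames(x), drop)
  list(counts = community_matrix(unclass(x)[keep_rows, keep_cols,
                                            drop = FALSE], "reads"),
       log = if (length(log)) do.call(rbind, log) else
         .log_entry(character(), character(), character(), numeric()))
}

# sum columns `from` into column `into`; drop `from`
.merge_columns <- function(m, from, into) {
  m[, into] <- m[, into] + rowSums(m[, from, drop = FALSE])
  m[, setdiff(colnames(m), from), drop = FALSE]
}

#' Hierarchical merging of rank-unassigned OTUs
#'
#' Resolves groups in which a coarser-rank OTU co-occurs with finer-rank OTUs
#' of the same clade, attributing ambiguous sequence variation to the most
#' abundant member. Genus-level groups are processed first, then
#' family-level groups; read totals decide dominance, with ties broken by
#' lexicographic taxon id; merging sums counts and never drops reads.
#'
#' Four cases: a genus-rank OTU dominating its genus absorbs all finer OTUs
#' at genus rank (G-i); a dominant species-rank OTU absorbs the genus-rank
#' OTU (G-ii); a family-rank OTU dominating its family absorbs all finer
#' OTUs at family rank (F-i); a dominant finer OTU absorbs the family-rank
#' OTU (F-ii).
#'
#' @param x `community_matrix` (reads), columns = OTUs.
#' @param annot annotation table (`otu_id`, `taxon_id`, `rank`).
#' @param tax a [taxonomy_tree()].
#' @return list with `counts`, updated `annot`, and a merge `log`.
#' @export
hierarchical_merge <- function(x, annot, tax) {
  m <- unclass(x)
  annot <- annot[match(colnames(m), annot$otu_id), , drop = FALSE]
  log <- list()

  # one merge step at `coarse_rank`; returns TRUE if a merge happened
  merge_once <- function(coarse_rank) {
    finer <- .rank_levels[seq_len(rank_index(coarse_rank) - 1)]
    group_of <- vapply(seq_len(ncol(m)), function(j) {
      tx <- annot$taxon_id[j]
      if (is.na(tx) || !annot$rank[j] %in% c(coarse_rank, finer)) {
        return(NA_character_)
      }
      ancestor_at_rank(tax, tx, coarse_rank)
    }, character(1))
    for (g in unique(stats::na.omit(group_of))) {
      j <- which(!is.na(group_of) & group_of == g)
      at_coarse <- j[annot$rank[j] == coarse_rank]
      if (length(j) < 2 || length(at_coarse) == 0) next
      tot <- colSums(m[, j, drop = FALSE])
      win <- j[order(-tot, annot$taxon_id[j])][1]
      if (annot$rank[win] == coarse_rank) {
        # (i) coarse-rank OTU dominates: whole group merges to the coarse level
        from <- setdiff(colnames(m)[j], colnames(m)[win])
        reason <- paste0(coarse_rank, "-level ", g)
        annot$taxon_id[win] <<- g
        annot$rank[win] <<- coarse_rank
        annot$provenance[win] <<- "merged-into"
      } else {
        # (ii) a finer OTU dominates: coarse-rank OTU(s) merge into it
        from <- colnames(m)[at_coarse]
        reason <- paste0("dominant ", annot$taxon_id[win])
      }
      m <<- .merge_columns(m, from, colnames(m)[win])
      for (f in from) {
        log[[length(log) + 1]] <<- .log_entry(f, "merged-into", reason, NA)
      }
      annot <<- annot[annot$otu_id %in% colnames(m), , drop = FALSE]
      return(TRUE)
    }
    FALSE
  }
  while (merge_once("genus")) {}
  while (merge_once("family")) {}
  list(counts = community_matrix(m, "reads"), annot = annot,
       log = if (length(log)) do.call(rbind, log) else
         .log_entry(character(), character(), character(), numeric()))
}

#' Define the regional taxon pool
#'
#' Applies the pool-definition filters in fixed order: (1) drop OTUs whose
#' taxa are outside the study region (`range_blacklist`); (2) drop OTUs
#' assigned coarser than family; (3) merge OTUs sharing a species annotation
#' (summing counts); (4) drop merged OTUs with fewer than `min_reads` total
#' reads; (5) hierarchical genus- then family-level merging. Unassigned OTUs
#' are dropped at step 2 and logged.
#'
#' @param x `community_matrix` (reads), columns = OTUs.
#' @param annot annotation table from [annotate_otus()].
#' @param tax a [taxonomy_tree()].
#' @param range_blacklist taxon ids whose geographic range excludes the study
#'   area.
#' @param min_reads minimum summed reads for an OTU to stay (default 5).
#' @return list with `counts` (columns renamed to assigned taxon ids),
#'   `annot`, and the curation `log`.
#' @export
define_regional_pool <- function(x, annot, tax, range_blacklist = character(),
                                 min_reads = 5) {
  m <- unclass(x)
  annot <- annot[match(colnames(m), annot$otu_id), , drop = FALSE]
  log <- list()
  drop_otus <- function(ids, reason) {
    for (o in ids) {
      log[[length(log) + 1]] <<- .log_entry(o, "dropped", reason, sum(m[, o]))
    }
    m <<- m[, setdiff(colnames(m), ids), drop = FALSE]
    annot <<- annot[annot$otu_id %in% colnames(m), , drop = FALSE]
  }

  # 1. geographic range filter
  out_of_range <- annot$otu_id[!is.na(annot$taxon_id) &
    vapply(annot$taxon_id, function(t)
      any(lineage(tax, t) %in% range_blacklist), logical(1))]
  drop_otus(out_of_range, "outside geographic range")

  # 2. rank filter: coarser than family (or unassigned) is uninformative
  too_coarse <- annot$otu_id[is.na(annot$rank) |
                               rank_index(annot$rank) > rank_index("family")]
  drop_otus(too_coarse, "rank above family")

  # 3. merge OTUs sharing a species annotation
  sp <- annot$rank == "species"
  for (t in unique(annot$taxon_id[sp])) {
    j <- which(annot$taxon_id == t & sp)
    if (length(j) < 2) next
    keep <- annot$otu_id[j][order(-colSums(m[, annot$otu_id[j],
                                             drop = FALSE]),
                                  annot$otu_id[j])][1]
    from <- setdiff(annot$otu_id[j], keep)
    m <- .merge_columns(m, from, keep)
    for (f in from) {
      log[[length(log) + 1]] <- .log_entry(f, "merged-into",
                                           paste0("species ", t), NA)
    }
    annot <- annot[annot$otu_id %in% colnames(m), , drop = FALSE]
    sp <- annot$rank == "species"
  }

  # 4. low-abundance filter on merged OTUs
  low <- colnames(m)[colSums(m) < min_reads]
  drop_otus(low, sprintf("fewer than %d reads", min_reads))

  if (ncol(m) == 0) {
    warning("no OTUs remain after pool filters")
    return(list(counts = community_matrix(m, "reads"), annot = annot,
                log = do.call(rbind, log)))
  }

  # 5. hierarchical merging
  hm <- hierarchical_merge(community_matrix(m, "reads"), annot, tax)
  log <- c(log, list(hm$log[nrow(hm$log) > 0, , drop = FALSE]))
  annot <- hm$annot
  m <- unclass(hm$counts)

  # present columns by their assigned taxon
  colnames(m) <- annot$taxon_id[match(colnames(m), annot$otu_id)]
  list(counts = community_matrix(m, "reads"), annot = annot,
       log = do.call(rbind, log))
}
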