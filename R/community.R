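#' Construct a community matrix
#'
#' A community matrix holds sample-by-taxon abundances together with a declared
#' abundance mode: `"reads"` for eDNA sequence counts (integer) or `"biomass"`
#' for visual-census biomass (non-negative continuous). Rows are samples,
#' columns are taxa; both must carry unique labels.
#'
#' @param abundance numeric matrix, samples in rows, taxa in columns, with
#'   unique dimnames.
#' @param mode `"reads"` or `"biomass"`.
#' @return a `community_matrix`: the abundance matrix with class and `mode`
#'   attributes. Taxa whose column is all zero are permitted but flagged via
#'   the `"zero_taxa"` attribute.
#' @export
community_matrix <- function(abundance, mode = c("reads", "biomass")) {
  mode <- match.arg(mode)
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance))) {
    stop("abundance matrix must have sample rownames and taxon colnames")
  }
  if (anyDuplicated(rownames(abundance))) {
    stop("duplicate sample labels: ",
         paste(unique(rownames(abundance)[duplicated(rownames(abundance))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(abundance))) {
    stop("duplicate taxon labels: ",
         paste(unique(colnames(abundance)[duplicated(colnames(abundance))]),
               collapse = ", "))
  }
  if (any(!is.finite(abundance))) stop("abundances must be finite")
  neg <- which(abundance < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative abundance at sample '", rownames(abundance)[neg[1, 1]],
         "', taxon '", colnames(abundance)[neg[1, 2]], "'")
  }
  if (mode == "reads") {
    if (any(abundance != round(abundance))) {
      bad <- which(abundance != round(abundance), arr.ind = TRUE)
      stop("non-integer read count at sample '",
           rownames(abundance)[bad[1, 1]], "', taxon '",
           colnames(abundance)[bad[1, 2]], "'")
    }
    storage.mode(abundance) <- "integer"
  }
  structure(abundance,
            mode = mode,
            zero_taxa = colnames(abundance)[colSums(abundance) == 0],
            class = c("community_matrix", "matrix", "array"))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community matrix:", nrow(x), "samples x", ncol(x), "taxa, mode =",
      attr(x, "mode"), "\n")
  nz <- length(attr(x, "zero_taxa"))
  if (nz > 0) cat("  (", nz, "all-zero taxa flagged )\n")
  invisible(x)
}

#' Abundance mode of a community matrix
#' @param x a `community_matrix`.
#' @return `"reads"` or `"biomass"`.
#' @export
abundance_mode <- function(x) attr(x, "mode") %||% "reads"

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a community table from delimited text
#'
#' Expects samples in rows and taxa in columns, with the first column holding
#' sample identifiers and the header row holding taxon identifiers. Comma or
#' tab delimiters are auto-detected from the header line.
#'
#' @param path file path.
#' @param mode abundance mode, `"reads"` or `"biomass"`.
#' @return a [community_matrix()].
#' @export
read_community_table <- function(path, mode = c("reads", "biomass")) {
  mode <- match.arg(mode)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("community table needs a sample column plus taxa")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))),
                 arr.ind = TRUE)
    stop("non-numeric abundance at row ", bad[1, 1], " (sample '",
         ids[bad[1, 1]], "'), column '", colnames(m)[bad[1, 2]], "'")
  }
  rownames(m) <- ids
  community_matrix(m, mode)
}

#' Write a community table to delimited text
#'
#' @param x a `community_matrix`.
#' @param path file path; `.tsv` extension selects tab, otherwise comma.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a sample design table
#'
#' A sample design describes the nested survey hierarchy: each row is one
#' sample (a water bottle for eDNA, a transect for UVC) with its site,
#' transect, optional bottle replicate label, and coordinates in decimal
#' degrees.
#'
#' @param df data frame with columns `sample_id`, `method` (`"eDNA"` or
#'   `"UVC"`), `site_id`, `transect_id`, `replicate_id` (empty for UVC),
#'   `lat`, `lon`.
#' @return the validated data frame with class `sample_design`.
#' @export
sample_design <- function(df) {
  req <- c("sample_id", "method", "site_id", "transect_id", "replicate_id",
           "lat", "lon")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("sample design missing columns: ",
                             paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if (!all(df$method %in% c("eDNA", "UVC"))) {
    stop("method must be 'eDNA' or 'UVC'")
  }
  # every transect belongs to exactly one site
  ts <- unique(df[, c("site_id", "transect_id")])
  if (anyDuplicated(ts$transect_id)) {
    stop("transect assigned to more than one site: ",
         paste(unique(ts$transect_id[duplicated(ts$transect_id)]),
               collapse = ", "))
  }
  rep_on_uvc <- df$method == "UVC" & !is.na(df$replicate_id) &
    nzchar(df$replicate_id)
  if (any(rep_on_uvc)) stop("replicate_id must be empty for UVC samples")
  if (any(!is.finite(df$lat)) || any(!is.finite(df$lon))) {
    stop("missing or non-finite coordinate for sample(s): ",
         paste(df$sample_id[!is.finite(df$lat) | !is.finite(df$lon)],
               collapse = ", "))
  }
  if (any(df$lat < -90 | df$lat > 90)) stop("latitude outside [-90, 90]")
  if (any(df$lon < -180 | df$lon > 180)) stop("longitude outside [-180, 180]")
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Read a sample design table from delimited text
#' @param path file path (CSV or TSV; auto-detected).
#' @return a [sample_design()].
#' @export
read_sample_design <- function(path) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          fileEncoding = "UTF-8",
                          colClasses = c(replicate_id = "character"))
  sample_design(df)
}

#' Great-circle distances among samples
#'
#' Haversine distances on a 6371-km sphere, in kilometres. Replicate bottles
#' collected at identical coordinates get distance exactly zero.
#'
#' @param design a [sample_design()] (or data frame with `sample_id`, `lat`,
#'   `lon`).
#' @return symmetric matrix of distances (km) with sample ids as dimnames.
#' @export
geo_distances <- function(design) {
  if (any(!is.finite(design$lat)) || any(!is.finite(design$lon))) {
    stop("missing coordinate for sample(s): ",
         paste(design$sample_id[!is.finite(design$lat) |
                                  !is.finite(design$lon)], collapse = ", "))
  }
  pts <- cbind(design$lon, design$lat)
  d <- geosphere::distm(pts, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  diag(d) <- 0
  dimnames(d) <- list(design$sample_id, design$sample_id)
  d
}

#' Rarefy read counts to a common depth
#'
#' Draws, for every sample independently, a without-replacement subsample of
#' `depth` reads (a single draw per sample, not an average over draws), so
#' every row of the result sums exactly to `depth`.
#'
#' @param x a `community_matrix` with mode `"reads"`.
#' @param depth target depth; defaults to the minimum row sum.
#' @param seed integer seed for reproducibility.
#' @return a rarefied `community_matrix` (mode `"reads"`).
#' @export
rarefy_counts <- function(x, depth = NULL, seed = NULL) {
  if (abundance_mode(x) != "reads") stop("rarefaction requires read counts")
  tot <- rowSums(x)
  depth <- depth %||% min(tot)
  small <- tot < depth
  if (any(small)) {
    stop("depth ", depth, " exceeds the read total of sample(s): ",
         paste(rownames(x)[small], collapse = ", "))
  }
  out <- with_seed(seed, suppressWarnings(vegan::rrarefy(unclass(x), depth)))
  community_matrix(out, "reads")
}
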