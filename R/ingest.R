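#' Read a gene-by-library count matrix
#'
#' Reads a tab-separated count table whose first column holds gene
#' identifiers and whose remaining columns are one library each. Counts
#' must be non-negative integers; duplicate gene or library identifiers
#' are an error.
#'
#' @param path Path to a TSV file with a header row.
#' @return Integer matrix, genes in rows, libraries in columns.
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop2("count table needs a gene id column plus >= 1 library")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop2("duplicate gene ids: ",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  libs <- colnames(tab)[-1]
  if (anyDuplicated(libs)) stop2("duplicate library ids: ",
                                 paste(unique(libs[duplicated(libs)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop2("counts must be numeric")
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
    stop2("non-integer or negative counts, e.g. gene ", ids[bad[1, 1]],
          " library ", libs[bad[1, 2]])
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Read a library design table
#'
#' The design maps each sequencing library to its individual and group and
#' carries the technical covariates (mapped reads, RIN). Optional trait
#' columns (sex, weight, length, delivery, maternal_age, bmi, alcohol,
#' vegetarian) and any further columns are preserved.
#'
#' @param path Path to a TSV file with columns `library_id`,
#'   `individual_id`, `group`, `mapped_reads`, `rin` and optional traits.
#' @param counts Optional count matrix to validate against: every library
#'   in the design must be a column of `counts` and vice versa.
#' @return A data.frame, one row per library.
#' @export
read_design <- function(path, counts = NULL) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("library_id", "individual_id", "group", "mapped_reads", "rin")
  miss <- setdiff(req, colnames(d))
  if (length(miss)) stop2("design lacks required columns: ", paste(miss, collapse = ", "))
  d$library_id <- as.character(d$library_id)
  d$individual_id <- as.character(d$individual_id)
  d$group <- as.character(d$group)
  if (anyDuplicated(d$library_id))
    stop2("duplicate library ids in design: ",
          paste(unique(d$library_id[duplicated(d$library_id)]), collapse = ", "))
  ## every individual maps to exactly one group
  g_per_ind <- tapply(d$group, d$individual_id, function(g) length(unique(g)))
  if (any(g_per_ind > 1))
    stop2("individuals mapped to multiple groups: ",
          paste(names(g_per_ind)[g_per_ind > 1], collapse = ", "))
  if (!is.null(counts)) {
    extra <- setdiff(d$library_id, colnames(counts))
    if (length(extra)) stop2("design libraries absent from counts: ",
                             paste(extra, collapse = ", "))
    extra2 <- setdiff(colnames(counts), d$library_id)
    if (length(extra2)) stop2("count libraries absent from design: ",
                              paste(extra2, collapse = ", "))
  }
  d
}

#' Median-of-ratios library size factors
#'
#' Per-library scaling factors computed as the median, over genes with a
#' positive geometric mean across libraries, of the ratio of the library's
#' count to that geometric mean.
#'
#' @param counts Gene-by-library count matrix.
#' @param pseudo_reference If no gene is expressed in every library, set
#'   `TRUE` to compute the geometric mean over positive counts only
#'   (pseudo-reference fallback) instead of erroring.
#' @return Named positive numeric vector, one factor per library.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  if (ncol(counts) == 1L) return(stats::setNames(1, colnames(counts)))
  lg <- log(counts)
  if (pseudo_reference) {
    lg[!is.finite(lg)] <- NA
    ref <- exp(rowMeans(lg, na.rm = TRUE))
    use <- is.finite(ref) & ref > 0
  } else {
    ref <- exp(rowMeans(lg))
    use <- is.finite(ref) & ref > 0
    if (!any(use))
      stop2("no gene has a nonzero count in every library; ",
            "re-run with pseudo_reference = TRUE")
  }
  sf <- apply(counts[use, , drop = FALSE], 2, function(col)
    stats::median(col / ref[use], na.rm = TRUE))
  if (any(!is.finite(sf) | sf <= 0))
    stop2("non-positive size factor for library ",
          paste(colnames(counts)[!is.finite(sf) | sf <= 0], collapse = ", "))
  sf
}

#' Shifted-log variance stabilization
#'
#' Divides counts by their library size factors and applies
#' `log2(x + pseudocount)`. A deterministic, monotone stand-in for
#' model-based variance-stabilizing transforms; the method and pseudocount
#' are recorded in the `normalization` attribute.
#'
#' @param counts Gene-by-library count matrix.
#' @param factors Size factors from [size_factors()]; computed if missing.
#' @param pseudocount Added before the log; default 1 so a zero count maps
#'   to 0 on the log2 scale.
#' @return Numeric matrix of normalized expression with a `normalization`
#'   attribute describing provenance.
#' @export
variance_stabilize <- function(counts, factors = NULL, pseudocount = 1) {
  if (is.null(factors)) factors <- size_factors(counts)
  if (any(!is.finite(factors) | factors <= 0)) stop2("size factors must be positive")
  if (!all(colnames(counts) %in% names(factors) | is.null(names(factors))))
    factors <- factors[colnames(counts)]
  expr <- log2(sweep(counts, 2, factors, "/") + pseudocount)
  attr(expr, "normalization") <- list(method = "shifted-log2-median-of-ratios",
                                      pseudocount = pseudocount)
  expr
}

#' Sum replicate libraries into individual-level counts
#'
#' Raw counts of each individual's replicate libraries are summed per gene;
#' individual-level data should be re-normalized independently afterwards.
#'
#' @param counts Gene-by-library count matrix.
#' @param design Library design (see [read_design()]).
#' @return Gene-by-individual integer matrix, columns ordered by first
#'   appearance of each individual in the design.
#' @export
sum_replicates <- function(counts, design) {
  design <- assert_expr_design(counts + 0, design)
  ind <- factor(design$individual_id, levels = unique(design$individual_id))
  out <- t(rowsum(t(counts), ind))
  storage.mode(out) <- "integer"
  out
}

#' Individual-level rows of a library design
#'
#' Collapses a library-level design to one row per individual, keeping the
#' group and trait columns and summing `mapped_reads` over replicates.
#'
#' @param design Library design.
#' @return data.frame keyed by `individual_id`.
#' @export
individual_design <- function(design) {
  ind <- unique(design$individual_id)
  first <- design[match(ind, design$individual_id), , drop = FALSE]
  first$mapped_reads <- as.vector(tapply(design$mapped_reads, design$individual_id,
                                         sum)[ind])
  first$rin <- as.vector(tapply(design$rin, design$individual_id, mean)[ind])
  first$library_id <- NULL
  rownames(first) <- NULL
  first
}

#' Replicate-pairing quality control
#'
#' Computes the library-by-library expression distance `1 - |r|` (Pearson's
#' r across genes), clusters libraries by average linkage, and flags each
#' individual as "paired" if and only if its replicate libraries form their
#' own clade in the tree (for two replicates, a cherry of mutual nearest
#' siblings). Unpaired individuals are listed for removal, mirroring
#' replicate-dissection QC where failure to pair indicates dissection or
#' processing error.
#'
#' @param expr Normalized gene-by-library expression matrix.
#' @param design Library design; every individual needs >= 2 libraries.
#' @return Object of class `replicate_qc`: the distance matrix, the
#'   `hclust` tree, a per-individual paired flag, and `dropped` (unpaired
#'   individual ids).
#' @export
replicate_qc <- function(expr, design) {
  design <- assert_expr_design(expr, design)
  nrep <- table(design$individual_id)
  if (any(nrep < 2))
    stop2("replicate QC needs >= 2 libraries per individual; offending: ",
          paste(names(nrep)[nrep < 2], collapse = ", "))
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0))
    warning("constant library (zero variance): ",
            paste(colnames(expr)[sds == 0], collapse = ", "),
            "; correlation undefined, distance set to 1")
  r <- suppressWarnings(stats::cor(expr))
  d <- 1 - abs(r)
  d[!is.finite(d)] <- 1
  diag(d) <- 0
  d <- (d + t(d)) / 2
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  clades <- hclust_leafsets(hc)
  paired <- vapply(unique(design$individual_id), function(id) {
    libs <- sort(design$library_id[design$individual_id == id])
    any(vapply(clades, function(s) identical(sort(s), libs), logical(1)))
  }, logical(1))
  out <- list(distance = d, tree = hc,
              paired = paired, dropped = names(paired)[!paired])
  class(out) <- "replicate_qc"
  out
}

## Leaf label sets of every internal node of an hclust tree.
hclust_leafsets <- function(hc) {
  n <- nrow(hc$merge)
  sets <- vector("list", n)
  for (k in seq_len(n)) {
    grab <- function(j) if (j < 0) hc$labels[-j] else sets[[j]]
    sets[[k]] <- c(grab(hc$merge[k, 1]), grab(hc$merge[k, 2]))
  }
  sets
}

#' @export
print.replicate_qc <- function(x, ...) {
  cat("Replicate-pairing QC on", ncol(x$distance), "libraries /",
      length(x$paired), "individuals\n")
  cat("  paired:", sum(x$paired), " unpaired:", sum(!x$paired), "\n")
  if (length(x$dropped))
    cat("  flagged for removal:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Drop unpaired individuals from counts and design
#'
#' @param counts Gene-by-library count matrix.
#' @param design Library design.
#' @param qc A [replicate_qc()] report.
#' @return List with filtered `counts` and `design`.
#' @export
drop_unpaired <- function(counts, design, qc) {
  keep <- !design$individual_id %in% qc$dropped
  list(counts = counts[, design$library_id[keep], drop = FALSE],
       design = design[keep, , drop = FALSE])
}
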