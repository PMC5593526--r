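#' p53repress: discovery and validation of a p53-repressed gene module
#'
#' Implements the full screening-and-validation pipeline for genes repressed
#' in a p53-dependent manner under genotoxic stress: three expression screens
#' (microarray time course, multi-tissue mouse RNA-seq, tumor cohort),
#' cross-dataset intersection, delta-delta-Ct qPCR classification, TSS-window
#' peak enrichment and median-split survival analysis, together with seeded
#' synthetic generators for every input modality.
#'
#' @keywords internal
#' @aliases p53repress-package
"_PACKAGE"

# ---- symbol normalization ----------------------------------------------

#' Normalize gene symbols
#'
#' Human symbols are upper-cased; mouse symbols use the capitalized
#' convention (first letter upper, rest lower). Normalization is applied
#' before any set operation so that cross-species comparisons through an
#' ortholog map are case-stable.
#'
#' @param x character vector of gene symbols.
#' @param species `"human"` or `"mouse"`.
#' @return character vector of normalized symbols.
#' @export
normalize_symbols <- function(x, species = c("human", "mouse")) {
  species <- match.arg(species)
  x <- as.character(x)
  if (species == "human") return(toupper(x))
  paste0(toupper(substr(x, 1L, 1L)), tolower(substr(x, 2L, nchar(x))))
}

# ---- condition codes ----------------------------------------------------

#' Derive the condition code for a sample
#'
#' The code is a pure function of (genotype, treatment, timepoint):
#' \itemize{
#'   \item a non-missing timepoint gives the cell time-course codes
#'     `W0/W12/W24/W48` (p53 wild type) or `K0/K12/K24/K48` (p53 null);
#'   \item a missing timepoint with a stated treatment gives the mouse codes
#'     `W`/`WX`/`K`/`KX` (`X` marks irradiation);
#'   \item a missing treatment marks a tumor-cohort sample,
#'     `cohort_wt` or `cohort_mut` by p53 status.
#' }
#'
#' @param genotype character, each `"p53_wt"`, `"p53_null"` or `"p53_mut"`.
#' @param treatment character, each `"none"`, `"ADR"`, `"irradiation"` or `NA`.
#' @param timepoint numeric hours (0/12/24/48) or `NA`.
#' @return character vector of condition codes.
#' @export
condition_code <- function(genotype, treatment, timepoint = NA) {
  n <- max(length(genotype), length(treatment), length(timepoint))
  genotype <- rep_len(as.character(genotype), n)
  treatment <- rep_len(as.character(treatment), n)
  timepoint <- rep_len(timepoint, n)
  bad <- !genotype %in% c("p53_wt", "p53_null", "p53_mut")
  if (any(bad)) stop("unknown genotype: ", paste(unique(genotype[bad]), collapse = ", "))
  bad <- !(is.na(treatment) | treatment %in% c("none", "ADR", "irradiation"))
  if (any(bad)) stop("unknown treatment: ", paste(unique(treatment[bad]), collapse = ", "))

  out <- character(n)
  cohort <- is.na(treatment)
  out[cohort & genotype == "p53_wt"] <- "cohort_wt"
  out[cohort & genotype == "p53_mut"] <- "cohort_mut"
  if (any(cohort & genotype == "p53_null")) {
    stop("p53_null genotype is not a cohort genotype")
  }
  timed <- !cohort & !is.na(timepoint)
  if (any(timed & genotype == "p53_mut")) {
    stop("time-course codes are defined for p53_wt/p53_null only")
  }
  out[timed] <- paste0(ifelse(genotype[timed] == "p53_wt", "W", "K"),
                       as.integer(timepoint[timed]))
  mouse <- !cohort & is.na(timepoint)
  if (any(mouse & genotype == "p53_mut")) {
    stop("irradiation codes are defined for p53_wt/p53_null only")
  }
  out[mouse] <- paste0(ifelse(genotype[mouse] == "p53_wt", "W", "K"),
                       ifelse(treatment[mouse] == "irradiation", "X", ""))
  out
}

#' Build a validated sample-design table
#'
#' @param sample_id unique sample identifiers.
#' @param genotype,treatment,timepoint,tissue per-sample metadata
#'   (see [condition_code()]).
#' @return data.frame with the inputs plus a derived `condition_code` column.
#' @export
make_design <- function(sample_id, genotype, treatment, timepoint = NA,
                        tissue = NA) {
  if (anyDuplicated(sample_id)) stop("duplicated sample ids")
  n <- length(sample_id)
  d <- data.frame(
    sample_id = as.character(sample_id),
    genotype = rep_len(as.character(genotype), n),
    treatment = rep_len(as.character(treatment), n),
    timepoint = rep_len(timepoint, n),
    tissue = rep_len(as.character(tissue), n),
    stringsAsFactors = FALSE
  )
  d$condition_code <- condition_code(d$genotype, d$treatment, d$timepoint)
  d
}

# ---- expression matrices ------------------------------------------------

validate_expression_matrix <- function(values, feature_kind) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicated feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing expression value at feature '%s', sample '%s'",
                 rownames(values)[idx[1L]], colnames(values)[idx[2L]]))
  }
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative expression value at feature '%s', sample '%s'",
                 rownames(values)[idx[1L]], colnames(values)[idx[2L]]))
  }
  attr(values, "feature_kind") <- match.arg(feature_kind, c("probe", "gene"))
  values
}

#' Read an expression table
#'
#' Expects a TSV with a header row of sample ids and feature ids in the
#' first column. Values must be complete and non-negative; duplicated
#' feature or sample ids and malformed numeric cells are errors.
#'
#' @param path file path.
#' @param feature_kind `"probe"` or `"gene"`.
#' @param sep field separator (tab by default).
#' @return numeric matrix (features x samples) with a `feature_kind` attribute.
#' @export
read_expression_table <- function(path, feature_kind = c("gene", "probe"),
                                  sep = "\t") {
  feature_kind <- match.arg(feature_kind)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) stop("duplicated feature ids in ", path)
  num <- as.matrix(raw[-1L])
  vals <- suppressWarnings(matrix(as.numeric(num), nrow = nrow(num),
                                  dimnames = list(ids, colnames(num))))
  bad <- which(is.na(vals) , arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or missing cell at feature '%s', sample '%s' in %s",
                 ids[bad[1L, 1L]], colnames(num)[bad[1L, 2L]], path))
  }
  validate_expression_matrix(vals, feature_kind)
}

#' Write an expression table
#'
#' Inverse of [read_expression_table()]; round-trips bit-identically on
#' valid input (values are written with full precision).
#'
#' @param values expression matrix with feature rownames / sample colnames.
#' @param path output path.
#' @param feature_col name for the feature-id column.
#' @export
write_expression_table <- function(values, path, feature_col = "feature_id") {
  df <- data.frame(rownames(values),
                   as.data.frame(format(values, digits = 17, trim = TRUE,
                                        scientific = FALSE)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(feature_col, colnames(values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sample-design table
#'
#' TSV with columns `sample_id`, `genotype`, `treatment`, `timepoint`,
#' `tissue`; the condition code is re-derived on read.
#'
#' @param path file path.
#' @return design data.frame (see [make_design()]).
#' @export
read_design_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = "NA")
  req <- c("sample_id", "genotype", "treatment", "timepoint", "tissue")
  miss <- setdiff(req, colnames(d))
  if (length(miss)) stop("design table missing columns: ",
                         paste(miss, collapse = ", "))
  make_design(d$sample_id, d$genotype, d$treatment, d$timepoint, d$tissue)
}

#' @rdname read_design_table
#' @param design design data.frame.
#' @export
write_design_table <- function(design, path) {
  utils::write.table(design[, c("sample_id", "genotype", "treatment",
                                "timepoint", "tissue")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# ---- gene sets and maps -------------------------------------------------

#' Read/write a gene set (one symbol per line, `#` comments allowed)
#'
#' Members are case-normalized and de-duplicated on read.
#'
#' @param path file path.
#' @param species passed to [normalize_symbols()].
#' @return character vector of unique symbols.
#' @export
read_gene_set <- function(path, species = "human") {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(normalize_symbols(lines[nzchar(lines)], species))
}

#' @rdname read_gene_set
#' @param genes character vector of symbols.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(as.character(genes), path)
}

#' Translate mouse symbols to human through an ortholog map
#'
#' Lookup is case-normalized on both sides. Unmapped symbols are returned,
#' never silently dropped.
#'
#' @param mouse_symbols character vector of mouse symbols.
#' @param orthologs data.frame with columns `human`, `mouse`.
#' @return list with `human` (mapped, unique) and `unmapped` (mouse symbols
#'   with no ortholog).
#' @export
map_orthologs <- function(mouse_symbols, orthologs) {
  stopifnot(all(c("human", "mouse") %in% colnames(orthologs)))
  ms <- normalize_symbols(mouse_symbols, "mouse")
  key <- normalize_symbols(orthologs$mouse, "mouse")
  hit <- match(ms, key)
  list(
    human = unique(normalize_symbols(orthologs$human[hit[!is.na(hit)]], "human")),
    unmapped = unique(ms[is.na(hit)])
  )
}

# ---- genomic intervals --------------------------------------------------

#' Read BED3 intervals
#'
#' Coordinates are 0-based half-open. Intervals with `start >= end` or
#' non-integer coordinates are rejected; overlapping intervals are retained
#' as-is (no merging). The result is sorted within chromosome.
#'
#' @param path BED file path.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed_intervals <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(raw) < 3L) stop("BED input needs at least 3 columns")
  start <- suppressWarnings(as.numeric(raw[[2L]]))
  end <- suppressWarnings(as.numeric(raw[[3L]]))
  if (anyNA(start) || anyNA(end) ||
      any(start != floor(start)) || any(end != floor(end))) {
    bad <- which(is.na(start) | is.na(end) |
                   start != floor(start) | end != floor(end))[1L]
    stop("non-integer coordinate on BED line ", bad)
  }
  validate_peaks(data.frame(chrom = raw[[1L]], start = as.integer(start),
                            end = as.integer(end), stringsAsFactors = FALSE))
}

validate_peaks <- function(peaks) {
  stopifnot(all(c("chrom", "start", "end") %in% colnames(peaks)))
  bad <- which(peaks$start >= peaks$end)
  if (length(bad)) {
    stop("interval with start >= end (line ", bad[1L], "): ",
         peaks$chrom[bad[1L]], ":", peaks$start[bad[1L]], "-", peaks$end[bad[1L]])
  }
  peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
}

#' @rdname read_bed_intervals
#' @param peaks interval data.frame.
#' @export
write_bed_intervals <- function(peaks, path) {
  utils::write.table(peaks[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read a TSS annotation table
#'
#' TSV with columns `gene`, `chrom`, `tss_position` (0-based single base),
#' `strand` (`+`/`-`). One TSS per gene; the strand determines which end of
#' the transcript the TSS base is, upstream of this package.
#'
#' @param path file path.
#' @param species symbol normalization species.
#' @return data.frame with one row per gene.
#' @export
read_tss_table <- function(path, species = "human") {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  req <- c("gene", "chrom", "tss_position", "strand")
  miss <- setdiff(req, colnames(d))
  if (length(miss)) stop("TSS table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(d$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  d$gene <- normalize_symbols(d$gene, species)
  if (anyDuplicated(d$gene)) stop("duplicated gene in TSS table")
  d
}

#' @rdname read_tss_table
#' @param tss TSS data.frame.
#' @export
write_tss_table <- function(tss, path) {
  utils::write.table(tss[, c("gene", "chrom", "tss_position", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# ---- cohort container ---------------------------------------------------

#' Construct a validated cohort table
#'
#' @param expr genes x patients expression matrix (non-negative, complete).
#' @param patients data.frame with columns `patient_id`, `p53_status`
#'   (`wt`/`mut`), `time` (days, >= 0), `event` (logical/0-1).
#' @return object of class `cohort_table`.
#' @export
cohort_table <- function(expr, patients) {
  expr <- validate_expression_matrix(expr, "gene")
  req <- c("patient_id", "p53_status", "time", "event")
  miss <- setdiff(req, colnames(patients))
  if (length(miss)) stop("patient table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!identical(colnames(expr), as.character(patients$patient_id))) {
    stop("expression columns must match patient_id order")
  }
  if (!all(patients$p53_status %in% c("wt", "mut"))) {
    stop("p53_status must be 'wt' or 'mut'")
  }
  if (any(patients$time < 0)) stop("negative survival time")
  patients$event <- as.logical(patients$event)
  structure(list(expr = expr, patients = patients), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$expr), "genes x", ncol(x$expr), "patients (",
      sum(x$patients$p53_status == "wt"), "wt /",
      sum(x$patients$p53_status == "mut"), "mut p53 )\n")
  invisible(x)
}
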