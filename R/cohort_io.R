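#' Construct an expression cohort
#'
#' An `ExpressionCohort` bundles a log2 expression matrix (genes in rows,
#' samples in columns) with an optional paired normal/tumor design and a
#' cohort label. All expression values are expected on the log2 scale;
#' linear-scale input is not accepted anywhere in the package, so a single
#' scale convention holds end to end.
#'
#' @param mat numeric matrix of log2 expression, genes x samples, with
#'   unique non-empty rownames (gene symbols) and colnames (sample ids).
#' @param pairing optional data.frame with columns `normal` and `tumor`
#'   (sample ids, one row per patient); every id must be a column of `mat`.
#' @param cohort_name label carried through downstream results.
#' @return an object of class `ExpressionCohort`: a list with elements
#'   `matrix`, `pairing`, `cohort_name`.
#' @export
expression_cohort <- function(mat, pairing = NULL, cohort_name = "cohort") {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression must be a numeric matrix (genes x samples)")
  gid <- rownames(mat)
  sid <- colnames(mat)
  if (nrow(mat) > 0 && (is.null(gid) || any(gid == "")))
    stop("matrix must have gene symbols as rownames")
  if (is.null(gid)) {       # empty cohorts keep well-typed dimnames
    gid <- character(0)
    dimnames(mat) <- list(gid, sid)
  }
  if (is.null(sid) || any(sid == "")) stop("matrix must have sample ids as colnames")
  dup <- gid[duplicated(gid)]
  if (length(dup)) stop("duplicate gene symbol(s): ", paste(unique(dup), collapse = ", "))
  dup <- sid[duplicated(sid)]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(mat)) stop("expression matrix contains missing values")
  if (!is.null(pairing)) {
    pairing <- as.data.frame(pairing)
    if (!all(c("normal", "tumor") %in% names(pairing)))
      stop("pairing must have columns 'normal' and 'tumor'")
    bad <- setdiff(c(pairing$normal, pairing$tumor), sid)
    if (length(bad)) stop("pairing references unknown sample(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(list(matrix = mat, pairing = pairing, cohort_name = cohort_name),
            class = "ExpressionCohort")
}

#' @export
print.ExpressionCohort <- function(x, ...) {
  cat(sprintf("ExpressionCohort '%s': %d genes x %d samples%s\n",
              x$cohort_name, nrow(x$matrix), ncol(x$matrix),
              if (is.null(x$pairing)) "" else
                sprintf(", %d normal/tumor pairs", nrow(x$pairing))))
  invisible(x)
}

#' Read a log2 expression matrix from TSV
#'
#' Expected layout: header row `gene_id<TAB>sample1<TAB>sample2...`, one
#' row per gene, "." as decimal separator. Duplicate gene symbols and
#' non-numeric cells are hard errors (the offending symbol / coordinates
#' are named), never silently coerced.
#'
#' @param path path to a tab-delimited file.
#' @param pairing optional pairing data.frame (see [expression_cohort()])
#'   or path to a two-column TSV (`normal_sample_id`, `tumor_sample_id`).
#' @param cohort_name cohort label; defaults to the file name.
#' @return an `ExpressionCohort`.
#' @export
read_expression <- function(path, pairing = NULL, cohort_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("expression file needs a gene column plus >= 1 sample")
  genes <- raw[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicate gene symbol(s) in ", path, ": ",
                        paste(unique(dup), collapse = ", "))
  mat <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
                dimnames = list(genes, names(raw)[-1]))
  for (j in seq_len(ncol(mat))) {
    cell <- raw[[j + 1L]]
    v <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(v) & !is.na(cell) & !(cell %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   raw[[j + 1L]][bad[1]], genes[bad[1]], colnames(mat)[j]))
    if (anyNA(v))
      stop(sprintf("missing value at gene '%s', sample '%s'",
                   genes[which(is.na(v))[1]], colnames(mat)[j]))
    mat[, j] <- v
  }
  if (is.character(pairing) && length(pairing) == 1L) pairing <- read_pairing(pairing)
  expression_cohort(mat, pairing = pairing,
                    cohort_name = cohort_name %||% basename(path))
}

#' Write an expression cohort to TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the doubles exactly.
#'
#' @param cohort an `ExpressionCohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(cohort, path) {
  stopifnot(inherits(cohort, "ExpressionCohort"))
  mat <- cohort$matrix
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(mat)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i], sprintf("%.17g", mat[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a sample pairing table (normal/tumor)
#'
#' @param path two-column TSV with header `normal_sample_id`,
#'   `tumor_sample_id`.
#' @return data.frame with columns `normal`, `tumor`.
#' @export
read_pairing <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("pairing file must have two columns")
  data.frame(normal = df[[1]], tumor = df[[2]], stringsAsFactors = FALSE)
}

#' Read a clinical table
#'
#' One row per sample. Recognised columns: `sample`, `overall_time`,
#' `overall_event`, `recurrence_time`, `recurrence_event`, `age`,
#' `gender` (M/F), `stage` (ordinal integer), `smoking` (ever/never),
#' `myc` (high/low), `mutation` (+/-), `subtype` (AC/SCC). A covariate is
#' either present for all samples or absent as a column. Times may be in
#' days or months: a first line `# time_unit: months` (or `days`, the
#' default) declares the unit, and months are converted to days
#' internally (30.4375 days/month).
#'
#' @param path tab-delimited clinical file.
#' @return data.frame, times in days, events integer 0/1.
#' @export
read_clinical <- function(path) {
  first <- readLines(path, n = 1L)
  unit <- "days"
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("time_unit[:= ]+\\s*(days|months)", first))[[1]]
    if (length(m) == 2L) unit <- m[2]
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  fac <- if (unit == "months") 30.4375 else 1
  for (col in c("overall_time", "recurrence_time")) if (col %in% names(df)) {
    df[[col]] <- as.numeric(df[[col]]) * fac
    if (any(df[[col]] < 0, na.rm = TRUE)) stop(col, " contains negative times")
  }
  for (col in c("overall_event", "recurrence_event")) if (col %in% names(df)) {
    df[[col]] <- as.integer(df[[col]])
    if (!all(df[[col]] %in% c(0L, 1L))) stop(col, " must be 0/1")
  }
  df
}

#' Read a presence-call matrix
#'
#' Same layout as the expression TSV but with 0/1 entries marking whether
#' a gene was detected in a sample (microarray "present" calls).
#'
#' @param path TSV path.
#' @return logical matrix, genes x samples.
#' @export
read_presence_calls <- function(path) {
  cohort <- read_expression(path)
  mat <- cohort$matrix
  if (!all(mat %in% c(0, 1))) stop("presence calls must be 0/1")
  mode(mat) <- "logical"
  mat
}

#' Retain genes detected in a minimum fraction of samples
#'
#' Keeps exactly the genes whose detected fraction across the cohort's
#' samples is at least `fraction` (inclusive, matching the "at least
#' two-thirds" retention rule); the sample set is unchanged.
#'
#' @param cohort an `ExpressionCohort`.
#' @param calls logical or 0/1 gene x sample matrix covering the cohort.
#' @param fraction required detected fraction, in (0, 1]; default 2/3.
#' @return filtered `ExpressionCohort`.
#' @export
filter_present <- function(cohort, calls, fraction = 2 / 3) {
  stopifnot(inherits(cohort, "ExpressionCohort"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  mat <- cohort$matrix
  missing_g <- setdiff(rownames(mat), rownames(calls))
  missing_s <- setdiff(colnames(mat), colnames(calls))
  if (length(missing_g) || length(missing_s))
    stop("presence calls do not cover the cohort")
  calls <- calls[rownames(mat), colnames(mat), drop = FALSE] != 0
  keep <- rowMeans(calls) >= fraction
  expression_cohort(mat[keep, , drop = FALSE], pairing = cohort$pairing,
                    cohort_name = cohort$cohort_name)
}

#' Drop genes on the sex chromosomes
#'
#' Removes genes annotated to chromosome X or Y (a gender-confounding
#' guard). Genes with no annotation are retained with a warning rather
#' than silently dropped.
#'
#' @param cohort an `ExpressionCohort`.
#' @param annotation named character vector, gene symbol -> chromosome
#'   ("1".."22", "X", "Y"; a "chr" prefix is tolerated).
#' @return filtered `ExpressionCohort`.
#' @export
exclude_sex_chromosomes <- function(cohort, annotation) {
  stopifnot(inherits(cohort, "ExpressionCohort"))
  genes <- rownames(cohort$matrix)
  chrom <- sub("^chr", "", unname(annotation[genes]))
  unann <- is.na(chrom)
  if (any(unann))
    warning(sum(unann), " gene(s) without chromosome annotation retained: ",
            paste(utils::head(genes[unann], 5), collapse = ", "),
            if (sum(unann) > 5) ", ..." else "")
  keep <- unann | !(chrom %in% c("X", "Y"))
  expression_cohort(cohort$matrix[keep, , drop = FALSE],
                    pairing = cohort$pairing, cohort_name = cohort$cohort_name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
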