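.detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; genes in rows, samples in columns. Only the delimiter is
#' auto-detected (tab, falling back to comma) — the orientation is never
#' guessed; use `transpose = TRUE` for samples-in-rows files.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) auto-detects.
#' @param transpose set `TRUE` when the file stores samples in rows.
#' @param impute `"error"` (default) rejects missing cells; `"median"`
#'   replaces them with the gene's median.
#' @return numeric matrix with gene rownames and sample colnames.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6 / 7, 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' writeExpression(m, f)
#' all.equal(loadExpression(f), m)
#' @export
loadExpression <- function(path, sep = NULL, transpose = FALSE,
                           impute = c("error", "median")) {
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) sep <- .detectSep(path)
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated gene identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cols <- colnames(df)[-1L]
  if (anyDuplicated(cols))
    stop("duplicated sample identifier(s): ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "" & toupper(v) != "NA")
      if (length(bad))
        stop("non-numeric value in row '", ids[bad[1L]], "', column '",
             cols[j], "': ", v[bad[1L]])
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  dimnames(m) <- list(ids, cols)
  if (transpose) m <- t(m)
  if (anyNA(m)) {
    if (impute == "error") {
      w <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop("missing value in row '", rownames(m)[w[1L]], "', column '",
           colnames(m)[w[2L]], "' (set impute = \"median\" to impute)")
    }
    for (i in which(rowSums(is.na(m)) > 0L)) {
      med <- stats::median(m[i, ], na.rm = TRUE)
      if (is.na(med)) stop("gene '", rownames(m)[i], "' is all-missing")
      m[i, is.na(m[i, ])] <- med
    }
  }
  m
}

#' Write an expression matrix as TSV
#'
#' Values are written with full double precision so that a
#' write/load round trip preserves identifiers exactly and values to
#' better than 1e-12.
#'
#' @param m numeric matrix with dimnames (or a `TFTargetExperiment`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(m, path) {
  if (is(m, "TFTargetExperiment")) m <- exprMatrix(m)
  df <- data.frame(gene_id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.loadTwoColumn <- function(path, what, values, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) sep <- .detectSep(path)
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop(what, " table needs two columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated identifier(s) in ", what, " table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  v <- as.character(df[[2L]])
  bad <- setdiff(unique(v), values)
  if (length(bad))
    stop("invalid ", what, " value(s): ", paste(bad, collapse = ", "))
  stats::setNames(v, ids)
}

#' Read a sample annotation table
#'
#' Two columns: `sample_id`, `class` (normal/primary/metastatic).
#' @param path file path.
#' @param sep field separator; `NULL` auto-detects.
#' @return named character vector sample -> class.
#' @export
loadSampleAnnotation <- function(path, sep = NULL) {
  .loadTwoColumn(path, "sample annotation",
                 c("normal", "primary", "metastatic"), sep)
}

#' Read a gene role table
#'
#' Two columns: `gene_id`, `role` (TF/target).
#' @param path file path.
#' @param sep field separator; `NULL` auto-detects.
#' @return named character vector gene -> role.
#' @export
loadGeneRoles <- function(path, sep = NULL) {
  .loadTwoColumn(path, "gene role", c("TF", "target"), sep)
}

#' Assemble a TFTargetExperiment from the three input files
#'
#' @param exprPath expression matrix TSV/CSV.
#' @param annotPath sample annotation TSV.
#' @param rolesPath gene role TSV.
#' @param ... passed to [loadExpression()].
#' @return a [TFTargetExperiment-class].
#' @export
loadTFTargetExperiment <- function(exprPath, annotPath, rolesPath, ...) {
  m <- loadExpression(exprPath, ...)
  annot <- loadSampleAnnotation(annotPath)
  roles <- loadGeneRoles(rolesPath)
  missA <- setdiff(colnames(m), names(annot))
  if (length(missA))
    stop("samples without annotation: ", paste(missA, collapse = ", "))
  missR <- setdiff(rownames(m), names(roles))
  if (length(missR))
    stop("genes without a role: ", paste(missR, collapse = ", "))
  TFTargetExperiment(m, annot[colnames(m)], roles[rownames(m)])
}

#' Write aberration calls as TSV
#'
#' One row per gene: the direction, the metastatic-enrichment p, and the
#' 0/1 call per sample.
#'
#' @param ab an [AberrationCalls-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAberrations <- function(ab, path) {
  df <- data.frame(gene_id = rownames(ab@flags),
                   direction = ab@direction,
                   enrich_p = ab@enrichP,
                   1L * ab@flags,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a pairwise regulation test table as TSV
#'
#' @param tests data.frame from [inferPairwise()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdgeTable <- function(tests, path) {
  keep <- c("tf", "target", "cutoff", "tp", "fp", "fn", "tn",
            "p", "q", "sign")
  utils::write.table(tests[, intersect(keep, colnames(tests))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise regulation test table written by [writeEdgeTable()]
#'
#' The per-edge explained-sample sets are not stored in the TSV, so a
#' network pruned from a re-loaded table uses the plain additive
#' objective.
#'
#' @param path file path.
#' @return data.frame of tests.
#' @export
readEdgeTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Oncoprint-style text matrix of TF overexpression calls
#'
#' One line per TF: `X` marks samples carrying an over-expression call,
#' `.` the rest. Mutually exclusive drivers show as non-overlapping `X`
#' blocks.
#'
#' @param ab an [AberrationCalls-class].
#' @param tfs TF identifiers to show (default: all genes with direction
#'   `over`).
#' @return character vector of lines (first line is the sample header).
#' @export
oncoprintText <- function(ab, tfs = NULL) {
  over <- rownames(ab@flags)[ab@direction == "over"]
  if (is.null(tfs)) tfs <- over
  tfs <- intersect(tfs, rownames(ab@flags))
  width <- max(nchar(c("sample", tfs)))
  lines <- sprintf("%-*s %s", width, "sample",
                   paste(colnames(ab@flags), collapse = " "))
  pads <- vapply(colnames(ab@flags), nchar, 1L)
  for (tf in tfs) {
    marks <- ifelse(ab@flags[tf, ] & ab@direction[
      match(tf, rownames(ab@flags))] == "over", "X", ".")
    cells <- vapply(seq_along(marks),
                    function(j) formatC(marks[j], width = pads[j]), "")
    lines <- c(lines, sprintf("%-*s %s", width, tf,
                              paste(cells, collapse = " ")))
  }
  lines
}
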