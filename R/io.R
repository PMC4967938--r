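# Readers/writers for GMT, GCT 1.2, CLS and plain TSV. UTF-8; LF and CRLF
# line endings both accepted. Parsers never silently drop records: every
# skipped item is reported via message() with a reason.

.read_lines <- function(path) {
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sub("\r$", "", x)
}

#' Read a GMT gene-set file
#'
#' Broad GMT dialect: one set per line, tab-separated
#' \code{name<TAB>description<TAB>member...}. Fields beyond position 2 are
#' members; empty member fields (trailing tabs) are ignored. Duplicate member
#' symbols within a line are collapsed; symbol case is preserved.
#'
#' @param path path to a GMT file.
#' @return a [gene_sets] collection (empty file gives an empty collection).
#' @export
read_gmt <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[lines != ""]
  if (length(lines) == 0L)
    return(structure(list(), descriptions = character(0), class = "gene_sets"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], ": fewer than 3 tab-separated fields")
  nm <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  gene_sets(stats::setNames(members, nm), desc)
}

#' Write a gene-set collection as GMT
#' @param sets a [gene_sets] collection.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature-by-sample expression matrix
#'
#' Supports GCT 1.2 (\code{#1.2} header line, then declared row/column counts,
#' then a header and one row per feature with name and description columns)
#' and plain TSV (header row of sample ids, first column feature ids). GCT
#' declared dimensions must match the parsed content.
#'
#' @param path path to the file.
#' @param format \code{"gct"} or \code{"tsv"}; default guesses from the
#'   file extension.
#' @return numeric matrix, features x samples, dimnames set.
#' @export
read_expression <- function(path, format = c("auto", "gct", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  lines <- .read_lines(path)
  if (format == "gct") {
    if (length(lines) < 3L || trimws(lines[1L]) != "#1.2")
      stop("not a GCT 1.2 file (missing '#1.2' header): ", path)
    dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]), "[ \t]+")[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2]))
      stop("GCT dimension line unreadable: ", path)
    n_row <- dims[1L]; n_col <- dims[2L]
    header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
    sample_ids <- header[-(1:2)]
    if (length(sample_ids) != n_col)
      stop("GCT declares ", n_col, " samples but header has ",
           length(sample_ids))
    body <- lines[-(1:3)]
    body <- body[body != ""]
    if (length(body) != n_row)
      stop("GCT declares ", n_row, " rows but body has ", length(body))
    fields <- strsplit(body, "\t", fixed = TRUE)
    feat <- vapply(fields, `[`, "", 1L)
    vals <- lapply(fields, function(f) f[-(1:2)])
    if (any(lengths(vals) != n_col))
      stop("GCT row with wrong number of value fields")
    m <- matrix(NA_real_, n_row, n_col,
                dimnames = list(feat, sample_ids))
    for (i in seq_len(n_row)) {
      v <- suppressWarnings(as.numeric(vals[[i]]))
      if (anyNA(v)) {
        j <- which(is.na(v))[1L]
        stop("non-numeric expression value at row ", i, " (", feat[i],
             "), sample column ", j)
      }
      m[i, ] <- v
    }
    m
  } else {
    fields <- strsplit(lines[lines != ""], "\t", fixed = TRUE)
    if (length(fields) < 2L) stop("TSV expression file has no data rows")
    header <- fields[[1L]]
    sample_ids <- header[-1L]
    body <- fields[-1L]
    if (any(lengths(body) != length(header)))
      stop("TSV row with wrong field count (expected ", length(header), ")")
    feat <- vapply(body, `[`, "", 1L)
    m <- matrix(NA_real_, length(body), length(sample_ids),
                dimnames = list(feat, sample_ids))
    for (i in seq_along(body)) {
      v <- suppressWarnings(as.numeric(body[[i]][-1L]))
      if (anyNA(v))
        stop("non-numeric expression value at row ", i, " (", feat[i],
             "), sample column ", which(is.na(v))[1L])
      m[i, ] <- v
    }
    m
  }
}

#' Write an expression matrix as GCT 1.2
#' @param values numeric matrix with dimnames.
#' @param path output path.
#' @param descriptions optional per-feature description column (default "na").
#' @export
write_gct <- function(values, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", nrow(values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(values), ncol(values), sep = "\t"),
               paste(c("NAME", "Description", colnames(values)),
                     collapse = "\t")), con)
  body <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i], descriptions[i],
            format(values[i, ], trim = TRUE, digits = 15)), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Read per-sample phenotype labels
#'
#' CLS (categorical): first line \code{"<n> <k> 1"} with exactly k = 2
#' classes, second line \code{"# name1 name2"}, third line the per-sample
#' labels (either class names or 0/1 indices). TSV: two columns
#' (sample id, label), no header required; a header row whose first field is
#' \code{"sample"} is tolerated.
#'
#' @param path path to the file.
#' @param format \code{"cls"} or \code{"tsv"}; default guesses from extension.
#' @return character vector of labels (named by sample id for TSV input).
#' @export
read_phenotype <- function(path, format = c("auto", "cls", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cls$", path, ignore.case = TRUE)) "cls" else "tsv"
  lines <- .read_lines(path)
  lines <- lines[lines != ""]
  if (format == "cls") {
    if (length(lines) < 3L) stop("CLS file needs 3 lines")
    hd <- as.integer(strsplit(trimws(lines[1L]), "[ \t]+")[[1L]])
    n <- hd[1L]; k <- hd[2L]
    if (is.na(k) || k != 2L)
      stop("unsupported CLS design: ", k,
           " classes (only two-class designs are supported)")
    names_line <- strsplit(trimws(lines[2L]), "[ \t]+")[[1L]]
    class_names <- setdiff(names_line, "#")
    labs <- strsplit(trimws(lines[3L]), "[ \t]+")[[1L]]
    if (length(labs) != n)
      stop("CLS declares ", n, " samples but ", length(labs),
           " labels found")
    if (all(labs %in% c("0", "1")) && !all(labs %in% class_names))
      labs <- class_names[as.integer(labs) + 1L]
    if (length(unique(labs)) != 2L)
      stop("CLS labels do not form two classes")
    labs
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 2L))
      stop("phenotype TSV needs two columns (sample, label)")
    if (tolower(fields[[1L]][1L]) == "sample") fields <- fields[-1L]
    labs <- vapply(fields, `[`, "", 2L)
    names(labs) <- vapply(fields, `[`, "", 1L)
    labs
  }
}

#' Read a two-column symbol map
#'
#' Used for probe-to-symbol and mouse-to-human ortholog tables. A source id
#' mapping to two different targets is an error; exact duplicate rows are
#' collapsed. Rows with an empty target are skipped with a message.
#'
#' @param path TSV with columns (source, target); a header row whose first
#'   field is "source" is tolerated.
#' @return named character vector: names are source ids, values targets.
#' @export
read_symbol_map <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[lines != ""]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("symbol map needs two tab-separated columns")
  if (length(fields) && tolower(fields[[1L]][1L]) == "source")
    fields <- fields[-1L]
  src <- vapply(fields, `[`, "", 1L)
  tgt <- vapply(fields, `[`, "", 2L)
  empty <- tgt == ""
  if (any(empty)) {
    message(sum(empty), " map row(s) skipped: empty target symbol")
    src <- src[!empty]; tgt <- tgt[!empty]
  }
  keep <- !duplicated(paste(src, tgt, sep = "\r"))
  src <- src[keep]; tgt <- tgt[keep]
  if (anyDuplicated(src))
    stop("source id maps to two targets: ",
         paste(unique(src[duplicated(src)]), collapse = ", "))
  stats::setNames(tgt, src)
}

# stable TSV writer used by all result exports
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
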