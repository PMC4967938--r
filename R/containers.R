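#' Construct a two-class expression dataset
#'
#' Bundles a numeric feature-by-sample matrix with a two-class phenotype
#' assignment. Expression values are used as given (log or linear scale as
#' provided); no transformation is applied. The assumed scale can be recorded
#' for provenance via \code{scale_note}.
#'
#' @param values numeric matrix, features (probes or gene symbols) in rows,
#'   samples in columns. Row and column names are required and must be unique.
#' @param phenotype character or factor of per-sample class labels, length
#'   \code{ncol(values)}, with exactly two distinct values and no missing entry.
#' @param case label of the class to treat as case (disease/treatment).
#' @param control label of the control class. Defaults to the other class.
#' @param scale_note free-text provenance note on the value scale (e.g.
#'   \code{"log2"}); not interpreted.
#'
#' @return an object of class \code{"expr_dataset"}: a list with elements
#'   \code{values}, \code{phenotype} (factor with levels
#'   \code{c(control, case)}), \code{case}, \code{control}, \code{scale_note}.
#' @examples
#' m <- matrix(rnorm(24), 4, 6,
#'             dimnames = list(paste0("G", 1:4), paste0("S", 1:6)))
#' ds <- expression_dataset(m, rep(c("ctrl", "dis"), each = 3), case = "dis")
#' ds
#' @export
expression_dataset <- function(values, phenotype, case,
                               control = NULL, scale_note = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have row (feature) and column (sample) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids in 'values'")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in 'values'")
  phenotype <- as.character(phenotype)
  if (length(phenotype) != ncol(values))
    stop("phenotype length (", length(phenotype),
         ") does not match sample count (", ncol(values), ")")
  if (anyNA(phenotype)) stop("missing phenotype label")
  classes <- unique(phenotype)
  if (length(classes) != 2L)
    stop("exactly two phenotype classes required, found ", length(classes))
  if (!case %in% classes) stop("case class '", case, "' not among labels")
  if (is.null(control)) control <- setdiff(classes, case)
  if (!control %in% classes || control == case)
    stop("control class must be the non-case label")
  counts <- table(phenotype)
  if (any(counts < 2L))
    stop("each phenotype class needs >= 2 samples")
  structure(
    list(values = values,
         phenotype = factor(phenotype, levels = c(control, case)),
         case = case, control = control, scale_note = scale_note),
    class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("Two-class expression dataset\n")
  cat(sprintf("  features: %d   samples: %d\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  case: %s (n=%d)   control: %s (n=%d)\n",
              x$case, sum(x$phenotype == x$case),
              x$control, sum(x$phenotype == x$control)))
  if (!is.na(x$scale_note)) cat("  scale note:", x$scale_note, "\n")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Construct a gene-set collection
#'
#' A named collection of gene-symbol sets, the in-memory form of a GMT file.
#' Member symbols are deduplicated per set; case is preserved.
#'
#' @param sets named list of character vectors of gene symbols.
#' @param descriptions optional character vector of per-set descriptions,
#'   recycled from \code{""}.
#' @return object of class \code{"gene_sets"}: a named list of unique-symbol
#'   character vectors with a \code{"descriptions"} attribute.
#' @examples
#' gs <- gene_sets(list(TLR = c("TLR4", "CD14"), IL6 = c("IL6", "IL6R", "STAT3")))
#' gs
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (!is.list(sets)) stop("'sets' must be a list")
  nm <- names(sets)
  if (is.null(nm) || any(nm == "") || anyNA(nm))
    stop("every set must be named")
  if (anyDuplicated(nm))
    stop("duplicate set name: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(sets, function(s) unique(as.character(s[!is.na(s) & s != ""])))
  if (any(lengths(sets) == 0L)) stop("empty gene set after parsing")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- nm
  structure(sets, descriptions = descriptions, class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("Gene-set collection: %d sets, sizes %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' @export
`[.gene_sets` <- function(x, i) {
  gene_sets(unclass(x)[i], attr(x, "descriptions")[i])
}
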