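#' Gene-by-sample expression dataset
#'
#' Lightweight container for a log-expression matrix (genes in rows, samples
#' in columns) together with tissue labels and a species tag. Values are
#' expected on a log scale (e.g. log-transformed FPKM); no transformation is
#' applied by the constructor.
#'
#' @param values Numeric matrix, genes x samples. Row names are gene (or
#'   ortholog) identifiers, column names the sample/tissue labels; both may
#'   alternatively be supplied via `gene_ids` / `sample_labels`.
#' @param gene_ids Character vector of unique gene identifiers.
#' @param sample_labels Character vector of unique sample (tissue) labels.
#' @param species Short species tag, e.g. `"speciesA"`.
#'
#' @return An object of class `"ExpressionDataset"`: a list with elements
#'   `values` (named numeric matrix) and `species`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' expression_dataset(m, species = "demo")
expression_dataset <- function(values, gene_ids = rownames(values),
                               sample_labels = colnames(values),
                               species = "") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(gene_ids)) stop("gene identifiers are required")
  if (is.null(sample_labels)) {
    sample_labels <- paste0("sample", seq_len(ncol(values)))
  }
  gene_ids <- as.character(gene_ids)
  sample_labels <- as.character(sample_labels)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match row count")
  if (length(sample_labels) != ncol(values))
    stop("sample_labels length does not match column count")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_labels))
    stop("duplicate sample labels")
  dimnames(values) <- list(gene_ids, sample_labels)
  structure(list(values = values, species = as.character(species)),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s': %d genes x %d samples\n",
              x$species, nrow(x$values), ncol(x$values)))
  cat("samples:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' @rdname expression_dataset
#' @param x An `ExpressionDataset`.
#' @export
is_expression_dataset <- function(x) inherits(x, "ExpressionDataset")

# Row-wise SD ignoring NAs; genes with < 2 observations get NA.
row_sds <- function(m) {
  apply(m, 1L, stats::sd, na.rm = TRUE)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb the global stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
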