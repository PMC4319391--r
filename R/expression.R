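# Expression matrices, case/control group designs and control-group
# statistics. Expression values are linear-scale and non-negative;
# log-transformed data must be de-logged before use, since the activation
# score mixes ratios of levels with logs of those ratios.

#' Validate a gene-by-sample expression matrix
#'
#' @param x numeric matrix, genes in rows (rownames = symbols, stored
#'   upper-case), samples in columns (colnames = sample ids). Values must be
#'   finite, non-negative, linear-scale.
#' @return the validated matrix with class `"expression_matrix"` prepended.
#' @export
as_expression_matrix <- function(x) {
  assert_that(is.matrix(x) && is.numeric(x),
              "expression data must be a numeric matrix")
  assert_that(!is.null(rownames(x)) && !is.null(colnames(x)),
              "expression matrix needs gene rownames and sample colnames")
  rownames(x) <- toupper(rownames(x))
  if (anyDuplicated(rownames(x))) {
    stop("duplicate gene id(s): ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample id(s): ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop("missing value at gene '", rownames(x)[idx[1]], "', sample '",
         colnames(x)[idx[2]], "'", call. = FALSE)
  }
  if (any(x < 0)) {
    idx <- which(x < 0, arr.ind = TRUE)[1, ]
    stop("negative value at gene '", rownames(x)[idx[1]], "', sample '",
         colnames(x)[idx[2]], "' (values must be linear-scale, >= 0)",
         call. = FALSE)
  }
  if (!inherits(x, "expression_matrix")) {
    class(x) <- c("expression_matrix", class(x))
  }
  x
}

#' Read an expression matrix from tab-separated text
#'
#' First row holds sample ids, first column gene symbols; remaining cells are
#' linear-scale non-negative expression values. Lines starting with `#` are
#' skipped. Empty cells, negative values and duplicate gene or sample ids
#' raise errors naming the offending coordinates.
#'
#' @param path file path.
#' @return an [as_expression_matrix()] object.
#' @export
read_expression_matrix <- function(path) {
  assert_that(file.exists(path), "expression file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "", na.strings = c("NA", ""))
  assert_that(ncol(raw) >= 2, "expression file needs a gene column plus at ",
              "least one sample column")
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("empty cell at gene '", genes[idx[1]], "', sample '",
         samples[idx[2]], "'", call. = FALSE)
  }
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric value '", vals[idx[1], idx[2]], "' at gene '",
         genes[idx[1]], "', sample '", samples[idx[2]], "'", call. = FALSE)
  }
  dimnames(num) <- list(genes, samples)
  as_expression_matrix(num)
}

#' Write an expression matrix as tab-separated text
#'
#' @param m expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize an expression matrix across samples
#'
#' `"quantile"` replaces each column by the mean order statistics across
#' columns, preserving within-column ranks; tied values receive the mean of
#' the tied target values. All samples (case and control) are normalized
#' jointly, so the scale-free expression ratios compare like with like.
#' `"none"` returns the input unchanged.
#'
#' @param m expression matrix.
#' @param method `"quantile"` (default) or `"none"`.
#' @return normalized expression matrix with the same dimnames.
#' @export
normalize_expression <- function(m, method = c("quantile", "none")) {
  method <- match.arg(method)
  m <- as_expression_matrix(unclass(m))
  if (method == "none") return(m)
  out <- limma::normalizeQuantiles(unclass(m), ties = TRUE)
  dimnames(out) <- dimnames(m)
  as_expression_matrix(out)
}

#' Define a case/control group design
#'
#' @param case character vector of case sample ids (>= 1).
#' @param control character vector of control sample ids.
#' @return an object of class `"group_design"`.
#' @export
group_design <- function(case, control) {
  case <- as.character(case)
  control <- as.character(control)
  assert_that(length(case) >= 1, "need at least one case sample")
  assert_that(length(control) >= 1, "need at least one control sample")
  both <- intersect(case, control)
  assert_that(length(both) == 0, "sample(s) assigned to both groups: ",
              paste(both, collapse = ", "))
  assert_that(!anyDuplicated(case) && !anyDuplicated(control),
              "duplicate sample id in group design")
  structure(list(case = case, control = control), class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  cat("group_design:", length(x$case), "case /", length(x$control),
      "control samples\n")
  invisible(x)
}

#' Read a group design from a two-column TSV
#'
#' Columns `sample_id` and `group` (header required); group values are
#' `case` or `control` (case-insensitive).
#'
#' @param path file path.
#' @return a [group_design()].
#' @export
read_group_design <- function(path) {
  assert_that(file.exists(path), "design file not found: ", path)
  df <- read_tsv_plain(path)
  assert_that(all(c("sample_id", "group") %in% colnames(df)),
              "design file must have columns 'sample_id' and 'group'")
  grp <- tolower(df$group)
  bad <- setdiff(unique(grp), c("case", "control"))
  assert_that(length(bad) == 0, "unknown group label(s): ",
              paste(bad, collapse = ", "))
  group_design(case = df$sample_id[grp == "case"],
               control = df$sample_id[grp == "control"])
}

#' Write a group design as a two-column TSV
#' @param design a [group_design()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_group_design <- function(design, path) {
  df <- data.frame(
    sample_id = c(design$case, design$control),
    group = c(rep("case", length(design$case)),
              rep("control", length(design$control))),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_design <- function(m, design, min_control_n = 3L) {
  assert_that(inherits(design, "group_design"),
              "'design' must be a group_design")
  missing <- setdiff(c(design$case, design$control), colnames(m))
  assert_that(length(missing) == 0,
              "design sample(s) absent from the expression matrix: ",
              paste(missing, collapse = ", "))
  assert_that(length(design$control) >= min_control_n,
              "need at least ", min_control_n, " control samples (got ",
              length(design$control), "); the standard-deviation tolerance ",
              "criterion is degenerate with fewer")
  invisible(design)
}

#' Per-gene control-group statistics
#'
#' Mean and sample standard deviation (n - 1 denominator) of each gene over
#' the control columns only; the tolerance filter compares each case sample
#' against these.
#'
#' @param m expression matrix.
#' @param design a [group_design()] whose samples exist in `m`.
#' @param min_control_n minimum number of control samples (default 3).
#' @return data frame with rownames = gene ids and columns `control_mean`,
#'   `control_sd`.
#' @export
control_stats <- function(m, design, min_control_n = 3L) {
  m <- as_expression_matrix(unclass(m))
  validate_design(m, design, min_control_n)
  ctl <- m[, design$control, drop = FALSE]
  data.frame(control_mean = rowMeans(ctl),
             control_sd = apply(ctl, 1, stats::sd),
             row.names = rownames(m))
}
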