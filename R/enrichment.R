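# Gene-list enrichment against the pathway database: one-sided Fisher's
# exact test per pathway, Benjamini-Hochberg adjustment across pathways.

#' One-sided Fisher's exact test for enrichment
#'
#' Upper-tail hypergeometric probability P(X >= a) for a 2x2 table with
#' fixed margins: `a` = genes in both the list and the pathway, `b` = list
#' genes outside the pathway, `c` = pathway genes outside the list, `d` =
#' background genes in neither. Vectorized over tables.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return one-sided p-value(s) in (0, 1].
#' @export
fisher_one_sided <- function(a, b, c, d) {
  counts <- cbind(a, b, c, d)
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "cell counts must be non-negative integers")
  stats::phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param p p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  assert_that(all(p > 0 & p <= 1), "p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pathway enrichment of a gene list
#'
#' Tests every pathway in the database for over-representation of the gene
#' list by the one-sided (greater) Fisher's exact test, against a background
#' universe. List genes outside the universe are dropped with a warning.
#' The reported odds ratio is the sample cross-product `(a*d)/(b*c)`
#' (infinite when `b*c = 0`); pass `haldane = TRUE` for the +0.5-corrected
#' variant. Overlap percentage is `100 * a / pathway size within the
#' universe`.
#'
#' @param gene_list character vector of gene symbols (case-insensitive).
#' @param db a [pathway_db()].
#' @param universe background gene set; defaults to [gene_universe()] of the
#'   database.
#' @param haldane apply the Haldane-Anscombe 0.5 correction to the odds
#'   ratio (the p-value is unaffected). Default `FALSE`.
#' @return data frame sorted by ascending p-value (ties by pathway id) with
#'   columns `pathway_id`, `name`, `pathway_size`, `overlap_count`,
#'   `overlap_pct`, `odds_ratio`, `p_value`, `p_adjusted`, and an attribute
#'   `n_dropped` counting list genes outside the universe.
#' @export
enrich_pathways <- function(gene_list, db, universe = gene_universe(db),
                            haldane = FALSE) {
  assert_that(inherits(db, "pathway_db"), "'db' must be a pathway_db")
  gene_list <- unique(toupper(as.character(gene_list)))
  universe <- unique(toupper(as.character(universe)))
  dropped <- setdiff(gene_list, universe)
  if (length(dropped) > 0) {
    warning(length(dropped), " gene(s) in the list are absent from the ",
            "universe and were dropped", call. = FALSE)
    gene_list <- intersect(gene_list, universe)
  }
  assert_that(length(gene_list) > 0,
              "gene list is empty after restricting to the universe")

  n_univ <- length(universe)
  rows <- lapply(db, function(p) {
    pw <- intersect(p$members$gene_id, universe)
    a <- length(intersect(gene_list, pw))
    b <- length(gene_list) - a
    cc <- length(pw) - a
    d <- n_univ - a - b - cc
    or <- if (haldane) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else if (b * cc == 0) {
      Inf
    } else {
      (a * d) / (b * cc)
    }
    data.frame(pathway_id = p$pathway_id, name = p$name,
               pathway_size = length(pw), overlap_count = a,
               overlap_pct = if (length(pw) > 0) 100 * a / length(pw)
                             else NA_real_,
               odds_ratio = or,
               p_value = fisher_one_sided(a, b, cc, d),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- bh_adjust(res$p_value)
  res <- res[order(res$p_value, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- length(dropped)
  res
}

#' Read a gene list (one symbol per line)
#'
#' Blank lines and lines starting with `#` are ignored; symbols are
#' upper-cased and de-duplicated.
#'
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  assert_that(file.exists(path), "gene list file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(toupper(x))
}
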