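# Pathway model: gene sets whose members carry signed activator/repressor
# role weights (ARR). The sign of the weight is forced by the role:
# activators have arr > 0, repressors arr < 0, neutral members arr = 0.

.ROLE_TOKENS <- c(act = "activator", rep = "repressor", neu = "neutral",
                  activator = "activator", repressor = "repressor",
                  neutral = "neutral")

role_to_sign <- function(role) {
  unname(c(activator = 1, repressor = -1, neutral = 0)[role])
}

#' Construct a pathway with role-annotated members
#'
#' A pathway is a named gene set in which every member gene carries an
#' activator/repressor role (ARR) weight: positive for activators, negative
#' for repressors, zero for neutral members. Weights default to +1/-1/0 and
#' may be attenuated to magnitudes in (0, 1] for graded roles.
#'
#' @param pathway_id unique pathway identifier.
#' @param genes character vector of member gene symbols (case-insensitive,
#'   stored upper-case, unique within the pathway).
#' @param roles character vector, one of `"act"`/`"activator"`,
#'   `"rep"`/`"repressor"`, `"neu"`/`"neutral"`, recycled if length 1.
#' @param weights optional numeric magnitudes in (0, 1] (ignored sign); for
#'   neutral members the weight must be absent or zero. Default 1.
#' @param name free-text pathway name; defaults to `pathway_id`.
#' @return an object of class `"pathway"`: a list with `pathway_id`, `name`
#'   and a `members` data frame (`gene_id`, `role`, `arr`).
#' @export
pathway <- function(pathway_id, genes, roles, weights = NULL,
                    name = pathway_id) {
  assert_that(is.character(pathway_id) && length(pathway_id) == 1 &&
                nzchar(pathway_id), "'pathway_id' must be a non-empty string")
  assert_that(length(genes) >= 1, "pathway '", pathway_id,
              "' must have at least one member gene")
  genes <- toupper(as.character(genes))
  if (anyDuplicated(genes)) {
    stop("pathway '", pathway_id, "': duplicate member gene(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(roles) == 1) roles <- rep(roles, length(genes))
  assert_that(length(roles) == length(genes),
              "pathway '", pathway_id, "': 'roles' length must match 'genes'")
  role <- .ROLE_TOKENS[tolower(roles)]
  if (anyNA(role)) {
    stop("pathway '", pathway_id, "': unknown role token(s): ",
         paste(unique(roles[is.na(role)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(weights)) {
    w <- ifelse(role == "neutral", 0, 1)
  } else {
    assert_that(length(weights) == length(genes),
                "pathway '", pathway_id,
                "': 'weights' length must match 'genes'")
    w <- abs(as.numeric(weights))
    bad <- role != "neutral" & (!is.finite(w) | w <= 0 | w > 1)
    if (any(bad)) {
      stop("pathway '", pathway_id, "': weights must lie in (0, 1] for ",
           "activator/repressor members (offending gene(s): ",
           paste(genes[bad], collapse = ", "), ")", call. = FALSE)
    }
    w[role == "neutral"] <- 0
  }
  members <- data.frame(gene_id = genes, role = unname(role),
                        arr = role_to_sign(role) * w,
                        stringsAsFactors = FALSE)
  structure(list(pathway_id = pathway_id, name = name, members = members),
            class = "pathway")
}

#' Assemble a validated pathway database
#'
#' @param pathways a list of [pathway()] objects.
#' @return an object of class `"pathway_db"`: a list of pathways named by
#'   `pathway_id`.
#' @export
pathway_db <- function(pathways) {
  assert_that(length(pathways) >= 1, "a pathway database must contain at ",
              "least one pathway")
  assert_that(all(vapply(pathways, inherits, logical(1), "pathway")),
              "all elements must be 'pathway' objects")
  ids <- vapply(pathways, `[[`, character(1), "pathway_id")
  if (anyDuplicated(ids)) {
    stop("duplicate pathway_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(pathways) <- ids
  structure(pathways, class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  sizes <- vapply(x, function(p) nrow(p$members), integer(1))
  cat("pathway_db:", length(x), "pathways,",
      length(gene_universe(x)), "distinct genes\n")
  cat("  member counts:", paste(range(sizes), collapse = "-"), "\n")
  invisible(x)
}

#' @export
print.pathway <- function(x, ...) {
  cat("pathway '", x$pathway_id, "' (", x$name, "): ",
      nrow(x$members), " members (",
      sum(x$members$arr > 0), " activators, ",
      sum(x$members$arr < 0), " repressors, ",
      sum(x$members$arr == 0), " neutral)\n", sep = "")
  invisible(x)
}

#' All gene symbols covered by a pathway database
#'
#' The union of member genes across pathways, used as the default background
#' universe for enrichment testing.
#'
#' @param db a [pathway_db()].
#' @return sorted character vector of distinct gene symbols.
#' @export
gene_universe <- function(db) {
  assert_that(inherits(db, "pathway_db"), "'db' must be a pathway_db")
  sort(unique(unlist(lapply(db, function(p) p$members$gene_id),
                     use.names = FALSE)))
}

parse_gene_token <- function(token, line_no) {
  parts <- strsplit(token, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2 || length(parts) > 3 || !nzchar(parts[1]) ||
      !nzchar(parts[2])) {
    stop("line ", line_no, ": malformed gene token '", token,
         "' (expected GENE:role[:weight] with role act|rep|neu)",
         call. = FALSE)
  }
  role <- .ROLE_TOKENS[tolower(parts[2])]
  if (is.na(role)) {
    stop("line ", line_no, ": malformed gene token '", token,
         "' (unknown role '", parts[2], "')", call. = FALSE)
  }
  weight <- NA_real_
  if (length(parts) == 3) {
    weight <- suppressWarnings(as.numeric(parts[3]))
    if (!is.finite(weight)) {
      stop("line ", line_no, ": malformed gene token '", token,
           "' (non-numeric weight '", parts[3], "')", call. = FALSE)
    }
  }
  list(gene = toupper(parts[1]), role = unname(role), weight = weight)
}

#' Read a role-annotated GMT pathway database
#'
#' The dialect is tab-separated with one pathway per line:
#' `pathway_id<TAB>description<TAB>GENE:role[:weight] ...` where role is one
#' of `act`, `rep`, `neu`. Omitted weights default to +1 (act), -1 (rep) and
#' 0 (neu); an explicit weight gives the ARR magnitude, its sign always
#' forced by the role. Plain GMT without role tokens is rejected because the
#' activation score is undefined without activator/repressor assignment.
#'
#' @param path file path; UTF-8 text, blank lines ignored.
#' @param dialect currently only `"role_gmt"`.
#' @return a [pathway_db()].
#' @export
read_pathway_db <- function(path, dialect = "role_gmt") {
  dialect <- match.arg(dialect, "role_gmt")
  assert_that(file.exists(path), "pathway file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  pathways <- list()
  seen <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("line ", i, ": expected at least 3 tab-separated fields ",
           "(id, description, gene tokens), got ", length(fields),
           call. = FALSE)
    }
    id <- fields[1]
    if (id %in% seen) {
      stop("line ", i, ": duplicate pathway_id '", id, "'", call. = FALSE)
    }
    tokens <- lapply(fields[-(1:2)], parse_gene_token, line_no = i)
    genes <- vapply(tokens, `[[`, character(1), "gene")
    if (anyDuplicated(genes)) {
      stop("line ", i, ": duplicate gene '",
           genes[duplicated(genes)][1], "' within pathway '", id, "'",
           call. = FALSE)
    }
    roles <- vapply(tokens, `[[`, character(1), "role")
    weights <- vapply(tokens, `[[`, numeric(1), "weight")
    weights <- ifelse(is.na(weights), ifelse(roles == "neutral", 0, 1),
                      weights)
    pathways[[length(pathways) + 1]] <-
      pathway(id, genes, roles, weights, name = fields[2])
    seen <- c(seen, id)
  }
  pathway_db(pathways)
}

#' Write a pathway database in the role-annotated GMT dialect
#'
#' The writer is byte-stable: members are emitted sorted by gene symbol and
#' default weights are omitted, so a load/write/load round trip reproduces
#' an identical database and identical bytes.
#'
#' @param db a [pathway_db()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pathway_db <- function(db, path) {
  assert_that(inherits(db, "pathway_db"), "'db' must be a pathway_db")
  fmt_member <- function(gene_id, role, arr) {
    short <- c(activator = "act", repressor = "rep", neutral = "neu")[role]
    w <- abs(arr)
    if (role == "neutral" || w == 1) {
      paste0(gene_id, ":", short)
    } else {
      paste0(gene_id, ":", short, ":", format(w, digits = 17, trim = TRUE))
    }
  }
  lines <- vapply(db, function(p) {
    m <- p$members[order(p$members$gene_id), , drop = FALSE]
    toks <- mapply(fmt_member, m$gene_id, m$role, m$arr, USE.NAMES = FALSE)
    paste(c(p$pathway_id, p$name, toks), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
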