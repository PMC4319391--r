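# Shared fixtures, built in code at test time.

# Three-pathway database: sizes 4, 5, 6 with two genes shared across
# pathways, so the universe has 13 distinct symbols.
fixture_db <- function() {
  pathway_db(list(
    pathway("P1", c("CREB1", "GSK3B", "PDE4", "SHARED1"),
            c("act", "rep", "rep", "act")),
    pathway("P2", c("IGF1R", "AKT1", "PTEN", "SHARED1", "SHARED2"),
            c("act", "act", "rep", "act", "neu")),
    pathway("P3", c("ADCY1", "PRKACA", "PDE4B", "CREBBP", "GRIN1",
                    "SHARED2"),
            c("act", "act", "rep", "act", "act", "neu"))))
}

# Write a role-GMT file for a database and return its path.
fixture_gmt <- function(db = fixture_db()) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  write_pathway_db(db, path)
  path
}

# Small deterministic expression matrix: 2 case + 3 control samples.
fixture_matrix <- function(genes, case, control) {
  stopifnot(length(case) == length(genes) * 2,
            length(control) == length(genes) * 3)
  m <- cbind(matrix(case, length(genes), 2),
             matrix(control, length(genes), 3))
  dimnames(m) <- list(genes, c("c1", "c2", "n1", "n2", "n3"))
  as_expression_matrix(m)
}

fixture_design <- function() group_design(c("c1", "c2"), c("n1", "n2", "n3"))

# Random role-annotated database for property tests.
random_db <- function(n_pathways = 5, max_size = 8) {
  pws <- lapply(seq_len(n_pathways), function(k) {
    size <- sample(2:max_size, 1)
    genes <- sprintf("R%d_%d", k, seq_len(size))
    roles <- sample(c("act", "rep", "neu"), size, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
    weights <- ifelse(roles == "neu", 0,
                      sample(c(1, 0.5, 0.25), size, replace = TRUE))
    pathway(sprintf("RP%d", k), genes, roles, weights)
  })
  pathway_db(pws)
}

# Exhaustive hypergeometric oracle: sum the probabilities of all 2x2 tables
# with the same margins and first cell >= a, using only choose().
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  xs <- max(0, k - n_):min(m, k)
  probs <- choose(m, xs) * choose(n_, k - xs) / choose(m + n_, k)
  sum(probs[xs >= a])
}
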