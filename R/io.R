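# Readers and writers for the on-disk formats: Newick trees and
# tab-separated tables (counts, traits, GO map, family membership,
# expression, result tables). All readers validate and reject rather than
# silently coerce.

#' Read a rooted phylogeny from a Newick file
#'
#' Parses a single-tree Newick string via \pkg{ape} after a syntax pre-check
#' that reports the byte offset of unbalanced parentheses. Branch lengths
#' are mandatory because the downstream Brownian-motion PGLS is defined by
#' root-to-ancestor path lengths.
#'
#' @param path Path to a Newick file containing exactly one tree.
#' @return An [ape::phylo] object with unique tip labels and nonnegative
#'   branch lengths.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) {
    ssd_error(sprintf("tree file not found: %s", path), "ssd_io_error")
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_newick_syntax(txt)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) {
    ssd_error(sprintf("malformed Newick in %s", path), "ssd_parse_error")
  }
  if (inherits(tree, "multiPhylo")) {
    ssd_error("expected a single tree, found several", "ssd_parse_error")
  }
  validate_tree(tree)
  tree
}

# balanced-parenthesis scan; errors name the 1-based byte offset
check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      depth <- depth + 1L
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (depth == 0L) {
        ssd_error(sprintf("malformed Newick: unmatched ')' at byte %d", i),
                  "ssd_parse_error")
      }
      depth <- depth - 1L
      stack <- stack[-length(stack)]
    }
  }
  if (depth > 0L) {
    ssd_error(
      sprintf("malformed Newick: unmatched '(' at byte %d", stack[1]),
      "ssd_parse_error"
    )
  }
  if (!grepl(";", txt, fixed = TRUE)) {
    ssd_error(sprintf("malformed Newick: missing ';' terminator at byte %d",
                      length(chars) + 1L), "ssd_parse_error")
  }
  invisible(TRUE)
}

validate_tree <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    ssd_error(
      "tree has missing branch lengths; Brownian-motion PGLS requires branch lengths on every edge",
      "ssd_tree_error"
    )
  }
  if (any(tree$edge.length < 0)) {
    ssd_error("negative branch lengths are not allowed", "ssd_tree_error")
  }
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    ssd_error(sprintf("duplicate tip labels: %s", paste(dup, collapse = ", ")),
              "ssd_tree_error")
  }
  invisible(tree)
}

#' Write a phylogeny as Newick
#'
#' Branch lengths are written with enough digits that a write-then-read
#' round trip preserves them to 1e-9.
#'
#' @param tree An [ape::phylo] object.
#' @param path Output file path.
#' @return `invisible(path)`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

.table_schemas <- list(
  counts     = character(0),  # header: family + one column per species
  traits     = c("species", "male_mass", "female_mass"),
  go_map     = c("gene", "term"),
  membership = c("gene", "family"),
  expression = c("gene", "tissue", "stage", "sex", "value")
)

#' Read and validate a tab-separated pipeline table
#'
#' @param path Path to a TSV file with a header row.
#' @param schema One of `"counts"`, `"traits"`, `"go_map"`, `"membership"`,
#'   `"expression"`. The counts schema returns an integer matrix (families
#'   in rows, species in columns); the others return data frames with at
#'   least the schema's required columns.
#' @return A validated matrix or data frame.
#' @export
read_table <- function(path, schema = names(.table_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    ssd_error(sprintf("table file not found: %s", path), "ssd_io_error")
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- .table_schemas[[schema]]
  if (schema == "counts") {
    if (ncol(df) < 2) {
      ssd_error("counts table needs a family column plus at least one species column",
                "ssd_schema_error")
    }
    return(validate_counts_df(df))
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    ssd_error(
      sprintf("schema '%s' requires columns {%s}; missing {%s}; found {%s}",
              schema, paste(required, collapse = ", "),
              paste(missing, collapse = ", "),
              paste(names(df), collapse = ", ")),
      "ssd_schema_error"
    )
  }
  switch(schema,
    traits = validate_traits_df(df),
    expression = validate_expression_df(df),
    go_map = ,
    membership = {
      for (col in required) df[[col]] <- as.character(df[[col]])
      df
    }
  )
}

validate_counts_df <- function(df) {
  fam <- as.character(df[[1]])
  if (anyDuplicated(fam)) {
    ssd_error("duplicate family identifiers in counts table", "ssd_schema_error")
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(apply(mat, 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(mat), dimnames = dimnames(mat))
  bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(df) > 0 && length(bad) > 0) {
    ssd_error(sprintf("non-numeric count at row %d, column '%s'",
                      bad[1, 1], colnames(mat)[bad[1, 2]]), "ssd_validation_error")
  }
  if (anyNA(num)) {
    ssd_error("missing values in counts table", "ssd_validation_error")
  }
  neg <- which(num < 0, arr.ind = TRUE)
  if (length(neg) > 0) {
    ssd_error(sprintf("negative count at row %d, column '%s'",
                      neg[1, 1], colnames(mat)[neg[1, 2]]), "ssd_validation_error")
  }
  if (any(num != floor(num))) {
    ssd_error("counts must be integers", "ssd_validation_error")
  }
  out <- matrix(as.integer(num), nrow = nrow(num),
                dimnames = list(fam, normalize_species(colnames(num))))
  out
}

validate_traits_df <- function(df) {
  df$species <- normalize_species(df$species)
  if (anyDuplicated(df$species)) {
    ssd_error("duplicate species in traits table", "ssd_schema_error")
  }
  numeric_cols <- intersect(c("male_mass", "female_mass", "brain_mass"), names(df))
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad) > 0) {
      ssd_error(sprintf("non-numeric mass in column '%s' at row %d", col, bad[1]),
                "ssd_validation_error")
    }
    df[[col]] <- vals
  }
  for (col in c("male_mass", "female_mass")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad) > 0) {
      ssd_error(sprintf("nonpositive mass in column '%s' at row %d", col, bad[1]),
                "ssd_validation_error")
    }
  }
  df
}

validate_expression_df <- function(df) {
  df$gene <- as.character(df$gene)
  df$tissue <- as.character(df$tissue)
  df$stage <- as.character(df$stage)
  df$sex <- as.character(df$sex)
  vals <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(vals) & !is.na(df$value))
  if (length(bad) > 0) {
    ssd_error(sprintf("non-numeric expression value at row %d", bad[1]),
              "ssd_validation_error")
  }
  df$value <- vals
  if (any(df$value < 0, na.rm = TRUE)) {
    ssd_error("expression values must be nonnegative", "ssd_validation_error")
  }
  df
}

#' Write a result table as TSV
#'
#' Numeric columns are rounded to 6 significant digits so that re-reading
#' reproduces values to that precision and identical runs produce
#' byte-identical files.
#'
#' @param table A nonempty data frame or matrix (matrices gain a leading
#'   `family` column from their row names).
#' @param path Output file path.
#' @return `invisible(path)`.
#' @export
write_results <- function(table, path) {
  if (is.matrix(table)) {
    table <- data.frame(family = rownames(table) %||% seq_len(nrow(table)),
                        table, check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(table) || nrow(table) == 0) {
    ssd_error("refusing to write an empty result table", "ssd_io_error")
  }
  out <- table
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- signif(out[[col]], 6)
  }
  ok <- tryCatch({
    utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    ssd_error(sprintf("could not write %s: %s", path, conditionMessage(ok)),
              "ssd_io_error")
  }
  invisible(path)
}
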