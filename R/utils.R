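#' @importFrom stats phyper p.adjust rgeom runif setNames
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read a tab-separated evidence table
#'
#' All pipeline inputs are UTF-8 TSV files with a mandatory header row;
#' lines starting with `#` are ignored. Fields are read as character and
#' converted by the caller, so malformed numeric cells can be reported
#' with their line numbers.
#'
#' @param path Path to the TSV file.
#' @param required Character vector of column names that must be present.
#' @param what Human-readable table name used in error messages.
#' @return A data.frame of character columns.
#' @keywords internal
read_evidence_tsv <- function(path, required, what = "table") {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "", na.strings = NULL)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing mandatory column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

# Parse a character column to numeric, reporting 1-based data row numbers
# of unparseable cells.
parse_numeric_col <- function(x, col, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("%s: unparseable %s at data row(s) %s",
                 what, col, paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}

#' Evidence channel vocabulary
#'
#' The closed set of evidence classes a gene-disease association can carry:
#' monogenic phenotype annotation, coding GWAS variant, eQTL regulation,
#' differential expression, text mining, and drug target.
#'
#' @return Character vector of the six channel labels.
#' @export
evidence_channels <- function() {
  c("monogenic", "coding_gwas", "eqtl", "diff_expr", "text_mining",
    "drug_target")
}

assert_channels <- function(x) {
  bad <- setdiff(x, evidence_channels())
  if (length(bad)) {
    stop("unknown evidence channel(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Normalize gene identifiers into one declared namespace
#'
#' One gene namespace is declared per run: `"symbol"` (case-insensitive,
#' upper-cased on normalization) or `"numeric"` (stable numeric IDs kept
#' verbatim). Mixing the two in one vector is refused rather than silently
#' merged, because sources that disagree on the namespace cannot be
#' reconciled by guessing. An optional alias table (alias -> canonical)
#' is applied before the namespace check.
#'
#' @param genes Character vector of gene identifiers.
#' @param namespace Either `"symbol"` or `"numeric"`.
#' @param alias Optional named character vector mapping alias to canonical id.
#' @return Character vector of normalized identifiers.
#' @export
normalize_genes <- function(genes, namespace = c("symbol", "numeric"),
                            alias = NULL) {
  namespace <- match.arg(namespace)
  genes <- as.character(genes)
  if (!is.null(alias) && length(alias)) {
    hit <- genes %in% names(alias)
    genes[hit] <- unname(alias[genes[hit]])
  }
  numeric_like <- grepl("^[0-9]+$", genes)
  if (namespace == "symbol") {
    if (any(numeric_like)) {
      stop("gene id(s) look numeric under the 'symbol' namespace: ",
           paste(utils::head(genes[numeric_like], 5), collapse = ", "),
           call. = FALSE)
    }
    genes <- toupper(genes)
  } else {
    if (any(!numeric_like)) {
      stop("non-numeric gene id(s) under the 'numeric' namespace: ",
           paste(utils::head(genes[!numeric_like], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  genes
}

#' Read a gene alias table
#'
#' Two-column TSV (alias, canonical) used to harmonize gene identifiers
#' before assembly.
#'
#' @param path Path to the alias TSV.
#' @return Named character vector mapping alias to canonical identifier.
#' @export
read_alias_table <- function(path) {
  df <- read_evidence_tsv(path, c("alias", "canonical"), "alias table")
  setNames(df$canonical, df$alias)
}

# Deterministic C-locale string ordering.
order_c <- function(...) order(..., method = "radix")

sort_c <- function(x) {
  if (!length(x)) return(character(0))
  sort(x, method = "radix")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
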