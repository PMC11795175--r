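#' Construct a ranked gene signature
#'
#' A gene signature is a named, species-tagged list of genes carrying signed
#' effect scores (log2 fold changes, or meta-analysis S-values used in place
#' of fold changes) and optionally per-gene p-values. Entries are ranked by
#' absolute score, descending; equal absolute scores are ordered by symbol so
#' the ranking is deterministic. Downstream overlap scans only evaluate
#' cutoffs at tie-group boundaries, so this tie order never affects a p-value.
#'
#' Symbols are case-normalized (upper case) and must be unique after
#' normalization: duplicates are collapsed to the entry with the largest
#' absolute score, with a warning. Zero or non-finite scores are rejected --
#' every signature member must have a defined direction, \code{sign(score)}.
#'
#' @param symbols character vector of gene identifiers.
#' @param scores numeric vector of signed scores, same length as
#'   \code{symbols}; zero or non-finite values are an error.
#' @param p_values optional numeric vector of per-gene p-values in (0, 1].
#' @param name signature name.
#' @param species free-text species tag (e.g. \code{"mouse"}).
#' @return An object of class \code{gene_signature}: a list with elements
#'   \code{name}, \code{species} and \code{entries}, a data frame with columns
#'   \code{symbol}, \code{score}, \code{p_value}, ordered by decreasing
#'   \code{abs(score)}.
#' @examples
#' sig <- gene_signature(c("Bdnf", "Gfap", "Fos"), c(1.2, -0.5, 2.0))
#' sig$entries$symbol  # FOS, BDNF, GFAP
#' @export
gene_signature <- function(symbols, scores, p_values = NULL,
                           name = "signature", species = "unknown") {
  symbols <- trimws(as.character(symbols))
  scores <- as.numeric(scores)
  if (length(symbols) != length(scores))
    stop("`symbols` and `scores` must have equal length")
  if (any(!nzchar(symbols)))
    stop("empty gene symbols are not allowed")
  bad <- !is.finite(scores) | scores == 0
  if (any(bad))
    stop(sum(bad), " entries have zero or non-finite scores; ",
         "signature members must have a nonzero direction")
  if (is.null(p_values)) p_values <- rep(NA_real_, length(symbols))
  if (length(p_values) != length(symbols))
    stop("`p_values` must match `symbols` in length")
  if (any(!is.na(p_values) & (p_values <= 0 | p_values > 1)))
    stop("p-values must lie in (0, 1]")

  entries <- data.frame(symbol = toupper(symbols), score = scores,
                        p_value = p_values, stringsAsFactors = FALSE)
  entries <- dedup_max_abs(entries, warn = TRUE)
  entries <- entries[order(-abs(entries$score), entries$symbol), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(name = name, species = species, entries = entries),
            class = "gene_signature")
}

# Collapse duplicate symbols keeping the largest |score|; deterministic:
# within a duplicate group the max-|score| entry is unique by construction of
# the tie-break (first in |score| desc, symbol order after stable sort).
dedup_max_abs <- function(entries, warn = FALSE) {
  if (!anyDuplicated(entries$symbol)) return(entries)
  ndup <- sum(duplicated(entries$symbol))
  entries <- entries[order(entries$symbol, -abs(entries$score)), , drop = FALSE]
  entries <- entries[!duplicated(entries$symbol), , drop = FALSE]
  if (warn)
    warning(ndup, " duplicate symbol(s) collapsed, keeping largest |score|")
  entries
}

#' @export
print.gene_signature <- function(x, ...) {
  up <- sum(x$entries$score > 0)
  cat("Gene signature '", x$name, "' (", x$species, "): ",
      nrow(x$entries), " genes (", up, " up, ",
      nrow(x$entries) - up, " down)\n", sep = "")
  print(utils::head(x$entries, 5))
  if (nrow(x$entries) > 5) cat("... and", nrow(x$entries) - 5, "more\n")
  invisible(x)
}

#' Up- and down-regulated symbol sets of a signature
#'
#' @param sig a \code{gene_signature}.
#' @return list with character vectors \code{up} (score > 0) and \code{down}
#'   (score < 0); the two partition the signature exactly.
#' @export
signature_directions <- function(sig) {
  stopifnot(inherits(sig, "gene_signature"))
  list(up = sig$entries$symbol[sig$entries$score > 0],
       down = sig$entries$symbol[sig$entries$score < 0])
}

#' Read a DEG table into a gene signature
#'
#' Reads a tab-separated table with a header containing a \code{gene} column
#' and a score column named \code{log2fc} or \code{score}; a \code{p_value}
#' column is optional. Rows with zero or non-finite scores are dropped with a
#' message; duplicate symbols keep the largest absolute score.
#'
#' When \code{score_column_is_log2 = FALSE} the score column holds linear fold
#' changes and is converted to log2: positive values \code{fc} become
#' \code{log2(fc)}; negative values follow the signed fold-change convention
#' common in differential-expression exports, \code{-1.5} meaning 1.5-fold
#' down, and become \code{-log2(-fc)} (values in (-1, 0) are rejected as
#' ambiguous).
#'
#' @param path file path.
#' @param score_column_is_log2 logical; if \code{FALSE}, convert linear fold
#'   changes to log2 (see Details).
#' @param name,species passed to \code{\link{gene_signature}}; \code{name}
#'   defaults to the file name.
#' @return a \code{gene_signature}.
#' @export
read_deg_table <- function(path, score_column_is_log2 = TRUE,
                           name = NULL, species = "unknown") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0) stop("empty DEG table: ", path)
  cols <- tolower(names(tab))
  gcol <- match("gene", cols)
  scol <- match("log2fc", cols)
  if (is.na(scol)) scol <- match("score", cols)
  if (is.na(gcol) || is.na(scol))
    stop("DEG table must have columns `gene` and `log2fc` (or `score`): ", path)
  pcol <- match("p_value", cols)

  sc <- as.numeric(tab[[scol]])
  if (!score_column_is_log2) {
    neg <- !is.na(sc) & sc < 0
    amb <- neg & sc > -1
    if (any(amb)) {
      message(sum(amb), " row(s) with ambiguous linear fold change in (-1, 0) dropped")
      sc[amb] <- NA_real_
    }
    neg <- !is.na(sc) & sc < 0
    sc[neg] <- -log2(-sc[neg])
    sc[!neg] <- log2(sc[!neg])
  }
  keep <- is.finite(sc) & sc != 0 & nzchar(trimws(as.character(tab[[gcol]])))
  if (any(!keep))
    message(sum(!keep), " row(s) with zero/non-finite scores or blank symbols dropped")
  if (!any(keep)) stop("no usable rows in DEG table: ", path)
  pv <- if (is.na(pcol)) NULL else as.numeric(tab[[pcol]])[keep]
  gene_signature(tab[[gcol]][keep], sc[keep], p_values = pv,
                 name = if (is.null(name)) basename(path) else name,
                 species = species)
}

#' Write a gene signature as a DEG table
#'
#' Writes the TSV dialect read by \code{\link{read_deg_table}} (columns
#' \code{gene}, \code{log2fc}, \code{p_value}), with scores at full double
#' precision so a read/write round trip is exact.
#'
#' @param sig a \code{gene_signature}.
#' @param path output file path.
#' @export
write_deg_table <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  e <- sig$entries
  lines <- c("gene\tlog2fc\tp_value",
             sprintf("%s\t%.17g\t%s", e$symbol, e$score,
                     ifelse(is.na(e$p_value), "NA", sprintf("%.17g", e$p_value))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' \code{name}, \code{description}, then member gene symbols. Symbols are
#' case-normalized; sets left empty are dropped with a warning; duplicate set
#' names or lines with fewer than three fields are an error.
#'
#' @param path GMT file path.
#' @return An object of class \code{gene_set_collection}: list with
#'   \code{sets} (named list of character vectors), \code{descriptions} and
#'   \code{provenance}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields: ", path)
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s) in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(toupper(trimws(f[-(1:2)]))))
  sets <- lapply(sets, function(s) s[nzchar(s)])
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sum(empty), " empty gene set(s) dropped from GMT")
    sets <- sets[!empty]; nm <- nm[!empty]; desc <- desc[!empty]
  }
  names(sets) <- nm
  structure(list(sets = sets, descriptions = stats::setNames(desc, nm),
                 provenance = path),
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param collection a \code{gene_set_collection}.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  nm <- names(collection$sets)
  desc <- collection$descriptions[nm]
  desc[is.na(desc)] <- "na"
  lines <- vapply(seq_along(nm), function(i)
    paste(c(nm[i], desc[i], collection$sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column ortholog map
#'
#' TSV with header columns \code{source_gene}, \code{target_gene}. The map
#' must be functional: a source symbol mapping to two distinct targets is an
#' error.
#'
#' @param path file path.
#' @return named character vector (names = source, values = target), both
#'   case-normalized.
#' @export
read_ortholog_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source_gene", "target_gene")
  if (!all(need %in% tolower(names(tab))))
    stop("ortholog map must have columns `source_gene`, `target_gene`")
  names(tab) <- tolower(names(tab))
  src <- toupper(trimws(tab$source_gene))
  tgt <- toupper(trimws(tab$target_gene))
  keep <- !duplicated(paste(src, tgt))
  src <- src[keep]; tgt <- tgt[keep]
  if (anyDuplicated(src))
    stop("ortholog map is not functional: source symbol(s) with multiple targets: ",
         paste(unique(src[duplicated(src)]), collapse = ", "))
  stats::setNames(tgt, src)
}

#' Harmonize signature symbols across species
#'
#' With \code{map = NULL}, symbols are upper-cased (the symbol-identity
#' ortholog proxy: mouse "Fos" and human "FOS" coincide). With a named map,
#' symbols are translated and unmapped entries dropped. Duplicates produced
#' by either route are collapsed to the largest absolute score. Drop and
#' merge counts are reported via a message and attached as attributes
#' \code{n_dropped} and \code{n_merged}.
#'
#' @param sig a \code{gene_signature}.
#' @param map optional named character vector as returned by
#'   \code{\link{read_ortholog_map}}.
#' @return a harmonized \code{gene_signature}.
#' @export
harmonize <- function(sig, map = NULL) {
  stopifnot(inherits(sig, "gene_signature"))
  e <- sig$entries
  n_dropped <- 0L
  if (!is.null(map)) {
    tgt <- unname(map[e$symbol])
    drop <- is.na(tgt)
    n_dropped <- sum(drop)
    e <- e[!drop, , drop = FALSE]
    e$symbol <- tgt[!drop]
    if (nrow(e) == 0) stop("no symbols of '", sig$name, "' are covered by the map")
  }
  n_before <- nrow(e)
  e <- dedup_max_abs(e)
  n_merged <- n_before - nrow(e)
  if (n_dropped > 0 || n_merged > 0)
    message("harmonize('", sig$name, "'): dropped ", n_dropped,
            " unmapped, merged ", n_merged, " duplicate entries")
  out <- gene_signature(e$symbol, e$score, e$p_value,
                        name = sig$name, species = sig$species)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_merged") <- n_merged
  out
}

#' Build the background gene universe
#'
#' The universe is the denominator population of every hypergeometric overlap
#' and enrichment test. It is a required, explicit choice: either the
#' intersection (default: genes assayed on every platform) or the union of
#' the supplied symbol collections.
#'
#' @param ... one or more character vectors of symbols, or
#'   \code{gene_signature} objects, or a single list of such.
#' @param mode \code{"intersection"} (default) or \code{"union"}.
#' @return object of class \code{gene_universe}: list with sorted
#'   case-normalized \code{symbols} and integer \code{size}.
#' @export
build_universe <- function(..., mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) &&
      !inherits(args[[1]], "gene_signature"))
    args <- args[[1]]
  if (length(args) == 0) stop("at least one symbol collection is required")
  lists <- lapply(args, function(a) {
    if (inherits(a, "gene_signature")) a$entries$symbol
    else unique(toupper(trimws(as.character(a))))
  })
  if (any(lengths(lists) == 0)) stop("empty symbol collection supplied")
  syms <- Reduce(if (mode == "intersection") intersect else union, lists)
  if (length(syms) == 0)
    stop("universe is empty under intersection; consider mode = \"union\"")
  structure(list(symbols = sort(syms), size = length(syms)),
            class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat("Gene universe of", x$size, "symbols\n")
  invisible(x)
}

# TRUE when all signature symbols lie in the universe.
universe_covers <- function(universe, sig) {
  all(sig$entries$symbol %in% universe$symbols)
}
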