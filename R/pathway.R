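#' Overlap gene set between a dataset and a reference signature
#'
#' Direction-agnostic intersection of the two signatures' symbol sets: the
#' genes a dataset shares with a reference signature, the unit fed into
#' pathway enrichment.
#'
#' @param dataset,reference \code{gene_signature} objects (harmonized).
#' @return sorted character vector of shared symbols.
#' @export
overlap_gene_set <- function(dataset, reference) {
  stopifnot(inherits(dataset, "gene_signature"),
            inherits(reference, "gene_signature"))
  sort(intersect(dataset$entries$symbol, reference$entries$symbol))
}

#' Hypergeometric enrichment of a gene set against a GMT collection
#'
#' One fixed-set hypergeometric upper-tail test per term (no internal rank
#' structure remains in an intersected overlap set, so no running scan is
#' used here). Terms are intersected with the universe before testing and
#' \code{term_size} is the post-intersection size. P-values are reported raw:
#' downstream meta-analysis is ranking-based, so no multiple-testing
#' correction is applied.
#'
#' @param query character vector of symbols (must lie within the universe).
#' @param collection a \code{gene_set_collection}.
#' @param universe a \code{gene_universe}.
#' @param dataset optional dataset label recorded in the output rows.
#' @return data frame with one row per term: \code{dataset}, \code{term},
#'   \code{overlap}, \code{term_size}, \code{query_size}, \code{universe_n},
#'   \code{p}.
#' @export
enrich <- function(query, collection, universe, dataset = NA_character_) {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(universe, "gene_universe"))
  query <- unique(toupper(trimws(as.character(query))))
  if (!all(query %in% universe$symbols))
    stop("query contains symbols outside the universe")
  if (length(query) == 0)
    warning("empty query gene set; all enrichment p-values are 1")
  rows <- lapply(names(collection$sets), function(term) {
    tset <- intersect(collection$sets[[term]], universe$symbols)
    ov <- length(intersect(query, tset))
    p <- if (length(query) == 0 || length(tset) == 0) 1
    else hypergeom_upper_tail(universe$size, length(tset), length(query), ov)
    data.frame(dataset = dataset, term = term, overlap = ov,
               term_size = length(tset), query_size = length(query),
               universe_n = universe$size, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Meta-analyze enrichment across datasets
#'
#' Aggregates per-dataset enrichment rows into one score per term:
#' \code{meta_score = sum(-log10 p)} over the datasets in which the term was
#' tested (rank-equivalent to Fisher's combined statistic when every term is
#' tested in every dataset). Terms are ranked by descending meta-score, ties
#' broken lexicographically by term name; ranks are dense and 1-based. The
#' table is truncated to the top \code{top_k} terms.
#'
#' @param rows enrichment rows as returned by \code{\link{enrich}} (rbind
#'   rows from several datasets, each with its \code{dataset} label).
#' @param top_k number of top terms to keep (default 15).
#' @return data frame of class \code{meta_enrichment_table}: \code{term},
#'   \code{meta_score}, \code{n_datasets_tested}, \code{rank}.
#' @export
meta_rank <- function(rows, top_k = 15) {
  if (!is.data.frame(rows) || !all(c("term", "p") %in% names(rows)))
    stop("`rows` must be enrichment rows with columns term and p")
  if (!(is.numeric(top_k) && top_k >= 1)) stop("`top_k` must be >= 1")
  sc <- stats::aggregate(list(meta_score = -log10(rows$p)),
                         by = list(term = rows$term), FUN = sum)
  nd <- stats::aggregate(list(n_datasets_tested = rows$p),
                         by = list(term = rows$term), FUN = length)
  out <- merge(sc, nd, by = "term")
  out <- out[order(-out$meta_score, out$term), , drop = FALSE]
  # dense 1-based rank: equal meta-scores share a rank
  out$rank <- cumsum(!duplicated(out$meta_score))
  out <- utils::head(out, min(as.integer(top_k), nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("meta_enrichment_table", "data.frame")
  out
}
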