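#' Hypergeometric upper-tail probability
#'
#' P(X >= x) for X ~ Hypergeometric(N, K, n): the chance of drawing at least
#' \code{x} members of a reference set of size \code{K} in \code{n} draws
#' without replacement from a universe of \code{N} genes. This is the
#' one-sided Fisher exact overlap test at a fixed cutoff. Vectorised over
#' \code{n} and \code{x}.
#'
#' @param N universe size.
#' @param K reference-set size (0 <= K <= N).
#' @param n draw (query) size, vectorised.
#' @param x observed overlap, vectorised.
#' @return exact tail probabilities in (0, 1].
#' @examples
#' hypergeom_upper_tail(10, 5, 4, 4)  # 5/210
#' @export
hypergeom_upper_tail <- function(N, K, n, x) {
  if (length(N) != 1 || length(K) != 1)
    stop("`N` and `K` must be scalars")
  if (N < 1 || K < 0 || K > N) stop("need 0 <= K <= N, N >= 1")
  if (any(n < 0) || any(n > N)) stop("need 0 <= n <= N")
  if (any(x < 0) || any(x > pmin(K, n)) || any(x < pmax(0, K + n - N)))
    stop("overlap x outside hypergeometric support")
  p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  pmin(1, pmax(p, .Machine$double.xmin))
}

#' Running hypergeometric overlap scan
#'
#' The core of the running Fisher statistic. The query side enters as a gene
#' list ranked by absolute score (strongest fold changes first); the
#' reference side as a fixed gene set. At every rank cutoff \code{k} the scan
#' computes the hypergeometric upper-tail p of the overlap between the top-k
#' query genes and the reference set; the minimum over cutoffs is then
#' Bonferroni-corrected by the number of cutoffs evaluated. Cutoffs are only
#' placed at tie-group boundaries (all genes of equal absolute score enter
#' together), so the lexicographic tie order inside a group can never change
#' a p-value.
#'
#' @param ranked_symbols character vector of query symbols, ranked by
#'   decreasing absolute score.
#' @param abs_scores absolute scores aligned with \code{ranked_symbols},
#'   non-increasing; used only to locate tie-group boundaries.
#' @param reference_set character vector of reference symbols.
#' @param universe_n universe size.
#' @return list with \code{p_raw} (minimum scan p), \code{p_corrected}
#'   (\code{min(1, p_raw * n_cutoffs)}), \code{k_best} (smallest cutoff
#'   attaining the minimum), \code{n_cutoffs}. Degenerate inputs (empty query
#'   or reference) give p = 1 and \code{k_best = 0}.
#' @export
running_scan <- function(ranked_symbols, abs_scores, reference_set,
                         universe_n) {
  m <- length(ranked_symbols)
  K <- length(reference_set)
  if (m == 0 || K == 0)
    return(list(p_raw = 1, p_corrected = 1, k_best = 0L, n_cutoffs = 0L))
  if (length(abs_scores) != m)
    stop("`abs_scores` must align with `ranked_symbols`")
  if (is.unsorted(rev(abs_scores)))
    stop("`abs_scores` must be non-increasing (rank by |score| first)")
  if (m > universe_n || K > universe_n)
    stop("query or reference larger than the universe")
  # last index of each tie group = cutoff positions; the full list is always
  # the final boundary
  ks <- if (m == 1) 1L else c(which(abs_scores[-m] != abs_scores[-1]), m)
  hits <- cumsum(ranked_symbols %in% reference_set)
  ps <- hypergeom_upper_tail(universe_n, K, ks, hits[ks])
  i <- which.min(ps)  # first minimum -> smallest k
  list(p_raw = ps[i],
       p_corrected = min(1, ps[i] * length(ks)),
       k_best = as.integer(ks[i]),
       n_cutoffs = length(ks))
}

#' Directional four-way partition of a signature overlap
#'
#' Splits the intersection of two signatures by direction pair: up-up and
#' down-down (concordant), up-down and down-up (discordant; first label is
#' the query side). The four sets are pairwise disjoint and union to the
#' full intersection, since every signature member has a nonzero direction.
#'
#' @param query,reference \code{gene_signature} objects with harmonized
#'   symbols.
#' @return named list of character vectors \code{up_up}, \code{down_down},
#'   \code{up_down}, \code{down_up}.
#' @export
directional_partition <- function(query, reference) {
  qd <- signature_directions(query)
  rd <- signature_directions(reference)
  list(up_up = intersect(qd$up, rd$up),
       down_down = intersect(qd$down, rd$down),
       up_down = intersect(qd$up, rd$down),
       down_up = intersect(qd$down, rd$up))
}

# Run one directional scan: query entries restricted to those with the given
# sign, reference restricted to its direction set.
scan_direction <- function(query, ref_set, sign_q, universe_n) {
  e <- query$entries
  sel <- if (sign_q > 0) e$score > 0 else e$score < 0
  running_scan(e$symbol[sel], abs(e$score[sel]), ref_set, universe_n)
}

#' Rank-based overlap test between two gene signatures
#'
#' The full running Fisher comparison: four directional sub-tests (up-up,
#' down-down, up-down, down-up), each a running hypergeometric scan of the
#' query-side ranking against the reference-side direction set, plus one
#' unsigned scan (full query ranking against the full reference set) that
#' yields the overall overlap p-value. Concordant and discordant evidence are
#' summarised as sums of -log10 corrected directional p-values, and the
#' dominant direction is whichever sum is larger (ties fall to positive with
#' a warning).
#'
#' @param query a \code{gene_signature} (typically a DEG list), ranked by
#'   absolute fold change.
#' @param reference a \code{gene_signature} (a reference gene set with
#'   directions).
#' @param universe a \code{gene_universe} covering both signatures.
#' @return object of class \code{overlap_result}: list with \code{query},
#'   \code{reference}, \code{universe_n}, \code{total_shared},
#'   \code{directional} (per direction pair: overlap gene set, counts,
#'   \code{p_raw}, \code{p_corrected}, \code{k_best}, \code{n_cutoffs}),
#'   \code{overall_p}, \code{concordant_score}, \code{discordant_score},
#'   \code{dominant} (\code{"positive"} or \code{"negative"}).
#' @export
signature_overlap <- function(query, reference, universe) {
  stopifnot(inherits(query, "gene_signature"),
            inherits(reference, "gene_signature"),
            inherits(universe, "gene_universe"))
  if (!universe_covers(universe, query))
    stop("query signature has symbols outside the universe")
  if (!universe_covers(universe, reference))
    stop("reference signature has symbols outside the universe")

  rd <- signature_directions(reference)
  parts <- directional_partition(query, reference)
  scans <- list(
    up_up = scan_direction(query, rd$up, +1, universe$size),
    down_down = scan_direction(query, rd$down, -1, universe$size),
    up_down = scan_direction(query, rd$down, +1, universe$size),
    down_up = scan_direction(query, rd$up, -1, universe$size))
  directional <- lapply(names(scans), function(pr) {
    c(list(pair = pr, overlap_genes = parts[[pr]],
           overlap_count = length(parts[[pr]])), scans[[pr]])
  })
  names(directional) <- names(scans)

  overall <- running_scan(query$entries$symbol, abs(query$entries$score),
                          reference$entries$symbol, universe$size)
  conc <- -log10(scans$up_up$p_corrected) - log10(scans$down_down$p_corrected)
  disc <- -log10(scans$up_down$p_corrected) - log10(scans$down_up$p_corrected)
  if (conc == disc && conc > 0)
    warning("concordant and discordant scores tie; dominant set to positive")
  structure(list(query = query$name, reference = reference$name,
                 universe_n = universe$size,
                 total_shared = sum(lengths(parts)),
                 directional = directional,
                 overall_p = overall$p_corrected,
                 overall_scan = overall,
                 concordant_score = conc, discordant_score = disc,
                 dominant = if (conc >= disc) "positive" else "negative"),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Signature overlap:", x$query, "vs", x$reference,
      "(universe", x$universe_n, ")\n")
  cat("  shared genes:", x$total_shared, " overall p:",
      format(x$overall_p, digits = 3), " dominant:", x$dominant, "\n")
  for (d in x$directional)
    cat(sprintf("  %-9s n=%4d  p_corrected=%s\n", d$pair, d$overlap_count,
                format(d$p_corrected, digits = 3)))
  invisible(x)
}

#' Summarise overlap results as a table
#'
#' @param results a single \code{overlap_result} or a list of them.
#' @return data frame with one row per comparison: query, reference,
#'   total_shared, the four directional counts and corrected p-values,
#'   overall_p and dominant direction.
#' @export
overlap_summary <- function(results) {
  if (inherits(results, "overlap_result")) results <- list(results)
  do.call(rbind, lapply(results, function(x) {
    d <- x$directional
    data.frame(query = x$query, reference = x$reference,
               universe_n = x$universe_n, total_shared = x$total_shared,
               n_up_up = d$up_up$overlap_count,
               n_down_down = d$down_down$overlap_count,
               n_up_down = d$up_down$overlap_count,
               n_down_up = d$down_up$overlap_count,
               p_up_up = d$up_up$p_corrected,
               p_down_down = d$down_down$p_corrected,
               p_up_down = d$up_down$p_corrected,
               p_down_up = d$down_up$p_corrected,
               overall_p = x$overall_p, dominant = x$dominant,
               stringsAsFactors = FALSE)
  }))
}

#' Write an overlap result as JSON
#'
#' One JSON document per comparison, including the four directional gene
#' lists and scan details.
#'
#' @param result an \code{overlap_result}.
#' @param path output path.
#' @export
write_overlap_json <- function(result, path) {
  stopifnot(inherits(result, "overlap_result"))
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
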