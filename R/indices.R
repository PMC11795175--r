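#' Make three reference signatures pairwise disjoint
#'
#' Cross-dataset correlations of the three similarity indices are only
#' interpretable when the underlying reference gene sets share no genes, so
#' any gene appearing in two or more of the maturity, pH, and hyperexcitation
#' signatures is removed from all of them. Removal counts per pairwise
#' overlap are reported and attached as attribute \code{removed}.
#'
#' @param maturity,ph,hyper \code{gene_signature} objects with harmonized
#'   symbols.
#' @return named list of three disjoint \code{gene_signature}s
#'   (\code{maturity}, \code{ph}, \code{hyperexcitation}); error if any would
#'   be emptied.
#' @export
disjointify <- function(maturity, ph, hyper) {
  sigs <- list(maturity = maturity, ph = ph, hyperexcitation = hyper)
  stopifnot(all(vapply(sigs, inherits, TRUE, "gene_signature")))
  syms <- lapply(sigs, function(s) s$entries$symbol)
  shared <- unique(unlist(lapply(utils::combn(3, 2, simplify = FALSE),
                                 function(ij) intersect(syms[[ij[1]]],
                                                        syms[[ij[2]]]))))
  removed <- c(maturity_ph = length(intersect(syms[[1]], syms[[2]])),
               maturity_hyperexcitation = length(intersect(syms[[1]], syms[[3]])),
               ph_hyperexcitation = length(intersect(syms[[2]], syms[[3]])))
  out <- lapply(sigs, function(s) {
    e <- s$entries[!(s$entries$symbol %in% shared), , drop = FALSE]
    if (nrow(e) == 0)
      stop("disjointify would empty signature '", s$name, "'")
    gene_signature(e$symbol, e$score, e$p_value, name = s$name,
                   species = s$species)
  })
  if (length(shared))
    message("disjointify: removed ", length(shared),
            " gene(s) shared between reference signatures")
  attr(out, "removed") <- removed
  out
}

#' Signed similarity index from an overlap result
#'
#' The similarity index is the negative base-10 logarithm of the overall
#' overlap p-value, signed by the dominant correlation direction: positive
#' when concordant (same-direction) overlap dominates, negative when
#' discordant overlap dominates (e.g. an immature or acidified expression
#' profile). An overall p of 1 gives index 0 regardless of dominance.
#'
#' @param x an \code{overlap_result}, or a numeric overall p-value in (0, 1].
#' @param dominant when \code{x} is numeric: \code{"positive"} or
#'   \code{"negative"}.
#' @param reference optional label for which reference signature the index
#'   measures (\code{"maturity"}, \code{"ph"}, \code{"hyperexcitation"}).
#' @return object of class \code{similarity_index}: list with \code{value}
#'   (signed -log10 p), \code{reference}, \code{source_p}, \code{dominant}.
#' @examples
#' similarity_index(9.7e-9, dominant = "negative")$value  # -8.0132...
#' @export
similarity_index <- function(x, dominant = NULL, reference = NA_character_) {
  if (inherits(x, "overlap_result")) {
    p <- x$overall_p
    dominant <- x$dominant
    if (is.na(reference)) reference <- x$reference
  } else {
    p <- as.numeric(x)
    if (is.null(dominant) || !dominant %in% c("positive", "negative"))
      stop("`dominant` must be \"positive\" or \"negative\"")
  }
  if (!(length(p) == 1 && is.finite(p) && p > 0 && p <= 1))
    stop("overall p must lie in (0, 1]")
  value <- if (p == 1) 0 else (if (dominant == "positive") 1 else -1) * -log10(p)
  structure(list(value = value, reference = reference, source_p = p,
                 dominant = dominant),
            class = "similarity_index")
}

#' @export
print.similarity_index <- function(x, ...) {
  cat("Similarity index", if (!is.na(x$reference)) paste0("(", x$reference, ")"),
      "=", format(x$value, digits = 4),
      " [p =", format(x$source_p, digits = 3), ",", x$dominant, "]\n")
  invisible(x)
}

#' Build the per-dataset index table
#'
#' Runs the overlap test of every dataset signature against each of the
#' three (disjointified) reference signatures and transforms the overall
#' p-values to signed similarity indices. Datasets on which any comparison
#' fails are kept as rows but flagged incomplete; incomplete rows are
#' excluded from correlations.
#'
#' @param datasets named list of \code{gene_signature} DEG lists.
#' @param references list with elements \code{maturity}, \code{ph},
#'   \code{hyperexcitation} (as from \code{\link{disjointify}}).
#' @param universe a \code{gene_universe} covering datasets and references.
#' @return data frame of class \code{index_table}: columns \code{dataset},
#'   \code{maturity_index}, \code{ph_index}, \code{hyperexcitation_index},
#'   \code{complete}.
#' @export
build_index_table <- function(datasets, references, universe) {
  if (length(datasets) == 0) stop("at least one dataset is required")
  if (!all(c("maturity", "ph", "hyperexcitation") %in% names(references)))
    stop("`references` must contain maturity, ph and hyperexcitation")
  if (is.null(names(datasets)))
    names(datasets) <- vapply(datasets, function(d) d$name, "")
  rows <- lapply(names(datasets), function(nm) {
    vals <- vapply(c("maturity", "ph", "hyperexcitation"), function(ref) {
      tryCatch(similarity_index(signature_overlap(datasets[[nm]],
                                                  references[[ref]],
                                                  universe))$value,
               error = function(e) {
                 warning("dataset '", nm, "' vs ", ref, " failed: ",
                         conditionMessage(e))
                 NA_real_
               })
    }, numeric(1))
    data.frame(dataset = nm, maturity_index = vals[["maturity"]],
               ph_index = vals[["ph"]],
               hyperexcitation_index = vals[["hyperexcitation"]],
               complete = !anyNA(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("index_table", "data.frame")
  out
}

#' Correlate two similarity indices across datasets
#'
#' Pearson correlation (two-sided p via the t transform on n - 2 degrees of
#' freedom) and the ordinary least-squares line between two index columns of
#' an index table, using complete rows only. Spearman rank correlation is
#' available as an option (no regression line is reported in that case).
#'
#' @param table an \code{index_table} (or data frame with the index columns).
#' @param pair one of \code{"maturity_ph"}, \code{"maturity_hyperexcitation"},
#'   \code{"ph_hyperexcitation"}, or \code{"all"} (default) for all three.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return data frame with columns \code{pair}, \code{n}, \code{r}, \code{p},
#'   \code{slope}, \code{intercept} (one row per pair).
#' @export
correlate_indices <- function(table,
                              pair = c("all", "maturity_ph",
                                       "maturity_hyperexcitation",
                                       "ph_hyperexcitation"),
                              method = c("pearson", "spearman")) {
  pair <- match.arg(pair)
  method <- match.arg(method)
  cols <- c(maturity = "maturity_index", ph = "ph_index",
            hyperexcitation = "hyperexcitation_index")
  tab <- table[if ("complete" %in% names(table)) table$complete else TRUE, ,
               drop = FALSE]
  pairs <- if (pair == "all")
    c("maturity_ph", "maturity_hyperexcitation", "ph_hyperexcitation")
  else pair
  do.call(rbind, lapply(pairs, function(pr) {
    ab <- strsplit(pr, "_", fixed = TRUE)[[1]]
    x <- tab[[cols[ab[1]]]]; y <- tab[[cols[ab[2]]]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop("need at least 3 complete rows for ", pr)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("zero variance in an index; correlation undefined for ", pr)
    ct <- stats::cor.test(x, y, method = method, exact = FALSE)
    if (method == "pearson") {
      fit <- stats::lm(y ~ x)
      slope <- unname(stats::coef(fit)[2]); icpt <- unname(stats::coef(fit)[1])
    } else slope <- icpt <- NA_real_
    data.frame(pair = pr, n = length(x), r = unname(ct$estimate),
               p = ct$p.value, slope = slope, intercept = icpt,
               stringsAsFactors = FALSE)
  }))
}

#' Scatter plot of two similarity indices
#'
#' Auxiliary base-graphics rendering of one panel of the two-dimensional
#' index analysis, with the least-squares line.
#'
#' @param table an \code{index_table}.
#' @param pair which index pair to plot (as in \code{\link{correlate_indices}}).
#' @param ... passed to \code{plot}.
#' @export
plot_indices <- function(table, pair = "maturity_ph", ...) {
  cols <- c(maturity = "maturity_index", ph = "ph_index",
            hyperexcitation = "hyperexcitation_index")
  ab <- strsplit(pair, "_", fixed = TRUE)[[1]]
  tab <- table[if ("complete" %in% names(table)) table$complete else TRUE, ]
  x <- tab[[cols[ab[1]]]]; y <- tab[[cols[ab[2]]]]
  plot(x, y, xlab = paste(ab[1], "index"), ylab = paste(ab[2], "index"),
       pch = 19, ...)
  graphics::abline(stats::lm(y ~ x), lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey70")
  invisible(NULL)
}
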