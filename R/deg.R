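#' Construct a two-group expression matrix
#'
#' Container for a genes x samples expression matrix with a case/control
#' group label per sample. Values may be on the linear scale (all positive)
#' or already log2-transformed. Both groups need at least two samples and no
#' missing values are allowed.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param genes character vector of gene symbols (row names used if missing).
#' @param groups character vector of per-sample labels, each \code{"case"} or
#'   \code{"control"}.
#' @param scale \code{"linear"} or \code{"log2"}.
#' @return object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, genes = rownames(values), groups,
                              scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(genes)) stop("gene symbols are required")
  genes <- toupper(trimws(as.character(genes)))
  if (length(genes) != nrow(values))
    stop("`genes` must match the number of matrix rows")
  if (anyDuplicated(genes)) stop("duplicate gene symbols in matrix")
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stop("`groups` must match the number of matrix columns")
  if (!all(groups %in% c("case", "control")))
    stop("group labels must be \"case\" or \"control\"")
  if (min(table(factor(groups, c("case", "control")))) < 2)
    stop("each group needs at least 2 samples")
  if (anyNA(values) || any(!is.finite(values)))
    stop("missing or non-finite expression values are not allowed")
  if (scale == "linear" && any(values <= 0))
    stop("linear-scale expression values must be positive")
  rownames(values) <- genes
  structure(list(values = values, genes = genes, groups = groups,
                 scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples (", sum(x$groups == "case"), "case /",
      sum(x$groups == "control"), "control ),", x$scale, "scale\n")
  invisible(x)
}

#' Read an expression matrix with group assignments
#'
#' The matrix TSV has a first column \code{gene} and one column per sample;
#' groups come either from a two-column TSV (\code{sample}, \code{group}) or
#' a character vector aligned with the sample columns.
#'
#' @param path matrix TSV path.
#' @param groups character vector or path to a groups TSV.
#' @param scale \code{"linear"} or \code{"log2"}.
#' @return an \code{expression_matrix}.
#' @export
read_expression_matrix <- function(path, groups, scale = c("linear", "log2")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (tolower(names(tab)[1]) != "gene")
    stop("first column of an expression matrix must be `gene`")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
    g <- utils::read.delim(groups, stringsAsFactors = FALSE)
    names(g) <- tolower(names(g))
    if (!all(c("sample", "group") %in% names(g)))
      stop("groups file must have columns `sample`, `group`")
    groups <- g$group[match(colnames(vals), g$sample)]
    if (anyNA(groups)) stop("groups file does not cover all samples")
  }
  expression_matrix(vals, genes = tab[[1]], groups = groups,
                    scale = match.arg(scale))
}

#' Signed log2 fold change between two groups
#'
#' Linear scale: \code{log2(mean(case) / mean(control))} of the raw values.
#' Log2 scale: difference of group means. Direction is case over control.
#'
#' @param case,control numeric vectors of per-sample values for one gene.
#' @param scale \code{"linear"} or \code{"log2"}.
#' @return signed log2 fold change.
#' @export
fold_change <- function(case, control, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (scale == "linear") {
    mc <- mean(case); mo <- mean(control)
    if (mc <= 0 || mo <= 0)
      stop("non-positive group mean on the linear scale")
    log2(mc / mo)
  } else {
    mean(case) - mean(control)
  }
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Degenerate variance handling: when both sample
#' variances are zero and the means coincide there is no computable evidence
#' and p = 1 is returned with a warning; when both variances are zero but the
#' means differ the separation is unbounded relative to the (zero) noise, so
#' the statistic is signed infinite and p is the smallest positive double --
#' probabilities stay in (0, 1].
#'
#' @param a,b numeric vectors, each of length >= 2 (a = case, b = control).
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  d <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (d == 0) {
      warning("both groups constant and equal; no evidence computable (p = 1)")
      return(list(statistic = 0, df = NA_real_, p_value = 1))
    }
    return(list(statistic = sign(d) * Inf, df = NA_real_,
                p_value = .Machine$double.xmin))
  }
  sa <- va / length(a); sb <- vb / length(b)
  se <- sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  t <- d / se
  list(statistic = t, df = df,
       p_value = min(1, 2 * stats::pt(abs(t), df, lower.tail = FALSE)))
}

# Vectorised row-wise Welch test over a log2-scale matrix. Same degenerate
# rules as welch_t(). Returns list of vectors (t, df, p).
row_welch <- function(logm, case_idx, ctrl_idx) {
  na <- length(case_idx); nb <- length(ctrl_idx)
  A <- logm[, case_idx, drop = FALSE]
  B <- logm[, ctrl_idx, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  d <- ma - mb
  sa <- va / na; sb <- vb / nb
  se <- sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  t <- d / se
  p <- pmin(1, 2 * stats::pt(abs(t), df, lower.tail = FALSE))
  zero <- va == 0 & vb == 0
  if (any(zero)) {
    eq <- zero & d == 0
    t[eq] <- 0; p[eq] <- 1; df[eq] <- NA_real_
    ne <- zero & d != 0
    t[ne] <- sign(d[ne]) * Inf; p[ne] <- .Machine$double.xmin; df[ne] <- NA_real_
  }
  list(statistic = t, df = df, p_value = p)
}

#' Call differentially expressed genes from a two-group matrix
#'
#' A gene is a DEG when its absolute fold change strictly exceeds
#' \code{fc_threshold} (on the linear fold-change scale; default 1.2) and its
#' two-sided Welch t-test p-value is strictly below \code{p_threshold}
#' (default 0.05). No multiple-testing correction is applied: the raw
#' per-gene p is the criterion. The t-test runs on log2-scale values (the
#' matrix is log2-transformed first when it is linear), the standard practice
#' for expression data; the fold change follows \code{\link{fold_change}}.
#'
#' @param mat an \code{expression_matrix}.
#' @param fc_threshold linear fold-change threshold, > 1.
#' @param p_threshold p-value threshold in (0, 1).
#' @param name,species passed to the resulting \code{\link{gene_signature}}.
#' @return a \code{gene_signature} of the DEGs, scores = signed log2 fold
#'   change, with per-gene p-values.
#' @export
call_degs <- function(mat, fc_threshold = 1.2, p_threshold = 0.05,
                      name = "degs", species = "unknown") {
  stopifnot(inherits(mat, "expression_matrix"))
  if (!(is.numeric(fc_threshold) && fc_threshold > 1))
    stop("`fc_threshold` must be > 1")
  if (!(is.numeric(p_threshold) && p_threshold > 0 && p_threshold < 1))
    stop("`p_threshold` must be in (0, 1)")
  case_idx <- which(mat$groups == "case")
  ctrl_idx <- which(mat$groups == "control")
  if (mat$scale == "linear") {
    lfc <- log2(rowMeans(mat$values[, case_idx, drop = FALSE]) /
                rowMeans(mat$values[, ctrl_idx, drop = FALSE]))
    logm <- log2(mat$values)
  } else {
    logm <- mat$values
    lfc <- rowMeans(logm[, case_idx, drop = FALSE]) -
      rowMeans(logm[, ctrl_idx, drop = FALSE])
  }
  tt <- row_welch(logm, case_idx, ctrl_idx)
  keep <- abs(lfc) > log2(fc_threshold) & tt$p_value < p_threshold
  if (!any(keep))
    return(structure(list(name = name, species = species,
                          entries = data.frame(symbol = character(),
                                               score = numeric(),
                                               p_value = numeric())),
                     class = "gene_signature"))
  gene_signature(mat$genes[keep], lfc[keep], p_values = tt$p_value[keep],
                 name = name, species = species)
}
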