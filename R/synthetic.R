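#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data module. The defaults are the
#' study conditions the generator emulates: a gene universe of 5000 symbols;
#' a maturity signature of 800 genes (an infant-vs-adult contrast); a pH
#' signature of exactly 39 up- and 268 down-regulated genes whose S-value-like
#' scores stand in for fold changes; a hyperexcitation signature of 1200
#' genes (a desk-scale stand-in for the published ~7000-gene seizure
#' signature, configurable up to that size); expression matrices with 3 case
#' and 3 control samples, mean planted effect |log2FC| = 1 and log2-scale
#' Gaussian noise with sd 0.25.
#'
#' @param universe_size number of genes in the universe.
#' @param maturity_size,ph_up_size,ph_down_size,hyper_size reference
#'   signature sizes.
#' @param n_case,n_control samples per group.
#' @param effect_log2fc mean planted absolute log2 fold change; per-gene
#'   magnitudes jitter uniformly within 10\% of this mean.
#' @param noise_sd per-sample residual standard deviation on the log2 scale.
#' @param rho_concordant,rho_discordant default planted overlap fractions
#'   (of each reference's size) applied when a dataset does not specify its
#'   own; both in [0, 1] with sum <= 1.
#' @param n_background_degs planted differential genes outside all three
#'   references (off-reference signal).
#' @param seed integer seed; mandatory, all generation is deterministic
#'   given it.
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(universe_size = 5000, maturity_size = 800,
                             ph_up_size = 39, ph_down_size = 268,
                             hyper_size = 1200, n_case = 3, n_control = 3,
                             effect_log2fc = 1.0, noise_sd = 0.25,
                             rho_concordant = 0, rho_discordant = 0,
                             n_background_degs = 100, seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("an integer `seed` is mandatory for synthetic generation")
  cfg <- list(universe_size = as.integer(universe_size),
              maturity_size = as.integer(maturity_size),
              ph_up_size = as.integer(ph_up_size),
              ph_down_size = as.integer(ph_down_size),
              hyper_size = as.integer(hyper_size),
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              effect_log2fc = effect_log2fc, noise_sd = noise_sd,
              rho_concordant = rho_concordant,
              rho_discordant = rho_discordant,
              n_background_degs = as.integer(n_background_degs),
              seed = as.integer(seed))
  sizes <- with(cfg, c(maturity_size, ph_up_size + ph_down_size, hyper_size))
  if (any(sizes > cfg$universe_size) ||
      sum(sizes) + cfg$n_background_degs > cfg$universe_size)
    stop("signature sizes (plus background) exceed the universe size")
  if (cfg$rho_concordant < 0 || cfg$rho_discordant < 0 ||
      cfg$rho_concordant + cfg$rho_discordant > 1)
    stop("rho fractions must be in [0, 1] with sum <= 1")
  if (cfg$n_case < 2 || cfg$n_control < 2)
    stop("at least 2 samples per group are required")
  if (cfg$noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(cfg, class = "synthetic_config")
}

# Deterministic universe symbols for a config.
universe_symbols <- function(cfg) sprintf("G%05d", seq_len(cfg$universe_size))

#' Gene universe of a synthetic configuration
#' @param cfg a \code{synthetic_config}.
#' @return a \code{gene_universe} over all generated symbols.
#' @export
synthetic_universe <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  build_universe(universe_symbols(cfg), mode = "union")
}

#' Generate the three reference signatures
#'
#' Maturity and hyperexcitation signatures get log-normal absolute log2
#' fold-change magnitudes with random signs; the pH signature has exactly
#' \code{ph_up_size} positive and \code{ph_down_size} negative S-value-like
#' scores. With \code{disjoint = TRUE} (default) the three draw
#' non-overlapping symbol blocks, so no later disjointification is needed.
#' Deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{synthetic_config}.
#' @param disjoint generate pairwise-disjoint signatures.
#' @return named list of \code{gene_signature}s: \code{maturity}, \code{ph},
#'   \code{hyperexcitation}.
#' @export
generate_references <- function(cfg, disjoint = TRUE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  syms <- universe_symbols(cfg)
  n_ph <- cfg$ph_up_size + cfg$ph_down_size
  sizes <- c(cfg$maturity_size, n_ph, cfg$hyper_size)
  if (disjoint) {
    pick <- sample(syms, sum(sizes))
    blocks <- split(pick, rep(1:3, sizes))
  } else {
    blocks <- lapply(sizes, function(k) sample(syms, k))
  }
  mag <- function(n) stats::rlnorm(n, meanlog = log(0.8), sdlog = 0.5)
  maturity <- gene_signature(
    blocks[[1]], mag(sizes[1]) * sample(c(-1, 1), sizes[1], replace = TRUE),
    name = "maturity", species = "mouse")
  ph <- gene_signature(
    blocks[[2]], mag(n_ph) * rep(c(1, -1), c(cfg$ph_up_size, cfg$ph_down_size)),
    name = "ph", species = "human")
  hyper <- gene_signature(
    blocks[[3]], mag(sizes[3]) * sample(c(-1, 1), sizes[3], replace = TRUE),
    name = "hyperexcitation", species = "rat")
  list(maturity = maturity, ph = ph, hyperexcitation = hyper)
}

# Normalise a planted-rho argument: named list of c(concordant, discordant)
# per reference, falling back to the config defaults.
planted_rho <- function(cfg, planted) {
  refs <- c("maturity", "ph", "hyperexcitation")
  out <- lapply(refs, function(r) {
    v <- if (!is.null(planted[[r]])) planted[[r]]
    else c(cfg$rho_concordant, cfg$rho_discordant)
    v <- unname(v)
    if (length(v) != 2 || any(v < 0) || sum(v) > 1)
      stop("planted rho for ", r, " must be c(concordant, discordant) in [0,1], sum <= 1")
    v
  })
  stats::setNames(out, refs)
}

#' Generate one synthetic expression dataset with planted overlaps
#'
#' Control means are drawn log-normal on the linear scale. For each
#' reference, \code{floor(rho_concordant * size)} of its genes are shifted in
#' the same direction as their reference score and
#' \code{floor(rho_discordant * size)} in the opposite direction; a further
#' \code{n_background_degs} off-reference genes are shifted in random
#' directions. Case means are control times \code{2^(direction * effect *
#' jitter)} with per-gene jitter uniform in [0.9, 1.1]; every sample then
#' receives independent Gaussian noise on the log2 scale. The truth record
#' lists every planted gene with its intended role.
#'
#' @param cfg a \code{synthetic_config}.
#' @param references reference signatures from
#'   \code{\link{generate_references}}.
#' @param name dataset name.
#' @param planted optional named list (\code{maturity}, \code{ph},
#'   \code{hyperexcitation}) of \code{c(concordant, discordant)} fractions;
#'   defaults to the config's rho values.
#' @param seed per-dataset seed (defaults to \code{cfg$seed}).
#' @return list of class \code{synthetic_dataset}: \code{name},
#'   \code{matrix} (an \code{\link{expression_matrix}}), \code{truth} (per
#'   reference, character vectors \code{concordant} and \code{discordant},
#'   plus \code{background}).
#' @export
generate_dataset <- function(cfg, references, name = "dataset",
                             planted = NULL, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  rho <- planted_rho(cfg, planted)
  set.seed(as.integer(seed))
  syms <- universe_symbols(cfg)
  N <- cfg$universe_size
  mu <- stats::rlnorm(N, meanlog = log(100), sdlog = 1)
  names(mu) <- syms
  delta <- stats::setNames(numeric(N), syms)
  truth <- list()
  for (r in names(references)) {
    ref <- references[[r]]
    nref <- nrow(ref$entries)
    n_c <- floor(rho[[r]][1] * nref)
    n_d <- floor(rho[[r]][2] * nref)
    if (n_c + n_d > nref)
      stop("planted counts exceed the size of reference '", r, "'")
    pick <- if (n_c + n_d > 0) sample(ref$entries$symbol, n_c + n_d) else character()
    conc <- pick[seq_len(n_c)]
    disc <- pick[n_c + seq_len(n_d)]
    refsign <- stats::setNames(sign(ref$entries$score), ref$entries$symbol)
    delta[conc] <- refsign[conc]
    delta[disc] <- -refsign[disc]
    truth[[r]] <- list(concordant = sort(conc), discordant = sort(disc))
  }
  offref <- setdiff(syms, unlist(lapply(references, function(s) s$entries$symbol)))
  bg <- sample(offref, min(cfg$n_background_degs, length(offref)))
  delta[bg] <- sample(c(-1, 1), length(bg), replace = TRUE)
  truth$background <- sort(bg)

  active <- delta != 0
  jit <- stats::runif(sum(active), 0.9, 1.1)
  delta[active] <- delta[active] * cfg$effect_log2fc * jit

  n_s <- cfg$n_case + cfg$n_control
  means <- cbind(matrix(mu * 2^delta, N, cfg$n_case),
                 matrix(mu, N, cfg$n_control))
  noise <- matrix(stats::rnorm(N * n_s, 0, cfg$noise_sd), N, n_s)
  vals <- means * 2^noise
  colnames(vals) <- c(sprintf("case_%d", seq_len(cfg$n_case)),
                      sprintf("control_%d", seq_len(cfg$n_control)))
  groups <- rep(c("case", "control"), c(cfg$n_case, cfg$n_control))
  structure(list(name = name,
                 matrix = expression_matrix(vals, genes = syms,
                                            groups = groups, scale = "linear"),
                 truth = truth),
            class = "synthetic_dataset")
}

#' Generate a synthetic multi-dataset cohort
#'
#' Generates the three reference signatures, \code{n_datasets} expression
#' datasets whose planted overlap fractions follow a severity schedule, and a
#' GMT collection containing one planted enriched term. Under the default
#' \code{trend = "signature"} schedule, maturity discordance, pH discordance
#' and hyperexcitation concordance all increase along a common severity ramp
#' across datasets (each dataset also carries a small constant opposite-side
#' fraction), so the cohort reproduces the sign structure seen in disease
#' models: the maturity and pH indices co-vary negatively with severity while
#' the hyperexcitation index co-varies positively. \code{trend = "null"}
#' plants nothing. Fully deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{synthetic_config}.
#' @param n_datasets number of datasets (>= 3 for downstream correlation).
#' @param trend \code{"signature"} (default) or \code{"null"}.
#' @param n_gmt_terms,gmt_term_size size of the generated GMT collection;
#'   one additional term (\code{"PLANTED_TERM"}) is drawn from the maturity
#'   signature's genes.
#' @param dir optional directory: when given, all fixtures (reference and
#'   truth tables, per-dataset matrices, GMT) are written there as TSV/GMT/
#'   JSON.
#' @return list of class \code{synthetic_study}: \code{config},
#'   \code{references}, \code{datasets} (list of \code{synthetic_dataset}),
#'   \code{truth} (per dataset), \code{gmt} (with attribute
#'   \code{planted_term}), \code{universe}, \code{severity}.
#' @export
generate_cohort <- function(cfg, n_datasets = 20,
                            trend = c("signature", "null"),
                            n_gmt_terms = 50, gmt_term_size = 30,
                            dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  trend <- match.arg(trend)
  if (n_datasets < 3) stop("need `n_datasets` >= 3 for downstream correlation")
  references <- generate_references(cfg, disjoint = TRUE)
  universe <- synthetic_universe(cfg)

  set.seed(cfg$seed)
  sev <- seq(0.1, 0.9, length.out = n_datasets) +
    stats::rnorm(n_datasets, 0, 0.02)
  sev <- pmin(pmax(sev, 0), 1)
  datasets <- vector("list", n_datasets)
  names(datasets) <- sprintf("dataset_%02d", seq_len(n_datasets))
  dseeds <- (as.numeric(cfg$seed) * 1009 + seq_len(n_datasets)) %% 2147483647
  for (i in seq_len(n_datasets)) {
    rho <- if (trend == "null") {
      list(maturity = c(0, 0), ph = c(0, 0), hyperexcitation = c(0, 0))
    } else {
      list(maturity = c(0.03, 0.08 + 0.4 * sev[i]),
           ph = c(0.03, 0.08 + 0.4 * sev[i]),
           hyperexcitation = c(0.08 + 0.4 * sev[i], 0.03))
    }
    datasets[[i]] <- generate_dataset(cfg, references, names(datasets)[i],
                                      planted = rho, seed = dseeds[i])
  }

  set.seed((as.numeric(cfg$seed) * 2017 + 1) %% 2147483647)
  syms <- universe$symbols
  gmt_sets <- lapply(seq_len(n_gmt_terms), function(i)
    sample(syms, gmt_term_size))
  names(gmt_sets) <- sprintf("TERM_%03d", seq_len(n_gmt_terms))
  gmt_sets$PLANTED_TERM <-
    sample(references$maturity$entries$symbol,
           min(gmt_term_size, nrow(references$maturity$entries)))
  gmt <- structure(list(sets = gmt_sets,
                        descriptions = stats::setNames(
                          c(rep("random (synthetic)", n_gmt_terms),
                            "planted enriched term (synthetic)"),
                          names(gmt_sets)),
                        provenance = "synthetic"),
                   class = "gene_set_collection")
  attr(gmt, "planted_term") <- "PLANTED_TERM"

  study <- structure(list(config = cfg, references = references,
                          datasets = datasets,
                          truth = lapply(datasets, `[[`, "truth"),
                          gmt = gmt, universe = universe, severity = sev),
                     class = "synthetic_study")
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", length(x$datasets), "datasets, universe",
      x$universe$size, "genes, seed", x$config$seed, "\n")
  cat("  references:",
      paste(vapply(x$references, function(s)
        paste0(s$name, "(", nrow(s$entries), ")"), ""), collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic study to a fixture directory
#'
#' Emits the same plain-text formats the readers consume: reference
#' signatures as DEG tables, per-dataset expression matrices and group
#' tables as TSV, the GMT collection, and \code{truth.json} with the full
#' planted bookkeeping and config echo.
#'
#' @param study a \code{synthetic_study}.
#' @param dir output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in names(study$references))
    write_deg_table(study$references[[r]],
                    file.path(dir, paste0("reference_", r, ".tsv")))
  for (nm in names(study$datasets)) {
    m <- study$datasets[[nm]]$matrix
    tab <- data.frame(gene = m$genes, m$values, check.names = FALSE)
    utils::write.table(tab, file.path(dir, paste0(nm, "_matrix.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample = colnames(m$values),
                                  group = m$groups),
                       file.path(dir, paste0(nm, "_groups.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_gmt(study$gmt, file.path(dir, "gene_sets.gmt"))
  jsonlite::write_json(list(config = unclass(study$config),
                            severity = study$severity,
                            planted_term = attr(study$gmt, "planted_term"),
                            truth = study$truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
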