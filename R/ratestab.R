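#' Classify a continuous dietary index into diet classes
#'
#' Negative indices mark plant-visiting species, positive indices
#' animal-feeding ones. An index of exactly zero is undefined under that
#' convention; it is assigned to "animal" with a warning so the case is
#' auditable.
#'
#' @param diet_index Finite numeric scalar or vector.
#' @return Character vector of "plant" / "animal".
#' @examples
#' classify_diet(-0.5)  # "plant"
#' classify_diet(0.5)   # "animal"
#' @export
classify_diet <- function(diet_index) {
  if (any(!is.finite(diet_index))) {
    stop("diet_index must be finite", call. = FALSE)
  }
  if (any(diet_index == 0)) {
    warning("diet_index of exactly 0 assigned to 'animal' ",
            "(convention covers only <0 and >0)", call. = FALSE)
  }
  ifelse(diet_index < 0, "plant", "animal")
}

#' Build the per-gene rate table from paired gene trees
#'
#' One row per (gene, tip): the codon root-to-tip length from the
#' codon-model tree and the nucleotide root-to-tip length from the
#' nucleotide-model tree, both via [root_to_tip()]. The two trees of a pair
#' must carry identical tip sets.
#'
#' @param pairs List of gene records
#'   (`gene_id`, `subfamily`, `codon_tree`, `nucleotide_tree`), as produced
#'   by [simulate_gene_tree_pairs()] or assembled from files.
#' @return Data frame: `gene_id`, `species`, `subfamily`, `codon_rtt`,
#'   `nucl_rtt`.
#' @export
build_rate_table <- function(pairs) {
  if (length(pairs) == 0L) {
    return(data.frame(gene_id = character(0), species = character(0),
                      subfamily = character(0), codon_rtt = numeric(0),
                      nucl_rtt = numeric(0), stringsAsFactors = FALSE))
  }
  out <- lapply(pairs, function(p) {
    ct <- sort(p$codon_tree$tip.label)
    nt <- sort(p$nucleotide_tree$tip.label)
    if (!identical(ct, nt)) {
      stop("tip-set mismatch between codon and nucleotide trees of gene ",
           p$gene_id, call. = FALSE)
    }
    cr <- root_to_tip(p$codon_tree)
    nr <- root_to_tip(p$nucleotide_tree)
    data.frame(gene_id = p$gene_id, species = names(cr),
               subfamily = p$subfamily, codon_rtt = unname(cr),
               nucl_rtt = unname(nr[names(cr)]), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove species with too few detected genes
#'
#' Species represented by fewer than `min_genes` gene records are dropped
#' from the rate table (the analogue of removing a species with a single
#' intact reading frame, attributable to low detection rather than true OR
#' loss). Removals are reported via message and returned.
#'
#' @param table Rate table from [build_rate_table()].
#' @param min_genes Minimum gene records a species must have (default 2).
#' @return List: `table` (filtered), `removed` (character vector of species).
#' @export
filter_low_detection <- function(table, min_genes = 2L) {
  if (min_genes < 1L) stop("min_genes must be >= 1", call. = FALSE)
  counts <- table(table$species)
  removed <- names(counts)[counts < min_genes]
  if (length(removed)) {
    message("filter_low_detection: removing ", length(removed),
            " species with < ", min_genes, " genes: ",
            paste(removed, collapse = ", "))
  }
  list(table = table[!(table$species %in% removed), , drop = FALSE],
       removed = removed)
}

#' Principal components analysis of codon and nucleotide branch lengths
#'
#' Eigen-decomposition of the covariance of the centered (not rescaled)
#' `codon_rtt` and `nucl_rtt` columns, so the variance loaded on PC1 is
#' reported in the original branch-length units.
#'
#' @param table Rate table with >= 2 rows.
#' @return List of class "pca_rates": `loadings` (2x2, columns = PCs),
#'   `proportion` (variance proportions, non-increasing), `scores`
#'   (per-record PC scores), `sdev`.
#' @export
pca_rates <- function(table) {
  X <- as.matrix(table[, c("codon_rtt", "nucl_rtt")])
  if (nrow(X) < 2L) stop("need >= 2 records for PCA", call. = FALSE)
  for (col in colnames(X)) {
    if (stats::var(X[, col]) == 0) {
      stop("zero variance in column ", col, call. = FALSE)
    }
  }
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  prop <- p$sdev^2 / sum(p$sdev^2)
  structure(list(loadings = p$rotation, proportion = prop, scores = p$x,
                 sdev = p$sdev), class = "pca_rates")
}

#' Simple OLS quality-control regression with F-test
#'
#' Ordinary least squares of `y` on `x` with the F-test of zero slope on
#' (1, n-2) degrees of freedom; used e.g. to check whether the number of ORs
#' detected per species depends on RNA integrity.
#'
#' @param x Numeric predictor (>= 3 finite paired values, non-constant).
#' @param y Numeric response, same length.
#' @return List: `slope`, `slope_se`, `F`, `p`, `df` (c(1, n-2)),
#'   `intercept`, `n`.
#' @export
qc_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 paired finite observations", call. = FALSE)
  if (stats::var(x) == 0) stop("zero predictor variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  Fst <- sm$coefficients["x", "t value"]^2
  list(slope = unname(stats::coef(fit)["x"]),
       slope_se = unname(sm$coefficients["x", "Std. Error"]),
       F = unname(Fst),
       p = unname(stats::pf(Fst, 1, n - 2, lower.tail = FALSE)),
       df = c(1L, n - 2L),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       n = n)
}

#' Read/write rate and species tables
#'
#' Tab-separated with the canonical headers (`gene_id`, `species`,
#' `subfamily`, `codon_rtt`, `nucl_rtt`; `species`, `mass_g`,
#' `surface_area`, `diet_index`, ...).
#'
#' @param table Data frame.
#' @param file Path.
#' @return The data frame (read) or `file` invisibly (write).
#' @export
write_table_tsv <- function(table, file) {
  utils::write.table(table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
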