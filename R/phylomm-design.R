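`%||%` <- function(a, b) if (is.null(a)) b else a

#' Declare a random-effect block
#'
#' A block is a design (intercept and/or covariate columns, as a one-sided
#' formula), a grouping factor, a variance structure — `"us"` estimates the
#' full (unstructured) covariance among the design columns, `"idh"`
#' independent variances with zero covariances — and an optional phylogenetic
#' association: a [relatedness_matrix()] whose labels cover the grouping
#' levels, making the block an animal-model effect.
#'
#' @param formula One-sided design formula, e.g. `~1` (random intercept) or
#'   `~1 + log_mass` (intercept and slope).
#' @param group Name of the grouping factor column.
#' @param structure `"us"` or `"idh"`.
#' @param relatedness Optional "relatedness" object (see
#'   [relatedness_matrix()]).
#' @param name Optional block label (defaults to `structure(design):group`).
#' @return List of class "ran_block".
#' @export
ran_block <- function(formula, group, structure = c("us", "idh"),
                      relatedness = NULL, name = NULL) {
  structure <- match.arg(structure)
  if (!is.null(relatedness) && !inherits(relatedness, "relatedness")) {
    stop("relatedness must come from relatedness_matrix()", call. = FALSE)
  }
  tl <- attr(stats::terms(formula), "term.labels")
  if (attr(stats::terms(formula), "intercept")) tl <- c("1", tl)
  lab <- name %||% paste0(structure, "(", paste(tl, collapse = "+"),
                          "):", group)
  base::structure(list(formula = formula, group = group,
                       struct = structure, relatedness = relatedness,
                       name = lab),
                  class = "ran_block")
}

#' Declare MCMC settings
#'
#' @param n_iterations Total Gibbs iterations.
#' @param burn_in Iterations discarded (must be < `n_iterations`).
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param seed Integer seed.
#' @param chains Number of chains (run sequentially with seeds
#'   `seed, seed+1, ...`; samples are pooled).
#' @return List of class "mcmc_config".
#' @export
mcmc_config <- function(n_iterations = 13000, burn_in = 3000, thin = 10,
                        seed = 1L, chains = 1L) {
  stopifnot(burn_in < n_iterations, thin >= 1, chains >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), chains = as.integer(chains)),
            class = "mcmc_config")
}

#' Declare priors for the Gaussian mixed model
#'
#' Fixed effects get independent normal priors; each variance block and the
#' residual get inverse-Wishart priors (scale `V`, degrees of freedom `nu`;
#' the one-dimensional case is the inverse-gamma with shape `nu/2`, rate
#' `V/2`). Defaults, filled per-model at fit time, are weakly informative:
#' `fixed_var = 1e8`; block `V` diagonal with each design column scaled by
#' half the variance of the responses that column touches (so trait-specific
#' columns of a multiresponse stack use their own trait's variance), and
#' `nu = dim + 0.002`; residual likewise per trait.
#'
#' @param fixed_mean,fixed_var Normal prior mean and variance for every
#'   fixed effect.
#' @param blocks Optional list, one element per random block, each
#'   `list(V=, nu=)` (matrix V of the block's design dimension).
#' @param residual Optional `list(V=, nu=)` for the residual variance
#'   (scalar for iid, 2x2 for the two-trait residual), or
#'   `list(fixed = <value or matrix>)` to treat the residual (co)variance
#'   as known (no residual updates; used e.g. when checking the sampler
#'   against the conjugate closed-form posterior).
#' @return List of class "prior_spec".
#' @export
prior_spec <- function(fixed_mean = 0, fixed_var = 1e8, blocks = NULL,
                       residual = NULL) {
  stopifnot(fixed_var > 0)
  structure(list(fixed_mean = fixed_mean, fixed_var = fixed_var,
                 blocks = blocks, residual = residual),
            class = "prior_spec")
}

#' Build the stacked design for a (possibly multiresponse) mixed model
#'
#' Assembles the response vector, fixed-effect design matrix, and one
#' design matrix per random block from a data frame. For two-trait
#' (multiresponse) models the data must already be in long form (one row
#' per unit x trait, see [stack_multiresponse()]) and the residual is the
#' unstructured 2x2 per-unit covariance `us(trait):units`; otherwise the
#' residual is iid. Missing response values are flagged for Gibbs
#' augmentation; missing covariates are an error.
#'
#' @param data Data frame.
#' @param response Name of the response column (NAs allowed).
#' @param fixed One-sided fixed-effects formula, e.g. `~ log_mass` or
#'   `~ 0 + trait + nucl_c`.
#' @param blocks List of [ran_block()] objects (may be empty).
#' @param residual `"iid"`, or `list(type = "us_trait", trait = <col>,
#'   unit = <col>)` naming the trait factor (2 levels) and unit id column.
#' @return List of class "mm_design".
#' @export
build_design <- function(data, response, fixed = ~1, blocks = list(),
                         residual = "iid") {
  if (!response %in% names(data)) {
    stop("response column '", response, "' not in data", call. = FALSE)
  }
  y <- as.numeric(data[[response]])
  if (all(!is.finite(y))) {
    stop("response '", response, "' is entirely missing", call. = FALSE)
  }
  mf <- stats::model.frame(fixed, data, na.action = stats::na.pass)
  X <- stats::model.matrix(fixed, mf)
  if (anyNA(X)) stop("missing values in fixed-effect covariates",
                     call. = FALSE)
  n <- length(y)
  stopifnot(nrow(X) == n)

  blist <- lapply(blocks, function(b) {
    stopifnot(inherits(b, "ran_block"))
    if (!b$group %in% names(data)) {
      stop("grouping column '", b$group, "' not in data", call. = FALSE)
    }
    g <- factor(data[[b$group]])
    levs <- levels(g)
    L <- length(levs)
    Dm <- stats::model.matrix(b$formula,
                              stats::model.frame(b$formula, data,
                                                 na.action = stats::na.pass))
    if (anyNA(Dm)) stop("missing values in random-effect design of block ",
                        b$name, call. = FALSE)
    q <- ncol(Dm)
    Ainv <- NULL
    if (!is.null(b$relatedness)) {
      missing_levs <- setdiff(levs, b$relatedness$labels)
      if (length(missing_levs)) {
        stop("levels of '", b$group, "' missing from relatedness matrix: ",
             paste(missing_levs, collapse = ", "), call. = FALSE)
      }
      Ainv <- b$relatedness$Ainv[levs, levs, drop = FALSE]
    }
    # effect (d, l) sits in column (d-1)*L + l: covariance G %x% A
    Z <- matrix(0, n, q * L)
    gi <- as.integer(g)
    for (d in seq_len(q)) {
      Z[cbind(seq_len(n), (d - 1L) * L + gi)] <- Dm[, d]
    }
    colnames(Z) <- paste0(b$name, ".",
                          rep(colnames(Dm), each = L), ".", rep(levs, q))
    list(name = b$name, Z = Z, q = q, L = L, struct = b$struct,
         Ainv = Ainv, levels = levs, design_names = colnames(Dm))
  })

  res <- residual
  if (identical(res, "iid")) {
    res <- list(type = "iid")
  } else {
    stopifnot(is.list(res), identical(res$type, "us_trait"))
    tr <- factor(data[[res$trait]])
    if (nlevels(tr) != 2L) {
      stop("trait factor must have exactly 2 levels", call. = FALSE)
    }
    un <- factor(data[[res$unit]])
    if (!all(table(un, tr) == 1L)) {
      stop("each unit must have exactly one row per trait", call. = FALSE)
    }
    ord <- order(un, tr)
    idx1 <- ord[seq(1, 2 * nlevels(un), by = 2)]
    idx2 <- ord[seq(2, 2 * nlevels(un), by = 2)]
    res <- list(type = "us_trait", trait_names = levels(tr),
                n_units = nlevels(un), idx1 = idx1, idx2 = idx2)
  }

  structure(list(y = y, X = X, blocks = blist, residual = res,
                 n = n, observed = is.finite(y)),
            class = "mm_design")
}

#' Stack a rate table and species table into two-trait long form
#'
#' Each gene record (one gene x species observation) becomes one unit with
#' two rows: trait `"codon"` carries the codon root-to-tip length with the
#' nucleotide length as its covariate; trait `"sa"` carries the species'
#' log olfactory-epithelium surface area (repeated across that species'
#' genes, NA where morphology is missing — to be imputed by the sampler)
#' with log mass split by diet class as its covariates. Trait-specific
#' covariates are zeroed on the other trait's rows.
#'
#' @param rate_table Data frame from [build_rate_table()].
#' @param species_table Species table with `species`, `mass_g`,
#'   `surface_area`, `diet_class` (or `diet_index`).
#' @return Long data frame with columns `unit`, `trait`, `y`, `species`,
#'   `subfamily`, `nucl_c`, `sa_diet_plant`, `sa_mass_plant`,
#'   `sa_mass_animal`.
#' @export
stack_multiresponse <- function(rate_table, species_table) {
  unknown <- setdiff(rate_table$species, species_table$species)
  if (length(unknown)) {
    stop("species in rate table missing from species table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(species_table$diet_class)) {
    species_table$diet_class <- classify_diet(species_table$diet_index)
  }
  m <- match(rate_table$species, species_table$species)
  log_sa <- log(species_table$surface_area)[m]
  log_mass <- log(species_table$mass_g)[m]
  diet <- species_table$diet_class[m]
  nu <- nrow(rate_table)
  long <- data.frame(
    unit = rep(seq_len(nu), each = 2L),
    trait = rep(c("codon", "sa"), nu),
    y = as.vector(rbind(rate_table$codon_rtt, log_sa)),
    species = rep(rate_table$species, each = 2L),
    subfamily = rep(rate_table$subfamily, each = 2L),
    nucl_c = as.vector(rbind(rate_table$nucl_rtt, 0)),
    sa_diet_plant = as.vector(rbind(0, as.numeric(diet == "plant"))),
    sa_mass_plant = as.vector(rbind(0, log_mass * (diet == "plant"))),
    sa_mass_animal = as.vector(rbind(0, log_mass * (diet == "animal"))),
    stringsAsFactors = FALSE
  )
  long
}
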