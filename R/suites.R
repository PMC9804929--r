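#' Select the best model by DIC
#'
#' Minimum DIC wins; ties (within `tol`) are broken toward the candidate
#' with fewer variance parameters, then by candidate id for full
#' determinism. Order-invariant.
#'
#' @param candidates Data frame with columns `id`, `dic`,
#'   `n_variance_params`.
#' @param tol Numerical tie tolerance (default 1e-6).
#' @return The selected `id`.
#' @export
select_model <- function(candidates, tol = 1e-6) {
  stopifnot(all(c("id", "dic", "n_variance_params") %in% names(candidates)))
  ok <- is.finite(candidates$dic)
  if (!any(ok)) stop("all candidate DICs are non-finite", call. = FALSE)
  cand <- candidates[ok, , drop = FALSE]
  best <- min(cand$dic)
  tied <- cand[cand$dic <= best + tol, , drop = FALSE]
  tied <- tied[order(tied$n_variance_params, tied$id), , drop = FALSE]
  tied$id[1]
}

#' Configure an analysis-suite run
#'
#' @param partitions For the rates suite: which intercept/slope partitions
#'   to compare (subset of `"none"`, `"plant_diet"`, `"diet_categories"`,
#'   `"subfamily"`, `"species"`).
#' @param exclude_mormoopids Also rerun with the flagged clade removed
#'   (paired results; the full-data fit is always kept).
#' @param mcmc An [mcmc_config()].
#' @param priors A [prior_spec()].
#' @return List of class "suite_config".
#' @export
suite_config <- function(partitions = c("none", "plant_diet", "subfamily"),
                         exclude_mormoopids = FALSE,
                         mcmc = mcmc_config(), priors = prior_spec()) {
  valid <- c("none", "plant_diet", "diet_categories", "subfamily", "species")
  bad <- setdiff(partitions, valid)
  if (length(bad)) stop("unknown partitions: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (length(partitions) == 0) stop("need at least one partition",
                                    call. = FALSE)
  structure(list(partitions = partitions,
                 exclude_mormoopids = isTRUE(exclude_mormoopids),
                 mcmc = mcmc, priors = priors), class = "suite_config")
}

prepare_species <- function(species_table) {
  st <- species_table
  if (is.null(st$diet_class)) st$diet_class <- classify_diet(st$diet_index)
  if (is.null(st$log_mass)) st$log_mass <- log(st$mass_g)
  if (!is.null(st$surface_area)) st$log_sa <- log(st$surface_area)
  st
}

new_suite_result <- function(suite, candidates, fits, config, extra = list()) {
  sel <- select_model(candidates)
  structure(c(list(suite = suite, candidates = candidates, fits = fits,
                   selected = sel, config = config), extra),
            class = "suite_result")
}

#' Allometry suite: log surface area on log body mass
#'
#' Fits three nested phylogenetic regressions of log olfactory-epithelium
#' surface area on log body mass, each with an animal-model species effect:
#' M0 (one intercept and slope), M1 (diet-specific intercepts via a random
#' diet intercept), and M2 (diet-specific intercepts and slopes via an
#' unstructured `us(1 + log mass):diet` block). Models are compared by DIC.
#' Per-diet slope posteriors for M2 are the fixed slope plus the diet-level
#' slope deviations.
#'
#' @param species_table Species table (`species`, `mass_g`, `surface_area`,
#'   `diet_index` or `diet_class`, optionally `is_mormoopid`).
#' @param species_tree Species phylogeny covering all species.
#' @param config A [suite_config()].
#' @return "suite_result": candidate table with DICs, fits, the selected
#'   id, per-diet slope summaries (`diet_slopes`), and (if requested) the
#'   mormoopid-excluded rerun under `$excluded_rerun`.
#' @export
run_allometry_suite <- function(species_table, species_tree,
                                config = suite_config()) {
  st <- prepare_species(species_table)
  need <- c("species", "mass_g", "surface_area")
  miss <- need[!need %in% names(st)]
  if (length(miss)) stop("species table lacks: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(st$mass_g) || anyNA(st$surface_area)) {
    stop("missing mass or surface-area values", call. = FALSE)
  }
  if (nrow(st) < 6L) stop("need >= 6 species", call. = FALSE)
  if (length(unique(st$diet_class)) < 2L) {
    stop("only one diet class present; diet models are unidentifiable",
         call. = FALSE)
  }
  rel <- relatedness_matrix(species_tree, species = st$species)
  sp_block <- ran_block(~1, "species", "us", relatedness = rel,
                        name = "species")
  mc <- config$mcmc
  fits <- list(
    M0 = gibbs_fit(
      build_design(st, "log_sa", fixed = ~log_mass, blocks = list(sp_block)),
      priors = config$priors, mcmc = mc),
    M1 = gibbs_fit(
      build_design(st, "log_sa", fixed = ~log_mass,
                   blocks = list(ran_block(~1, "diet_class", "us",
                                           name = "diet"), sp_block)),
      priors = config$priors, mcmc = mc),
    M2 = gibbs_fit(
      build_design(st, "log_sa", fixed = ~log_mass,
                   blocks = list(ran_block(~1 + log_mass, "diet_class",
                                           "us", name = "diet"), sp_block)),
      priors = config$priors, mcmc = mc)
  )
  candidates <- data.frame(
    id = names(fits),
    dic = vapply(fits, `[[`, numeric(1), "dic"),
    n_variance_params = vapply(fits, `[[`, numeric(1), "n_variance_params"),
    stringsAsFactors = FALSE
  )
  diet_slopes <- level_effect_summary(fits$M2, block = "diet",
                                      design_col = "log_mass",
                                      fixed_col = "fixed.log_mass")
  extra <- list(diet_slopes = diet_slopes)
  if (config$exclude_mormoopids && any(st$is_mormoopid %in% TRUE)) {
    keep <- st[!st$is_mormoopid, , drop = FALSE]
    cfg2 <- config; cfg2$exclude_mormoopids <- FALSE
    extra$excluded_rerun <- run_allometry_suite(keep, species_tree, cfg2)
  }
  new_suite_result("allometry", candidates, fits, config, extra)
}

# posterior summaries of fixed + per-level random deviation (e.g. per-diet
# or per-subfamily slope)
level_effect_summary <- function(fit, block, design_col, fixed_col) {
  pat <- paste0("^", gsub("([()+])", "\\\\\\1", block), "\\.",
                gsub("([()+])", "\\\\\\1", design_col), "\\.")
  cols <- grep(pat, colnames(fit$samples), value = TRUE)
  if (!length(cols)) return(NULL)
  base <- if (fixed_col %in% colnames(fit$samples))
    fit$samples[, fixed_col] else 0
  out <- lapply(cols, function(cn) {
    sl <- base + fit$samples[, cn]
    hp <- suppressWarnings(hpd_interval(sl))
    data.frame(level = sub(pat, "", cn), mean = mean(sl),
               lower = hp[1], upper = hp[2], ess = ess_chain(sl),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rates suite: codon on nucleotide branch lengths
#'
#' Regresses per-gene codon root-to-tip lengths on nucleotide root-to-tip
#' lengths, comparing candidates that partition the intercept and slope by
#' nothing, plant diet, multiple diet categories, OR subfamily, or species
#' (each partition an unstructured `us(1 + nucleotide):factor` block on top
#' of the global fixed intercept and slope). Partition levels with fewer
#' than 3 records are dropped with a warning. Candidates are compared by
#' DIC and per-level slope posteriors are reported.
#'
#' @param rate_table Rate table (`gene_id`, `species`, `subfamily`,
#'   `codon_rtt`, `nucl_rtt`).
#' @param species_table Optional species table supplying `diet_class` (and
#'   `diet_category`, `is_mormoopid`) joined by species; required for the
#'   diet partitions.
#' @param config A [suite_config()].
#' @return "suite_result" with per-partition fits, DIC table, selected id,
#'   and `slopes` (per-level slope summaries of the selected fit).
#' @export
run_rates_suite <- function(rate_table, species_table = NULL,
                            config = suite_config()) {
  rt <- rate_table
  if (!is.null(species_table)) {
    st <- prepare_species(species_table)
    m <- match(rt$species, st$species)
    rt$diet_class <- st$diet_class[m]
    if (!is.null(st$diet_category)) rt$diet_category <- st$diet_category[m]
    if (!is.null(st$is_mormoopid)) rt$is_mormoopid <- st$is_mormoopid[m]
  }
  mc <- config$mcmc
  part_col <- c(plant_diet = "diet_class", diet_categories = "diet_category",
                subfamily = "subfamily", species = "species")
  fits <- list()
  for (p in config$partitions) {
    if (p == "none") {
      des <- build_design(rt, "codon_rtt", fixed = ~nucl_rtt)
      fits[["none"]] <- gibbs_fit(des, priors = config$priors, mcmc = mc)
      next
    }
    col <- part_col[[p]]
    if (is.null(rt[[col]])) {
      warning("partition '", p, "' skipped: column '", col, "' unavailable",
              call. = FALSE)
      next
    }
    counts <- table(rt[[col]])
    drop_levs <- names(counts)[counts < 3L]
    sub <- rt
    if (length(drop_levs)) {
      warning("partition '", p, "': dropping levels with < 3 records: ",
              paste(drop_levs, collapse = ", "), call. = FALSE)
      sub <- rt[!(rt[[col]] %in% drop_levs), , drop = FALSE]
    }
    des <- build_design(sub, "codon_rtt", fixed = ~nucl_rtt,
                        blocks = list(ran_block(~1 + nucl_rtt, col, "us",
                                                name = p)))
    fits[[p]] <- gibbs_fit(des, priors = config$priors, mcmc = mc)
  }
  if (!length(fits)) stop("no fittable partitions", call. = FALSE)
  candidates <- data.frame(
    id = names(fits),
    dic = vapply(fits, `[[`, numeric(1), "dic"),
    n_variance_params = vapply(fits, `[[`, numeric(1), "n_variance_params"),
    stringsAsFactors = FALSE
  )
  sel <- select_model(candidates)
  slopes <- if (sel == "none") NULL else
    level_effect_summary(fits[[sel]], block = sel, design_col = "nucl_rtt",
                         fixed_col = "fixed.nucl_rtt")
  new_suite_result("rates", candidates, fits, config,
                   list(slopes = slopes))
}

#' Multiresponse suite: codon rates and surface area modeled jointly
#'
#' Stacks each gene record into a two-trait unit (codon root-to-tip length;
#' log olfactory-epithelium surface area of its species, repeated within
#' species and imputed where morphology is missing) and fits two candidate
#' multiresponse models sharing the mean structure — trait-specific
#' intercepts, subfamily-specific nucleotide slopes on the codon trait,
#' diet intercept and log mass split by diet on the surface-area trait —
#' and the unstructured 2x2 per-unit residual
#' `us(trait):units`, differing in the phylogenetically structured species
#' block: independent per-trait variances (`idh(trait):species`) versus the
#' full between-trait covariance (`us(trait):species`). DIC compares the
#' two. The derived species-level codon/surface-area coefficients (block
#' covariance divided by a trait variance) come from the us-species fit,
#' the only candidate able to carry that covariance; the residual-level
#' ratio is reported alongside.
#'
#' @param rate_table Rate table.
#' @param species_table Species table (all rate-table species must appear).
#' @param species_tree Species phylogeny.
#' @param config A [suite_config()].
#' @return "suite_result" with the fit, the derived coefficients
#'   (`coef_codon_on_sa`, `coef_sa_on_codon`), mass-coefficient summaries,
#'   and (if requested) `$excluded_rerun`.
#' @export
run_multiresponse_suite <- function(rate_table, species_table, species_tree,
                                    config = suite_config()) {
  st <- prepare_species(species_table)
  overlap <- intersect(rate_table$species, st$species)
  if (length(overlap) < 5L) {
    stop("need >= 5 species shared between rate and species tables",
         call. = FALSE)
  }
  long <- stack_multiresponse(rate_table, st)
  rel <- relatedness_matrix(species_tree, species = unique(long$species))
  mk_design <- function(struct) build_design(
    long, "y",
    fixed = ~ 0 + trait + nucl_c:subfamily + sa_diet_plant +
      sa_mass_plant + sa_mass_animal,
    blocks = list(ran_block(~ 0 + trait, "species", struct,
                            relatedness = rel, name = "species")),
    residual = list(type = "us_trait", trait = "trait", unit = "unit")
  )
  fits <- list(
    idh_species = gibbs_fit(mk_design("idh"), priors = config$priors,
                            mcmc = config$mcmc),
    us_species = gibbs_fit(mk_design("us"), priors = config$priors,
                           mcmc = config$mcmc)
  )
  candidates <- data.frame(
    id = names(fits),
    dic = vapply(fits, `[[`, numeric(1), "dic"),
    n_variance_params = vapply(fits, `[[`, numeric(1), "n_variance_params"),
    stringsAsFactors = FALSE
  )
  fit_us <- fits$us_species
  sel_fit <- fits[[select_model(candidates)]]
  extra <- list(
    # species-level covariance/variance ratios, from the us(trait):species
    # block (the block able to carry between-trait covariance)
    coef_codon_on_sa = derived_coefficient(fit_us, "species", denom = 2L),
    coef_sa_on_codon = derived_coefficient(fit_us, "species", denom = 1L),
    coef_residual = derived_coefficient(fit_us, "residual", denom = 2L),
    mass_coefs = sel_fit$summary[
      sel_fit$summary$parameter %in% c("fixed.sa_mass_plant",
                                       "fixed.sa_mass_animal") |
        grepl("^fixed\\.nucl_c", sel_fit$summary$parameter), ]
  )
  if (config$exclude_mormoopids && !is.null(st$is_mormoopid) &&
      any(st$is_mormoopid)) {
    keep_sp <- st$species[!st$is_mormoopid]
    cfg2 <- config; cfg2$exclude_mormoopids <- FALSE
    extra$excluded_rerun <- run_multiresponse_suite(
      rate_table[rate_table$species %in% keep_sp, , drop = FALSE],
      st[!st$is_mormoopid, , drop = FALSE], species_tree, cfg2)
  }
  new_suite_result("multiresponse", candidates, fits, config, extra)
}

#' Consolidated report over suite results
#'
#' @param suite_results List of "suite_result" objects.
#' @return List of class "suite_report": `text` (human-readable lines) and
#'   `tables` (machine-readable: one coefficient table per suite, every
#'   parameter carrying mean, 95% HPD bounds, ESS and Geweke z).
#' @export
report <- function(suite_results) {
  if (inherits(suite_results, "suite_result")) {
    suite_results <- list(suite_results)
  }
  stopifnot(length(suite_results) >= 1)
  text <- character(0)
  tables <- list()
  for (res in suite_results) {
    text <- c(text, sprintf("== Suite: %s ==", res$suite),
              sprintf("selected model: %s", res$selected),
              utils::capture.output(print(res$candidates, digits = 6)))
    fit <- res$fits[[res$selected]]
    tab <- fit$summary[fit$summary$parameter %in%
                         c(fit$param_map$fixed, fit$param_map$G,
                           fit$param_map$residual), ]
    low_ess <- tab$parameter[is.finite(tab$ess) & tab$ess < 200]
    if (length(low_ess)) {
      text <- c(text, paste("WARNING low ESS (<200):",
                            paste(low_ess, collapse = ", ")))
    }
    for (nm in c("diet_slopes", "slopes")) {
      if (!is.null(res[[nm]])) {
        text <- c(text, sprintf("-- %s --", nm),
                  utils::capture.output(print(res[[nm]], digits = 4)))
      }
    }
    if (!is.null(res$coef_codon_on_sa)) {
      dc <- res$coef_codon_on_sa
      text <- c(text, sprintf(
        "derived codon~surface-area coefficient: mean %.4g [%.4g, %.4g], P(<0) = %.3f",
        dc$mean, dc$hpd[1], dc$hpd[2], dc$p_negative))
    }
    text <- c(text, utils::capture.output(print(tab, digits = 4)), "")
    tables[[res$suite]] <- tab
  }
  structure(list(text = text, tables = tables), class = "suite_report")
}

#' @export
print.suite_report <- function(x, ...) {
  cat(paste(x$text, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.suite_result <- function(x, ...) {
  cat(sprintf("Suite '%s': %d candidate(s), selected '%s'\n",
              x$suite, nrow(x$candidates), x$selected))
  print(x$candidates, digits = 6)
  invisible(x)
}
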