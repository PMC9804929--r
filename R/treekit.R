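#' Validate a phylogeny for use in rate extraction and mixed models
#'
#' Checks the invariants assumed throughout the package: an `ape` "phylo"
#' object that is rooted, has unique tip labels, and carries a non-negative
#' branch length on every edge.
#'
#' @param tree An object of class "phylo".
#' @param what Label used in error messages.
#' @return `tree`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_phylogeny <- function(tree, what = "tree") {
  if (!inherits(tree, "phylo")) {
    stop(what, " is not a 'phylo' object", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop(what, " has duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop(what, " has no branch lengths", call. = FALSE)
  }
  if (anyNA(tree$edge.length)) {
    stop(what, " has missing branch lengths on ",
         sum(is.na(tree$edge.length)), " edge(s)", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop(what, " has negative branch length(s): min = ",
         format(min(tree$edge.length)), call. = FALSE)
  }
  # exactly one root is guaranteed by the "phylo" edge table; basal
  # polytomies are accepted (the tree is taken as rooted where written)
  invisible(tree)
}

#' Read a rooted phylogeny from Newick text or file
#'
#' Parses a Newick string (or the first tree of a file) into an `ape`
#' "phylo" object and validates it: all edges must carry branch lengths,
#' lengths must be non-negative, tip labels must be unique, and the tree
#' must be rooted. Single-quoted labels and square-bracket comments are
#' tolerated. A length on the root edge, if present, is ignored (treated
#' as 0) as is conventional.
#'
#' @param text Newick string, e.g. `"((A:1,B:1):1,C:2);"`.
#' @param file Path to a Newick file (one tree per line; the first is read
#'   unless `n` is given). Exactly one of `text`/`file` must be supplied.
#' @return A validated "phylo" object.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' root_to_tip(tr)
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of 'text' or 'file'", call. = FALSE)
  }
  if (!is.null(file)) {
    if (!file.exists(file)) stop("no such file: ", file, call. = FALSE)
    text <- readLines(file, warn = FALSE)
    text <- text[nzchar(trimws(text))][1L]
    if (is.na(text)) stop("empty Newick file: ", file, call. = FALSE)
  }
  # strip square-bracket comments before handing to ape
  text <- gsub("\\[[^]]*\\]", "", text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tree)) {
    stop("Newick parse error in: ", substr(text, 1, 60), call. = FALSE)
  }
  # normalize single-quoted labels ('A x' -> A x)
  tree$tip.label <- sub("^'(.*)'$", "\\1", tree$tip.label)
  validate_phylogeny(tree, what = "parsed tree")
}

#' Write a phylogeny to Newick
#'
#' @param tree A "phylo" object.
#' @param file Optional path; if omitted the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when writing to file).
#' @export
write_newick <- function(tree, file = NULL, digits = 15) {
  validate_phylogeny(tree)
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the summed branch length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip depths.
#' Under Brownian motion this matrix, scaled by the rate, is the expected
#' trait covariance among tips.
#'
#' @param tree A validated "phylo" object (>= 1 tip).
#' @return A symmetric matrix with tip labels as dimnames.
#' @examples
#' phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
#' @export
phylo_vcv <- function(tree) {
  validate_phylogeny(tree)
  n <- length(tree$tip.label)
  if (n == 1L) {
    d <- sum(tree$edge.length)
    return(matrix(d, 1, 1, dimnames = list(tree$tip.label, tree$tip.label)))
  }
  ape::vcv.phylo(tree)
}

#' Cumulative root-to-tip branch lengths
#'
#' Sums branch lengths from the root to every tip by explicit traversal of
#' the edge table (independent of [phylo_vcv()], whose diagonal it equals).
#' This is the per-tip rate statistic used for codon- and nucleotide-model
#' gene trees: trees in substitutions per (codon or nucleotide) site yield
#' cumulative substitutions per site.
#'
#' @param tree A validated "phylo" object.
#' @return Named numeric vector of depths, one per tip, in tip-label order.
#' @examples
#' root_to_tip(read_newick("((A:1,B:1):1,C:2);"))  # A=2, B=2, C=2
#' @export
root_to_tip <- function(tree) {
  validate_phylogeny(tree)
  n <- length(tree$tip.label)
  if (n == 1L) {
    out <- sum(tree$edge.length)
    names(out) <- tree$tip.label
    return(out)
  }
  nnode <- tree$Nnode
  depth <- numeric(n + nnode)
  root <- n + 1L
  # preorder: parents appear before children
  ord <- rev(ape::postorder(tree))
  for (k in ord) {
    par <- tree$edge[k, 1L]
    chi <- tree$edge[k, 2L]
    depth[chi] <- depth[par] + tree$edge.length[k]
  }
  out <- depth[seq_len(n)]
  names(out) <- tree$tip.label
  out
}

#' Species relatedness matrix (and inverse) for phylogenetic random effects
#'
#' Builds the phylogenetic covariance among the requested species, optionally
#' rescaled so the maximum diagonal equals 1, and computes its inverse. If the
#' matrix is numerically singular (e.g. effectively identical tips), a ridge
#' `ridge * max(diag)` is added to the diagonal with a warning so downstream
#' samplers stay well-posed.
#'
#' @param tree Species phylogeny containing all modeled species as tips.
#' @param species Optional character vector; the matrix is restricted (by
#'   pruning) to these species. Species absent from the tree are an error.
#' @param normalize Rescale so `max(diag) == 1` (default TRUE).
#' @param ridge Relative ridge added to the diagonal if inversion fails.
#' @return List with elements `A` (covariance), `Ainv` (inverse), `labels`,
#'   and `ridged` (logical), of class "relatedness".
#' @export
relatedness_matrix <- function(tree, species = NULL, normalize = TRUE,
                               ridge = 1e-8) {
  validate_phylogeny(tree)
  if (!is.null(species)) {
    missing_sp <- setdiff(species, tree$tip.label)
    if (length(missing_sp)) {
      stop("species missing from tree: ", paste(missing_sp, collapse = ", "),
           call. = FALSE)
    }
    if (length(species) < length(tree$tip.label)) {
      tree <- prune_tips(tree, species)
    }
  }
  A <- phylo_vcv(tree)
  if (normalize) {
    m <- max(diag(A))
    if (m <= 0) stop("tree has zero depth; cannot normalize", call. = FALSE)
    A <- A / m
  }
  ridged <- FALSE
  Ainv <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
  if (is.null(Ainv)) {
    ridged <- TRUE
    warning("relatedness matrix singular; adding ridge ", ridge,
            " * max(diag) to the diagonal", call. = FALSE)
    diag(A) <- diag(A) + ridge * max(diag(A))
    Ainv <- chol2inv(chol(A))
  }
  dimnames(Ainv) <- dimnames(A)
  structure(list(A = A, Ainv = Ainv, labels = rownames(A), ridged = ridged),
            class = "relatedness")
}

#' Prune a phylogeny to a set of tips
#'
#' Returns the induced subtree on `keep`: unbranched internal nodes are
#' collapsed with their lengths summed, so root-to-tip depths and pairwise
#' covariances of the kept tips are unchanged. Used for taxa-exclusion
#' reruns (e.g. refitting without mormoopids).
#'
#' @param tree A validated "phylo" object.
#' @param keep Non-empty character vector of tip labels to retain.
#' @return The pruned "phylo" object.
#' @export
prune_tips <- function(tree, keep) {
  validate_phylogeny(tree)
  keep <- unique(as.character(keep))
  if (length(keep) == 0L) stop("'keep' must be non-empty", call. = FALSE)
  bad <- setdiff(keep, tree$tip.label)
  if (length(bad)) {
    stop("tips not in tree: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(keep) == length(tree$tip.label)) return(tree)
  if (length(keep) == 1L) {
    # ape cannot represent the 1-tip case via keep.tip; build it directly
    d <- root_to_tip(tree)[[keep]]
    return(read_newick(sprintf("(%s:%.17g);", keep, d)))
  }
  sub <- ape::keep.tip(tree, keep)
  # keep.tip re-roots at the MRCA of `keep`; retain the lost basal path as
  # a single-child root stem so root-to-tip depths stay unchanged
  stem <- root_to_tip(tree)[[keep[1]]] - root_to_tip(sub)[[keep[1]]]
  if (stem > 1e-12) {
    core <- sub(";\\s*$", "", ape::write.tree(sub, digits = 15))
    sub <- read_newick(sprintf("(%s:%.15g);", core, stem))
  }
  sub
}

#' Export a labelled matrix as delimited text
#'
#' @param m Matrix with dimnames (e.g. from [phylo_vcv()]).
#' @param file Output path (tab-separated, header row and label column).
#' @export
write_matrix_tsv <- function(m, file) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
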