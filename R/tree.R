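#' Read and validate a rooted phylogeny from Newick text or a file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contract the rest
#' of the package relies on: a single rooted tree, unique non-empty tip
#' labels, and finite non-negative branch lengths on every edge (the root
#' edge is optional). Internal node labels are accepted but ignored with a
#' warning; NHX-style annotations are not supported.
#'
#' @param text Newick string (use this or `file`).
#' @param file Path to a Newick file.
#' @return An object of class `phylo`.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tree_height(tr)
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick input")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop(sprintf("malformed Newick: %d '(' vs %d ')'", n_open, n_close))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: no tree found")
  validate_tree(tr)
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Validate the structural invariants of a phylogeny
#'
#' Checks tip-label uniqueness, presence and finiteness of branch lengths,
#' and non-negativity. Returns the tree invisibly cleaned of internal node
#' labels (warning if any were present).
#'
#' @param tree A `phylo` object.
#' @return The validated `phylo` object.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labs <- trimws(tree$tip.label)
  if (any(!nzchar(labs))) stop("empty tip label(s) at position(s): ",
                               paste(which(!nzchar(labs)), collapse = ", "))
  dup <- labs[duplicated(labs)]
  if (length(dup)) stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "))
  tree$tip.label <- labs
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; all edges must carry a length")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("non-finite or missing branch length on edge(s): ",
         paste(which(!is.finite(tree$edge.length)), collapse = ", "))
  if (any(tree$edge.length < 0))
    stop("negative branch length on edge(s): ",
         paste(which(tree$edge.length < 0), collapse = ", "))
  if (!is.null(tree$node.label) && any(nzchar(tree$node.label))) {
    warning("internal node labels present; they are ignored")
    tree$node.label <- NULL
  }
  tree
}

#' Root-to-tip depth of every tip
#' @param tree A `phylo` object.
#' @return Named numeric vector of tip depths.
#' @export
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  names(d) <- tree$tip.label
  d
}

#' Height of a tree (maximum root-to-tip path length)
#' @inheritParams tip_depths
#' @export
tree_height <- function(tree) max(tip_depths(tree))

#' Is the tree ultrametric (all tips equidistant from the root)?
#' @inheritParams tip_depths
#' @param tol Absolute tolerance on depth differences.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-8) {
  d <- tip_depths(tree)
  diff(range(d)) <= tol * max(1, max(d))
}

#' Brownian-motion phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the depth of the most recent common ancestor of tips i
#' and j; diagonal entries are root-to-tip path lengths. This is the trait
#' covariance structure implied by Brownian motion on the tree (up to the
#' rate sigma^2).
#'
#' @param tree A `phylo` object.
#' @return Symmetric positive semidefinite matrix with tip labels as
#'   dimnames, in `tree$tip.label` order.
#' @export
tree_vcv <- function(tree) {
  tree <- validate_tree(tree)
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Transform a BM covariance matrix under a named trait-evolution model
#'
#' Given the Brownian covariance `C` of an (ultrametric, for OU) tree, build
#' the among-species covariance implied by one of four models:
#' \describe{
#'   \item{BM}{identity transform.}
#'   \item{lambda}{Pagel's lambda: off-diagonals multiplied by
#'     `lambda` in `[0, 1]`, diagonal unchanged.}
#'   \item{OU}{stationary Ornstein-Uhlenbeck with pull `alpha >= 0`:
#'     entry (i,j) = exp(-2 alpha (T - s_ij)) (1 - exp(-2 alpha s_ij)) / (2 alpha)
#'     where T is tree height and s_ij the MRCA depth. Requires an
#'     ultrametric covariance. alpha = 0 returns BM.}
#'   \item{EB}{early burst with rate-decay `a <= 0`: node depths remapped by
#'     d' = (exp(a d) - 1) / a, applied entrywise. a = 0 returns BM.}
#' }
#' The multiplicative rate sigma^2 is not applied here; it scales the result
#' wherever a likelihood is formed.
#'
#' @param C Covariance matrix from [tree_vcv()].
#' @param model One of "BM", "lambda", "OU", "EB".
#' @param params Named list: `lambda`, `alpha` or `a` as the model requires.
#' @param tol Ultrametricity tolerance for OU.
#' @return Transformed covariance matrix (same dimnames).
#' @export
transform_covariance <- function(C, model = c("BM", "lambda", "OU", "EB"),
                                 params = list(), tol = 1e-6) {
  model <- match.arg(model)
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  switch(model,
    BM = C,
    lambda = {
      lam <- params$lambda
      if (is.null(lam) || !is.finite(lam) || lam < 0 || lam > 1)
        stop("lambda must be in [0, 1]")
      d <- diag(C)
      C2 <- C * lam
      diag(C2) <- d
      C2
    },
    OU = {
      alpha <- params$alpha
      if (is.null(alpha) || !is.finite(alpha) || alpha < 0)
        stop("OU alpha must be >= 0")
      d <- diag(C)
      if (diff(range(d)) > tol * max(1, max(d)))
        stop("OU transform requires an ultrametric tree (equal tip depths)")
      if (alpha == 0) return(C)
      Th <- max(d)
      V <- exp(-2 * alpha * (Th - C)) * (1 - exp(-2 * alpha * C)) / (2 * alpha)
      dimnames(V) <- dimnames(C)
      V
    },
    EB = {
      a <- params$a
      if (is.null(a) || !is.finite(a) || a > 0)
        stop("EB rate a must be <= 0")
      if (a == 0) return(C)
      V <- (exp(a * C) - 1) / a
      dimnames(V) <- dimnames(C)
      V
    })
}

#' Match a named trait vector to a tree, pruning unmatched tips
#'
#' Labels are matched exactly after trimming whitespace. Tips without trait
#' values are pruned (reported via message); trait entries without tips are
#' dropped likewise.
#'
#' @param tree A `phylo` object.
#' @param x Named numeric vector of trait values.
#' @return List with elements `tree` and `x`, aligned to `tree$tip.label`.
#' @export
match_tree_data <- function(tree, x) {
  tree <- validate_tree(tree)
  names(x) <- trimws(names(x))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("trait vector must be fully named")
  if (anyNA(x) || any(!is.finite(x))) stop("trait values must be finite")
  common <- intersect(tree$tip.label, names(x))
  if (length(common) < length(tree$tip.label)) {
    drop_tips <- setdiff(tree$tip.label, common)
    message("pruning ", length(drop_tips), " tip(s) without trait data: ",
            paste(utils::head(drop_tips, 5), collapse = ", "),
            if (length(drop_tips) > 5) ", ..." else "")
    if (length(common) < 2) stop("fewer than 2 tips matched between tree and data")
    tree <- ape::drop.tip(tree, drop_tips)
  }
  if (length(common) < length(x))
    message("dropping ", length(x) - length(common), " trait value(s) not in tree")
  list(tree = tree, x = x[tree$tip.label])
}
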