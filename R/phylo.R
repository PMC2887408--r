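#' Read and validate a comparative tree
#'
#' Parses Newick text or a file via \pkg{ape}.  The comparative analyses
#' assume a rooted, fully bifurcating tree; polytomies are rejected rather
#' than arbitrarily resolved, because an arbitrary resolution with unit
#' branch lengths changes the contrasts (use \code{resolve = TRUE} to
#' multifurcate-split with unit branches explicitly).  Absent branch
#' lengths default to one, reflecting ignorance of how evolution proceeds
#' along these lineages.
#'
#' @param source Newick text (contains a parenthesis) or a file path.
#' @param resolve if TRUE, resolve polytomies by zero-length splits then
#'   floor all branch lengths at 1 (explicitly opt-in).
#' @return an \pkg{ape} \code{phylo} tree with branch lengths set.
#' @examples
#' tr <- read_tree("((A:1,B:1):1,C:1);")
#' @export
read_tree <- function(source, resolve = FALSE) {
  tree <- if (grepl("(", source, fixed = TRUE))
    ape::read.tree(text = source) else ape::read.tree(source)
  if (is.null(tree)) stop("could not parse Newick input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    if (!resolve)
      stop("tree contains a polytomy (or an unrooted basal trichotomy); ",
           "supply a rooted, fully bifurcating tree or set resolve = TRUE ",
           "to split polytomies (unit branches)")
    tree <- ape::multi2di(tree)
    if (!is.null(tree$edge.length)) tree$edge.length <- pmax(tree$edge.length, 1)
  }
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(1, nrow(tree$edge))
  if (any(is.na(tree$edge.length)))
    tree$edge.length[is.na(tree$edge.length)] <- 1
  if (any(tree$edge.length <= 0))
    stop("branch lengths must be positive")
  tree
}

#' Felsenstein's phylogenetically independent contrasts
#'
#' Post-order pruning: at each internal node joining subtrees i and j with
#' trait values \eqn{x_i, x_j} and accumulated variances \eqn{v_i, v_j},
#' the standardized contrast is \eqn{(x_i - x_j)/\sqrt{v_i + v_j}}, the
#' ancestral value is the \eqn{1/v}-weighted average, and the node's own
#' branch is extended by \eqn{v_i v_j/(v_i + v_j)}.  A tree with n tips
#' yields n - 1 contrasts.
#'
#' @param tree a rooted bifurcating \code{phylo} tree (see
#'   \code{\link{read_tree}}).
#' @param trait named numeric vector of tip values (names = tip labels).
#' @return a data.frame of class \code{"contrast_set"}: \code{node},
#'   \code{raw_difference}, \code{variance} (the standardizing sum
#'   \eqn{v_i + v_j}), \code{contrast}; attribute \code{"ancestral"} holds
#'   the node trait estimates.
#' @examples
#' tr <- read_tree("((A:1,B:1):1,(C:1,D:1):1);")
#' independent_contrasts(tr, c(A = 0, B = 2, C = 1, D = 5))
#' @export
independent_contrasts <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree)) stop("tree must be fully bifurcating")
  ntip <- length(tree$tip.label)
  missing_tips <- setdiff(tree$tip.label, names(trait))
  if (length(missing_tips))
    stop("missing trait value for tip(s): ",
         paste(missing_tips, collapse = ", "))
  if (any(is.na(trait[tree$tip.label])))
    stop("missing trait value for tip(s): ",
         paste(tree$tip.label[is.na(trait[tree$tip.label])], collapse = ", "))

  tree <- ape::reorder.phylo(tree, "postorder")
  nnode <- tree$Nnode
  x <- c(as.numeric(trait[tree$tip.label]), rep(NA_real_, nnode))
  # v[k]: branch length above node k, extended during pruning
  v <- rep(NA_real_, ntip + nnode)
  v[tree$edge[, 2L]] <- tree$edge.length
  root <- ntip + 1L
  if (is.na(v[root])) v[root] <- 0

  out_node <- integer(nnode)
  raw <- var_sum <- contrast <- numeric(nnode)
  k <- 0L
  # postorder edges come in sibling pairs for a binary tree
  for (e in seq(1L, nrow(tree$edge), by = 2L)) {
    parent <- tree$edge[e, 1L]
    ci <- tree$edge[e, 2L]
    cj <- tree$edge[e + 1L, 2L]
    stopifnot(tree$edge[e + 1L, 1L] == parent)
    vi <- v[ci]; vj <- v[cj]
    k <- k + 1L
    out_node[k] <- parent
    raw[k] <- x[ci] - x[cj]
    var_sum[k] <- vi + vj
    contrast[k] <- raw[k] / sqrt(vi + vj)
    x[parent] <- (x[ci] / vi + x[cj] / vj) / (1 / vi + 1 / vj)
    v[parent] <- v[parent] + vi * vj / (vi + vj)
  }
  res <- data.frame(node = out_node, raw_difference = raw,
                    variance = var_sum, contrast = contrast)
  class(res) <- c("contrast_set", "data.frame")
  attr(res, "ancestral") <- x[(ntip + 1L):(ntip + nnode)]
  res
}

#' Correlate two traits through independent contrasts
#'
#' Computes standardized contrasts of both traits on the same tree, fixes
#' the sign convention by making each x-contrast positive (flipping the
#' paired y-contrast with it), then runs the randomization correlation and
#' regression through the origin on the paired contrasts.
#'
#' @param tree a rooted bifurcating \code{phylo}.
#' @param trait_x,trait_y named numeric tip-value vectors.
#' @param B randomization iterations.
#' @param seed integer seed.
#' @return list with \code{contrasts} (data.frame of paired signed
#'   contrasts), \code{correlation} (a \code{randomization_result}) and
#'   \code{origin} (the regression-through-origin summary).
#' @export
contrast_correlation <- function(tree, trait_x, trait_y, B = 100000L, seed) {
  cx <- independent_contrasts(tree, trait_x)
  cy <- independent_contrasts(tree, trait_y)
  stopifnot(identical(cx$node, cy$node))
  flip <- ifelse(cx$contrast < 0, -1, 1)
  xs <- cx$contrast * flip
  ys <- cy$contrast * flip
  list(contrasts = data.frame(node = cx$node, x = xs, y = ys),
       correlation = randomization_correlation(xs, ys, B = B, seed = seed),
       origin = regression_through_origin(xs, ys))
}
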