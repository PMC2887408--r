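#' Within-host dominance hierarchy
#'
#' Dominant trematode species kill subordinate species when both infect the
#' same snail.  The hierarchy is a strict, acyclic (but not necessarily
#' transitive) relation over species codes: real guilds are "largely"
#' hierarchical, with exceptions such as tissue-refuge species that tolerate
#' co-infection with some ranks.  Tolerated pairs are represented simply by
#' omitting the edge.
#'
#' @param edges a two-column data.frame or matrix, columns
#'   \code{killer}, \code{victim} (order matters: killer dominates victim).
#' @param species optional character vector of all species codes, including
#'   species appearing in no edge.
#' @return an object of class \code{"dominance_hierarchy"}.
#' @examples
#' h <- dominance_hierarchy(data.frame(killer = "hima", victim = "euha"))
#' dominates(h, "hima", "euha")
#' @export
dominance_hierarchy <- function(edges, species = NULL) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    stopifnot(ncol(edges) >= 2L)
    edges <- data.frame(killer = as.character(edges[[1L]]),
                        victim = as.character(edges[[2L]]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(killer = character(), victim = character(),
                        stringsAsFactors = FALSE)
  }
  if (any(edges$killer == edges$victim))
    stop("a species cannot dominate itself")
  edges <- unique(edges)
  sp <- sort(unique(c(edges$killer, edges$victim, species)))
  h <- structure(list(species = sp, edges = edges),
                 class = "dominance_hierarchy")
  cyc <- .find_cycle(h)
  if (!is.null(cyc))
    stop("dominance relation contains a cycle: ",
         paste(cyc, collapse = " > "))
  h
}

# depth-first search for a directed cycle; returns the cycle path or NULL
.find_cycle <- function(h) {
  adj <- split(h$edges$victim, factor(h$edges$killer, levels = h$species))
  state <- stats::setNames(rep(0L, length(h$species)), h$species) # 0 new, 1 open, 2 done
  path <- character()
  visit <- function(v) {
    if (state[[v]] == 1L) return(c(path[which(path == v)[1L]:length(path)], v))
    if (state[[v]] == 2L) return(NULL)
    state[[v]] <<- 1L
    path <<- c(path, v)
    for (w in adj[[v]]) {
      res <- visit(w)
      if (!is.null(res)) return(res)
    }
    path <<- path[-length(path)]
    state[[v]] <<- 2L
    NULL
  }
  for (v in h$species) {
    res <- visit(v)
    if (!is.null(res)) return(res)
  }
  NULL
}

#' @export
print.dominance_hierarchy <- function(x, ...) {
  cat(sprintf("Dominance hierarchy: %d species, %d killer->victim edges\n",
              length(x$species), nrow(x$edges)))
  invisible(x)
}

#' Does species a kill species b in co-infection?
#'
#' @param h a \code{\link{dominance_hierarchy}}.
#' @param a,b species codes (\code{b} may be a vector).
#' @return logical.
#' @export
dominates <- function(h, a, b) {
  stopifnot(inherits(h, "dominance_hierarchy"))
  paste(a, b) %in% paste(h$edges$killer, h$edges$victim)
}

#' Species that dominate a focal species
#'
#' @param h a \code{\link{dominance_hierarchy}}.
#' @param focal a species code.
#' @return character vector of codes of species that kill \code{focal}.
#' @export
dominants_of <- function(h, focal) {
  stopifnot(inherits(h, "dominance_hierarchy"))
  unique(h$edges$killer[h$edges$victim == focal])
}

#' Read a dominance hierarchy from a delimited edge list
#'
#' The file must have a header and two columns, killer then victim.
#'
#' @param path path to a delimited text file.
#' @param sep field separator (default comma).
#' @inheritParams dominance_hierarchy
#' @return a \code{\link{dominance_hierarchy}}.
#' @export
read_dominance <- function(path, sep = ",", species = NULL) {
  edges <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  dominance_hierarchy(edges, species = species)
}

#' Write a dominance hierarchy edge list
#'
#' @param h a \code{\link{dominance_hierarchy}}.
#' @param path output path.
#' @param sep field separator (default comma).
#' @export
write_dominance <- function(h, path, sep = ",") {
  stopifnot(inherits(h, "dominance_hierarchy"))
  utils::write.table(h$edges, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
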