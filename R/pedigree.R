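#' Family pedigrees and genetic coefficients
#'
#' A pedigree is a directed acyclic family graph in which each member has
#' zero, one or two recorded parents and an affected flag. The genetic
#' coefficient between two members is `(1/2)^M` along a direct line of
#' descent with `M` generation steps, and otherwise the sum over their
#' most-recent common ancestors `N` of `k(X, N) * k(Y, N)`. Inbred
#' pedigrees (a member whose parents are related) are rejected, because
#' the most-recent-common-ancestor form is not well defined under
#' inbreeding.
#'
#' @name pedigree-module
NULL

#' Construct and validate a pedigree
#'
#' @param members data frame with columns `id`, `father`, `mother`
#'   (identifiers, `"0"` meaning unknown parent) and `affected` (0/1).
#'   Extra columns are kept.
#' @return object of class `pedigree`: the validated `members` table plus
#'   internal parent lookup.
#' @examples
#' trio <- data.frame(id = c("F", "M", "C"), father = c("0", "0", "F"),
#'                    mother = c("0", "0", "M"), affected = c(1, 0, 0))
#' ped <- pedigree(trio)
#' genetic_coefficient(ped, "F", "C")
#' @export
pedigree <- function(members) {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  need <- c("id", "father", "mother", "affected")
  if (!all(need %in% names(members))) {
    stop("pedigree table needs columns id, father, mother, affected",
         call. = FALSE)
  }
  for (col in c("id", "father", "mother")) {
    members[[col]] <- as.character(members[[col]])
  }
  members$affected <- as.integer(members$affected)
  if (anyDuplicated(members$id)) {
    stop("duplicate member ids in pedigree", call. = FALSE)
  }
  known <- c("0", members$id)
  bad <- setdiff(c(members$father, members$mother), known)
  if (length(bad)) {
    stop(sprintf("parent id(s) not in pedigree: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  ped <- structure(
    list(members = members,
         father = stats::setNames(members$father, members$id),
         mother = stats::setNames(members$mother, members$id)),
    class = "pedigree"
  )
  # acyclicity + no-inbreeding: walk every member's ancestor paths,
  # counting path multiplicity; a repeat on one walk is a cycle or loop
  for (id in members$id) {
    seen <- character(0)
    stack <- id
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (cur %in% seen && cur != id) {
        stop(sprintf(
          "pedigree is inbred or cyclic at member %s (ancestor %s reachable by more than one path); inbred pedigrees are not supported",
          id, cur), call. = FALSE)
      }
      if (cur != id) seen <- c(seen, cur)
      for (p in c(ped$father[[cur]], ped$mother[[cur]])) {
        if (p != "0") {
          if (p == id) {
            stop(sprintf("pedigree contains a cycle through member %s", id),
                 call. = FALSE)
          }
          stack <- c(stack, p)
        }
      }
    }
  }
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree: %d members, %d affected>\n",
              nrow(x$members), sum(x$members$affected)))
  invisible(x)
}

check_member <- function(ped, id, field) {
  id <- as.character(id)
  if (!id %in% ped$members$id) {
    stop(sprintf("unknown pedigree member `%s` (argument %s)", id, field),
         call. = FALSE)
  }
  id
}

parents_of <- function(ped, id) {
  p <- c(ped$father[[id]], ped$mother[[id]])
  p[p != "0"]
}

# set of ancestors of `id`, including `id` itself
ancestors_incl_self <- function(ped, id) {
  out <- character(0)
  stack <- id
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (!cur %in% out) {
      out <- c(out, cur)
      stack <- c(stack, parents_of(ped, cur))
    }
  }
  out
}

#' Generation distance along a direct line of descent
#'
#' Number of parent-child links on the recorded path from `descendant` up
#' to `ancestor`; `NA` if `ancestor` is not an ancestor of `descendant`.
#' The distance from a member to itself is 0. In a non-inbred pedigree
#' the path, when it exists, is unique.
#'
#' @param ped a [pedigree].
#' @param ancestor,descendant member ids.
#' @return non-negative integer, or `NA_integer_` when there is no
#'   ancestral path.
#' @export
lineage_distance <- function(ped, ancestor, descendant) {
  stopifnot(inherits(ped, "pedigree"))
  ancestor <- check_member(ped, ancestor, "ancestor")
  descendant <- check_member(ped, descendant, "descendant")
  # breadth-first walk upward from the descendant
  frontier <- descendant
  depth <- 0L
  while (length(frontier)) {
    if (ancestor %in% frontier) return(depth)
    frontier <- unique(unlist(lapply(frontier, parents_of, ped = ped)))
    depth <- depth + 1L
  }
  NA_integer_
}

is_ancestor_of <- function(ped, a, d) {
  md <- lineage_distance(ped, a, d)
  !is.na(md)
}

#' Genetic coefficient along a direct lineage
#'
#' `(1/2)^M` where `M` is the [lineage_distance] between the two members;
#' 1/2 for parent and child, 1 for a member and itself.
#'
#' @param ped a [pedigree].
#' @param X,Y member ids, one an ancestor of the other (or equal).
#' @return coefficient in `[0, 1]`.
#' @export
direct_coefficient <- function(ped, X, Y) {
  stopifnot(inherits(ped, "pedigree"))
  X <- check_member(ped, X, "X")
  Y <- check_member(ped, Y, "Y")
  M <- lineage_distance(ped, X, Y)
  if (is.na(M)) M <- lineage_distance(ped, Y, X)
  if (is.na(M)) {
    stop(sprintf(
      "%s and %s are not in a direct line of descent; use genetic_coefficient(), which handles common-ancestor relationships",
      X, Y), call. = FALSE)
  }
  0.5^M
}

#' Most-recent common ancestors of two members
#'
#' The common ancestors of `X` and `Y` (members count as their own
#' ancestors) none of whose strict descendants is also a common ancestor.
#' For two full siblings this is exactly their two parents; for unrelated
#' founders it is empty.
#'
#' @param ped a [pedigree].
#' @param X,Y member ids.
#' @return character vector of member ids (possibly empty).
#' @export
mrca_pair <- function(ped, X, Y) {
  stopifnot(inherits(ped, "pedigree"))
  X <- check_member(ped, X, "X")
  Y <- check_member(ped, Y, "Y")
  ca <- intersect(ancestors_incl_self(ped, X), ancestors_incl_self(ped, Y))
  if (length(ca) == 0L) return(character(0))
  keep <- vapply(ca, function(a) {
    !any(vapply(setdiff(ca, a), function(other) {
      d <- lineage_distance(ped, a, other)
      !is.na(d) && d > 0L
    }, logical(1)))
  }, logical(1))
  unname(ca[keep])
}

#' Genetic coefficient between two pedigree members
#'
#' If one member is an ancestor of the other (or they are the same
#' member), the direct-lineage form `(1/2)^M` applies. Otherwise the
#' coefficient is the sum over their most-recent common ancestors `N` of
#' `k(X, N) * k(Y, N)` — the two-parent case for full siblings gives
#' `1/4 + 1/4 = 1/2` — and 0 when no common ancestor exists.
#'
#' @param ped a [pedigree].
#' @param X,Y member ids.
#' @return coefficient in `[0, 1]`.
#' @examples
#' ped <- generate_pedigree(3, seed = 7)
#' ids <- ped$members$id
#' genetic_coefficient(ped, ids[1], ids[2])
#' @export
genetic_coefficient <- function(ped, X, Y) {
  stopifnot(inherits(ped, "pedigree"))
  X <- check_member(ped, X, "X")
  Y <- check_member(ped, Y, "Y")
  if (X == Y) return(1)
  if (is_ancestor_of(ped, X, Y) || is_ancestor_of(ped, Y, X)) {
    return(direct_coefficient(ped, X, Y))
  }
  mrcas <- mrca_pair(ped, X, Y)
  if (length(mrcas) == 0L) return(0)
  sum(vapply(mrcas, function(N) {
    direct_coefficient(ped, X, N) * direct_coefficient(ped, Y, N)
  }, numeric(1)))
}

#' Familial diabetes risk of a proband
#'
#' Sum of [genetic_coefficient]s between the proband `R` and every
#' affected member of the pedigree other than `R` itself; 0 when there
#' are no affected relatives. The pedigree gives no rule for combining
#' this with the Diabetes Index, so the two are reported side by side.
#'
#' @param ped a [pedigree].
#' @param R proband id.
#' @return non-negative real.
#' @export
familial_risk <- function(ped, R) {
  stopifnot(inherits(ped, "pedigree"))
  R <- check_member(ped, R, "R")
  affected <- setdiff(ped$members$id[ped$members$affected == 1L], R)
  if (length(affected) == 0L) return(0)
  sum(vapply(affected, function(P) genetic_coefficient(ped, R, P),
             numeric(1)))
}
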