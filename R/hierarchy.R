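#' Standard burden-of-disease age groups
#'
#' The 23 ordered age groups used throughout: three neonatal/post-neonatal
#' groups under age 1, ages 1-4, eighteen 5-year groups from 5-9 to 90-94,
#' and a terminal open-ended group at 95+. Intervals are closed-open.
#'
#' @return A tibble with columns `age` (0-based group index), `label`, and
#'   `midpoint` (approximate midpoint in years, used for age offsets and the
#'   packaged standard tables).
#' @export
age_groups <- function() {
  labels <- c(
    "0-6 days", "7-27 days", "28-364 days", "1-4 years",
    paste(seq(5, 90, by = 5), seq(9, 94, by = 5), sep = "-"),
    "95 plus"
  )
  midpoints <- c(
    3.5 / 365, 17 / 365, 196 / 365, 3,
    seq(7.5, 92.5, by = 5),
    97.5
  )
  tibble::tibble(age = seq_along(labels) - 1L, label = labels, midpoint = midpoints)
}

#' Construct a cause hierarchy
#'
#' A 4-level, mutually exclusive and collectively exhaustive cause tree with
#' an attached set of garbage codes. Garbage codes are not causes: they are
#' ill-defined or intermediate codes whose deaths must be redistributed.
#' A garbage code's `level` records the hierarchy span it redistributes
#' across; levels 1-2 are "major" garbage.
#'
#' @param causes Data frame with columns `cause` (character id), `parent`
#'   (character id or NA for top-level causes), `level` (integer, 1-4).
#' @param garbage Data frame with columns `code` and `level` (1-4), or NULL
#'   for a hierarchy without garbage codes.
#' @return An object of class `cause_hierarchy`.
#' @export
cause_hierarchy <- function(causes, garbage = NULL) {
  causes <- tibble::as_tibble(causes)
  stopifnot(all(c("cause", "parent", "level") %in% names(causes)))
  if (anyDuplicated(causes$cause) > 0) {
    stop("duplicate cause ids: ",
         paste(unique(causes$cause[duplicated(causes$cause)]), collapse = ", "))
  }
  known <- causes$cause
  bad_parent <- !is.na(causes$parent) & !(causes$parent %in% known)
  if (any(bad_parent)) {
    stop("unknown parent ids: ", paste(causes$parent[bad_parent], collapse = ", "))
  }
  if (!all(causes$level %in% 1:4)) stop("cause levels must be in 1..4")
  if (is.null(garbage)) {
    garbage <- tibble::tibble(code = character(), level = integer())
  }
  garbage <- tibble::as_tibble(garbage)
  stopifnot(all(c("code", "level") %in% names(garbage)))
  if (any(garbage$code %in% known)) {
    stop("garbage codes overlap cause ids: ",
         paste(intersect(garbage$code, known), collapse = ", "))
  }
  structure(list(causes = causes, garbage = garbage), class = "cause_hierarchy")
}

#' @export
print.cause_hierarchy <- function(x, ...) {
  cat("<cause_hierarchy> ", nrow(x$causes), " causes (",
      sum(is_leaf_cause(x, x$causes$cause)), " most-detailed), ",
      nrow(x$garbage), " garbage codes\n", sep = "")
  invisible(x)
}

#' Most-detailed (leaf) causes of a hierarchy
#' @param hierarchy A `cause_hierarchy`.
#' @return Character vector of leaf cause ids.
#' @export
leaf_causes <- function(hierarchy) {
  hierarchy$causes$cause[is_leaf_cause(hierarchy, hierarchy$causes$cause)]
}

is_leaf_cause <- function(hierarchy, cause) {
  !(cause %in% hierarchy$causes$parent)
}

#' Classify a vector of recorded codes
#'
#' @param codes Character vector of cause codes as they appear in records.
#' @param hierarchy A `cause_hierarchy`.
#' @return Character vector with values "cause", "major_garbage",
#'   "minor_garbage"; unresolvable codes raise an error listing them.
#' @export
classify_codes <- function(codes, hierarchy) {
  out <- rep(NA_character_, length(codes))
  out[codes %in% hierarchy$causes$cause] <- "cause"
  major <- hierarchy$garbage$code[hierarchy$garbage$level <= 2]
  minor <- hierarchy$garbage$code[hierarchy$garbage$level > 2]
  out[codes %in% major] <- "major_garbage"
  out[codes %in% minor] <- "minor_garbage"
  if (anyNA(out)) {
    stop("unresolvable codes: ", paste(unique(codes[is.na(out)]), collapse = ", "))
  }
  out
}

#' Level of each cause id
#' @keywords internal
cause_level <- function(codes, hierarchy) {
  hierarchy$causes$level[match(codes, hierarchy$causes$cause)]
}

#' A small synthetic cause hierarchy
#'
#' Builds the default desk-scale tree: three Level 1 groups (CMNN diseases,
#' non-communicable diseases, injuries), two Level 2 groups each, and
#' `n_leaves` Level 3 most-detailed causes spread across them, plus one major
#' and one minor garbage code.
#'
#' @param n_leaves Number of most-detailed causes (>= 6).
#' @return A `cause_hierarchy`.
#' @export
toy_hierarchy <- function(n_leaves = 12) {
  stopifnot(n_leaves >= 6)
  l1 <- c("cmnn", "ncd", "inj")
  l2 <- paste0(rep(l1, each = 2), c("_a", "_b"))
  leaf_parent <- rep_len(l2, n_leaves)
  leaves <- paste0(leaf_parent, "_", stats::ave(seq_len(n_leaves), leaf_parent, FUN = seq_along))
  causes <- tibble::tibble(
    cause = c(l1, l2, leaves),
    parent = c(rep(NA_character_, 3), rep(l1, each = 2), leaf_parent),
    level = c(rep(1L, 3), rep(2L, 6), rep(3L, n_leaves))
  )
  garbage <- tibble::tibble(
    code = c("gc_major", "gc_minor"),
    level = c(1L, 3L)
  )
  cause_hierarchy(causes, garbage)
}

#' Level 1 group of each most-detailed cause
#' @keywords internal
cause_group <- function(codes, hierarchy) {
  parent_of <- stats::setNames(hierarchy$causes$parent, hierarchy$causes$cause)
  level_of <- stats::setNames(hierarchy$causes$level, hierarchy$causes$cause)
  vapply(codes, function(cc) {
    while (!is.na(parent_of[[cc]])) cc <- parent_of[[cc]]
    cc
  }, character(1), USE.NAMES = FALSE)
}
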