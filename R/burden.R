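#' Synthetic standard life table
#'
#' A swappable stand-in for the reference life table used in YLL
#' computation: standard life expectancy is 86.6 years at birth and
#' strictly decreasing in age, following a smooth exponential decline to
#' about 4 remaining years in the terminal open-ended group. Replace with
#' [read_life_table()] to use an external table.
#'
#' @return Tibble with `age` (group index) and `sle` (standard life
#'   expectancy, years).
#' @export
standard_life_table <- function() {
  a <- age_groups()
  tibble::tibble(age = a$age, sle = 86.6 * exp(-0.031 * a$midpoint))
}

#' Synthetic standard population
#'
#' Normalised age weights approximating a young world standard population;
#' a swappable stand-in for the reference standard. Weights are
#' non-negative and sum to 1.
#'
#' @return Tibble with `age` and `weight`.
#' @export
standard_population <- function() {
  a <- age_groups()
  span <- c(7 / 365, 21 / 365, 337 / 365, 4, rep(5, 18), 10)
  w <- span * exp(-a$midpoint / 40)
  tibble::tibble(age = a$age, weight = w / sum(w))
}

#' Read a two-column life table or standard population file
#'
#' @param path Delimited text with columns `age` and `sle` (life table) or
#'   `age` and `weight` (standard population).
#' @export
read_life_table <- function(path) {
  x <- tibble::as_tibble(utils::read.delim(path))
  if (!all(c("age", "sle") %in% names(x))) stop("expected columns age, sle")
  if (any(diff(x$sle[order(x$age)]) >= 0)) {
    stop("standard life expectancy must be strictly decreasing in age")
  }
  x
}

#' @rdname read_life_table
#' @export
read_standard_population <- function(path) {
  x <- tibble::as_tibble(utils::read.delim(path))
  if (!all(c("age", "weight") %in% names(x))) stop("expected columns age, weight")
  if (any(x$weight < 0) || abs(sum(x$weight) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1")
  }
  x
}

#' Years of life lost
#'
#' Each death contributes the standard life expectancy at its age group:
#' `YLL(a) = deaths(a) * SLE(a)`. Operates draw-wise on a `draw_cube`
#' (multiplying every draw in each row by its age's SLE).
#'
#' @param deaths Tibble with `age` and `deaths`, or a `draw_cube` whose key
#'   contains `age`.
#' @param life_table Tibble `age`, `sle`; defaults to the packaged
#'   synthetic standard.
#' @return For a tibble: the input with a `yll` column and the total as
#'   attribute `total`. For a `draw_cube`: a YLL `draw_cube`.
#' @export
ylls <- function(deaths, life_table = standard_life_table()) {
  if (inherits(deaths, "draw_cube")) {
    sle <- life_table$sle[match(deaths$key$age, life_table$age)]
    if (anyNA(sle)) stop("ages outside the life table")
    return(draw_cube(deaths$key, deaths$draws * sle))
  }
  sle <- life_table$sle[match(deaths$age, life_table$age)]
  if (anyNA(sle)) stop("ages outside the life table")
  out <- deaths
  out$yll <- deaths$deaths * sle
  attr(out, "total") <- sum(out$yll)
  out
}

#' Age-standardised rate
#'
#' Weighted average of age-specific rates with fixed standard-population
#' weights; the result is on the same scale as the input rates (use rates
#' per 100 000 for standardised rates per 100 000).
#'
#' @param rates Tibble with `age` and `rate`.
#' @param std_pop Tibble `age`, `weight`; defaults to the packaged
#'   standard. Age sets must match exactly.
#' @return The standardised rate (scalar).
#' @export
age_standardise <- function(rates, std_pop = standard_population()) {
  if (!setequal(rates$age, std_pop$age) || anyDuplicated(rates$age)) {
    stop("age groups of rates and standard population do not align")
  }
  w <- std_pop$weight[match(rates$age, std_pop$age)]
  sum(w * rates$rate)
}

#' Aggregate draws up the cause hierarchy
#'
#' Parent causes are the per-draw sums of their children; applied from the
#' most-detailed level upward, so every hierarchy level is populated and
#' the Level 1 causes together carry the all-cause total.
#'
#' @param draws A `draw_cube` whose `cause` column holds most-detailed
#'   causes only.
#' @param hierarchy A `cause_hierarchy`.
#' @return A `draw_cube` covering every cause in the hierarchy.
#' @export
aggregate_hierarchy <- function(draws, hierarchy) {
  leaves <- leaf_causes(hierarchy)
  orphan <- setdiff(unique(draws$key$cause), leaves)
  if (length(orphan)) {
    stop("causes not most-detailed in the hierarchy: ",
         paste(orphan, collapse = ", "))
  }
  cell_cols <- setdiff(names(draws$key), "cause")
  parent_of <- stats::setNames(hierarchy$causes$parent, hierarchy$causes$cause)
  pieces <- list(draws)
  current <- draws
  for (lev in sort(unique(hierarchy$causes$level), decreasing = TRUE)) {
    up <- unname(parent_of[current$key$cause])
    keep <- !is.na(up)
    if (!any(keep)) break
    key <- current$key[keep, , drop = FALSE]
    key$cause <- up[keep]
    g <- do.call(paste, c(key[c(cell_cols, "cause")], sep = "\r"))
    gi <- match(g, unique(g))
    summed <- rowsum(current$draws[keep, , drop = FALSE], gi)
    newkey <- key[!duplicated(gi), , drop = FALSE]
    # rowsum orders rows by group id; realign to first-occurrence order
    current <- draw_cube(newkey,
                         summed[match(unique(gi), as.integer(rownames(summed))), ,
                                drop = FALSE])
    pieces[[length(pieces) + 1]] <- current
  }
  key <- dplyr::bind_rows(lapply(pieces, function(p) p$key))
  draw_cube(key, do.call(rbind, lapply(pieces, function(p) p$draws)))
}

#' Change metrics between two periods
#'
#' Per matched cell and draw: percent change `100 (v2 - v1) / v1` and the
#' annualised rate of change `100 log(v2 / v1) / years`, summarised by
#' [point_and_ui()] with significance from [significant_change()]. Draws
#' with `v1 = 0` (or non-positive ratios for the ARC) are dropped for that
#' cell and counted in `n_dropped`.
#'
#' @param cube_t1,cube_t2 `draw_cube`s with identical keys and draw counts.
#' @param years Elapsed years (> 0).
#' @return Key tibble with percent-change and ARC summaries, `direction`,
#'   and `n_dropped`.
#' @export
change_metrics <- function(cube_t1, cube_t2, years) {
  stopifnot(years > 0)
  if (!identical(dim(cube_t1), dim(cube_t2)) ||
      !identical(cube_t1$key, cube_t2$key)) {
    stop("the two periods must share key and draw count")
  }
  v1 <- cube_t1$draws
  v2 <- cube_t2$draws
  bad <- v1 <= 0 | v2 <= 0
  pct <- 100 * (v2 - v1) / v1
  arc <- 100 * log(v2 / v1) / years
  pct[bad] <- NA
  arc[bad] <- NA
  summ <- function(m) {
    t(apply(m, 1, function(x) {
      x <- x[is.finite(x)]
      if (length(x) < 2) return(c(NA, NA, NA))
      c(mean(x), stats::quantile(x, c(0.025, 0.975), type = 7, names = FALSE))
    }))
  }
  sp <- summ(pct)
  sa <- summ(arc)
  out <- cube_t1$key
  out$pct_change <- sp[, 1]; out$pct_lower <- sp[, 2]; out$pct_upper <- sp[, 3]
  out$arc <- sa[, 1]; out$arc_lower <- sa[, 2]; out$arc_upper <- sa[, 3]
  out$direction <- significant_change(v1, v2)
  out$n_dropped <- rowSums(bad)
  out
}
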