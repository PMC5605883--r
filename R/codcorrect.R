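#' Draw cube: cause-specific estimates with posterior draws
#'
#' A compact container for draw-level estimates: a key tibble identifying
#' each cell (any id columns, typically `location`, `year`, `age`, `sex`,
#' and `cause`) and a numeric matrix with one row per cell and one column
#' per draw.
#'
#' @param key Tibble of cell identifiers, one row per cell.
#' @param draws Numeric matrix, `nrow(key)` x number of draws.
#' @return An object of class `draw_cube`.
#' @export
draw_cube <- function(key, draws) {
  key <- tibble::as_tibble(key)
  draws <- as.matrix(draws)
  dimnames(draws) <- NULL
  stopifnot(nrow(key) == nrow(draws), is.numeric(draws))
  if (any(!is.finite(draws))) stop("draws must be finite")
  structure(list(key = key, draws = draws), class = "draw_cube")
}

#' @export
print.draw_cube <- function(x, ...) {
  cat("<draw_cube> ", nrow(x$key), " cells x ", ncol(x$draws), " draws; key: ",
      paste(names(x$key), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.draw_cube <- function(x) c(nrow(x$key), ncol(x$draws))

#' Flatten a draw cube to a long tibble
#' @param x A `draw_cube`.
#' @param ... Unused.
#' @exportS3Method tibble::as_tibble
as_tibble.draw_cube <- function(x, ...) {
  long <- x$key[rep(seq_len(nrow(x$key)), ncol(x$draws)), , drop = FALSE]
  long$draw <- rep(seq_len(ncol(x$draws)), each = nrow(x$key))
  long$value <- as.vector(x$draws)
  long
}

#' Write / read a draw cube as delimited text
#'
#' The key columns are followed by `draw_1 ... draw_N`.
#' @param x A `draw_cube`.
#' @param path File path.
#' @export
write_draw_cube <- function(x, path) {
  m <- as.data.frame(x$draws)
  names(m) <- paste0("draw_", seq_len(ncol(m)))
  utils::write.table(cbind(as.data.frame(x$key), m), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_draw_cube
#' @export
read_draw_cube <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  dc <- grepl("^draw_", names(df))
  draw_cube(df[, !dc, drop = FALSE], as.matrix(df[, dc, drop = FALSE]))
}

cell_index <- function(key, cols) {
  interaction(key[, cols, drop = FALSE], drop = TRUE, lex.order = TRUE)
}

#' Rescale cause-specific draws to the all-cause envelope
#'
#' Within each location-year-age-sex cell and each draw, every cause is
#' multiplied by `envelope / sum(causes)`, so the corrected causes sum to
#' the envelope draw exactly. Draws are matched positionally (draw i of the
#' causes with draw i of the envelope) so correlation propagates. Cells
#' where every cause is zero but the envelope is positive raise an error:
#' no silent imputation.
#'
#' @param cause_draws A `draw_cube` over most-detailed, mutually exclusive
#'   causes; the key must contain a `cause` column.
#' @param envelope A `draw_cube` of all-cause deaths keyed by the remaining
#'   cell columns, with the same number of draws.
#' @return A corrected `draw_cube` with the same key as `cause_draws`.
#' @export
rescale_draws <- function(cause_draws, envelope) {
  stopifnot(inherits(cause_draws, "draw_cube"), inherits(envelope, "draw_cube"))
  if (ncol(cause_draws$draws) != ncol(envelope$draws)) {
    stop("draw counts differ between causes and envelope")
  }
  cell_cols <- setdiff(names(cause_draws$key), "cause")
  stopifnot("cause" %in% names(cause_draws$key),
            all(cell_cols %in% names(envelope$key)))
  ck <- do.call(paste, c(cause_draws$key[cell_cols], sep = "\r"))
  ek <- do.call(paste, c(envelope$key[cell_cols], sep = "\r"))
  g <- match(ck, ek)
  if (anyNA(g)) stop("envelope missing cells: ", unique(ck[is.na(g)])[1])
  sums <- rowsum(cause_draws$draws, group = g)
  env <- envelope$draws[as.integer(rownames(sums)), , drop = FALSE]
  bad <- sums == 0 & env > 0
  if (any(bad)) {
    i <- which(rowSums(bad) > 0)[1]
    cell <- ek[as.integer(rownames(sums))[i]]
    stop("all causes are zero but the envelope is positive in cell ",
         gsub("\r", "/", cell))
  }
  scale <- env / sums
  scale[sums == 0] <- 1
  gi <- match(g, as.integer(rownames(sums)))
  draw_cube(cause_draws$key, cause_draws$draws * scale[gi, , drop = FALSE])
}

#' Point estimate and 95% uncertainty interval from draws
#'
#' The point estimate is the mean of the draws; the uncertainty interval is
#' the 2.5th and 97.5th percentiles, computed with linear interpolation
#' between order statistics (R quantile type 7).
#'
#' @param draws Numeric vector of draws, or a `draw_cube` (summarised per
#'   cell).
#' @return For a vector: a tibble with `mean`, `lower`, `upper`. For a
#'   `draw_cube`: the key tibble with those columns appended.
#' @export
point_and_ui <- function(draws) {
  if (inherits(draws, "draw_cube")) {
    q <- t(apply(draws$draws, 1, stats::quantile, probs = c(0.025, 0.975),
                 type = 7, names = FALSE))
    out <- draws$key
    out$mean <- rowMeans(draws$draws)
    out$lower <- q[, 1]
    out$upper <- q[, 2]
    return(out)
  }
  draws <- as.numeric(draws)
  if (length(draws) == 0) stop("empty draw vector")
  if (length(draws) < 2) stop("at least 2 draws are required")
  q <- stats::quantile(draws, probs = c(0.025, 0.975), type = 7, names = FALSE)
  tibble::tibble(mean = mean(draws), lower = q[1], upper = q[2])
}

#' Significance of change between two sets of draws
#'
#' A change is statistically significant when the posterior probability of
#' an increase (or decrease) is at least 95%, i.e. when the quantity moved
#' in that direction in at least 95% of positionally matched draws.
#'
#' @param draws_t1,draws_t2 Numeric vectors (or matrices with cells in rows)
#'   of equal draw count, matched by index.
#' @return `"increase"`, `"decrease"`, or `"not significant"` (vector when
#'   matrices are given).
#' @export
significant_change <- function(draws_t1, draws_t2, level = 0.95) {
  if (is.null(dim(draws_t1))) draws_t1 <- matrix(draws_t1, nrow = 1)
  if (is.null(dim(draws_t2))) draws_t2 <- matrix(draws_t2, nrow = 1)
  if (!all(dim(draws_t1) == dim(draws_t2))) {
    stop("draw counts must match between the two periods")
  }
  p_up <- rowMeans(draws_t2 > draws_t1)
  p_down <- rowMeans(draws_t2 < draws_t1)
  out <- rep("not significant", nrow(draws_t1))
  out[p_up >= level] <- "increase"
  out[p_down >= level] <- "decrease"
  out
}
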