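#' Construct an item bank for the partial credit model
#'
#' An item bank holds the calibration of a polytomous instrument: the
#' `J x (M-1)` matrix of category thresholds `delta_jl` on the logit scale.
#' The item location `delta_j` is the mean of the item's thresholds and is
#' computed, not stored independently.
#'
#' @param thresholds Numeric matrix with one row per item and one column per
#'   category threshold (so `M - 1` columns for items with `M` response
#'   categories, responses coded `0..M-1`). All entries must be finite.
#'
#' @return An object of class `item_bank`: a list with elements `J`, `M`,
#'   `thresholds` (the input matrix) and `locations` (row means).
#' @seealso [make_archetype_bank()], [write_item_bank()]
#' @export
#' @examples
#' b <- item_bank(rbind(c(-1, 0), c(0, 1)))
#' b$locations
item_bank <- function(thresholds) {
  thresholds <- as.matrix(thresholds)
  storage.mode(thresholds) <- "double"
  if (nrow(thresholds) < 1L || ncol(thresholds) < 1L)
    stop("'thresholds' must have at least one row and one column")
  if (!all(is.finite(thresholds)))
    stop("all category thresholds must be finite")
  dimnames(thresholds) <- list(
    paste0("item", seq_len(nrow(thresholds))),
    paste0("delta_", seq_len(ncol(thresholds)))
  )
  structure(
    list(
      J = nrow(thresholds),
      M = ncol(thresholds) + 1L,
      thresholds = thresholds,
      locations = rowMeans(thresholds)
    ),
    class = "item_bank"
  )
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("Partial credit model item bank: %d items, %d categories (0..%d)\n",
              x$J, x$M, x$M - 1L))
  print(round(cbind(location = x$locations, x$thresholds), 4))
  invisible(x)
}

#' Build one of the two archetype item banks
#'
#' Two archetypes of PRO instruments are covered. In the first, item
#' locations are tightly packed (regularly spaced from -0.25 to 0.25) with
#' widely dispersed category thresholds (normal-percentile offsets, SD 2.5)
#' -- the "parallel items" pattern typical of instruments developed under
#' classical test theory. In the second, item locations span the continuum
#' (regularly spaced from -1 to 1) with tight thresholds (SD 1.5) -- the
#' "item hierarchy" pattern typical of Rasch-built instruments.
#'
#' Thresholds for item `j` are `delta_j + s * qnorm(q)` with `q = (1/3, 2/3)`
#' for 3 response categories and `q = (0.2, 0.4, 0.6, 0.8)` for 5. Finally
#' all thresholds are shifted by a common constant so that their grand mean
#' is exactly 0, anchoring the origin of the latent scale (for the default
#' exact-percentile offsets the shift is zero by symmetry).
#'
#' @param J Number of items: 4, 7 or 10.
#' @param M Number of response categories: 3 or 5.
#' @param archetype 1 (packed locations, dispersed thresholds) or
#'   2 (dispersed locations, tight thresholds).
#' @param percentiles `"exact"` (default) places the 3-category thresholds at
#'   the exact 1/3 and 2/3 quantiles of the normal; `"literal"` uses 0.33 and
#'   0.66 instead (slightly asymmetric). Ignored for `M = 5`.
#'
#' @return An [item_bank()].
#' @export
#' @examples
#' make_archetype_bank(4, 3, archetype = 2)
make_archetype_bank <- function(J, M, archetype,
                                percentiles = c("exact", "literal")) {
  percentiles <- match.arg(percentiles)
  if (!(length(J) == 1L && J %in% c(4, 7, 10)))
    stop("'J' must be one of 4, 7, 10")
  if (!(length(M) == 1L && M %in% c(3, 5)))
    stop("'M' must be one of 3, 5")
  if (!(length(archetype) == 1L && archetype %in% c(1, 2)))
    stop("'archetype' must be 1 or 2")

  loc <- if (archetype == 1) seq(-0.25, 0.25, length.out = J)
         else seq(-1, 1, length.out = J)
  s <- if (archetype == 1) 2.5 else 1.5
  q <- if (M == 3) {
    if (percentiles == "exact") c(1, 2) / 3 else c(0.33, 0.66)
  } else {
    c(0.2, 0.4, 0.6, 0.8)
  }
  thr <- outer(loc, s * qnorm(q), "+")
  thr <- thr - mean(thr)   # grand mean of all delta_jl set to 0
  item_bank(thr)
}

#' Partial credit model category probabilities
#'
#' Evaluates `P(X = k | theta)` for `k = 0..M-1` for a single item with the
#' given category thresholds, where the unnormalized log-probability of
#' category `k` is `k * theta - sum(delta[1:k])` (empty sum for `k = 0`).
#' Computation is carried out in log space with max-subtraction, so extreme
#' latent trait values do not overflow.
#'
#' @param theta Latent trait value(s), finite. May be a vector.
#' @param thresholds Numeric vector of `M - 1` finite category thresholds for
#'   one item.
#'
#' @return If `theta` is scalar, a probability vector of length `M`;
#'   otherwise a `length(theta) x M` matrix with one row per theta.
#' @export
#' @examples
#' category_probabilities(0, c(0, 0))       # uniform over 3 categories
#' category_probabilities(1, c(-0.5, 0.5))
category_probabilities <- function(theta, thresholds) {
  if (!all(is.finite(theta))) stop("'theta' must be finite")
  if (!all(is.finite(thresholds))) stop("'thresholds' must be finite")
  M <- length(thresholds) + 1L
  cum <- c(0, cumsum(thresholds))
  lg <- outer(as.numeric(theta), 0:(M - 1L)) -
    matrix(cum, nrow = length(theta), ncol = M, byrow = TRUE)
  mx <- do.call(pmax, as.data.frame(lg))
  p <- exp(lg - mx)
  p <- p / rowSums(p)
  if (length(theta) == 1L) drop(p) else p
}

#' Expected total score of an instrument at a latent trait value
#'
#' Sums `E(X_j | theta)` over the items of a bank; strictly increasing in
#' `theta` with range `(0, J * (M - 1))`.
#'
#' @param theta Latent trait value(s), finite.
#' @param bank An [item_bank()].
#' @return Numeric vector of expected total scores, one per `theta`.
#' @export
expected_score <- function(theta, bank) {
  stopifnot(inherits(bank, "item_bank"))
  if (!all(is.finite(theta))) stop("'theta' must be finite")
  k <- 0:(bank$M - 1L)
  out <- numeric(length(theta))
  for (j in seq_len(bank$J)) {
    p <- category_probabilities(theta, bank$thresholds[j, ])
    out <- out + if (is.matrix(p)) drop(p %*% k) else sum(p * k)
  }
  out
}

#' Read and write item banks as plain tab-separated tables
#'
#' The on-disk format has one row per item with columns `item`, `location`
#' and `delta_1 .. delta_{M-1}`; it is the hand-off format between a
#' calibration fit and an anchored trial analysis, and the format for
#' user-supplied banks.
#'
#' @param bank An [item_bank()].
#' @param file Path to write to / read from.
#' @return `write_item_bank()` returns `file` invisibly; `read_item_bank()`
#'   returns an [item_bank()].
#' @export
write_item_bank <- function(bank, file) {
  stopifnot(inherits(bank, "item_bank"))
  df <- data.frame(item = seq_len(bank$J),
                   location = bank$locations,
                   bank$thresholds,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE, check.names = FALSE)
  cols <- grep("^delta_", names(df))
  if (length(cols) == 0L) stop("no 'delta_*' columns found in ", file)
  item_bank(as.matrix(df[, cols, drop = FALSE]))
}
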