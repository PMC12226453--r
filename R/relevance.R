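#' Per-slice attribution map for the survival network
#'
#' Signed per-pixel relevance of a slice for the network's predicted
#' survival at one grid interval. The sign convention follows the survivor
#' output: positive relevance means the pixel pushes predicted survival up
#' (lower PIRA risk); negative relevance pushes it down (higher risk).
#'
#' The reference backend is gradient x input with a zero baseline,
#' computed by exact backpropagation of \eqn{\partial S_k / \partial x}
#' through the network (for the survivor \eqn{S_k = \prod_{j \le k}
#' (1-h_j)}, the gradient at the pre-sigmoid outputs is \eqn{-S_k h_j} for
#' \eqn{j \le k}). The backend is pluggable: a Shapley-value style deep
#' attribution can be supplied as a function `(model, slice, interval) ->
#' map` without changing any downstream step.
#'
#' @param model A fitted [pira_dsn()].
#' @param slice One `(H, W, 2)` slice array.
#' @param output_interval Grid interval of the survivor output to explain
#'   (default 1, the first-interval probability used in the headline
#'   threshold analysis).
#' @param backend `"gradxinput"` (default), `"gradient"`, or a function.
#' @return A numeric `(H, W, 2)` array of signed relevance.
#' @export
attribute <- function(model, slice, output_interval = 1L,
                      backend = "gradxinput") {
  stopifnot(inherits(model, "pira_dsn"))
  if (is.function(backend)) return(backend(model, slice, output_interval))
  backend <- match.arg(backend, c("gradxinput", "gradient"))
  k <- as.integer(output_interval)
  stopifnot(k >= 1, k <= model$grid$n_intervals)
  d <- dim(slice)
  stopifnot(length(d) == 3)
  X <- array(slice, c(1, d))
  fw <- net_forward(model$net, X, keep_cache = TRUE)
  h <- pmin(pmax(fw$h, 1e-7), 1 - 1e-7)
  Sk <- prod(1 - h[1, seq_len(k)])
  # dS_k/dz_j = -S_k * h_j for j <= k, 0 otherwise
  dz <- matrix(0, 1, ncol(h))
  dz[1, seq_len(k)] <- -Sk * h[1, seq_len(k)]
  grad <- net_backward(model$net, fw$cache, dz)$dX
  g <- array(grad, d)
  if (backend == "gradxinput") g * slice else g
}

#' Normalize and binarize a relevance map into a trinary mask
#'
#' The map is scaled by its maximum absolute value, then thresholded at the
#' 95th percentile separately for positive values and for magnitudes of
#' negative values (linear-interpolation percentile): pixels at or above
#' the positive cut become `+1`, pixels at or below the negative cut become
#' `-1`, all others `0`. The output is invariant to positive rescaling of
#' the input and antisymmetric under sign flip; an all-zero map stays
#' all-zero.
#'
#' @param map Numeric array of signed relevance.
#' @param pct Percentile threshold (default 95).
#' @return An array of the same shape with values in `{-1, 0, 1}`.
#' @export
normalize_binarize <- function(map, pct = 95) {
  stopifnot(all(is.finite(map)), pct > 0, pct < 100)
  m <- max(abs(map))
  out <- array(0, dim(map) %||% length(map))
  if (m == 0) return(out)
  x <- map / m
  posv <- x[x > 0]
  if (length(posv)) {
    cut <- quantile(posv, pct / 100, type = 7, names = FALSE)
    out[x > 0 & x >= cut] <- 1
  }
  negv <- -x[x < 0]
  if (length(negv)) {
    cut <- quantile(negv, pct / 100, type = 7, names = FALSE)
    out[x < 0 & -x >= cut] <- -1
  }
  out
}

#' Population-average relevance per parcellation region
#'
#' Multiplies trinary relevance masks by an integer-labelled parcellation
#' and aggregates across the population: for every region, the fraction of
#' its pixels flagged `+1` and `-1` (averaged over maps), flagged pixel
#' counts, a net direction, and a ranking by total flagged fraction.
#'
#' @param maps List of trinary arrays (from [normalize_binarize()]), each
#'   of exactly the parcellation's shape.
#' @param atlas Integer array of region labels (0 = background/ignored).
#' @param region_names Optional named translation of labels.
#' @return A data.frame (one row per region, ranked by `total_frac`
#'   descending) with `region`, `n_pixels`, `pos_frac`, `neg_frac`,
#'   `total_frac`, `n_pos`, `n_neg`, `net_direction`. Empty input maps give
#'   a zero-row ranking.
#' @export
population_region_table <- function(maps, atlas, region_names = NULL) {
  stopifnot(is.list(maps))
  atlas <- array(as.integer(atlas), dim(atlas) %||% length(atlas))
  regions <- sort(unique(atlas[atlas > 0L]))
  if (!length(maps) || !length(regions))
    return(data.frame(region = integer(), n_pixels = integer(),
                      pos_frac = numeric(), neg_frac = numeric(),
                      total_frac = numeric(), n_pos = numeric(),
                      n_neg = numeric(), net_direction = integer()))
  rsize <- vapply(regions, function(r) sum(atlas == r), numeric(1))
  pos <- neg <- matrix(0, length(maps), length(regions))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    if (!identical(dim(m) %||% length(m), dim(atlas) %||% length(atlas)))
      stop_pirasurv("map and parcellation shapes differ",
                    "pirasurv_shape_mismatch")
    for (j in seq_along(regions)) {
      sel <- atlas == regions[j]
      pos[i, j] <- sum(m[sel] == 1)
      neg[i, j] <- sum(m[sel] == -1)
    }
  }
  pos_frac <- colMeans(pos) / rsize
  neg_frac <- colMeans(neg) / rsize
  out <- data.frame(region = regions, n_pixels = rsize,
                    pos_frac = pos_frac, neg_frac = neg_frac,
                    total_frac = pos_frac + neg_frac,
                    n_pos = colMeans(pos), n_neg = colMeans(neg),
                    net_direction = sign(pos_frac - neg_frac))
  if (!is.null(region_names))
    out$name <- region_names[as.character(out$region)]
  out[order(-out$total_frac), , drop = FALSE]
}
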