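# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Translate a matrix by integer offsets
#'
#' Shifts `img` by `dy` rows (downwards, i.e. towards larger row indices) and
#' `dx` columns (rightwards). Vacated pixels are filled with `fill`.
#'
#' @param img numeric or logical matrix.
#' @param dy,dx integer offsets (row, col).
#' @param fill value used for pixels shifted in from outside the image.
#' @return matrix of the same dimensions and mode as `img`.
#' @keywords internal
shift_image <- function(img, dy, dx, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1L & src_r <= h
  ok_c <- src_c >= 1L & src_c <= w
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  if (is.logical(img)) storage.mode(out) <- "logical"
  out
}

#' Run code with a temporarily fixed RNG state
#'
#' Seeds the default Mersenne-Twister stream, evaluates `expr`, and restores
#' whatever `.Random.seed` was present before, so simulations are reproducible
#' without clobbering the caller's stream.
#'
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' 8-connected components of a binary mask
#'
#' Simple breadth-first labelling; background is 0.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (1..K row-major discovery order).
#' @keywords internal
connected_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  noff <- cbind(dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  nextlab <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    labels[start] <- nextlab
    while (length(queue)) {
      px <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      r0 <- ((px - 1L) %% h) + 1L
      c0 <- ((px - 1L) %/% h) + 1L
      for (k in 1:8) {
        r <- r0 + noff[k, 1L]; cc <- c0 + noff[k, 2L]
        if (r < 1L || r > h || cc < 1L || cc > w) next
        j <- r + (cc - 1L) * h
        if (mask[j] && labels[j] == 0L) {
          labels[j] <- nextlab
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

#' Gaussian smoothing of an image
#'
#' Separable Gaussian convolution with edge replication. Used to stabilise the
#' watershed landscape; `sigma = 0` is the identity.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels.
#' @return smoothed numeric matrix.
#' @keywords internal
gaussian_smooth <- function(img, sigma = 2) {
  if (sigma <= 0) return(img)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  conv1 <- function(m, along_rows) {
    acc <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(kern)) {
      off <- i - half - 1L
      acc <- acc + kern[i] * (if (along_rows) shift_replicate(m, off, 0L)
                              else shift_replicate(m, 0L, off))
    }
    acc
  }
  conv1(conv1(img, TRUE), FALSE)
}

# shift with edge replication (for convolution boundaries)
shift_replicate <- function(img, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  src_r <- pmin(pmax(seq_len(h) - dy, 1L), h)
  src_c <- pmin(pmax(seq_len(w) - dx, 1L), w)
  img[src_r, src_c, drop = FALSE]
}

stop_fretkit <- function(...) stop(..., call. = FALSE)

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x)) stop_fretkit(sprintf("`%s` must be a matrix", name))
  invisible(x)
}
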