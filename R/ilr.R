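# Isometric log-ratio machinery for time-budget compositions -----------------

#' Build an ILR basis from a sequential binary partition
#'
#' A sequential binary partition (SBP) over D parts is given as a
#' (D-1) x D sign matrix: row j splits the parts still in play into a +1
#' group and a -1 group (0 = not involved). Each row yields one balance
#' coordinate; the implied contrast matrix has orthonormal rows, each
#' orthogonal to the all-ones vector, so the transform is an isometry of the
#' Aitchison geometry.
#'
#' @param sbp integer matrix of -1/0/+1 with D-1 rows and D columns; column
#'   names label the parts.
#' @return An object of class `ilr_basis`: list with `contrast`
#'   ((D-1) x D orthonormal matrix), `sbp` and `parts`.
#' @export
ilr_basis <- function(sbp) {
  sbp <- as.matrix(sbp)
  if (is.null(colnames(sbp))) colnames(sbp) <- paste0("part", seq_len(ncol(sbp)))
  D <- ncol(sbp)
  if (nrow(sbp) != D - 1L) stop("SBP needs D-1 rows", call. = FALSE)
  if (!all(sbp %in% c(-1, 0, 1))) stop("SBP entries must be -1/0/+1", call. = FALSE)
  V <- matrix(0, D - 1L, D, dimnames = list(NULL, colnames(sbp)))
  for (j in seq_len(D - 1L)) {
    plus <- sbp[j, ] == 1
    minus <- sbp[j, ] == -1
    r <- sum(plus); s <- sum(minus)
    if (r == 0L || s == 0L) stop("each SBP row needs both signs", call. = FALSE)
    V[j, plus] <- sqrt(s / (r * (r + s)))
    V[j, minus] <- -sqrt(r / (s * (r + s)))
  }
  G <- V %*% t(V)
  if (max(abs(G - diag(D - 1L))) > 1e-10) {
    stop("SBP rows are not a valid partition hierarchy", call. = FALSE)
  }
  structure(list(contrast = V, sbp = sbp, parts = colnames(sbp)),
            class = "ilr_basis")
}

#' @export
print.ilr_basis <- function(x, ...) {
  cat(sprintf("ILR basis over %d parts (%s): %d balance coordinates\n",
              length(x$parts), paste(x$parts, collapse = ", "),
              nrow(x$contrast)))
  invisible(x)
}

#' Default ILR bases for the two budgets
#'
#' For the merged postural budget the documented split order is lying vs
#' non-lying first, then within lying (udder exposed vs hidden, then sternal
#' vs lateral), then standing vs sitting/kneeling. For the standing-activity
#' budget: maintenance (eat+drink) vs other, then eat vs drink. Any
#' orthonormal basis gives isometric coordinates, so cluster assignments do
#' not depend on this choice.
#'
#' @return An `ilr_basis`.
#' @export
posture_ilr_basis <- function() {
  sbp <- rbind(c(-1, -1, 1, 1, 1),   # lying vs non-lying
               c(0, 0, -1, -1, 1),   # udder exposed vs other lying
               c(0, 0, 1, -1, 0),    # sternal vs lateral (hidden)
               c(1, -1, 0, 0, 0))    # standing vs sitting/kneeling
  colnames(sbp) <- c("ST", "SIK", "SL", "LL", "LLU")
  ilr_basis(sbp)
}

#' @rdname posture_ilr_basis
#' @export
activity_ilr_basis <- function() {
  sbp <- rbind(c(1, 1, -1),          # maintenance vs other
               c(1, -1, 0))          # eat vs drink
  colnames(sbp) <- c("EAT", "DRINK", "OTHER")
  ilr_basis(sbp)
}

#' Multiplicative zero replacement
#'
#' The ILR transform needs strictly positive parts. Zero parts are set to a
#' small `delta` and the non-zero parts are rescaled by `1 - z * delta`
#' (z = number of zeros), preserving closure and the ratios among the
#' non-zero parts. The default `delta` is half of one 5-s tick's share of a
#' full day, `1 / (2 * 17280)`.
#'
#' @param comp numeric composition (vector or matrix, rows = compositions).
#' @param delta replacement value, `0 < delta < ` smallest non-zero part.
#' @return Strictly positive closed composition(s).
#' @export
zero_replace <- function(comp, delta = 1 / (2 * 17280)) {
  f <- function(x) {
    if (anyNA(x)) return(x)
    z <- x == 0
    if (!any(z)) return(x)
    if (delta <= 0 || delta >= min(x[!z])) {
      stop("delta must lie in (0, min non-zero part)", call. = FALSE)
    }
    x[z] <- delta
    x[!z] <- x[!z] * (1 - sum(z) * delta)
    x / sum(x)
  }
  if (is.matrix(comp)) t(apply(comp, 1L, f)) else f(comp)
}

#' Isometric log-ratio transform and its inverse
#'
#' `ilr_transform()` maps a strictly positive closed D-part composition to
#' D-1 unconstrained coordinates, `y = V %*% log(x)`; `ilr_inverse()` maps
#' back via the softmax of `t(V) %*% y`. Euclidean distance between
#' coordinates equals Aitchison distance between compositions.
#'
#' @param comp composition (vector, or matrix with rows as compositions)
#'   with parts ordered/named as in the basis.
#' @param basis an [ilr_basis()].
#' @return Coordinate vector/matrix of width D-1.
#' @export
ilr_transform <- function(comp, basis) {
  V <- basis$contrast
  m <- if (is.matrix(comp)) comp else matrix(comp, nrow = 1L,
                                             dimnames = list(NULL, names(comp)))
  if (!is.null(colnames(m)) && all(basis$parts %in% colnames(m))) {
    m <- m[, basis$parts, drop = FALSE]
  }
  if (ncol(m) != ncol(V)) stop("composition width does not match basis",
                               call. = FALSE)
  if (any(m <= 0)) stop("ILR needs strictly positive parts; zero_replace() first",
                        call. = FALSE)
  y <- log(m) %*% t(V)
  colnames(y) <- paste0("ilr", seq_len(ncol(y)))
  if (is.matrix(comp)) y else drop(y)
}

#' @rdname ilr_transform
#' @param y ILR coordinates (vector or matrix of width D-1).
#' @export
ilr_inverse <- function(y, basis) {
  V <- basis$contrast
  m <- if (is.matrix(y)) y else matrix(y, nrow = 1L)
  if (ncol(m) != nrow(V)) stop("coordinate width does not match basis",
                               call. = FALSE)
  lx <- m %*% V
  x <- exp(lx - apply(lx, 1L, max))
  x <- x / rowSums(x)
  colnames(x) <- basis$parts
  if (is.matrix(y)) x else drop(x)
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between centred log-ratio vectors; equals the
#' Euclidean distance between ILR coordinates under any orthonormal basis.
#'
#' @param x,y strictly positive closed compositions of equal length.
#' @return Non-negative scalar.
#' @export
aitchison_dist <- function(x, y) {
  clr <- function(z) log(z) - mean(log(z))
  sqrt(sum((clr(x) - clr(y))^2))
}
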