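#' Kernel specifications
#'
#' Constructors for the kernels available to the classifier:
#' \describe{
#'   \item{linear}{`k(x, z) = x . z`}
#'   \item{polynomial}{`k(x, z) = (x . z + a)^b` with offset `a` and integer
#'     degree `b >= 1`}
#'   \item{rbf}{`k(x, z) = exp(-||x - z||^2 / (2 sigma^2))` with width
#'     `sigma > 0`}
#'   \item{sigmoid}{`k(x, z) = tanh(a x . z - b)`; not positive semi-definite
#'     in general, so training with it emits a warning}
#' }
#' The radial basis kernel is the experiment default: it is the customary
#' choice when tuning `(C, sigma)` by population search and makes the
#' hyperparameter space two-dimensional.
#'
#' @param sigma RBF width, `> 0`.
#' @param offset polynomial additive constant `a` / sigmoid offset `b`.
#' @param degree polynomial degree `b`, integer `>= 1`.
#' @param scale sigmoid slope `a`.
#' @return An object of class `svm_kernel`.
#' @name kernels
NULL

new_kernel <- function(kind, params) {
  structure(list(kind = kind, params = params), class = "svm_kernel")
}

#' @rdname kernels
#' @export
kernel_linear <- function() new_kernel("linear", list())

#' @rdname kernels
#' @export
kernel_rbf <- function(sigma = 1) {
  stopifnot(is.numeric(sigma), length(sigma) == 1, sigma > 0)
  new_kernel("rbf", list(sigma = sigma))
}

#' @rdname kernels
#' @export
kernel_polynomial <- function(offset = 1, degree = 3) {
  stopifnot(degree >= 1, degree == round(degree))
  new_kernel("polynomial", list(offset = offset, degree = degree))
}

#' @rdname kernels
#' @export
kernel_sigmoid <- function(scale = 1, offset = 0) {
  new_kernel("sigmoid", list(scale = scale, offset = offset))
}

#' @export
print.svm_kernel <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste0("(", paste(names(x$params), unlist(x$params), sep = " = ",
                      collapse = ", "), ")")
  } else ""
  cat("kernel:", x$kind, ps, "\n")
  invisible(x)
}

#' Evaluate a kernel on a pair of vectors
#'
#' @param spec an `svm_kernel` from one of the [kernels] constructors.
#' @param x,z numeric vectors of equal length.
#' @return the scalar kernel value; symmetric in `(x, z)`.
#' @export
kernel_eval <- function(spec, x, z) {
  if (length(x) != length(z)) {
    stop("dimension mismatch: length(x) = ", length(x),
         ", length(z) = ", length(z))
  }
  drop(kernel_matrix(spec, matrix(x, 1), matrix(z, 1)))
}

#' Kernel Gram matrix
#'
#' Computes `K[i, j] = k(X[i, ], Z[j, ])` for all row pairs.
#'
#' @param spec an `svm_kernel`.
#' @param X numeric matrix (rows are samples).
#' @param Z numeric matrix; defaults to `X` (the symmetric Gram matrix).
#' @return `nrow(X) x nrow(Z)` numeric matrix.
#' @export
kernel_matrix <- function(spec, X, Z = X) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (ncol(X) != ncol(Z)) {
    stop("dimension mismatch: ", ncol(X), " vs ", ncol(Z), " features")
  }
  G <- tcrossprod(X, Z)
  K <- switch(spec$kind,
    linear = G,
    polynomial = (G + spec$params$offset)^spec$params$degree,
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * G
      d2[d2 < 0] <- 0  # guard against rounding
      exp(-d2 / (2 * spec$params$sigma^2))
    },
    sigmoid = tanh(spec$params$scale * G - spec$params$offset),
    stop("unknown kernel kind: ", spec$kind)
  )
  if (!all(is.finite(K))) stop("non-finite kernel values")
  K
}
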