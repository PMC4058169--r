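#' Hyperparameter search space
#'
#' Describes the box the optimizers search over: one row per dimension with a
#' name, bounds, and a scale. Log-scaled dimensions are searched in log2
#' coordinates (the optimizers see an encoded box; positions are decoded back
#' before an SVM is trained), which is the customary treatment of the penalty
#' `C` and the RBF width `sigma` since plausible values span orders of
#' magnitude. The default space is `C` in `[2^-5, 2^15]` and `sigma` in
#' `[2^-4, 2^4]`, both log-scaled.
#'
#' @param dims data.frame with columns `name`, `lower`, `upper`, `scale`
#'   (`"linear"` or `"log"`); `lower < upper`, and log dims need `lower > 0`.
#' @return An object of class `search_space`.
#' @export
search_space <- function(dims = data.frame(
                           name = c("C", "sigma"),
                           lower = c(2^-5, 2^-4),
                           upper = c(2^15, 2^4),
                           scale = c("log", "log"))) {
  stopifnot(is.data.frame(dims),
            all(c("name", "lower", "upper", "scale") %in% names(dims)),
            all(dims$lower < dims$upper),
            all(dims$scale %in% c("linear", "log")),
            all(dims$lower[dims$scale == "log"] > 0))
  structure(dims, class = c("search_space", "data.frame"))
}

#' Encoded bounds of a search space
#'
#' The optimizers work on the encoded box: log-scaled dimensions are mapped
#' to log2 coordinates.
#'
#' @param space a [search_space()].
#' @return 2-row matrix (`lower`, `upper`) with one column per dimension.
#' @export
space_bounds <- function(space) {
  lo <- ifelse(space$scale == "log", log2(space$lower), space$lower)
  hi <- ifelse(space$scale == "log", log2(space$upper), space$upper)
  rbind(lower = lo, upper = hi)
}

#' Decode an encoded position to raw hyperparameter values
#'
#' @param space a [search_space()].
#' @param position numeric vector in encoded coordinates.
#' @return named numeric vector of raw values (log dims exponentiated).
#' @export
space_decode <- function(space, position) {
  stopifnot(length(position) == nrow(space))
  out <- ifelse(space$scale == "log", 2^position, position)
  names(out) <- space$name
  out
}
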