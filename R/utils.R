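#' @useDynLib somaspat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate runif rnorm rpois predict
NULL

# 1 mm^3 in um^3; all coordinates are carried in micrometres, all reported
# volumes in cubic millimetres.
UM3_PER_MM3 <- 1e9

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded generators are reproducible without
#' disturbing the caller's random stream. With `seed = NULL` the expression
#' uses (and advances) the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed for simulation i under a master seed (kept well
# below .Machine$integer.max).
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483629L)
}

stop_somaspat <- function(..., class) {
  stop(structure(class = c(class, "somaspat_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

as_coord_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  if (ncol(p) != 3) stop("points must have 3 columns (x, y, z in um)")
  storage.mode(p) <- "double"
  if (nrow(p) > 0 && any(!is.finite(p)))
    stop_somaspat("non-finite coordinates", class = "somaspat_coord_error")
  dimnames(p) <- list(NULL, c("x_um", "y_um", "z_um"))
  p
}
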