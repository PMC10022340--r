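#' Define a DEA envelopment problem
#'
#' Bundles the input and output matrices of a set of decision-making units
#' (DMUs) together with the model choices used throughout the pipeline:
#' output orientation and, by default, variable returns to scale (VRS).
#' Here a DMU is one country-year observation of a national HIV programme,
#' with one input (HIV spending per person living with HIV) and two outputs
#' (ART coverage and PMTCT coverage, both percentages).
#'
#' @param X numeric matrix (or vector) of inputs, one row per DMU; all
#'   entries must be strictly positive.
#' @param Y numeric matrix of outputs, one row per DMU, nonnegative; no DMU
#'   may have every output equal to zero.
#' @param rts returns-to-scale assumption, `"vrs"` (convexity constraint
#'   \eqn{\sum\lambda = 1}) or `"crs"`.
#' @param dmu_ids optional character labels, one per DMU.
#' @return An object of class `dea_problem`.
#' @export
dea_problem <- function(X, Y, rts = c("vrs", "crs"), dmu_ids = NULL) {
  rts <- match.arg(rts)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  storage.mode(X) <- "double"
  storage.mode(Y) <- "double"
  if (nrow(X) != nrow(Y)) {
    stop("X and Y must have one row per DMU (", nrow(X), " vs ", nrow(Y), ")")
  }
  if (any(!is.finite(X)) || any(!is.finite(Y))) {
    stop("X and Y must be finite")
  }
  if (any(X <= 0)) stop("inputs must be strictly positive for every DMU")
  if (any(Y < 0)) stop("outputs must be nonnegative")
  zero_out <- rowSums(Y > 0) == 0
  if (any(zero_out)) {
    stop("DMU(s) with all-zero outputs cannot be scored: ",
         paste(which(zero_out), collapse = ", "))
  }
  if (is.null(dmu_ids)) dmu_ids <- as.character(seq_len(nrow(X)))
  if (length(dmu_ids) != nrow(X)) stop("dmu_ids must have one label per DMU")
  structure(list(X = X, Y = Y, rts = rts, orientation = "output",
                 dmu_ids = as.character(dmu_ids)),
            class = "dea_problem")
}

#' @export
print.dea_problem <- function(x, ...) {
  cat(sprintf("DEA problem: %d DMUs, %d input(s), %d output(s), output-oriented, %s\n",
              nrow(x$X), ncol(x$X), ncol(x$Y), toupper(x$rts)))
  invisible(x)
}

#' Score one DMU
#'
#' Solves the output-oriented envelopment linear program for DMU `i` against
#' the problem's own reference set:
#' maximise \eqn{\delta} subject to \eqn{\sum_j \lambda_j x_j \le x_i},
#' \eqn{\sum_j \lambda_j y_j \ge \delta y_i}, \eqn{\sum_j \lambda_j = 1}
#' (VRS; dropped under CRS), \eqn{\lambda \ge 0}.  The distance
#' \eqn{\delta \ge 1} is the feasible proportional expansion of all outputs;
#' technical efficiency is its reciprocal \eqn{1/\delta \in (0,1]}.
#'
#' @param problem a [dea_problem()].
#' @param i DMU index to score.
#' @return A list with `delta`, `efficiency`, `lambda` (intensity weights over
#'   the reference DMUs) and `solver_status` (`"ok"` unless the LP failed).
#' @export
dea_score <- function(problem, i) {
  stopifnot(inherits(problem, "dea_problem"))
  i <- as.integer(i)
  if (i < 1L || i > nrow(problem$X)) stop("DMU index out of range")
  res <- .dea_solve_cpp(problem$X[i, , drop = FALSE],
                        problem$Y[i, , drop = FALSE],
                        problem$X, problem$Y,
                        problem$rts == "vrs", TRUE)
  if (res$status[1] != 0L) {
    stop("DEA solver failed for DMU ", problem$dmu_ids[i],
         " (status ", res$status[1], ")")
  }
  delta <- max(res$delta[1], 1) # clamp solver noise; self is in the reference set
  lambda <- drop(res$lambda)
  names(lambda) <- problem$dmu_ids
  list(delta = delta, efficiency = 1 / delta, lambda = lambda,
       solver_status = "ok")
}

#' Score every DMU of a problem
#'
#' @param problem a [dea_problem()].
#' @param lambda logical; also return the matrix of intensity weights
#'   (one row per DMU).  Off by default: the bootstrap only needs distances.
#' @return A data.frame with columns `dmu_id`, `delta`, `efficiency`; the
#'   lambda matrix is attached as attribute `"lambda"` when requested.
#' @export
dea_score_all <- function(problem, lambda = FALSE) {
  stopifnot(inherits(problem, "dea_problem"))
  res <- .dea_solve_cpp(problem$X, problem$Y, problem$X, problem$Y,
                        problem$rts == "vrs", lambda)
  bad <- which(res$status != 0L)
  if (length(bad)) {
    stop("DEA solver failed for DMU(s): ",
         paste(problem$dmu_ids[bad], collapse = ", "))
  }
  delta <- pmax(res$delta, 1)
  out <- data.frame(dmu_id = problem$dmu_ids, delta = delta,
                    efficiency = 1 / delta, stringsAsFactors = FALSE)
  if (lambda) {
    dimnames(res$lambda) <- list(problem$dmu_ids, problem$dmu_ids)
    attr(out, "lambda") <- res$lambda
  }
  out
}

# Score arbitrary evaluation points against an external reference set.
# Used by the bootstrap: the original units are rescored on pseudo-data, so
# distances below 1 are legitimate there and are NOT clamped.
dea_score_ref <- function(X, Y, Xref, Yref, rts = "vrs") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Xref <- as.matrix(Xref); Yref <- as.matrix(Yref)
  storage.mode(X) <- storage.mode(Y) <- "double"
  storage.mode(Xref) <- storage.mode(Yref) <- "double"
  res <- .dea_solve_cpp(X, Y, Xref, Yref, identical(rts, "vrs"), FALSE)
  bad <- which(res$status != 0L)
  if (length(bad)) {
    stop("DEA rescoring failed for row(s): ", paste(bad, collapse = ", "))
  }
  res$delta
}

#' Brute-force reference value for an output-oriented VRS distance
#'
#' Enumerates the intensity weights \eqn{\lambda} over the whole unit-simplex
#' grid at the stated resolution and returns the best attainable proportional
#' output expansion for the evaluated unit.  This is a slow, exhaustive check
#' completely independent of the linear-programming solver; it is only
#' practical for a handful of reference DMUs and is used to validate
#' [dea_score()] on small instances.
#'
#' @param problem a VRS [dea_problem()] with at most 6 DMUs.
#' @param i DMU index to evaluate.
#' @param resolution grid spacing denominator (weights move in steps of
#'   `1/resolution`).
#' @return The grid optimum, a lower bound on the LP optimum that converges
#'   to it as `resolution` grows.
#' @export
dea_grid_search <- function(problem, i, resolution = 400L) {
  stopifnot(inherits(problem, "dea_problem"), problem$rts == "vrs")
  if (ncol(problem$X) != 1L) stop("grid oracle supports a single input")
  .dea_grid_cpp(problem$X[, 1], problem$Y, problem$X[i, 1],
                problem$Y[i, ], as.integer(resolution))
}
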