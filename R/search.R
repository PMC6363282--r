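#' @include AllClasses.R eqsort.R
NULL

#' Construct a discrete parameter grid
#'
#' @param mu,rhoE,rhoS,tau numeric vectors of candidate values
#' @return a list of class \code{ParameterGrid}
#' @export
parameterGrid <- function(mu, rhoE, rhoS, tau) {
  structure(list(mu = mu, rhoE = rhoE, rhoS = rhoS, tau = tau),
            class = "ParameterGrid")
}

#' The default parameter grid
#'
#' The spans used for the genome-scale analyses: 20 values of mu in [0, 1],
#' 26 radius values (1..52 plus Inf) for each of rho_e and rho_s, and 30
#' window sizes (1..40 plus Inf is not included; tau spans 1..40 in steps
#' that widen past 20). Under the constraint rho_e <= rho_s the grid holds
#' 210,600 admissible tuples.
#'
#' @return a \code{ParameterGrid}
#' @examples
#' gridSize(defaultGrid())  # 210600
#' @export
defaultGrid <- function() {
  parameterGrid(
    mu = c(0, 0.025, 0.05, 0.075, 0.1, 0.125, 0.15, 0.175, 0.2, 0.25,
           0.3, 0.35, 0.4, 0.45, 0.5, 0.6, 0.7, 0.8, 0.9, 1),
    rhoE = c(1:12, seq(14, 24, 2), seq(28, 52, 4), Inf),
    rhoS = c(1:12, seq(14, 24, 2), seq(28, 52, 4), Inf),
    tau = c(1:20, seq(22, 40, 2)))
}

#' Number of admissible tuples in a grid
#'
#' Counts (mu, rho_e, rho_s, tau) combinations satisfying rho_e <= rho_s.
#'
#' @param grid a \code{ParameterGrid}
#' @return integer count
#' @export
gridSize <- function(grid) {
  stopifnot(inherits(grid, "ParameterGrid"))
  nPairs <- sum(vapply(grid$rhoE, function(e) sum(grid$rhoS >= e), 0))
  length(grid$mu) * nPairs * length(grid$tau)
}

#' Heuristic coordinate-descent parameter search with restarts
#'
#' Minimises an objective (a p-value) over the admissible tuples of a
#' parameter grid. From a random admissible start, one parameter at a time
#' is swept over its admissible values (holding the others fixed) and set
#' to the argmin; sweeps cycle in the order mu, rho_e, rho_s, tau. When a
#' full cycle leaves the tuple unchanged (a local optimum), the search
#' restarts from a new random point. The search stops after \code{maxSteps}
#' unique objective evaluations (repeated tuples are memoised and not
#' recounted) and returns the best tuple seen overall. Ties keep the
#' earlier value in the grid list.
#'
#' @param objective function taking an \code{\linkS4class{EqParams}} and
#'   returning the quantity to minimise
#' @param grid a \code{ParameterGrid}
#' @param maxSteps maximum number of unique objective evaluations
#' @param seed integer seed for the random starts
#' @return list with \code{bestParams} (\code{EqParams}),
#'   \code{bestPValue}, \code{evaluations} and \code{trace} (data.frame of
#'   unique evaluations in order)
#' @export
heuristicSearch <- function(objective, grid, maxSteps = 1000, seed = 1) {
  stopifnot(inherits(grid, "ParameterGrid"), maxSteps >= 1)
  rng <- .seededRNG(seed)
  memo <- new.env(parent = emptyenv())
  nEval <- 0L
  trace <- list()
  evalTuple <- function(tp) {
    key <- paste(tp, collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (nEval >= maxSteps) return(NA_real_)
    val <- objective(eqParams(mu = tp[1], rhoE = tp[2], rhoS = tp[3], tau = tp[4]))
    nEval <<- nEval + 1L
    memo[[key]] <- val
    trace[[length(trace) + 1L]] <<- c(tp, val)
    val
  }
  randomStart <- function() {
    repeat {
      tp <- c(grid$mu[rng$sample(length(grid$mu), 1)],
              grid$rhoE[rng$sample(length(grid$rhoE), 1)],
              grid$rhoS[rng$sample(length(grid$rhoS), 1)],
              grid$tau[rng$sample(length(grid$tau), 1)])
      if (tp[2] <= tp[3]) return(tp)
    }
  }
  budget <- min(maxSteps, gridSize(grid))
  best <- NULL; bestVal <- Inf
  while (nEval < budget) {
    cur <- randomStart()
    curVal <- evalTuple(cur)
    if (is.na(curVal)) break
    repeat {
      changed <- FALSE
      for (d in 1:4) {
        cand <- switch(d, grid$mu, grid$rhoE, grid$rhoS, grid$tau)
        vals <- vapply(cand, function(v) {
          tp <- cur; tp[d] <- v
          if (tp[2] > tp[3]) return(NA_real_)
          evalTuple(tp)
        }, 0)
        if (all(is.na(vals))) next
        k <- which.min(vals)   # NA-safe: which.min skips NA
        if (!is.na(vals[k]) && vals[k] < curVal - 1e-15) {
          cur[d] <- cand[k]; curVal <- vals[k]; changed <- TRUE
        }
      }
      if (!changed || nEval >= budget) break
    }
    if (curVal < bestVal) { bestVal <- curVal; best <- cur }
    if (nEval >= budget) break
  }
  tr <- if (length(trace)) {
    df <- as.data.frame(do.call(rbind, trace))
    names(df) <- c("mu", "rhoE", "rhoS", "tau", "value")
    df$best <- cummin(df$value)
    df
  } else data.frame()
  list(bestParams = eqParams(best[1], best[2], best[3], best[4]),
       bestPValue = bestVal, evaluations = nEval, trace = tr)
}
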