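# Random survival forest with minimal-depth variable selection.

#' Fit a random survival forest
#'
#' Grows `ntree` survival trees on bootstrap samples with log-rank
#' splitting: at each node `mtry` candidate variables are drawn and
#' `nsplit` random cutpoints are tried per candidate; nodes are split
#' while they contain at least `nodesize` unique event times.  Terminal
#' nodes carry Nelson-Aalen cumulative-hazard estimates, and out-of-bag
#' ensemble mortality gives the prediction error
#' `1 - Harrell concordance`.
#'
#' @param data A [survival_dataset()] with at least one event.
#' @param ntree Number of trees (default 1000).
#' @param mtry Candidate variables per node (default `ceiling(sqrt(p))`).
#' @param nodesize Minimum unique event count for a node to be split.
#' @param nsplit Random cutpoints tried per candidate variable.
#' @param seed Optional integer seed; the same seed reproduces the forest
#'   exactly.
#' @return An object of class `survsel_rsf`: the tree node tables, the
#'   fitting parameters, per-subject OOB mortality, and `oob_error`
#'   (NA when some subject was never out-of-bag).
#' @export
fit_rsf <- function(data, ntree = 1000, mtry = NULL, nodesize = 3,
                    nsplit = 10, seed = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  if (sum(data$event) == 0) stop("cannot fit a survival forest: no events")
  if (ntree < 1) stop("ntree must be >= 1")
  mtry <- mtry %||% ceiling(sqrt(data$p))
  if (mtry < 1 || mtry > data$p) stop("mtry must lie in [1, p]")
  res <- with_seed(seed, {
    cpp_rsf_fit(data$X, data$time, as.numeric(data$event),
                as.integer(ntree), as.integer(mtry),
                as.integer(nodesize), as.integer(nsplit))
  })
  oob_ok <- all(res$oob_count > 0)
  mortality <- ifelse(res$oob_count > 0, res$oob_sum / res$oob_count,
                      NA_real_)
  oob_error <- if (oob_ok) {
    1 - cpp_concordance(data$time, as.numeric(data$event), mortality)
  } else {
    warning("some subjects were never out-of-bag; oob_error undefined")
    NA_real_
  }
  structure(
    list(trees = res$trees, ntree = ntree, mtry = mtry,
         nodesize = nodesize, nsplit = nsplit, p = data$p,
         feature_names = data$feature_names,
         oob_mortality = mortality, oob_error = oob_error),
    class = "survsel_rsf"
  )
}

#' @export
print.survsel_rsf <- function(x, ...) {
  cat("survsel_rsf:", x$ntree, "trees, mtry =", x$mtry,
      ", nodesize =", x$nodesize,
      sprintf("| OOB error %.3f\n", x$oob_error))
  invisible(x)
}

#' Minimal depth profile of a forest
#'
#' For each variable and tree, the minimal depth is the depth of the
#' shallowest node split on that variable (the root has depth 0) -- the
#' distance to the nearest maximal subtree for the variable.  Variables a
#' tree never splits on receive that tree's maximal terminal depth + 1 as
#' a sentinel.  Values are averaged over trees.
#'
#' The selection threshold is the expected minimal depth of an irrelevant
#' variable, computed in closed form from each tree's topology: under the
#' null a node splits on a given variable with probability `1/p`, so
#' `P(D >= d) = prod_{d' < d} (1 - 1/p)^{n_d'}` with `n_d'` internal nodes
#' at depth `d'`, and a never-chosen variable scores the sentinel.
#'
#' @param forest A `survsel_rsf` (or a compatible list with elements
#'   `trees`, `p`, and optionally `feature_names`), with at least 1 tree.
#' @return An object of class `depth_profile`: `minimal_depth` (average
#'   per variable) and `threshold` (mean null expected depth).
#' @export
minimal_depth <- function(forest) {
  trees <- forest$trees
  p <- forest$p
  if (length(trees) < 1) stop("forest has no trees")
  md_sum <- numeric(p)
  thr_sum <- 0
  for (tm in trees) {
    var <- tm[, "var"]
    depth <- tm[, "depth"]
    internal <- !is.na(var)
    sentinel <- max(depth[!internal]) + 1
    md <- rep(sentinel, p)
    if (any(internal)) {
      agg <- tapply(depth[internal], var[internal], min)
      md[as.integer(names(agg))] <- agg
    }
    md_sum <- md_sum + md
    # null expected depth from the depth-wise internal node counts
    if (any(internal)) {
      cnt <- table(factor(depth[internal],
                          levels = 0:max(depth[internal])))
      surv <- cumprod((1 - 1 / p)^as.numeric(cnt))  # P(D >= d+1)
      psurv <- c(1, surv)                           # P(D >= d), d = 0..
      pd <- psurv[-length(psurv)] - psurv[-1]       # P(D = d)
      dvals <- seq_along(pd) - 1
      thr_sum <- thr_sum +
        sum(dvals * pd) + sentinel * psurv[length(psurv)]
    } else {
      thr_sum <- thr_sum + sentinel
    }
  }
  md_avg <- md_sum / length(trees)
  names(md_avg) <- forest$feature_names %||% paste0("x", seq_len(p))
  structure(
    list(minimal_depth = md_avg, threshold = thr_sum / length(trees),
         ntree = length(trees)),
    class = "depth_profile"
  )
}

#' Select variables by minimal depth
#'
#' Default rule: select variables whose average minimal depth is strictly
#' below the threshold (the null expected depth from [minimal_depth()]);
#' when all depths are tied at the threshold nothing is selected.  A
#' `top_k` variant instead returns the `k` variables with smallest
#' average minimal depth (the shortlist used for real-data analyses).
#'
#' @param profile A `depth_profile`.
#' @param threshold Selection cutoff; defaults to the profile's null
#'   expected depth.
#' @param top_k If non-`NULL`, ignore the threshold and select the
#'   `top_k` shallowest variables.
#' @return Sorted integer vector of selected (1-based) indices.
#' @export
select_by_minimal_depth <- function(profile, threshold = NULL,
                                    top_k = NULL) {
  stopifnot(inherits(profile, "depth_profile"))
  md <- profile$minimal_depth
  if (!is.null(top_k)) {
    if (top_k < 1 || top_k > length(md)) stop("top_k must lie in [1, p]")
    return(sort(order(md)[seq_len(top_k)]))
  }
  threshold <- threshold %||% profile$threshold
  sort(unname(which(md < threshold)))
}
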