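# Benchmark harness: methods x selection rules over seeded replicates,
# scored by TPR / TNR / FPR.

#' Operating characteristics of a selected set
#'
#' With q true variables among p, `TPR = |selected ∩ support| / q`,
#' `TNR = |excluded irrelevant| / (p - q)`, and
#' `FPR = |selected \ support| / (p - q)`, so `TNR + FPR = 1`.  The
#' `"total"` denominator variant divides all three counts by p instead
#' (an audit option mirroring a common mis-statement of the formulas; it
#' breaks the TNR + FPR identity).
#'
#' @param selected Integer vector of selected (1-based) indices.
#' @param true_support Integer vector of the true support.
#' @param p Total number of variables.
#' @param denominator `"conventional"` (default) or `"total"`.
#' @return A list of class `operating_characteristics` with `tpr`, `tnr`,
#'   `fpr`, `n_selected`.
#' @export
operating_characteristics <- function(selected, true_support, p,
                                      denominator = c("conventional",
                                                      "total")) {
  denominator <- match.arg(denominator)
  selected <- as.integer(selected)
  true_support <- as.integer(true_support)
  if (length(selected) && (min(selected) < 1 || max(selected) > p))
    stop("selected indices out of range 1..p")
  q <- length(true_support)
  if (q == 0) stop("true support is empty: TPR undefined")
  tp <- length(intersect(selected, true_support))
  fp <- length(setdiff(selected, true_support))
  tn <- (p - q) - fp
  if (denominator == "conventional") {
    out <- list(tpr = tp / q, tnr = tn / (p - q), fpr = fp / (p - q))
  } else {
    out <- list(tpr = tp / p, tnr = tn / p, fpr = fp / p)
  }
  out$n_selected <- length(unique(selected))
  structure(out, class = "operating_characteristics")
}

# Fit one method on one replicate and return a list of selected sets,
# one per applicable rule.
bench_fit_method <- function(method, data, truth, foldid, rules, control) {
  sets <- list()
  if (method %in% c("lasso", "elastic_net", "ridge")) {
    fit <- fit_cv_penalized(data, method, foldid = foldid)
    sets[["nonzero"]] <- select_nonzero(fit)
  } else if (method == "adaptive_lasso") {
    fit <- fit_adaptive_lasso(data, foldid = foldid)
    sets[["nonzero"]] <- select_nonzero(fit)
  } else if (method == "rsf") {
    fit <- fit_rsf(data, ntree = control$ntree %||% 1000,
                   seed = control$rsf_seed)
    sets[["mindepth"]] <- select_by_minimal_depth(minimal_depth(fit))
  } else if (method %in% c("ssvs", "sslasso", "gsslasso")) {
    fit <- switch(method,
                  ssvs = fit_ssvs_cox(data, foldid = foldid),
                  sslasso = fit_sslasso_cox(data, foldid = foldid),
                  gsslasso = fit_gsslasso_cox(data, foldid = foldid))
    for (rule in rules) {
      sets[[rule]] <- switch(
        rule,
        ci75 = ci_rule(fit$beta, fit$se, 0.25),
        ci90 = ci_rule(fit$beta, fit$se, 0.10),
        ci95 = ci_rule(fit$beta, fit$se, 0.05),
        bic = bic_threshold(fit$beta, data),
        mbic = modified_bic_threshold(fit$beta, data),
        stop("unknown rule: ", rule)
      )
    }
  } else if (method == "oracle") {
    sets[["oracle"]] <- truth$support
  } else {
    stop("unknown method: ", method)
  }
  sets
}

#' Run the simulation benchmark
#'
#' For each design and replicate, one dataset is generated (seed
#' `seed_base + replicate`), every method is fitted with a shared CV fold
#' assignment, each applicable selection rule is applied, and TPR/TNR/FPR
#' are recorded.  Failed fits are logged and excluded from the affected
#' cells (never imputed).
#'
#' @param designs List of [simulation_design()] objects or integer design
#'   ids (1..4).
#' @param methods Character vector from `lasso`, `elastic_net`,
#'   `adaptive_lasso`, `ridge`, `rsf`, `ssvs`, `sslasso`, `gsslasso`,
#'   `oracle`.
#' @param rules Rules applied to the Bayesian fits (penalized methods use
#'   non-zero coefficients and the forest uses minimal depth regardless):
#'   subset of `ci75, ci90, ci95, bic, mbic`.
#' @param reps Replicates per design (the reference study used 100).
#' @param seed_base Integer base seed; replicate r uses `seed_base + r`.
#' @param folds CV folds shared by all methods within a replicate.
#' @param control List of extras (`ntree` for the forest, ...).
#' @param verbose Print progress lines.
#' @return An object of class `survsel_benchmark` holding the long
#'   per-replicate results, the aggregated summary, and exclusion counts.
#' @export
run_benchmark <- function(designs, methods, rules = c("ci90", "ci95",
                                                      "bic", "mbic"),
                          reps = 100, seed_base = 1, folds = 10,
                          control = list(), verbose = FALSE) {
  if (reps < 1) stop("reps must be >= 1")
  designs <- lapply(designs, function(d) {
    if (inherits(d, "simulation_design")) d else simulation_design(d)
  })
  rows <- list()
  for (d in designs) {
    if (is.na(d$censor_rate_c)) {
      d$censor_rate_c <- calibrate_censoring(
        d, seed = sub_seed(seed_base, d$design_id %||% 0))
    }
    did <- d$design_id %||% 0L   # 0 labels ad-hoc (custom) designs
    for (r in seq_len(reps)) {
      seed_r <- seed_base + r
      rep <- generate_replicate(d, seed = seed_r)
      foldid <- make_folds(rep$data$event, folds, seed = seed_r)
      ctrl <- control
      ctrl$rsf_seed <- sub_seed(seed_r, 99)
      for (m in methods) {
        t0 <- proc.time()[["elapsed"]]
        sets <- tryCatch(
          bench_fit_method(m, rep$data, rep$truth, foldid, rules, ctrl),
          error = function(e) e
        )
        if (inherits(sets, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            design = did, rep = r, method = m, rule = NA_character_,
            tpr = NA_real_, tnr = NA_real_, fpr = NA_real_,
            n_selected = NA_integer_, failed = TRUE,
            error = conditionMessage(sets))
          next
        }
        for (rule in names(sets)) {
          oc <- operating_characteristics(sets[[rule]], rep$truth$support,
                                          d$p)
          rows[[length(rows) + 1L]] <- data.frame(
            design = did, rep = r, method = m, rule = rule,
            tpr = oc$tpr, tnr = oc$tnr, fpr = oc$fpr,
            n_selected = oc$n_selected, failed = FALSE, error = "")
        }
        vmessage(verbose, sprintf(
          "design %s rep %d %s: %.1fs", did, r, m,
          proc.time()[["elapsed"]] - t0))
      }
    }
  }
  results <- do.call(rbind, rows)
  structure(
    list(results = results, summary = aggregate_benchmark(results),
         reps = reps, seed_base = seed_base,
         exclusions = sum(results$failed)),
    class = "survsel_benchmark"
  )
}

# Mean TPR/TNR/FPR per (design, method, rule) cell, with +-1.96 sd/sqrt(m)
# halfwidths and exclusion counts.
aggregate_benchmark <- function(results) {
  ok <- results[!results$failed, , drop = FALSE]
  if (nrow(ok) == 0) return(ok)
  agg <- aggregate(cbind(tpr, tnr, fpr, n_selected) ~ design + method +
                     rule, data = ok, FUN = mean)
  hw <- aggregate(cbind(tpr, tnr, fpr) ~ design + method + rule, data = ok,
                  FUN = function(x) 1.96 * sd(x) / sqrt(length(x)))
  cnt <- aggregate(rep ~ design + method + rule, data = ok, FUN = length)
  names(hw)[4:6] <- paste0(names(hw)[4:6], "_hw")
  names(cnt)[4] <- "n_reps"
  out <- merge(merge(agg, hw), cnt)
  out[order(out$design, out$method, out$rule), ]
}

#' @export
print.survsel_benchmark <- function(x, digits = 2, ...) {
  cat("survsel_benchmark:", x$reps, "replicates per design, seed base",
      x$seed_base, "\n")
  if (x$exclusions > 0)
    cat("  excluded (failed) fits:", x$exclusions, "\n")
  s <- x$summary
  s[c("tpr", "tnr", "fpr")] <- lapply(s[c("tpr", "tnr", "fpr")], round,
                                      digits = digits)
  print(s[c("design", "method", "rule", "tpr", "tnr", "fpr", "n_reps")],
        row.names = FALSE)
  invisible(x)
}

#' Write benchmark tables to CSV
#'
#' Produces one wide CSV per method family present (penalized + forest;
#' Bayesian BIC rules; gsslasso CI rules; SSVS CI rules), each laid out
#' with designs as rows and method-rule TPR/TNR/FPR triplets as columns,
#' plus `replicates.csv` with the full per-replicate long results.
#' Re-aggregating the long file reproduces the wide tables exactly.
#'
#' @param bench A `survsel_benchmark`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
render_tables <- function(bench, dir) {
  stopifnot(inherits(bench, "survsel_benchmark"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  long_path <- file.path(dir, "replicates.csv")
  write.csv(bench$results, long_path, row.names = FALSE)
  files <- c(files, long_path)
  s <- bench$summary
  layouts <- list(
    penalized_rsf = expand.grid(
      method = c("lasso", "elastic_net", "adaptive_lasso", "rsf"),
      rule = c("nonzero", "mindepth"), stringsAsFactors = FALSE),
    bayes_bic = expand.grid(
      method = c("gsslasso", "ssvs", "sslasso"),
      rule = c("bic", "mbic"), stringsAsFactors = FALSE),
    gsslasso_ci = expand.grid(
      method = "gsslasso", rule = c("ci75", "ci90", "ci95"),
      stringsAsFactors = FALSE),
    ssvs_ci = expand.grid(
      method = "ssvs", rule = c("ci75", "ci90", "ci95"),
      stringsAsFactors = FALSE)
  )
  for (nm in names(layouts)) {
    lay <- layouts[[nm]]
    cells <- merge(lay, s)
    path <- file.path(dir, paste0(nm, ".csv"))
    if (nrow(cells) == 0) {
      writeLines("design", path)
      files <- c(files, path)
      next
    }
    wide <- NULL
    for (i in seq_len(nrow(unique(cells[c("method", "rule")])))) {
      mr <- unique(cells[c("method", "rule")])[i, ]
      sub <- cells[cells$method == mr$method & cells$rule == mr$rule,
                   c("design", "tpr", "tnr", "fpr")]
      names(sub)[2:4] <- paste(mr$method, mr$rule,
                               c("TPR", "TNR", "FPR"), sep = ".")
      wide <- if (is.null(wide)) sub else merge(wide, sub, all = TRUE)
    }
    write.csv(wide[order(wide$design), ], path, row.names = FALSE)
    files <- c(files, path)
  }
  invisible(files)
}
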