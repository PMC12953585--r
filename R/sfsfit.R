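#' Demographic model specification for SFS fitting
#'
#' Three competing three-population histories for the origin of the
#' southwest-Asian population, fitted to a folded 3D SFS:
#'
#' * `"A"` (divergence): strictly bifurcating — Indian splits from the
#'   Holarctic/central stock at `T_ind`, SWAsia from Central at `T_sw`.
#' * `"B"` (introgression): model A plus a pulse of Indian ancestry of
#'   proportion `alpha` into SWAsia at `T_intro` (< `T_sw`).
#' * `"C"` (hybrid origin): SWAsia founded at `T_found` as a mixture of the
#'   Indian (contribution `h`) and Central (`1 - h`) populations.
#'
#' Population sizes and the deep Indian divergence are fixed at desk scale;
#' the free parameters and their search ranges can be overridden.
#'
#' @param model `"A"`, `"B"` or `"C"`.
#' @param fixed named list of fixed parameters, overriding the defaults
#'   `N_Indian`, `N_SWAsia`, `N_Central`, `N_anc`, `T_ind`, `mu`.
#' @param ranges named list of `c(lower, upper)` search ranges for the free
#'   parameters.
#' @param subsample diploid sample sizes (Indian, SWAsia, Central) the
#'   observed SFS was built with.
#' @return An `sfs_model_spec` object.
#' @export
sfs_model_spec <- function(model = c("A", "B", "C"), fixed = list(),
                           ranges = list(), subsample = c(3L, 6L, 9L)) {
  model <- match.arg(model)
  fx <- list(N_Indian = 3000, N_SWAsia = 5000, N_Central = 20000,
             N_anc = 20000, T_ind = 100000 / 4.4, mu = 4.5e-9)
  fx[names(fixed)] <- fixed
  rg <- switch(model,
    A = list(T_sw = c(500, 12000)),
    B = list(T_sw = c(500, 12000), alpha = c(0.01, 0.5),
             T_intro = c(100, 5000)),
    C = list(T_found = c(500, 12000), h = c(0.05, 0.95)))
  rg[names(ranges)] <- ranges
  bad <- vapply(rg, function(r) any(!is.finite(r)) || any(r <= 0) ||
                  r[2] <= r[1], logical(1))
  if (any(bad)) stopf("invalid search range for %s",
                      paste(names(rg)[bad], collapse = ", "))
  structure(list(model = model,
                 id = switch(model, A = "A_divergence", B = "B_introgression",
                             C = "C_hybrid"),
                 fixed = fx, ranges = rg,
                 free = names(rg), subsample = as.integer(subsample)),
            class = "sfs_model_spec")
}

# realize a spec + free-parameter values as a simulable demographic model
build_sfs_model <- function(spec, params) {
  fx <- spec$fixed
  for (nm in spec$free) {
    r <- spec$ranges[[nm]]
    if (is.na(params[nm]) || params[nm] < r[1] || params[nm] > r[2])
      stopf("parameter %s out of range", nm)
  }
  pops <- data.frame(name = c("Indian", "SWAsia", "Central"),
                     size = c(fx$N_Indian, fx$N_SWAsia, fx$N_Central),
                     stringsAsFactors = FALSE)
  sc <- data.frame(time = fx$T_ind, pop = "Central", size = fx$N_anc,
                   stringsAsFactors = FALSE)
  if (spec$model %in% c("A", "B")) {
    splits <- data.frame(time = c(params[["T_sw"]], fx$T_ind),
                         derived = c("SWAsia", "Indian"),
                         ancestral = c("Central", "Central"),
                         stringsAsFactors = FALSE)
    admix <- NULL
    if (spec$model == "B") {
      if (params[["T_intro"]] >= params[["T_sw"]])
        stopf("invalid parameter combination: introgression (T_intro = %g) predates the SWAsia split (T_sw = %g)",
              params[["T_intro"]], params[["T_sw"]])
      admix <- data.frame(time = params[["T_intro"]], source = "Indian",
                          dest = "SWAsia", prop = params[["alpha"]],
                          stringsAsFactors = FALSE)
    }
  } else {
    tf <- params[["T_found"]]
    splits <- data.frame(time = c(tf, fx$T_ind),
                         derived = c("SWAsia", "Indian"),
                         ancestral = c("Central", "Central"),
                         stringsAsFactors = FALSE)
    # hybrid founding: just before merging into Central, a fraction h of
    # SWAsia ancestry traces to the Indian population
    admix <- data.frame(time = tf * (1 - 1e-9), source = "Indian",
                        dest = "SWAsia", prop = params[["h"]],
                        stringsAsFactors = FALSE)
  }
  demographic_model(pops, splits, admix, size_changes = sc,
                    mutation_rate = fx$mu, generation_time = 4.4,
                    sequence_length = 1, chromosome_count = 1L)
}

#' Expected folded SFS of a model by coalescent simulation
#'
#' Simulates `n_loci` unlinked loci under the model, tabulates the folded
#' joint SFS of polymorphic sites, adds a pseudocount of `1 / (10 n_loci)`
#' to empty polymorphic cells and normalizes to probabilities.
#'
#' @param spec an [sfs_model_spec()].
#' @param params named numeric vector of the spec's free parameters.
#' @param n_loci number of simulated loci (>= 1000).
#' @param seed integer seed (same seed, same spectrum).
#' @param locus_len locus length in bp.
#' @return A probability array over the folded cells (class `folded_sfs`
#'   with probabilities in `counts`; the untransformed simulated site
#'   counts are kept in `raw_counts`).
#' @export
expected_sfs <- function(spec, params = numeric(), n_loci = 5000L, seed = 1L,
                         locus_len = 5000) {
  if (n_loci < 1000L) stopf("n_loci must be at least 1000")
  model <- build_sfs_model(spec, params)
  events <- compile_events(model)
  nhap <- 2L * spec$subsample
  raw <- with_seed(seed,
    .sim_sfs_cpp(nhap, model$populations$size, events,
                 model$mutation_rate, locus_len, as.integer(n_loci)))
  sfs <- folded_sfs(raw, nhap, 0, sprintf("expected:%s", spec$id))
  raw_counts <- sfs$counts
  v <- as.vector(sfs$counts)
  poly <- polymorphic_cells(nhap)
  eps <- 1 / (10 * n_loci)
  v[poly][v[poly] == 0] <- eps
  v <- v / sum(v)
  sfs$counts <- array(v, dim(sfs$counts))
  sfs$raw_counts <- raw_counts
  sfs
}

#' Search configuration for [fit_model()]
#'
#' @param grid_points coarse log-grid points per free parameter.
#' @param refine_iter Nelder-Mead iterations for local refinement (0
#'   disables refinement).
#' @return A `search_config` object.
#' @export
search_config <- function(grid_points = 4L, refine_iter = 40L) {
  if (grid_points < 1L) stopf("search budget must be positive")
  structure(list(grid_points = as.integer(grid_points),
                 refine_iter = as.integer(refine_iter)),
            class = "search_config")
}

#' Fit a demographic model to a folded 3D SFS
#'
#' Maximizes the composite log-likelihood over the spec's free parameters
#' by a seeded coarse grid (log-spaced within the search ranges) followed by
#' Nelder-Mead refinement on the log-parameter scale. Every likelihood
#' evaluation reuses the same simulation seed (common random numbers), so
#' the fit is deterministic given `seed` and the search budget. The
#' composite likelihood from all SNPs drives the search; for model
#' comparison the likelihood is recomputed at the optimum on the unlinked
#' one-SNP-per-block spectrum, and `AIC = 2k - 2 lnL_unlinked`.
#'
#' @param observed result of [build_folded_3dsfs()] (elements `all` and
#'   `unlinked`).
#' @param spec an [sfs_model_spec()].
#' @param n_loci simulated loci per likelihood evaluation.
#' @param search a [search_config()].
#' @param seed integer seed.
#' @return An `sfs_fit` object with `print`, `coef` and `logLik` methods.
#' @export
fit_model <- function(observed, spec, n_loci = 5000L,
                      search = search_config(), seed = 1L) {
  stopifnot(inherits(spec, "sfs_model_spec"))
  if (!all(c("all", "unlinked") %in% names(observed)))
    stopf("observed must carry both the all-SNP and unlinked spectra")
  eval_seed <- derive_seed(seed, 977L)
  objective <- function(p) {
    names(p) <- spec$free
    tryCatch(
      composite_loglik(observed$all,
                       expected_sfs(spec, p, n_loci, eval_seed)),
      error = function(e) -Inf)
  }
  grids <- lapply(spec$free, function(nm) {
    r <- spec$ranges[[nm]]
    exp(seq(log(r[1]), log(r[2]), length.out = search$grid_points + 2L))[
      seq_len(search$grid_points) + 1L]
  })
  cand <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  colnames(cand) <- spec$free
  ll <- apply(cand, 1L, objective)
  best <- cand[which.max(ll), , drop = TRUE]
  best_ll <- max(ll)
  if (search$refine_iter > 0L && length(spec$free) >= 1L) {
    lower <- log(vapply(spec$ranges, `[`, numeric(1), 1L))
    upper <- log(vapply(spec$ranges, `[`, numeric(1), 2L))
    obj_log <- function(lp) {
      lp <- pmin(pmax(lp, lower), upper)
      -objective(exp(lp))
    }
    opt <- if (length(spec$free) == 1L)
      optim(log(best), obj_log, method = "Brent", lower = lower,
            upper = upper, control = list(maxit = search$refine_iter))
    else
      optim(log(best), obj_log, method = "Nelder-Mead",
            control = list(maxit = search$refine_iter))
    cand_par <- exp(pmin(pmax(opt$par, lower), upper))
    if (-opt$value > best_ll) { best <- cand_par; best_ll <- -opt$value }
  }
  names(best) <- spec$free
  lnl_unlinked <- composite_loglik(observed$unlinked,
                                   expected_sfs(spec, best, n_loci, eval_seed))
  k <- length(spec$free)
  structure(list(model = spec$model, id = spec$id, par = best,
                 lnL_all = best_ll, lnL_unlinked = lnl_unlinked,
                 k = k, AIC = 2 * k - 2 * lnl_unlinked,
                 n_loci = n_loci, seed = seed,
                 data_digest = sfs_digest(observed), spec = spec),
            class = "sfs_fit")
}

sfs_digest <- function(observed) {
  paste(paste(observed$all$nhap, collapse = ","),
        format(sum(observed$all$counts)),
        format(sum(observed$unlinked$counts)), sep = "|")
}

#' @exportS3Method base::print
print.sfs_fit <- function(x, ...) {
  cat(sprintf("SFS fit, model %s (%s)\n", x$model, x$id))
  for (nm in names(x$par)) cat(sprintf("  %s = %.4g\n", nm, x$par[nm]))
  cat(sprintf("  lnL (all SNPs) = %.2f; lnL (unlinked) = %.2f; k = %d; AIC = %.2f\n",
              x$lnL_all, x$lnL_unlinked, x$k, x$AIC))
  invisible(x)
}

#' @exportS3Method stats::coef
coef.sfs_fit <- function(object, ...) object$par

#' @exportS3Method stats::logLik
logLik.sfs_fit <- function(object, ...) {
  structure(object$lnL_unlinked, df = object$k, class = "logLik")
}

#' Compare fitted demographic models by AIC
#'
#' `dAIC_i = AIC_i - min(AIC)`; Akaike weight
#' `w_i = exp(-dAIC_i / 2) / sum_j exp(-dAIC_j / 2)` (the model's relative
#' likelihood). All fits must come from the same observed spectra.
#'
#' @param ... two or more [fit_model()] results (or one list of them).
#' @return An `sfs_model_comparison` data frame, best model first.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "sfs_fit")) fits <- fits[[1L]]
  if (length(fits) < 2L) stopf("need at least 2 fits to compare")
  dig <- vapply(fits, `[[`, character(1), "data_digest")
  if (length(unique(dig)) != 1L)
    stopf("fits were made on different observed data")
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  daic <- aic - min(aic)
  w <- exp(-daic / 2); w <- w / sum(w)
  out <- data.frame(model = vapply(fits, `[[`, character(1), "model"),
                    id = vapply(fits, `[[`, character(1), "id"),
                    k = vapply(fits, `[[`, numeric(1), "k"),
                    lnL_unlinked = vapply(fits, `[[`, numeric(1), "lnL_unlinked"),
                    AIC = aic, dAIC = daic, akaike_weight = w,
                    best = daic == 0, stringsAsFactors = FALSE)
  out <- out[order(out$AIC), ]
  rownames(out) <- NULL
  class(out) <- c("sfs_model_comparison", "data.frame")
  out
}

#' @exportS3Method base::print
print.sfs_model_comparison <- function(x, ...) {
  cat("model comparison (composite likelihood on unlinked SNPs)\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %s%-16s AIC %9.2f  dAIC %7.2f  weight %.3f\n",
                if (x$best[i]) "* " else "  ", x$id[i], x$AIC[i], x$dAIC[i],
                x$akaike_weight[i]))
  invisible(x)
}
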