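#' Classify CLOGs into core / accessory / unique at a taxonomic level
#'
#' A CLOG is core in a group when it is present in at least
#' `ceiling(core_fraction * group size)` of the group's strains (the 90%
#' rule used for per-group core sets); in `strict` mode the threshold is
#' presence in every strain of the group. A CLOG present in exactly one
#' strain of the whole dataset is unique; everything else it touches is
#' accessory. Groups smaller than `min_group_size` are skipped.
#'
#' @param pattern a [phyletic_pattern()].
#' @param metadata data.frame with a `strain` column and the grouping
#'   column; ignored when `level = "all"`.
#' @param level `"all"` (single group of every strain), `"sub_cluster"` or
#'   `"clade"`.
#' @param core_fraction presence fraction defining core (default 0.9).
#' @param min_group_size smallest group for which a core set is inferred.
#' @param strict logical; `TRUE` uses the 100% presence rule instead.
#' @return object of class `pangenome_summary`: `groups` (group -> strains),
#'   `core` (group -> core CLOG ids), `core_size`, `pan_size`, `unique`
#'   (CLOG ids), and `per_strain` (data.frame of core/accessory/unique
#'   counts per strain, relative to the strain's group).
#' @export
classify_clogs <- function(pattern, metadata = NULL,
                           level = c("all", "sub_cluster", "clade"),
                           core_fraction = 0.9, min_group_size = 3,
                           strict = FALSE) {
  level <- match.arg(level)
  pres <- presence_matrix(pattern)
  if (level == "all") {
    groups <- list(all = pattern$strains)
  } else {
    if (is.null(metadata)) stop("metadata required for level '", level, "'")
    if (!level %in% names(metadata)) stop("metadata lacks column '", level, "'")
    md <- metadata[match(pattern$strains, metadata$strain), ]
    groups <- split(pattern$strains, md[[level]])
  }
  groups <- groups[lengths(groups) >= min_group_size]
  total_presence <- colSums(pres)
  pan_size <- sum(total_presence >= 1L)
  uniq <- pattern$clogs[total_presence == 1L]
  core <- lapply(groups, function(strains) {
    thr <- if (strict) length(strains) else ceiling(core_fraction * length(strains))
    pattern$clogs[colSums(pres[strains, , drop = FALSE]) >= thr]
  })
  strain_group <- rep(names(groups), lengths(groups))
  names(strain_group) <- unlist(groups, use.names = FALSE)
  per_strain <- do.call(rbind, lapply(pattern$strains, function(s) {
    present <- pattern$clogs[pres[s, ] == 1L]
    g <- strain_group[s]
    n_core <- if (!is.na(g)) sum(present %in% core[[g]]) else NA_integer_
    n_unique <- sum(present %in% uniq)
    data.frame(strain = s, group = if (is.na(g)) NA_character_ else g,
               n_present = length(present), core = n_core,
               unique = n_unique,
               accessory = length(present) - n_core - n_unique,
               stringsAsFactors = FALSE)
  }))
  structure(list(level = level, core_fraction = core_fraction, strict = strict,
                 groups = groups, core = core,
                 core_size = vapply(core, length, integer(1)),
                 pan_size = pan_size, unique = uniq, per_strain = per_strain),
            class = "pangenome_summary")
}

#' @export
print.pangenome_summary <- function(x, ...) {
  cat("pangenome_summary (level ", x$level, "): pan ", x$pan_size,
      " CLOGs, ", length(x$unique), " unique\n", sep = "")
  for (g in names(x$core))
    cat("  core[", g, "] = ", x$core_size[[g]], " (n = ",
        length(x$groups[[g]]), " strains)\n", sep = "")
  invisible(x)
}

# Internal: pan/core trajectory for one genome order.
pan_core_trajectory <- function(pres, ord, core_fraction) {
  cum <- apply(pres[ord, , drop = FALSE], 2, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
  n <- seq_len(nrow(cum))
  pan <- rowSums(cum >= 1L)
  core <- vapply(n, function(k) sum(cum[k, ] >= ceiling(core_fraction * k)),
                 numeric(1))
  list(pan = pan, core = core)
}

#' Pan/core rarefaction curves
#'
#' Genomes are added in random order; at each depth `n` the pan size is the
#' number of families present in at least one of the first `n` genomes and
#' the core size the number present in at least `core_fraction` of them.
#' Quartiles are taken across permutations at fixed `n`. With
#' `method = "exhaustive"` every order is enumerated (only sensible for a
#' handful of genomes).
#'
#' @param pattern a [phyletic_pattern()].
#' @param n_permutations number of random genome orders.
#' @param core_fraction presence fraction defining core.
#' @param seed optional integer seed.
#' @param method `"random"` or `"exhaustive"`.
#' @return object of class `rarefaction_curve`: data.frame `curve` with
#'   columns `n`, `pan_median`, `pan_q1`, `pan_q3`, `core_median`,
#'   `core_q1`, `core_q3`, plus matrices `pan` and `core`
#'   (permutation x depth) and the call parameters.
#' @export
rarefaction <- function(pattern, n_permutations = 1000, core_fraction = 0.9,
                        seed = NULL, method = c("random", "exhaustive")) {
  method <- match.arg(method)
  pres <- presence_matrix(pattern)
  N <- nrow(pres)
  if (method == "exhaustive") {
    perms <- all_permutations(N)
  } else {
    if (n_permutations < 1) stop("n_permutations must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    perms <- lapply(seq_len(n_permutations), function(i) sample.int(N))
  }
  pan <- matrix(0, nrow = length(perms), ncol = N)
  core <- matrix(0, nrow = length(perms), ncol = N)
  for (i in seq_along(perms)) {
    tr <- pan_core_trajectory(pres, perms[[i]], core_fraction)
    pan[i, ] <- tr$pan
    core[i, ] <- tr$core
  }
  q <- function(m, p) apply(m, 2, stats::quantile, probs = p, names = FALSE)
  curve <- data.frame(
    n = seq_len(N),
    pan_median = apply(pan, 2, stats::median),
    pan_q1 = q(pan, 0.25), pan_q3 = q(pan, 0.75),
    core_median = apply(core, 2, stats::median),
    core_q1 = q(core, 0.25), core_q3 = q(core, 0.75))
  structure(list(curve = curve, pan = pan, core = core,
                 n_permutations = length(perms),
                 core_fraction = core_fraction, seed = seed, method = method),
            class = "rarefaction_curve")
}

# Internal: list of all permutations of 1..n (n <= 8).
all_permutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to 8 genomes")
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (i in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = i - 1L)
  }
  out
}

#' Fit the exponential core-size asymptote
#'
#' Fits `core(n) = kappa * exp(-n / tau) + omega` to the median core curve
#' by nonlinear least squares; `omega` is reported as the asymptotic core
#' size. Starting values are `(first - last, N/3, last)`.
#'
#' @param curve a `rarefaction_curve`.
#' @return list with `kappa`, `tau`, `omega`, `omega_se`, `residuals` and
#'   the `nls` fit object (`NULL` for a degenerate flat curve).
#' @export
fit_core_asymptote <- function(curve) {
  stopifnot(inherits(curve, "rarefaction_curve"))
  df <- data.frame(n = curve$curve$n, y = curve$curve$core_median)
  if (stats::sd(df$y) < .Machine$double.eps^0.5 || nrow(df) < 4) {
    return(list(kappa = 0, tau = NA_real_, omega = df$y[nrow(df)],
                omega_se = 0, residuals = rep(0, nrow(df)), fit = NULL))
  }
  start <- list(kappa = df$y[1] - df$y[nrow(df)], tau = nrow(df) / 3,
                omega = df$y[nrow(df)])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ kappa * exp(-n / tau) + omega, data = df,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("core asymptote fit did not converge from start (",
                             paste(signif(unlist(start), 4), collapse = ", "),
                             "): ", conditionMessage(e)))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  list(kappa = unname(est["kappa"]), tau = unname(est["tau"]),
       omega = unname(est["omega"]), omega_se = unname(se["omega"]),
       residuals = stats::residuals(fit), fit = fit)
}
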