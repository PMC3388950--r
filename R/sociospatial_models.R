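# Multilevel count models of accessibility on deprivation, with
# spatial-autocorrelation diagnostics.
#
# Counts of accessible facilities are modelled on income-deprivation quintile
# (most affluent quintile Q1 as baseline) with a log-population offset and a
# local-authority random intercept. The family is negative binomial unless a
# Poisson fit shows no overdispersion. Moran's I over shared-border
# contiguity, tested by permutation, screens for spatial autocorrelation; a
# response-dependent spatial lag covariate is added only when it reduces the
# residual autocorrelation. Rate ratios are reported with 99% confidence
# intervals (a conservative level, acknowledging residual autocorrelation
# that the covariate may not fully remove).

#' Shared-border zone adjacency
#'
#' @param edges data frame with columns `a`, `b`: pairs of adjacent zone ids.
#'   Self-pairs are rejected; symmetry is implied (pairs are unordered).
#' @param zone_ids ids of all zones (isolated zones allowed).
#' @return an object of class `zone_adjacency` with binary contiguity weights.
#' @export
zone_adjacency <- function(edges, zone_ids) {
  stopifnot(is.data.frame(edges), all(c("a", "b") %in% names(edges)))
  if (any(edges$a == edges$b)) stop("self-adjacency not allowed", call. = FALSE)
  if (!all(c(edges$a, edges$b) %in% zone_ids)) {
    stop("adjacency references unknown zones", call. = FALSE)
  }
  key <- ifelse(edges$a < edges$b, paste(edges$a, edges$b),
                paste(edges$b, edges$a))
  edges <- edges[!duplicated(key), c("a", "b"), drop = FALSE]
  rownames(edges) <- NULL
  structure(list(zone_ids = as.character(zone_ids),
                 edges = data.frame(a = as.character(edges$a),
                                    b = as.character(edges$b),
                                    stringsAsFactors = FALSE)),
            class = "zone_adjacency")
}

#' Subset an adjacency to a set of zones
#' @param adj a [zone_adjacency()].
#' @param zone_ids zones to keep.
#' @return a `zone_adjacency` over `zone_ids` with internal edges only.
#' @export
subset_adjacency <- function(adj, zone_ids) {
  zone_ids <- as.character(zone_ids)
  keep <- adj$edges$a %in% zone_ids & adj$edges$b %in% zone_ids
  zone_adjacency(adj$edges[keep, , drop = FALSE], zone_ids)
}

#' Neighbour lists of an adjacency
#' @param adj a [zone_adjacency()].
#' @return named list mapping each zone id to its neighbours' ids.
#' @export
neighbour_list <- function(adj) {
  nb <- setNames(vector("list", length(adj$zone_ids)), adj$zone_ids)
  for (i in seq_len(nrow(adj$edges))) {
    a <- adj$edges$a[i]; b <- adj$edges$b[i]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  nb
}

#' Moran's I with binary contiguity weights
#'
#' `I = (n/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `w_ij = 1` for zones sharing a border and `W = sum w_ij`.
#'
#' @param values numeric vector, one value per zone in `adj$zone_ids` order.
#' @param adj a [zone_adjacency()] with at least one edge.
#' @return the Moran's I statistic.
#' @export
morans_i <- function(values, adj) {
  stopifnot(inherits(adj, "zone_adjacency"))
  n <- length(adj$zone_ids)
  if (length(values) != n) stop("one value per zone required", call. = FALSE)
  if (n < 2L) stop("need at least two zones", call. = FALSE)
  if (nrow(adj$edges) == 0L) stop("adjacency has no edges", call. = FALSE)
  z <- values - mean(values)
  s2 <- sum(z^2)
  if (s2 == 0) stop("Moran's I undefined for constant values", call. = FALSE)
  ia <- match(adj$edges$a, adj$zone_ids)
  ib <- match(adj$edges$b, adj$zone_ids)
  W <- 2 * nrow(adj$edges)
  (n / W) * 2 * sum(z[ia] * z[ib]) / s2
}

#' Moran's I permutation test
#'
#' One-sided test for positive spatial autocorrelation: zone values are
#' randomly permuted over the zones and
#' `p = (1 + #permuted I >= observed I) / (1 + n_permutations)`.
#'
#' @param values numeric vector, one value per zone.
#' @param adj a [zone_adjacency()].
#' @param n_permutations default 999.
#' @param seed RNG seed recorded in the result.
#' @return list (`spatial_diagnostic`) with `morans_i`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
morans_i_permutation_test <- function(values, adj, n_permutations = 999,
                                      seed = 1) {
  obs <- morans_i(values, adj)
  n <- length(values)
  ia <- match(adj$edges$a, adj$zone_ids)
  ib <- match(adj$edges$b, adj$zone_ids)
  z <- values - mean(values)
  s2 <- sum(z^2)
  W <- 2 * nrow(adj$edges)
  perm_i <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) {
      zp <- z[sample.int(n)]
      (n / W) * 2 * sum(zp[ia] * zp[ib]) / s2
    }, numeric(1))
  })
  p <- (1 + sum(perm_i >= obs)) / (1 + n_permutations)
  structure(list(morans_i = obs, p_value = p,
                 n_permutations = n_permutations, seed = seed),
            class = "spatial_diagnostic")
}

#' @export
print.spatial_diagnostic <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f, permutation p = %.4f (%d permutations, seed %d)\n",
              x$morans_i, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

#' Response-dependent spatial lag covariate
#'
#' `log(1 + mean response over border-sharing neighbours)`; zones without
#' neighbours get `log(1 + 0) = 0`.
#'
#' @param response numeric vector, one value per zone in `adj$zone_ids` order.
#' @param adj a [zone_adjacency()].
#' @return numeric vector of covariate values in the same order.
#' @export
spatial_lag_covariate <- function(response, adj) {
  stopifnot(length(response) == length(adj$zone_ids))
  nb <- neighbour_list(adj)
  r <- setNames(response, adj$zone_ids)
  vapply(adj$zone_ids, function(zid) {
    v <- nb[[zid]]
    if (length(v) == 0L) 0 else log1p(mean(r[v]))
  }, numeric(1), USE.NAMES = FALSE)
}

# Pearson dispersion statistic of a fitted count model.
pearson_dispersion <- function(fit) {
  pr <- residuals(fit, type = "pearson")
  sum(pr^2) / df.residual(fit)
}

#' Choose Poisson or negative binomial by overdispersion
#'
#' The negative binomial family is adopted when the Pearson dispersion
#' statistic of the Poisson fit exceeds 1 AND a likelihood-ratio test of the
#' negative binomial against the Poisson is significant at `alpha`; otherwise
#' the Poisson family is kept (no overdispersion found). If the negative
#' binomial fit is unavailable (non-convergence), the decision defaults to
#' negative binomial with a note.
#'
#' @param poisson_fit fitted Poisson model (`glm` or `glmerMod`).
#' @param nb_fit matching negative binomial fit, or `NULL` if it failed.
#' @param alpha LRT significance level, default 0.05.
#' @return list with `family` (`"poisson"` or `"nb"`), `dispersion`, `lrt_p`.
#' @export
overdispersion_decision <- function(poisson_fit, nb_fit = NULL, alpha = 0.05) {
  disp <- pearson_dispersion(poisson_fit)
  if (disp <= 1) {
    return(list(family = "poisson", dispersion = disp, lrt_p = NA_real_))
  }
  if (is.null(nb_fit)) {
    return(list(family = "nb", dispersion = disp, lrt_p = NA_real_,
                note = "NB fit unavailable; defaulting to negative binomial"))
  }
  stat <- as.numeric(2 * (logLik(nb_fit) - logLik(poisson_fit)))
  p <- pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
  list(family = if (p < alpha) "nb" else "poisson",
       dispersion = disp, lrt_p = p)
}

#' Model specification for a stratified count model
#'
#' @param stratum `"urban"`, `"small town"` or `"rural"`.
#' @param intensity,mode,threshold the accessibility slice modelled.
#' @param family `"nb"`, `"poisson"` or `"auto"` (overdispersion decision).
#' @param level confidence level for rate-ratio intervals; default 0.99, the
#'   conservative level used in the presence of residual spatial
#'   autocorrelation.
#' @param spatial_alpha significance level of the pre-model Moran screen for
#'   offering the spatial covariate; default 0.05.
#' @param nagq adaptive Gauss-Hermite quadrature points for the random
#'   intercept; default 10.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(stratum = "urban", intensity = "moderate",
                       mode = "walk", threshold = 20,
                       family = c("auto", "nb", "poisson"), level = 0.99,
                       spatial_alpha = 0.05, nagq = 10) {
  family <- match.arg(family)
  stopifnot(level > 0, level < 1)
  structure(list(stratum = stratum, intensity = intensity, mode = mode,
                 threshold = threshold, family = family, level = level,
                 spatial_alpha = spatial_alpha, nagq = as.integer(nagq)),
            class = "model_spec")
}

# Fit one count model (fixed quintile effects + log-population offset), with a
# local-authority random intercept when >= 2 authorities are present.
.fit_one <- function(dat, family, nagq, use_spatial) {
  rhs <- "quintile + offset(log(population))"
  if (use_spatial) rhs <- paste(rhs, "+ spatial_cov")
  multi <- length(unique(dat$la_id)) >= 2L
  if (multi) {
    f <- as.formula(paste("count ~", rhs, "+ (1 | la_id)"))
    if (family == "poisson") {
      fit <- suppressMessages(
        lme4::glmer(f, data = dat, family = stats::poisson(), nAGQ = nagq))
    } else {
      # Laplace approximation: glmer.nb's theta profiling is only reliable
      # under the default integration scheme
      fit <- suppressMessages(lme4::glmer.nb(f, data = dat))
    }
  } else {
    f <- as.formula(paste("count ~", rhs))
    fit <- if (family == "poisson") {
      stats::glm(f, data = dat, family = stats::poisson())
    } else {
      MASS::glm.nb(f, data = dat)
    }
  }
  fit
}

.fit_converged <- function(fit) {
  if (inherits(fit, "glmerMod")) {
    length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L
  } else {
    isTRUE(fit$converged)
  }
}

.fixef <- function(fit) if (inherits(fit, "glmerMod")) lme4::fixef(fit) else coef(fit)

# Rate-ratio table from a fitted model: exponentiated quintile coefficients
# with Wald intervals at `level`; the baseline Q1 row is RR 1 by construction.
.rr_table <- function(fit, level, quintiles_present) {
  b <- .fixef(fit)
  se <- sqrt(diag(as.matrix(suppressWarnings(vcov(fit)))))
  zq <- qnorm(1 - (1 - level) / 2)
  rows <- data.frame(quintile = 1L, rr = 1, ci_low = 1, ci_high = 1)
  for (q in 2:5) {
    nm <- paste0("quintileQ", q)
    if (!q %in% quintiles_present || !nm %in% names(b)) next
    rows <- rbind(rows, data.frame(
      quintile = q, rr = exp(b[[nm]]),
      ci_low = exp(b[[nm]] - zq * se[[nm]]),
      ci_high = exp(b[[nm]] + zq * se[[nm]])))
  }
  rownames(rows) <- NULL
  rows
}

#' Fit a multilevel count model of accessibility on deprivation
#'
#' Models `count ~ quintile + offset(log(population)) + (1 | la_id)` by
#' adaptive Gauss-Hermite quadrature, negative binomial or Poisson family
#' (chosen by [overdispersion_decision()] when `family = "auto"`). When an
#' adjacency is supplied, the response is screened for positive spatial
#' autocorrelation with the Moran's I permutation test; if significant, the
#' [spatial_lag_covariate()] is added, and kept only when it reduces the
#' residual |Moran's I| of the Pearson residuals. Rate ratios versus the most
#' affluent quintile Q1 are reported with Wald intervals at `spec$level`.
#'
#' @param data data frame with columns `count`, `quintile` (1--5),
#'   `population`, `la_id`, and optionally `zone_id` (required for spatial
#'   screening).
#' @param spec a [model_spec()].
#' @param adjacency optional [zone_adjacency()] covering `data$zone_id`.
#' @param n_permutations permutations for Moran tests, default 199.
#' @param seed seed for the permutation tests, default 1.
#' @return an object of class `model_result`: rate-ratio table plus family,
#'   dispersion, convergence flag, spatial-covariate indicator and residual
#'   Moran diagnostic.
#' @export
fit_count_glmm <- function(data, spec = model_spec(), adjacency = NULL,
                           n_permutations = 199, seed = 1) {
  stopifnot(all(c("count", "quintile", "population", "la_id") %in% names(data)))
  dat <- data
  dat$quintile <- factor(paste0("Q", dat$quintile),
                         levels = paste0("Q", 1:5))
  dat <- droplevels(dat)
  quintiles_present <- sort(unique(data$quintile))
  missing_q <- setdiff(1:5, quintiles_present)
  notes <- character(0)
  if (length(missing_q)) {
    notes <- c(notes, sprintf("quintile(s) %s absent; their RRs omitted",
                              paste(missing_q, collapse = ",")))
  }

  # spatial screen on the response
  pre_moran <- NULL
  spatial_candidate <- FALSE
  if (!is.null(adjacency) && "zone_id" %in% names(dat)) {
    adjacency <- subset_adjacency(adjacency, dat$zone_id)
    v <- dat$count[match(adjacency$zone_ids, dat$zone_id)]
    pre_moran <- tryCatch(
      morans_i_permutation_test(v, adjacency, n_permutations, seed),
      error = function(e) NULL)
    spatial_candidate <- !is.null(pre_moran) &&
      pre_moran$p_value <= spec$spatial_alpha
    if (spatial_candidate) {
      sc <- spatial_lag_covariate(v, adjacency)
      dat$spatial_cov <- sc[match(dat$zone_id, adjacency$zone_ids)]
    }
  }

  # family decision
  family <- spec$family
  dispersion <- NA_real_
  lrt_p <- NA_real_
  pois <- tryCatch(suppressWarnings(.fit_one(dat, "poisson", spec$nagq, FALSE)),
                   error = function(e) NULL)
  if (family == "auto") {
    if (is.null(pois)) {
      family <- "nb"
      notes <- c(notes, "Poisson fit failed; defaulting to negative binomial")
    } else {
      nb <- tryCatch(suppressWarnings(.fit_one(dat, "nb", spec$nagq, FALSE)),
                     error = function(e) NULL)
      dec <- overdispersion_decision(pois, nb)
      family <- dec$family
      dispersion <- dec$dispersion
      lrt_p <- dec$lrt_p
      if (!is.null(dec$note)) notes <- c(notes, dec$note)
    }
  } else if (!is.null(pois)) {
    dispersion <- pearson_dispersion(pois)
  }

  fit_or_null <- function(use_spatial) {
    tryCatch(suppressWarnings(.fit_one(dat, family, spec$nagq, use_spatial)),
             error = function(e) NULL)
  }
  base_fit <- fit_or_null(FALSE)
  fit <- base_fit
  spatial_included <- FALSE
  resid_moran <- NULL

  resid_i <- function(f) {
    if (is.null(f) || is.null(adjacency)) return(NA_real_)
    r <- residuals(f, type = "pearson")
    v <- r[match(adjacency$zone_ids, dat$zone_id)]
    tryCatch(morans_i(v, adjacency), error = function(e) NA_real_)
  }

  # adopt the spatial covariate only when it reduces residual |I|
  if (spatial_candidate && !is.null(base_fit)) {
    sp_fit <- fit_or_null(TRUE)
    i_base <- resid_i(base_fit)
    i_sp <- resid_i(sp_fit)
    if (!is.null(sp_fit) && is.finite(i_sp) && is.finite(i_base) &&
        abs(i_sp) < abs(i_base)) {
      fit <- sp_fit
      spatial_included <- TRUE
    }
  }

  if (is.null(fit)) {
    return(structure(list(
      rr = data.frame(quintile = 1L, rr = 1, ci_low = 1, ci_high = 1),
      family = family, dispersion = dispersion, lrt_p = lrt_p,
      converged = FALSE, spatial_cov = FALSE, pre_moran = pre_moran,
      residual_moran = NULL, n = nrow(dat),
      notes = c(notes, "model fit failed")), class = "model_result"))
  }

  if (!is.null(adjacency)) {
    r <- residuals(fit, type = "pearson")
    v <- r[match(adjacency$zone_ids, dat$zone_id)]
    resid_moran <- tryCatch(
      morans_i_permutation_test(v, adjacency, n_permutations, seed),
      error = function(e) NULL)
  }

  structure(list(
    rr = .rr_table(fit, spec$level, quintiles_present),
    family = family, dispersion = dispersion, lrt_p = lrt_p,
    converged = .fit_converged(fit), spatial_cov = spatial_included,
    pre_moran = pre_moran, residual_moran = resid_moran,
    n = nrow(dat), level = spec$level, notes = notes, fit = fit),
    class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("Count model (%s family, %d zones%s)%s\n",
              x$family, x$n,
              if (x$spatial_cov) ", spatial covariate" else "",
              if (x$converged) "" else "  [NOT CONVERGED]"))
  rr <- x$rr
  rr$rr <- round(rr$rr, 3); rr$ci_low <- round(rr$ci_low, 3)
  rr$ci_high <- round(rr$ci_high, 3)
  print(rr)
  if (!is.null(x$residual_moran)) {
    cat("Residual "); print(x$residual_moran)
  }
  for (nt in x$notes) cat("note:", nt, "\n")
  invisible(x)
}

#' Stratified models across intensity, mode and threshold
#'
#' Fits one model per stratum (urban / small town / rural) x intensity x
#' mode x threshold combination present in the accessibility table, with the
#' family chosen by the overdispersion decision, and tabulates rate ratios
#' for rate-ratio-versus-quintile figures. Strata with fewer than 30 zones
#' are fitted but flagged `low_n`; combinations that cannot be fitted are
#' recorded in `skipped`, not silently dropped.
#'
#' @param acc_table an [accessibility_table()].
#' @param zones data frame with `zone_id`, `population`, `quintile`,
#'   `stratum`, `la_id`.
#' @param adjacency a [zone_adjacency()] over all zones (optional).
#' @param level confidence level, default 0.99.
#' @param n_permutations,seed passed to the Moran permutation tests.
#' @return list with `results` (tidy data frame: one row per quintile RR),
#'   `models` (named list of `model_result`s) and `skipped` (data frame).
#' @export
stratified_analysis <- function(acc_table, zones, adjacency = NULL,
                                level = 0.99, n_permutations = 199, seed = 1) {
  stopifnot(all(c("zone_id", "population", "quintile", "stratum",
                  "la_id") %in% names(zones)))
  combos <- unique(acc_table[, c("mode", "intensity", "threshold")])
  strata <- c("urban", "small town", "rural")
  results <- list(); models <- list(); skipped <- list()
  for (s in strata) {
    zs <- zones[zones$stratum == s, , drop = FALSE]
    if (nrow(zs) == 0L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        stratum = s, mode = NA, intensity = NA, threshold = NA,
        reason = "no zones in stratum", stringsAsFactors = FALSE)
      next
    }
    low_n <- nrow(zs) < 30L
    for (i in seq_len(nrow(combos))) {
      cm <- combos[i, ]
      sel <- acc_table$mode == cm$mode & acc_table$intensity == cm$intensity &
        acc_table$threshold == cm$threshold &
        acc_table$zone_id %in% zs$zone_id
      dat <- acc_table[sel, c("zone_id", "count")]
      dat <- merge(dat, zs[, c("zone_id", "population", "quintile", "la_id")],
                   by = "zone_id", sort = TRUE)
      key <- sprintf("%s|%s|%s|%d", s, cm$intensity, cm$mode, cm$threshold)
      spec <- model_spec(stratum = s, intensity = cm$intensity,
                         mode = cm$mode, threshold = cm$threshold,
                         family = "auto", level = level)
      res <- tryCatch(
        fit_count_glmm(dat, spec, adjacency = adjacency,
                       n_permutations = n_permutations, seed = seed),
        error = function(e) e)
      if (inherits(res, "error")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          stratum = s, mode = cm$mode, intensity = cm$intensity,
          threshold = cm$threshold, reason = conditionMessage(res),
          stringsAsFactors = FALSE)
        next
      }
      models[[key]] <- res
      rr <- res$rr
      results[[length(results) + 1L]] <- data.frame(
        stratum = s, intensity = cm$intensity, mode = cm$mode,
        threshold = cm$threshold, quintile = rr$quintile, rr = rr$rr,
        ci_low = rr$ci_low, ci_high = rr$ci_high, family = res$family,
        spatial_cov = res$spatial_cov,
        morans_i = if (!is.null(res$residual_moran))
          res$residual_moran$morans_i else NA_real_,
        p_perm = if (!is.null(res$residual_moran))
          res$residual_moran$p_value else NA_real_,
        converged = res$converged, low_n = low_n,
        stringsAsFactors = FALSE)
    }
  }
  empty_skip <- data.frame(stratum = character(0), mode = character(0),
                           intensity = character(0), threshold = numeric(0),
                           reason = character(0))
  list(results = if (length(results)) do.call(rbind, results) else
         data.frame(),
       models = models,
       skipped = if (length(skipped)) do.call(rbind, skipped) else empty_skip)
}
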