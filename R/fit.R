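#' Weighted global least-squares fit of spectroscopic constants
#'
#' Fits rotational, centrifugal distortion and hyperfine parameters to a
#' line list of measured transition frequencies with per-line uncertainties,
#' minimising `sum(((obs - calc)/u)^2)` by Levenberg-Marquardt.  Line lists
#' may mix sources of very different accuracy (e.g. 2 kHz cavity FTMW and
#' 50 kHz millimetre-wave measurements); weighting by 1/u^2 combines them
#' into one global fit and the deviation of fit is reported per source
#' subset.
#'
#' Hyperfine-resolved lines carry `F`/`Itot` labels and are matched to the
#' corresponding first-order hyperfine component; blended lines (shared
#' `blend` id) are matched to the intensity-weighted centroid of their
#' components.  Parameters not listed in `free` stay fixed at the model
#' values, which is how deuterated species inherit parent distortion
#' constants.
#'
#' @param lines Data.frame with columns `J_up, Ka_up, Kc_up, J_lo, Ka_lo,
#'   Kc_lo`, `frequency` (MHz), `uncertainty` (MHz, > 0), optional
#'   `F_up, Itot_up, F_lo, Itot_lo` (NA for hyperfine-free lines),
#'   optional `source` (subset tag) and `blend` (shared id for blended
#'   components, NA otherwise).
#' @param model A [spectrum_model()]; its constants are the starting values
#'   and its `tensors` seed the hyperfine parameters.
#' @param free Character vector of free parameter names among `A, B, C, DJ,
#'   DJK, DK, dJ, dK, HK` and, with tensors present, `N1_32chiaa, N1_bbcc4,
#'   N1_chiab, N2_32chiaa, N2_bbcc4, N2_chiab` (nucleus order as in
#'   `model$tensors`).  May be empty to evaluate residuals only.
#' @param control List with `maxiter` (default 50) and `ftol` (relative
#'   convergence tolerance, default 1e-10).
#' @return An object of class `fit_result`: `params` (all parameter values
#'   at convergence), `se` (standard errors of the free parameters, from
#'   the unscaled covariance `(J^T J)^{-1}` of the weighted problem, i.e.
#'   taking the stated uncertainties at face value), `sigma_fit` (rms of
#'   obs - calc in kHz, per source subset and overall), `residuals` (per
#'   observation), `n_lines`, `niter`, `converged`.
#' @export
fit_constants <- function(lines, model, free = c("A", "B", "C"),
                          control = list()) {
  stopifnot(is.data.frame(lines), inherits(model, "spectrum_model"))
  if (nrow(lines) == 0) stop("empty line list")
  if (any(!is.finite(lines$uncertainty)) || any(lines$uncertainty <= 0)) {
    stop("all line uncertainties must be positive")
  }
  ctrl <- utils::modifyList(list(maxiter = 100, ftol = 1e-10, ptol = 1e-8),
                            control)
  p0 <- pack_params(model)
  unknown <- setdiff(free, names(p0))
  if (length(unknown) > 0) {
    stop("unknown free parameters: ", paste(unknown, collapse = ", "))
  }
  obs <- collapse_blends(lines)
  J_need <- max(lines$J_up, lines$J_lo)

  resid_fun <- function(pfree) {
    p <- p0
    p[free] <- pfree
    calc <- predict_lines(p, model, lines, obs, J_need)
    (obs$frequency - calc) / obs$uncertainty
  }

  if (length(free) > 0) {
    fit <- suppressWarnings(minpack.lm::nls.lm(
      par = p0[free], fn = resid_fun,
      control = minpack.lm::nls.lm.control(
        maxiter = ctrl$maxiter, ftol = ctrl$ftol, ptol = ctrl$ptol)))
    if (fit$info %in% c(0, 9) || (fit$info == -1 && length(fit$rsstrace) > 2 &&
        abs(diff(utils::tail(fit$rsstrace, 2))) >
          100 * ctrl$ftol * utils::tail(fit$rsstrace, 1))) {
      stop("fit did not converge within the iteration cap; rss trace: ",
           paste(signif(utils::tail(fit$rsstrace, 8), 6), collapse = " "))
    }
    pfree <- unlist(fit$par)
    niter <- fit$niter
  } else {
    pfree <- numeric(0)
    niter <- 0L
  }
  p <- p0
  p[free] <- pfree
  calc <- predict_lines(p, model, lines, obs, J_need)
  r_w <- (obs$frequency - calc) / obs$uncertainty

  se <- setNames(numeric(0), character(0))
  if (length(free) > 0) {
    Jm <- fd_jacobian(resid_fun, pfree)
    qrJ <- qr(Jm)
    if (qrJ$rank < length(free)) {
      bad <- free[qrJ$pivot[(qrJ$rank + 1):length(free)]]
      stop("rank-deficient fit; unconstrained parameter(s): ",
           paste(bad, collapse = ", "))
    }
    cov <- chol2inv(qr.R(qrJ)[, order(qrJ$pivot), drop = FALSE])
    se <- setNames(sqrt(diag(cov)), free)
  }

  resid <- data.frame(obs, calc = calc, omc = obs$frequency - calc)
  src <- if ("source" %in% names(obs)) obs$source else rep("all", nrow(obs))
  sig <- vapply(split(resid$omc, src), function(x) sqrt(mean(x^2)) * 1000,
                numeric(1))
  sig <- c(sig, overall = sqrt(mean(resid$omc^2)) * 1000)
  structure(list(params = p, se = se, sigma_fit = sig, residuals = resid,
                 n_lines = nrow(obs), niter = niter,
                 converged = TRUE, free = free),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Global fit: %d lines, %d free parameters, %d iterations\n",
              x$n_lines, length(x$free), x$niter))
  for (nm in x$free) {
    cat(sprintf("  %-10s %16.8f +- %.8f\n", nm, x$params[nm], x$se[nm]))
  }
  for (nm in names(x$sigma_fit)) {
    cat(sprintf("  sigma_fit[%s] = %.3f kHz\n", nm, x$sigma_fit[nm]))
  }
  invisible(x)
}

## Parameter vector from a spectrum model (MHz / kHz / Hz as in the tables).
pack_params <- function(model) {
  p <- c(A = model$rc$A, B = model$rc$B, C = model$rc$C,
         DJ = model$dist$DJ, DJK = model$dist$DJK, DK = model$dist$DK,
         dJ = model$dist$dJ, dK = model$dist$dK, HK = model$dist$HK)
  if (!is.null(model$tensors)) {
    tt <- normalize_tensor_pair(model$tensors)
    for (i in 1:2) {
      fp <- fit_params_from_tensor(tt[[i]])
      p[sprintf("N%d_32chiaa", i)] <- fp$three_halves_chi_aa
      p[sprintf("N%d_bbcc4", i)] <- fp$quarter_bb_minus_cc
      p[sprintf("N%d_chiab", i)] <- fp$chi_ab
    }
  }
  p
}

## Rebuild model pieces from a parameter vector (no A>=B>=C validation so
## the optimizer may probe freely near the solution).
unpack_params <- function(p, model) {
  rc <- structure(list(A = p[["A"]], B = p[["B"]], C = p[["C"]],
                       state_label = model$rc$state_label),
                  class = "rotational_constants")
  dist <- structure(list(DJ = p[["DJ"]], DJK = p[["DJK"]], DK = p[["DK"]],
                         dJ = p[["dJ"]], dK = p[["dK"]], HK = p[["HK"]],
                         reduction = "A", representation = "Ir"),
                    class = "distortion_set")
  tensors <- NULL
  if (!is.null(model$tensors)) {
    tensors <- lapply(1:2, function(i) {
      tensor_from_fit_params(p[[sprintf("N%d_32chiaa", i)]],
                             p[[sprintf("N%d_bbcc4", i)]],
                             p[[sprintf("N%d_chiab", i)]],
                             nucleus = sprintf("N%d", i))
    })
  }
  list(rc = rc, dist = dist, tensors = tensors)
}

## Group blended rows into single observations.
collapse_blends <- function(lines) {
  if (!("blend" %in% names(lines)) || all(is.na(lines$blend))) {
    lines$.group <- seq_len(nrow(lines))
  } else {
    lines$.group <- ifelse(is.na(lines$blend),
                           paste0("s", seq_len(nrow(lines))),
                           paste0("b", lines$blend))
  }
  first <- !duplicated(lines$.group)
  obs <- lines[first, , drop = FALSE]
  rownames(obs) <- NULL
  obs
}

## Predicted frequency for every observation (blend groups -> centroid).
predict_lines <- function(p, model, lines, obs, J_need) {
  mp <- unpack_params(p, model)
  st <- rotor_states(mp$rc, mp$dist, J_need)
  has_hf <- "F_up" %in% names(lines) && any(!is.na(lines$F_up))
  hf_cache <- new.env(parent = emptyenv())
  shift_of <- function(J, Ka, Kc, F, Itot) {
    key <- paste(J, Ka, Kc, sep = "_")
    hl <- hf_cache[[key]]
    if (is.null(hl)) {
      hl <- hyperfine_levels(st, J, Ka, Kc, mp$tensors)
      hf_cache[[key]] <- hl
    }
    sel <- which(hl$F == F & hl$Itot == Itot)
    if (length(sel) == 0) stop(sprintf(
      "no hyperfine sublevel F=%s Itot=%s in level %d_%d,%d", F, Itot, J, Ka, Kc))
    hl$shift[sel[1]]
  }
  one_freq <- function(row) {
    nu <- level_energy(st, row$J_up, row$Ka_up, row$Kc_up) -
      level_energy(st, row$J_lo, row$Ka_lo, row$Kc_lo)
    if (has_hf && !is.na(row$F_up)) {
      if (is.null(mp$tensors)) stop("hyperfine-resolved lines need model$tensors")
      nu <- nu +
        shift_of(row$J_up, row$Ka_up, row$Kc_up, row$F_up, row$Itot_up) -
        shift_of(row$J_lo, row$Ka_lo, row$Kc_lo, row$F_lo, row$Itot_lo)
    }
    nu
  }
  freqs <- vapply(seq_len(nrow(lines)), function(i) one_freq(lines[i, ]),
                  numeric(1))
  # intensity weights for blend centroids
  if (!("blend" %in% names(lines)) || all(is.na(lines$blend))) {
    return(freqs)
  }
  grp <- if (!is.null(lines$.group)) lines$.group else {
    ifelse(is.na(lines$blend), paste0("s", seq_len(nrow(lines))),
           paste0("b", lines$blend))
  }
  w <- blend_weights(lines, st, mp$tensors, has_hf)
  vapply(unique(grp), function(g) {
    sel <- grp == g
    sum(freqs[sel] * w[sel]) / sum(w[sel])
  }, numeric(1))[match(obs_groups(obs, lines), unique(grp))]
}

obs_groups <- function(obs, lines) {
  if (!is.null(obs$.group)) obs$.group else seq_len(nrow(obs))
}

## Relative intensity of each line row within its blend group: hyperfine
## component intensities where labels exist, equal weights otherwise.
blend_weights <- function(lines, st, tensors, has_hf) {
  w <- rep(1, nrow(lines))
  if (!has_hf || is.null(tensors)) return(w)
  for (i in seq_len(nrow(lines))) {
    if (is.na(lines$F_up[i])) next
    pat <- hyperfine_pattern(st,
                             c(lines$J_up[i], lines$Ka_up[i], lines$Kc_up[i]),
                             c(lines$J_lo[i], lines$Ka_lo[i], lines$Kc_lo[i]),
                             tensors, collapse_tol = 0)
    sel <- pat$F_up == lines$F_up[i] & pat$F_lo == lines$F_lo[i] &
      pat$Itot_up == lines$Itot_up[i] & pat$Itot_lo == lines$Itot_lo[i]
    if (any(sel)) w[i] <- pat$rel_intensity[which(sel)[1]]
  }
  w
}

## Forward-difference Jacobian with relative steps.
fd_jacobian <- function(fn, p, rel = 1e-6, abs_floor = 1e-9) {
  f0 <- fn(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- max(abs(p[j]) * rel, abs_floor)
    pp <- p; pp[j] <- pp[j] + h
    J[, j] <- (fn(pp) - f0) / h
  }
  J
}
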