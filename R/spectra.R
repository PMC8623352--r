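## Boltzmann constant in MHz/K units: h nu / (k T) = nu_MHz * HK_OVER_K / T
H_OVER_K_MHZ <- 4.799243073e-5  # K per MHz

#' Spectrum model for one vibronic state
#'
#' Bundles the rotational constants, distortion set, electric dipole
#' components and rotational temperature needed for forward prediction.
#' Inversion sublevels (0+/0-) are independent models predicted separately.
#'
#' @param rc A [rotational_constants()] object.
#' @param dist A [distortion_set()].
#' @param mu Length-3 numeric `c(mu_a, mu_b, mu_c)` dipole components in
#'   Debye.  At least one component must be nonzero for a nonempty
#'   prediction.
#' @param temperature Rotational temperature in K (about 1 K in a
#'   supersonic jet, ~300 K for a room-temperature spectrometer cell).
#' @param tensors Optional list of one or two [quadrupole_tensor()] objects
#'   used when hyperfine substructure is requested.
#' @return An object of class `spectrum_model`.
#' @export
spectrum_model <- function(rc, dist = distortion_set(), mu = c(0, 0, 0),
                           temperature = 1, tensors = NULL) {
  stopifnot(inherits(rc, "rotational_constants"),
            inherits(dist, "distortion_set"),
            length(mu) == 3, temperature > 0)
  structure(list(rc = rc, dist = dist, mu = mu, temperature = temperature,
                 tensors = tensors),
            class = "spectrum_model")
}

#' Predict the rotational spectrum of an asymmetric top
#'
#' Enumerates electric-dipole transitions (|dJ| <= 1) in a frequency
#' window.  Line strengths come from eigenvector-based dipole matrix
#' elements in the signed-k basis, which makes the a-type (dKa even, dKc
#' odd) and b-type (dKa odd, dKc odd) selection rules emerge from the
#' angular momentum algebra rather than from a hand-written filter.
#' Intensities are `nu * S * exp(-E_lower h / k T)` normalised to the
#' strongest line.
#'
#' @param model A [spectrum_model()].
#' @param f_min,f_max Frequency window in MHz.
#' @param J_max Highest J included.
#' @param max_dKa Enumeration cap on |dKa| (default 2 covers the strong a-
#'   and b-type branches; 0 restricts to the dKa = 0 a-type lines that
#'   dominate high-J type-II bands).
#' @param strengths If `FALSE`, skip dipole matrix elements and weight lines
#'   by degeneracy and Boltzmann factor only (fast path for band-structure
#'   scans over thousands of lines).
#' @param hyperfine If `TRUE`, attach hyperfine components from
#'   [hyperfine_pattern()] to every line (requires `model$tensors`).
#' @param min_rel_intensity Lines weaker than this fraction of the strongest
#'   line are dropped.
#' @return A data.frame of transitions: quantum labels, `frequency` (MHz),
#'   `strength` (line strength S in units of the squared dipole), `type`
#'   (`"a"`, `"b"` or `"c"`), `intensity` (relative, max 1).  With
#'   `hyperfine = TRUE` rows are duplicated per component with extra
#'   columns `F_up`, `Itot_up`, `F_lo`, `Itot_lo`, `offset`,
#'   `rel_intensity`, and `frequency` includes the offset.
#' @export
#' @examples
#' rc <- rotational_constants(5780.375, 2733.504, 1857.675, "0+")
#' m <- spectrum_model(rc, mu = c(0.166, 0.86, 0), temperature = 1)
#' head(predict_spectrum(m, 4000, 20000, J_max = 3))
predict_spectrum <- function(model, f_min, f_max, J_max, max_dKa = 2,
                             strengths = TRUE, hyperfine = FALSE,
                             min_rel_intensity = 0) {
  stopifnot(inherits(model, "spectrum_model"))
  if (f_min >= f_max) stop("f_min must be below f_max")
  empty <- data.frame(J_up = integer(), Ka_up = integer(), Kc_up = integer(),
                      J_lo = integer(), Ka_lo = integer(), Kc_lo = integer(),
                      frequency = numeric(), strength = numeric(),
                      type = character(), intensity = numeric())
  if (all(model$mu == 0)) {
    warning("all dipole components are zero; no transitions predicted")
    return(empty)
  }
  st <- rotor_states(model$rc, model$dist, J_max)
  lv <- st$levels
  rows <- list()
  for (Jl in 0:J_max) {
    lo <- lv[lv$J == Jl, ]
    lo_idx <- seq_len(nrow(lo))
    for (Ju in Jl:min(Jl + 1, J_max)) {
      up <- lv[lv$J == Ju, ]
      for (i in seq_len(nrow(up))) {
        for (j in lo_idx) {
          nu <- up$energy[i] - lo$energy[j]
          if (nu <= 0 || nu < f_min || nu > f_max) next
          dKa <- abs(up$Ka[i] - lo$Ka[j])
          dKc <- abs(up$Kc[i] - lo$Kc[j])
          if (dKa > max_dKa) next
          type <- if (dKc %% 2 == 1) {
            if (dKa %% 2 == 0) "a" else "b"
          } else {
            if (dKa %% 2 == 1) "c" else next   # (even, even) is forbidden
          }
          mu_g <- model$mu[match(type, c("a", "b", "c"))]
          if (mu_g == 0) next
          S <- NA_real_
          if (strengths) {
            S <- line_strength(st, c(Ju, up$Ka[i], up$Kc[i]),
                               c(Jl, lo$Ka[j], lo$Kc[j]), model$mu)
            if (S < 1e-10) next
          }
          rows[[length(rows) + 1]] <- data.frame(
            J_up = Ju, Ka_up = up$Ka[i], Kc_up = up$Kc[i],
            J_lo = Jl, Ka_lo = lo$Ka[j], Kc_lo = lo$Kc[j],
            frequency = nu, strength = S, type = type,
            E_lo = lo$energy[j])
        }
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  boltz <- exp(-out$E_lo * H_OVER_K_MHZ / model$temperature)
  wS <- ifelse(is.na(out$strength), (2 * out$J_lo + 1), out$strength)
  out$intensity <- out$frequency * wS * boltz
  out$intensity <- out$intensity / max(out$intensity)
  out$E_lo <- NULL
  out <- out[out$intensity >= min_rel_intensity, ]
  out <- out[order(out$frequency), ]
  rownames(out) <- NULL
  if (hyperfine) {
    if (is.null(model$tensors)) stop("hyperfine = TRUE requires model$tensors")
    hf <- lapply(seq_len(nrow(out)), function(i) {
      pat <- hyperfine_pattern(st, c(out$J_up[i], out$Ka_up[i], out$Kc_up[i]),
                               c(out$J_lo[i], out$Ka_lo[i], out$Kc_lo[i]),
                               model$tensors)
      cbind(out[rep(i, nrow(pat)), ], pat, row.names = NULL)
    })
    out <- do.call(rbind, hf)
    out$frequency <- out$frequency + out$offset
    rownames(out) <- NULL
  }
  out
}

#' Line strength of one rotational transition
#'
#' Squared reduced dipole matrix element summed over space-fixed components
#' and degeneracies, in units of the squared dipole moment; the conventional
#' normalisation gives S = mu_a^2 for the 1_01 <- 0_00 a-type line.
#'
#' @param states A [rotor_states()] object.
#' @param upper,lower `c(J, Ka, Kc)` labels.
#' @param mu Length-3 dipole vector (Debye).
#' @return Numeric line strength.
#' @export
line_strength <- function(states, upper, lower, mu) {
  Ju <- upper[1]; Jl <- lower[1]
  if (abs(Ju - Jl) > 1) return(0)
  cu <- level_vector(states, Ju, upper[2], upper[3])
  cl <- level_vector(states, Jl, lower[2], lower[3])
  ks <- -Jl:Jl
  # molecule-frame spherical dipole: T0 = mu_a, T+-1 = (-mu_b - i mu_c)/sqrt2 etc.
  Tq <- list(`-1` = complex(real = mu[2], imaginary = -mu[3]) / sqrt(2),
             `0` = complex(real = mu[1]),
             `1` = complex(real = -mu[2], imaginary = -mu[3]) / sqrt(2))
  G <- 0 + 0i
  for (q in -1:1) {
    if (Tq[[as.character(q)]] == 0) next
    kq <- ks + q
    ok <- abs(kq) <= Ju
    if (!any(ok)) next
    cg <- cg_dipole(Jl, ks[ok], q, Ju)
    G <- G + Tq[[as.character(q)]] * sum(cu[kq[ok] + Ju + 1] * cl[ok] * cg)
  }
  (2 * Jl + 1) * Mod(G)^2
}

#' Spacing of high-J type-II bands
#'
#' In near-planar asymmetric tops the high-J R-branch transitions pile up
#' into characteristic clumps ("type-II bands") whose spacing approaches
#' twice the smallest rotational constant, 2C.  This detector builds an
#' intensity-weighted kernel density of the line frequencies, locates the
#' band centres as local maxima, and returns the mean spacing between
#' successive bands.
#'
#' @param transitions A data.frame from [predict_spectrum()] with columns
#'   `frequency` (MHz) and `intensity`.
#' @param bw Gaussian kernel bandwidth in MHz (default 120, a fraction of a
#'   typical band width).
#' @param grid_step Evaluation grid step in MHz.
#' @param min_rel_height Peaks below this fraction of the tallest peak are
#'   ignored.
#' @return Mean band spacing in MHz, with the detected band centres in
#'   attribute `"band_centers"`.
#' @export
type2_band_spacing <- function(transitions, bw = 120, grid_step = 10,
                               min_rel_height = 0.25) {
  stopifnot(is.data.frame(transitions), nrow(transitions) > 0)
  f <- transitions$frequency
  w <- transitions$intensity
  grid <- seq(min(f) - 3 * bw, max(f) + 3 * bw, by = grid_step)
  dens <- vapply(grid, function(g) sum(w * exp(-0.5 * ((f - g) / bw)^2)),
                 numeric(1))
  n <- length(dens)
  is_peak <- c(FALSE, dens[2:(n - 1)] > dens[1:(n - 2)] &
                 dens[2:(n - 1)] >= dens[3:n], FALSE)
  is_peak <- is_peak & dens >= min_rel_height * max(dens)
  centers <- grid[is_peak]
  heights <- dens[is_peak]
  # suppress satellite maxima: greedily keep the tallest peaks that are at
  # least 5 bandwidths apart
  keep <- numeric(0)
  for (i in order(-heights)) {
    if (all(abs(centers[i] - keep) >= 5 * bw)) keep <- c(keep, centers[i])
  }
  centers <- sort(keep)
  # refine each centre as the local intensity-weighted mean within +-3 bw
  centers <- vapply(centers, function(cc) {
    sel <- abs(f - cc) < 3 * bw
    sum(f[sel] * w[sel]) / sum(w[sel])
  }, numeric(1))
  if (length(centers) < 2) {
    stop("fewer than two type-II bands detected in the window")
  }
  structure(mean(diff(centers)), band_centers = centers)
}
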