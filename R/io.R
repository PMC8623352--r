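#' Read spectroscopic constants from a YAML config
#'
#' The config mirrors the conventional table layout: rotational constants
#' in MHz, quartic distortion constants in kHz, the sextic `HK` in Hz, and
#' hyperfine blocks holding the direct parameters of fit
#' `chi32aa = (3/2) chi_aa` and `bbcc4 = (chi_bb - chi_cc)/4` (MHz) plus an
#' optional `chi_ab`.
#'
#' ```yaml
#' species: AMP
#' states:
#'   "0+":
#'     A: 5780.37487
#'     B: 2733.50446
#'     C: 1857.675172
#'     DJ: 0.137392      # kHz
#'     HK: 0.000643      # Hz
#' hyperfine:
#'   Na: {chi32aa: 3.5854, bbcc4: 1.50413}
#'   Nr: {chi32aa: -0.0789, bbcc4: -1.15823, chi_ab: 2.92}
#' ```
#'
#' @param path Path to the YAML file.
#' @return A list with `species`, `states` (named list of lists holding a
#'   [rotational_constants()] as `rc` and a [distortion_set()] as `dist`)
#'   and `tensors` (named list of [quadrupole_tensor()], possibly empty).
#' @export
read_constants <- function(path) {
  y <- yaml::read_yaml(path)
  states <- lapply(names(y$states), function(nm) {
    s <- y$states[[nm]]
    num <- function(k) if (is.null(s[[k]])) 0 else as.numeric(s[[k]])
    list(rc = rotational_constants(num("A"), num("B"), num("C"), nm),
         dist = distortion_set(num("DJ"), num("DJK"), num("DK"),
                               num("dJ"), num("dK"), num("HK")))
  })
  names(states) <- names(y$states)
  tensors <- list()
  if (!is.null(y$hyperfine)) {
    tensors <- lapply(names(y$hyperfine), function(nm) {
      h <- y$hyperfine[[nm]]
      tensor_from_fit_params(as.numeric(h$chi32aa), as.numeric(h$bbcc4),
                             chi_ab = if (is.null(h$chi_ab)) 0
                                      else as.numeric(h$chi_ab),
                             nucleus = nm)
    })
    names(tensors) <- names(y$hyperfine)
  }
  list(species = y$species, states = states, tensors = tensors,
       extra = y$extra)
}

#' @param species Species tag written to the file.
#' @param states Named list of `list(rc =, dist =)` pairs.
#' @param tensors Named list of [quadrupole_tensor()] (optional).
#' @rdname read_constants
#' @export
write_constants <- function(path, species, states, tensors = list()) {
  y <- list(species = species, states = lapply(states, function(s) {
    list(A = s$rc$A, B = s$rc$B, C = s$rc$C,
         DJ = s$dist$DJ, DJK = s$dist$DJK, DK = s$dist$DK,
         dJ = s$dist$dJ, dK = s$dist$dK, HK = s$dist$HK)
  }))
  if (length(tensors) > 0) {
    y$hyperfine <- lapply(tensors, function(t) {
      fp <- fit_params_from_tensor(t)
      list(chi32aa = fp$three_halves_chi_aa, bbcc4 = fp$quarter_bb_minus_cc,
           chi_ab = fp$chi_ab)
    })
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read / write measured line lists (lin-style columnar text)
#'
#' Strict whitespace-separated format with a mandatory header naming the
#' columns; quantum numbers first, then frequency (MHz), uncertainty
#' (MHz), source tag and blend id.  Missing hyperfine labels are written
#' as `NA`.  Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return `read_linelist()` returns the line data.frame.
#' @export
read_linelist <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("J_up", "Ka_up", "Kc_up", "J_lo", "Ka_lo", "Kc_lo",
            "frequency", "uncertainty")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("line list is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(df$uncertainty <= 0)) stop("line uncertainties must be positive")
  df
}

#' @param lines Line data.frame to write.
#' @rdname read_linelist
#' @export
write_linelist <- function(lines, path) {
  utils::write.table(format(lines, digits = 12), path, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a prediction in JPL-catalog-style columns
#'
#' Fixed-width text with frequency (MHz), base-10 log of relative
#' intensity, and the quantum numbers of both states (J Ka Kc and, when
#' present, Itot F).
#'
#' @param transitions Data.frame from [predict_spectrum()].
#' @param path Output path.
#' @export
write_cat <- function(transitions, path) {
  hf <- "F_up" %in% names(transitions)
  lines <- vapply(seq_len(nrow(transitions)), function(i) {
    t <- transitions[i, ]
    qn_up <- sprintf("%3d%3d%3d", t$J_up, t$Ka_up, t$Kc_up)
    qn_lo <- sprintf("%3d%3d%3d", t$J_lo, t$Ka_lo, t$Kc_lo)
    if (hf) {
      qn_up <- paste0(qn_up, sprintf("%3d%3d", t$Itot_up, t$F_up))
      qn_lo <- paste0(qn_lo, sprintf("%3d%3d", t$Itot_lo, t$F_lo))
    }
    sprintf("%13.4f %8.4f  %s  %s", t$frequency,
            log10(max(t$intensity, 1e-30)), qn_up, qn_lo)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Path to a packaged reference data file
#'
#' @param name File name under the package's `extdata` directory; empty to
#'   list available files.
#' @return Full file path.
#' @export
rotspec_example <- function(name = "") {
  if (name == "") {
    dir(system.file("extdata", package = "rotspec"))
  } else {
    system.file("extdata", name, package = "rotspec", mustWork = TRUE)
  }
}
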