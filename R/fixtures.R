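# Default geometry fixture and deterministic test-support generators.
#
# The shipped cross-section is a schematic digitization of a guinea-pig
# apical organ of Corti: landmark proportions follow published micrographs
# (20 um scale bar) and morphometric anchors (BM inclined 37.26 degrees to
# the reticular lamina), and the remaining digitization freedom is
# calibrated so that the model's emergent quantities (critical Deiters'
# extensibility, operating-point gains, Hensen radial-sign boundary) match
# the values the model is known to produce for this organ. The fixture is
# static data; see inst/extdata/default_geometry.yaml.

the <- new.env(parent = emptyenv())

#' Default guinea-pig apex geometry config
#'
#' @return the geometry config list shipped with the package (units um),
#'   including digitization metadata (`metadata$digitization_ranges`, the
#'   scale-bar-consistent length ranges the coordinates were read from).
#' @export
default_fixture <- function() {
  path <- system.file("extdata", "default_geometry.yaml", package = "cortikin")
  if (!nzchar(path)) stop("default geometry fixture not found", call. = FALSE)
  yaml::read_yaml(path)
}

#' Default built geometry (cached)
#'
#' @return an `oc_geometry` built from [default_fixture()].
#' @export
default_geometry <- function() {
  if (is.null(the$default_geometry)) {
    the$default_geometry <- build_reference_geometry(default_fixture())
  }
  the$default_geometry
}

#' Seeded perturbed geometry fixtures
#'
#' Generates randomly perturbed copies of a preset geometry for robustness
#' testing. Landmark positions and lengths are perturbed by a fractional
#' magnitude (relative to the OHC resting length for positions); the
#' Hensen control polygon is carried along by an anchor/apex-matching blend
#' plus a small interior jitter. Draws that violate the geometry invariants
#' (including a simple, non-crossing contour) are resampled with bounded
#' retries. Generation is reproducible: all randomness flows through the
#' seed recorded in the result.
#'
#' @param spec a fixture spec: list with `preset` ("default"), `seed`,
#'   `magnitude` (fractional, <= 0.1) and `n` (number of fixtures).
#' @return list of `n` geometry configs; attributes `seed` and `magnitude`.
#' @export
perturbed_fixtures <- function(spec = list(preset = "default", seed = 1L,
                                           magnitude = 0.05, n = 20L)) {
  stopifnot(spec$magnitude <= 0.1, spec$magnitude >= 0)
  base <- switch(spec$preset %||% "default",
                 default = default_fixture(),
                 stop("unknown preset: ", spec$preset, call. = FALSE))
  n <- spec$n %||% 20L

  rng <- local_rng(spec$seed %||% 1L)
  on.exit(rng(), add = TRUE)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- NULL
    for (try in 1:60) {
      cand <- perturb_config(base, spec$magnitude)
      ok <- tryCatch({ build_reference_geometry(cand); TRUE },
                     error = function(e) FALSE)
      if (ok) { cfg <- cand; break }
    }
    if (is.null(cfg)) {
      stop("could not generate an invariant-preserving perturbation after 60 tries",
           call. = FALSE)
    }
    out[[i]] <- cfg
  }
  structure(out, seed = spec$seed %||% 1L, magnitude = spec$magnitude)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# save/restore the global RNG state around seeded generation
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

perturb_config <- function(cfg, magnitude) {
  cfg <- canonical_config(cfg)
  if (magnitude == 0) return(cfg)
  L <- cfg$l_ohc
  jitter_pt <- function(p, m = magnitude) p + m * L * runif(2L, -1, 1)

  old_anchor <- cfg$hensen_control_points[1L, ]
  old_apex <- cfg$hensen_control_points[nrow(cfg$hensen_control_points), ]

  cfg$pivot_rl <- jitter_pt(cfg$pivot_rl)
  cfg$dc_anchor <- c(cfg$dc_anchor[1L] + magnitude * L * runif(1L, -1, 1),
                     cfg$dc_anchor[2L])
  cfg$outer_pillar_foot <- c(cfg$outer_pillar_foot[1L] + magnitude * L * runif(1L, -1, 1),
                             cfg$outer_pillar_foot[2L])
  cfg$l_rl <- cfg$l_rl * (1 + magnitude * runif(1L, -1, 1))
  cfg$l_ohc <- cfg$l_ohc * (1 + magnitude * runif(1L, -1, 1))
  cfg$phi0 <- cfg$phi0 * (1 + magnitude * runif(1L, -1, 1))
  cfg$ohc_tilt_deg <- cfg$ohc_tilt_deg + 10 * magnitude * runif(1L, -1, 1)

  # recompute the apex implied by the perturbed pivot/arm and carry the
  # control polygon along by an endpoint-matching blend
  th <- cfg$rl_bm_angle_deg * pi / 180
  theta_bm <- atan2(cfg$bm_axis[2L], cfg$bm_axis[1L])
  new_apex <- cfg$pivot_rl + cfg$l_rl * c(cos(theta_bm + th), sin(theta_bm + th))
  new_anchor <- c(old_anchor[1L] + magnitude * L * runif(1L, -1, 1), old_anchor[2L])

  cp <- cfg$hensen_control_points
  w <- seq(0, 1, length.out = nrow(cp))
  shift <- outer(1 - w, new_anchor - old_anchor) + outer(w, new_apex - old_apex)
  jit <- 0.3 * magnitude * L * matrix(runif(2L * nrow(cp), -1, 1), ncol = 2L)
  jit[c(1L, nrow(cp)), ] <- 0
  cfg$hensen_control_points <- cp + shift + jit
  cfg$hensen_coeffs <- bezier_to_poly(cfg$hensen_control_points)
  cfg
}
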