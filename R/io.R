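#' Build a direct-coexistence slab configuration
#'
#' Random packing of N particles into a central liquid slab at the target
#' density, vacuum elsewhere, in a box with lateral edges
#' \eqn{L_x = L_y = 3 r_c} and \eqn{L_z} set so the overall density matches
#' `overall_density` (conventionally chosen near the critical density so the
#' state point sits inside the two-phase region).  Insertion uses a soft
#' minimum-separation floor and is deterministic given the seed.
#'
#' @param n_particles number of particles
#' @param liquid_density target slab density, nm^-3
#' @param r_c local-density cutoff, nm (sets the lateral box rule)
#' @param overall_density target overall density N/V, nm^-3; must be below
#'   `liquid_density`
#' @param seed integer RNG seed
#' @param min_separation soft floor on pair distances inside the slab, nm
#' @param lateral_multiple lateral box rule multiplier (default 3)
#' @return a [configuration()]; attribute `slab_bounds` holds the z-interval
#'   of the initial liquid region
#' @export
build_slab_configuration <- function(n_particles, liquid_density, r_c,
                                     overall_density, seed = 1L,
                                     min_separation = 0.05,
                                     lateral_multiple = 3) {
  if (liquid_density <= 0 || overall_density <= 0) {
    stop("densities must be positive")
  }
  if (overall_density >= liquid_density) {
    stop("overall density must be below the liquid density (two-phase region)")
  }
  L_lat <- lateral_multiple * r_c
  L_z <- n_particles / (overall_density * L_lat^2)
  slab_thickness <- n_particles / (liquid_density * L_lat^2)
  if (slab_thickness >= L_z) stop("infeasible: slab thicker than the box")
  if (L_z < 2 * r_c) stop("box too short along z for the requested cutoff")
  z_lo <- (L_z - slab_thickness) / 2
  z_hi <- z_lo + slab_thickness

  set.seed(seed)
  pos <- matrix(NA_real_, n_particles, 3)
  n_placed <- 0
  max_tries <- 200L * n_particles
  tries <- 0
  min2 <- min_separation^2
  while (n_placed < n_particles && tries < max_tries) {
    tries <- tries + 1
    cand <- c(stats::runif(2, 0, L_lat), stats::runif(1, z_lo, z_hi))
    ok <- TRUE
    if (n_placed > 0 && min_separation > 0) {
      d <- sweep(pos[seq_len(n_placed), , drop = FALSE], 2, cand, `-`)
      box <- c(L_lat, L_lat, L_z)
      d <- d - sweep(round(sweep(d, 2, box, `/`)), 2, box, `*`)
      ok <- min(rowSums(d^2)) > min2
    }
    if (ok) {
      n_placed <- n_placed + 1
      pos[n_placed, ] <- cand
    }
  }
  if (n_placed < n_particles) {
    stop("could not place all particles; lower min_separation or density")
  }
  out <- configuration(pos, c(L_lat, L_lat, L_z))
  attr(out, "slab_bounds") <- c(z_lo, z_hi)
  out
}

#' Build a homogeneous bulk configuration
#'
#' Jittered simple-cubic lattice at the requested density in a cubic box.
#' A lattice start keeps the initial local densities close to the bulk value,
#' which matters for free-energy backends with a finite density domain.
#'
#' @param n_particles number of particles (rounded up to the next cube for
#'   lattice placement; exactly `n_particles` sites are kept)
#' @param rho target number density, nm^-3
#' @param seed integer RNG seed for the jitter
#' @param jitter uniform displacement amplitude as a fraction of the lattice
#'   spacing
#' @return a [configuration()]
#' @export
build_bulk_configuration <- function(n_particles, rho, seed = 1L,
                                     jitter = 0.2) {
  if (rho <= 0) stop("rho must be positive")
  L <- (n_particles / rho)^(1 / 3)
  m <- ceiling(n_particles^(1 / 3))
  sp <- L / m
  g <- (seq_len(m) - 0.5) * sp
  lat <- as.matrix(expand.grid(x = g, y = g, z = g))[seq_len(n_particles), ]
  set.seed(seed)
  pos <- lat + matrix(stats::runif(3 * n_particles, -jitter * sp,
                                   jitter * sp), ncol = 3)
  configuration(pos, rep(L, 3))
}

#' Read and write XYZ configuration files
#'
#' Multi-frame XYZ with the box carried on the comment line as
#' `"Lx Ly Lz"` in nm.  Coordinates are written with 9 decimal digits, so a
#' write/read round trip is exact at that precision.
#'
#' @param path file path
#' @param frames a [configuration()] or list of configurations
#' @param element atom label written in column 1
#' @return `read_xyz` returns a list of [configuration()] frames;
#'   `write_xyz` returns `path` invisibly
#' @export
write_xyz <- function(path, frames, element = "W") {
  if (inherits(frames, "configuration")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    stopifnot(inherits(f, "configuration"))
    writeLines(as.character(nrow(f$positions)), con)
    writeLines(sprintf("%.9f %.9f %.9f", f$box[1], f$box[2], f$box[3]), con)
    writeLines(sprintf("%s %.9f %.9f %.9f", element,
                       f$positions[, 1], f$positions[, 2], f$positions[, 3]),
               con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty XYZ file: ", path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i])) {
      stop(sprintf("XYZ parse error at line %d: expected atom count", i))
    }
    n <- as.integer(lines[i])
    if (i + 1 > length(lines)) {
      stop(sprintf("XYZ parse error at line %d: missing box comment line", i + 1))
    }
    box <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 1]),
                                                "\\s+")[[1]]))
    if (length(box) != 3 || any(is.na(box))) {
      stop(sprintf("XYZ parse error at line %d: box line must be 'Lx Ly Lz'",
                   i + 1))
    }
    if (i + 1 + n > length(lines)) {
      stop(sprintf("XYZ parse error at line %d: truncated frame", i))
    }
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad) > 0) {
      stop(sprintf("XYZ parse error at line %d: need 'element x y z'",
                   i + 1 + bad[1]))
    }
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(is.na(coords))) stop("XYZ parse error: non-numeric coordinate")
    frames[[length(frames) + 1]] <- configuration(coords, box)
    i <- i + 2 + n
  }
  frames
}

# ---- model registry ------------------------------------------------------

registry_dir <- function() {
  system.file("extdata", "models", package = "ldpmc")
}

#' Model registry
#'
#' Named equation-of-state parameter sets shipped as JSON files under
#' `inst/extdata/models`.  `list_models()` returns the available names;
#' `load_model(name)` builds the corresponding [eos_model].  A path to a
#' user-supplied JSON file of the same schema is also accepted.
#'
#' Shipped entries: `associating` (temperature-independent Mie with a
#' four-site hydrogen-bonding term), `vle` and `ift` (temperature-dependent
#' Mie, polynomial \eqn{\epsilon(T)}, \eqn{\sigma(T)}; refit in-package, see
#' each file's `provenance` field), `vdw-water` (a van der Waals fluid with
#' water-like critical constants, used widely in the tests) and `ideal`.
#'
#' @param name registry name or path to a JSON model file
#' @return `load_model`: an [eos_model]; `list_models`: character vector
#' @export
list_models <- function() {
  sub("\\.json$", "", list.files(registry_dir(), pattern = "\\.json$"))
}

#' @rdname list_models
#' @export
load_model <- function(name) {
  path <- if (file.exists(name)) name else
    file.path(registry_dir(), paste0(name, ".json"))
  if (!file.exists(path)) {
    stop("unknown model '", name, "'; registered models: ",
         paste(list_models(), collapse = ", "))
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  assoc <- NULL
  if (!is.null(j$assoc)) {
    assoc <- association_parameters(j$assoc$epsilon_over_kB,
                                    j$assoc$bond_volume_nm3)
  }
  model <- switch(j$kind,
    ideal = eos_ideal(name = j$name),
    vdw = eos_vdw(a = j$a_K_nm3, b = j$b_nm3, name = j$name),
    mie = eos_mie(mie_parameters(j$epsilon_over_kB, j$sigma_nm,
                                 j$lambda_r, j$lambda_a),
                  assoc = assoc, name = j$name),
    mie_tdep = eos_mie_tdep(eps_coef = j$eps_coef, sigma_coef = j$sigma_coef,
                            lambda_r = j$lambda_r, lambda_a = j$lambda_a,
                            T_range = j$T_range, assoc = assoc,
                            name = j$name),
    stop("unknown model kind in ", path, ": ", j$kind))
  if (!is.null(j$kappa_coef)) {
    attr(model, "kappa_coef") <- j$kappa_coef
    attr(model, "kappa_T_range") <- j$kappa_T_range
    attr(model, "kappa_r_c_sigma") <- j$kappa_r_c_sigma
  }
  model
}

#' Square-gradient coefficient of a registered model
#'
#' Evaluates the calibrated cubic \eqn{\kappa(T)} stored alongside a registry
#' model (calibrated at a stated cutoff; \eqn{\kappa} is specific to the
#' cutoff it was calibrated with).  Errors when the model carries no
#' calibration; warns outside the calibrated window.
#'
#' @param model a registry-loaded [eos_model]
#' @param T temperature, kelvin
#' @return kappa in K nm^8
#' @export
kappa_for_model <- function(model, T) {
  cf <- attr(model, "kappa_coef")
  if (is.null(cf)) stop("model '", model$name, "' has no kappa(T) calibration")
  rng <- attr(model, "kappa_T_range")
  if (!is.null(rng) && (T < rng[1] || T > rng[2])) {
    warning(sprintf("kappa(T) evaluated outside calibrated range [%g, %g] K",
                    rng[1], rng[2]))
  }
  polyval_T(cf, T)
}

#' Read a reference property table
#'
#' CSV schema for %AAD scoring and calibration targets: columns `T_K`,
#' `property`, `value`, `units`, with `property` one of `rho_l`, `rho_v`,
#' `p_v`, `gamma`, `beta_T`.
#'
#' @param path CSV file path
#' @return a data.frame with those columns
#' @export
read_reference_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("T_K", "property", "value")
  if (!all(need %in% names(df))) {
    stop("reference table must have columns T_K, property, value (and units)")
  }
  ok <- c("rho_l", "rho_v", "p_v", "gamma", "beta_T")
  if (!all(df$property %in% ok)) {
    stop("unknown property in reference table; allowed: ",
         paste(ok, collapse = ", "))
  }
  df
}
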